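---
title: "Methods: quantifying and predicting m6A readouts"
author: "readingm6a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and predicting m6A readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readingm6a)
```

# The problem

N6-methyladenosine (m6A) is the most abundant internal mRNA modification.
Its *readout* — what actually happens to the methylated transcript — is
not fixed: the same mark can shorten a transcript's half-life, shift its
translation efficiency (TE), or change the inclusion of a cassette exon,
depending on which RNA-binding proteins (RBPs) engage the site. This
package provides the full analysis chain for that question:

1. quantify the three readouts by comparing m6A-normal cells (shControl)
   against writer-knockdown cells (shMETTL3), from count-level inputs;
2. build single-nucleotide m6A maps from GLORI-style tables or projected
   MeRIP-seq peaks;
3. encode the RBP-binding context of every methylated gene or exon into
   eleven feature sets;
4. train per-cell-type gradient-boosted classifiers that predict the
   readout category from that context, and interpret them;
5. call RBP target sites from HyperTRIBE editing matrices.

A seeded synthetic-data generator emulates every input with known ground
truth, so the whole pipeline is testable without any external download.

# Readout quantification

## mRNA half-life

Transcription is blocked with actinomycin D and RNA is sampled at 0, 1,
3 and 6 h, two replicates per point, with ERCC spike-ins added per
sample. Spike-in normalization (`ercc_normalize()`) divides each
sample's counts by its total spike-in count, which removes arbitrary
library-depth differences — in particular the deliberately ultra-deep
0 h libraries (the 0 h sample doubles as the splicing and Ribo-seq input
and is sequenced ~4x deeper). Abundance then follows first-order decay,

$$\log_2\!\left(\frac{A_t}{A_0}\,\delta\right) = -k\,t,$$

where $\delta$ is a per-time-point regulating factor correcting global
drift of the RNA:spike-in ratio. Rates are computed at $t = 3$ and
$t = 6$ h against 0 h and combined by their arithmetic mean (the source
method computes both and does not state a combination rule; the mean is
the simplest symmetric choice). The half-life is $1/k$ hours for
$k > 0$. Replicates are averaged after normalization, before the ratio —
with two replicates, per-replicate fits are unstable.

**The delta rule.** How $\delta$ is chosen is not specified by the
method's description beyond its purpose. We define, per time point,
$\delta_t = \min(1,\, 1/\mathrm{median}_g(A_t/A_0))$: if the median gene
appears to *gain* material after transcription shutoff — a physical
impossibility that indicates normalization drift — the ratio is
re-centred so the median gene is non-increasing; otherwise the data are
left untouched. A numeric override is exposed.

Genes are called `HL_down`/`HL_up` when the half-life fold change
(control over knockdown) is at or beyond 1.5-fold in either direction;
genes without a finite positive half-life in both conditions are
excluded with a reason code.

## Translation efficiency

TE per gene and replicate is the library-normalized RPF fraction over
the library-normalized mRNA fraction. The change statistic is the
difference of mean replicate-level $\log_2$ TE between conditions,
tested with a two-sample Welch t-test; calls require a 1.5-fold change
and raw $p < 0.05$ (deliberately relaxed gates, matching how such
screens are thresholded to retain enough genes; raw rather than adjusted
p is the default and is configurable). Zero counts receive a +0.5
pseudocount. This is a transparent, replicate-level substitute for
specialised differential-TE models, documented as such — it is not a
reimplementation of any published package's internal model.

## Exon inclusion

For a skipped-exon event with inclusion junction count $I$, skipping
count $S$ and effective lengths $l_I, l_S$,

$$\Psi = \frac{I/l_I}{I/l_I + S/l_S}.$$

Between conditions we pool counts, compute
$\Delta\Psi = \Psi_{ctrl} - \Psi_{kd}$, test the pooled 2x2 junction
table with a two-sided Fisher's exact test, adjust across events by
Benjamini-Hochberg, and call events with $|\Delta\Psi| \ge 0.1$ and
FDR < 0.05. The likelihood model of dedicated splicing callers is out of
scope; the pooled Fisher test is the substitute, with the effect-size
gate identical.

# m6A maps

GLORI-style single-base tables are filtered by two gates: modification
rate > 0.1 in *all* replicates (the two-replicate wording of the source
generalizes to "all" for more replicates), and exclusion of any site
also called in the knockdown cells — keyed on exact (chrom, pos,
strand), with no tolerance window, since the exclusion is stated without
one. MeRIP-seq peaks are projected to single-nucleotide resolution by
intersecting them with a user-supplied site catalogue; retained sites
must match the DRACH consensus (D=[A/G/U], R=[A/G], A, C, H=[A/C/U]) in
the strand-oriented genomic 5-mer and inherit the maximum overlapping
peak score (maximum chosen because the source is silent on multi-peak
overlap). Metagene profiles place sites on the 3-segment axis (5'UTR to
[0,1), CDS to [1,2), 3'UTR to [2,3), linear within each segment — the
axis convention is ours, as topology plots rarely define it); histogram
bins are left-closed so the start and stop codon land in the segment
they begin.

# Feature encoding

Eleven feature sets per m6A-positive gene, per RBP track where
applicable:

1. score of the nearest binding site on the genome,
2. score of the nearest binding site on the transcript,
3. minimum RBP-to-m6A genomic distance over the gene's sites,
4. minimum transcript distance,
5. maximum genomic distance,
6. maximum transcript distance,
7. site-to-gene topology (min distance to start/stop codon, mean
   metagene position, site count),
8. per-tissue expression (user-supplied gene x tissue table),
9. gene dependency score (user-supplied),
10. per-k-mer nearest transcript distance from the gene's m6A sites,
11. per-k-mer maximum occurrence count within +-100 nt of a site.

Transcript-space features live on one representative transcript per
gene: the longest annotated coding isoform, ties broken
lexicographically (the source does not state which isoform carries
transcript-coordinate features; this is flagged as an open choice, not
derived). Distances are point-to-interval: 0 inside a binding site,
otherwise nucleotides to the nearest covered base. Genomic distances
ignore strand; transcript distances are inherently stranded. k-mer
features anchor on the m6A sites (consistent with sets 3-6; anchoring on
the gene start was the alternative). The default k-mer vocabulary is the
18 DRACH 5-mers — the full 4^6 6-mer enumeration is supported but dense,
and the source does not state a vocabulary.

Missing values (no qualifying binding site, gene absent from the
expression/dependency tables) are encoded as `NA` and handled natively
by the tree model as *missing*, never as 0 — a distance of 0 means
physical overlap. Binding scores are used as-is within each track: the
model is tree-based and therefore invariant to monotone per-track
rescaling, so heterogeneous CLIP score scales do not need normalization.

Exon-level encoding anchors all RBP features on the single m6A site
closest to the exon boundary (required within 10 kb; ties toward the 5'
boundary), with no min/max aggregation, and omits the gene-level-only
sets 8-9.

# The readout classifier

One binary gradient-boosted model (XGBoost) per cell type and readout
category, evaluated by stratified 10-fold cross-validation with
out-of-fold scores. Negatives are m6A-positive units that pass encoding
but received no call in that readout layer (the natural complement given
that the model's scope is methylated genes only); no class balancing is
applied by default. Hyperparameters are fixed (depth 6, 300 rounds,
learning rate 0.1, subsample 0.8): this task family is insensitive to
tuning, and a fixed configuration keeps runs comparable. AUC is computed
in the Mann-Whitney form with ties at 1/2; sensitivity at 80%
specificity uses the conservative stepwise convention without ROC
interpolation. Every stochastic step takes a mandatory seed and is fully
reproducible.

Feature-set contributions use greedy forward selection over the eleven
sets ("heuristic search" made concrete): each selected set's gain is the
CV-AUC after minus before its addition; unselected sets are reported
with their marginal gain at termination, so the output carries both a
cumulative and a marginal column. Per-RBP importance is the maximum
XGBoost total-gain over that RBP's feature columns, averaged across fold
models.

# HyperTRIBE calling

Editing sites pass, per fusion replicate, when the editing rate lies in
[5%, 99%], is at least 1.5x the control (ADAR-alone) rate, and has at
least two mutations; the position must not be an annotated SNP. A site
is retained when it passes in all three replicates with a mean fusion
rate of at least 5% (the mean is over the fusion replicates only). Two
numerical details: a zero control rate passes the ratio gate (any
editing exceeds 1.5 x 0 — the ratio is undefined there otherwise), and
the ratio gate is evaluated by cross-multiplication of integer counts so
a site at exactly 1.5x control is not lost to floating-point rounding.
The 5-99% window applies to raw fusion rates, before any control
consideration, matching the order in which the filters are described.

# The synthetic-data generator

`sim_config()` fixes the study conditions; they are generation
parameters, not tuning knobs:

* 300 genes on one toy chromosome, alternating strands, 2-3 exons each,
  5'UTR/CDS/3'UTR of ~150/600/450 nt; DRACH 5-mers written into the
  stop-codon-proximal region with 80% of them methylated — emulating the
  stop-codon enrichment of real m6A maps.
* Decay counts: Poisson around
  `depth x gene_factor x 2^(-k t) x lib_scale`, baseline depth 200,
  lognormal gene factors (sdlog 0.5), k lognormal with median 0.2/h
  (half-life 5 h, a realistic mammalian median), two replicates, 0 h
  libraries 4x deeper, 92 time-constant ERCC rows. Planted effects:
  2-fold half-life changes in 20% (down) and 5% (up) of genes. Poisson
  rather than negative-binomial noise is the default because the decay
  fit uses ratios of means, where overdispersion mainly widens
  tolerances; NB is a config switch away for stress tests.
* TE/Psi: RPF counts Poisson around abundance x TE with 2-fold planted
  TE shifts in 10%+10% of genes; junction counts binomial with the
  inclusion probability chosen so the expected length-normalized Psi
  equals the planted truth exactly; planted Psi shifts of 0.4.
* RBP context: 20 tracks; one designated reader places a site within
  50 nt of an m6A site on every methylated gene and carries a
  high-scoring site with probability 0.95 on positive-label genes versus
  0.05 on negatives (a dominant-reader scenario: the label signal lives
  in the binding *score*, mirroring the observation that score features
  contribute the most AUC); decoys are uniform. Labels are sampled from
  the planted rule, not from running the readout callers, so model tests
  are independent of caller correctness.
* Editing matrices: negative-binomial coverage, binomial mutations,
  planted true sites clamped inside all filter gates and null rows
  clamped below the rate gate, so recovery is exact by construction
  under any seed; a separate deterministic boundary fixture probes each
  gate one at a time.

**What the generator does not emulate:** mapping ambiguity, positional
coverage biases, overdispersed biological replicate variation beyond the
count model, isoform complexity (one transcript per gene), and correlated
RBP co-binding. Passing tests therefore demonstrate correctness of the
estimators and the detectability of planted signal under clean
conditions — not performance on real libraries.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF is converted on
  read, BED round-trips bit-exactly.
* Exonic misses in coordinate conversion return `NA`, not an error;
  non-coding transcripts signal "no CDS" for codon-relative features.
* `compute_psi` is undefined (`NA`) at I = S = 0; zero-baseline genes
  are skipped from decay fits with a reason code; samples with zero
  spike-in totals abort normalization.
* Fisher p-values are clamped at 1 (guarding floating-point overshoot
  in the two-sided sum).
* Nearest-site ties break toward the higher score, then the earlier
  site, making feature tables byte-reproducible.

# Problem sizes and expected performance

The test-suite simulations use 1,000 genes for decay recovery, 10,000
units for null false-call rates, 100 random instances for encoder
oracles, and ten seeded repetitions of the ~275-unit classifier runs.
At these sizes, planted 2-fold half-life changes are recovered with
F1 ≈ 0.92-0.97, null call rates stay below 3%, classifier AUROC is
≈ 0.95 with the reader ranked first, and the largest feature-set gain
falls on the RBP binding-score sets. Two honest limitations of the
default conditions are worth stating. First, per-gene half-life
precision is bounded by counting noise: at a per-replicate baseline of
200 counts the relative standard deviation of k is ~9%, so only
~72% of genes land within 10% of their true half-life — tighter
precision needs roughly 4x the depth or replicates, not a better
estimator. Second, with two replicates and 2-fold planted TE shifts the
Welch test recovers only ~60% of planted TE changes at the relaxed
gates; this mirrors the modest power of real two-replicate Ribo-seq
designs.
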