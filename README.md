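# readingm6a

Quantify the regulatory **readouts** of N6-methyladenosine (m6A) — mRNA
half-life, translation efficiency (TE), and exon inclusion — and predict
them from the RNA-binding-protein (RBP) context of individual m6A sites.

m6A does not have one fixed consequence: depending on which reader
proteins engage a site, the same mark can destabilize a transcript,
change its translation, or shift splicing of a nearby exon. This package
implements the full analysis chain for dissecting that, for
bioinformaticians working with METTL3-perturbation experiments:

* **Readout quantification** from count-level inputs, comparing
  m6A-normal (shControl) against writer-knockdown (shMETTL3) cells:
  * half-life via ERCC spike-in anchored actinomycin D time courses and
    the first-order model `log2(A_t/A_0 · δ) = −k·t` (rates at 3 h and
    6 h, averaged; half-life `1/k`; 1.5-fold call threshold);
  * TE changes from RPF/RNA count pairs (replicate-level Welch test on
    log2 TE; 1.5-fold and p < 0.05 gates);
  * exon inclusion `Ψ = (I/lI)/(I/lI + S/lS)` with pooled Fisher tests,
    BH correction, and `|ΔΨ| ≥ 0.1`, FDR < 0.05 gates.
* **Single-nucleotide m6A maps**: GLORI-style table filtering (rate
  > 0.1 in all replicates, knockdown-background exclusion), MeRIP peak
  projection onto site catalogues, DRACH consensus validation, metagene
  topology profiles.
* **Feature encoding**: eleven feature sets per methylated gene (or
  exon) — nearest-RBP binding scores and min/max m6A-to-RBP distances in
  genomic and transcript space, site topology, tissue expression, gene
  dependency, and k-mer context.
* **Readout classifiers** ("Reading-m6A"): per-cell-type XGBoost models
  with seeded stratified 10-fold cross-validation, ROC/AUC, sensitivity
  at 80% specificity, greedy feature-set AUC-gain search, and per-RBP
  importance ranking.
* **HyperTRIBE calling**: RBP target sites from A-to-I editing matrices
  (rate in [5%, 99%], ≥ 1.5× control, ≥ 2 mutations, no SNP overlap,
  three-replicate support), proximity profiles around m6A sites, and
  Fisher overlap tests of target-gene sets.
* **Synthetic data**: a fully seeded generator that emulates every input
  (genome + GTF with planted DRACH sites, decay/TE/junction counts, RBP
  tracks with a planted reader, editing matrices) with ground truth, so
  the entire pipeline is testable offline.

## Worked example

Simulate a 100-gene study, call half-life readouts, and train the
readout classifier on the planted RBP context:

```r
library(readingm6a)

cfg   <- sim_config(seed = 42, n_genes = 100)
sim   <- gen_transcriptome(cfg)           # toy genome + m6A map
truth <- gen_ground_truth(cfg, sim)       # planted rates and labels

cm <- ercc_normalize(gen_decay_experiment(cfg, truth))
hl <- classify_halflife(fit_decay(cm, "shControl"),
                        fit_decay(cm, "shMETTL3"))
table(called = hl$call, truth = truth$hl_call[hl$gene_id])
#>          truth
#> called    HL_down HL_up none
#>   HL_down      20     0    2
#>   HL_up         0     5    3
#>   none          0     0   70
```

All 25 planted half-life changes are recovered, with 5 false calls among
70 unaffected genes — the 1.5-fold gate on a 2-replicate, depth-200
design. Now the classifier:

```r
fx <- gen_readout_features(cfg, sim)      # 20 RBP tracks, one reader
f  <- assemble_features(unique(sim$m6a$gene_id), sim$m6a, fx$tracks,
                        sim$txome, genome = sim$genome, level = "gene")
cv <- train_cv(f, fx$labels, seed = 1, nrounds = 150)
cv
#> cv_result: 91 units (46 pos), AUC 0.974, sensitivity 0.978 @ 80% specificity
head(rbp_importance(cv)$rbp_ranking, 3)
#>     rbp  importance
#> 1 RBP01 0.879753479
#> 2 RBP09 0.006275261
#> 3 RBP16 0.003938411
```

The planted reader (`RBP01`) dominates the importance ranking: its
binding scores near m6A sites carry the label signal, and the model
finds it. Target-gene overlaps use Fisher's exact test:

```r
ov <- overlap_fisher(paste0("g", 1:5), paste0("g", c(1:4, 6)),
                     paste0("g", 1:10))
sprintf("overlap p = %.4f, OR = %.1f", ov$p, ov$odds_ratio)
#> [1] "overlap p = 0.2063, OR = 16.0"
```

`run_pipeline(pipeline_config(seed = 3), "runs/demo")` executes the whole
chain end to end and writes stamped TSVs (`readout_calls.tsv`,
`cv_scores.tsv`, `importance.tsv`, ...) plus a resolved-config copy.

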