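#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators in one validated
#' list. The defaults reproduce the study conditions the pipeline is
#' designed for: actinomycin D time courses at 0/1/3/6 h with two
#' replicates and an ultra-deep 0 h library, a 1.5-fold half-life call
#' threshold with planted 2-fold effects, DRACH-anchored m6A sites near
#' stop codons, twenty RBP tracks with one planted reader whose binding
#' scores are coupled to the readout labels, and editing matrices with
#' deliberate filter-boundary cases.
#'
#' @param seed Mandatory RNG seed; recorded in every generated object.
#' @param n_genes Number of genes (default 300).
#' @param depth Mean gene-level counts per sample (default 200).
#' @param gene_sdlog Lognormal sdlog of per-gene abundance factors (0.5).
#' @param k_meanlog,k_sdlog Lognormal parameters of the baseline
#'   degradation rate in 1/h (defaults `log(0.2)`, 0.4: median half-life
#'   5 h).
#' @param frac_hl_down,frac_hl_up Fractions of genes with planted
#'   half-life down/up readouts (0.2, 0.05).
#' @param hl_effect_fc Planted half-life fold change (default 2).
#' @param times Time points in hours (0, 1, 3, 6).
#' @param n_replicates Replicates per time point/condition (default 2).
#' @param lib_scale_0h Library-depth multiplier of the 0 h samples
#'   (default 4; the ultra-deep design).
#' @param te_frac_up,te_frac_down,te_effect_fc Planted TE readout
#'   fractions and fold change (0.1, 0.1, 2).
#' @param psi_frac_up,psi_frac_down,psi_shift Planted exon-inclusion
#'   readout fractions and Psi shift (0.1, 0.1, 0.4).
#' @param junction_depth Junction reads per event and condition (200).
#' @param n_rbp Number of RBP tracks (20).
#' @param reader Name of the planted reader track (`"RBP01"`).
#' @param p_signal Probability that a positive-label gene's reader site
#'   carries a high binding score (0.95).
#' @param p_background Same probability for negative-label genes (0.05).
#' @param coupling_dist Maximum reader-site-to-m6A distance in nt (50).
#' @param m6a_rate Probability that a planted DRACH position is
#'   methylated (0.8).
#' @param utr5_len,cds_len,utr3_len Mean segment lengths (150, 600, 450).
#' @param n_editing_sites Random editing-matrix rows (300).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 300, depth = 200, gene_sdlog = 0.5,
                       k_meanlog = log(0.2), k_sdlog = 0.4,
                       frac_hl_down = 0.2, frac_hl_up = 0.05,
                       hl_effect_fc = 2,
                       times = c(0, 1, 3, 6), n_replicates = 2,
                       lib_scale_0h = 4,
                       te_frac_up = 0.1, te_frac_down = 0.1,
                       te_effect_fc = 2,
                       psi_frac_up = 0.1, psi_frac_down = 0.1,
                       psi_shift = 0.4, junction_depth = 200,
                       n_rbp = 20, reader = "RBP01",
                       p_signal = 0.95, p_background = 0.05,
                       coupling_dist = 50, m6a_rate = 0.8,
                       utr5_len = 150, cds_len = 600, utr3_len = 450,
                       n_editing_sites = 300) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1)
  cfg <- as.list(environment())
  probs <- c(frac_hl_down, frac_hl_up, te_frac_up, te_frac_down,
             psi_frac_up, psi_frac_down, p_signal, p_background, m6a_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (frac_hl_down + frac_hl_up > 1 || te_frac_up + te_frac_down > 1 ||
      psi_frac_up + psi_frac_down > 1)
    stop("planted fractions of one readout must sum to <= 1")
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

#' Generate a toy transcriptome with planted DRACH-anchored m6A sites
#'
#' Builds a single-chromosome genome of `n_genes` multi-exon coding
#' transcripts (alternating strands, non-overlapping). Each transcript
#' has a 5'UTR/CDS/3'UTR structure; DRACH 5-mers (`GGACT`) are written
#' into the stop-codon-proximal region and a fraction `m6a_rate` of them
#' is marked methylated, giving the true m6A map.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_transcriptome`: `genome` (DNAStringSet),
#'   `txome` ([transcriptome()]), `m6a` (true methylated sites,
#'   [m6a_sites()]), `drach_positions` (all planted DRACH sites incl.
#'   unmethylated ones), `seed`.
#' @export
gen_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  txs <- vector("list", n)
  site_rows <- list()
  chrom <- "chrS"
  cursor <- 100
  chrom_parts <- list(rand_dna(100))
  for (i in seq_len(n)) {
    gid <- sprintf("G%04d", i)
    tid <- sprintf("T%04d", i)
    strand <- if (i %% 2 == 0) "-" else "+"
    l5 <- round(cfg$utr5_len * stats::runif(1, 0.7, 1.3))
    lc <- round(cfg$cds_len * stats::runif(1, 0.7, 1.3) / 3) * 3
    l3 <- round(cfg$utr3_len * stats::runif(1, 0.7, 1.3))
    tlen <- l5 + lc + l3
    tseq <- rand_dna(tlen)
    # plant DRACH 5-mers in the stop-proximal window (on transcript strand)
    cds_end_t <- l5 + lc
    lo <- max(2, cds_end_t - 50)
    hi <- min(tlen - 3, cds_end_t + round(0.6 * l3))
    n_sites <- min(1 + stats::rpois(1, 1), 3)
    cand <- seq(lo, hi)
    tpos <- sort(sample(cand, n_sites))
    while (any(diff(tpos) < 6) && length(cand) > 10)  # keep motifs disjoint
      tpos <- sort(sample(cand, n_sites))
    for (p in tpos)
      substr(tseq, p - 1, p + 3) <- "GGACT"  # A at 0-based tpos
    # exon structure: 2-3 exons, introns of 100-500 nt; cuts must not
    # split a planted motif so the genomic 5-mer stays DRACH
    n_ex <- sample(2:3, 1)
    repeat {
      cuts <- sort(sample(seq(50, tlen - 50), n_ex - 1))
      if (all(vapply(cuts, function(cc) all(abs(cc - tpos) > 5), TRUE)))
        break
    }
    seg_st <- c(0, cuts); seg_en <- c(cuts, tlen)
    seg_len <- seg_en - seg_st
    introns <- round(stats::runif(n_ex - 1, 100, 500))
    tx_parts <- substring(tseq, seg_st + 1, seg_en)
    if (strand == "-") {
      # transcript runs right-to-left on the genome: the 3'-most
      # transcript segment becomes the leftmost genomic exon
      tx_parts <- rev(vapply(tx_parts, function(s)
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
        ""))
      glen <- rev(seg_len)
    } else glen <- seg_len
    ex_starts <- numeric(n_ex); ex_ends <- numeric(n_ex)
    gpos <- cursor
    gseqs <- character(0)
    for (e in seq_len(n_ex)) {
      ex_starts[e] <- gpos
      ex_ends[e] <- gpos + glen[e]
      gpos <- ex_ends[e] + if (e < n_ex) introns[e] else 0
    }
    for (e in seq_len(n_ex)) {
      gseqs <- c(gseqs, tx_parts[e])
      if (e < n_ex) gseqs <- c(gseqs, rand_dna(introns[e]))
    }
    chrom_parts[[length(chrom_parts) + 1]] <- paste(gseqs, collapse = "")
    gap <- round(stats::runif(1, 300, 800))
    chrom_parts[[length(chrom_parts) + 1]] <- rand_dna(gap)
    tx <- transcript_model(tid, gid, chrom, strand, ex_starts, ex_ends,
                           cds_start_t = l5, cds_end_t = cds_end_t)
    txs[[i]] <- tx
    gsite <- transcript_to_genome(tx, tpos)
    site_rows[[i]] <- data.frame(chrom = chrom, pos = gsite,
                                 strand = strand, gene_id = gid,
                                 methylated = stats::runif(n_sites) <
                                   cfg$m6a_rate)
    cursor <- gpos + gap
  }
  genome <- Biostrings::DNAStringSet(
    stats::setNames(paste(unlist(chrom_parts), collapse = ""), chrom))
  drach <- do.call(rbind, site_rows)
  meth <- drach[drach$methylated, , drop = FALSE]
  m6a <- m6a_sites(meth$chrom, meth$pos, meth$strand,
                   rates = cbind(stats::runif(nrow(meth), 0.3, 0.9),
                                 stats::runif(nrow(meth), 0.3, 0.9)),
                   gene_id = meth$gene_id, source = "GLORI")
  structure(list(genome = genome, txome = transcriptome(txs), m6a = m6a,
                 drach_positions = drach, seed = cfg$seed),
            class = "sim_transcriptome")
}

#' Write a simulated transcriptome to FASTA + GTF
#'
#' @param sim A `sim_transcriptome` from [gen_transcriptome()].
#' @param fasta,gtf Output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcriptome <- function(sim, fasta, gtf) {
  Biostrings::writeXStringSet(sim$genome, fasta)
  lines <- character(0)
  for (tx in sim$txome$transcripts) {
    attr_ <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id, tx$transcript_id)
    for (e in seq_along(tx$exon_starts))
      lines <- c(lines, paste(tx$chrom, "sim", "exon",
                              tx$exon_starts[e] + 1, tx$exon_ends[e], ".",
                              tx$strand, ".", attr_, sep = "\t"))
    if (is_coding(tx)) {
      cds_t <- seq(tx$cds_start_t, tx$cds_end_t - 1)
      g <- sort(transcript_to_genome(tx, cds_t))
      brk <- c(0, which(diff(g) != 1), length(g))
      for (j in seq_len(length(brk) - 1)) {
        s <- g[brk[j] + 1]; e <- g[brk[j + 1]]
        lines <- c(lines, paste(tx$chrom, "sim", "CDS", s + 1, e + 1, ".",
                                tx$strand, "0", attr_, sep = "\t"))
      }
    }
  }
  writeLines(lines, gtf)
  invisible(c(fasta = fasta, gtf = gtf))
}

#' Plant per-gene decay rates and readout truth
#'
#' @param cfg A [sim_config()].
#' @param sim Optional `sim_transcriptome` (gene ids are taken from it;
#'   otherwise `G0001..`).
#' @return List of class `sim_truth` with `genes`, `k` (gene x condition
#'   matrix of true degradation rates), `hl_call` (true readout label per
#'   gene), `te_log2fc`, `te_call`, `psi` (true Psi per condition),
#'   `psi_call`.
#' @export
gen_ground_truth <- function(cfg, sim = NULL) {
  set.seed(cfg$seed + 1)
  genes <- if (!is.null(sim)) names(sim$txome$representative)
           else sprintf("G%04d", seq_len(cfg$n_genes))
  n <- length(genes)
  k_kd <- stats::rlnorm(n, cfg$k_meanlog, cfg$k_sdlog)
  hl_call <- sample(c(rep("HL_down", round(cfg$frac_hl_down * n)),
                      rep("HL_up", round(cfg$frac_hl_up * n)),
                      rep("none", n - round(cfg$frac_hl_down * n) -
                            round(cfg$frac_hl_up * n))))
  # HL_down: control half-life shorter => control k larger
  k_ctrl <- k_kd * ifelse(hl_call == "HL_down", cfg$hl_effect_fc,
                          ifelse(hl_call == "HL_up", 1 / cfg$hl_effect_fc, 1))
  te_call <- sample(c(rep("TE_up", round(cfg$te_frac_up * n)),
                      rep("TE_down", round(cfg$te_frac_down * n)),
                      rep("none", n - round(cfg$te_frac_up * n) -
                            round(cfg$te_frac_down * n))))
  te_log2fc <- ifelse(te_call == "TE_up", log2(cfg$te_effect_fc),
                      ifelse(te_call == "TE_down", -log2(cfg$te_effect_fc), 0))
  psi_kd <- stats::runif(n, 0.25, 0.75)
  psi_call <- sample(c(rep("PSI_up", round(cfg$psi_frac_up * n)),
                       rep("PSI_down", round(cfg$psi_frac_down * n)),
                       rep("none", n - round(cfg$psi_frac_up * n) -
                             round(cfg$psi_frac_down * n))))
  psi_ctrl <- pmin(0.98, pmax(0.02,
    psi_kd + ifelse(psi_call == "PSI_up", cfg$psi_shift,
                    ifelse(psi_call == "PSI_down", -cfg$psi_shift, 0))))
  structure(list(genes = genes,
                 k = cbind(shControl = k_ctrl, shMETTL3 = k_kd),
                 hl_call = stats::setNames(hl_call, genes),
                 te_log2fc = stats::setNames(te_log2fc, genes),
                 te_call = stats::setNames(te_call, genes),
                 psi = cbind(ctrl = psi_ctrl, kd = psi_kd),
                 psi_call = stats::setNames(psi_call, genes)),
            class = "sim_truth")
}

#' Generate an actinomycin D decay time-course count matrix
#'
#' Counts are Poisson with mean
#' `depth * gene_factor * 2^(-k t) * lib_scale(t)`; 92 ERCC spike-in rows
#' have time-constant expectation scaled only by the library factor, so
#' spike-in normalization removes the depth imbalance of the ultra-deep
#' 0 h samples.
#'
#' @param cfg A [sim_config()].
#' @param truth A `sim_truth` from [gen_ground_truth()].
#' @return A [count_matrix()] covering both conditions.
#' @export
gen_decay_experiment <- function(cfg, truth) {
  set.seed(cfg$seed + 2)
  genes <- truth$genes
  gf <- stats::rlnorm(length(genes), 0, cfg$gene_sdlog)
  ercc_ids <- sprintf("ERCC-%05d", 1:92)
  ercc_mu <- stats::rlnorm(92, log(cfg$depth / 2), 0.8)
  cols <- list(); meta <- list()
  for (cond in colnames(truth$k)) {
    k <- truth$k[, cond]
    for (t in cfg$times) for (r in seq_len(cfg$n_replicates)) {
      ls <- if (t == 0) cfg$lib_scale_0h else 1
      lam <- c(cfg$depth * gf * 2^(-k * t), ercc_mu) * ls
      cols[[length(cols) + 1]] <- stats::rpois(length(lam), lam)
      meta[[length(meta) + 1]] <- data.frame(
        sample = sprintf("%s_t%g_r%d", cond, t, r),
        condition = cond, time_h = t, replicate = r)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- c(genes, ercc_ids)
  count_matrix(counts, do.call(rbind, meta))
}

#' Generate matched Ribo-seq / RNA-seq count matrices
#'
#' RNA counts are Poisson around the per-gene abundance; RPF counts are
#' Poisson around abundance x TE, with the planted TE fold changes
#' applied to the control condition.
#'
#' @param cfg A [sim_config()].
#' @param truth A `sim_truth`.
#' @param n_replicates Replicates per condition (default
#'   `cfg$n_replicates`).
#' @param depth Mean counts (default `cfg$depth`).
#' @return List with `rpf` and `rna` [count_matrix()] objects.
#' @export
gen_te_experiment <- function(cfg, truth, n_replicates = cfg$n_replicates,
                              depth = cfg$depth) {
  set.seed(cfg$seed + 3)
  genes <- truth$genes
  gf <- stats::rlnorm(length(genes), 0, cfg$gene_sdlog)
  te_base <- stats::rlnorm(length(genes), 0, 0.3)
  make <- function(kind) {
    cols <- list(); meta <- list()
    for (cond in c("shControl", "shMETTL3")) {
      te <- te_base * if (cond == "shControl") 2^truth$te_log2fc else 1
      for (r in seq_len(n_replicates)) {
        lam <- depth * gf * if (kind == "rpf") te else 1
        cols[[length(cols) + 1]] <- stats::rpois(length(lam), lam)
        meta[[length(meta) + 1]] <- data.frame(
          sample = sprintf("%s_%s_r%d", kind, cond, r),
          condition = cond, time_h = 0, replicate = r)
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- genes
    # one nominal spike-in row so the container contract holds
    counts <- rbind(counts, "ERCC-00001" = stats::rpois(ncol(counts), 1000))
    count_matrix(counts, do.call(rbind, meta))
  }
  list(rpf = make("rpf"), rna = make("rna"))
}

#' Generate an exon-event junction-count table
#'
#' Junction reads per event and condition are binomial with inclusion
#' probability `q = psi*lI / (psi*lI + (1-psi)*lS)`, so the expected
#' length-normalized Psi equals the planted truth exactly.
#'
#' @param cfg A [sim_config()].
#' @param truth A `sim_truth`.
#' @param sim Optional `sim_transcriptome` used to attach exon
#'   coordinates to events.
#' @return data.frame consumable by [classify_splicing()], one event per
#'   gene, with `exon_start`/`exon_end` when `sim` is given.
#' @export
gen_psi_experiment <- function(cfg, truth, sim = NULL) {
  set.seed(cfg$seed + 4)
  genes <- truth$genes
  lI <- 2; lS <- 1
  q <- function(psi) psi * lI / (psi * lI + (1 - psi) * lS)
  n <- cfg$junction_depth
  I_ctrl <- stats::rbinom(length(genes), n, q(truth$psi[, "ctrl"]))
  I_kd <- stats::rbinom(length(genes), n, q(truth$psi[, "kd"]))
  ev <- data.frame(event_id = paste0(genes, "_SE1"), gene_id = genes,
                   I_ctrl = I_ctrl, S_ctrl = n - I_ctrl,
                   I_kd = I_kd, S_kd = n - I_kd, lI = lI, lS = lS)
  if (!is.null(sim)) {
    ev$exon_start <- NA_real_; ev$exon_end <- NA_real_
    for (i in seq_along(genes)) {
      tx <- representative_tx(sim$txome, genes[i])
      if (is.null(tx) || length(tx$exon_starts) < 2) next
      e <- if (length(tx$exon_starts) >= 3) 2 else sample(1:2, 1)
      ev$exon_start[i] <- tx$exon_starts[e]
      ev$exon_end[i] <- tx$exon_ends[e]
    }
  }
  ev
}

#' Generate RBP tracks with a planted reader coupled to readout labels
#'
#' One designated reader track receives a binding site near an m6A site
#' of every m6A-positive gene; its binding score is drawn from a high
#' distribution with probability `p_signal` for positive-label genes and
#' `p_background` for negative ones (the planted rule). Decoy tracks get
#' uniformly placed sites with background scores. Labels are sampled
#' independently of the readout callers so model tests do not depend on
#' caller correctness.
#'
#' @param cfg A [sim_config()].
#' @param sim A `sim_transcriptome`.
#' @return List of class `sim_features`: `tracks` ([rbp_track()]),
#'   `labels` (named logical per m6A-positive gene), `reader` (track
#'   name).
#' @export
gen_readout_features <- function(cfg, sim) {
  if (cfg$p_signal < 0 || cfg$p_signal > 1) stop("p_signal must be in [0, 1]")
  set.seed(cfg$seed + 5)
  rbps <- sprintf("RBP%02d", seq_len(cfg$n_rbp))
  if (!cfg$reader %in% rbps) rbps[1] <- cfg$reader
  genes <- unique(sim$m6a$gene_id)
  labels <- stats::setNames(stats::runif(length(genes)) < 0.5, genes)
  rows <- list()
  hi_score <- function(n) stats::rgamma(n, shape = 20, rate = 2)
  lo_score <- function(n) stats::rgamma(n, shape = 4, rate = 2)
  for (g in genes) {
    tx <- representative_tx(sim$txome, g)
    span <- c(min(tx$exon_starts), max(tx$exon_ends))
    gs <- sim$m6a[sim$m6a$gene_id == g, , drop = FALSE]
    anchor <- gs$pos[sample(nrow(gs), 1)]
    off <- sample(c(-1, 1), 1) * sample(10:cfg$coupling_dist, 1)
    center <- min(max(anchor + off, span[1] + 10), span[2] - 10)
    p_hi <- if (labels[[g]]) cfg$p_signal else cfg$p_background
    sc <- if (stats::runif(1) < p_hi) hi_score(1) else lo_score(1)
    rows[[length(rows) + 1]] <- data.frame(
      rbp = cfg$reader, chrom = tx$chrom,
      start = center - 10, end = center + 10, score = sc,
      strand = tx$strand)
    for (r in setdiff(rbps, cfg$reader)) {
      pos <- sample(seq(span[1], span[2] - 20), 1)
      rows[[length(rows) + 1]] <- data.frame(
        rbp = r, chrom = tx$chrom, start = pos, end = pos + 20,
        score = lo_score(1), strand = tx$strand)
    }
  }
  tr <- do.call(rbind, rows)
  structure(list(tracks = rbp_track(tr$rbp, tr$chrom, tr$start, tr$end,
                                    tr$score, tr$strand),
                 labels = labels, reader = cfg$reader, rbps = rbps),
            class = "sim_features")
}

#' Generate a HyperTRIBE editing matrix with planted sites
#'
#' Random rows: a configurable number of true sites (rates well inside
#' the filter window, zero control editing) and null rows below the
#' thresholds. Coverage is negative binomial, mutation counts binomial,
#' clamped so that every true site clears all filter gates and every null
#' row fails the rate gate in at least one replicate -- recovery is exact
#' by construction, under any seed.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_editing`: `records` (editing matrix),
#'   `snp_mask`, `true_sites` (logical per row).
#' @export
gen_editing_data <- function(cfg) {
  set.seed(cfg$seed + 6)
  n <- cfg$n_editing_sites
  true <- stats::runif(n) < 0.3
  rate <- ifelse(true, stats::runif(n, 0.15, 0.6), stats::runif(n, 0, 0.02))
  pos <- sort(sample(1e6, n))
  covm <- matrix(stats::rnbinom(n * 3, mu = 60, size = 10) + 20, n, 3)
  mutm <- matrix(stats::rbinom(length(covm), covm, rate), n, 3)
  lo <- pmax(2, ceiling(0.06 * covm))   # true sites stay inside the window
  hi <- floor(0.9 * covm)
  nullcap <- floor(0.045 * covm)        # null rows stay below the 5% gate
  mutm <- ifelse(matrix(true, n, 3), pmin(pmax(mutm, lo), hi),
                 pmin(mutm, nullcap))
  cov_ctrl <- stats::rnbinom(n, mu = 60, size = 10) + 20
  mut_ctrl <- ifelse(true, 0L, stats::rbinom(n, cov_ctrl, 0.002))
  rec <- data.frame(chrom = "chrS", pos = pos, strand = "+",
                    gene_id = sprintf("G%04d",
                                      1 + pos %% max(1, cfg$n_genes)),
                    cov_rep1 = covm[, 1], mut_rep1 = mutm[, 1],
                    cov_rep2 = covm[, 2], mut_rep2 = mutm[, 2],
                    cov_rep3 = covm[, 3], mut_rep3 = mutm[, 3],
                    cov_ctrl = cov_ctrl, mut_ctrl = mut_ctrl)
  structure(list(records = rec,
                 snp_mask = data.frame(chrom = character(0),
                                       pos = numeric(0)),
                 true_sites = true),
            class = "sim_editing")
}

#' Deterministic editing-filter boundary fixture
#'
#' A hand-constructed editing matrix in which each failing site violates
#' exactly one filter gate (rate below 5%, rate above 99%, control ratio
#' below 1.5, a single mutation, SNP overlap, or support in only two of
#' three replicates) and each passing site clears all gates. Used to
#' check exact set equality of the editing-site caller.
#'
#' @return List with `records`, `snp_mask` and `expected_pass` (logical).
#' @export
editing_boundary_fixture <- function() {
  rec <- rbind(
    # pass: clean site, zero control editing
    data.frame(name = "pass_clean", cov = 100, mut = 10, ctrl_rate = 0),
    # pass: control edited but ratio >= 1.5 (0.30 vs 0.20)
    data.frame(name = "pass_ratio_ok", cov = 100, mut = 30, ctrl_rate = 0.2),
    # pass: exactly at the 5% lower bound with 2 mutations
    data.frame(name = "pass_lower_bound", cov = 40, mut = 2, ctrl_rate = 0),
    # fail: rate 4% < 5%
    data.frame(name = "fail_rate_low", cov = 100, mut = 4, ctrl_rate = 0),
    # fail: rate 100% > 99%
    data.frame(name = "fail_rate_high", cov = 50, mut = 50, ctrl_rate = 0),
    # fail: ratio 1.25 < 1.5 (0.50 vs 0.40)
    data.frame(name = "fail_ratio", cov = 100, mut = 50, ctrl_rate = 0.4),
    # fail: only one mutation (rate 5% kept by cov = 20)
    data.frame(name = "fail_one_mut", cov = 20, mut = 1, ctrl_rate = 0),
    # fail: SNP overlap (otherwise clean)
    data.frame(name = "fail_snp", cov = 100, mut = 20, ctrl_rate = 0))
  n <- nrow(rec)
  out <- data.frame(chrom = "chrS", pos = seq_len(n) * 1000, strand = "+",
                    name = rec$name,
                    cov_rep1 = rec$cov, mut_rep1 = rec$mut,
                    cov_rep2 = rec$cov, mut_rep2 = rec$mut,
                    cov_rep3 = rec$cov, mut_rep3 = rec$mut,
                    cov_ctrl = 100, mut_ctrl = round(100 * rec$ctrl_rate))
  # fail: passes in only 2 of 3 replicates (third replicate at 4%)
  out <- rbind(out, data.frame(
    chrom = "chrS", pos = (n + 1) * 1000, strand = "+",
    name = "fail_two_of_three",
    cov_rep1 = 100, mut_rep1 = 20, cov_rep2 = 100, mut_rep2 = 20,
    cov_rep3 = 100, mut_rep3 = 4, cov_ctrl = 100, mut_ctrl = 0))
  list(records = out,
       snp_mask = data.frame(chrom = "chrS",
                             pos = out$pos[out$name == "fail_snp"]),
       expected_pass = startsWith(out$name, "pass_"))
}
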