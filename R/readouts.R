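#' Count matrix with sample metadata
#'
#' Wraps a gene x sample count matrix together with a sample sheet.
#' ERCC spike-in rows are recognized by the row-name prefix `"ERCC-"`.
#'
#' @param counts Numeric matrix, genes in rows (row names = gene ids,
#'   spike-ins prefixed `"ERCC-"`), samples in columns.
#' @param samples data.frame with one row per column of `counts` and
#'   columns `sample`, `condition`, `time_h`, `replicate`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as row names")
  stopifnot(is.data.frame(samples),
            all(c("sample", "condition", "time_h", "replicate") %in%
                  names(samples)),
            nrow(samples) == ncol(counts))
  if (any(counts < 0)) stop("negative counts")
  colnames(counts) <- samples$sample
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes (%d ERCC) x %d samples\n",
              sum(!is_ercc(rownames(x$counts))),
              sum(is_ercc(rownames(x$counts))), ncol(x$counts)))
  invisible(x)
}

is_ercc <- function(ids) startsWith(ids, "ERCC-")

#' ERCC spike-in normalization to an absolute scale
#'
#' Divides each sample's gene counts by that sample's total ERCC spike-in
#' count (the per-sample size factor), putting all samples on a common
#' absolute scale independent of library depth. Spike-in rows are dropped
#' from the output.
#'
#' @param cm A [count_matrix()] with at least one positive-total ERCC row
#'   per sample.
#' @return A `count_matrix` of normalized abundances without ERCC rows.
#' @export
ercc_normalize <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  ercc <- is_ercc(rownames(cm$counts))
  if (!any(ercc)) stop("no ERCC spike-in rows (prefix 'ERCC-') found")
  size <- colSums(cm$counts[ercc, , drop = FALSE])
  if (any(size <= 0))
    stop("un-normalizable sample(s) with zero ERCC total: ",
         paste(cm$samples$sample[size <= 0], collapse = ", "))
  out <- sweep(cm$counts[!ercc, , drop = FALSE], 2, size, "/")
  count_matrix(out, cm$samples)
}

#' Fit first-order decay rates from an actinomycin D time course
#'
#' Models RNA abundance after transcription shutoff as
#' `A_t = A_0 * 2^(-k t)`, i.e. `log2(A_t / A_0 * delta) = -k t`, where
#' `delta` is a per-time-point regulating factor correcting global drift
#' of the RNA:spike-in ratio. Per-time-point rates are computed at 3 h and
#' 6 h against 0 h and combined by their arithmetic mean; the half-life is
#' `1/k` (hours) for `k > 0` and `Inf` otherwise.
#'
#' Replicates are averaged after normalization, before the ratio. With
#' `delta = "auto"`, delta at time t is `min(1, 1 / median(A_t/A_0))`
#' across genes, so a globally drifted ratio is re-centred while unbiased
#' data are left untouched.
#'
#' @param abs_cm A spike-in normalized [count_matrix()]
#'   (see [ercc_normalize()]).
#' @param condition Condition label to fit (matched against the sample
#'   sheet's `condition` column).
#' @param delta `"auto"`, or a numeric scalar / length-2 vector giving the
#'   regulating factor for the 3 h and 6 h ratios.
#' @return data.frame with columns `gene_id`, `condition`, `k3`, `k6`,
#'   `k`, `half_life`, `delta3`, `delta6`. Genes with `A_0 = 0` are
#'   returned with `NA` rates and `reason = "zero_baseline"`.
#' @export
fit_decay <- function(abs_cm, condition, delta = "auto") {
  stopifnot(inherits(abs_cm, "count_matrix"))
  sm <- abs_cm$samples
  sel <- sm$condition == condition
  if (!any(sel)) stop("condition not present: ", condition)
  sm <- sm[sel, , drop = FALSE]
  m <- abs_cm$counts[, sel, drop = FALSE]
  need <- c(0, 3, 6)
  if (!all(need %in% sm$time_h))
    stop("condition must have samples at 0, 3 and 6 h")
  avg <- do.call(cbind, lapply(need, function(t)
    rowMeans(m[, sm$time_h == t, drop = FALSE])))
  colnames(avg) <- c("A0", "A3", "A6")
  ok <- avg[, "A0"] > 0
  ratio3 <- ifelse(ok, avg[, "A3"] / avg[, "A0"], NA_real_)
  ratio6 <- ifelse(ok, avg[, "A6"] / avg[, "A0"], NA_real_)
  if (identical(delta, "auto")) {
    d3 <- min(1, 1 / stats::median(ratio3, na.rm = TRUE))
    d6 <- min(1, 1 / stats::median(ratio6, na.rm = TRUE))
  } else {
    stopifnot(is.numeric(delta), length(delta) %in% c(1, 2), all(delta > 0))
    d3 <- delta[1]; d6 <- delta[length(delta)]
  }
  k3 <- -log2(ratio3 * d3) / 3
  k6 <- -log2(ratio6 * d6) / 6
  k <- (k3 + k6) / 2
  data.frame(gene_id = rownames(m), condition = condition,
             k3 = k3, k6 = k6, k = k,
             half_life = ifelse(!is.na(k) & k > 0, 1 / k, Inf),
             delta3 = d3, delta6 = d6,
             reason = ifelse(ok, "", "zero_baseline"),
             row.names = NULL)
}

#' Classify half-life readout calls between two conditions
#'
#' Compares per-gene half-lives between a control (normal m6A) and a
#' knockdown (disrupted m6A) condition. The fold change is
#' `half_life_control / half_life_kd`; genes at or beyond a 1.5-fold
#' change in either direction are called.
#'
#' @param dc_control,dc_kd data.frames from [fit_decay()].
#' @param fc_threshold Fold-change threshold (default 1.5).
#' @return data.frame with `gene_id`, `log2fc` (control over knockdown),
#'   `call` in `{"HL_down", "HL_up", "none"}` and `reason`. Genes lacking
#'   a finite positive half-life in either condition get `call = "none"`
#'   with `reason = "no_finite_halflife"`.
#' @export
classify_halflife <- function(dc_control, dc_kd, fc_threshold = 1.5) {
  m <- merge(dc_control[, c("gene_id", "k", "half_life")],
             dc_kd[, c("gene_id", "k", "half_life")],
             by = "gene_id", suffixes = c("_ctrl", "_kd"))
  finite <- !is.na(m$k_ctrl) & !is.na(m$k_kd) &
    m$k_ctrl > 0 & m$k_kd > 0
  fc <- ifelse(finite, m$half_life_ctrl / m$half_life_kd, NA_real_)
  call <- rep("none", nrow(m))
  call[finite & fc <= 1 / fc_threshold] <- "HL_down"
  call[finite & fc >= fc_threshold] <- "HL_up"
  data.frame(gene_id = m$gene_id, log2fc = log2(fc), call = call,
             reason = ifelse(finite, "", "no_finite_halflife"),
             row.names = NULL)
}

#' Translation-efficiency change between conditions
#'
#' Translation efficiency per gene and replicate is the library-normalized
#' ribosome-protected-fragment fraction over the library-normalized mRNA
#' fraction: `TE = (rpf_g / sum(rpf)) / (rna_g / sum(rna))`. The change is
#' the mean replicate-level `log2 TE` in the control minus the knockdown,
#' tested by a two-sample Welch t-test on replicate-level `log2 TE`.
#' Calls use a 1.5-fold change and raw `p < 0.05` gate.
#'
#' Zero counts get a +0.5 pseudocount before the ratio; genes with all-zero
#' counts in either assay are skipped. This is a transparent methodological
#' substitute for specialised differential-TE models, not a reimplementation
#' of any of them.
#'
#' @param rpf,rna [count_matrix()] objects with matching gene ids; the
#'   sample sheets must share the `condition` values in `conditions`.
#' @param conditions Length-2 character: control condition first,
#'   knockdown (background) second.
#' @param fc_threshold Fold-change gate (default 1.5).
#' @param p_threshold Raw p-value gate (default 0.05).
#' @return data.frame with `gene_id`, `log2fc`, `p`, `call` in
#'   `{"TE_up", "TE_down", "none"}`.
#' @export
te_change <- function(rpf, rna, conditions = c("shControl", "shMETTL3"),
                      fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(inherits(rpf, "count_matrix"), inherits(rna, "count_matrix"),
            length(conditions) == 2)
  genes <- intersect(rownames(rpf$counts), rownames(rna$counts))
  genes <- genes[!is_ercc(genes)]
  if (length(genes) == 0) stop("no shared genes between rpf and rna")

  log2te <- function(cond) {
    rp <- rpf$counts[genes, rpf$samples$condition == cond, drop = FALSE]
    rn <- rna$counts[genes, rna$samples$condition == cond, drop = FALSE]
    if (ncol(rp) < 2 || ncol(rn) < 2)
      stop("need >= 2 replicates per condition: ", cond)
    if (ncol(rp) != ncol(rn))
      stop("rpf and rna replicate counts differ for condition ", cond)
    rp[rp == 0] <- 0.5; rn[rn == 0] <- 0.5
    rp <- sweep(rp, 2, colSums(rp), "/")
    rn <- sweep(rn, 2, colSums(rn), "/")
    log2(rp / rn)
  }
  lc <- log2te(conditions[1]); lk <- log2te(conditions[2])
  allzero <- rowSums(rpf$counts[genes, , drop = FALSE]) == 0 |
    rowSums(rna$counts[genes, , drop = FALSE]) == 0
  fc <- rowMeans(lc) - rowMeans(lk)
  p <- vapply(seq_along(genes), function(i) {
    if (allzero[i]) return(NA_real_)
    x <- lc[i, ]; y <- lk[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y)$p.value
  }, 0)
  call <- rep("none", length(genes))
  sig <- !is.na(p) & p < p_threshold & abs(fc) >= log2(fc_threshold)
  call[sig & fc > 0] <- "TE_up"
  call[sig & fc < 0] <- "TE_down"
  out <- data.frame(gene_id = genes, log2fc = fc, p = p, call = call,
                    row.names = NULL)
  out[!allzero, , drop = FALSE]
}

#' Exon inclusion ratio (Psi)
#'
#' Length-normalized percent-spliced-in:
#' `Psi = (I/lI) / (I/lI + S/lS)`, with inclusion junction count `I`,
#' skipping junction count `S` and effective lengths `lI`, `lS`.
#'
#' @param I,S Junction counts (vectorized).
#' @param lI,lS Effective lengths (positive).
#' @return Psi in `[0,1]`; `NA` where `I + S = 0` (undefined).
#' @export
compute_psi <- function(I, S, lI = 2, lS = 1) {
  stopifnot(all(lI > 0), all(lS > 0))
  if (any(I < 0 | S < 0)) stop("negative junction counts")
  inc <- I / lI; skp <- S / lS
  ifelse(I + S == 0, NA_real_, inc / (inc + skp))
}

#' Classify exon-inclusion readout calls
#'
#' For each skipped-exon event, pools junction counts per condition,
#' computes `delta_psi = Psi(control) - Psi(kd)`, tests association with a
#' two-sided Fisher's exact test on the pooled 2x2 table
#' `[[I_ctrl, S_ctrl], [I_kd, S_kd]]`, adjusts across events by
#' Benjamini-Hochberg, and calls events with `|delta_psi| >= 0.1` and
#' `FDR < 0.05`.
#'
#' @param events data.frame with one row per event and columns `event_id`,
#'   `gene_id`, `I_ctrl`, `S_ctrl`, `I_kd`, `S_kd`, and optionally `lI`,
#'   `lS` (default 2 and 1, the junction-count convention for one shared
#'   exon-exon junction versus two inclusion junctions).
#' @param dpsi_threshold Effect-size gate (default 0.1).
#' @param fdr_threshold FDR gate (default 0.05).
#' @return The input with added `psi_ctrl`, `psi_kd`, `delta_psi`, `p`,
#'   `fdr`, `call` in `{"PSI_up", "PSI_down", "none"}`.
#' @export
classify_splicing <- function(events, dpsi_threshold = 0.1,
                              fdr_threshold = 0.05) {
  need <- c("event_id", "I_ctrl", "S_ctrl", "I_kd", "S_kd")
  stopifnot(is.data.frame(events), all(need %in% names(events)))
  if (is.null(events$lI)) events$lI <- 2
  if (is.null(events$lS)) events$lS <- 1
  events$psi_ctrl <- compute_psi(events$I_ctrl, events$S_ctrl,
                                 events$lI, events$lS)
  events$psi_kd <- compute_psi(events$I_kd, events$S_kd,
                               events$lI, events$lS)
  events$delta_psi <- events$psi_ctrl - events$psi_kd
  events$p <- vapply(seq_len(nrow(events)), function(i) {
    tab <- matrix(c(events$I_ctrl[i], events$S_ctrl[i],
                    events$I_kd[i], events$S_kd[i]), 2, byrow = TRUE)
    if (any(is.na(tab)) || sum(tab) == 0) return(NA_real_)
    min(1, stats::fisher.test(tab)$p.value)  # guard FP overshoot past 1
  }, 0)
  events$fdr <- bh_fdr(events$p)
  call <- rep("none", nrow(events))
  sig <- !is.na(events$delta_psi) & !is.na(events$fdr) &
    abs(events$delta_psi) >= dpsi_threshold & events$fdr < fdr_threshold
  call[sig & events$delta_psi > 0] <- "PSI_up"
  call[sig & events$delta_psi < 0] <- "PSI_down"
  events$call <- call
  events
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement.
#' `NA` values are passed through without contributing to the number of
#' tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
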