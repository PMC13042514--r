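#' Call RBP target sites from HyperTRIBE editing matrices
#'
#' Applies the editing-site filters to a per-position editing matrix from
#' an RBP-ADAR fusion experiment: per fusion replicate a site passes iff
#' its editing rate (mutations / coverage) lies in `[rate_min, rate_max]`,
#' is at least `control_ratio` times the control rate, and has at least
#' `min_mutations` A-to-G mutations; the position must not overlap an
#' annotated SNP. A site is retained iff it passes in all fusion
#' replicates and its mean fusion editing rate is at least `rate_min`.
#' A replicate with zero coverage fails (no division); a control rate of
#' 0 passes the ratio gate (any editing exceeds 1.5 x 0).
#'
#' @param records data.frame with `chrom`, `pos` (0-based), `strand`, and
#'   per-sample coverage/mutation columns `cov_rep1`, `mut_rep1`, ...,
#'   `cov_ctrl`, `mut_ctrl`. Optionally `gene_id`.
#' @param snp_mask Optional data.frame with `chrom`, `pos` of annotated
#'   SNP positions, or `NULL`.
#' @param rate_min,rate_max Editing-rate window (defaults 0.05, 0.99).
#' @param control_ratio Required fold over the control rate (default 1.5).
#' @param min_mutations Minimum mutation count per replicate (default 2).
#' @return List of class `editing_calls`: `sites` (retained rows with
#'   `mean_rate` added), `target_genes` (unique gene ids of retained
#'   sites, if `gene_id` present), and the thresholds used.
#' @export
call_editing_sites <- function(records, snp_mask = NULL,
                               rate_min = 0.05, rate_max = 0.99,
                               control_ratio = 1.5, min_mutations = 2) {
  cov_cols <- grep("^cov_rep", names(records), value = TRUE)
  mut_cols <- sub("^cov_", "mut_", cov_cols)
  stopifnot(length(cov_cols) >= 3, all(mut_cols %in% names(records)),
            all(c("cov_ctrl", "mut_ctrl") %in% names(records)))
  cov <- as.matrix(records[, cov_cols, drop = FALSE])
  mut <- as.matrix(records[, mut_cols, drop = FALSE])
  if (any(mut > cov)) stop("mutation count exceeds coverage")
  rate <- ifelse(cov > 0, mut / cov, NA_real_)
  # control-ratio gate cross-multiplied so a site at exactly 1.5x the
  # control rate passes without floating-point artefacts
  ratio_ok <- mut * records$cov_ctrl >=
    control_ratio * records$mut_ctrl * cov
  pass <- !is.na(rate) & rate >= rate_min & rate <= rate_max &
    mut >= min_mutations & ratio_ok
  all_pass <- rowSums(pass) == ncol(pass)
  mean_rate <- rowMeans(rate)
  is_snp <- if (is.null(snp_mask) || nrow(snp_mask) == 0) FALSE
            else paste(records$chrom, records$pos) %in%
                 paste(snp_mask$chrom, snp_mask$pos)
  keep <- all_pass & !is.na(mean_rate) & mean_rate >= rate_min & !is_snp
  sites <- records[keep, , drop = FALSE]
  sites$mean_rate <- mean_rate[keep]
  rownames(sites) <- NULL
  structure(list(
    sites = sites,
    target_genes = if (!is.null(sites$gene_id))
      sort(unique(sites$gene_id[!is.na(sites$gene_id)])) else character(0),
    thresholds = list(rate_min = rate_min, rate_max = rate_max,
                      control_ratio = control_ratio,
                      min_mutations = min_mutations)),
    class = "editing_calls")
}

#' @export
print.editing_calls <- function(x, ...) {
  cat(sprintf("editing_calls: %d sites, %d target genes\n",
              nrow(x$sites), length(x$target_genes)))
  invisible(x)
}

#' Proximity profile of editing sites around m6A sites
#'
#' Histogram of signed, strand-oriented distances from each m6A site to
#' the editing calls within `window` nt on the same chromosome (positive
#' = editing site downstream of the m6A site on its strand). When a
#' genome and transcriptome are supplied, a background profile is
#' computed around an equal-size random set of exonic, non-m6A adenosines
#' (seeded).
#'
#' @param calls An `editing_calls` object or a data.frame with `chrom`,
#'   `pos`.
#' @param m6a An [m6a_sites()] table.
#' @param window Half-width in nt (default 1000).
#' @param bins Number of bins (default 50).
#' @param genome,txome Optional, for the background profile.
#' @param seed Seed for background sampling (default 1).
#' @return List with `breaks`, `counts`, `density` and, when a background
#'   is computed, `background_density`.
#' @export
proximity_profile <- function(calls, m6a, window = 1000, bins = 50,
                              genome = NULL, txome = NULL, seed = 1) {
  edits <- if (inherits(calls, "editing_calls")) calls$sites else calls
  shared <- intersect(unique(edits$chrom), unique(m6a$chrom))
  if (length(shared) == 0) stop("no shared chromosomes between calls and m6A sites")
  signed_dists <- function(anchors) {
    out <- numeric(0)
    for (ch in unique(anchors$chrom)) {
      ep <- sort(edits$pos[edits$chrom == ch])
      if (length(ep) == 0) next
      a <- anchors[anchors$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(a))) {
        nearby <- ep[ep >= a$pos[i] - window & ep <= a$pos[i] + window]
        if (length(nearby) == 0) next
        d <- nearby - a$pos[i]
        if (!is.null(a$strand) && a$strand[i] == "-") d <- -d
        out <- c(out, d)
      }
    }
    out
  }
  d <- signed_dists(m6a)
  breaks <- seq(-window, window, length.out = bins + 1)
  h <- graphics::hist(pmin(pmax(d, -window), window), breaks = breaks,
                      plot = FALSE)
  res <- list(breaks = breaks, counts = h$counts,
              density = if (sum(h$counts) > 0)
                h$counts / sum(h$counts) / diff(breaks)[1] else h$counts)
  if (!is.null(genome) && !is.null(txome)) {
    bg <- sample_background_a_sites(genome, txome, n = nrow(m6a),
                                    exclude = m6a, seed = seed)
    db <- signed_dists(bg)
    hb <- graphics::hist(pmin(pmax(db, -window), window), breaks = breaks,
                         plot = FALSE)
    res$background_density <- if (sum(hb$counts) > 0)
      hb$counts / sum(hb$counts) / diff(breaks)[1] else hb$counts
  }
  res
}

# Random exonic adenosines (on the transcribed strand) that are not in
# `exclude`; used as a null anchor set for proximity profiles.
sample_background_a_sites <- function(genome, txome, n, exclude = NULL,
                                      seed = 1) {
  pool <- list()
  for (tid in unname(txome$representative)) {
    tx <- txome$transcripts[[tid]]
    seq <- transcript_seq(tx, genome)
    tpos <- kmer_positions(seq, "A")
    if (length(tpos) == 0) next
    gpos <- transcript_to_genome(tx, tpos)
    pool[[tid]] <- data.frame(chrom = tx$chrom, pos = gpos,
                              strand = tx$strand)
  }
  pool <- do.call(rbind, pool)
  if (!is.null(exclude))
    pool <- pool[!paste(pool$chrom, pool$pos, pool$strand) %in%
                   paste(exclude$chrom, exclude$pos, exclude$strand), ,
                 drop = FALSE]
  if (nrow(pool) == 0) stop("no background adenosines available")
  set.seed(seed)
  pool[sample(nrow(pool), min(n, nrow(pool))), , drop = FALSE]
}

#' Fisher's exact test for target-gene set overlap
#'
#' Two-sided Fisher's exact test on the 2x2 membership table of two gene
#' sets within a universe. The odds ratio is the sample (cross-product)
#' odds ratio with a Haldane 0.5 correction applied when any cell is 0.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Character vector of all considered genes.
#' @return List with `odds_ratio`, `p`, and `table` (the 2x2 matrix).
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  a <- sum(set_a %in% set_b)
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- length(universe) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c("in_a", "not_a"), c("in_b", "not_b")))
  p <- min(1, stats::fisher.test(tab, alternative = "two.sided")$p.value)
  or <- if (any(tab == 0)) ((a + .5) * (d + .5)) / ((b + .5) * (c_ + .5))
        else (a * d) / (b * c_)
  list(odds_ratio = or, p = p, table = tab)
}
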