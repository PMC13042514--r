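# Independent brute-force oracles used across the suite. These never call
# the code paths they check.

# All exonic genomic positions of a transcript in 5'->3' transcript order,
# by direct enumeration.
oracle_exonic_bases <- function(strand, exon_starts, exon_ends) {
  bases <- unlist(mapply(function(s, e) seq(s, e - 1), exon_starts,
                         exon_ends, SIMPLIFY = FALSE))
  bases <- sort(bases)
  if (strand == "-") rev(bases) else bases
}

# Random toy transcript (as argument list, not a package object).
random_tx_args <- function(max_exons = 10, max_len = 5000) {
  n_ex <- sample(seq_len(max_exons), 1)
  lens <- sample(10:max(10, max_len %/% n_ex), n_ex, replace = TRUE)
  gaps <- sample(5:200, n_ex, replace = TRUE)
  starts <- cumsum(c(sample(0:100, 1), lens[-n_ex] + gaps[-n_ex]))
  list(strand = sample(c("+", "-"), 1),
       exon_starts = starts, exon_ends = starts + lens)
}

# O(n*m) nearest interval to a point (0-based half-open intervals);
# ties resolved toward higher score then earlier row, mirroring the
# documented convention.
oracle_nearest_interval <- function(pos, starts, ends, scores) {
  if (length(starts) == 0) return(list(distance = NA_real_, score = NA_real_))
  d <- vapply(seq_along(starts), function(i) {
    if (pos >= starts[i] && pos < ends[i]) return(0)
    min(abs(pos - starts[i]), abs(pos - (ends[i] - 1)))
  }, 0)
  best <- order(d, -scores)[1]
  list(distance = d[best], score = scores[best])
}

# Pairwise-comparison AUC with ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  s / (length(pos) * length(neg))
}

# Two-sided Fisher p by full hypergeometric enumeration over tables with
# the observed margins (probability-mass ordering with the customary
# 1e-7 relative tolerance on equality).
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Sensitivity at fixed specificity by direct threshold sweep.
oracle_sens_at_spec <- function(scores, labels, spec) {
  labels <- as.logical(labels)
  best <- 0
  for (t in c(unique(scores), Inf)) {
    specificity <- mean(scores[!labels] < t)
    if (specificity >= spec)
      best <- max(best, mean(scores[labels] >= t))
  }
  best
}

# Small deterministic genome + transcript for sequence-dependent tests.
toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)
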