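#' Single-nucleotide m6A site tables
#'
#' Site tables are plain data.frames with columns `chrom`, `pos` (0-based
#' position of the methylated A), `strand`, optional per-replicate
#' modification rate columns `rate_rep1`, `rate_rep2`, ..., an optional
#' `score` (for MeRIP-derived sites), a `source` label in
#' `{"GLORI", "MeRIP"}` and optionally `gene_id`.
#'
#' @param chrom,pos,strand Site coordinates (0-based position of the A).
#' @param rates Optional matrix/data.frame of per-replicate modification
#'   rates in `[0,1]` (one row per site).
#' @param score Optional non-negative peak score.
#' @param source `"GLORI"` or `"MeRIP"`.
#' @param gene_id Optional gene assignment.
#' @return data.frame of class `m6a_sites`.
#' @export
m6a_sites <- function(chrom, pos, strand, rates = NULL, score = NULL,
                      source = "GLORI", gene_id = NA_character_) {
  stopifnot(all(strand %in% c("+", "-")), all(pos >= 0))
  df <- data.frame(chrom = chrom, pos = pos, strand = strand,
                   gene_id = gene_id, source = source, row.names = NULL)
  if (!is.null(rates)) {
    rates <- as.matrix(rates)
    if (any(rates < 0 | rates > 1, na.rm = TRUE))
      stop("modification rates must be in [0, 1]")
    colnames(rates) <- paste0("rate_rep", seq_len(ncol(rates)))
    df <- cbind(df, rates)
  }
  if (!is.null(score)) {
    if (any(score < 0, na.rm = TRUE)) stop("scores must be >= 0")
    df$score <- score
  }
  class(df) <- c("m6a_sites", "data.frame")
  df
}

site_key <- function(df) paste(df$chrom, df$pos, df$strand, sep = ":")

rate_cols <- function(df) grep("^rate_rep", names(df), value = TRUE)

#' Filter GLORI sites by replicate support and knockdown background
#'
#' Retains sites whose modification rate exceeds 0.1 in every replicate
#' and whose exact `(chrom, pos, strand)` is absent from the writer
#' knockdown site set (false-positive control). Sites with a missing
#' replicate rate are rejected.
#'
#' @param sites_ctrl Sites from the control (m6A-normal) cells, with
#'   replicate rate columns.
#' @param sites_kd Sites called in the knockdown cells (may be empty or
#'   `NULL`); only coordinates are used.
#' @param min_rate Per-replicate rate threshold (default 0.1, exclusive).
#' @return The retained subset of `sites_ctrl`.
#' @export
filter_glori <- function(sites_ctrl, sites_kd = NULL, min_rate = 0.1) {
  rc <- rate_cols(sites_ctrl)
  if (length(rc) == 0) stop("no replicate rate columns (rate_rep*) present")
  rm_ <- as.matrix(sites_ctrl[, rc, drop = FALSE])
  pass_rate <- rowSums(is.na(rm_)) == 0 & apply(rm_ > min_rate, 1, all)
  in_kd <- if (is.null(sites_kd) || nrow(sites_kd) == 0) FALSE
           else site_key(sites_ctrl) %in% site_key(sites_kd)
  out <- sites_ctrl[pass_rate & !in_kd, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DRACH motif check at single-nucleotide sites
#'
#' Tests whether the strand-oriented 5-mer centred on a site's adenosine
#' matches the m6A consensus DRACH (D = A/G/U, R = A/G, then A, C,
#' H = A/C/U; DNA T is treated as U). Sites whose 5-mer window runs off
#' the sequence end return `FALSE`.
#'
#' @param genome Named `DNAStringSet` or named character vector.
#' @param sites An [m6a_sites()] data.frame (or any data.frame with
#'   `chrom`, `pos`, `strand`).
#' @return Logical vector, one element per site.
#' @export
drach_match <- function(genome, sites) {
  vapply(seq_len(nrow(sites)), function(i) {
    chrseq <- genome_chrom(genome, sites$chrom[i])
    p <- sites$pos[i]
    if (p - 2 < 0 || p + 2 >= nchar(chrseq)) return(FALSE)
    kmer <- substr(chrseq, p - 1, p + 3)  # 1-based window [pos-2, pos+2]
    if (sites$strand[i] == "-")
      kmer <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(kmer)))
    is_drach(kmer)
  }, TRUE)
}

#' @rdname drach_match
#' @param kmer Character vector of 5-mers (DNA or RNA alphabet).
#' @export
is_drach <- function(kmer) {
  k <- chartr("Uu", "Tt", toupper(kmer))
  grepl("^[AGT][AG]AC[ACT]$", k)
}

#' Project peak-level m6A calls to single-nucleotide sites
#'
#' Intersects interval-level m6A peaks (e.g. from MeRIP-seq) with a
#' catalogue of known single-nucleotide sites; catalogue sites inside a
#' peak are retained if their 5-mer matches DRACH, inherit the maximum
#' overlapping peak score, and are re-labelled as MeRIP-derived.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `score`.
#' @param catalogue An [m6a_sites()] table with strand annotation.
#' @param genome Genome sequences for the DRACH gate.
#' @return An `m6a_sites` table with `source = "MeRIP"` and inherited
#'   `score`. An empty catalogue yields an empty result.
#' @export
peaks_to_single_nt <- function(peaks, catalogue, genome) {
  if (nrow(catalogue) == 0) return(catalogue)
  if (nrow(peaks) == 0) return(catalogue[0, , drop = FALSE])
  pk <- GenomicRanges::GRanges(peaks$chrom,
    IRanges::IRanges(peaks$start + 1, peaks$end))
  st <- GenomicRanges::GRanges(catalogue$chrom,
    IRanges::IRanges(catalogue$pos + 1, catalogue$pos + 1))
  hits <- GenomicRanges::findOverlaps(st, pk, ignore.strand = TRUE)
  if (length(hits) == 0) return(catalogue[0, , drop = FALSE])
  best <- tapply(peaks$score[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits), max)
  idx <- as.integer(names(best))
  out <- catalogue[idx, , drop = FALSE]
  out$score <- as.numeric(best)
  out$source <- "MeRIP"
  keep <- drach_match(genome, out)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Metagene profile of m6A sites
#'
#' Places each site on its gene's representative transcript, maps the
#' transcript position to the 3-segment metagene axis
#' (see [metagene_position()]) and bins the result over `[0, 3)`.
#'
#' @param sites An [m6a_sites()] table. Sites are assigned to a transcript
#'   via their `gene_id` when present, otherwise by genomic lookup.
#' @param txome A [transcriptome()].
#' @param bins Number of bins (default 100).
#' @return List with `breaks`, `density` (integrates to 1 over mapped
#'   sites), `counts`, `n_mapped` and `n_unmapped`.
#' @export
metagene_profile <- function(sites, txome, bins = 100) {
  mg <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tx <- NULL
    if (!is.null(sites$gene_id) && !is.na(sites$gene_id[i]))
      tx <- representative_tx(txome, sites$gene_id[i])
    if (is.null(tx)) {
      ids <- locate_transcripts(txome, sites$chrom[i], sites$pos[i],
                                sites$strand[i])
      ids <- ids[ids %in% unname(txome$representative)]
      if (length(ids) > 0) tx <- txome$transcripts[[ids[1]]]
    }
    if (is.null(tx) || !is_coding(tx)) next
    if (tx$strand != sites$strand[i] || tx$chrom != sites$chrom[i]) next
    tp <- genome_to_transcript(tx, sites$pos[i])
    if (is.na(tp)) next
    l5 <- tx$cds_start_t; lc <- tx$cds_end_t - tx$cds_start_t
    l3 <- tx$length - tx$cds_end_t
    if (l5 <= 0 || lc <= 0 || l3 <= 0) next
    mg[i] <- metagene_position(tx, tp)
  }
  mapped <- mg[!is.na(mg)]
  if (length(mapped) == 0) stop("empty profile: no site maps to a coding representative transcript")
  breaks <- seq(0, 3, length.out = bins + 1)
  # left-closed bins so segment boundaries (1.0, 2.0) land in their segment
  counts <- graphics::hist(mapped, breaks = breaks, plot = FALSE,
                           right = FALSE)$counts
  width <- 3 / bins
  list(breaks = breaks, counts = counts,
       density = counts / sum(counts) / width,
       n_mapped = length(mapped), n_unmapped = sum(is.na(mg)))
}

#' Read a GLORI-style site table
#'
#' Expects a TSV with columns `chrom`, `pos` (0-based), `strand` and one
#' or more `rate_rep*` columns.
#'
#' @param path TSV file path.
#' @param source Source label attached to the sites.
#' @return An [m6a_sites()] table.
#' @export
read_glori <- function(path, source = "GLORI") {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(df)))
  m6a_sites(df$chrom, df$pos, df$strand,
            rates = df[, rate_cols(df), drop = FALSE],
            gene_id = if (is.null(df$gene_id)) NA_character_ else df$gene_id,
            source = source)
}

#' Read a BED6 file into a 0-based interval data.frame
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open coordinates).
#' @export
read_bed <- function(path) {
  bed <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(bed)),
             start = GenomicRanges::start(bed) - 1,
             end = GenomicRanges::end(bed),
             name = if (is.null(bed$name)) NA_character_ else bed$name,
             score = if (is.null(bed$score)) NA_real_ else bed$score,
             strand = as.character(GenomicRanges::strand(bed)),
             row.names = NULL)
}

#' Write intervals as BED6
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns (0-based half-open).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(df$chrom, df$start, df$end,
                    if (is.null(df$name)) "." else df$name,
                    if (is.null(df$score)) 0 else df$score,
                    if (is.null(df$strand)) "." else df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
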