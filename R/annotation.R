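#' Transcript model
#'
#' A minimal exon-level model of one transcript: ordered exons in genomic
#' coordinates plus, for coding transcripts, the transcript-coordinate
#' positions of the start codon and of the stop codon (first base each).
#' All coordinates are 0-based, half-open (BED convention); GTF input is
#' converted on read.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of exon boundaries
#'   (0-based start, exclusive end), non-overlapping. They are sorted by
#'   start internally.
#' @param cds_start_t,cds_end_t Transcript-coordinate (0-based, 5'->3')
#'   positions of the first base of the start codon and of the stop codon,
#'   or `NA` for non-coding transcripts.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exon_starts, exon_ends,
                             cds_start_t = NA_integer_, cds_end_t = NA_integer_) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  o <- order(exon_starts)
  exon_starts <- as.numeric(exon_starts[o]); exon_ends <- as.numeric(exon_ends[o])
  if (any(exon_starts >= exon_ends)) stop("exon with start >= end")
  if (length(exon_starts) > 1 &&
      any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
    stop("overlapping exons")
  len <- sum(exon_ends - exon_starts)
  if (!is.na(cds_start_t)) {
    if (is.na(cds_end_t) || cds_start_t < 0 || cds_start_t >= cds_end_t ||
        cds_end_t >= len)
      stop("invalid CDS coordinates: need 0 <= cds_start_t < cds_end_t < length")
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, chrom = chrom,
    strand = strand, exon_starts = exon_starts, exon_ends = exon_ends,
    length = len,
    cds_start_t = as.numeric(cds_start_t), cds_end_t = as.numeric(cds_end_t)),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s [%d exon(s), %d nt]%s\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              length(x$exon_starts), x$length,
              if (is_coding(x)) sprintf(" CDS %d-%d", x$cds_start_t, x$cds_end_t)
              else " non-coding"))
  invisible(x)
}

#' @rdname transcript_model
#' @param tx A `transcript_model`.
#' @export
is_coding <- function(tx) !is.na(tx$cds_start_t)

#' Convert genomic positions to transcript coordinates
#'
#' Maps 0-based genomic positions to 0-based 5'->3' transcript offsets.
#' On the minus strand, transcript position 0 corresponds to the largest
#' exonic genomic coordinate. Positions falling outside every exon map to
#' `NA` (a miss, not an error).
#'
#' @param tx A [transcript_model()].
#' @param pos Integer vector of genomic positions (0-based).
#' @return Numeric vector of transcript positions, `NA` where `pos` is
#'   not exonic.
#' @export
genome_to_transcript <- function(tx, pos) {
  if (any(pos < 0, na.rm = TRUE)) stop("genomic positions must be >= 0")
  ns <- length(tx$exon_starts)
  cum <- c(0, cumsum(tx$exon_ends - tx$exon_starts))  # plus-strand offsets
  out <- rep(NA_real_, length(pos))
  idx <- findInterval(pos, tx$exon_starts)
  hit <- idx >= 1 & !is.na(pos)
  hit[hit] <- pos[hit] < tx$exon_ends[idx[hit]]
  if (any(hit)) {
    plus_off <- cum[idx[hit]] + (pos[hit] - tx$exon_starts[idx[hit]])
    out[hit] <- if (tx$strand == "+") plus_off else tx$length - 1 - plus_off
  }
  out
}

#' Convert transcript coordinates to genomic positions
#'
#' Inverse of [genome_to_transcript()].
#'
#' @param tx A [transcript_model()].
#' @param tpos Transcript positions in `[0, length)`.
#' @return Genomic 0-based positions.
#' @export
transcript_to_genome <- function(tx, tpos) {
  if (any(tpos < 0 | tpos >= tx$length, na.rm = TRUE))
    stop("transcript position out of range")
  plus_off <- if (tx$strand == "+") tpos else tx$length - 1 - tpos
  cum <- c(0, cumsum(tx$exon_ends - tx$exon_starts))
  idx <- findInterval(plus_off, cum, rightmost.closed = FALSE)
  idx[idx > length(tx$exon_starts)] <- length(tx$exon_starts)
  tx$exon_starts[idx] + (plus_off - cum[idx])
}

#' Distances from a transcript position to the start and stop codons
#'
#' @param tx A coding [transcript_model()].
#' @param tpos Transcript positions.
#' @return A data.frame with columns `dist_to_start`, `dist_to_stop`
#'   (absolute nucleotide distances).
#' @export
distance_to_codons <- function(tx, tpos) {
  if (!is_coding(tx)) stop("no CDS: transcript is non-coding")
  if (any(tpos < 0 | tpos >= tx$length)) stop("transcript position out of range")
  data.frame(dist_to_start = abs(tpos - tx$cds_start_t),
             dist_to_stop = abs(tpos - tx$cds_end_t))
}

#' Metagene position of a transcript coordinate
#'
#' Maps a transcript position onto the conventional 3-segment metagene
#' axis: 5'UTR to `[0,1)`, CDS to `[1,2)`, 3'UTR to `[2,3)`, by linear
#' scaling within each segment. The start codon maps to exactly 1 and the
#' stop codon (first base) to exactly 2.
#'
#' @param tx A coding [transcript_model()] with non-empty 5'UTR, CDS and
#'   3'UTR segments.
#' @param tpos Transcript positions.
#' @return Numeric vector in `[0, 3)`.
#' @export
metagene_position <- function(tx, tpos) {
  if (!is_coding(tx)) stop("no CDS: transcript is non-coding")
  l5 <- tx$cds_start_t
  lc <- tx$cds_end_t - tx$cds_start_t
  l3 <- tx$length - tx$cds_end_t
  if (l5 <= 0 || lc <= 0 || l3 <= 0)
    stop("degenerate segment: empty 5'UTR, CDS or 3'UTR")
  if (any(tpos < 0 | tpos >= tx$length)) stop("transcript position out of range")
  ifelse(tpos < tx$cds_start_t, tpos / l5,
    ifelse(tpos < tx$cds_end_t, 1 + (tpos - tx$cds_start_t) / lc,
      2 + (tpos - tx$cds_end_t) / l3))
}

#' Transcriptome container
#'
#' Bundles transcript models with a per-gene representative transcript
#' (the longest coding transcript, ties broken lexicographically by
#' transcript id; if a gene has no coding transcript, its longest
#' transcript) and a genomic interval index for point lookup.
#'
#' @param transcripts A list of [transcript_model()] objects.
#' @return An object of class `transcriptome` with elements `transcripts`
#'   (named list), `representative` (named character: gene id ->
#'   transcript id) and `index` (a `GRanges` of transcript spans).
#' @export
transcriptome <- function(transcripts) {
  stopifnot(length(transcripts) >= 1)
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  gene <- vapply(transcripts, `[[`, "", "gene_id")
  len <- vapply(transcripts, `[[`, 0, "length")
  coding <- vapply(transcripts, is_coding, TRUE)
  rep_tx <- vapply(split(seq_along(transcripts), gene), function(i) {
    cand <- if (any(coding[i])) i[coding[i]] else i
    cand <- cand[order(-len[cand], names(transcripts)[cand])]
    names(transcripts)[cand[1]]
  }, "")
  index <- GenomicRanges::GRanges(
    seqnames = vapply(transcripts, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(transcripts, function(t) min(t$exon_starts), 0) + 1,
      end = vapply(transcripts, function(t) max(t$exon_ends), 0)),
    strand = vapply(transcripts, `[[`, "", "strand"),
    transcript_id = names(transcripts))
  structure(list(transcripts = transcripts, representative = rep_tx,
                 index = index),
            class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("transcriptome: %d transcripts, %d genes\n",
              length(x$transcripts), length(x$representative)))
  invisible(x)
}

#' Representative transcript of a gene
#' @param txome A [transcriptome()].
#' @param gene_id Gene identifier.
#' @return A `transcript_model` or `NULL` if the gene is unknown.
#' @export
representative_tx <- function(txome, gene_id) {
  if (!gene_id %in% names(txome$representative)) return(NULL)
  txome$transcripts[[txome$representative[[gene_id]]]]
}

#' Read a transcriptome from a GTF file
#'
#' Parses an Ensembl-dialect GTF (attributes `gene_id` and `transcript_id`
#' required) into [transcript_model()] objects. Exon records define the
#' transcript structure; CDS records, when present, define the coding
#' region. The stop codon first base is taken as the transcript position
#' immediately after the last CDS base.
#'
#' @param gtf_file Path to a GTF file.
#' @return A [transcriptome()].
#' @export
read_transcriptome <- function(gtf_file) {
  g <- rtracklayer::import(gtf_file, format = "gtf")
  ex <- g[g$type == "exon"]
  if (length(ex) == 0) stop("no exon records in GTF")
  cds <- g[g$type == "CDS"]
  cds_by_tx <- split(cds, cds$transcript_id)
  txs <- lapply(split(ex, ex$transcript_id), function(e) {
    st <- GenomicRanges::start(e) - 1  # to 0-based half-open
    en <- GenomicRanges::end(e)
    strand <- as.character(GenomicRanges::strand(e))[1]
    tid <- e$transcript_id[1]
    tx <- transcript_model(tid, e$gene_id[1],
                           as.character(GenomicRanges::seqnames(e))[1],
                           strand, st, en)
    cd <- cds_by_tx[[tid]]
    if (!is.null(cd) && length(cd) > 0) {
      gmin <- min(GenomicRanges::start(cd)) - 1
      gmax <- max(GenomicRanges::end(cd)) - 1
      first <- if (strand == "+") gmin else gmax
      last <- if (strand == "+") gmax else gmin
      cs <- genome_to_transcript(tx, first)
      ce <- genome_to_transcript(tx, last) + 1  # first base of stop codon
      if (!is.na(cs) && !is.na(ce) && ce < tx$length)
        tx <- transcript_model(tid, tx$gene_id, tx$chrom, strand, st, en,
                               cds_start_t = cs, cds_end_t = ce)
    }
    tx
  })
  transcriptome(unname(txs))
}

#' Locate transcripts covering a genomic point
#'
#' @param txome A [transcriptome()].
#' @param chrom Chromosome.
#' @param pos Genomic 0-based position.
#' @param strand Optional strand filter (`"+"`, `"-"`, or `NULL` for both).
#' @return Character vector of transcript ids whose span covers the point.
#' @export
locate_transcripts <- function(txome, chrom, pos, strand = NULL) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1, pos + 1),
                              strand = if (is.null(strand)) "*" else strand)
  # unknown chromosomes are a miss, not a seqlevel warning
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, txome$index,
    ignore.strand = is.null(strand)))
  txome$index$transcript_id[S4Vectors::subjectHits(hits)]
}

#' Point-to-interval distance
#'
#' Distance in nucleotides from a point to a 0-based half-open interval:
#' 0 if the point is covered, otherwise the distance to the nearest
#' covered base.
#'
#' @param pos Point position(s).
#' @param start,end Interval boundaries (vectorized, recycled).
#' @return Numeric distances.
#' @export
point_interval_distance <- function(pos, start, end) {
  pmax(start - pos, pos - (end - 1), 0)
}

# Spliced transcript sequence (5'->3') from a genome.
# genome: named DNAStringSet or named character vector.
transcript_seq <- function(tx, genome) {
  chrseq <- genome_chrom(genome, tx$chrom)
  parts <- substring(chrseq, tx$exon_starts + 1, tx$exon_ends)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

genome_chrom <- function(genome, chrom) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    return(as.character(genome[[chrom]]))
  }
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    return(genome[[chrom]])
  }
  stop("genome must be a named DNAStringSet or character vector")
}

#' Read a genome FASTA into a named sequence set
#' @param fasta_file Path to FASTA.
#' @return A `DNAStringSet` keyed by sequence name.
#' @export
read_genome <- function(fasta_file) {
  g <- Biostrings::readDNAStringSet(fasta_file)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
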