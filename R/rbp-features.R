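#' RBP binding-site tracks
#'
#' A track is a data.frame with columns `rbp`, `chrom`, `start`, `end`
#' (0-based half-open), `score` (non-negative, technology-specific) and
#' optionally `strand`. Multiple RBPs may share one data.frame; functions
#' subset by the `rbp` column.
#'
#' @param rbp RBP name(s).
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param score Non-negative binding scores.
#' @param strand Optional strand (defaults to `"*"`).
#' @return data.frame of class `rbp_track`.
#' @export
rbp_track <- function(rbp, chrom, start, end, score, strand = "*") {
  stopifnot(all(start >= 0), all(start < end))
  if (any(score < 0, na.rm = TRUE)) stop("binding scores must be >= 0")
  df <- data.frame(rbp = rbp, chrom = chrom, start = start, end = end,
                   score = score, strand = strand, row.names = NULL)
  class(df) <- c("rbp_track", "data.frame")
  df
}

# Map a genomic interval onto transcript coordinates of tx: returns a
# matrix with columns tmin, tmax for each exon-overlapping segment, or
# NULL if the interval has no exonic overlap.
interval_to_tx_segments <- function(tx, start, end) {
  s <- pmax(tx$exon_starts, start)
  e <- pmin(tx$exon_ends, end)
  keep <- s < e
  if (!any(keep)) return(NULL)
  t1 <- genome_to_transcript(tx, s[keep])
  t2 <- genome_to_transcript(tx, e[keep] - 1)
  cbind(tmin = pmin(t1, t2), tmax = pmax(t1, t2))
}

#' Nearest RBP binding site to an anchor position
#'
#' Finds the binding site of one RBP track at minimal point-to-interval
#' distance from an anchor, in genomic or transcript coordinate space.
#' In transcript space both the anchor and the site intervals are first
#' mapped onto the gene's representative transcript via
#' [genome_to_transcript()]; sites without exonic overlap on that
#' transcript do not qualify. Genomic distances ignore strand. Ties are
#' broken toward the higher score, then the earlier site.
#'
#' @param track An [rbp_track()] subset for a single RBP (rows on other
#'   chromosomes are ignored automatically).
#' @param chrom,pos Anchor position (0-based).
#' @param space `"genome"` or `"transcript"`.
#' @param tx Representative [transcript_model()]; required for
#'   `space = "transcript"`.
#' @return List with `distance` and `score`; both `NA` when no site
#'   qualifies (missing-value sentinel).
#' @export
nearest_rbp <- function(track, chrom, pos, space = c("genome", "transcript"),
                        tx = NULL) {
  space <- match.arg(space)
  t <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(t) == 0) return(list(distance = NA_real_, score = NA_real_))
  if (space == "genome") {
    d <- point_interval_distance(pos, t$start, t$end)
    sc <- t$score
  } else {
    stopifnot(!is.null(tx))
    apos <- genome_to_transcript(tx, pos)
    if (is.na(apos)) return(list(distance = NA_real_, score = NA_real_))
    # only sites overlapping the transcript span can touch an exon
    t <- t[t$end > min(tx$exon_starts) & t$start < max(tx$exon_ends), ,
           drop = FALSE]
    d <- numeric(0); sc <- numeric(0)
    for (i in seq_len(nrow(t))) {
      seg <- interval_to_tx_segments(tx, t$start[i], t$end[i])
      if (is.null(seg)) next
      d <- c(d, min(pmax(seg[, "tmin"] - apos, apos - seg[, "tmax"], 0)))
      sc <- c(sc, t$score[i])
    }
    if (length(d) == 0) return(list(distance = NA_real_, score = NA_real_))
  }
  best <- order(d, -sc)[1]
  list(distance = d[best], score = sc[best])
}

#' Per-gene min/max of nearest-RBP distances over m6A sites
#'
#' For each m6A site of a gene, takes the distance to its nearest binding
#' site of one RBP ([nearest_rbp()]), then summarizes across sites by min
#' and max. The scores reported are those of the nearest site attached to
#' the minimizing site (used as feature sets 1 and 2).
#'
#' @param sites An [m6a_sites()] table for one gene.
#' @param track An [rbp_track()] for a single RBP.
#' @param space `"genome"` or `"transcript"`.
#' @param tx Representative transcript (for transcript space).
#' @return List with `min_distance`, `max_distance`, `nearest_score`
#'   (score at the minimizing site); all `NA` if no site/RBP pair
#'   qualifies.
#' @export
m6a_rbp_distance_summary <- function(sites, track,
                                     space = c("genome", "transcript"),
                                     tx = NULL) {
  space <- match.arg(space)
  if (nrow(sites) == 0) stop("gene has no m6A sites")
  res <- lapply(seq_len(nrow(sites)), function(i)
    nearest_rbp(track, sites$chrom[i], sites$pos[i], space, tx))
  d <- vapply(res, `[[`, 0, "distance")
  sc <- vapply(res, `[[`, 0, "score")
  ok <- !is.na(d)
  if (!any(ok))
    return(list(min_distance = NA_real_, max_distance = NA_real_,
                nearest_score = NA_real_))
  i <- which(ok)[order(d[ok], -sc[ok])[1]]
  list(min_distance = min(d[ok]), max_distance = max(d[ok]),
       nearest_score = sc[i])
}

# Overlapping-occurrence start positions (0-based) of kmer in seq.
kmer_positions <- function(seq, kmer) {
  hits <- gregexpr(paste0("(?=", kmer, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits) - 1L
}

#' k-mer environment features of a gene's m6A sites
#'
#' Two feature families on the representative transcript sequence:
#' the nearest distance from any of the gene's m6A sites to each k-mer's
#' occurrence start (overlapping scan; minimized over sites), and the
#' maximum, over sites, of the k-mer occurrence count inside a +/- `flank`
#' nt window around the site (truncated at transcript ends).
#'
#' @param genome Genome sequences.
#' @param sites [m6a_sites()] of one gene (must lie on `tx`).
#' @param tx Representative [transcript_model()].
#' @param kmers Character vector of k-mers (DNA alphabet; U is accepted).
#' @param flank Window half-width in nt (default 100).
#' @return data.frame with one row per k-mer: `kmer`, `nearest_distance`
#'   (`NA` if the k-mer is absent from the transcript), `max_flank_count`.
#' @export
kmer_features <- function(genome, sites, tx, kmers, flank = 100) {
  seq <- transcript_seq(tx, genome)
  kmers_dna <- chartr("Uu", "Tt", toupper(kmers))
  tpos <- genome_to_transcript(tx, sites$pos)
  tpos <- tpos[!is.na(tpos)]
  out <- lapply(kmers_dna, function(km) {
    occ <- kmer_positions(seq, km)
    nd <- if (length(occ) == 0 || length(tpos) == 0) NA_real_
          else min(vapply(tpos, function(p) min(abs(p - occ)), 0))
    mc <- if (length(tpos) == 0) NA_real_
          else max(vapply(tpos, function(p)
            sum(occ >= p - flank & occ <= p + flank), 0))
    data.frame(nearest_distance = nd, max_flank_count = mc)
  })
  cbind(data.frame(kmer = kmers), do.call(rbind, out))
}

#' Default k-mer vocabulary: the 18 DRACH 5-mers
#'
#' @return Character vector of the DRACH-consensus 5-mers (DNA alphabet).
#' @export
drach_kmers <- function() {
  g <- expand.grid(D = c("A", "G", "T"), R = c("A", "G"),
                   A = "A", C = "C", H = c("A", "C", "T"),
                   stringsAsFactors = FALSE)
  sort(apply(g, 1, paste, collapse = ""))
}

#' Assemble readout feature vectors
#'
#' Encodes each unit (gene, or skipped-exon event) into the eleven
#' feature sets describing its m6A RBP-binding context:
#' per-RBP nearest-site score on genome (1) and transcript (2), min
#' RBP-to-m6A distance on genome (3) and transcript (4), max distances
#' (5, 6); site-to-gene topology (7); per-tissue expression (8); gene
#' dependency score (9); per-k-mer nearest transcript distance (10) and
#' max count in the m6A flanks (11).
#'
#' Gene level: units need at least one m6A site on a coding representative
#' transcript; min/max aggregate over the gene's sites. Exon level: all
#' RBP features anchor on the single m6A site closest to the exon
#' boundary (must lie within `exon_window` of either boundary; ties go to
#' the 5' boundary), no min/max aggregation, and the gene-level-only sets
#' (8, 9) are omitted. Units failing these preconditions are excluded.
#' Missing values (no qualifying binding site, unknown gene in the
#' expression/dependency tables) are encoded as `NA`, which the
#' tree-based model treats as missing rather than zero.
#'
#' @param units Character vector of gene ids (gene level) or a data.frame
#'   of exon events with `event_id`, `gene_id`, `exon_start`, `exon_end`
#'   (exon level).
#' @param sites An [m6a_sites()] table with `gene_id` filled in.
#' @param tracks An [rbp_track()] data.frame covering all RBPs.
#' @param txome A [transcriptome()].
#' @param genome Genome sequences (for k-mer sets; `NULL` skips sets
#'   10-11).
#' @param expression Optional gene x tissue data.frame (`gene_id` column +
#'   numeric tissue columns) for set 8.
#' @param dependency Optional data.frame with `gene_id`, `dependency`
#'   for set 9.
#' @param level `"gene"` or `"exon"`.
#' @param kmers k-mer vocabulary for sets 10-11 (default the 18 DRACH
#'   5-mers; full 6-mer enumeration is possible but dense).
#' @param exon_window Maximum m6A-to-exon-boundary distance (default
#'   10000 nt).
#' @return data.frame: one row per retained unit, `unit_id` plus feature
#'   columns named `<rbp>.score_genome`, `<rbp>.score_tx`,
#'   `<rbp>.min_dist_genome`, ... `topo.*`, `expr.*`, `dep.dependency`,
#'   `kmer.<kmer>.dist`, `kmer.<kmer>.flankmax`. Carries the feature-set
#'   partition as attribute `"feature_sets"`.
#' @export
assemble_features <- function(units, sites, tracks, txome, genome = NULL,
                              expression = NULL, dependency = NULL,
                              level = c("gene", "exon"),
                              kmers = drach_kmers(),
                              exon_window = 10000) {
  level <- match.arg(level)
  rbps <- sort(unique(tracks$rbp))
  track_by_rbp <- split(tracks, tracks$rbp)

  encode_unit <- function(unit_id, gene_id, anchor_sites) {
    tx <- representative_tx(txome, gene_id)
    if (is.null(tx) || !is_coding(tx)) return(NULL)
    row <- list(unit_id = unit_id)
    for (r in rbps) {
      tr <- track_by_rbp[[r]]
      if (level == "gene") {
        sg <- m6a_rbp_distance_summary(anchor_sites, tr, "genome")
        st <- m6a_rbp_distance_summary(anchor_sites, tr, "transcript", tx)
        row[[paste0(r, ".score_genome")]] <- sg$nearest_score
        row[[paste0(r, ".score_tx")]] <- st$nearest_score
        row[[paste0(r, ".min_dist_genome")]] <- sg$min_distance
        row[[paste0(r, ".min_dist_tx")]] <- st$min_distance
        row[[paste0(r, ".max_dist_genome")]] <- sg$max_distance
        row[[paste0(r, ".max_dist_tx")]] <- st$max_distance
      } else {
        ng <- nearest_rbp(tr, anchor_sites$chrom[1], anchor_sites$pos[1],
                          "genome")
        nt <- nearest_rbp(tr, anchor_sites$chrom[1], anchor_sites$pos[1],
                          "transcript", tx)
        row[[paste0(r, ".score_genome")]] <- ng$score
        row[[paste0(r, ".score_tx")]] <- nt$score
        row[[paste0(r, ".dist_genome")]] <- ng$distance
        row[[paste0(r, ".dist_tx")]] <- nt$distance
      }
    }
    tp <- genome_to_transcript(tx, anchor_sites$pos)
    tp <- tp[!is.na(tp)]
    if (length(tp) > 0) {
      dc <- distance_to_codons(tx, tp)
      row[["topo.min_dist_start"]] <- min(dc$dist_to_start)
      row[["topo.min_dist_stop"]] <- min(dc$dist_to_stop)
      l5 <- tx$cds_start_t; lc <- tx$cds_end_t - tx$cds_start_t
      l3 <- tx$length - tx$cds_end_t
      row[["topo.mean_metagene"]] <-
        if (l5 > 0 && lc > 0 && l3 > 0) mean(metagene_position(tx, tp))
        else NA_real_
      row[["topo.n_sites"]] <- if (level == "gene") length(tp) else 1
    } else {
      row[c("topo.min_dist_start", "topo.min_dist_stop",
            "topo.mean_metagene", "topo.n_sites")] <- NA_real_
    }
    if (level == "gene") {
      if (!is.null(expression)) {
        tis <- setdiff(names(expression), "gene_id")
        m <- expression[match(gene_id, expression$gene_id), tis, drop = FALSE]
        for (t in tis) row[[paste0("expr.", t)]] <- as.numeric(m[[t]])
      }
      if (!is.null(dependency))
        row[["dep.dependency"]] <-
          dependency$dependency[match(gene_id, dependency$gene_id)]
    }
    if (!is.null(genome) && length(kmers) > 0) {
      kf <- kmer_features(genome, anchor_sites, tx, kmers)
      for (j in seq_len(nrow(kf))) {
        row[[paste0("kmer.", kf$kmer[j], ".dist")]] <- kf$nearest_distance[j]
        row[[paste0("kmer.", kf$kmer[j], ".flankmax")]] <- kf$max_flank_count[j]
      }
    }
    row
  }

  rows <- list()
  if (level == "gene") {
    for (g in units) {
      gs <- sites[!is.na(sites$gene_id) & sites$gene_id == g, , drop = FALSE]
      if (nrow(gs) == 0) next
      r <- encode_unit(g, g, gs)
      if (!is.null(r)) rows[[length(rows) + 1]] <- r
    }
  } else {
    stopifnot(is.data.frame(units),
              all(c("event_id", "gene_id", "exon_start", "exon_end") %in%
                    names(units)))
    for (i in seq_len(nrow(units))) {
      gs <- sites[!is.na(sites$gene_id) &
                    sites$gene_id == units$gene_id[i], , drop = FALSE]
      if (nrow(gs) == 0) next
      d5 <- abs(gs$pos - units$exon_start[i])
      d3 <- abs(gs$pos - (units$exon_end[i] - 1))
      d <- pmin(d5, d3)
      inside <- gs$pos >= units$exon_start[i] & gs$pos < units$exon_end[i]
      d[inside] <- 0
      if (min(d) > exon_window) next
      # ties toward the 5' boundary: prefer smaller d5 at equal d
      best <- order(d, d5)[1]
      r <- encode_unit(units$event_id[i], units$gene_id[i],
                       gs[best, , drop = FALSE])
      if (!is.null(r)) rows[[length(rows) + 1]] <- r
    }
  }
  if (length(rows) == 0)
    stop("no unit passed the feature-encoding preconditions")
  cols <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(lapply(cols, function(cn)
    unlist(lapply(rows, function(r)
      if (is.null(r[[cn]])) NA_real_ else r[[cn]]))),
    col.names = cols, stringsAsFactors = FALSE, check.names = FALSE)
  attr(df, "feature_sets") <- feature_set_partition(names(df), level)
  df
}

#' Feature-set partition of an encoded feature table
#'
#' Maps each feature column to one of the eleven feature sets (gene
#' level) or their exon-level counterparts.
#'
#' @param cols Column names of a feature table.
#' @param level `"gene"` or `"exon"`.
#' @return Named list: set label -> character vector of column names.
#' @export
feature_set_partition <- function(cols, level = "gene") {
  cols <- setdiff(cols, "unit_id")
  sets <- list(
    rbp_score_genome = grep("\\.score_genome$", cols, value = TRUE),
    rbp_score_tx = grep("\\.score_tx$", cols, value = TRUE),
    topology = grep("^topo\\.", cols, value = TRUE),
    kmer_dist = grep("^kmer\\..*\\.dist$", cols, value = TRUE),
    kmer_flank_count = grep("^kmer\\..*\\.flankmax$", cols, value = TRUE))
  if (level == "gene") {
    sets <- c(sets, list(
      rbp_min_dist_genome = grep("\\.min_dist_genome$", cols, value = TRUE),
      rbp_min_dist_tx = grep("\\.min_dist_tx$", cols, value = TRUE),
      rbp_max_dist_genome = grep("\\.max_dist_genome$", cols, value = TRUE),
      rbp_max_dist_tx = grep("\\.max_dist_tx$", cols, value = TRUE),
      expression = grep("^expr\\.", cols, value = TRUE),
      dependency = grep("^dep\\.", cols, value = TRUE)))
  } else {
    sets <- c(sets, list(
      rbp_dist_genome = grep("\\.dist_genome$", cols, value = TRUE),
      rbp_dist_tx = grep("(?<!min|max)\\.dist_tx$", cols, value = TRUE,
                         perl = TRUE)))
  }
  sets[vapply(sets, length, 0) > 0]
}

#' Cross-cell-type variability metrics
#'
#' Per gene: the coefficient of variation (sample SD over mean) of the
#' m6A-to-reader binding-site transcript distances across cell types, and
#' the standard deviation of the readout log2 fold change across cell
#' types.
#'
#' @param distances Numeric matrix/data.frame, genes x cell types, of
#'   m6A-to-reader transcript distances.
#' @param log2fc Numeric matrix/data.frame, genes x cell types, of
#'   readout log2 fold changes.
#' @return data.frame with `gene_id`, `cv_distance` (`NA` and flagged
#'   when the mean distance is 0 or fewer than 2 cell types observed) and
#'   `sd_log2fc`.
#' @export
variability_metrics <- function(distances, log2fc) {
  distances <- as.matrix(distances); log2fc <- as.matrix(log2fc)
  stopifnot(nrow(distances) == nrow(log2fc))
  cv <- apply(distances, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2 || mean(x) == 0) return(NA_real_)
    stats::sd(x) / mean(x)
  })
  sdfc <- apply(log2fc, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x)
  })
  data.frame(gene_id = rownames(distances) %||% seq_len(nrow(distances)),
             cv_distance = cv, sd_log2fc = sdfc, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
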