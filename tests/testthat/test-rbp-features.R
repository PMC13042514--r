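test_that("nearest RBP site matches the worked example and edge cases", {
  tr <- rbp_track("X", "chr1", c(950, 1100), c(960, 1110), c(5, 8))
  res <- nearest_rbp(tr, "chr1", 1000, "genome")
  # nearest covered bases are 959 (d=41) and 1100 (d=100)
  expect_equal(res$distance, 41)
  expect_equal(res$score, 5)
  inside <- nearest_rbp(tr, "chr1", 955, "genome")
  expect_equal(inside$distance, 0)
  expect_equal(inside$score, 5)
  empty <- nearest_rbp(tr[0, ], "chr1", 1000, "genome")
  expect_true(is.na(empty$distance) && is.na(empty$score))
})

test_that("nearest RBP equals brute force in both coordinate spaces", {
  set.seed(404)
  for (rep in 1:100) {
    n_sites <- sample(1:40, 1)
    starts <- sample(0:3000, n_sites)
    widths <- sample(5:50, n_sites, replace = TRUE)
    scores <- round(runif(n_sites, 0, 10), 3)
    tr <- rbp_track("X", "chr1", starts, starts + widths, scores)
    a <- random_tx_args(max_exons = 5, max_len = 2000)
    tx <- transcript_model("t", "g", "chr1", a$strand,
                           a$exon_starts, a$exon_ends)
    pos <- sample(0:3000, 1)
    # genome space
    got <- nearest_rbp(tr, "chr1", pos, "genome")
    want <- oracle_nearest_interval(pos, starts, starts + widths, scores)
    expect_identical(got$distance, want$distance)
    expect_identical(got$score, want$score)
    # transcript space: enumerate every exonic base of every site
    tpos_anchor <- genome_to_transcript(tx, pos)
    exonic <- oracle_exonic_bases(a$strand, a$exon_starts, a$exon_ends)
    got_t <- nearest_rbp(tr, "chr1", pos, "transcript", tx)
    if (is.na(tpos_anchor)) {
      expect_true(is.na(got_t$distance))
    } else {
      dists <- rep(NA_real_, n_sites)
      for (i in seq_len(n_sites)) {
        covered <- which(exonic >= starts[i] & exonic < starts[i] + widths[i])
        if (length(covered) == 0) next
        dists[i] <- min(abs((covered - 1) - tpos_anchor))
      }
      if (all(is.na(dists))) {
        expect_true(is.na(got_t$distance))
      } else {
        ok <- which(!is.na(dists))
        best <- ok[order(dists[ok], -scores[ok])[1]]
        expect_equal(got_t$distance, dists[best])
        expect_equal(got_t$score, scores[best])
      }
    }
  }
})

test_that("per-gene distance summary reduces over sites correctly", {
  tr <- rbp_track("X", "chr1", c(100, 1000), c(110, 1010), c(2, 9))
  sites <- m6a_sites("chr1", c(105, 1500), "+")   # nearest d: 0 and 491
  s <- m6a_rbp_distance_summary(sites, tr, "genome")
  expect_equal(s$min_distance, 0)
  expect_equal(s$max_distance, 491)
  expect_equal(s$nearest_score, 2)
  one <- m6a_rbp_distance_summary(sites[1, ], tr, "genome")
  expect_equal(one$min_distance, one$max_distance)
  nada <- m6a_rbp_distance_summary(sites, tr[0, ], "genome")
  expect_true(is.na(nada$min_distance) && is.na(nada$max_distance))
})

test_that("k-mer features use overlapping scans and flank windows", {
  #                     0123456789
  tseq <- paste0("GGACTGGACT", strrep("T", 90))
  genome <- toy_genome(c(chr1 = tseq))
  tx <- transcript_model("t", "g", "chr1", "+", 0, 100)
  # site at transcript position 7: occurrences of GGACT at 0 and 5
  sites <- m6a_sites("chr1", 7, "+")
  kf <- kmer_features(genome, sites, tx, kmers = c("GGACT", "AAAAA"),
                      flank = 100)
  expect_equal(kf$nearest_distance[kf$kmer == "GGACT"], 2)   # |7-5|
  expect_equal(kf$max_flank_count[kf$kmer == "GGACT"], 2)
  expect_true(is.na(kf$nearest_distance[kf$kmer == "AAAAA"]))
  # overlapping occurrences are all counted within the window
  g2 <- toy_genome(c(chr1 = paste0("AAAAAAA", strrep("C", 93))))
  tx2 <- transcript_model("t", "g", "chr1", "+", 0, 100)
  kf2 <- kmer_features(g2, m6a_sites("chr1", 3, "+"), tx2,
                       kmers = "AAAAA", flank = 100)
  expect_equal(kf2$max_flank_count, 3)  # starts 0, 1, 2
  # window truncation: flank = 1 keeps only starts within +-1 of the site
  kf3 <- kmer_features(g2, m6a_sites("chr1", 3, "+"), tx2,
                       kmers = "AAAAA", flank = 1)
  expect_equal(kf3$max_flank_count, 1)  # only start 2
})

test_that("gene-level feature assembly has the full eleven-set schema", {
  cfg <- sim_config(seed = 21, n_genes = 12)
  sim <- gen_transcriptome(cfg)
  fx <- gen_readout_features(cfg, sim)
  genes <- unique(sim$m6a$gene_id)
  expr <- data.frame(gene_id = genes, liver = runif(length(genes)),
                     brain = runif(length(genes)))
  dep <- data.frame(gene_id = genes, dependency = rnorm(length(genes)))
  f <- assemble_features(genes, sim$m6a, fx$tracks, sim$txome,
                         genome = sim$genome, expression = expr,
                         dependency = dep, level = "gene")
  sets <- attr(f, "feature_sets")
  expect_setequal(names(sets),
                  c("rbp_score_genome", "rbp_score_tx",
                    "rbp_min_dist_genome", "rbp_min_dist_tx",
                    "rbp_max_dist_genome", "rbp_max_dist_tx",
                    "topology", "expression", "dependency",
                    "kmer_dist", "kmer_flank_count"))
  expect_equal(length(sets$rbp_score_genome), cfg$n_rbp)
  expect_setequal(unlist(sets), setdiff(names(f), "unit_id"))
  # deterministic: identical inputs give identical tables
  f2 <- assemble_features(genes, sim$m6a, fx$tracks, sim$txome,
                          genome = sim$genome, expression = expr,
                          dependency = dep, level = "gene")
  expect_identical(f, f2)
  # unknown gene in expression table is masked missing, not dropped
  expr2 <- expr[-1, ]
  f3 <- assemble_features(genes, sim$m6a, fx$tracks, sim$txome,
                          expression = expr2, dependency = dep,
                          level = "gene", kmers = character(0))
  expect_true(f3$unit_id[1] %in% expr$gene_id[1])
  expect_true(is.na(f3[["expr.liver"]][1]))
})

test_that("exon-level vectors omit gene-only sets and apply the 10 kb gate", {
  cfg <- sim_config(seed = 22, n_genes = 12)
  sim <- gen_transcriptome(cfg)
  fx <- gen_readout_features(cfg, sim)
  genes <- unique(sim$m6a$gene_id)
  # events on real exons + one event far from any m6A site
  ev <- gen_psi_experiment(cfg, gen_ground_truth(cfg, sim), sim)
  ev <- ev[!is.na(ev$exon_start), ][1:6, ]
  far <- data.frame(event_id = "far", gene_id = genes[1],
                    exon_start = 9e6, exon_end = 9e6 + 100)
  dep <- data.frame(gene_id = genes, dependency = rnorm(length(genes)))
  f <- assemble_features(rbind(ev[, names(far)], far), sim$m6a, fx$tracks,
                         sim$txome, genome = sim$genome,
                         dependency = dep, level = "exon")
  expect_false("far" %in% f$unit_id)
  sets <- attr(f, "feature_sets")
  expect_false(any(c("expression", "dependency") %in% names(sets)))
  expect_false(any(grepl("\\.(min|max)_dist_(genome|tx)$", names(f))))
  expect_setequal(names(sets),
                  c("rbp_score_genome", "rbp_score_tx", "rbp_dist_genome",
                    "rbp_dist_tx", "topology", "kmer_dist",
                    "kmer_flank_count"))
})

test_that("variability metrics follow the CV and SD definitions", {
  d <- rbind(g1 = c(100, 100, 100), g2 = c(50, 150, NA))
  fc <- rbind(g1 = c(1, 1, 1), g2 = c(0.5, 2.5, 1))
  v <- variability_metrics(d, fc)
  expect_equal(v$cv_distance[1], 0)
  expect_equal(v$cv_distance[2], sd(c(50, 150)) / 100)
  expect_equal(v$sd_log2fc[1], 0)
  expect_equal(v$sd_log2fc[2], sd(c(0.5, 2.5, 1)))
  z <- variability_metrics(rbind(g = c(0, 0)), rbind(g = c(1, 2)))
  expect_true(is.na(z$cv_distance))
})
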