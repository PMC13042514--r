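make_cm <- function(counts, condition, time_h) {
  samples <- data.frame(sample = paste0("s", seq_len(ncol(counts))),
                        condition = condition, time_h = time_h,
                        replicate = seq_len(ncol(counts)))
  count_matrix(counts, samples)
}

test_that("ERCC normalization puts samples on a common absolute scale", {
  counts <- rbind(geneA = c(100, 200), "ERCC-1" = c(10000, 20000))
  cm <- make_cm(counts, "c", 0)
  norm <- ercc_normalize(cm)
  expect_equal(unname(norm$counts["geneA", ]), c(0.01, 0.01))
  expect_false(any(startsWith(rownames(norm$counts), "ERCC-")))
  # exact invariance to uniform per-sample scaling
  cm4 <- make_cm(counts * 4, "c", 0)
  expect_identical(ercc_normalize(cm4)$counts, norm$counts)
  # zero stays zero; zero spike-in total errors
  cm0 <- make_cm(rbind(g = c(0, 0), "ERCC-1" = c(1, 1)), "c", 0)
  expect_equal(unname(ercc_normalize(cm0)$counts["g", ]), c(0, 0))
  cmbad <- make_cm(rbind(g = c(1, 1), "ERCC-1" = c(0, 1)), "c", 0)
  expect_error(ercc_normalize(cmbad), "zero ERCC")
})

test_that("decay fitting recovers exact exponentials and handles delta", {
  counts <- cbind(1000, 500, 250)
  rownames(counts) <- "g1"
  counts <- rbind(counts, "ERCC-1" = c(1, 1, 1))
  cm <- make_cm(counts, "c", c(0, 3, 6))
  dc <- fit_decay(ercc_normalize(cm), "c", delta = 1)
  expect_equal(dc$k3, 1 / 3)
  expect_equal(dc$k6, 1 / 3)
  expect_equal(dc$half_life, 3)
  # delta cancels the ratio: A3/A0 = 0.5 with delta = 2 gives k3 = 0
  dc2 <- fit_decay(ercc_normalize(cm), "c", delta = 2)
  expect_equal(dc2$k3, 0)
  # negative rate when abundance grows
  up <- rbind(g1 = c(100, 200, 400), "ERCC-1" = c(1, 1, 1))
  dcu <- fit_decay(ercc_normalize(make_cm(up, "c", c(0, 3, 6))), "c",
                   delta = 1)
  expect_equal(dcu$k3, -1 / 3)
  expect_equal(dcu$half_life, Inf)
  # zero baseline is skipped with a reason
  z <- rbind(g1 = c(0, 5, 5), g2 = c(10, 5, 5), "ERCC-1" = c(1, 1, 1))
  dz <- fit_decay(ercc_normalize(make_cm(z, "c", c(0, 3, 6))), "c", delta = 1)
  expect_true(is.na(dz$k[dz$gene_id == "g1"]))
  expect_equal(dz$reason[dz$gene_id == "g1"], "zero_baseline")
})

test_that("auto delta re-centres a globally drifted time point", {
  set.seed(1)
  # 100 genes whose 3 h ratio is uniformly inflated 2x; 6 h decays normally
  counts <- cbind(rpois(100, 1000), rpois(100, 2000), rpois(100, 800))
  rownames(counts) <- paste0("g", 1:100)
  counts <- rbind(counts, "ERCC-1" = c(1000, 1000, 1000))
  dc <- fit_decay(ercc_normalize(make_cm(counts, "c", c(0, 3, 6))), "c",
                  delta = "auto")
  expect_lt(abs(median(dc$k3)), 0.02)   # drift removed
  expect_equal(dc$delta3[1], 1 / median(counts[1:100, 2] / counts[1:100, 1]))
  # an undrifted time point keeps delta = 1 (capped above at 1)
  expect_equal(dc$delta6[1], 1)
})

test_that("half-life classification applies the 1.5-fold gate inclusively", {
  mk <- function(hl) data.frame(gene_id = paste0("g", seq_along(hl)),
                                k = 1 / hl, half_life = hl)
  ctrl <- mk(c(2, 3, 4.5, 3));  kd <- mk(c(3, 3, 3, -1))
  kd$half_life[4] <- Inf; kd$k[4] <- -0.1
  calls <- classify_halflife(ctrl, kd)
  expect_equal(calls$call, c("HL_down", "none", "HL_up", "none"))
  expect_equal(calls$reason[4], "no_finite_halflife")
})

test_that("TE change is null on identical matrices and compositionally invariant", {
  set.seed(2)
  counts <- matrix(rpois(200, 100), 50, 4,
                   dimnames = list(paste0("g", 1:50), NULL))
  sheet <- data.frame(sample = paste0("s", 1:4),
                      condition = rep(c("shControl", "shMETTL3"), each = 2),
                      time_h = 0, replicate = c(1, 2, 1, 2))
  rpf <- count_matrix(counts, sheet); rna <- count_matrix(counts, sheet)
  res <- te_change(rpf, rna)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$call == "none"))
  # doubling rpf uniformly in one condition changes nothing
  c2 <- counts; c2[, 1:2] <- c2[, 1:2] * 2
  res2 <- te_change(count_matrix(c2, sheet), rna)
  expect_equal(res2$log2fc, res$log2fc)
})

test_that("a planted strong TE increase is recovered with high power", {
  # planted 4x TE increase, 6 replicates, high counts
  set.seed(3)
  n_rep <- 6
  hits <- 0
  for (mc in 1:20) {
    base <- rpois(2 * n_rep, 1000)
    rna <- rbind(g1 = rpois(2 * n_rep, 2000),
                 filler = rpois(2 * n_rep, 5000))
    rpf <- rbind(g1 = c(rpois(n_rep, 4 * 2000), rpois(n_rep, 2000)),
                 filler = rpois(2 * n_rep, 5000))
    sheet <- data.frame(sample = paste0("s", 1:(2 * n_rep)),
                        condition = rep(c("shControl", "shMETTL3"),
                                        each = n_rep),
                        time_h = 0, replicate = rep(1:n_rep, 2))
    res <- te_change(count_matrix(rpf, sheet), count_matrix(rna, sheet))
    hits <- hits + (res$call[res$gene_id == "g1"] == "TE_up")
  }
  expect_gte(hits / 20, 0.95)
})

test_that("Psi matches its closed form on an exhaustive grid", {
  grid <- expand.grid(I = 0:50, S = 0:50)
  got <- compute_psi(grid$I, grid$S, lI = 2, lS = 1)
  want <- ifelse(grid$I + grid$S == 0, NA_real_,
                 (grid$I / 2) / (grid$I / 2 + grid$S / 1))
  expect_equal(got, want)
  expect_equal(compute_psi(60, 20, 2, 1), 0.6)
  expect_equal(compute_psi(10, 0), 1)
  expect_equal(compute_psi(0, 10), 0)
  expect_true(is.na(compute_psi(0, 0)))
})

test_that("splicing calls combine the delta-Psi gate with BH-adjusted Fisher", {
  ev <- data.frame(event_id = c("e1", "e2", "e3"), gene_id = "g",
                   I_ctrl = c(90, 50, 52), S_ctrl = c(10, 50, 48),
                   I_kd = c(50, 50, 48), S_kd = c(50, 50, 52),
                   lI = 1, lS = 1)
  res <- classify_splicing(ev)
  expect_equal(res$delta_psi, c(0.4, 0, 0.04))
  expect_equal(res$p[1], oracle_fisher_p(90, 10, 50, 50), tolerance = 1e-10)
  expect_equal(res$call, c("PSI_up", "none", "none"))
  # tiny p with small effect stays uncalled (effect-size gate)
  big <- data.frame(event_id = "e", gene_id = "g",
                    I_ctrl = 5500, S_ctrl = 4500, I_kd = 5000, S_kd = 5000,
                    lI = 1, lS = 1)
  resb <- classify_splicing(big)
  expect_lt(resb$p, 0.05)
  expect_equal(resb$call, "none")
  # identical tables in both conditions produce no calls
  same <- data.frame(event_id = paste0("e", 1:5), gene_id = "g",
                     I_ctrl = 30, S_ctrl = 70, I_kd = 30, S_kd = 70)
  expect_true(all(classify_splicing(same)$call == "none"))
})

test_that("BH adjustment reproduces hand-derived step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})
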