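test_that("AUC equals the pairwise Mann-Whitney oracle, ties at 1/2", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))$auc, 3 / 4)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)
  set.seed(505)
  for (rep in 1:50) {
    n <- sample(4:200, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(round(runif(n, 0, 1), 2))  # duplicates force ties
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
    # label inversion flips AUC
    expect_equal(roc_auc(scores, !labels)$auc,
                 1 - roc_auc(scores, labels)$auc)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(506)
  scores <- runif(300); labels <- runif(300) > 0.6
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE))))
})

test_that("sensitivity at fixed specificity uses the stepwise convention", {
  # perfect classifier
  expect_equal(sensitivity_at_specificity(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  set.seed(507)
  for (rep in 1:30) {
    n <- sample(10:150, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(runif(n, 0, 1), 2)
    expect_equal(sensitivity_at_specificity(scores, labels, 0.8),
                 oracle_sens_at_spec(scores, labels, 0.8))
  }
  # random scores at large n sit near the chance diagonal (~0.20)
  set.seed(508)
  scores <- runif(20000); labels <- rep(c(TRUE, FALSE), 10000)
  expect_equal(sensitivity_at_specificity(scores, labels, 0.8), 0.2,
               tolerance = 0.05)
})

test_that("stratified folds are balanced and seeded", {
  labels <- c(rep(TRUE, 33), rep(FALSE, 67))
  f <- make_folds(labels, 10, seed = 3)
  expect_true(all(range(table(f[labels])) %in% 3:4))
  expect_true(all(range(table(f[!labels])) %in% 6:7))
  expect_identical(f, make_folds(labels, 10, seed = 3))
  expect_false(identical(f, make_folds(labels, 10, seed = 4)))
})

test_that("a perfectly separating feature yields AUC 1 and reproducible CV", {
  set.seed(1)
  n <- 60
  f <- data.frame(unit_id = paste0("u", 1:n),
                  x = c(rnorm(n / 2, 5), rnorm(n / 2, -5)),
                  noise = rnorm(n))
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  cv <- train_cv(f, labels, seed = 11, nrounds = 50)
  expect_gte(cv$auc, 0.99)
  cv2 <- train_cv(f, labels, seed = 11, nrounds = 50)
  expect_identical(cv$scores, cv2$scores)
  expect_error(train_cv(f[1:25, ], labels[1:25], seed = 1),
               "insufficient data")
})

test_that("greedy feature-set search finds the informative set", {
  set.seed(12)
  n <- 120
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  f <- data.frame(unit_id = paste0("u", 1:n),
                  sig.a = ifelse(labels, rnorm(n, 2), rnorm(n, 0)),
                  noise1.a = rnorm(n), noise2.a = rnorm(n))
  sets <- list(signal = "sig.a", noise1 = "noise1.a", noise2 = "noise2.a")
  res <- featureset_auc_gain(f, labels, seed = 5, sets = sets,
                             nfolds = 3, nrounds = 60)
  expect_equal(res$set[res$order == 1 & !is.na(res$order)], "signal")
  sig_gain <- res$gain[res$set == "signal"]
  expect_gt(sig_gain, 0.2)
  expect_true(all(res$gain[res$set != "signal"] < sig_gain))
  # a duplicate of an already-informative set adds nothing
  f$dup.a <- f$sig.a
  sets$dup <- "dup.a"
  res2 <- featureset_auc_gain(f, labels, seed = 5, sets = sets,
                              nfolds = 3, nrounds = 60)
  first <- res2$set[!is.na(res2$order) & res2$order == 1]
  expect_true(first %in% c("signal", "dup"))
  other <- setdiff(c("signal", "dup"), first)
  expect_lt(abs(res2$gain[res2$set == other]), 0.05)
})

test_that("importance aggregates gain per RBP and zeroes unused tracks", {
  set.seed(13)
  n <- 80
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  f <- data.frame(unit_id = paste0("u", 1:n),
                  RBPA.score_genome = ifelse(labels, rnorm(n, 3), rnorm(n)),
                  RBPA.min_dist_genome = rnorm(n),
                  RBPB.score_genome = rnorm(n),
                  RBPC.score_genome = NA_real_)
  cv <- train_cv(f, labels, seed = 7, nrounds = 60)
  imp <- rbp_importance(cv, rbps = c("RBPA", "RBPB", "RBPC"))
  expect_setequal(imp$rbp_ranking$rbp, c("RBPA", "RBPB", "RBPC"))
  expect_equal(imp$rbp_ranking$rbp[1], "RBPA")
  expect_equal(imp$rbp_ranking$importance[imp$rbp_ranking$rbp == "RBPC"], 0)
  # per-RBP score is the max over that RBP's features
  ga <- imp$feature_gain$gain[imp$feature_gain$feature ==
                                "RBPA.score_genome"]
  expect_equal(imp$rbp_ranking$importance[imp$rbp_ranking$rbp == "RBPA"],
               max(ga, imp$feature_gain$gain[
                 imp$feature_gain$feature == "RBPA.min_dist_genome"]))
})

test_that("cross-cell-type transfer degrades against within-type CV", {
  # two cell types with opposite planted rules: the reader's high score
  # marks positives in type A but negatives in type B
  make_type <- function(seed, flip) {
    set.seed(seed)
    n <- 150
    labels <- rep(c(TRUE, FALSE), length.out = n)
    eff <- xor(labels, flip)
    data.frame(unit_id = paste0("u", seed, "_", 1:n),
               R1.score_genome = ifelse(eff, rnorm(n, 3, 1), rnorm(n, 0, 1)),
               R2.score_genome = rnorm(n),
               lab = labels)
  }
  a <- make_type(31, flip = FALSE)
  b <- make_type(32, flip = TRUE)
  fa <- a[, 1:3]; fb <- b[, 1:3]
  within_b <- train_cv(fb, b$lab, seed = 2, nfolds = 5, nrounds = 80)$auc
  # train on A, test on B
  m <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 6, eta = 0.1,
                  subsample = 0.8, nthread = 1),
    data = xgboost::xgb.DMatrix(as.matrix(fa[, -1]),
                                label = as.numeric(a$lab)),
    nrounds = 80, verbose = 0)
  cross <- roc_auc(predict(m, xgboost::xgb.DMatrix(as.matrix(fb[, -1]))),
                   b$lab)$auc
  expect_lt(cross, within_b)
})
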