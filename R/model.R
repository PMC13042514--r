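#' ROC curve and AUC
#'
#' AUC in the Mann-Whitney form: the probability that a random positive
#' outscores a random negative, with ties counted 1/2. The ROC points are
#' computed by a threshold sweep over the unique scores.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical or 0/1 vector; both classes must be present.
#' @return List with `auc` and `roc` (data.frame `threshold`, `tpr`,
#'   `fpr`, sorted by decreasing threshold).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores[labels] >= t) / np, 0)
  fpr <- vapply(th, function(t) sum(scores[!labels] >= t) / nn, 0)
  roc <- data.frame(threshold = c(Inf, th), tpr = c(0, tpr), fpr = c(0, fpr))
  list(auc = auc, roc = roc)
}

#' Sensitivity at a fixed specificity
#'
#' Maximum sensitivity over score thresholds whose specificity is at
#' least `specificity` (conservative stepwise convention, no ROC
#' interpolation).
#'
#' @param scores,labels As in [roc_auc()].
#' @param specificity Required specificity (default 0.80).
#' @return Sensitivity (fraction of positives recovered).
#' @export
sensitivity_at_specificity <- function(scores, labels, specificity = 0.80) {
  r <- roc_auc(scores, labels)$roc
  ok <- 1 - r$fpr >= specificity
  if (!any(ok)) return(0)
  max(r$tpr[ok])
}

#' Stratified cross-validation folds
#'
#' @param labels Logical/0-1 class labels.
#' @param nfolds Number of folds.
#' @param seed Mandatory RNG seed.
#' @return Integer fold assignment per unit; within each class, fold
#'   sizes differ by at most 1.
#' @export
make_folds <- function(labels, nfolds = 10, seed) {
  stopifnot(!missing(seed))
  labels <- as.logical(labels)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in c(TRUE, FALSE)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

default_xgb_params <- function() {
  list(objective = "binary:logistic", max_depth = 6, eta = 0.1,
       subsample = 0.8, nthread = 1, eval_metric = "logloss")
}

feature_matrix <- function(features) {
  cols <- setdiff(names(features), "unit_id")
  m <- as.matrix(features[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- features$unit_id
  m
}

#' Train and evaluate a readout classifier by cross-validation
#'
#' Fits gradient-boosted trees (XGBoost, binary logistic) under
#' stratified k-fold cross-validation and scores every unit out of fold.
#' Hyperparameters are fixed defaults (depth 6, 300 rounds, learning rate
#' 0.1, subsample 0.8); performance is insensitive to tuning for this
#' task family. Missing feature values (`NA`) are handled natively by the
#' trees as missing, not as zeros.
#'
#' @param features Feature table from [assemble_features()] (or any
#'   data.frame with `unit_id` + numeric columns).
#' @param labels Named logical/0-1 vector or a vector aligned with
#'   `features` rows; `TRUE` = positive readout class.
#' @param seed Mandatory RNG seed (folds and boosting are seeded).
#' @param nfolds Folds (default 10).
#' @param nrounds Boosting rounds (default 300).
#' @param min_class Minimum units per class (default 20).
#' @param params Override list merged over the defaults.
#' @return Object of class `cv_result`: `scores` (out-of-fold), `labels`,
#'   `fold`, `auc`, `roc`, `sens_at_80spec`, `models` (per-fold xgboost
#'   handles), `feature_names`.
#' @export
train_cv <- function(features, labels, seed, nfolds = 10, nrounds = 300,
                     min_class = 20, params = list()) {
  stopifnot(!missing(seed))
  m <- feature_matrix(features)
  if (!is.null(names(labels))) labels <- labels[rownames(m)]
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(m), !anyNA(labels))
  if (sum(labels) < min_class || sum(!labels) < min_class)
    stop("insufficient data: need >= ", min_class, " units per class")
  fold <- make_folds(labels, nfolds, seed)
  prm <- utils::modifyList(default_xgb_params(), params)
  scores <- numeric(nrow(m))
  models <- vector("list", nfolds)
  for (f in seq_len(nfolds)) {
    tr <- fold != f; te <- !tr
    set.seed(seed + f)
    dtr <- xgboost::xgb.DMatrix(m[tr, , drop = FALSE],
                                label = as.numeric(labels[tr]))
    booster <- xgboost::xgb.train(params = prm, data = dtr,
                                  nrounds = nrounds, verbose = 0)
    scores[te] <- stats::predict(booster,
                                 xgboost::xgb.DMatrix(m[te, , drop = FALSE]))
    models[[f]] <- booster
  }
  ra <- roc_auc(scores, labels)
  structure(list(scores = stats::setNames(scores, rownames(m)),
                 labels = labels, fold = fold, auc = ra$auc, roc = ra$roc,
                 sens_at_80spec = sensitivity_at_specificity(scores, labels),
                 models = models, feature_names = colnames(m)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: %d units (%d pos), AUC %.3f, sensitivity %.3f @ 80%% specificity\n",
    length(x$scores), sum(x$labels), x$auc, x$sens_at_80spec))
  invisible(x)
}

#' Greedy feature-set AUC-gain search
#'
#' Heuristic forward selection over a partition of the feature columns
#' into named sets: starting from the empty model, repeatedly adds the
#' set with the largest cross-validated AUC, until no set improves the
#' AUC by more than `tol`. A selected set's gain is the AUC after its
#' addition minus the AUC before (0.5 for the first); unselected sets are
#' reported with their marginal gain on top of the final selection.
#'
#' @param features,labels,seed As in [train_cv()].
#' @param sets Named list mapping set label -> feature column names
#'   (default: the table's `"feature_sets"` attribute). Must cover all
#'   feature columns.
#' @param nfolds,nrounds CV shape for the search (defaults 3 and 100;
#'   lighter than the final model, the ranking is what matters).
#' @param tol Minimal AUC improvement to continue (default 1e-3).
#' @return data.frame with `set`, `selected`, `order` (NA if unselected),
#'   `auc_after`, `gain` (cumulative for selected sets, marginal for the
#'   rest).
#' @export
featureset_auc_gain <- function(features, labels, seed,
                                sets = attr(features, "feature_sets"),
                                nfolds = 3, nrounds = 100, tol = 1e-3) {
  stopifnot(!is.null(sets), length(sets) >= 1)
  all_cols <- setdiff(names(features), "unit_id")
  if (!setequal(unlist(sets), all_cols))
    stop("feature-set partition must cover all feature columns")
  cv_auc <- function(cols) {
    f <- features[, c("unit_id", cols), drop = FALSE]
    train_cv(f, labels, seed = seed, nfolds = nfolds, nrounds = nrounds)$auc
  }
  selected <- character(0); current_auc <- 0.5
  res <- data.frame(set = names(sets), selected = FALSE, order = NA_integer_,
                    auc_after = NA_real_, gain = NA_real_)
  remaining <- names(sets)
  step <- 0
  while (length(remaining) > 0) {
    aucs <- vapply(remaining, function(s)
      cv_auc(unlist(sets[c(selected, s)])), 0)
    best <- remaining[which.max(aucs)]
    gain <- max(aucs) - current_auc
    if (gain <= tol) break
    step <- step + 1
    i <- res$set == best
    res$selected[i] <- TRUE; res$order[i] <- step
    res$auc_after[i] <- max(aucs); res$gain[i] <- gain
    current_auc <- max(aucs)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  for (s in remaining) {
    a <- cv_auc(unlist(sets[c(selected, s)]))
    i <- res$set == s
    res$auc_after[i] <- a; res$gain[i] <- a - current_auc
  }
  res[order(-res$selected, res$order, -res$gain), ]
}

#' Feature and RBP importance from cross-validated models
#'
#' Per-feature importance is the total split gain reported by XGBoost,
#' averaged over the fold models (features never used get 0). The per-RBP
#' score is the maximum over that RBP's feature columns; RBPs are ranked
#' descending.
#'
#' @param cv A `cv_result` from [train_cv()].
#' @param rbps Optional character vector of RBP names; defaults to the
#'   prefixes of the `<rbp>.<feature>` columns.
#' @return List with `feature_gain` (data.frame `feature`, `gain`) and
#'   `rbp_ranking` (data.frame `rbp`, `importance`, sorted).
#' @export
rbp_importance <- function(cv, rbps = NULL) {
  stopifnot(inherits(cv, "cv_result"))
  gain <- stats::setNames(numeric(length(cv$feature_names)),
                          cv$feature_names)
  for (b in cv$models) {
    imp <- xgboost::xgb.importance(model = b)
    if (nrow(imp) > 0)
      gain[imp$Feature] <- gain[imp$Feature] + imp$Gain
  }
  gain <- gain / length(cv$models)
  fg <- data.frame(feature = names(gain), gain = as.numeric(gain),
                   row.names = NULL)
  rbp_cols <- grep("^(topo|expr|dep|kmer)\\.", names(gain),
                   invert = TRUE, value = TRUE)
  if (is.null(rbps))
    rbps <- unique(sub("\\..*$", "", rbp_cols))
  imp_rbp <- vapply(rbps, function(r) {
    cols <- rbp_cols[startsWith(rbp_cols, paste0(r, "."))]
    if (length(cols) == 0) 0 else max(gain[cols])
  }, 0)
  rk <- data.frame(rbp = names(imp_rbp), importance = as.numeric(imp_rbp),
                   row.names = NULL)
  rk <- rk[order(-rk$importance, rk$rbp), ]
  rownames(rk) <- NULL
  list(feature_gain = fg[order(-fg$gain), ], rbp_ranking = rk)
}
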