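#' Stratified random half-split of a feature matrix
#'
#' Rows are split into disjoint, exhaustive train/test halves, stratified by
#' label so the class ratio is preserved within one row per class.
#'
#' @param fm a [feature_matrix()].
#' @param seed integer seed making the split reproducible.
#' @param fraction fraction of each class assigned to the training half.
#' @return list with elements `train` and `test`, both `feature_matrix`
#'   objects.
#' @export
split_half <- function(fm, seed, fraction = 0.5) {
  counts <- table(fm$labels)
  if (any(counts < 2))
    stop("each class needs at least 2 rows to split")
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(levels(fm$labels), function(l) {
      idx <- which(fm$labels == l)
      sample(idx, round(length(idx) * fraction))
    }))
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(fm$labels), train_idx)
  list(train = subset_feature_matrix(fm, train_idx),
       test = subset_feature_matrix(fm, test_idx))
}

#' Min-max scale features to [0, 1] using training statistics only
#'
#' Per-column minima and maxima are learned on the training half; the test
#' half is transformed with the same record and clamped to `[0, 1]`.
#' Constant training columns map to 0 everywhere.
#'
#' @param train,test [feature_matrix()] objects.
#' @return list with scaled `train`, `test` and the `record`
#'   (`list(min, max)`).
#' @export
scale_features <- function(train, test) {
  mins <- apply(train$features, 2, min)
  maxs <- apply(train$features, 2, max)
  rng <- maxs - mins
  transform <- function(x) {
    out <- sweep(x, 2, mins)
    out <- sweep(out, 2, ifelse(rng > 0, rng, 1), "/")
    out[, rng == 0] <- 0
    pmin(pmax(out, 0), 1)
  }
  list(train = feature_matrix(transform(train$features), train$labels,
                              train$sites, train$discarded),
       test = feature_matrix(transform(test$features), test$labels,
                             test$sites, test$discarded),
       record = list(min = mins, max = maxs))
}

# stratified fold assignment, one integer in 1..folds per row
fold_assignment <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  withr::with_seed(seed, {
    for (l in levels(labels)) {
      idx <- which(labels == l)
      assign[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  })
  assign
}

svm_kernel <- function(kernel) switch(kernel, rbf = "radial", linear = "linear")

#' Train a support-vector classifier and score test rows
#'
#' Fits a soft-margin C-classification SVM (libSVM via \pkg{e1071}) on the
#' training half and returns real-valued decision scores on the test half,
#' oriented so that higher means more positive-like.  Deterministic given the
#' inputs.
#'
#' @param train,test scaled [feature_matrix()] objects.
#' @param C soft-margin cost.
#' @param gamma RBF bandwidth (ignored for the linear kernel).
#' @param kernel `"rbf"` or `"linear"`.
#' @return numeric decision scores, one per test row.
#' @export
train_and_score <- function(train, test, C, gamma, kernel = "rbf") {
  fit <- e1071::svm(x = train$features, y = train$labels,
                    type = "C-classification",
                    kernel = svm_kernel(kernel),
                    cost = C, gamma = gamma, scale = FALSE)
  pred <- predict(fit, test$features, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  scores <- as.numeric(dv[, 1])
  # libSVM's decision value is signed toward the first internal class label
  if (!startsWith(colnames(dv)[1], "positive")) scores <- -scores
  scores
}

#' Select SVM hyperparameters by stratified cross-validation
#'
#' Exhaustive grid search maximizing the mean held-out AUC over seeded,
#' stratified folds.  Ties are broken toward the smallest `C`, then the
#' smallest `gamma`.  Duplicate grid entries are deduplicated; a singleton
#' grid is returned without cross-validation work.
#'
#' @param train a scaled [feature_matrix()].
#' @param config a [model_config()].
#' @return list with `C`, `gamma` and the full `cv` grid
#'   (`data.frame(C, gamma, auc)`).
#' @export
select_hyperparameters <- function(train, config = model_config()) {
  grid <- unique(expand.grid(C = config$C_grid, gamma = config$gamma_grid))
  if (config$kernel == "linear")
    grid <- unique(data.frame(C = config$C_grid, gamma = config$gamma_grid[1]))
  if (nrow(grid) == 1)
    return(list(C = grid$C[1], gamma = grid$gamma[1],
                cv = cbind(grid, auc = NA_real_)))
  if (length(train$labels) < config$folds)
    stop("fewer rows than folds")
  if (any(table(train$labels) < config$folds))
    stop("each class needs at least `folds` rows for stratified CV")
  assign <- fold_assignment(train$labels, config$folds,
                            derive_seed(config$seed, "cv_folds"))
  grid$auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(seq_len(config$folds), function(k) {
      tr <- subset_feature_matrix(train, assign != k)
      ho <- subset_feature_matrix(train, assign == k)
      sc <- train_and_score(tr, ho, grid$C[g], grid$gamma[g], config$kernel)
      roc_auc(sc, ho$labels)$auc
    }, numeric(1))
    grid$auc[g] <- mean(aucs)
  }
  ord <- order(-grid$auc, grid$C, grid$gamma)
  best <- grid[ord[1], ]
  list(C = best$C, gamma = best$gamma, cv = grid)
}

#' ROC curve and AUC from decision scores
#'
#' The AUC is the Mann-Whitney rank statistic (ties counted half), which
#' equals the trapezoidal area under the tie-aware ROC curve.
#'
#' @param scores numeric decision scores, higher = more positive-like.
#' @param labels factor (or character) with classes `negative`/`positive`.
#' @return an object of class `roc_result`: list with non-decreasing `fpr`
#'   and `tpr` (from (0,0) to (1,1)), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- factor(labels, levels = c("negative", "positive"))
  if (anyNA(labels)) stop("labels must be 'negative' or 'positive'")
  n_pos <- sum(labels == "positive")
  n_neg <- sum(labels == "negative")
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores)                      # midranks: ties get half credit
  auc <- (sum(r[labels == "positive"]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == "positive"
  grp_end <- which(c(diff(s) != 0, TRUE)) # group tied scores
  tp <- cumsum(pos)[grp_end]
  fp <- cumsum(!pos)[grp_end]
  structure(
    list(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
         auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Run the full classification harness once
#'
#' Half-split, scale, grid-search hyperparameters on the training half,
#' refit on the full training half, score the test half, and evaluate.
#'
#' @param fm a [feature_matrix()].
#' @param config a [model_config()]; its `seed` drives the split and folds.
#' @return list with `roc` ([roc_auc()] result), `C`, `gamma`, `n_pos`,
#'   `n_neg` (test-half class sizes) and the test `scores`.
#' @export
evaluate_design <- function(fm, config = model_config()) {
  halves <- split_half(fm, derive_seed(config$seed, "half_split"),
                       config$split_fraction)
  scaled <- scale_features(halves$train, halves$test)
  sel <- select_hyperparameters(scaled$train, config)
  scores <- train_and_score(scaled$train, scaled$test, sel$C, sel$gamma,
                            config$kernel)
  roc <- roc_auc(scores, scaled$test$labels)
  list(roc = roc, C = sel$C, gamma = sel$gamma,
       n_pos = roc$n_pos, n_neg = roc$n_neg, scores = scores)
}

#' Compare feature designs (per-reagent and combined) on one site set
#'
#' Runs the full split / scale / cross-validate / train / ROC harness once
#' per design, sharing the split seed so every design sees the same
#' train/test partition of the same sites.
#'
#' @param matrices named list of [feature_matrix()] objects (e.g.
#'   `flexibility`, `accessibility`, `combined`) built on the same rows.
#' @param config a [model_config()].
#' @return data frame with one row per design: `design`, `n_pos`, `n_neg`,
#'   `C`, `gamma`, `auc`; the `roc_result` objects are attached as the
#'   `"roc"` attribute.
#' @export
compare_reagents <- function(matrices, config = model_config()) {
  n <- unique(vapply(matrices, function(m) length(m$labels), integer(1)))
  if (length(n) != 1)
    stop("all designs must be built on the same site set")
  runs <- lapply(matrices, evaluate_design, config = config)
  out <- data.frame(
    design = names(matrices),
    n_pos = vapply(runs, function(r) r$n_pos, integer(1)),
    n_neg = vapply(runs, function(r) r$n_neg, integer(1)),
    C = vapply(runs, function(r) r$C, numeric(1)),
    gamma = vapply(runs, function(r) r$gamma, numeric(1)),
    auc = vapply(runs, function(r) r$roc$auc, numeric(1)))
  rownames(out) <- NULL
  attr(out, "roc") <- lapply(runs, function(r) r$roc)
  out
}

#' Sensitivity at fixed specificity
#'
#' Reads the ROC curve at `1 - specificity` on the FPR axis (step
#' interpolation), a complementary operating-point summary to the AUC.
#'
#' @param roc a `roc_result`.
#' @param specificity target specificity (default 0.9).
#' @return sensitivity (TPR) at the requested specificity.
#' @export
sensitivity_at_specificity <- function(roc, specificity = 0.9) {
  fpr_max <- 1 - specificity
  max(roc$tpr[roc$fpr <= fpr_max])
}
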