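# toy feature matrix with controllable class separation
toy_fm <- function(n_per_class, p = 4, shift = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), n_per_class, p),
               matrix(rnorm(n_per_class * p, mean = shift), n_per_class, p))
  })
  colnames(x) <- paste0("accessibility_+", seq_len(p) - 1)
  feature_matrix(x, rep(c("negative", "positive"), each = n_per_class),
                 data.frame(transcript_id = "t", start = seq_len(2 * n_per_class)))
}

test_that("half-split is stratified, disjoint, exhaustive and seeded", {
  fm <- toy_fm(50)
  sp <- split_half(fm, seed = 7)
  expect_equal(length(sp$train$labels), 50)
  expect_equal(as.vector(table(sp$train$labels)), c(25, 25))
  expect_equal(as.vector(table(sp$test$labels)), c(25, 25))
  sp2 <- split_half(fm, seed = 7)
  expect_identical(sp$train$sites$start, sp2$train$sites$start)
  # union == original, intersection empty (random sizes)
  for (n in c(11, 23)) {
    f <- toy_fm(n, seed = n)
    s <- split_half(f, seed = n)
    ids <- c(s$train$sites$start, s$test$sites$start)
    expect_setequal(ids, f$sites$start)
    expect_equal(length(ids), length(unique(ids)))
  }
  expect_error(split_half(toy_fm(1), 1), "at least 2")
})

test_that("min-max scaling learns on train only and clamps test", {
  tr <- feature_matrix(matrix(c(0, 2, 4), 3, 1,
                              dimnames = list(NULL, "a_+0")),
                       c("positive", "negative", "positive"),
                       data.frame(transcript_id = "t", start = 1:3))
  te <- feature_matrix(matrix(c(-1, 5), 2, 1, dimnames = list(NULL, "a_+0")),
                       c("positive", "negative"),
                       data.frame(transcript_id = "t", start = 4:5))
  sc <- scale_features(tr, te)
  expect_equal(as.vector(sc$train$features), c(0, 0.5, 1))
  expect_equal(as.vector(sc$test$features), c(0, 1))    # clamped

  # columnwise (x - min) / (max - min) oracle on a random matrix
  fm <- toy_fm(20, p = 6, seed = 3)
  sp <- split_half(fm, 1)
  sc2 <- scale_features(sp$train, sp$test)
  mins <- apply(sp$train$features, 2, min)
  maxs <- apply(sp$train$features, 2, max)
  oracle <- sweep(sweep(sp$train$features, 2, mins), 2, maxs - mins, "/")
  expect_equal(sc2$train$features, oracle, tolerance = 1e-12)

  # constant training columns map to zero
  tr$features[, 1] <- 2
  sc3 <- scale_features(tr, te)
  expect_true(all(sc3$train$features == 0))
  expect_true(all(sc3$test$features == 0))
})

test_that("ROC/AUC equals the concordant-pair count with half-credit ties", {
  r <- roc_auc(c(1, 1, 0, 0), c("positive", "positive", "negative", "negative"))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c("positive", "negative"), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, rep("positive", 3)), "both classes")

  withr::with_seed(99, {
    scores <- sample(round(rnorm(200), 1))     # rounded to force ties
    labels <- sample(rep(c("positive", "negative"), c(120, 80)))
  })
  r <- roc_auc(scores, labels)
  pos <- scores[labels == "positive"]
  neg <- scores[labels == "negative"]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_identical(r$auc, mean(pairs))
  # curve contract: ends, monotonicity, trapezoid area == rank AUC
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(max(r$fpr), max(r$tpr)), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(scores), labels)$auc, r$auc)
  expect_equal(roc_auc(rank(scores), labels)$auc, r$auc)
})

test_that("SVM scoring is deterministic, separable-sane and label-symmetric", {
  fm <- toy_fm(30, shift = 3, seed = 5)
  sp <- split_half(fm, 2)
  sc <- scale_features(sp$train, sp$test)
  s1 <- train_and_score(sc$train, sc$test, C = 1, gamma = 0.25)
  s2 <- train_and_score(sc$train, sc$test, C = 1, gamma = 0.25)
  expect_identical(s1, s2)
  # separable toy: positives score above negatives
  expect_gt(roc_auc(s1, sc$test$labels)$auc, 0.95)
  expect_gt(mean(s1[sc$test$labels == "positive"]),
            mean(s1[sc$test$labels == "negative"]))
  # flipping the training labels flips the ranking: AUC -> 1 - AUC
  flipped <- feature_matrix(sc$train$features,
                            ifelse(sc$train$labels == "positive",
                                   "negative", "positive"),
                            sc$train$sites)
  s_flip <- train_and_score(flipped, sc$test, C = 1, gamma = 0.25)
  expect_equal(roc_auc(s_flip, sc$test$labels)$auc,
               1 - roc_auc(s1, sc$test$labels)$auc, tolerance = 1e-9)
})

test_that("grid search maximizes cross-validated AUC with ordered tie-breaks", {
  cfg1 <- model_config(C_grid = 2, gamma_grid = 0.1, seed = 1)
  fm <- toy_fm(25, shift = 2, seed = 8)
  sel1 <- select_hyperparameters(fm, cfg1)
  expect_equal(sel1$C, 2)                      # singleton grid: no CV work
  expect_equal(sel1$gamma, 0.1)

  cfg2 <- model_config(C_grid = c(1, 1, 10), gamma_grid = c(0.1, 0.1), seed = 1)
  sel2 <- select_hyperparameters(fm, cfg2)
  expect_equal(nrow(sel2$cv), 2)               # duplicates removed
  # argmax property: the selected pair attains the maximal CV AUC
  expect_equal(max(sel2$cv$auc),
               sel2$cv$auc[sel2$cv$C == sel2$C & sel2$cv$gamma == sel2$gamma])
  expect_error(select_hyperparameters(toy_fm(2), cfg2), "folds")
})

test_that("duplicated features add no information to the combined design", {
  fm <- toy_fm(40, shift = 1, seed = 13)
  dup <- fm$features
  colnames(dup) <- sub("accessibility", "flexibility", colnames(dup))
  combined <- feature_matrix(cbind(fm$features, dup), fm$labels, fm$sites)
  # doubling every feature doubles squared distances; halving gamma makes
  # the RBF kernel identical, so scores and AUC must match exactly
  single <- evaluate_design(fm, model_config(C_grid = 1, gamma_grid = 0.2,
                                             seed = 4))
  both <- evaluate_design(combined, model_config(C_grid = 1, gamma_grid = 0.1,
                                                 seed = 4))
  expect_equal(both$roc$auc, single$roc$auc, tolerance = 1e-9)
})

test_that("compare_reagents shares the split across designs", {
  fm <- toy_fm(30, shift = 1.5, seed = 21)
  res <- compare_reagents(list(accessibility = fm, combined = fm),
                          model_config(C_grid = 1, gamma_grid = 0.1, seed = 3))
  expect_equal(res$design, c("accessibility", "combined"))
  expect_equal(res$auc[1], res$auc[2])         # identical design, same split
  expect_equal(res$n_pos + res$n_neg, c(30, 30))
  rocs <- attr(res, "roc")
  expect_s3_class(rocs$combined, "roc_result")
  # sensitivity at fixed specificity is a valid operating point
  sens <- sensitivity_at_specificity(rocs$combined, 0.9)
  expect_true(sens >= 0 && sens <= 1)
})
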