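#' Scoring parameters for reactivity calculation
#'
#' Parameters of the RT-stop enrichment score and of the percentile
#' normalization applied afterwards.
#'
#' @param alpha background-subtraction factor in `[0, 1]`: the fraction of the
#'   (library-size scaled) control stop count subtracted from the treatment
#'   stop count.
#' @param epsilon density floor (in scaled-count units) protecting the
#'   denominator where coverage is low; must be `> 0`.
#' @param winsor_lo,winsor_hi percentile bounds (on the 0-100 scale) of the
#'   positive raw scores whose mean defines the per-transcript normalization
#'   scale.
#' @param min_hit_coverage minimum treatment stop count below which a position
#'   is reported as `NA`.  The default 0 filters nothing, matching probing
#'   pipelines run with the coverage filters switched off.
#' @param min_background_density minimum (scaled) control base density below
#'   which a position is reported as `NA`; default 0 filters nothing.
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(alpha = 0.25, epsilon = 1, winsor_lo = 90,
                           winsor_hi = 99, min_hit_coverage = 0,
                           min_background_density = 0) {
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("`epsilon` must be a positive density floor")
  if (winsor_lo >= winsor_hi)
    stop("`winsor_lo` must be smaller than `winsor_hi`")
  if (min_hit_coverage < 0 || min_background_density < 0)
    stop("coverage filters must be non-negative")
  structure(
    list(alpha = alpha, epsilon = epsilon,
         winsor_lo = winsor_lo, winsor_hi = winsor_hi,
         min_hit_coverage = min_hit_coverage,
         min_background_density = min_background_density),
    class = "scoring_params")
}

#' Per-position RT-stop track for one library on one transcript
#'
#' @param transcript_id transcript identifier.
#' @param stops non-negative per-position RT-stop counts (position `i` of the
#'   vector is transcript position `i - 1` in 0-based coordinates).
#' @param density non-negative per-position base density (coverage).
#' @param condition `"in_cell"` or `"in_vitro"`.
#' @param reagent `"flexibility"`, `"accessibility"` or `"control"`.
#' @param total_mapped positive library size used for scaling; defaults to the
#'   track's total stop count (floored at 1 so empty tracks stay valid).
#' @return an object of class `stop_count_track`.
#' @export
stop_count_track <- function(transcript_id, stops, density,
                             condition = c("in_cell", "in_vitro"),
                             reagent = c("flexibility", "accessibility", "control"),
                             total_mapped = max(sum(stops), 1)) {
  condition <- match.arg(condition)
  reagent <- match.arg(reagent)
  stops <- as.numeric(stops)
  density <- as.numeric(density)
  if (length(stops) != length(density))
    stop("`stops` and `density` must have equal length")
  if (any(stops < 0) || any(density < 0))
    stop("stop counts and densities must be non-negative")
  if (!is.numeric(total_mapped) || total_mapped <= 0)
    stop("`total_mapped` must be positive")
  structure(
    list(transcript_id = as.character(transcript_id), stops = stops,
         density = density, condition = condition, reagent = reagent,
         total_mapped = total_mapped),
    class = "stop_count_track")
}

#' @export
print.stop_count_track <- function(x, ...) {
  cat(sprintf("<stop_count_track> %s | %s/%s | %d nt | %d stops\n",
              x$transcript_id, x$reagent, x$condition,
              length(x$stops), sum(x$stops)))
  invisible(x)
}

#' Normalized per-nucleotide reactivity profile
#'
#' Scores are in `[0, 1]`; `NA` marks positions with no defined reactivity
#' (filtered or never covered).
#'
#' @param transcript_id transcript identifier.
#' @param scores numeric vector of per-position scores in `[0, 1]` or `NA`.
#' @param reagent `"flexibility"` or `"accessibility"`.
#' @param condition `"in_cell"` or `"in_vitro"`.
#' @return an object of class `reactivity_profile`.
#' @export
reactivity_profile <- function(transcript_id, scores,
                               reagent = c("flexibility", "accessibility"),
                               condition = c("in_cell", "in_vitro")) {
  reagent <- match.arg(reagent)
  condition <- match.arg(condition)
  scores <- as.numeric(scores)
  ok <- scores[!is.na(scores)]
  if (length(ok) && (any(ok < 0) || any(ok > 1)))
    stop("non-NA reactivity scores must lie in [0, 1]")
  structure(
    list(transcript_id = as.character(transcript_id), scores = scores,
         reagent = reagent, condition = condition),
    class = "reactivity_profile")
}

#' @export
print.reactivity_profile <- function(x, ...) {
  cat(sprintf("<reactivity_profile> %s | %s/%s | %d nt | %d NA\n",
              x$transcript_id, x$reagent, x$condition,
              length(x$scores), sum(is.na(x$scores))))
  invisible(x)
}

#' In-cell minus in-vitro reactivity difference track
#'
#' @param transcript_id transcript identifier.
#' @param reagent probing reagent the difference refers to.
#' @param diffs numeric per-position differences in `[-1, 1]`, `NA` where
#'   either input profile was `NA`.
#' @return an object of class `vtd_track`.
#' @export
vtd_track <- function(transcript_id, reagent, diffs) {
  diffs <- as.numeric(diffs)
  ok <- diffs[!is.na(diffs)]
  if (length(ok) && (any(ok < -1) || any(ok > 1)))
    stop("VTD values must lie in [-1, 1]")
  structure(
    list(transcript_id = as.character(transcript_id),
         reagent = reagent, diffs = diffs),
    class = "vtd_track")
}

#' Feature matrix of reactivity windows at labeled motif sites
#'
#' @param features numeric matrix, one row per surviving site.
#' @param labels factor with levels `c("negative", "positive")` aligned with
#'   the rows.
#' @param sites data frame describing the surviving sites (one row per matrix
#'   row).
#' @param discarded data frame logging sites dropped for `NA` scores or
#'   windows exiting the transcript.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, labels, sites,
                           discarded = data.frame()) {
  features <- as.matrix(features)
  labels <- factor(labels, levels = c("negative", "positive"))
  if (nrow(features) != length(labels))
    stop("`labels` must align with feature rows")
  if (nrow(features) != nrow(sites))
    stop("`sites` must align with feature rows")
  if (anyNA(features))
    stop("feature matrices must be NA-free after window filtering")
  structure(
    list(features = features, labels = labels, sites = sites,
         discarded = discarded),
    class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d x %d | %d positive / %d negative | %d discarded\n",
              nrow(x$features), ncol(x$features),
              sum(x$labels == "positive"), sum(x$labels == "negative"),
              nrow(x$discarded)))
  invisible(x)
}

#' Subset a feature matrix by row index
#'
#' @param fm a [feature_matrix()].
#' @param idx integer or logical row index.
#' @return a `feature_matrix` with the selected rows.
#' @export
subset_feature_matrix <- function(fm, idx) {
  feature_matrix(fm$features[idx, , drop = FALSE], fm$labels[idx],
                 fm$sites[idx, , drop = FALSE], fm$discarded)
}

#' SVM harness configuration
#'
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param C_grid candidate soft-margin costs for grid search.
#' @param gamma_grid candidate RBF bandwidths (ignored by the linear kernel
#'   beyond grid bookkeeping).
#' @param folds number of cross-validation folds (default 5).
#' @param split_fraction fraction of rows assigned to the training half.
#' @param seed integer seed driving the half-split and fold assignment.
#' @return an object of class `model_config`.
#' @export
model_config <- function(kernel = c("rbf", "linear"),
                         C_grid = 2^seq(-5, 15, by = 2),
                         gamma_grid = 2^seq(-15, 3, by = 2),
                         folds = 5, split_fraction = 0.5, seed = 1) {
  kernel <- match.arg(kernel)
  if (!length(C_grid) || any(C_grid <= 0))
    stop("`C_grid` must contain positive values")
  if (!length(gamma_grid) || any(gamma_grid <= 0))
    stop("`gamma_grid` must contain positive values")
  if (folds < 2) stop("`folds` must be at least 2")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("`split_fraction` must be in (0, 1)")
  structure(
    list(kernel = kernel, C_grid = C_grid, gamma_grid = gamma_grid,
         folds = as.integer(folds), split_fraction = split_fraction,
         seed = as.integer(seed)),
    class = "model_config")
}
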