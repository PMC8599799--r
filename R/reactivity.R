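#' Convert aligned-read 5' ends into RT-stop counts
#'
#' Reverse transcription terminates one nucleotide 3' of a chemical adduct, so
#' a read whose 5'-most aligned base sits at 0-based position `p` contributes
#' one stop at `p - 1`.  Reads starting at position 0 have no upstream base
#' and are discarded.
#'
#' @param read_5prime_positions integer vector of 0-based 5'-end positions.
#' @param transcript_length transcript length.
#' @return numeric vector of per-position stop counts (length
#'   `transcript_length`).
#' @export
stops_from_read_ends <- function(read_5prime_positions, transcript_length) {
  p <- as.integer(read_5prime_positions)
  if (length(p) && (any(p < 0) || any(p >= transcript_length)))
    stop("read positions must lie in [0, transcript_length)")
  # stop position p - 1 (0-based) is vector index p (1-based)
  tabulate(p[p >= 1L], nbins = transcript_length)
}

#' Per-position RT-stop enrichment score
#'
#' Contrasts a probe-treated library against a no-probe control.  With the
#' library-size factor `f = treatment$total_mapped / control$total_mapped`
#' applied to the control counts `B` and densities `D`, the raw score at
#' position `i` is
#' \deqn{s_i = \frac{T_i - \alpha f B_i}{\max(f D_i, \epsilon)}}
#' floored at zero.  Positions failing the (default-off) coverage filters
#' `T_i < T_min` or `f D_i < t_min` are reported `NA`.
#'
#' @param treatment [stop_count_track()] for the probe-treated library.
#' @param control [stop_count_track()] for the control library (carries the
#'   base density used in the denominator).
#' @param params a [scoring_params()] object.
#' @return numeric vector of non-negative raw scores with `NA` at filtered
#'   positions.
#' @export
enrichment_score <- function(treatment, control, params = scoring_params()) {
  stopifnot(inherits(treatment, "stop_count_track"),
            inherits(control, "stop_count_track"),
            inherits(params, "scoring_params"))
  if (treatment$transcript_id != control$transcript_id)
    stop("treatment and control are for different transcripts")
  if (length(treatment$stops) != length(control$stops))
    stop("treatment and control track lengths differ")
  if (identical(treatment$reagent, "control"))
    stop("`treatment` must be a probe-treated track, not a control")
  f <- treatment$total_mapped / control$total_mapped
  B <- f * control$stops
  D <- f * control$density
  s <- (treatment$stops - params$alpha * B) / pmax(D, params$epsilon)
  s[D < params$min_background_density |
      treatment$stops < params$min_hit_coverage] <- NA_real_
  pmax(s, 0)
}

# Mean of the positive values between the winsor_lo and winsor_hi percentile
# bounds (type-7 quantiles); the per-transcript normalization scale.
normalization_scale <- function(positive, params) {
  bounds <- quantile(positive, c(params$winsor_lo, params$winsor_hi) / 100,
                     names = FALSE)
  sel <- positive[positive >= bounds[1] & positive <= bounds[2]]
  if (!length(sel)) return(bounds[2])
  mean(sel)
}

#' Normalize raw enrichment scores to a [0, 1] reactivity profile
#'
#' Per transcript, raw scores are divided by the mean of the positive scores
#' lying between the `winsor_lo` and `winsor_hi` percentiles, then clamped to
#' `[0, 1]`.  All-`NA` or all-zero input passes through unchanged.
#'
#' @param raw_scores non-negative raw scores (`NA` allowed), e.g. from
#'   [enrichment_score()].
#' @param params a [scoring_params()] carrying the percentile bounds.
#' @param transcript_id,reagent,condition metadata for the returned profile.
#' @return a [reactivity_profile()].
#' @export
normalize_profile <- function(raw_scores, params = scoring_params(),
                              transcript_id = "tx",
                              reagent = c("flexibility", "accessibility"),
                              condition = c("in_cell", "in_vitro")) {
  raw <- as.numeric(raw_scores)
  if (any(raw < 0, na.rm = TRUE))
    stop("raw scores must be non-negative")
  positive <- raw[!is.na(raw) & raw > 0]
  if (!length(positive))
    return(reactivity_profile(transcript_id, raw, reagent = reagent,
                              condition = condition))
  scores <- pmin(pmax(raw / normalization_scale(positive, params), 0), 1)
  reactivity_profile(transcript_id, scores, reagent = reagent,
                     condition = condition)
}

#' Score one transcript end to end
#'
#' Convenience wrapper: [enrichment_score()] followed by
#' [normalize_profile()], inheriting metadata from the treatment track.
#'
#' @inheritParams enrichment_score
#' @return a [reactivity_profile()].
#' @export
score_track <- function(treatment, control, params = scoring_params()) {
  raw <- enrichment_score(treatment, control, params)
  normalize_profile(raw, params, transcript_id = treatment$transcript_id,
                    reagent = treatment$reagent,
                    condition = treatment$condition)
}

#' In-cell minus in-vitro reactivity difference (VTD)
#'
#' Negative values flag positions less reactive inside cells than in
#' protein-free refolded RNA, the signature of protein footprints.
#'
#' @param in_cell,in_vitro [reactivity_profile()] objects for the same
#'   transcript and reagent in the two conditions.
#' @return a [vtd_track()]; `NA` wherever either input is `NA`.
#' @export
vtd <- function(in_cell, in_vitro) {
  stopifnot(inherits(in_cell, "reactivity_profile"),
            inherits(in_vitro, "reactivity_profile"))
  if (in_cell$transcript_id != in_vitro$transcript_id)
    stop("profiles are for different transcripts")
  if (in_cell$reagent != in_vitro$reagent)
    stop("profiles are for different reagents")
  if (in_cell$condition != "in_cell" || in_vitro$condition != "in_vitro")
    stop("arguments must be the in-cell and in-vitro profiles, in that order")
  vtd_track(in_cell$transcript_id, in_cell$reagent,
            in_cell$scores - in_vitro$scores)
}

#' Mean VTD per hexamer across a transcript set
#'
#' Every hexamer occurrence whose six positions are all non-`NA` contributes
#' the mean VTD over those positions; occurrences containing `NA` are
#' skipped.  Hexamers with fewer than `min_occurrences` complete occurrences
#' are omitted.  Hexamers are reported in the RNA alphabet.
#'
#' @param vtd_tracks named list of [vtd_track()] objects keyed by transcript
#'   id.
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param min_occurrences minimum complete occurrences for a hexamer to be
#'   reported.
#' @return data frame with columns `hexamer`, `n`, `mean_vtd`, sorted by
#'   `mean_vtd`.
#' @export
hexamer_vtd <- function(vtd_tracks, transcripts, min_occurrences = 10) {
  k <- 6L
  per_tx <- lapply(names(vtd_tracks), function(id) {
    d <- vtd_tracks[[id]]$diffs
    len <- length(d)
    if (len < k) return(NULL)
    seq_chr <- as.character(transcripts[[id]])
    starts <- seq_len(len - k + 1L)
    # rolling sums of values and NA indicators over windows of width k
    dz <- ifelse(is.na(d), 0, d)
    cs <- cumsum(c(0, dz))
    cn <- cumsum(c(0, as.integer(is.na(d))))
    wsum <- cs[starts + k] - cs[starts]
    wna <- cn[starts + k] - cn[starts]
    hex <- substring(seq_chr, starts, starts + k - 1L)
    keep <- wna == 0L & !grepl("N", hex, fixed = TRUE)
    if (!any(keep)) return(NULL)
    data.frame(hexamer = hex[keep], occ_mean = wsum[keep] / k)
  })
  tab <- do.call(rbind, per_tx)
  if (is.null(tab) || !nrow(tab))
    return(data.frame(hexamer = character(), n = integer(),
                      mean_vtd = numeric()))
  agg <- aggregate(occ_mean ~ hexamer, tab,
                   function(v) c(n = length(v), mean = mean(v)))
  out <- data.frame(hexamer = chartr("T", "U", agg$hexamer),
                    n = as.integer(agg$occ_mean[, "n"]),
                    mean_vtd = agg$occ_mean[, "mean"])
  out <- out[out$n >= min_occurrences, , drop = FALSE]
  out <- out[order(out$mean_vtd), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Anchor-aligned mean reactivity metaprofile
#'
#' Averages profiles around anchor positions (e.g. start codons or PAS
#' motifs).  Windows truncated at transcript ends contribute only their
#' existing offsets; offsets with zero observations are `NA`.
#'
#' @param profiles named list of [reactivity_profile()] (or [vtd_track()])
#'   objects keyed by transcript id.
#' @param anchors data frame with columns `transcript_id` and `position`
#'   (0-based anchor position, offset 0 of the metaprofile).
#' @param flank_up,flank_down number of positions included upstream and
#'   downstream of the anchor.
#' @return data frame with columns `offset`, `mean_score`, `n`.
#' @export
metaprofile <- function(profiles, anchors, flank_up = 20, flank_down = 20) {
  offsets <- seq(-flank_up, flank_down)
  sums <- numeric(length(offsets))
  ns <- integer(length(offsets))
  for (i in seq_len(nrow(anchors))) {
    p <- profiles[[anchors$transcript_id[i]]]
    if (is.null(p)) stop("no profile for transcript ", anchors$transcript_id[i])
    scores <- if (inherits(p, "vtd_track")) p$diffs else p$scores
    len <- length(scores)
    pos <- anchors$position[i]
    if (pos < 0 || pos >= len)
      stop("anchor outside transcript: ", anchors$transcript_id[i])
    idx <- pos + offsets           # 0-based positions
    inside <- which(idx >= 0 & idx < len)
    vals <- scores[idx[inside] + 1L]
    slot <- inside[!is.na(vals)]
    sums[slot] <- sums[slot] + vals[!is.na(vals)]
    ns[slot] <- ns[slot] + 1L
  }
  data.frame(offset = offsets,
             mean_score = ifelse(ns > 0, sums / pmax(ns, 1L), NA_real_),
             n = ns)
}
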