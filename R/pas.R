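#' Pile up 3'-end positions of polyA-site sequencing reads
#'
#' @param end3 integer vector of 0-based read 3'-end (cleavage-junction)
#'   positions on one transcript.
#' @param transcript_length transcript length.
#' @return numeric vector of per-position read counts.
#' @export
pileup_3prime <- function(end3, transcript_length) {
  p <- as.integer(end3)
  if (length(p) && (any(p < 0) || any(p >= transcript_length)))
    stop("read 3'-end positions must lie in [0, transcript_length)")
  tabulate(p + 1L, nbins = transcript_length)
}

#' Call polyA sites from a 3'-end read pileup
#'
#' Positions with at least `min_reads` reads are clustered: consecutive
#' qualifying positions no more than `cluster_distance` nt apart join one
#' cluster.  Each cluster is reported at its modal position (ties resolved
#' toward the 3' end, mirroring heterogeneous cleavage) with the summed read
#' count of its member positions.
#'
#' @param pileup per-position read counts (see [pileup_3prime()]).
#' @param min_reads minimum reads for a position to seed/join a cluster.
#' @param cluster_distance maximum gap (nt) merged into one cluster.
#' @return data frame with columns `cleavage_pos` (0-based) and
#'   `read_count`, ordered 5' to 3'.
#' @export
call_pas_sites <- function(pileup, min_reads = 5, cluster_distance = 10) {
  if (min_reads < 1) stop("`min_reads` must be at least 1")
  qual <- which(pileup >= min_reads)     # 1-based indices
  if (!length(qual))
    return(data.frame(cleavage_pos = integer(), read_count = numeric()))
  cluster <- cumsum(c(1, diff(qual) > cluster_distance))
  out <- lapply(split(qual, cluster), function(members) {
    counts <- pileup[members]
    modal <- members[counts == max(counts)]
    data.frame(cleavage_pos = max(modal) - 1L, read_count = sum(counts))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Anchor called polyA sites to an upstream AAUAAA signal
#'
#' Scans upstream of each cleavage position for the canonical
#' polyadenylation signal whose 3' end lies between `d_min` and `d_max` nt
#' upstream of the cleavage site, choosing the closest candidate.  Sites
#' with no signal in the window stay unassigned.  The zero point used by
#' metaprofiles and windows is `signal_start + 2`, the uridine of AAUAAA.
#'
#' @param sites data frame from [call_pas_sites()] (columns `cleavage_pos`,
#'   `read_count`).
#' @param sequence the transcript sequence (character or
#'   [Biostrings::DNAString]).
#' @param d_min,d_max allowed distance (nt) from the signal 3' end to the
#'   cleavage position.
#' @param motif the signal motif (default AAUAAA).
#' @return `sites` with added columns `signal_start` (0-based or `NA`),
#'   `signal_distance` (`cleavage_pos - (signal_start + 6)` or `NA`) and
#'   `activity` (initialized `"unassigned"`).
#' @export
anchor_to_signal <- function(sites, sequence, d_min = 10, d_max = 40,
                             motif = "AAUAAA") {
  occ <- scan_motif(sequence, motif)
  sig_end <- occ + nchar(motif)
  sites$signal_start <- NA_integer_
  sites$signal_distance <- NA_integer_
  for (i in seq_len(nrow(sites))) {
    d <- sites$cleavage_pos[i] - sig_end
    ok <- which(d >= d_min & d <= d_max)
    if (length(ok)) {
      best <- ok[which.min(d[ok])]
      sites$signal_start[i] <- occ[best]
      sites$signal_distance[i] <- d[best]
    }
  }
  sites$activity <- "unassigned"
  sites
}

#' Label anchored polyA sites as active or inactive by read depth
#'
#' Signal-anchored sites with read counts at or above the `high_quantile`
#' of anchored-site counts are `active`; at or below the `low_quantile`,
#' `inactive`; the middle band stays `unassigned` and is excluded from
#' classifier training.  When all counts are equal the two quantiles
#' coincide and every anchored site is labeled `active` (count >= the upper
#' bound).
#'
#' @param sites data frame from [anchor_to_signal()].
#' @param high_quantile,low_quantile quantile bounds on the anchored sites'
#'   read counts.
#' @return `sites` with the `activity` column filled in.
#' @export
classify_activity <- function(sites, high_quantile = 0.75,
                              low_quantile = 0.25) {
  assigned <- which(!is.na(sites$signal_start))
  if (!length(assigned)) stop("no signal-anchored sites to classify")
  counts <- sites$read_count[assigned]
  hi <- quantile(counts, high_quantile, names = FALSE)
  lo <- quantile(counts, low_quantile, names = FALSE)
  act <- rep("unassigned", length(assigned))
  act[counts >= hi] <- "active"
  act[counts <= lo & counts < hi] <- "inactive"
  sites$activity[assigned] <- act
  sites
}

#' Call, anchor and classify polyA sites across a transcript set
#'
#' @param pas_reads data frame with columns `transcript_id` and `end3`
#'   (0-based read 3'-end positions).
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param min_reads,cluster_distance see [call_pas_sites()].
#' @param d_min,d_max see [anchor_to_signal()].
#' @param high_quantile,low_quantile see [classify_activity()]; the quantile
#'   strata are computed over all anchored sites transcriptome-wide.
#' @return data frame of sites with a `transcript_id` column, plus the
#'   per-transcript pileups as attribute `"pileups"`.
#' @export
call_pas_sites_set <- function(pas_reads, transcripts, min_reads = 5,
                               cluster_distance = 10, d_min = 10, d_max = 40,
                               high_quantile = 0.75, low_quantile = 0.25) {
  pileups <- lapply(names(transcripts), function(id) {
    len <- Biostrings::width(transcripts)[match(id, names(transcripts))]
    pileup_3prime(pas_reads$end3[pas_reads$transcript_id == id], len)
  })
  names(pileups) <- names(transcripts)
  per_tx <- lapply(names(transcripts), function(id) {
    s <- call_pas_sites(pileups[[id]], min_reads, cluster_distance)
    if (!nrow(s)) return(NULL)
    s <- anchor_to_signal(s, transcripts[[id]], d_min, d_max)
    cbind(transcript_id = id, s, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, per_tx)
  if (is.null(sites))
    sites <- data.frame(transcript_id = character(), cleavage_pos = integer(),
                        read_count = numeric(), signal_start = integer(),
                        signal_distance = integer(), activity = character())
  if (any(!is.na(sites$signal_start)))
    sites <- classify_activity(sites, high_quantile, low_quantile)
  rownames(sites) <- NULL
  attr(sites, "pileups") <- pileups
  sites
}

#' Build the 46-nt PAS feature matrix
#'
#' Positive rows are the signal positions of active polyA sites; negative
#' rows are AAUAAA occurrences not assigned to any called site.  Windows
#' span `[signal_start - flank, signal_start + 6 + flank)` (width 46 at the
#' default flank of 20); the `NA`/boundary discard rules of
#' [assemble_feature_matrix()] apply.
#'
#' @param profiles_by_reagent named list: reagent -> named list of
#'   [reactivity_profile()] keyed by transcript id.
#' @param positive_signals data frame (`transcript_id`, `start`) of active
#'   sites' signal starts.
#' @param negative_signals data frame (`transcript_id`, `start`) of
#'   unassigned motif occurrences.
#' @param flank flanking width (default 20).
#' @param mode see [assemble_feature_matrix()].
#' @return a [feature_matrix()].
#' @export
pas_feature_windows <- function(profiles_by_reagent, positive_signals,
                                negative_signals, flank = 20,
                                mode = "combined") {
  mk <- function(df, label) {
    if (!nrow(df))
      return(data.frame(transcript_id = character(), start = integer(),
                        motif = character(), label = character()))
    data.frame(transcript_id = df$transcript_id, start = df$start,
               motif = "AAUAAA", label = label, stringsAsFactors = FALSE)
  }
  pos <- mk(positive_signals, "positive")
  neg <- mk(negative_signals, "negative")
  assemble_feature_matrix(rbind(pos, neg), profiles_by_reagent,
                          motif_length = 6L, flank = flank, mode = mode)
}

#' Cumulative read density around the polyA signal uridine
#'
#' Sums 3'-end read counts at each offset relative to the signal zero point
#' (`signal_start + 2`, the U of AAUAAA) over all assigned sites.
#'
#' @param pileups named list of per-transcript pileups (e.g. the
#'   `"pileups"` attribute of [call_pas_sites_set()]).
#' @param sites data frame of anchored sites with `transcript_id` and
#'   `signal_start`.
#' @param flank_up,flank_down offsets included around the zero point.
#' @return data frame with columns `offset` and `read_count`.
#' @export
pas_metaprofile <- function(pileups, sites, flank_up = 50, flank_down = 80) {
  sites <- sites[!is.na(sites$signal_start), , drop = FALSE]
  offsets <- seq(-flank_up, flank_down)
  total <- numeric(length(offsets))
  for (i in seq_len(nrow(sites))) {
    pu <- pileups[[sites$transcript_id[i]]]
    center <- sites$signal_start[i] + 2L
    idx <- center + offsets
    inside <- which(idx >= 0 & idx < length(pu))
    total[inside] <- total[inside] + pu[idx[inside] + 1L]
  }
  data.frame(offset = offsets, read_count = total)
}
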