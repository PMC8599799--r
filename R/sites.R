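#' Exact motif scan on the sense strand
#'
#' Returns all (possibly overlapping) exact matches of `motif` in a
#' transcript sequence, as 0-based start positions in ascending order.
#' Motifs may be given in the RNA alphabet (U is rewritten to T).
#'
#' @param sequence a [Biostrings::DNAString], one element of a
#'   [Biostrings::DNAStringSet], or a character scalar.
#' @param motif motif string over A/C/G/U or A/C/G/T; treated as an exact
#'   string (no IUPAC degeneracy).
#' @return integer vector of 0-based start positions.
#' @export
scan_motif <- function(sequence, motif) {
  if (!nchar(motif)) stop("`motif` must be non-empty")
  motif <- chartr("U", "T", toupper(motif))
  if (is.character(sequence))
    sequence <- Biostrings::DNAString(chartr("U", "T", toupper(sequence)))
  m <- Biostrings::matchPattern(motif, sequence)
  as.integer(Biostrings::start(m)) - 1L
}

#' Scan a motif across a transcript set
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param motif motif string (RNA or DNA alphabet).
#' @return data frame with columns `transcript_id` and `start` (0-based).
#' @export
scan_motif_set <- function(transcripts, motif) {
  hits <- lapply(names(transcripts), function(id) {
    starts <- scan_motif(transcripts[[id]], motif)
    if (!length(starts)) return(NULL)
    data.frame(transcript_id = id, start = starts, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, hits)
  if (is.null(tab))
    tab <- data.frame(transcript_id = character(), start = integer())
  tab
}

# TRUE for occurrences whose motif span has >= 1 base inside some peak
overlaps_peak <- function(occ, peaks, m, buffer = 0) {
  if (!nrow(occ)) return(logical(0))
  hit <- logical(nrow(occ))
  for (tx in unique(occ$transcript_id)) {
    oi <- which(occ$transcript_id == tx)
    pk <- peaks[peaks$transcript_id == tx, , drop = FALSE]
    if (!nrow(pk)) next
    for (i in oi) {
      s <- occ$start[i]
      hit[i] <- any(s < pk$end + buffer & s + m > pk$start - buffer)
    }
  }
  hit
}

#' Build positive motif sites from peak annotations
#'
#' For each peak, every motif occurrence overlapping the peak (at least one
#' motif base inside the half-open peak interval) becomes a positive site.
#' Peaks containing no occurrence are dropped and counted.  Duplicate
#' `(transcript, start)` sites arising from overlapping peaks are collapsed.
#'
#' @param peaks data frame of peak intervals (see [read_intervals()]),
#'   already projected onto transcript coordinates.
#' @param motif the protein's binding motif (RNA or DNA alphabet).
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param first_per_peak if `TRUE`, keep only the 5'-most occurrence per
#'   peak instead of all of them.
#' @return data frame of positive sites (`transcript_id`, `start`, `motif`,
#'   `label`, `peak_name`), with attribute `discarded_peaks` counting
#'   motif-less peaks.
#' @export
build_positive_sites <- function(peaks, motif, transcripts,
                                 first_per_peak = FALSE) {
  m <- nchar(motif)
  occ <- scan_motif_set(transcripts, motif)
  rows <- list()
  discarded <- 0L
  for (i in seq_len(nrow(peaks))) {
    tx <- peaks$transcript_id[i]
    starts <- occ$start[occ$transcript_id == tx]
    inside <- starts[starts < peaks$end[i] & starts + m > peaks$start[i]]
    if (!length(inside)) {
      discarded <- discarded + 1L
      next
    }
    if (first_per_peak) inside <- inside[1]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tx, start = inside, motif = motif,
      label = "positive",
      peak_name = if ("name" %in% names(peaks)) peaks$name[i] else "",
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, rows)
  if (is.null(sites))
    sites <- data.frame(transcript_id = character(), start = integer(),
                        motif = character(), label = character(),
                        peak_name = character())
  sites <- sites[!duplicated(sites[, c("transcript_id", "start")]), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "discarded_peaks") <- discarded
  sites
}

#' Sample negative motif sites from peak-free occurrences
#'
#' The negative pool contains motif occurrences whose full span (plus an
#' optional buffer) is disjoint from every peak.  Exactly
#' `min(n_positives, pool size)` sites are sampled without replacement; a
#' warning is raised when the pool is too small to match the positives.
#'
#' @param occurrences data frame of all motif occurrences
#'   (`transcript_id`, `start`), e.g. from [scan_motif_set()].
#' @param peaks peak data frame for the same protein.
#' @param motif the motif string (its length defines the occupied span).
#' @param n_positives number of sites to draw.
#' @param seed optional integer seed for reproducible sampling.
#' @param buffer extra peak-free margin (nt) required around each negative.
#' @return data frame of negative sites (`transcript_id`, `start`, `motif`,
#'   `label`).
#' @export
sample_negative_sites <- function(occurrences, peaks, motif, n_positives,
                                  seed = NULL, buffer = 0) {
  m <- nchar(motif)
  pool <- occurrences[!overlaps_peak(occurrences, peaks, m, buffer), ,
                      drop = FALSE]
  k <- min(n_positives, nrow(pool))
  if (nrow(pool) < n_positives)
    warning(sprintf("negative pool (%d) smaller than positives (%d)",
                    nrow(pool), n_positives))
  pick <- if (k == 0) integer(0) else if (is.null(seed))
    sample(nrow(pool), k) else
    withr::with_seed(seed, sample(nrow(pool), k))
  out <- pool[sort(pick), c("transcript_id", "start"), drop = FALSE]
  if (nrow(out)) {
    out$motif <- motif
    out$label <- "negative"
  } else {
    out <- data.frame(transcript_id = character(), start = integer(),
                      motif = character(), label = character())
  }
  rownames(out) <- NULL
  out
}

#' Extract a fixed-width reactivity window at a motif site
#'
#' The window covers `[start - flank, start + motif_length + flank)`; element
#' `j` of the result is transcript position `start - flank + j - 1`.  Windows
#' leaving the transcript or containing any `NA` score are discarded
#' (returned as `NULL`).
#'
#' @param profile a [reactivity_profile()].
#' @param start 0-based motif start position.
#' @param motif_length motif length in nt.
#' @param flank flanking width on each side (5 for the RBP analysis, 20 for
#'   the PAS analysis).
#' @return numeric vector of length `motif_length + 2 * flank`, or `NULL`
#'   (discard).
#' @export
extract_window <- function(profile, start, motif_length, flank) {
  lo <- start - flank
  hi <- start + motif_length + flank     # half-open
  if (lo < 0 || hi > length(profile$scores)) return(NULL)
  v <- profile$scores[(lo + 1L):hi]
  if (anyNA(v)) return(NULL)
  v
}

window_colnames <- function(reagent, motif_length, flank) {
  offs <- seq(-flank, motif_length + flank - 1L)
  paste0(reagent, "_", ifelse(offs >= 0, paste0("+", offs), offs))
}

#' Assemble a labeled feature matrix of reactivity windows
#'
#' Extracts one window per site per reagent and binds them into the matrix
#' consumed by the classifier.  In `"combined"` mode only sites surviving
#' window extraction in every reagent are kept and the per-reagent windows
#' are concatenated row-wise (two reagents of width `w` give rows of width
#' `2 w`).  In `"single_reagent"` mode only the first profile set is used.
#'
#' @param sites data frame of labeled sites (`transcript_id`, `start`,
#'   `label`).
#' @param profiles_by_reagent named list: reagent -> named list of
#'   [reactivity_profile()] keyed by transcript id.
#' @param motif_length,flank window geometry (total width
#'   `motif_length + 2 * flank` per reagent).
#' @param mode `"combined"` or `"single_reagent"`.
#' @return a [feature_matrix()]; its `discarded` log records each dropped
#'   site with the reagent that caused the discard.
#' @export
assemble_feature_matrix <- function(sites, profiles_by_reagent, motif_length,
                                    flank, mode = c("combined", "single_reagent")) {
  mode <- match.arg(mode)
  reagents <- names(profiles_by_reagent)
  if (mode == "single_reagent") reagents <- reagents[1]
  n <- nrow(sites)
  width <- motif_length + 2L * flank
  mats <- list()
  keep <- rep(TRUE, n)
  reasons <- rep(NA_character_, n)
  for (rg in reagents) {
    profs <- profiles_by_reagent[[rg]]
    mat <- matrix(NA_real_, n, width,
                  dimnames = list(NULL, window_colnames(rg, motif_length, flank)))
    for (i in seq_len(n)) {
      p <- profs[[sites$transcript_id[i]]]
      if (is.null(p)) stop("no ", rg, " profile for transcript ",
                           sites$transcript_id[i])
      w <- extract_window(p, sites$start[i], motif_length, flank)
      if (is.null(w)) {
        keep[i] <- FALSE
        if (is.na(reasons[i])) reasons[i] <- rg
      } else {
        mat[i, ] <- w
      }
    }
    mats[[rg]] <- mat
  }
  if (!any(keep)) {
    counts <- table(factor(reasons[!keep], levels = reagents))
    stop("no sites survive window extraction (discards by reagent: ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")")
  }
  feats <- do.call(cbind, lapply(mats, function(m) m[keep, , drop = FALSE]))
  discarded <- cbind(sites[!keep, , drop = FALSE],
                     reason = reasons[!keep])
  rownames(discarded) <- NULL
  feature_matrix(feats, sites$label[keep], sites[keep, , drop = FALSE],
                 discarded)
}

#' Restrict transcripts to sufficiently expressed ones
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param rpkm named numeric vector (or data frame with columns
#'   `transcript_id` and `rpkm`) of expression estimates.
#' @param min_rpkm inclusive expression threshold (default 5 RPKM).
#' @return the subset of `transcripts` with `rpkm >= min_rpkm`; transcripts
#'   missing from the table are dropped with a warning.
#' @export
filter_rbp_targets <- function(transcripts, rpkm, min_rpkm = 5) {
  if (is.data.frame(rpkm))
    rpkm <- setNames(rpkm$rpkm, rpkm$transcript_id)
  missing <- setdiff(names(transcripts), names(rpkm))
  if (length(missing))
    warning(length(missing), " transcript(s) missing from the RPKM table; dropped")
  keep <- intersect(names(transcripts), names(rpkm))
  keep <- keep[rpkm[keep] >= min_rpkm]
  transcripts[keep]
}
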