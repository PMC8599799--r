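#' Read transcript sequences from FASTA
#'
#' Sequences are normalized to the DNA alphabet internally (U is rewritten to
#' T), so transcriptome FASTA files in either alphabet are accepted.  All
#' downstream coordinates are 0-based, half-open, on the sense strand.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return a named [Biostrings::DNAStringSet] with one entry per record.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("invalid sequence characters in record(s): ",
         paste(names(raw)[bad], collapse = ", "))
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate transcript id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read BED-like peak intervals in transcript coordinates
#'
#' Intervals are 0-based, half-open, exactly as in BED.  When a transcript set
#' is supplied, intervals extending past a transcript end are rejected and
#' intervals on unknown transcripts are handled per `on_unknown`.
#'
#' @param path path to a BED3+ file (`id`, `start`, `end`, optionally `name`
#'   and `score`).
#' @param transcripts optional [Biostrings::DNAStringSet] used for coordinate
#'   validation.
#' @param on_unknown what to do with intervals on transcripts absent from
#'   `transcripts`: `"warn"` (drop with a warning), `"error"` or `"ignore"`
#'   (drop silently).
#' @return a data frame with columns `transcript_id`, `start`, `end`, `name`,
#'   `score`.
#' @export
read_intervals <- function(path, transcripts = NULL,
                           on_unknown = c("warn", "error", "ignore")) {
  on_unknown <- match.arg(on_unknown)
  if (!file.exists(path)) stop("interval file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  peaks <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) ifelse(is.na(gr$name), "", gr$name) else "",
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    stringsAsFactors = FALSE)
  if (any(peaks$start < 0))
    stop("negative interval start in ", path)
  if (any(peaks$start >= peaks$end))
    stop("intervals must satisfy start < end (half-open, 0-based)")
  if (!is.null(transcripts)) {
    known <- peaks$transcript_id %in% names(transcripts)
    if (!all(known)) {
      msg <- paste0("intervals on unknown transcript(s): ",
                    paste(unique(peaks$transcript_id[!known]), collapse = ", "))
      if (on_unknown == "error") stop(msg)
      if (on_unknown == "warn") warning(msg)
      peaks <- peaks[known, , drop = FALSE]
    }
    lens <- Biostrings::width(transcripts)[match(peaks$transcript_id,
                                                 names(transcripts))]
    if (any(peaks$end > lens))
      stop("interval(s) extend past transcript end")
  }
  rownames(peaks) <- NULL
  peaks
}

#' Write peak/site intervals as BED6
#'
#' @param x data frame with columns `transcript_id`, `start`, `end` and
#'   optionally `name`, `score`.
#' @param path output path.
#' @export
write_intervals <- function(x, path) {
  bed <- data.frame(
    chrom = x$transcript_id,
    start = format(x$start, scientific = FALSE, trim = TRUE),
    end = format(x$end, scientific = FALSE, trim = TRUE),
    name = if ("name" %in% names(x)) x$name else ".",
    score = if ("score" %in% names(x)) x$score else 0,
    strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-position RT-stop count table
#'
#' The TSV must carry a header with columns `transcript_id`, `position`
#' (0-based), `stop_count` and `base_density`; one condition/reagent per file,
#' supplied as metadata arguments.  Positions absent from the table are filled
#' with zero counts and zero density, so every track densely covers its
#' transcript.
#'
#' @param path path to the TSV file.
#' @param transcripts named [Biostrings::DNAStringSet] defining transcript
#'   lengths.
#' @param condition,reagent library metadata recorded on every track.
#' @param total_mapped optional library size for scaling; defaults to the
#'   file-wide total stop count (floored at 1).
#' @return a named list of [stop_count_track()] objects, one per transcript in
#'   `transcripts`.
#' @export
read_stop_counts <- function(path, transcripts,
                             condition = c("in_cell", "in_vitro"),
                             reagent = c("flexibility", "accessibility", "control"),
                             total_mapped = NULL) {
  condition <- match.arg(condition)
  reagent <- match.arg(reagent)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "stop_count", "base_density")
  if (!all(need %in% names(tab)))
    stop("stop-count table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab)) {
    if (any(tab$stop_count < 0) || any(tab$base_density < 0))
      stop("negative counts in ", path)
    unknown <- setdiff(unique(tab$transcript_id), names(transcripts))
    if (length(unknown))
      stop("counts for unknown transcript(s): ", paste(unknown, collapse = ", "))
    lens <- Biostrings::width(transcripts)[match(tab$transcript_id,
                                                 names(transcripts))]
    if (any(tab$position < 0) || any(tab$position >= lens))
      stop("position outside [0, transcript length) in ", path)
  }
  if (is.null(total_mapped)) total_mapped <- max(sum(tab$stop_count), 1)
  out <- lapply(names(transcripts), function(id) {
    len <- Biostrings::width(transcripts)[match(id, names(transcripts))]
    stops <- numeric(len)
    density <- numeric(len)
    rows <- tab[tab$transcript_id == id, , drop = FALSE]
    if (nrow(rows)) {
      stops[rows$position + 1L] <- rows$stop_count
      density[rows$position + 1L] <- rows$base_density
    }
    stop_count_track(id, stops, density, condition = condition,
                     reagent = reagent, total_mapped = total_mapped)
  })
  names(out) <- names(transcripts)
  out
}

#' Write RT-stop count tracks as a TSV table
#'
#' Only positions with a non-zero stop count or density are written; the
#' reader restores the dense form.
#'
#' @param tracks named list of [stop_count_track()] objects.
#' @param path output path.
#' @export
write_stop_counts <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    keep <- which(tr$stops > 0 | tr$density > 0)
    if (!length(keep)) return(NULL)
    data.frame(transcript_id = tr$transcript_id, position = keep - 1L,
               stop_count = tr$stops[keep], base_density = tr$density[keep])
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(transcript_id = character(), position = integer(),
                      stop_count = numeric(), base_density = numeric())
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write reactivity (or VTD) tracks as bedGraph
#'
#' Contiguous runs of equal score are merged into single 0-based half-open
#' intervals; `NA` positions are omitted.  A write-then-read round trip
#' restores scores to at least six decimal places.
#'
#' @param profiles a single [reactivity_profile()]/[vtd_track()] or a list of
#'   them.
#' @param path output path.
#' @export
write_reactivity_bedgraph <- function(profiles, path) {
  if (inherits(profiles, "reactivity_profile") || inherits(profiles, "vtd_track"))
    profiles <- list(profiles)
  runs <- lapply(profiles, function(p) {
    scores <- if (inherits(p, "vtd_track")) p$diffs else p$scores
    r <- rle(ifelse(is.na(scores), NA, round(scores, 6)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths            # 0-based starts
    keep <- !is.na(r$values)
    if (!any(keep)) return(NULL)
    data.frame(transcript_id = p$transcript_id, start = starts[keep],
               end = ends[keep], score = r$values[keep])
  })
  tab <- do.call(rbind, runs)
  if (is.null(tab)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    tab$transcript_id,
    IRanges::IRanges(start = tab$start + 1L, end = tab$end),
    score = tab$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph reactivity track back into profiles
#'
#' @param path bedGraph file written by [write_reactivity_bedgraph()] (or any
#'   0-based half-open bedGraph in transcript coordinates).
#' @param transcripts named [Biostrings::DNAStringSet]; positions not covered
#'   by any interval become `NA`.
#' @param reagent,condition metadata recorded on every profile.
#' @return a named list of [reactivity_profile()] objects over `transcripts`.
#' @export
read_reactivity_bedgraph <- function(path, transcripts,
                                     reagent = c("flexibility", "accessibility"),
                                     condition = c("in_cell", "in_vitro")) {
  reagent <- match.arg(reagent)
  condition <- match.arg(condition)
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  empty <- file.size(path) == 0
  gr <- if (empty) GenomicRanges::GRanges() else
    rtracklayer::import(path, format = "bedGraph")
  tab <- data.frame(
    transcript_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = if (length(gr)) as.numeric(gr$score) else numeric())
  out <- lapply(names(transcripts), function(id) {
    len <- Biostrings::width(transcripts)[match(id, names(transcripts))]
    scores <- rep(NA_real_, len)
    rows <- tab[tab$transcript_id == id, , drop = FALSE]
    if (nrow(rows)) {
      if (any(rows$end > len)) stop("bedGraph interval past end of ", id)
      for (i in seq_len(nrow(rows)))
        scores[(rows$start[i] + 1L):rows$end[i]] <- rows$score[i]
    }
    reactivity_profile(id, scores, reagent = reagent, condition = condition)
  })
  names(out) <- names(transcripts)
  out
}

#' Write a feature matrix as TSV
#'
#' Columns name the reagent and motif-relative offset (e.g.
#' `accessibility_-5` ... `accessibility_+9`), preceded by the site columns
#' `transcript_id`, `start` and `label`.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @export
write_feature_matrix <- function(fm, path) {
  tab <- cbind(fm$sites[, c("transcript_id", "start")],
               label = as.character(fm$labels),
               as.data.frame(fm$features))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("transcript_id", "start", "label")
  feats <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  feature_matrix(feats, tab$label,
                 tab[, c("transcript_id", "start"), drop = FALSE])
}
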