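#' Parameters of the synthetic probing experiment
#'
#' Defines the generative model used to emulate a transcriptome-wide probing
#' experiment: random transcript sequences with planted protein-binding motif
#' instances (bound and unbound) and polyA signals near 3' ends; smooth
#' per-position accessibility/flexibility ground truth; protein footprints
#' that suppress in-cell reactivity at bound sites only; overdispersed
#' (negative-binomial) stop and density counts with reagent base
#' specificity; peak annotations over bound sites; and polyA-site-seq reads
#' piling up downstream of active signals.
#'
#' @param n_transcripts number of transcripts.
#' @param length_range min/max transcript length (nt), uniform.
#' @param seed master seed; every stage derives its own stream from it.
#' @param coverage mean per-position base density (lambda).
#' @param phi negative-binomial size (overdispersion; Poisson as
#'   `phi -> Inf`).
#' @param beta0 background RT-stop rate per covered base.
#' @param beta1 modification-driven stop rate scale; the stop rate at a
#'   position is `beta0 + beta1 * reactivity * basespec`.
#' @param delta footprint effect in `[0, 1]`: multiplicative suppression of
#'   in-cell reactivity at protected positions.
#' @param channel_balance probability that a bound site's footprint acts on
#'   the accessibility channel (otherwise the flexibility channel), making
#'   the two reagents complementary.
#' @param motif the RBP binding motif planted in sequences (RNA alphabet).
#' @param rbp_name label carried by peaks and sites.
#' @param bound_per_transcript,unbound_per_transcript planted motif
#'   instances per transcript with and without a protein footprint.
#' @param footprint_shoulder,shoulder_weight footprints cover the motif
#'   (weight 1) plus this many shoulder nt at the given weight.
#' @param motif_intrinsic_target,motif_intrinsic_weight every motif
#'   occurrence (bound or not) has its baseline reactivity blended toward
#'   this target with this weight, in both conditions and channels: the
#'   motif is intrinsically accessible/flexible, which is what makes it
#'   bindable, and bound instances are then footprinted on top.
#' @param basespec named list of per-base reactivity weights for each
#'   reagent (DNA alphabet): the accessibility probe strongly prefers A/G,
#'   the flexibility probe mildly prefers A/U.
#' @param peak_jitter maximum random extension (nt) of each peak beyond the
#'   bound motif span.
#' @param pas_active_fraction fraction of planted polyA signals that are
#'   used (receive reads and a CPSF footprint).
#' @param pas_reads_active,pas_reads_inactive mean read counts at active and
#'   inactive planted polyA sites.
#' @param pas_cleavage_range distance (nt) from signal 3' end to the
#'   cleavage position, uniform.
#' @param pas_read_sd per-read jitter (nt, rounded normal) around the
#'   cleavage position.
#' @param pas_decoys_per_transcript planted AAUAAA occurrences far from the
#'   3' end that are never used.
#' @param pas_background_rate per-nt Poisson rate of scattered background
#'   3'-end reads.
#' @return an object of class `simulation_params`.
#' @export
simulation_params <- function(n_transcripts = 250,
                              length_range = c(500, 1500),
                              seed = 1,
                              coverage = 200,
                              phi = 50,
                              beta0 = 0.02,
                              beta1 = 0.2,
                              delta = 0.5,
                              channel_balance = 0.5,
                              motif = "GCAUG",
                              rbp_name = "RBP1",
                              bound_per_transcript = 2,
                              unbound_per_transcript = 2,
                              footprint_shoulder = 2,
                              shoulder_weight = 0.5,
                              motif_intrinsic_target = 0.85,
                              motif_intrinsic_weight = 0.7,
                              basespec = list(
                                accessibility = c(A = 1, C = 0.1, G = 1, T = 0.1),
                                flexibility = c(A = 1, C = 0.6, G = 0.6, T = 1)),
                              peak_jitter = 10,
                              pas_active_fraction = 0.6,
                              pas_reads_active = 50,
                              pas_reads_inactive = 8,
                              pas_cleavage_range = c(15, 25),
                              pas_read_sd = 2,
                              pas_decoys_per_transcript = 1,
                              pas_background_rate = 0.005) {
  p <- as.list(environment())
  if (p$delta < 0 || p$delta > 1) stop("`delta` must be in [0, 1]")
  if (any(c(p$coverage, p$phi, p$beta0, p$beta1) < 0))
    stop("rates must be non-negative")
  if (p$length_range[1] > p$length_range[2] || p$length_range[1] < 200)
    stop("`length_range` must be increasing with minimum >= 200")
  structure(p, class = "simulation_params")
}

# sample one integer uniformly from lo..hi, safe for degenerate ranges
# (sample(n, 1) would draw from 1..n)
sample_range <- function(lo, hi) {
  x <- lo:hi
  x[sample.int(length(x), 1)]
}

# draw k positions from lo..hi pairwise separated by >= sep from each other
# and from `taken`; returns fewer than k if space runs out
draw_separated <- function(k, lo, hi, sep, taken = integer()) {
  chosen <- integer()
  tries <- 0L
  while (length(chosen) < k && tries < 500L) {
    tries <- tries + 1L
    cand <- sample_range(lo, hi)
    if (all(abs(cand - c(chosen, taken)) >= sep)) chosen <- c(chosen, cand)
  }
  chosen
}

#' Simulate transcript sequences with planted elements
#'
#' Generates random sequences and plants, per transcript, bound and unbound
#' RBP-motif instances (pairwise well separated), one polyA signal near the
#' 3' end with its true cleavage position, and decoy polyA signals in the
#' body.  Deterministic given `params$seed`.
#'
#' @param params a [simulation_params()].
#' @return the experiment skeleton: list with `transcripts`
#'   ([Biostrings::DNAStringSet]), `elements` (data frame with
#'   `transcript_id`, `type` in bound_motif/unbound_motif/pas/pas_decoy,
#'   `start`, `channel`, `active`, `cleavage_pos`) and `params`.
#' @export
simulate_transcriptome <- function(params) {
  withr::with_seed(derive_seed(params$seed, "transcriptome"), {
    motif_dna <- chartr("U", "T", toupper(params$motif))
    m <- nchar(motif_dna)
    pas_dna <- "AATAAA"
    seqs <- character(params$n_transcripts)
    rows <- list()
    for (t in seq_len(params$n_transcripts)) {
      id <- sprintf("tx%04d", t)
      L <- sample_range(params$length_range[1], params$length_range[2])
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      sep <- 30L                       # > motif span + maximal peak jitter
      body_hi <- L - 180L
      n_motifs <- params$bound_per_transcript + params$unbound_per_transcript
      taken <- integer()
      motif_pos <- draw_separated(n_motifs, 50L, body_hi, sep)
      taken <- motif_pos
      decoy_pos <- draw_separated(params$pas_decoys_per_transcript, 50L,
                                  body_hi, sep, taken)
      sig_pos <- sample_range(L - 80L, L - 50L)
      is_bound <- seq_along(motif_pos) <= min(params$bound_per_transcript,
                                              length(motif_pos))
      for (j in seq_along(motif_pos))
        s[(motif_pos[j] + 1):(motif_pos[j] + m)] <- strsplit(motif_dna, "")[[1]]
      for (j in seq_along(decoy_pos))
        s[(decoy_pos[j] + 1):(decoy_pos[j] + 6)] <- strsplit(pas_dna, "")[[1]]
      s[(sig_pos + 1):(sig_pos + 6)] <- strsplit(pas_dna, "")[[1]]
      active <- runif(1) < params$pas_active_fraction
      cleave <- sig_pos + 6L +
        sample_range(params$pas_cleavage_range[1], params$pas_cleavage_range[2])
      channel <- ifelse(runif(sum(is_bound)) < params$channel_balance,
                        "accessibility", "flexibility")
      rows[[t]] <- rbind(
        if (any(is_bound)) data.frame(
          transcript_id = id, type = "bound_motif",
          start = motif_pos[is_bound], channel = channel,
          active = NA, cleavage_pos = NA_integer_),
        if (any(!is_bound)) data.frame(
          transcript_id = id, type = "unbound_motif",
          start = motif_pos[!is_bound], channel = NA_character_,
          active = NA, cleavage_pos = NA_integer_),
        data.frame(transcript_id = id, type = "pas", start = sig_pos,
                   channel = NA_character_, active = active,
                   cleavage_pos = cleave),
        if (length(decoy_pos)) data.frame(
          transcript_id = id, type = "pas_decoy", start = decoy_pos,
          channel = NA_character_, active = FALSE,
          cleavage_pos = NA_integer_))
      seqs[t] <- paste(s, collapse = "")
    }
    transcripts <- Biostrings::DNAStringSet(seqs)
    names(transcripts) <- sprintf("tx%04d", seq_len(params$n_transcripts))
    elements <- do.call(rbind, rows)
    rownames(elements) <- NULL
    list(transcripts = transcripts, elements = elements, params = params)
  })
}

smooth_baseline <- function(L, window = 5) {
  x <- runif(L)
  ma <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  ma[is.na(ma)] <- mean(x)               # edge positions
  rng <- range(ma)
  if (diff(rng) == 0) return(rep(0.5, L))
  (ma - rng[1]) / diff(rng)
}

blend <- function(x, target, w) x + w * (target - x)

#' Simulate ground-truth reactivity profiles
#'
#' Baseline accessibility and flexibility are smooth random processes
#' (moving-average window 5 of uniform noise, rescaled to `[0, 1]`); the
#' in-vitro truth equals the baseline.  In-cell truth differs only at
#' protein-bound elements: bound motif sites are suppressed by
#' `delta` on their assigned channel over the motif plus shoulders, and
#' polyA signals receive the accessibility signature of signal recognition
#' (high at the leading two adenosines, low over the UAAA) - a weak
#' sequence-intrinsic component at every planted signal in both conditions
#' and a strong protein-footprint component at active signals in cells only,
#' with a mild in-cell flexibility suppression at active signals.
#'
#' @param params a [simulation_params()].
#' @param skeleton output of [simulate_transcriptome()].
#' @return nested list: `truth[[transcript]][[reagent]][[condition]]` is a
#'   numeric reactivity vector in `[0, 1]`.
#' @export
simulate_truth_profiles <- function(params, skeleton) {
  withr::with_seed(derive_seed(params$seed, "truth"), {
    m <- nchar(params$motif)
    sh <- params$footprint_shoulder
    truth <- lapply(names(skeleton$transcripts), function(id) {
      L <- Biostrings::width(skeleton$transcripts)[
        match(id, names(skeleton$transcripts))]
      acc <- smooth_baseline(L)
      flex <- smooth_baseline(L)
      tr <- list(accessibility = list(in_cell = acc, in_vitro = acc),
                 flexibility = list(in_cell = flex, in_vitro = flex))
      el <- skeleton$elements[skeleton$elements$transcript_id == id, ,
                              drop = FALSE]
      # sequence-intrinsic reactivity at every motif occurrence (bound or
      # not, planted or spontaneous): RBP motifs are accessible and flexible
      # when unbound, which is what makes them bindable; both conditions
      for (s in scan_motif(skeleton$transcripts[[id]], params$motif)) {
        idx <- (s + 1):(s + m)
        for (ch in c("accessibility", "flexibility"))
          for (cond in c("in_cell", "in_vitro"))
            tr[[ch]][[cond]][idx] <- blend(tr[[ch]][[cond]][idx],
                                           params$motif_intrinsic_target,
                                           params$motif_intrinsic_weight)
      }
      # RBP footprints: in-cell only, on the site's assigned channel
      bound <- el[el$type == "bound_motif", , drop = FALSE]
      for (i in seq_len(nrow(bound))) {
        idx <- (bound$start[i] - sh):(bound$start[i] + m + sh - 1)
        w <- c(rep(params$shoulder_weight, sh), rep(1, m),
               rep(params$shoulder_weight, sh))
        ok <- idx >= 0 & idx < L
        ch <- bound$channel[i]
        tr[[ch]]$in_cell[idx[ok] + 1] <-
          tr[[ch]]$in_cell[idx[ok] + 1] * (1 - params$delta * w[ok])
      }
      # polyA signal signature on the accessibility channel
      pas <- el[el$type == "pas", , drop = FALSE]
      for (i in seq_len(nrow(pas))) {
        aa <- pas$start[i] + 1:2        # 1-based: the two leading A's
        ua <- pas$start[i] + 3:6        # the UAAA
        for (cond in c("in_cell", "in_vitro")) {
          tr$accessibility[[cond]][aa] <- blend(tr$accessibility[[cond]][aa], 0.9, 0.5)
          tr$accessibility[[cond]][ua] <- blend(tr$accessibility[[cond]][ua], 0.2, 0.5)
        }
        if (isTRUE(pas$active[i])) {
          # the CPSF footprint is a protein effect: it scales with the same
          # footprint dial as RBP sites (full strength from delta = 0.5 up)
          fd <- min(2 * params$delta, 1)
          tr$accessibility$in_cell[aa] <- blend(tr$accessibility$in_cell[aa],
                                                0.95, 0.9 * fd)
          tr$accessibility$in_cell[ua] <- blend(tr$accessibility$in_cell[ua],
                                                0.05, 0.9 * fd)
          tr$flexibility$in_cell[c(aa, ua)] <-
            blend(tr$flexibility$in_cell[c(aa, ua)], 0.2, 0.5 * fd)
        }
      }
      tr
    })
    names(truth) <- names(skeleton$transcripts)
    truth
  })
}

#' Simulate probing stop-count tracks for one reagent and condition
#'
#' Per position, base density is negative-binomial with mean `coverage`;
#' treatment stops are negative-binomial with mean
#' `density * (beta0 + beta1 * reactivity * basespec)` and control stops
#' with mean `density * beta0`, where `basespec` is the reagent's per-base
#' weight (A/G for the accessibility probe, mild A/U for the flexibility
#' probe).  Treatment and control draw independent densities; library sizes
#' are fixed equal so the scaling factor is 1.
#'
#' @param truth output of [simulate_truth_profiles()].
#' @param skeleton output of [simulate_transcriptome()].
#' @param params a [simulation_params()].
#' @param reagent `"accessibility"` or `"flexibility"`.
#' @param condition `"in_cell"` or `"in_vitro"`.
#' @return list with `treatment` and `control`: named lists of
#'   [stop_count_track()] per transcript.
#' @export
simulate_probing_reads <- function(truth, skeleton, params,
                                   reagent = c("accessibility", "flexibility"),
                                   condition = c("in_cell", "in_vitro")) {
  reagent <- match.arg(reagent)
  condition <- match.arg(condition)
  withr::with_seed(derive_seed(params$seed, paste("reads", reagent, condition)), {
    bs <- params$basespec[[reagent]]
    out_t <- list()
    out_c <- list()
    for (id in names(skeleton$transcripts)) {
      chars <- strsplit(as.character(skeleton$transcripts[[id]]), "")[[1]]
      w <- unname(bs[chars])
      w[is.na(w)] <- 0                  # N bases never react
      r <- truth[[id]][[reagent]][[condition]]
      L <- length(r)
      d_t <- rnbinom(L, size = params$phi, mu = params$coverage)
      d_c <- rnbinom(L, size = params$phi, mu = params$coverage)
      t_stops <- rnbinom(L, size = params$phi,
                         mu = d_t * (params$beta0 + params$beta1 * r * w))
      c_stops <- rnbinom(L, size = params$phi, mu = d_c * params$beta0)
      out_t[[id]] <- stop_count_track(id, t_stops, d_t, condition = condition,
                                      reagent = reagent, total_mapped = 1e6)
      out_c[[id]] <- stop_count_track(id, c_stops, d_c, condition = condition,
                                      reagent = "control", total_mapped = 1e6)
    }
    list(treatment = out_t, control = out_c)
  })
}

#' Simulate eCLIP-style peak annotations over bound sites
#'
#' One peak per bound motif instance, spanning the motif extended on each
#' side by an independent uniform jitter in `[0, jitter]`, clipped to the
#' transcript.  Planted unbound instances stay uncovered because planting
#' enforces a separation larger than the maximal jitter.
#'
#' @param skeleton output of [simulate_transcriptome()].
#' @param jitter maximal peak extension (nt); defaults to the params value.
#' @return a peak data frame as returned by [read_intervals()].
#' @export
simulate_eclip_peaks <- function(skeleton, jitter = skeleton$params$peak_jitter) {
  params <- skeleton$params
  m <- nchar(params$motif)
  bound <- skeleton$elements[skeleton$elements$type == "bound_motif", ,
                             drop = FALSE]
  withr::with_seed(derive_seed(params$seed, "peaks"), {
    lens <- Biostrings::width(skeleton$transcripts)[
      match(bound$transcript_id, names(skeleton$transcripts))]
    left <- if (jitter > 0) sample(0:jitter, nrow(bound), replace = TRUE) else 0L
    right <- if (jitter > 0) sample(0:jitter, nrow(bound), replace = TRUE) else 0L
    data.frame(transcript_id = bound$transcript_id,
               start = pmax(bound$start - left, 0L),
               end = pmin(bound$start + m + right, lens),
               name = params$rbp_name, score = 1000,
               stringsAsFactors = FALSE)
  })
}

#' Simulate polyA-site-seq read 3' ends
#'
#' Active planted signals receive a Poisson number of reads (mean
#' `pas_reads_active`) whose 3' ends scatter with rounded-normal jitter
#' around the true cleavage position; inactive signals receive a trickle
#' (mean `pas_reads_inactive`); uniform background reads are added at
#' `pas_background_rate` per nt.
#'
#' @param skeleton output of [simulate_transcriptome()].
#' @param params a [simulation_params()].
#' @return data frame with columns `transcript_id` and `end3` (0-based).
#' @export
simulate_pas_reads <- function(skeleton, params = skeleton$params) {
  withr::with_seed(derive_seed(params$seed, "pas_reads"), {
    lens <- setNames(Biostrings::width(skeleton$transcripts),
                     names(skeleton$transcripts))
    pas <- skeleton$elements[skeleton$elements$type == "pas", , drop = FALSE]
    rows <- list()
    for (i in seq_len(nrow(pas))) {
      mu <- if (isTRUE(pas$active[i])) params$pas_reads_active else
        params$pas_reads_inactive
      n <- rpois(1, mu)
      if (n == 0) next
      L <- lens[[pas$transcript_id[i]]]
      ends <- pas$cleavage_pos[i] + round(rnorm(n, 0, params$pas_read_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = pas$transcript_id[i],
        end3 = pmin(pmax(ends, 0L), L - 1L))
    }
    for (id in names(lens)) {
      n_bg <- rpois(1, params$pas_background_rate * lens[[id]])
      if (n_bg == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, end3 = sample(0:(lens[[id]] - 1L), n_bg,
                                          replace = TRUE))
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab))
      tab <- data.frame(transcript_id = character(), end3 = integer())
    rownames(tab) <- NULL
    tab
  })
}

#' Run the whole synthetic experiment
#'
#' Convenience wrapper chaining [simulate_transcriptome()],
#' [simulate_truth_profiles()], [simulate_probing_reads()] for the requested
#' reagents and conditions, [simulate_eclip_peaks()] and
#' [simulate_pas_reads()].
#'
#' @param params a [simulation_params()].
#' @param conditions conditions to generate probing tracks for.
#' @return list with `skeleton`, `truth`,
#'   `tracks[[reagent]][[condition]]` (each a `treatment`/`control` pair),
#'   `peaks` and `pas_reads`.
#' @export
simulate_experiment <- function(params = simulation_params(),
                                conditions = c("in_cell", "in_vitro")) {
  skeleton <- simulate_transcriptome(params)
  truth <- simulate_truth_profiles(params, skeleton)
  tracks <- lapply(c(accessibility = "accessibility",
                     flexibility = "flexibility"), function(rg) {
    out <- lapply(conditions, function(cond)
      simulate_probing_reads(truth, skeleton, params, rg, cond))
    names(out) <- conditions
    out
  })
  list(skeleton = skeleton, truth = truth, tracks = tracks,
       peaks = simulate_eclip_peaks(skeleton),
       pas_reads = simulate_pas_reads(skeleton, params))
}

#' Score simulated tracks into reactivity profiles
#'
#' @param tracks a `treatment`/`control` pair as produced by
#'   [simulate_probing_reads()].
#' @param scoring a [scoring_params()].
#' @return named list of [reactivity_profile()] per transcript.
#' @export
profiles_from_tracks <- function(tracks, scoring = scoring_params()) {
  out <- lapply(names(tracks$treatment), function(id)
    score_track(tracks$treatment[[id]], tracks$control[[id]], scoring))
  names(out) <- names(tracks$treatment)
  out
}
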