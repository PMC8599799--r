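#' Default run configuration
#'
#' Nested list consumed by [run_all()] and the `footprintr` command-line
#' script; any subset of it can be overridden from a YAML file.
#'
#' @return a nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    outdir = "footprintr_run",
    simulation = list(),
    scoring = list(),
    model = list(kernel = "rbf", C_grid = c(1, 10),
                 gamma_grid = c(0.03, 0.3), folds = 5, split_fraction = 0.5),
    rbp = list(flank = 5, negative_buffer = 0),
    pas = list(flank = 20, min_reads = 5, cluster_distance = 10,
               d_min = 10, d_max = 40, high_quantile = 0.75,
               low_quantile = 0.25),
    hexamer = list(min_occurrences = 10))
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a YAML run configuration, merged over the defaults
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @param seed optional seed overriding the file's value.
#' @return a configuration list.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  config <- default_run_config()
  if (!is.null(path))
    config <- merge_config(config, yaml::read_yaml(path))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config
}

config_model <- function(config) {
  args <- config$model
  args$seed <- NULL                  # the run seed governs the model seed
  do.call(model_config,
          c(args, list(seed = derive_seed(config$seed, "model"))))
}

config_scoring <- function(config) do.call(scoring_params, config$scoring)

config_simulation <- function(config) {
  do.call(simulation_params, c(config$simulation, list(seed = config$seed)))
}

split_by_reagent <- function(fm) {
  reagents <- unique(sub("_[^_]*$", "", colnames(fm$features)))
  out <- lapply(reagents, function(rg) {
    cols <- startsWith(colnames(fm$features), paste0(rg, "_"))
    feature_matrix(fm$features[, cols, drop = FALSE], fm$labels, fm$sites,
                   fm$discarded)
  })
  names(out) <- reagents
  out
}

write_roc <- function(roc, path) {
  write.table(data.frame(fpr = roc$fpr, tpr = roc$tpr), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Predict RBP binding sites from in-cell reactivity windows
#'
#' Full binding-site experiment: scan the motif, anchor positives on peaks
#' (motif-less peaks are dropped and counted), sample an equal number of
#' peak-free negatives, extract 15-nt windows (motif plus `flank` on each
#' side) per reagent, and run the classifier harness once per feature
#' design (each single reagent and both combined).
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param profiles_by_reagent named list: reagent -> named list of in-cell
#'   [reactivity_profile()] per transcript.
#' @param peaks peak data frame in transcript coordinates.
#' @param motif the RBP's binding motif.
#' @param config run configuration (see [default_run_config()]).
#' @param outdir optional directory for result files (`rbp_sites.bed`,
#'   `rbp_results.tsv`, `rbp_features_combined.tsv`, `roc_rbp_<design>.tsv`).
#' @return list with `results` (data frame: design, n_pos, n_neg, C, gamma,
#'   auc), `sites`, the `designs` feature matrices and `log` (row counts and
#'   discards per stage).
#' @export
run_rbp_experiment <- function(transcripts, profiles_by_reagent, peaks, motif,
                               config = default_run_config(), outdir = NULL) {
  m <- nchar(motif)
  occ <- scan_motif_set(transcripts, motif)
  pos <- build_positive_sites(peaks, motif, transcripts)
  neg <- sample_negative_sites(occ, peaks, motif, nrow(pos),
                               seed = derive_seed(config$seed, "negatives"),
                               buffer = config$rbp$negative_buffer)
  keep_cols <- c("transcript_id", "start", "motif", "label")
  sites <- rbind(pos[, keep_cols], neg[, keep_cols])
  combined <- assemble_feature_matrix(sites, profiles_by_reagent, m,
                                      config$rbp$flank, mode = "combined")
  designs <- c(split_by_reagent(combined), list(combined = combined))
  results <- compare_reagents(designs, config_model(config))
  log <- list(n_occurrences = nrow(occ), n_positive = nrow(pos),
              n_negative = nrow(neg),
              discarded_peaks = attr(pos, "discarded_peaks"),
              discarded_windows = nrow(combined$discarded))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    bed <- data.frame(transcript_id = sites$transcript_id,
                      start = sites$start, end = sites$start + m,
                      name = if (nrow(peaks)) peaks$name[1] else "RBP",
                      score = as.integer(sites$label == "positive"))
    write_intervals(bed, file.path(outdir, "rbp_sites.bed"))
    write.table(results, file.path(outdir, "rbp_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_feature_matrix(combined,
                         file.path(outdir, "rbp_features_combined.tsv"))
    rocs <- attr(results, "roc")
    for (d in names(rocs))
      write_roc(rocs[[d]], file.path(outdir, sprintf("roc_rbp_%s.tsv", d)))
  }
  list(results = results, sites = sites, designs = designs, log = log)
}

#' Predict polyA-signal usage from reactivity windows
#'
#' Full polyA experiment: pile up read 3' ends, call and cluster sites,
#' anchor them to upstream AAUAAA signals, stratify activity by read depth,
#' build 46-nt windows (signal plus `flank` = 20 on each side) at active
#' signals (positives) and at motif occurrences not assigned to any called
#' site (negatives, sampled to match), and run the classifier per design.
#' Also emits the cumulative read-density metaprofile around the signal
#' uridine and the mean reactivity window per class.
#'
#' @param transcripts named [Biostrings::DNAStringSet].
#' @param profiles_by_reagent named list: reagent -> named list of in-cell
#'   [reactivity_profile()] per transcript.
#' @param pas_reads data frame with `transcript_id`, `end3`.
#' @param config run configuration.
#' @param outdir optional directory for result files (`pas_sites.bed`,
#'   `pas_results.tsv`, `pas_metaprofile.tsv`, `pas_window_means.tsv`,
#'   `roc_pas_<design>.tsv`).
#' @return list with `results`, `sites`, `designs`, `metaprofile`,
#'   `window_means` and `log`.
#' @export
run_pas_experiment <- function(transcripts, profiles_by_reagent, pas_reads,
                               config = default_run_config(), outdir = NULL) {
  pc <- config$pas
  sites <- call_pas_sites_set(pas_reads, transcripts,
                              min_reads = pc$min_reads,
                              cluster_distance = pc$cluster_distance,
                              d_min = pc$d_min, d_max = pc$d_max,
                              high_quantile = pc$high_quantile,
                              low_quantile = pc$low_quantile)
  if (!nrow(sites))
    return(list(results = NULL, sites = sites, designs = NULL,
                metaprofile = NULL, window_means = NULL,
                log = list(n_sites = 0L)))
  active <- sites[sites$activity == "active", , drop = FALSE]
  occ <- scan_motif_set(transcripts, "AAUAAA")
  assigned <- sites[!is.na(sites$signal_start),
                    c("transcript_id", "signal_start")]
  key <- paste(occ$transcript_id, occ$start)
  pool <- occ[!(key %in% paste(assigned$transcript_id, assigned$signal_start)), ,
              drop = FALSE]
  n_pos <- nrow(active)
  pick <- withr::with_seed(derive_seed(config$seed, "pas_negatives"),
                           sample(nrow(pool), min(n_pos, nrow(pool))))
  negatives <- pool[sort(pick), , drop = FALSE]
  fm <- pas_feature_windows(
    profiles_by_reagent,
    data.frame(transcript_id = active$transcript_id,
               start = active$signal_start),
    negatives, flank = pc$flank)
  designs <- c(split_by_reagent(fm), list(combined = fm))
  results <- compare_reagents(designs, config_model(config))
  meta <- pas_metaprofile(attr(sites, "pileups"), sites)
  wm <- window_mean_profiles(fm)
  log <- list(n_sites = nrow(sites), n_active = n_pos,
              n_negative_pool = nrow(pool),
              discarded_windows = nrow(fm$discarded))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    bed <- data.frame(transcript_id = sites$transcript_id,
                      start = sites$cleavage_pos,
                      end = sites$cleavage_pos + 1,
                      name = sites$activity, score = sites$read_count)
    write_intervals(bed, file.path(outdir, "pas_sites.bed"))
    write.table(results, file.path(outdir, "pas_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(meta, file.path(outdir, "pas_metaprofile.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(wm, file.path(outdir, "pas_window_means.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    rocs <- attr(results, "roc")
    for (d in names(rocs))
      write_roc(rocs[[d]], file.path(outdir, sprintf("roc_pas_%s.tsv", d)))
  }
  list(results = results, sites = sites, designs = designs,
       metaprofile = meta, window_means = wm, log = log)
}

#' Mean feature value per window offset and class
#'
#' @param fm a [feature_matrix()].
#' @return data frame with columns `feature`, `mean_positive`,
#'   `mean_negative`.
#' @export
window_mean_profiles <- function(fm) {
  pos <- fm$labels == "positive"
  data.frame(feature = colnames(fm$features),
             mean_positive = colMeans(fm$features[pos, , drop = FALSE]),
             mean_negative = colMeans(fm$features[!pos, , drop = FALSE]),
             row.names = NULL)
}

# ---- stage runners backing the command-line subcommands -------------------

sim_file <- function(outdir, ...) file.path(outdir, "sim", sprintf(...))

#' Materialize a synthetic experiment to disk
#'
#' Writes the formats the pipeline consumes: `sim/transcripts.fa`, one
#' stop-count TSV per reagent/condition/library, `sim/peaks.bed`,
#' `sim/pas_reads.tsv` and the ground truth as `sim/truth.json`.
#'
#' @param config run configuration; `config$simulation` parameterizes the
#'   generator and `config$seed` seeds it.
#' @return (invisibly) the simulated experiment object.
#' @export
run_simulate_stage <- function(config) {
  sim <- simulate_experiment(config_simulation(config))
  outdir <- config$outdir
  dir.create(file.path(outdir, "sim"), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$skeleton$transcripts,
                              sim_file(outdir, "transcripts.fa"))
  for (rg in names(sim$tracks))
    for (cond in names(sim$tracks[[rg]])) {
      pair <- sim$tracks[[rg]][[cond]]
      write_stop_counts(pair$treatment,
                        sim_file(outdir, "counts_%s_%s_treatment.tsv", rg, cond))
      write_stop_counts(pair$control,
                        sim_file(outdir, "counts_%s_%s_control.tsv", rg, cond))
    }
  write_intervals(sim$peaks, sim_file(outdir, "peaks.bed"))
  write.table(sim$pas_reads, sim_file(outdir, "pas_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$skeleton$elements, sim_file(outdir, "truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  invisible(sim)
}

score_file <- function(outdir, rg, cond)
  file.path(outdir, sprintf("reactivity_%s_%s.bedGraph", rg, cond))

#' Score materialized stop-count tables into reactivity bedGraphs
#'
#' @param config run configuration; reads `sim/` inputs under
#'   `config$outdir` and writes one bedGraph per reagent and condition.
#' @return (invisibly) the profile sets, nested reagent -> condition.
#' @export
run_score_stage <- function(config) {
  outdir <- config$outdir
  transcripts <- read_transcripts(sim_file(outdir, "transcripts.fa"))
  scoring <- config_scoring(config)
  profiles <- list()
  for (rg in c("accessibility", "flexibility")) {
    profiles[[rg]] <- list()
    for (cond in c("in_cell", "in_vitro")) {
      tf <- sim_file(outdir, "counts_%s_%s_treatment.tsv", rg, cond)
      cf <- sim_file(outdir, "counts_%s_%s_control.tsv", rg, cond)
      if (!file.exists(tf)) next
      treat <- read_stop_counts(tf, transcripts, condition = cond, reagent = rg)
      ctrl <- read_stop_counts(cf, transcripts, condition = cond,
                               reagent = "control")
      profs <- lapply(names(transcripts), function(id)
        score_track(treat[[id]], ctrl[[id]], scoring))
      names(profs) <- names(transcripts)
      profiles[[rg]][[cond]] <- profs
      write_reactivity_bedgraph(profs, score_file(outdir, rg, cond))
    }
  }
  invisible(profiles)
}

read_profiles <- function(outdir, transcripts, conditions = "in_cell") {
  out <- list()
  for (rg in c("accessibility", "flexibility"))
    for (cond in conditions) {
      path <- score_file(outdir, rg, cond)
      if (file.exists(path))
        out[[rg]][[cond]] <- read_reactivity_bedgraph(path, transcripts,
                                                      reagent = rg,
                                                      condition = cond)
    }
  out
}

#' Compute VTD tracks and the hexamer VTD table from scored bedGraphs
#'
#' @param config run configuration; requires in-cell and in-vitro bedGraphs
#'   under `config$outdir`; writes `vtd_<reagent>.bedGraph` and
#'   `hexamer_vtd_<reagent>.tsv`.
#' @return (invisibly) the per-reagent VTD track lists.
#' @export
run_vtd_stage <- function(config) {
  outdir <- config$outdir
  transcripts <- read_transcripts(sim_file(outdir, "transcripts.fa"))
  profiles <- read_profiles(outdir, transcripts,
                            conditions = c("in_cell", "in_vitro"))
  out <- list()
  for (rg in names(profiles)) {
    if (!all(c("in_cell", "in_vitro") %in% names(profiles[[rg]]))) next
    tracks <- lapply(names(transcripts), function(id)
      vtd(profiles[[rg]]$in_cell[[id]], profiles[[rg]]$in_vitro[[id]]))
    names(tracks) <- names(transcripts)
    out[[rg]] <- tracks
    write_reactivity_bedgraph(tracks,
                              file.path(outdir, sprintf("vtd_%s.bedGraph", rg)))
    hx <- hexamer_vtd(tracks, transcripts, config$hexamer$min_occurrences)
    write.table(hx, file.path(outdir, sprintf("hexamer_vtd_%s.tsv", rg)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Build labeled sites and feature windows from materialized inputs
#'
#' @param config run configuration; needs `sim/` inputs and scored in-cell
#'   bedGraphs under `config$outdir`; writes `rbp_sites.bed` and
#'   `rbp_features_combined.tsv`.
#' @param motif the RBP motif; defaults to the simulation's motif.
#' @return (invisibly) the combined [feature_matrix()].
#' @export
run_sites_stage <- function(config, motif = NULL) {
  outdir <- config$outdir
  if (is.null(motif)) motif <- config_simulation(config)$motif
  m <- nchar(motif)
  transcripts <- read_transcripts(sim_file(outdir, "transcripts.fa"))
  peaks <- read_intervals(sim_file(outdir, "peaks.bed"), transcripts)
  incell <- lapply(read_profiles(outdir, transcripts), `[[`, "in_cell")
  occ <- scan_motif_set(transcripts, motif)
  pos <- build_positive_sites(peaks, motif, transcripts)
  neg <- sample_negative_sites(occ, peaks, motif, nrow(pos),
                               seed = derive_seed(config$seed, "negatives"),
                               buffer = config$rbp$negative_buffer)
  keep_cols <- c("transcript_id", "start", "motif", "label")
  sites <- rbind(pos[, keep_cols], neg[, keep_cols])
  fm <- assemble_feature_matrix(sites, incell, m, config$rbp$flank, "combined")
  bed <- data.frame(transcript_id = sites$transcript_id, start = sites$start,
                    end = sites$start + m, name = peaks$name[1],
                    score = as.integer(sites$label == "positive"))
  write_intervals(bed, file.path(outdir, "rbp_sites.bed"))
  write_feature_matrix(fm, file.path(outdir, "rbp_features_combined.tsv"))
  invisible(fm)
}

#' Train and evaluate the classifier from a materialized feature table
#'
#' @param config run configuration; reads `rbp_features_combined.tsv` under
#'   `config$outdir` and writes `rbp_results.tsv` plus per-design ROC TSVs.
#' @return (invisibly) the results data frame.
#' @export
run_train_stage <- function(config) {
  outdir <- config$outdir
  fm <- read_feature_matrix(file.path(outdir, "rbp_features_combined.tsv"))
  designs <- c(split_by_reagent(fm), list(combined = fm))
  results <- compare_reagents(designs, config_model(config))
  write.table(results, file.path(outdir, "rbp_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rocs <- attr(results, "roc")
  for (d in names(rocs))
    write_roc(rocs[[d]], file.path(outdir, sprintf("roc_rbp_%s.tsv", d)))
  invisible(results)
}

#' Run the polyA experiment from materialized inputs
#'
#' @param config run configuration; needs `sim/transcripts.fa`,
#'   `sim/pas_reads.tsv` and scored in-cell bedGraphs under
#'   `config$outdir`.
#' @return (invisibly) the [run_pas_experiment()] result.
#' @export
run_pas_stage <- function(config) {
  outdir <- config$outdir
  transcripts <- read_transcripts(sim_file(outdir, "transcripts.fa"))
  pas_reads <- read.delim(sim_file(outdir, "pas_reads.tsv"))
  incell <- lapply(read_profiles(outdir, transcripts), `[[`, "in_cell")
  invisible(run_pas_experiment(transcripts, incell, pas_reads, config,
                               outdir = outdir))
}

#' Run the whole pipeline end to end
#'
#' Simulate (or reuse materialized inputs), score, compute VTD and hexamer
#' summaries, and run both the RBP and the polyA experiments.  Every
#' intermediate is written under `config$outdir`; the run is fully
#' deterministic given `config$seed`.
#'
#' @param config run configuration (see [default_run_config()] /
#'   [read_run_config()]).
#' @return list with the `rbp` and `pas` experiment results.
#' @export
run_all <- function(config = default_run_config()) {
  run_simulate_stage(config)
  run_score_stage(config)
  run_vtd_stage(config)
  run_sites_stage(config)
  rbp <- run_train_stage(config)
  pas <- run_pas_stage(config)
  invisible(list(rbp = rbp, pas = pas))
}
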