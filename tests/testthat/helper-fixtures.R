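# Shared fixture builders; everything is generated in code at test time.

tiny_transcripts <- function(seqs) {
  out <- Biostrings::DNAStringSet(chartr("U", "T", toupper(seqs)))
  names(out) <- names(seqs)
  out
}

flat_profile <- function(id, scores, reagent = "accessibility",
                         condition = "in_cell") {
  reactivity_profile(id, scores, reagent = reagent, condition = condition)
}

# deterministic random sequence in the DNA alphabet
random_seq <- function(n, seed = 1) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# small simulation shared by module tests (cheap but fully featured)
small_sim_params <- function(seed = 1, ...) {
  simulation_params(n_transcripts = 40, length_range = c(400, 800),
                    seed = seed, ...)
}

# profiles straight from ground truth (no count noise); useful when a test
# needs the probing signal without simulating reads
truth_profiles <- function(sim, reagent, condition = "in_cell") {
  out <- lapply(names(sim$skeleton$transcripts), function(id)
    reactivity_profile(id, sim$truth[[id]][[reagent]][[condition]],
                       reagent = reagent, condition = condition))
  names(out) <- names(sim$skeleton$transcripts)
  out
}

scored_profiles <- function(sim, condition = "in_cell") {
  list(accessibility = profiles_from_tracks(sim$tracks$accessibility[[condition]]),
       flexibility = profiles_from_tracks(sim$tracks$flexibility[[condition]]))
}

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fa")
  writeLines(lines, f)
  f
}
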