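test_that("the generator is deterministic given the seed at every stage", {
  p <- small_sim_params(seed = 5)
  a <- simulate_experiment(p, conditions = "in_cell")
  b <- simulate_experiment(p, conditions = "in_cell")
  expect_identical(as.character(a$skeleton$transcripts),
                   as.character(b$skeleton$transcripts))
  expect_identical(a$skeleton$elements, b$skeleton$elements)
  expect_identical(a$tracks$accessibility$in_cell$treatment$tx0001$stops,
                   b$tracks$accessibility$in_cell$treatment$tx0001$stops)
  expect_identical(a$peaks, b$peaks)
  expect_identical(a$pas_reads, b$pas_reads)
  c <- simulate_transcriptome(small_sim_params(seed = 6))
  expect_false(identical(as.character(a$skeleton$transcripts),
                         as.character(c$transcripts)))
})

test_that("element bookkeeping matches the requested counts", {
  p <- small_sim_params(seed = 3)
  sk <- simulate_transcriptome(p)
  el <- sk$elements
  expect_equal(sum(el$type == "bound_motif"),
               p$n_transcripts * p$bound_per_transcript)
  expect_equal(sum(el$type == "unbound_motif"),
               p$n_transcripts * p$unbound_per_transcript)
  expect_equal(sum(el$type == "pas"), p$n_transcripts)
  # planted motifs really sit in the sequences
  motif_dna <- chartr("U", "T", p$motif)
  for (i in which(el$type == "bound_motif")[1:20]) {
    seqc <- as.character(sk$transcripts[[el$transcript_id[i]]])
    expect_equal(substring(seqc, el$start[i] + 1, el$start[i] + 5), motif_dna)
  }
  # spontaneous occurrences are discoverable by scanning
  occ <- scan_motif_set(sk$transcripts, p$motif)
  planted <- el[el$type %in% c("bound_motif", "unbound_motif"), ]
  expect_gte(nrow(occ), nrow(planted))
})

test_that("footprints act in cells only, scaled by delta", {
  sk <- simulate_transcriptome(small_sim_params(seed = 7))

  p0 <- small_sim_params(seed = 7, delta = 0)
  t0 <- simulate_truth_profiles(p0, sk)
  for (id in names(t0)[1:5]) {
    expect_identical(t0[[id]]$accessibility$in_cell,
                     t0[[id]]$accessibility$in_vitro)
    expect_identical(t0[[id]]$flexibility$in_cell,
                     t0[[id]]$flexibility$in_vitro)
  }

  p1 <- small_sim_params(seed = 7, delta = 1)
  t1 <- simulate_truth_profiles(p1, sk)
  bound <- sk$elements[sk$elements$type == "bound_motif", ]
  for (i in seq_len(min(nrow(bound), 20))) {
    idx <- (bound$start[i] + 1):(bound$start[i] + 5)
    expect_equal(t1[[bound$transcript_id[i]]][[bound$channel[i]]]$in_cell[idx],
                 rep(0, 5))                    # full suppression on the motif
  }

  p5 <- small_sim_params(seed = 7, delta = 0.5)
  t5 <- simulate_truth_profiles(p5, sk)
  d <- unlist(lapply(seq_len(nrow(bound)), function(i) {
    idx <- (bound$start[i] + 1):(bound$start[i] + 5)
    tr <- t5[[bound$transcript_id[i]]][[bound$channel[i]]]
    tr$in_cell[idx] - tr$in_vitro[idx]
  }))
  expect_lt(mean(d), 0)
})

test_that("probing counts show the reagents' base specificity", {
  p <- small_sim_params(seed = 9)
  sim <- simulate_experiment(p, conditions = "in_cell")
  base_frac <- function(tracks, bases) {
    tot <- 0; at <- 0
    for (id in names(tracks$treatment)) {
      chars <- strsplit(as.character(sim$skeleton$transcripts[[id]]), "")[[1]]
      st <- tracks$treatment[[id]]$stops
      tot <- tot + sum(st)
      at <- at + sum(st[chars %in% bases])
    }
    at / tot
  }
  seq_frac <- function(bases) {
    chars <- unlist(strsplit(as.character(sim$skeleton$transcripts), ""))
    mean(chars %in% bases)
  }
  acc_ag <- base_frac(sim$tracks$accessibility$in_cell, c("A", "G"))
  flex_au <- base_frac(sim$tracks$flexibility$in_cell, c("A", "T"))
  expect_gt(acc_ag, seq_frac(c("A", "G")))      # marked A/G enrichment
  expect_gt(flex_au, seq_frac(c("A", "T")))     # milder A/U skew
  expect_gt(acc_ag / seq_frac(c("A", "G")), flex_au / seq_frac(c("A", "T")))
})

test_that("without modification the treatment matches the control", {
  ok <- 0L
  for (s in 1:5) {
    p <- simulation_params(n_transcripts = 4, length_range = c(400, 600),
                           seed = s, beta1 = 0)
    sim <- simulate_experiment(p, conditions = "in_cell")
    tr <- unlist(lapply(sim$tracks$accessibility$in_cell$treatment,
                        function(x) x$stops))
    ct <- unlist(lapply(sim$tracks$accessibility$in_cell$control,
                        function(x) x$stops))
    pval <- suppressWarnings(stats::wilcox.test(tr, ct)$p.value)
    if (pval > 0.01) ok <- ok + 1L
  }
  expect_gte(ok, 4L)
})

test_that("treatment counts match their expected rates", {
  p <- simulation_params(n_transcripts = 1, length_range = c(300, 300),
                         seed = 1)
  sk <- simulate_transcriptome(p)
  truth <- simulate_truth_profiles(p, sk)
  reps <- lapply(1:50, function(s) {
    ps <- p; ps$seed <- 1000 + s
    simulate_probing_reads(truth, sk, ps, "flexibility",
                           "in_cell")$treatment[[1]]$stops
  })
  m <- do.call(rbind, reps)
  chars <- strsplit(as.character(sk$transcripts[[1]]), "")[[1]]
  w <- unname(p$basespec$flexibility[chars])
  mu <- p$coverage * (p$beta0 + p$beta1 * truth[[1]]$flexibility$in_cell * w)
  z <- (colMeans(m) - mu) / (apply(m, 2, sd) / sqrt(50))
  expect_gte(mean(abs(z) <= 3), 0.9)
})

test_that("peaks cover exactly the bound sites", {
  p <- small_sim_params(seed = 11, peak_jitter = 0)
  sk <- simulate_transcriptome(p)
  pk0 <- simulate_eclip_peaks(sk, jitter = 0)
  bound <- sk$elements[sk$elements$type == "bound_motif", ]
  expect_equal(pk0$start, bound$start)
  expect_equal(pk0$end, bound$start + 5L)       # peak == motif span

  pk <- simulate_eclip_peaks(sk, jitter = 10)
  unbound <- sk$elements[sk$elements$type == "unbound_motif", ]
  for (i in seq_len(nrow(unbound))) {
    p_tx <- pk[pk$transcript_id == unbound$transcript_id[i], ]
    expect_false(any(unbound$start[i] < p_tx$end &
                     unbound$start[i] + 5 > p_tx$start))
  }
  # jittered peaks still yield every bound site as a positive
  pos <- build_positive_sites(pk, p$motif, sk$transcripts)
  key <- paste(pos$transcript_id, pos$start)
  expect_true(all(paste(bound$transcript_id, bound$start) %in% key))
})

test_that("polyA reads concentrate at the true cleavage positions", {
  p <- small_sim_params(seed = 13)
  sim <- simulate_experiment(p, conditions = "in_cell")
  pas <- sim$skeleton$elements
  pas <- pas[pas$type == "pas" & pas$active, ]
  truth_pos <- setNames(pas$cleavage_pos, pas$transcript_id)
  reads <- sim$pas_reads[sim$pas_reads$transcript_id %in% names(truth_pos), ]
  near <- abs(reads$end3 - truth_pos[reads$transcript_id]) <= 10
  expect_gte(mean(near), 0.90)    # background reads are included in the mix

  # no active sites, no trickle, no background -> no reads at all
  p0 <- small_sim_params(seed = 13, pas_active_fraction = 0,
                         pas_reads_inactive = 0, pas_background_rate = 0)
  sk0 <- simulate_transcriptome(p0)
  expect_equal(nrow(simulate_pas_reads(sk0, p0)), 0)
})

test_that("scored profiles track the planted reactivity truth", {
  p <- simulation_params(n_transcripts = 20, length_range = c(500, 800),
                         seed = 15)
  sim <- simulate_experiment(p, conditions = "in_cell")
  # each probe reads reactivity through its base preference, so the scored
  # profile must recover the probe-visible truth (reactivity x basespec)
  for (rg in c("flexibility", "accessibility")) {
    profs <- profiles_from_tracks(sim$tracks[[rg]]$in_cell)
    sc <- unlist(lapply(names(profs), function(id) profs[[id]]$scores))
    tv <- unlist(lapply(names(profs), function(id) {
      chars <- strsplit(as.character(sim$skeleton$transcripts[[id]]), "")[[1]]
      sim$truth[[id]][[rg]]$in_cell * unname(p$basespec[[rg]][chars])
    }))
    keep <- !is.na(sc)
    expect_gte(stats::cor(sc[keep], tv[keep], method = "spearman"), 0.6)
  }
})

test_that("classifier recovery strengthens with the footprint effect", {
  med_auc <- function(delta) {
    aucs <- vapply(1:3, function(s) {
      p <- simulation_params(n_transcripts = 80, length_range = c(400, 800),
                             seed = 20 + s, delta = delta)
      sim <- simulate_experiment(p, conditions = "in_cell")
      prof <- scored_profiles(sim)
      cfg <- default_run_config()
      cfg$seed <- 20 + s
      cfg$model <- list(kernel = "rbf", C_grid = 10, gamma_grid = 0.1,
                        folds = 5, split_fraction = 0.5)
      res <- run_rbp_experiment(sim$skeleton$transcripts, prof, sim$peaks,
                                p$motif, cfg)
      res$results$auc[res$results$design == "combined"]
    }, numeric(1))
    median(aucs)
  }
  aucs <- vapply(c(0, 0.5, 0.8), med_auc, numeric(1))
  expect_lt(aucs[1], 0.6)
  expect_gt(aucs[2], aucs[1])
  expect_gte(aucs[3], aucs[2] - 0.02)   # saturation tolerance at strong effects
})
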