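test_that("read 5' ends convert to RT stops one nucleotide upstream", {
  stops <- stops_from_read_ends(c(5, 5, 9), 10)
  expect_equal(stops[5], 2)          # 0-based position 4
  expect_equal(stops[9], 1)          # 0-based position 8
  expect_equal(sum(stops), 3)

  expect_equal(sum(stops_from_read_ends(0, 10)), 0)  # no upstream base
  expect_error(stops_from_read_ends(10, 10), "positions")

  reads <- withr::with_seed(5, sample(0:49, 1000, replace = TRUE))
  expect_equal(sum(stops_from_read_ends(reads, 50)), sum(reads > 0))
})

test_that("enrichment score matches its definition position by position", {
  tr <- function(T, B, D, tm_t = 1e6, tm_c = 1e6) list(
    t = stop_count_track("tx", T, numeric(length(T)), "in_cell",
                         "accessibility", tm_t),
    c = stop_count_track("tx", B, D, "in_cell", "control", tm_c))
  # background irrelevant when B = 0
  x <- tr(4, 0, 8)
  expect_equal(enrichment_score(x$t, x$c, scoring_params(epsilon = 1e-9)), 0.5)
  # exact cancellation
  x <- tr(2, 8, 10)
  expect_equal(enrichment_score(x$t, x$c, scoring_params(alpha = 0.25)), 0)

  # brute-force per-position oracle on random 20-nt tracks
  withr::with_seed(42, {
    T <- rpois(20, 30); B <- rpois(20, 6); D <- rpois(20, 100) + 1
  })
  x <- tr(T, B, D, tm_t = 2e6, tm_c = 1e6)
  p <- scoring_params(alpha = 0.25, epsilon = 1)
  got <- enrichment_score(x$t, x$c, p)
  f <- 2e6 / 1e6
  oracle <- vapply(1:20, function(i)
    max((T[i] - 0.25 * f * B[i]) / max(f * D[i], 1), 0), numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("enrichment score is monotone in T and library-size invariant", {
  withr::with_seed(8, {
    B <- rpois(15, 5); D <- rpois(15, 80) + 2; T <- rpois(15, 20)
  })
  p <- scoring_params()
  mk <- function(T, B, D, tt, tc) list(
    t = stop_count_track("tx", T, numeric(15), "in_cell", "accessibility", tt),
    c = stop_count_track("tx", B, D, "in_cell", "control", tc))
  x <- mk(T, B, D, 1e6, 1e6)
  s0 <- enrichment_score(x$t, x$c, p)
  s1 <- enrichment_score(mk(T + 3, B, D, 1e6, 1e6)$t, x$c, p)
  expect_true(all(s1 >= s0))
  # scale both libraries by a common constant
  y <- mk(3 * T, 3 * B, 3 * D, 3e6, 3e6)
  expect_equal(enrichment_score(y$t, y$c, p), s0, tolerance = 1e-12)
})

test_that("normalization matches a sort-based percentile oracle", {
  p <- scoring_params(winsor_lo = 90, winsor_hi = 99)
  # all-zero passthrough
  expect_equal(normalize_profile(c(0, 0, 0), p)$scores, c(0, 0, 0))
  # all-NA passthrough
  expect_true(all(is.na(normalize_profile(rep(NA_real_, 4), p)$scores)))
  # clamp contract on arbitrary input
  withr::with_seed(1, raw <- rexp(500, 1))
  out <- normalize_profile(raw, p)$scores
  expect_true(all(out >= 0 & out <= 1))
  # geometric ramp of 100 values: the scale is the mean of sorted
  # positives ranked 91..99 (the 90-99th percentile slice)
  ramp <- 1.05^(1:100)
  got <- normalize_profile(ramp, p)$scores
  slice <- sort(ramp)[91:99]
  expect_equal(got, pmin(ramp / mean(slice), 1), tolerance = 1e-12)
  # ordering of non-clamped values is preserved
  sub <- got[got < 1]
  expect_true(all(diff(sub) > 0))
})

test_that("VTD obeys its identities and null propagation", {
  mk <- function(s, cond) flat_profile("tx", s, "accessibility", cond)
  p <- mk(c(0.3, 0.8, 0.1), "in_cell")
  same <- mk(c(0.3, 0.8, 0.1), "in_vitro")
  expect_equal(vtd(p, same)$diffs, c(0, 0, 0))

  ic <- mk(c(0.9, NA), "in_cell")
  iv <- mk(c(0.4, 0.2), "in_vitro")
  expect_equal(vtd(ic, iv)$diffs, c(0.5, NA))

  expect_error(vtd(mk(0.5, "in_cell"),
                   flat_profile("tx", 0.5, "flexibility", "in_vitro")),
               "reagent")
  expect_error(vtd(same, same), "in-cell")

  withr::with_seed(3, {
    a <- runif(50); b <- runif(50)
    a[sample(50, 5)] <- NA; b[sample(50, 5)] <- NA
  })
  d <- vtd(mk(a, "in_cell"), mk(b, "in_vitro"))$diffs
  expect_equal(d, a - b)             # elementwise subtraction oracle
  # antisymmetry under swapping the condition assignment
  d2 <- vtd(mk(b, "in_cell"), mk(a, "in_vitro"))$diffs
  expect_equal(d, -d2)
})

test_that("hexamer VTD averages complete occurrences only", {
  tx <- tiny_transcripts(c(t1 = "AAAAAA"))
  v <- list(t1 = vtd_track("t1", "accessibility", rep(0.1, 6)))
  out <- hexamer_vtd(v, tx, min_occurrences = 1)
  expect_equal(out$hexamer, "AAAAAA")
  expect_equal(out$mean_vtd, 0.1)
  expect_equal(out$n, 1L)

  # an occurrence containing NA is skipped for that hexamer
  tx2 <- tiny_transcripts(c(t1 = "AAAAAAA"))  # two AAAAAA occurrences
  d <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, NA)
  v2 <- list(t1 = vtd_track("t1", "accessibility", d))
  out2 <- hexamer_vtd(v2, tx2, min_occurrences = 1)
  expect_equal(out2$n, 1L)
})

test_that("hexamers planted inside footprints show depressed VTD", {
  sim <- simulate_experiment(small_sim_params(seed = 2),
                             conditions = c("in_cell", "in_vitro"))
  acc_ic <- truth_profiles(sim, "accessibility", "in_cell")
  acc_iv <- truth_profiles(sim, "accessibility", "in_vitro")
  tracks <- lapply(names(acc_ic), function(id) vtd(acc_ic[[id]], acc_iv[[id]]))
  names(tracks) <- names(acc_ic)
  tab <- hexamer_vtd(tracks, sim$skeleton$transcripts, min_occurrences = 3)
  motif_dna <- chartr("U", "T", sim$skeleton$params$motif)
  in_motif <- grepl(chartr("T", "U", motif_dna), tab$hexamer, fixed = TRUE)
  expect_true(any(in_motif))
  expect_lt(mean(tab$mean_vtd[in_motif]), mean(tab$mean_vtd))
})

test_that("metaprofile averages across anchors with end truncation", {
  p1 <- flat_profile("t1", c(0.2, 0.6, 0.9))
  p2 <- flat_profile("t2", c(0.4, 0.1, 0.3))
  profs <- list(t1 = p1, t2 = p2)
  one <- metaprofile(profs, data.frame(transcript_id = "t1", position = 1),
                     flank_up = 0, flank_down = 0)
  expect_equal(one$mean_score, 0.6)

  two <- metaprofile(profs,
                     data.frame(transcript_id = c("t1", "t2"),
                                position = c(0, 0)),
                     flank_up = 1, flank_down = 1)
  expect_equal(two$mean_score[two$offset == 0], mean(c(0.2, 0.4)))
  # offset -1 falls off both transcripts: no observations
  expect_true(is.na(two$mean_score[two$offset == -1]))
  expect_equal(two$n[two$offset == -1], 0L)
})

test_that("metaprofile at planted motifs shows the intrinsic reactivity peak", {
  sim <- simulate_experiment(small_sim_params(seed = 4), conditions = "in_cell")
  acc <- truth_profiles(sim, "accessibility", "in_cell")
  el <- sim$skeleton$elements
  unbound <- el[el$type == "unbound_motif", ]
  mp <- metaprofile(acc, data.frame(transcript_id = unbound$transcript_id,
                                    position = unbound$start),
                    flank_up = 15, flank_down = 15)
  inside <- mp$mean_score[mp$offset %in% 0:4]
  outside <- mp$mean_score[mp$offset < -5 | mp$offset > 9]
  expect_gt(min(inside), mean(outside))
})
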