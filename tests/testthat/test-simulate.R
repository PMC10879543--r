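# The generative simulator: determinism, hazard structure, art condition,
# and end-to-end compatibility with the ingestion pipeline.

test_that("a fully tolerant caregiver never rejects", {
  cfg <- sim_config()
  for (seed in 1:5) {
    sim <- simulate_session(caregiver_style(0.8, 1, 0.8), infant_state(10),
                            cfg, seed = seed)
    expect_equal(sum(sim$session$events$behavior == "rejection"), 0)
  }
})

test_that("the same seed reproduces a session exactly", {
  cfg <- sim_config()
  a <- simulate_session(caregiver_style(0.5, 0.4, 0.6), infant_state(15), cfg, 99)
  b <- simulate_session(caregiver_style(0.5, 0.4, 0.6), infant_state(15), cfg, 99)
  expect_identical(a$session$events, b$session$events)
  expect_identical(a$session$calls, b$session$calls)
  expect_identical(a$truth$dismounts, b$truth$dismounts)
})

test_that("mean retrieval latency decreases with sensitivity", {
  cfg <- sim_config()
  mean_lat <- vapply(c(0.25, 0.5, 1), function(s) {
    lats <- vapply(1:60, function(k) {
      sim <- simulate_session(caregiver_style(s, 0.8, 0.8), infant_state(10),
                              cfg, seed = 1000 * s + k)
      rt <- sim$session$retrieval_time
      if (is.na(rt)) cfg$nominal_duration_s else rt
    }, double(1))
    mean(lats)
  }, double(1))
  expect_true(all(diff(mean_lat) < 0))
})

test_that("simulated truth labels agree with the measured intervals", {
  cfg <- sim_config()
  for (seed in c(3, 9, 27)) {
    sim <- simulate_session(caregiver_style(0.6, 0.2, 0.6),
                            infant_state(10, avoidance_base = 0.3), cfg, seed)
    if (nrow(sim$truth$dismounts) == 0) next
    dm <- extract_intervals(sim$session)
    lab <- classify_dismounts(dm, threshold_s = cfg$dismount_threshold_s)
    merged <- dplyr::inner_join(lab, sim$truth$dismounts,
                                by = c("session_id", "time"))
    # forced truth always classifies forced (delay support is the threshold)
    expect_true(all(merged$label[merged$truth == "forced"] == "forced"))
  }
})

test_that("cohort files parse through the full pipeline", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(n_families = 2, infants_per_birth = 2,
                        caregivers_per_family = 2, pnd_schedule = c(10, 30),
                        seed = 5, out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("events.csv", "calls.csv",
                                               "meta.csv", "truth.json")))))
  events <- read_event_stream(file.path(dir, "events.csv"))
  calls <- read_call_table(file.path(dir, "calls.csv"))
  meta <- read_session_meta(file.path(dir, "meta.csv"))
  sessions <- build_sessions(events, calls, meta)
  expect_equal(length(sessions), 16)
  # every generated session segments cleanly
  for (s in sessions) {
    tl <- segment_contexts(s)
    expect_equal(sum(tl$end_s - tl$start_s), s$window_end)
  }
  # styles are constant per caregiver: one row per caregiver in truth
  expect_equal(nrow(co$truth$styles), 4)
})

test_that("measured %Rejection tracks 1 - tolerance across caregivers", {
  co <- simulate_cohort(n_families = 15, infants_per_birth = 1,
                        caregivers_per_family = 2, pnd_schedule = c(8, 14, 20),
                        seed = 31)
  run <- run_retrieval_analysis(list(events = co$events, calls = co$calls,
                                     meta = co$meta, out_dir = NULL))
  by_cg <- run$dyads |>
    dplyr::left_join(co$truth$styles, by = "caregiver_id")
  r <- cor(by_cg$pct_rejection, 1 - by_cg$tolerance, method = "spearman",
           use = "pairwise.complete.obs")
  expect_gt(r, 0.6)
})

test_that("the art condition modifies only artificially reared infants", {
  cfg <- sim_config()
  fam <- infant_state(20, "family", 0.1)
  expect_identical(simulate_art_condition(fam, cfg), fam)

  art_young <- simulate_art_condition(infant_state(10, "artificial", 0.1), cfg)
  expect_equal(art_young$avoidance_base, 0.1 + cfg$art$avoidance_boost)
  expect_equal(art_young$direct_transfer_drop, 0)

  art_old <- simulate_art_condition(infant_state(35, "artificial", 0.1), cfg)
  expect_gt(art_old$alone_call_mult, cfg$art$alone_call_mult_base)
  expect_gt(art_old$direct_transfer_drop, 0)
})

test_that("art infants show more nondirect transfers after PND 12", {
  cfg <- sim_config()
  frac_nondirect <- function(rearing, pnd, seeds) {
    fr <- vapply(seeds, function(k) {
      inf <- simulate_art_condition(infant_state(pnd, rearing, 0.1), cfg)
      tr <- classify_transfers(simulate_reunion_bins(inf, cfg, seed = k))
      if (nrow(tr) == 0) NA_real_ else mean(tr$type == "nondirect")
    }, double(1))
    mean(fr, na.rm = TRUE)
  }
  expect_gt(frac_nondirect("artificial", 25, 1:40),
            frac_nondirect("family", 25, 1:40))
})

test_that("two-phase intervals are positive, on-grid and two-phased", {
  cfg <- sim_config()
  set.seed(12)
  iv <- simulate_dismount_intervals(500, cfg)
  expect_true(all(iv > 0))
  expect_true(all(abs(iv / 0.2 - round(iv / 0.2)) < 1e-9))
  # mass below the change point dominated by the forced phase
  expect_gt(mean(iv <= cfg$forced_delay$max_s), 0.75)
  expect_gt(max(iv), cfg$forced_delay$max_s)
})

test_that("invalid call-type mixes are rejected at config time", {
  expect_error(sim_config(calls = list(anxiety_mix = list(
    phee = 0.5, twitter = 0, tsik = 0, trill = 0, cry = 0, other = 0))),
    "sum to 1")
})
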