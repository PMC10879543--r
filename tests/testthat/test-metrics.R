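# Parenting parameters, infant metrics, transitions, distances, one-zero
# sampling and transfer classification.

test_that("parenting parameters match the hand-computed fixture", {
  s <- fixture_session_carried580()
  p <- parenting_params(s)
  expect_equal(p$ret_latency_s, 30)
  expect_false(p$censored)
  expect_equal(p$pct_carry, 100 * 580 / 630, tolerance = 1e-9)
  expect_equal(p$pct_rejection, 100 * 2 / 580, tolerance = 1e-9)
  expect_equal(round(p$pct_carry, 2), 92.06)
  expect_equal(round(p$pct_rejection, 3), 0.345)
})

test_that("degenerate sessions give censored latency and zero/NA rates", {
  ev <- make_events("T1", list("infant", "in_basket", 0, 600))
  s <- build_session(make_meta("T1"), ev)
  p <- parenting_params(s)
  expect_true(p$censored)
  expect_equal(p$ret_latency_s, 600)
  expect_equal(p$pct_carry, 0)
  expect_true(is.na(p$pct_rejection)) # never carried: undefined

  # carried but never rejected -> %Rejection = 0
  ev2 <- make_events(
    "T1",
    list("caregiver", "retrieval", 30, 30.2),
    list("caregiver", "carry_contact", 30, 630))
  expect_equal(parenting_params(build_session(make_meta("T1"), ev2))$pct_rejection, 0)
})

test_that("%Rejection is invariant under uniform time translation", {
  base <- function(shift) {
    ev <- make_events(
      "T1",
      list("caregiver", "retrieval", 30 + shift, 30.2 + shift),
      list("caregiver", "carry_contact", 30 + shift, 610 + shift),
      list("caregiver", "rejection", 100 + shift, 102 + shift))
    parenting_params(build_session(make_meta("T1"), ev))
  }
  expect_equal(base(0)$pct_rejection, base(40)$pct_rejection)
})

test_that("infant call metrics follow context durations and type mixes", {
  # 6 trills in 3 min of Holding -> 2 calls/min, trill proportion 1
  ev <- make_events(
    "T1",
    list("caregiver", "retrieval", 0, 0.2),
    list("caregiver", "carry_contact", 0, 180),
    list("infant", "dismount", 180, 180.2))
  calls <- tibble::tibble(
    session_id = "T1", caller = "infant", call_type = "trill",
    onset_s = seq(10, 160, length.out = 6), offset_s = seq(10, 160, length.out = 6) + 0.4)
  s <- build_session(make_meta("T1"), ev, calls)
  tl <- segment_contexts(s)
  m <- infant_metrics(s, tl)
  expect_equal(m$calls_carried_per_min, 2)
  mix <- m$call_type_mix[[1]]
  expect_equal(mix$prop[mix$context == "Holding" & mix$call_type == "trill"], 1)

  # no calls: carried frequency 0 (carried time exists), proportions absent
  s0 <- build_session(make_meta("T1"), ev)
  m0 <- infant_metrics(s0, segment_contexts(s0))
  expect_equal(m0$calls_carried_per_min, 0)
  expect_equal(nrow(m0$call_type_mix[[1]]), 0)
  # zero-duration context: frequency undefined, not zero
  rates <- m0$context_rates[[1]]
  expect_true(is.na(rates$calls_per_min[rates$context == "Transport"]))
})

test_that("avoidance counts voluntary dismounts plus cling refusals", {
  ev <- make_events(
    "T1",
    list("caregiver", "retrieval", 0, 0.2),
    list("caregiver", "carry_contact", 0, 100),
    list("infant", "dismount", 100, 100.2),   # no rejection -> voluntary
    list("caregiver", "contact", 200, 203))    # >= 1 s, no cling -> refusal
  s <- build_session(make_meta("T1"), ev)
  tl <- segment_contexts(s)
  lab <- classify_dismounts(extract_intervals(s))
  m <- infant_metrics(s, tl, lab)
  expect_equal(m$voluntary_dismounts, 1)
  expect_equal(m$cling_refusals, 1)
  expect_equal(m$avoidance_count, 2)
  expect_true(m$premature) # pnd 10 < 28

  # a fleeting touch (< 1 s) is not a refusal; a cling cancels one
  ev2 <- dplyr::bind_rows(
    make_events("T1",
                list("caregiver", "retrieval", 0, 0.2),
                list("caregiver", "carry_contact", 0, 100),
                list("infant", "dismount", 100, 100.2),
                list("caregiver", "contact", 200, 200.6),
                list("caregiver", "contact", 300, 303),
                list("infant", "cling", 301, 301.4)))
  s2 <- build_session(make_meta("T1"), ev2)
  m2 <- infant_metrics(s2, segment_contexts(s2),
                       classify_dismounts(extract_intervals(s2)))
  expect_equal(m2$cling_refusals, 0)
})

test_that("injecting voluntary dismounts never decreases avoidance", {
  set.seed(9)
  for (i in 1:8) {
    s <- random_session(300 + i)
    tl <- segment_contexts(s)
    lab <- classify_dismounts(extract_intervals(s))
    m1 <- infant_metrics(s, tl, lab)$avoidance_count
    extra <- dplyr::bind_rows(
      lab, tibble::tibble(session_id = s$meta$session_id, time = 1,
                          interval_s = NA_real_, pnd = s$meta$pnd,
                          label = "voluntary"))
    m2 <- infant_metrics(s, tl, extra)$avoidance_count
    expect_gte(m2, m1 + 1L)
  }
})

test_that("transition call ratios pair before/after counts", {
  ev <- make_events(
    "T1",
    list("infant", "in_basket", 0, 30),
    list("caregiver", "retrieval", 30, 30.2),
    list("caregiver", "carry_contact", 30, 630))
  # 4 calls in [20,30), 4 in [30,40) -> ratio 1
  calls <- tibble::tibble(
    session_id = "T1", caller = "infant", call_type = "phee",
    onset_s = c(21, 23, 25, 27, 31, 33, 35, 37),
    offset_s = c(21, 23, 25, 27, 31, 33, 35, 37) + 0.4)
  s <- build_session(make_meta("T1"), ev, calls)
  tl <- segment_contexts(s)
  tr <- transition_call_ratio(s, tl, "Alone_BeforeRET", "Holding")
  expect_equal(tr$before, 4)
  expect_equal(tr$after, 4)
  expect_equal(tr$ratio, 1)

  # calls stop at retrieval -> ratio 0
  calls2 <- dplyr::mutate(calls, onset_s = onset_s - 10, offset_s = offset_s - 10)
  s2 <- build_session(make_meta("T1"), ev, calls2)
  tr2 <- transition_call_ratio(s2, segment_contexts(s2),
                               "Alone_BeforeRET", "Holding")
  expect_equal(tr2$ratio, 0)

  # zero before-count is excluded-and-flagged
  calls3 <- dplyr::filter(calls, onset_s > 30)
  s3 <- build_session(make_meta("T1"), ev, calls3)
  tr3 <- transition_call_ratio(s3, segment_contexts(s3),
                               "Alone_BeforeRET", "Holding")
  expect_true(tr3$excluded)
  expect_true(is.na(tr3$ratio))
})

test_that("min-max normalization maps onto [0, 1] affinely", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- rnorm(20)
  n <- minmax_normalize(x)
  expect_equal(n[which.min(x)], 0)
  expect_equal(n[which.max(x)], 1)
  expect_error(minmax_normalize(c(3, 3, 3)), "constant")
  expect_error(minmax_normalize(5), "at least 2")
})

test_that("dyadic distances compare same-caregiver vs same-infant pairs", {
  summaries <- tibble::tibble(
    caregiver_id = c("M", "M", "F", "F"),
    infant_id = c("i1", "i2", "i1", "i2"),
    birth_id = "b1",
    avoidance_count = c(0, 0, 3, 6),
    calls_carried_per_min = c(0, 0, 4, 8))
  dp <- dyad_distance_pairs(summaries)
  # the two M dyads coincide at the normalized origin -> DI_SC includes 0
  expect_true(0 %in% dp$di_sc$distance)
  expect_equal(nrow(dp$di_sc), 2)
  expect_equal(nrow(dp$si_dc), 2)
  expect_s3_class(dp$test, "dyad_test")

  # hand-checked distance: points (0,0) and (0.3, 0.4) are 0.5 apart
  pts <- tibble::tibble(
    caregiver_id = c("M", "M"), infant_id = c("i1", "i2"), birth_id = "b1",
    avoidance_count = c(0, 0.3), calls_carried_per_min = c(0, 0.4))
  # normalize over a third dyad so the pair keeps its raw scale
  pts <- dplyr::bind_rows(pts, tibble::tibble(
    caregiver_id = "F", infant_id = "i1", birth_id = "b1",
    avoidance_count = 1, calls_carried_per_min = 1))
  dp2 <- dyad_distance_pairs(pts)
  di <- dp2$di_sc$distance[dp2$di_sc$caregiver_id == "M"]
  expect_equal(di, 0.5)

  expect_error(dyad_distance_pairs(summaries[1, ]), "at least 2")
})

test_that("distance comparison is invariant to order and affine rescaling", {
  set.seed(21)
  summaries <- tibble::tibble(
    caregiver_id = rep(c("M", "F"), each = 4),
    infant_id = rep(sprintf("i%d", 1:4), 2),
    birth_id = rep(c("b1", "b1", "b2", "b2"), 2),
    avoidance_count = runif(8, 0, 5),
    calls_carried_per_min = runif(8, 0, 10))
  d1 <- dyad_distance_pairs(summaries)
  shuffled <- summaries[sample(nrow(summaries)), ]
  d2 <- dyad_distance_pairs(shuffled)
  expect_equal(sort(d1$di_sc$distance), sort(d2$di_sc$distance))
  rescaled <- dplyr::mutate(summaries,
                            avoidance_count = 3 * avoidance_count + 7,
                            calls_carried_per_min = 0.5 * calls_carried_per_min - 2)
  d3 <- dyad_distance_pairs(rescaled)
  expect_equal(sort(d1$si_dc$distance), sort(d3$si_dc$distance))
})

test_that("one-zero sampling scores any overlap per 10-s bin", {
  ev <- tibble::tibble(session_id = "A", actor = "infant", behavior = "calling",
                       onset_s = 12, offset_s = 13)
  oz <- one_zero_aggregate(ev, bin_s = 10, span_s = 40)
  expect_equal(oz$occurred, c(0, 1, 0, 0))

  ev2 <- tibble::tibble(session_id = "A", actor = "infant", behavior = "calling",
                        onset_s = 8, offset_s = 31)
  oz2 <- one_zero_aggregate(ev2, bin_s = 10, span_s = 40)
  expect_equal(oz2$occurred, c(1, 1, 1, 1))

  oz3 <- one_zero_aggregate(ev2[0, ], bin_s = 10, span_s = 30)
  expect_true(all(oz3$occurred == 0))
})

test_that("transfers are classified direct vs nondirect", {
  expect_equal(classify_transfers(c("M", "M", "F"))$type, "direct")
  tr <- classify_transfers(c("M", "none", "F"))
  expect_equal(tr$type, "nondirect")
  expect_equal(nrow(classify_transfers(c("M", "M", "M"))), 0)
  tr2 <- classify_transfers(c("M", "M", "F", NA, NA, "S", "S"))
  expect_equal(tr2$type, c("direct", "nondirect"))
  expect_equal(tr2$from, c("M", "F"))
})
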