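# Rejection-to-dismount intervals, log-survivorship, the segmented fit and
# the forced/voluntary classification.

test_that("intervals attach to the most recent preceding rejection", {
  ev <- make_events(
    "T1",
    list("caregiver", "retrieval", 10, 10.2),
    list("caregiver", "carry_contact", 10, 100.4),
    list("caregiver", "rejection", 99, 100),
    list("infant", "dismount", 100.4, 100.6))
  dm <- extract_intervals(build_session(make_meta("T1"), ev))
  expect_equal(dm$interval_s, 0.4)

  # no preceding rejection -> interval absent
  ev2 <- make_events(
    "T1",
    list("caregiver", "retrieval", 10, 10.2),
    list("caregiver", "carry_contact", 10, 50),
    list("infant", "dismount", 50, 50.2))
  expect_true(is.na(extract_intervals(build_session(make_meta("T1"), ev2))$interval_s))

  # two rejections ending 50 and 90, dismount 95 -> interval 5
  ev3 <- make_events(
    "T1",
    list("caregiver", "retrieval", 10, 10.2),
    list("caregiver", "carry_contact", 10, 95),
    list("caregiver", "rejection", 49, 50),
    list("caregiver", "rejection", 89, 90),
    list("infant", "dismount", 95, 95.2))
  expect_equal(extract_intervals(build_session(make_meta("T1"), ev3))$interval_s, 5)
})

test_that("log-survivorship matches the definitional values", {
  s <- log_survivorship(c(1, 2, 3, 4))
  expect_equal(s$t, 1:4)
  expect_equal(s$surv, c(1, 0.75, 0.5, 0.25))
  expect_equal(s$ln_surv, log(c(1, 0.75, 0.5, 0.25)))

  s1 <- log_survivorship(5)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$ln_surv, 0)

  # duplicates collapse to the smallest survivor proportion at that t
  sd <- log_survivorship(c(2, 2, 3))
  expect_equal(sd$surv[sd$t == 2], 2 / 3)

  expect_error(log_survivorship(numeric()), "No intervals")
  expect_error(log_survivorship(c(1, 0)), "positive")
})

test_that("ln S is non-increasing for random interval sets", {
  set.seed(7)
  for (i in 1:20) {
    s <- log_survivorship(rexp(sample(5:50, 1), 0.2) + 0.1)
    expect_true(all(diff(s$ln_surv) <= 1e-12))
  }
})

test_that("the two-segment fit recovers an exact breakpoint with zero SSE", {
  t <- c(1:5, 6:10)
  y <- ifelse(t <= 5, -0.5 * t, -2.5 - 0.1 * (t - 5))
  fit <- fit_breakpoint(tibble::tibble(t = t, ln_surv = y))
  expect_equal(fit$breakpoint_s, 5)
  expect_lt(fit$sse, 1e-20)
  expect_equal(unname(fit$slopes), c(-0.5, -0.1), tolerance = 1e-9)
  expect_false(fit$degenerate)

  # collinear points: no real change point
  fit1 <- fit_breakpoint(tibble::tibble(t = 1:10, ln_surv = -0.3 * (1:10)))
  expect_true(fit1$degenerate)

  expect_error(fit_breakpoint(tibble::tibble(t = 1:5, ln_surv = -(1:5))),
               "at least 6")
})

test_that("the fit equals exhaustive constrained least squares on small inputs", {
  # independent oracle: for each admissible breakpoint solve the
  # continuity-constrained problem in the (value-at-c, slopes) basis
  oracle <- function(t, y) {
    cands <- unique(t)
    cands <- cands[vapply(cands, function(cc)
      sum(t <= cc) >= 3 && sum(t >= cc) >= 3 && cc > min(t) && cc < max(t),
      logical(1))]
    best <- NULL
    for (cc in cands) {
      X <- cbind(1, ifelse(t <= cc, t - cc, 0), ifelse(t > cc, t - cc, 0))
      beta <- solve(crossprod(X), crossprod(X, y))
      sse <- sum((y - X %*% beta)^2)
      if (is.null(best) || sse < best$sse - 1e-12) best <- list(c = cc, sse = sse)
    }
    best
  }
  set.seed(11)
  for (i in 1:15) {
    n <- sample(8:30, 1)
    t <- sort(runif(n, 0, 20))
    bp <- runif(1, 5, 15)
    y <- ifelse(t <= bp, -0.4 * t, -0.4 * bp - 0.05 * (t - bp)) + rnorm(n, 0, 0.05)
    fit <- fit_breakpoint(tibble::tibble(t = t, ln_surv = y))
    exp <- oracle(t, y)
    expect_equal(fit$breakpoint_s, exp$c)
    expect_equal(fit$sse, exp$sse, tolerance = 1e-8)
  }
})

test_that("classification applies the threshold rule with the boundary forced", {
  dm <- tibble::tibble(session_id = "A", time = 1:4,
                       interval_s = c(0.4, NA, 417.2, 9.4), pnd = 10L)
  lab <- classify_dismounts(dm, threshold_s = 9.4)
  expect_equal(lab$label, c("forced", "voluntary", "voluntary", "forced"))
  strict <- classify_dismounts(dm, threshold_s = 9.4, inclusive = FALSE)
  expect_equal(strict$label[4], "voluntary")
})

test_that("raising the threshold never converts forced to voluntary", {
  set.seed(3)
  dm <- tibble::tibble(session_id = "A", time = seq_len(80),
                       interval_s = ifelse(runif(80) < 0.2, NA, rexp(80, 0.1)),
                       pnd = 10L)
  prev <- classify_dismounts(dm, threshold_s = 1)$label
  for (th in c(3, 9.4, 30, 100)) {
    cur <- classify_dismounts(dm, threshold_s = th)$label
    expect_true(all(!(prev == "forced" & cur == "voluntary")))
    prev <- cur
  }
  # conservation: forced fraction = fraction of intervals <= threshold
  lab <- classify_dismounts(dm, threshold_s = 9.4)
  expect_equal(sum(lab$label == "forced"),
               sum(!is.na(dm$interval_s) & dm$interval_s <= 9.4))
})

test_that("voluntary proportions reproduce the worked-example composition", {
  lab <- classify_dismounts(example_dismounts(), threshold_s = 9.4)
  vp <- voluntary_proportions(lab, pnd_cut = 28)
  expect_equal(vp$pct_voluntary[vp$age_class == "pnd<28"], 23.4)
  expect_equal(vp$pct_voluntary[vp$age_class == "pnd>=28"], 52.6)
  expect_equal(vp$pct_voluntary[vp$age_class == "overall"], 33.5)
  expect_equal(vp$voluntary_n[vp$age_class == "overall"], 55)
  expect_equal(vp$total[vp$age_class == "overall"], 164)

  all_forced <- tibble::tibble(session_id = "A", time = 1:5,
                               interval_s = rep(1, 5), pnd = 10L) |>
    classify_dismounts()
  expect_equal(voluntary_proportions(all_forced)$pct_voluntary,
               c(0, 0))
})

test_that("breakpoint recovery works on simulated two-phase intervals", {
  cfg <- sim_config()
  for (seed in c(5, 17, 23)) {
    set.seed(seed)
    iv <- simulate_dismount_intervals(130, cfg)
    fit <- fit_breakpoint(log_survivorship(iv))
    expect_lt(abs(fit$breakpoint_s - 9.4), 2)
    expect_false(fit$degenerate)
  }
})

test_that("tidy and glance expose the fit as tibbles", {
  t <- 1:10
  y <- ifelse(t <= 5, -0.5 * t, -2.5 - 0.1 * (t - 5))
  fit <- fit_breakpoint(tibble::tibble(t = t, ln_surv = y))
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$term == "breakpoint"], 5)
  expect_equal(generics::glance(fit)$n_points, 10)
})
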