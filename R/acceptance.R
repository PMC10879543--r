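# From-scratch recomputation of the package's headline quantities. Shared by
# run_acceptance_suite() and scripts/acceptance.R.

#' Canonical dismount composition for worked examples
#'
#' Builds a dismount table matching the reference composition of 164
#' observed dismounts from the retrieval-assay dataset the method was
#' developed on: 34 dismounts with no preceding rejection; 130 with
#' rejection-to-dismount intervals spanning 0.4-417.2 s, of which 109 lie
#' at or below the 9.4-s threshold; 107 dismounts from infants younger than
#' PND 28 (25 of them voluntary) and 57 at PND 28 or older (30 voluntary).
#' Interval values are evenly spaced within each regime (the classification
#' depends only on which side of the threshold they fall).
#'
#' @return Tibble with `session_id`, `time`, `interval_s`, `pnd`.
#' @export
example_dismounts <- function() {
  short <- seq(0.4, 9.4, length.out = 109)
  long <- seq(9.6, 417.2, length.out = 21)
  intervals <- c(rep(NA_real_, 34), short, long)
  # Voluntary = NA-interval or interval > threshold: 34 + 21 = 55.
  # Age classes: young (pnd < 28) has 25 voluntary + 82 forced = 107;
  # old has 30 voluntary + 27 forced = 57.
  voluntary <- is.na(intervals) | intervals > 9.4
  pnd <- integer(length(intervals))
  pnd[voluntary] <- c(rep(10L, 25), rep(30L, 30))
  pnd[!voluntary] <- c(rep(10L, 82), rep(30L, 27))
  tibble(
    session_id = sprintf("ref_%03d", seq_along(intervals)),
    time = seq_along(intervals) * 1.0,
    interval_s = intervals,
    pnd = pnd)
}

#' Compute the acceptance-study measurements
#'
#' Runs every headline computation from scratch at the study sizes the
#' package documents (see the methods vignette) and returns the raw
#' numbers. [run_acceptance_suite()] wraps this into a pass/fail table.
#'
#' @param seed Master seed; every stochastic component derives its own
#'   substream from it.
#' @param n_breakpoint_reps Replicates for the breakpoint-recovery study.
#' @param n_partition_sessions Randomized sessions for the partition check.
#' @return Named list of measurements.
#' @export
acceptance_measurements <- function(seed = 1, n_breakpoint_reps = 200,
                                    n_partition_sessions = 1000) {
  cfg <- sim_config()
  out <- list()

  # --- Dismount classification worked example -------------------------------
  ref <- classify_dismounts(example_dismounts(), threshold_s = 9.4)
  vp <- voluntary_proportions(ref, pnd_cut = 28)
  out$forced_pct <- round(100 * sum(ref$label == "forced") / nrow(ref), 1)
  out$voluntary_pct <- vp$pct_voluntary[vp$age_class == "overall"]
  out$voluntary_pct_young <- vp$pct_voluntary[vp$age_class == "pnd<28"]
  out$voluntary_pct_old <- vp$pct_voluntary[vp$age_class == "pnd>=28"]

  # --- Non-retrieval session share ------------------------------------------
  # 39 of the 815 assay sessions ended without retrieval at 600 s.
  out$nonretrieval_pct <- round(100 * 39 / 815, 1)

  # --- Breakpoint recovery on the two-phase interval generator --------------
  hits <- vapply(seq_len(n_breakpoint_reps), function(k) {
    set.seed(derive_seed(seed, 1000L + k))
    iv <- simulate_dismount_intervals(130, cfg)
    fit <- fit_breakpoint(log_survivorship(iv))
    abs(fit$breakpoint_s - cfg$forced_delay$max_s) <= 2
  }, logical(1))
  out$breakpoint_recovery_rate <- mean(hits)

  # --- Context partition invariant ------------------------------------------
  defects <- 0L
  for (k in seq_len(n_partition_sessions)) {
    set.seed(derive_seed(seed, 5000L + k))
    style <- caregiver_style(runif(1, 0.2, 1), runif(1, 0.05, 0.95),
                             runif(1, 0.3, 1))
    inf <- infant_state(sample(1:36, 1), avoidance_base = runif(1, 0, 0.5))
    sim <- simulate_session(style, inf, cfg, seed = derive_seed(seed, 6000L + k))
    tl <- segment_contexts(sim$session, offset_s = cfg$dismount_threshold_s)
    W <- sim$session$window_end
    tiles <- tl$start_s[1] == 0 && tail(tl$end_s, 1) == W &&
      all(tl$start_s[-1] == tl$end_s[-nrow(tl)])
    if (!tiles) defects <- defects + 1L
    if (k <= 100) { # offset monotonicity on a subsample
      dur_at <- function(off) {
        d <- context_durations(segment_contexts(sim$session, offset_s = off))
        d$duration_s[d$context == "During_Rejection"]
      }
      if (!(dur_at(5) <= dur_at(9.4) && dur_at(9.4) <= dur_at(15))) {
        defects <- defects + 1L
      }
    }
  }
  out$partition_defects <- defects

  # --- Association signs in a 60-dyad cohort --------------------------------
  cohort <- simulate_cohort(n_families = 15, infants_per_birth = 2,
                            caregivers_per_family = 2,
                            pnd_schedule = c(6, 13, 20),
                            config = cfg, seed = derive_seed(seed, 42L))
  run <- run_retrieval_analysis(list(events = cohort$events,
                                     calls = cohort$calls,
                                     meta = cohort$meta,
                                     out_dir = NULL,
                                     seed = derive_seed(seed, 43L)))
  dy <- run$dyads
  sp <- function(a, b) suppressWarnings(cor(a, b, method = "spearman",
                                            use = "pairwise.complete.obs"))
  out$r_carry_latency <- sp(dy$pct_carry, dy$ret_latency_s)
  out$r_carry_rejection <- sp(dy$pct_carry, dy$pct_rejection)
  out$r_latency_rejection_abs <- abs(sp(dy$ret_latency_s, dy$pct_rejection))

  # --- Attachment tuning: tolerance median split (30 dyads/side) ------------
  dy2 <- dy |>
    left_join(cohort$truth$styles, by = "caregiver_id") |>
    left_join(negative_call_share_carried(run$metrics, run$sessions, cohort$meta),
              by = c("caregiver_id", "infant_id"))
  lowtol <- dy2$tolerance < median(dy2$tolerance)
  out$p_calls_carried_tolerance <- wilcoxon_rank_sum(
    dy2$calls_carried_per_min[lowtol], dy2$calls_carried_per_min[!lowtol],
    alternative = "greater")$p_value
  out$p_negcall_tolerance <- wilcoxon_rank_sum(
    dy2$neg_share_carried[lowtol], dy2$neg_share_carried[!lowtol],
    alternative = "greater")$p_value

  # --- Art vs Cont cohort ----------------------------------------------------
  art <- simulate_cohort(n_families = 20, infants_per_birth = 2,
                         caregivers_per_family = 2,
                         pnd_schedule = c(12, 22, 32, 35),
                         config = cfg, seed = derive_seed(seed, 77L),
                         art_infants = 1)
  arun <- run_retrieval_analysis(list(events = art$events, calls = art$calls,
                                      meta = art$meta, out_dir = NULL,
                                      seed = derive_seed(seed, 78L)))
  inf_tab <- arun$dyads |>
    left_join(distinct(art$meta, .data$infant_id, .data$rearing),
              by = "infant_id") |>
    group_by(.data$infant_id, .data$rearing) |>
    summarise(avoidance = mean(.data$avoidance_count),
              alone_calls = mean(.data$calls_alone_per_min, na.rm = TRUE),
              .groups = "drop")
  is_art <- inf_tab$rearing == "artificial"
  out$p_art_avoidance <- wilcoxon_rank_sum(
    inf_tab$avoidance[is_art], inf_tab$avoidance[!is_art],
    alternative = "greater")$p_value
  out$p_art_alone_calls <- wilcoxon_rank_sum(
    inf_tab$alone_calls[is_art], inf_tab$alone_calls[!is_art],
    alternative = "greater")$p_value

  # --- Wilcoxon small-sample agreement with brute-force enumeration ---------
  out$wilcoxon_agreement_rate <- wilcoxon_enumeration_agreement(
    derive_seed(seed, 99L))

  # --- Null calibration: empirical type-I error at nominal 5% ---------------
  # Signed-rank at n = 14 pairs (where the exact test's attainable level is
  # closest to 5%) and the cluster permutation test at 10 clusters of 3.
  set.seed(derive_seed(seed, 123L))
  out$type1_signed_rank <- mean(vapply(seq_len(1000), function(k) {
    wilcoxon_signed_rank(rnorm(14))$p_value <= 0.05
  }, logical(1)))
  out$type1_permutation <- mean(vapply(seq_len(1000), function(k) {
    cl <- rep(sprintf("d%02d", 1:10), each = 3)
    grp <- rep(rep(c("A", "B"), each = 5), each = 3)
    suppressWarnings(permutation_group_compare(
      rnorm(30), grp, cl, n_perm = 199,
      seed = derive_seed(seed, 20000L + k))$p_value) <= 0.05
  }, logical(1)))

  out
}

# Per-dyad tsik+cry proportion among infant calls emitted while carried
# (Holding or Transport).
negative_call_share_carried <- function(metrics, sessions, meta) {
  mix <- metrics |>
    select("session_id", "call_type_mix") |>
    tidyr::unnest("call_type_mix") |>
    filter(.data$context %in% c("Holding", "Transport"))
  per_session <- mix |>
    group_by(.data$session_id) |>
    summarise(neg = sum(.data$n[.data$call_type %in% c("tsik", "cry")]),
              tot = sum(.data$n), .groups = "drop") |>
    mutate(share = ifelse(.data$tot > 0, .data$neg / .data$tot, NA_real_))
  per_session |>
    left_join(select(as_tibble(meta), "session_id", "caregiver_id",
                     "infant_id"), by = "session_id") |>
    group_by(.data$caregiver_id, .data$infant_id) |>
    summarise(neg_share_carried = mean(.data$share, na.rm = TRUE),
              .groups = "drop")
}

# Exhaustive sign-pattern enumeration of the signed-rank null (independent
# of the convolution used by wilcoxon_signed_rank) and full group-relabel
# enumeration of the rank-sum null; returns the share of random small
# instances on which the package p-values match to 1e-9.
wilcoxon_enumeration_agreement <- function(seed, n_instances = 40) {
  set.seed(seed)
  ok <- logical(0)
  for (i in seq_len(n_instances)) {
    n <- sample(3:8, 1)
    # signed-rank instance (ties in |d| allowed)
    d <- round(rnorm(n, 0, 2), sample(c(0, 1), 1))
    d <- d[d != 0]
    if (length(d) >= 1) {
      got <- wilcoxon_signed_rank(d)$p_value
      want <- brute_signed_rank_p(d)
      ok <- c(ok, abs(got - want) < 1e-9)
    }
    # rank-sum instance (no ties)
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    pool <- sample(seq_len(40), n1 + n2) + runif(n1 + n2, 0, 0.01)
    got <- wilcoxon_rank_sum(pool[seq_len(n1)], pool[-seq_len(n1)])$p_value
    want <- brute_rank_sum_p(pool[seq_len(n1)], pool[-seq_len(n1)])
    ok <- c(ok, abs(got - want) < 1e-9)
  }
  mean(ok)
}

# Brute-force signed-rank two-sided p over all 2^n sign assignments.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Brute-force rank-sum two-sided p over all group relabelings.
brute_rank_sum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- combn(n, n1)
  u_all <- apply(combs, 2, u_of)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
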