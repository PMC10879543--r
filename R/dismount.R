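# Rejection-to-dismount interval analysis. An infant's dismount from the
# carrier is "forced" when it follows a rejection closely enough to be under
# its influence; the threshold separating forced from voluntary dismounts is
# estimated as the breakpoint of a two-segment regression on the
# log-survivorship curve of the rejection-to-dismount intervals.

#' Extract rejection-to-dismount intervals
#'
#' For every dismount event, measures the time since the end of the most
#' recent preceding rejection bout in the same session (across carrying
#' episodes; never across sessions). Dismounts with no preceding rejection
#' get an `NA` interval.
#'
#' @param sessions A `dyad_session` or list of them.
#' @return Tibble with one row per dismount: `session_id`, `time`,
#'   `interval_s` (NA when no rejection preceded) and `pnd`.
#' @export
extract_intervals <- function(sessions) {
  if (inherits(sessions, "dyad_session")) sessions <- list(sessions)
  rows <- purrr::map(sessions, function(s) {
    dm <- filter(s$events, .data$behavior == "dismount")
    if (nrow(dm) == 0) return(NULL)
    rej_ends <- filter(s$events, .data$behavior == "rejection")$offset_s
    interval <- vapply(dm$onset_s, function(t) {
      prev <- rej_ends[rej_ends <= t]
      if (length(prev) == 0) NA_real_ else t - max(prev)
    }, double(1))
    tibble(session_id = s$meta$session_id, time = dm$onset_s,
           interval_s = interval, pnd = s$meta$pnd)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(session_id = character(), time = double(),
                  interval_s = double(), pnd = integer())
  }
  out
}

#' Log-survivorship curve of interval data
#'
#' Computes the empirical survivor function S(t) = P(T >= t) at each observed
#' interval and returns its natural log. With sorted intervals t_(1) <= ... <=
#' t_(n), S(t_(i)) = (n - i + 1)/n; duplicated t values are collapsed to the
#' smallest S at that t.
#'
#' @param intervals Numeric vector of positive intervals (seconds).
#' @return Tibble with columns `t`, `surv`, `ln_surv`, one row per distinct
#'   interval value, `ln_surv` non-increasing in `t`.
#' @export
log_survivorship <- function(intervals) {
  intervals <- intervals[!is.na(intervals)]
  if (length(intervals) == 0) abort("No intervals supplied.")
  if (any(intervals <= 0)) abort("Intervals must be positive.")
  n <- length(intervals)
  t <- sort(intervals)
  s <- (n - seq_len(n) + 1) / n
  keep <- !duplicated(t, fromLast = TRUE) # smallest S per distinct t
  tibble(t = t[keep], surv = s[keep], ln_surv = log(s[keep]))
}

#' Fit a continuity-constrained two-segment regression
#'
#' Fits a piecewise-linear model with one breakpoint to (t, ln S) points by
#' profiled least squares: every observed t value with at least three points
#' on each side is a candidate breakpoint; for each candidate the hinge model
#' y ~ t + max(t - c, 0) (continuous at c) is fitted by OLS; the candidate
#' with minimal SSE wins, ties broken toward the smaller breakpoint.
#'
#' @param points Tibble/data frame with columns `t` and `ln_surv` (as from
#'   [log_survivorship()]), at least 6 points.
#' @return A `breakpoint_fit` object: breakpoint, left/right slopes and
#'   intercepts, SSE, single-line SSE, n, and a `degenerate` flag set when
#'   the two-segment fit improves on a single line by less than 1% of SSE.
#' @export
fit_breakpoint <- function(points) {
  points <- as_tibble(points)
  stopifnot(all(c("t", "ln_surv") %in% names(points)))
  t <- points$t; y <- points$ln_surv
  n <- length(t)
  if (n < 6) abort("Need at least 6 points to fit a breakpoint.")
  ord <- order(t); t <- t[ord]; y <- y[ord]

  fit1 <- stats::lm.fit(cbind(1, t), y)
  sse1 <- sum(fit1$residuals^2)

  cands <- unique(t)
  cands <- cands[vapply(cands, function(cc) {
    sum(t <= cc) >= 3 && sum(t >= cc) >= 3 && cc > min(t) && cc < max(t)
  }, logical(1))]
  if (length(cands) == 0) {
    return(new_breakpoint_fit(NA_real_, c(fit1$coefficients[2], fit1$coefficients[2]),
                              c(fit1$coefficients[1], fit1$coefficients[1]),
                              sse1, sse1, n, degenerate = TRUE))
  }

  sses <- vapply(cands, function(cc) {
    X <- cbind(1, t, pmax(t - cc, 0))
    sum(stats::lm.fit(X, y)$residuals^2)
  }, double(1))
  best <- which(sses <= min(sses) + 1e-12)
  cc <- min(cands[best]) # tie toward the smaller breakpoint
  X <- cbind(1, t, pmax(t - cc, 0))
  fit2 <- stats::lm.fit(X, y)
  b <- fit2$coefficients
  sse2 <- sum(fit2$residuals^2)

  degenerate <- if (sse1 <= 1e-12) TRUE else (sse1 - sse2) / sse1 < 0.01
  new_breakpoint_fit(
    breakpoint_s = cc,
    slopes = c(left = unname(b[2]), right = unname(b[2] + b[3])),
    intercepts = c(left = unname(b[1]), right = unname(b[1] - b[3] * cc)),
    sse = sse2, sse_single = sse1, n_points = n, degenerate = degenerate)
}

new_breakpoint_fit <- function(breakpoint_s, slopes, intercepts, sse,
                               sse_single, n_points, degenerate) {
  structure(
    list(breakpoint_s = breakpoint_s, slopes = slopes, intercepts = intercepts,
         sse = sse, sse_single = sse_single, n_points = n_points,
         degenerate = degenerate),
    class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf(
    "<breakpoint_fit> breakpoint %.2f s (n = %d)%s\n  slopes: %.4f / %.4f, SSE %.4g (single-line %.4g)\n",
    x$breakpoint_s, x$n_points, if (x$degenerate) " [degenerate]" else "",
    x$slopes[1], x$slopes[2], x$sse, x$sse_single))
  invisible(x)
}

#' @export
tidy.breakpoint_fit <- function(x, ...) {
  tibble(
    term = c("breakpoint", "slope_left", "slope_right",
             "intercept_left", "intercept_right"),
    estimate = unname(c(x$breakpoint_s, x$slopes[1], x$slopes[2],
                        x$intercepts[1], x$intercepts[2])))
}

#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble(breakpoint_s = x$breakpoint_s, sse = x$sse,
         sse_single = x$sse_single, n_points = x$n_points,
         degenerate = x$degenerate)
}

#' Plot a log-survivorship curve with its fitted two-segment line
#'
#' @param object A `breakpoint_fit`.
#' @param points The (t, ln_surv) tibble the fit was computed from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breakpoint_fit <- function(object, points, ...) {
  points <- as_tibble(points)
  pred <- function(t) {
    ifelse(t <= object$breakpoint_s,
           object$intercepts[1] + object$slopes[1] * t,
           object$intercepts[2] + object$slopes[2] * t)
  }
  grid <- tibble(t = seq(min(points$t), max(points$t), length.out = 200))
  grid$ln_surv <- pred(grid$t)
  ggplot2::ggplot(points, ggplot2::aes(.data$t, .data$ln_surv)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, color = "red") +
    ggplot2::geom_vline(xintercept = object$breakpoint_s, linetype = 2) +
    ggplot2::labs(x = "Rejection-to-dismount interval (s)",
                  y = "ln S(t)") +
    ggplot2::theme_minimal()
}

#' Classify dismounts as forced or voluntary
#'
#' A dismount is forced when its rejection-to-dismount interval is at most
#' `threshold_s`; dismounts with longer intervals or with no preceding
#' rejection are voluntary. The boundary case (interval exactly equal to the
#' threshold) is forced by default, consistent with the post-rejection
#' context offset spanning up to `threshold_s` after the rejection end; set
#' `inclusive = FALSE` for a strict-inequality rule.
#'
#' @param dismounts Tibble from [extract_intervals()].
#' @param threshold_s Threshold in seconds (default 9.4).
#' @param inclusive Is an interval exactly at the threshold forced? (default
#'   TRUE).
#' @return The input tibble with a `label` column, `"forced"`/`"voluntary"`.
#' @export
classify_dismounts <- function(dismounts, threshold_s = 9.4, inclusive = TRUE) {
  if (threshold_s <= 0) abort("threshold_s must be > 0.")
  dismounts <- as_tibble(dismounts)
  forced <- if (inclusive) {
    !is.na(dismounts$interval_s) & dismounts$interval_s <= threshold_s
  } else {
    !is.na(dismounts$interval_s) & dismounts$interval_s < threshold_s
  }
  mutate(dismounts, label = ifelse(forced, "forced", "voluntary"))
}

#' Voluntary-dismount proportions by age class
#'
#' @param dismounts Labeled dismount tibble (from [classify_dismounts()]),
#'   with `pnd` and `label` columns.
#' @param pnd_cut Postnatal-day cut between the younger and older class
#'   (default 28; the younger class is `pnd < pnd_cut`).
#' @return Tibble with one row per age class plus an overall row:
#'   `age_class`, `voluntary_n`, `total`, `pct_voluntary` (1 decimal).
#' @export
voluntary_proportions <- function(dismounts, pnd_cut = 28) {
  dismounts <- as_tibble(dismounts)
  stopifnot(all(c("pnd", "label") %in% names(dismounts)))
  cls <- ifelse(dismounts$pnd < pnd_cut,
                sprintf("pnd<%d", pnd_cut), sprintf("pnd>=%d", pnd_cut))
  per <- tibble(age_class = cls, label = dismounts$label) |>
    group_by(.data$age_class) |>
    summarise(voluntary_n = sum(.data$label == "voluntary"),
              total = dplyr::n(), .groups = "drop")
  overall <- tibble(age_class = "overall",
                    voluntary_n = sum(dismounts$label == "voluntary"),
                    total = nrow(dismounts))
  bind_rows(per, overall) |>
    mutate(pct_voluntary = round(100 * .data$voluntary_n / .data$total, 1))
}
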