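# Partition of a session's analysis window into the five social contexts.
# All endpoints are multiples of the 0.2-s coding bin, so the partition is
# computed on integer bin indices and is exact: segments tile the window with
# zero gaps and zero overlaps by construction.

#' Segment a session into social contexts
#'
#' Partitions the analysis window into the five mutually exclusive,
#' collectively exhaustive social contexts: `Alone_BeforeRET` before the
#' first retrieval; carried time split into `Transport` (caregiver locomotion
#' overlapping carrying) and `Holding` (carrying without locomotion);
#' `During_Rejection` from the start of each rejection bout to `offset_s`
#' seconds after its end (overlapping extents merged); all remaining
#' uncarried time after the first retrieval is `Alone_AfterRET`.
#'
#' Precedence is During_Rejection > Transport/Holding > Alone_AfterRET: the
#' post-rejection offset captures infant behavior still under the influence
#' of the preceding rejection, so it overrides the carried/alone states —
#' including time after a dismount that falls inside the offset.
#'
#' @param session A `dyad_session` (see [build_session()]).
#' @param offset_s Post-rejection offset in seconds (default 9.4, the
#'   empirically fitted dismount threshold rounded to the coding grid).
#' @return A `context_timeline` tibble with columns `session_id`, `start_s`,
#'   `end_s`, `context`, carrying attributes `offset_s`, `window_end` and
#'   `retrieval_time`. Segments are ordered, contiguous and exactly tile
#'   `[0, window_end)`.
#' @export
segment_contexts <- function(session, offset_s = 9.4) {
  stopifnot(inherits(session, "dyad_session"))
  if (offset_s < 0) abort("offset_s must be >= 0.")
  W <- to_bins(session$window_end)
  ev <- session$events
  ret <- session$retrieval_time

  labels <- context_levels()
  if (W <= 0) abort("Session window has zero length.")

  # Per-bin label vector; bin k covers [k*0.2, (k+1)*0.2).
  lab <- integer(W) # 0 = unassigned
  ALONE_B <- 1L; HOLD <- 2L; TRANS <- 3L; REJ <- 4L; ALONE_A <- 5L

  if (is.na(ret)) {
    lab[] <- ALONE_B
  } else {
    r <- to_bins(ret)
    if (r > 0) lab[seq_len(r)] <- ALONE_B
    if (r < W) lab[(r + 1L):W] <- ALONE_A

    mark <- function(tab, value, only_over = NULL) {
      if (nrow(tab) == 0) return(invisible(NULL))
      for (i in seq_len(nrow(tab))) {
        a <- max(to_bins(tab$onset_s[i]), r)
        b <- min(to_bins(tab$offset_s[i]), W)
        if (b > a) {
          idx <- (a + 1L):b
          if (!is.null(only_over)) idx <- idx[lab[idx] %in% only_over]
          if (length(idx)) lab[idx] <<- value
        }
      }
    }
    carry <- filter(ev, .data$behavior == "carry_contact")
    mark(carry, HOLD)
    loco <- filter(ev, .data$behavior == "locomotion", .data$actor == "caregiver")
    # transport = locomotion while carried
    mark(loco, TRANS, only_over = HOLD)

    rej <- filter(ev, .data$behavior == "rejection")
    if (nrow(rej) > 0) {
      if (any(to_bins(rej$onset_s) < r)) {
        abort("Rejection before the first retrieval is invalid.")
      }
      ext <- rej
      ext$offset_s <- ext$offset_s + offset_s
      mark(ext, REJ)
    }
  }

  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- c(0L, head(ends, -1L))
  timeline <- tibble(
    session_id = session$meta$session_id,
    start_s = from_bins(starts),
    end_s = from_bins(ends),
    context = factor(labels[runs$values], levels = labels)
  )
  attr(timeline, "offset_s") <- offset_s
  attr(timeline, "window_end") <- session$window_end
  attr(timeline, "retrieval_time") <- ret
  class(timeline) <- c("context_timeline", class(timeline))
  timeline
}

#' Per-context durations and proportions
#'
#' @param timeline A `context_timeline` from [segment_contexts()].
#' @return A tibble with one row per context (all five always present):
#'   `context`, `duration_s`, `proportion`. Durations sum to the window
#'   length and proportions to 1.
#' @export
context_durations <- function(timeline) {
  W <- attr(timeline, "window_end")
  if (is.null(W)) W <- max(timeline$end_s)
  tibble(context = factor(context_levels(), levels = context_levels())) |>
    left_join(
      as_tibble(timeline) |>
        group_by(.data$context) |>
        summarise(duration_s = sum(.data$end_s - .data$start_s), .groups = "drop"),
      by = "context") |>
    mutate(duration_s = tidyr::replace_na(.data$duration_s, 0),
           proportion = .data$duration_s / W)
}

#' Locate context transitions
#'
#' Finds every boundary where `from_label` ends and `to_label` begins, for
#' paired before/after call-count comparisons around context shifts.
#'
#' @param timeline A `context_timeline`.
#' @param from_label,to_label Context labels (distinct).
#' @param window_s Half-window length in seconds (default 10).
#' @return Tibble with `time` (the boundary) and `has_full_windows`, TRUE iff
#'   both `[time - window_s, time)` and `[time, time + window_s)` lie inside
#'   the analysis window.
#' @export
locate_transitions <- function(timeline, from_label, to_label, window_s = 10) {
  labels <- context_levels()
  stopifnot(from_label %in% labels, to_label %in% labels)
  if (from_label == to_label) abort("from_label and to_label must differ.")
  W <- attr(timeline, "window_end")
  if (is.null(W)) W <- max(timeline$end_s)
  ctx <- as.character(timeline$context)
  idx <- which(ctx[-length(ctx)] == from_label & ctx[-1] == to_label)
  if (length(idx) == 0) {
    return(tibble(session_id = character(), time = double(),
                  has_full_windows = logical()))
  }
  t <- timeline$end_s[idx]
  tibble(
    session_id = timeline$session_id[idx],
    time = t,
    has_full_windows = (t - window_s >= 0) & (t + window_s <= W)
  )
}

#' @export
print.context_timeline <- function(x, ...) {
  cat(sprintf("<context_timeline> %s: %d segments over [0, %.1f) s (offset %.1f s)\n",
              x$session_id[1], nrow(x), attr(x, "window_end"),
              attr(x, "offset_s")))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Plot a context timeline
#'
#' Horizontal bar of the session colored by social context.
#'
#' @param object A `context_timeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.context_timeline <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_s, xmax = .data$end_s, ymin = 0, ymax = 1,
      fill = .data$context)) +
    ggplot2::scale_fill_brewer(palette = "Set2", drop = FALSE) +
    ggplot2::labs(x = "Time (s)", y = NULL, fill = "Context") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
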