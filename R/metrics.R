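# Per-session caregiver parenting parameters and infant attachment metrics,
# dyad-level aggregation, and the dyadic-distance comparison.

#' Caregiver parenting parameters for one session
#'
#' Computes the three core caregiving parameters: retrieval latency
#' (RET_Latency, negatively reflecting caregiver sensitivity), rejection rate
#' (%Rejection, rejection-bout duration as a percentage of carried time,
#' negatively reflecting tolerance) and carrying rate (%Carry, carried time
#' as a percentage of the session window, the net care quantity).
#'
#' @param session A `dyad_session`.
#' @param timeline Its `context_timeline` (currently unused beyond
#'   consistency checks; parameters are computed from events so that carried
#'   time is not reduced by the During_Rejection context override).
#' @param rejection_denominator `"carried"` (default; rejecting time /
#'   carrying time, matching the family-reunion definition "rejecting bins /
#'   carrying bins") or `"window"` (per-session duration).
#' @return One-row tibble: `session_id`, `ret_latency_s`, `censored` (TRUE
#'   when no retrieval occurred; the latency is then set to the window
#'   length and should be excluded from means), `pct_rejection` (NA when the
#'   infant was never carried), `pct_carry`.
#' @export
parenting_params <- function(session, timeline = NULL,
                             rejection_denominator = c("carried", "window")) {
  rejection_denominator <- match.arg(rejection_denominator)
  ev <- session$events
  W <- session$window_end
  carried <- interval_union_length(filter(ev, .data$behavior == "carry_contact"), W)
  rej <- interval_union_length(filter(ev, .data$behavior == "rejection"), W)
  censored <- is.na(session$retrieval_time)
  denom <- if (rejection_denominator == "carried") carried else W
  tibble(
    session_id = session$meta$session_id,
    ret_latency_s = if (censored) W else session$retrieval_time,
    censored = censored,
    pct_rejection = if (denom > 0) 100 * rej / denom else NA_real_,
    pct_carry = 100 * carried / W
  )
}

# Total length of the union of [onset, offset) intervals, clipped to [0, W].
interval_union_length <- function(tab, W) {
  if (nrow(tab) == 0) return(0)
  a <- pmax(tab$onset_s, 0); b <- pmin(tab$offset_s, W)
  keep <- b > a
  if (!any(keep)) return(0)
  a <- a[keep]; b <- b[keep]
  o <- order(a)
  a <- a[o]; b <- b[o]
  total <- 0; cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] > cur_b) {
      total <- total + (cur_b - cur_a)
      cur_a <- a[i]; cur_b <- b[i]
    } else {
      cur_b <- max(cur_b, b[i])
    }
  }
  total + (cur_b - cur_a)
}

#' Infant attachment metrics for one session
#'
#' Computes avoidant-behavior counts and context-dependent call usage.
#' Avoidance is the sum of voluntary dismounts and cling refusals (a
#' caregiver contact bout of at least `refusal_min_s` seconds containing no
#' infant cling onset, or an explicit `refusal` event when coded).
#' Calls-while-carried counts infant calls with onset in Holding or
#' Transport (During_Rejection is its own category, reported separately);
#' calls-alone counts onsets in either Alone context. Frequencies are calls
#' per minute of context time and are `NA` (undefined, not zero) for
#' contexts of zero duration.
#'
#' @param session A `dyad_session`.
#' @param timeline Its `context_timeline`.
#' @param dismounts Labeled dismount tibble from [classify_dismounts()]
#'   (may cover many sessions; filtered by session id). NULL means no
#'   dismounts.
#' @param refusal_min_s Minimum contact-bout length to count a missing cling
#'   as a refusal (default 1.0 s; shorter touches are ignored as fleeting).
#' @param pnd_cut Premature-avoidance flag cut (default 28: postnatal weeks
#'   0-3).
#' @return One-row tibble with scalar metrics plus two list-columns:
#'   `context_rates` (per-context call counts, durations, calls/min) and
#'   `call_type_mix` (per-context call-type proportions over phee, twitter,
#'   tsik, trill, cry, other; rows only for contexts with calls).
#' @export
infant_metrics <- function(session, timeline, dismounts = NULL,
                           refusal_min_s = 1.0, pnd_cut = 28) {
  sid <- session$meta$session_id
  vol <- 0L
  if (!is.null(dismounts) && nrow(dismounts) > 0) {
    dm <- filter(as_tibble(dismounts), .data$session_id == sid)
    vol <- sum(dm$label == "voluntary")
  }
  refusals <- count_cling_refusals(session, refusal_min_s)

  calls <- filter(session$calls, .data$caller == "infant")
  durs <- context_durations(timeline)
  calls$context <- locate_context(timeline, calls$onset_s)

  rates <- durs |>
    left_join(count(calls, .data$context, name = "n_calls"), by = "context") |>
    mutate(n_calls = as.integer(tidyr::replace_na(.data$n_calls, 0L)),
           calls_per_min = ifelse(.data$duration_s > 0,
                                  .data$n_calls / (.data$duration_s / 60),
                                  NA_real_)) |>
    select("context", "n_calls", "duration_s", "calls_per_min")

  mix <- calls |>
    mutate(group = group_call_type(.data$call_type)) |>
    count(.data$context, .data$group, name = "n") |>
    group_by(.data$context) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup() |>
    rename(call_type = "group")

  rate_of <- function(ctxs) {
    sub <- filter(rates, .data$context %in% ctxs)
    dur <- sum(sub$duration_s)
    if (dur > 0) sum(sub$n_calls) / (dur / 60) else NA_real_
  }

  tibble(
    session_id = sid,
    avoidance_count = vol + refusals,
    voluntary_dismounts = vol,
    cling_refusals = refusals,
    calls_carried_per_min = rate_of(c("Holding", "Transport")),
    calls_alone_per_min = rate_of(c("Alone_BeforeRET", "Alone_AfterRET")),
    premature = session$meta$pnd < pnd_cut,
    context_rates = list(rates),
    call_type_mix = list(mix)
  )
}

# Context label at each time point (half-open segments).
locate_context <- function(timeline, times) {
  if (length(times) == 0) {
    return(factor(character(), levels = context_levels()))
  }
  idx <- findInterval(times, timeline$start_s)
  idx[idx < 1] <- NA_integer_
  out <- timeline$context[idx]
  out[!is.na(idx) & times >= max(timeline$end_s)] <- NA
  out
}

count_cling_refusals <- function(session, refusal_min_s) {
  ev <- session$events
  explicit <- filter(ev, .data$behavior == "refusal")
  if (nrow(explicit) > 0) return(nrow(explicit))
  contacts <- filter(ev, .data$actor == "caregiver", .data$behavior == "contact",
                     .data$offset_s - .data$onset_s >= refusal_min_s)
  if (nrow(contacts) == 0) return(0L)
  clings <- filter(ev, .data$actor == "infant", .data$behavior == "cling")
  sum(vapply(seq_len(nrow(contacts)), function(i) {
    !any(clings$onset_s >= contacts$onset_s[i] &
           clings$onset_s < contacts$offset_s[i])
  }, logical(1)))
}

#' Infant call-count changes around context transitions
#'
#' For each transition from `from_label` to `to_label` with full 10-s windows
#' on both sides, counts infant calls with onset in `[t - window_s, t)` and
#' `[t, t + window_s)` and their after/before ratio (1 means no change).
#' Transitions with zero before-counts have an undefined ratio; they are kept
#' in the table, flagged `excluded = TRUE`, and omitted from the summary.
#'
#' @param sessions `dyad_session` or list of them.
#' @param timelines Matching `context_timeline` or list (same order).
#' @param from_label,to_label Context labels.
#' @param window_s Window length (default 10 s).
#' @return Tibble with one row per eligible transition: `session_id`, `time`,
#'   `before`, `after`, `ratio`, `excluded`. The paired (before, after)
#'   columns feed [wilcoxon_signed_rank()]; attribute `mean_ratio` carries
#'   the summary ratio over non-excluded transitions.
#' @export
transition_call_ratio <- function(sessions, timelines, from_label, to_label,
                                  window_s = 10) {
  if (inherits(sessions, "dyad_session")) {
    sessions <- list(sessions); timelines <- list(timelines)
  }
  rows <- purrr::map2(sessions, timelines, function(s, tl) {
    tr <- locate_transitions(tl, from_label, to_label, window_s)
    tr <- filter(tr, .data$has_full_windows)
    if (nrow(tr) == 0) return(NULL)
    calls <- filter(s$calls, .data$caller == "infant")
    tibble(
      session_id = s$meta$session_id,
      time = tr$time,
      before = vapply(tr$time, function(t) {
        sum(calls$onset_s >= t - window_s & calls$onset_s < t)
      }, double(1)),
      after = vapply(tr$time, function(t) {
        sum(calls$onset_s >= t & calls$onset_s < t + window_s)
      }, double(1)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(session_id = character(), time = double(), before = double(),
                  after = double(), ratio = double(), excluded = logical())
    attr(out, "mean_ratio") <- NA_real_
    return(out)
  }
  out <- mutate(out,
                ratio = ifelse(.data$before > 0, .data$after / .data$before, NA_real_),
                excluded = .data$before == 0)
  attr(out, "mean_ratio") <- mean(out$ratio[!out$excluded])
  out
}

#' Min-max normalization
#'
#' Maps values affinely onto `[0, 1]`: `(x - min(x)) / (max(x) - min(x))`.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return Normalized vector.
#' @export
minmax_normalize <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) abort("Need at least 2 values.")
  rng <- range(values, na.rm = TRUE)
  if (diff(rng) == 0) abort("Cannot min-max normalize a constant vector.")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Dyadic distances: same caregiver vs same infant
#'
#' In the min-max-normalized 2D space of the two attachment metrics
#' (avoidance count, calls while carried), computes segment lengths between
#' the two littermate-infant dyads of one caregiver within one birth (DI_SC)
#' and between two caregiver dyads of the same infant (SI_DC), then compares
#' the two sets of lengths by the Wilcoxon rank-sum test. Shorter DI_SC than
#' SI_DC means a caregiver elicits similar attachment behavior from
#' different infants.
#'
#' @param summaries Tibble with one row per dyad: `caregiver_id`,
#'   `infant_id`, `birth_id`, `avoidance_count`, `calls_carried_per_min`.
#' @return List with `di_sc` and `si_dc` distance tibbles, the normalized
#'   `points`, and `test` (the rank-sum comparison of SI_DC vs DI_SC).
#' @export
dyad_distance_pairs <- function(summaries) {
  summaries <- as_tibble(summaries)
  need <- c("caregiver_id", "infant_id", "birth_id",
            "avoidance_count", "calls_carried_per_min")
  stopifnot(all(need %in% names(summaries)))
  summaries <- filter(summaries,
                      !is.na(.data$avoidance_count),
                      !is.na(.data$calls_carried_per_min))
  if (nrow(summaries) < 2) abort("Need at least 2 dyads with both metrics.")
  pts <- summaries |>
    mutate(x = minmax_normalize(.data$avoidance_count),
           y = minmax_normalize(.data$calls_carried_per_min))

  pair_dists <- function(tab) {
    if (nrow(tab) < 2) return(double())
    idx <- combn(nrow(tab), 2)
    sqrt((tab$x[idx[1, ]] - tab$x[idx[2, ]])^2 +
           (tab$y[idx[1, ]] - tab$y[idx[2, ]])^2)
  }
  di_sc <- pts |>
    group_by(.data$caregiver_id, .data$birth_id) |>
    dplyr::group_modify(~ tibble(distance = pair_dists(.x))) |>
    ungroup()
  si_dc <- pts |>
    group_by(.data$infant_id) |>
    dplyr::group_modify(~ tibble(distance = pair_dists(.x))) |>
    ungroup()
  if (nrow(di_sc) == 0 || nrow(si_dc) == 0) {
    abort("Need at least one DI_SC pair and one SI_DC pair.")
  }
  list(
    di_sc = di_sc, si_dc = si_dc, points = pts,
    test = wilcoxon_rank_sum(si_dc$distance, di_sc$distance)
  )
}

#' One-zero sampling of behaviors into fixed bins
#'
#' Scores each `bin_s`-second bin 1 if the behavior overlaps the bin at all,
#' else 0 (half-open overlap).
#'
#' @param events Event tibble with `behavior`, `onset_s`, `offset_s`.
#' @param bin_s Bin width in seconds (default 10).
#' @param span_s Observation span; defaults to the last offset rounded up to
#'   a whole bin.
#' @return Tibble: `behavior`, `bin_start`, `bin_end`, `occurred` (0/1),
#'   one row per behavior x bin.
#' @export
one_zero_aggregate <- function(events, bin_s = 10, span_s = NULL) {
  events <- as_tibble(events)
  span_s <- span_s %||% (if (nrow(events) == 0) bin_s else
    ceiling(max(events$offset_s) / bin_s) * bin_s)
  starts <- seq(0, span_s - bin_s, by = bin_s)
  behaviors <- unique(events$behavior)
  if (length(behaviors) == 0) behaviors <- NA_character_
  tidyr::expand_grid(behavior = behaviors, bin_start = starts) |>
    mutate(
      bin_end = .data$bin_start + bin_s,
      occurred = purrr::map2_int(.data$behavior, .data$bin_start, function(bh, bs) {
        if (is.na(bh)) return(0L)
        sub <- events[events$behavior == bh, ]
        as.integer(any(sub$onset_s < bs + bin_s & sub$offset_s > bs))
      }))
}

#' Classify carrier-to-carrier transfers
#'
#' Given the per-bin carrier identity of an infant during a family reunion
#' (NA or "none" when not carried), each change of carrier is a transfer:
#' direct when the two carriers occupy adjacent bins, nondirect when at
#' least one not-carried bin intervenes (the infant dismounted and stayed
#' alone before being picked up by the next carrier).
#'
#' @param carrier_sequence Character vector of per-bin carrier ids; NA or
#'   "none" marks bins with the infant not carried.
#' @return Tibble with one row per transfer: `from`, `to`, `bin`, `type`.
#' @export
classify_transfers <- function(carrier_sequence) {
  x <- as.character(carrier_sequence)
  x[is.na(x)] <- "none"
  r <- rle(x)
  carriers <- which(r$values != "none")
  if (length(carriers) < 2) {
    return(tibble(from = character(), to = character(), bin = integer(),
                  type = character()))
  }
  ends <- cumsum(r$lengths)
  rows <- purrr::map(seq_along(carriers)[-1], function(k) {
    i <- carriers[k - 1]; j <- carriers[k]
    if (r$values[i] == r$values[j]) return(NULL)
    tibble(from = r$values[i], to = r$values[j],
           bin = ends[j - 1] + 1L,
           type = if (j == i + 1) "direct" else "nondirect")
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(from = character(), to = character(), bin = integer(),
                  type = character())
  }
  out
}

#' Aggregate per-session measures to dyads
#'
#' Averages parenting parameters and infant metrics per caregiver-infant
#' dyad. Censored retrieval latencies and sessions without a defined
#' %Rejection (never carried) are excluded from the respective means.
#'
#' @param params Row-bound [parenting_params()] output for all sessions.
#' @param metrics Row-bound [infant_metrics()] output.
#' @param meta Session metadata tibble.
#' @return Tibble with one row per dyad: ids, averaged measures,
#'   `n_sessions`.
#' @export
summarize_dyads <- function(params, metrics, meta) {
  meta <- as_tibble(meta)
  birth <- if ("birth_id" %in% names(meta)) meta$birth_id else meta$family_id
  key <- meta |>
    mutate(birth_id = birth) |>
    select("session_id", "caregiver_id", "infant_id", "birth_id")
  as_tibble(params) |>
    left_join(select(as_tibble(metrics), "session_id", "avoidance_count",
                     "calls_carried_per_min", "calls_alone_per_min"),
              by = "session_id") |>
    left_join(key, by = "session_id") |>
    group_by(.data$caregiver_id, .data$infant_id, .data$birth_id) |>
    summarise(
      ret_latency_s = mean(.data$ret_latency_s[!.data$censored]),
      pct_rejection = mean(.data$pct_rejection, na.rm = TRUE),
      pct_carry = mean(.data$pct_carry),
      avoidance_count = mean(.data$avoidance_count),
      calls_carried_per_min = mean(.data$calls_carried_per_min, na.rm = TRUE),
      calls_alone_per_min = mean(.data$calls_alone_per_min, na.rm = TRUE),
      n_sessions = dplyr::n(),
      .groups = "drop")
}
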