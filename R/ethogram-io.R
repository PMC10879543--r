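# Reading and validating behavioral event streams, call tables and session
# metadata. Event times are coded in 0.2-s bins by the annotation software;
# on ingestion every time is snapped to that grid and intervals are treated
# as half-open [onset, offset).

# Behavior codes the pipeline interprets. The coding vocabulary is open:
# unknown codes are kept (with a warning) so drifting ethograms do not break
# ingestion.
CORE_BEHAVIORS <- c(
  "carry_contact", "locomotion", "rejection", "contact", "cling",
  "dismount", "retrieval", "in_basket", "refusal"
)

event_cols <- c("session_id", "actor", "behavior", "onset_s", "offset_s")
call_cols  <- c("session_id", "caller", "call_type", "onset_s", "offset_s")
meta_cols  <- c("session_id", "family_id", "caregiver_id", "caregiver_role",
                "infant_id", "infant_sex", "pnd", "rearing", "assay",
                "nominal_duration")

#' Read a behavioral event stream
#'
#' Reads a CSV export of manually coded behaviors (one row per behavior bout,
#' columns `session_id, actor, behavior, onset_s, offset_s`), snaps times to
#' the coding-bin grid, and validates each record.
#'
#' @param path Path to the event CSV, or a data frame already in memory.
#' @param bin_width Coding-bin width in seconds (default 0.2).
#' @return A tibble of events sorted by `session_id` then `onset_s`, with
#'   times on the bin grid and intervals half-open `[onset, offset)`.
#' @details Unknown behavior codes are retained with a warning; a record whose
#'   offset is not strictly greater than its onset is an error that names the
#'   offending row. An empty (header-only) file yields an empty tibble with a
#'   warning.
#' @export
read_event_stream <- function(path, bin_width = BIN_WIDTH) {
  raw <- read_table_input(path, event_cols, "event stream")
  if (nrow(raw) == 0) {
    warn("Event stream is empty (header only).")
    return(empty_events())
  }
  ev <- raw |>
    mutate(
      session_id = as.character(.data$session_id),
      actor = as.character(.data$actor),
      behavior = as.character(.data$behavior),
      onset_s = snap_to_grid(as.numeric(.data$onset_s), bin_width),
      offset_s = snap_to_grid(as.numeric(.data$offset_s), bin_width)
    )
  validate_events(ev)
  arrange(ev, .data$session_id, .data$onset_s, .data$offset_s)
}

validate_events <- function(ev) {
  bad_actor <- !ev$actor %in% c("caregiver", "infant")
  if (any(bad_actor)) {
    abort(sprintf("Unknown actor in event row(s) %s (must be caregiver/infant).",
                  paste(which(bad_actor), collapse = ", ")))
  }
  bad_order <- ev$offset_s <= ev$onset_s
  if (any(bad_order)) {
    abort(sprintf("Event row(s) %s have offset <= onset.",
                  paste(which(bad_order), collapse = ", ")))
  }
  if (any(ev$onset_s < 0)) {
    abort("Event onsets must be >= 0.")
  }
  unknown <- setdiff(unique(ev$behavior), CORE_BEHAVIORS)
  if (length(unknown) > 0) {
    warn(sprintf("Unknown behavior code(s) kept as-is: %s.",
                 paste(unknown, collapse = ", ")))
  }
  invisible(ev)
}

empty_events <- function() {
  tibble(session_id = character(), actor = character(), behavior = character(),
         onset_s = double(), offset_s = double())
}

empty_calls <- function() {
  tibble(session_id = character(), caller = character(), call_type = character(),
         onset_s = double(), offset_s = double())
}

read_table_input <- function(path, required, what) {
  if (is.data.frame(path)) {
    tab <- as_tibble(path)
  } else {
    if (!file.exists(path)) abort(sprintf("%s file not found: %s", what, path))
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  tab[required]
}

#' Read a call-annotation table
#'
#' Reads manually annotated calls either from a CSV
#' (`session_id, caller, call_type, onset_s, offset_s`) or from a PRAAT
#' TextGrid with one interval tier per caller (tier name = caller).
#'
#' @param path Path to the file, or a data frame (CSV dialect only).
#' @param dialect `"csv"` or `"textgrid"`.
#' @param session_id Session identifier to stamp on TextGrid records (a
#'   TextGrid carries no session column).
#' @return A tibble of call records. Call types are lower-cased; the infant
#'   distress label "ngä"/"nga" maps to `cry`; labels outside the vocabulary
#'   are kept with `call_type = "other"` and a warning. Records whose caller
#'   cannot be attributed (`unspecified`) are retained on read; downstream
#'   infant analyses exclude them.
#' @export
read_call_table <- function(path, dialect = c("csv", "textgrid"),
                            session_id = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "textgrid") {
    tab <- read_textgrid_intervals(path)
    tab$session_id <- as.character(session_id %||% "textgrid")
    tab <- tab[c("session_id", "caller", "call_type", "onset_s", "offset_s")]
  } else {
    tab <- read_table_input(path, call_cols, "call table")
  }
  if (nrow(tab) == 0) return(empty_calls())
  tab <- tab |>
    mutate(
      session_id = as.character(.data$session_id),
      caller = normalize_caller(as.character(.data$caller)),
      call_type = normalize_call_type(as.character(.data$call_type)),
      onset_s = as.numeric(.data$onset_s),
      offset_s = as.numeric(.data$offset_s)
    ) |>
    filter(.data$call_type != "") # empty labels dropped
  if (any(tab$offset_s < tab$onset_s)) {
    abort("Call record(s) with offset < onset.")
  }
  arrange(tab, .data$session_id, .data$onset_s)
}

normalize_caller <- function(x) {
  x <- tolower(trimws(x))
  ifelse(x %in% c("infant", "caregiver"), x, "unspecified")
}

normalize_call_type <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("ngä", "nga")] <- "cry"
  unknown <- setdiff(unique(x[x != ""]), call_types())
  if (length(unknown) > 0) {
    warn(sprintf("Unknown call label(s) mapped to 'other': %s.",
                 paste(unknown, collapse = ", ")))
    x[x %in% unknown] <- "other"
  }
  x
}

# Minimal PRAAT TextGrid interval-tier reader (long or short text format).
# Returns a tibble(caller, call_type, onset_s, offset_s); empty labels dropped.
read_textgrid_intervals <- function(path) {
  if (!file.exists(path)) abort(sprintf("TextGrid not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  txt <- paste(lines, collapse = "\n")
  if (!grepl("IntervalTier", txt)) {
    abort("TextGrid contains no interval tier.")
  }
  nums <- function(s) as.numeric(sub('^.*= *', '', s))
  quoted <- function(s) {
    m <- regmatches(s, regexpr('"[^"]*"', s))
    if (length(m) == 0) "" else substr(m, 2, nchar(m) - 1)
  }
  out <- list()
  tier_name <- NA_character_
  xmin <- NA_real_; xmax <- NA_real_; label <- NULL
  # Long format: lines like 'name = "infant"', 'xmin = 0', 'text = "phee"'.
  for (ln in lines) {
    t <- trimws(ln)
    if (grepl('^name *=', t)) {
      tier_name <- quoted(t)
    } else if (grepl('^xmin *=', t)) {
      xmin <- nums(t)
    } else if (grepl('^xmax *=', t)) {
      xmax <- nums(t)
    } else if (grepl('^text *=', t)) {
      label <- quoted(t)
      if (!is.na(tier_name) && nzchar(label) && !is.na(xmin) && !is.na(xmax)) {
        out[[length(out) + 1L]] <- tibble(
          caller = tier_name, call_type = label,
          onset_s = xmin, offset_s = xmax
        )
      }
      label <- NULL
    }
  }
  if (length(out) == 0) {
    return(tibble(caller = character(), call_type = character(),
                  onset_s = double(), offset_s = double()))
  }
  bind_rows(out)
}

#' Read session metadata
#'
#' @param path Path to a metadata CSV (one row per session) or a data frame.
#' @return A validated tibble with one row per session.
#' @export
read_session_meta <- function(path) {
  meta <- read_table_input(path, meta_cols, "metadata")
  meta <- meta |>
    mutate(
      session_id = as.character(.data$session_id),
      family_id = as.character(.data$family_id),
      caregiver_id = as.character(.data$caregiver_id),
      caregiver_role = as.character(.data$caregiver_role),
      infant_id = as.character(.data$infant_id),
      infant_sex = as.character(.data$infant_sex),
      pnd = as.integer(.data$pnd),
      rearing = as.character(.data$rearing),
      assay = as.character(.data$assay),
      nominal_duration = as.numeric(.data$nominal_duration)
    )
  if (anyDuplicated(meta$session_id)) abort("Duplicate session_id in metadata.")
  if (any(meta$pnd < 0, na.rm = TRUE)) abort("pnd must be >= 0.")
  if (!all(meta$nominal_duration %in% c(300, 600))) {
    abort("nominal_duration must be 300 or 600 s.")
  }
  if (!all(meta$caregiver_role %in% c("mother", "father", "sibling", "unfamiliar"))) {
    abort("caregiver_role must be mother/father/sibling/unfamiliar.")
  }
  if (!all(meta$rearing %in% c("family", "artificial"))) {
    abort("rearing must be family or artificial.")
  }
  if (!all(meta$assay %in% c("retrieval", "reunion", "isolation"))) {
    abort("assay must be retrieval, reunion or isolation.")
  }
  meta
}

#' Assemble a validated session object
#'
#' Combines one session's metadata row, events and calls into a `dyad_session`
#' object with the analysis window resolved: `[0, retrieval_time +
#' nominal_duration]` when a retrieval occurred, else `[0, nominal_duration]`.
#' Events and calls are truncated to the window.
#'
#' @param meta One-row metadata tibble (see [read_session_meta()]).
#' @param events Event tibble for this session (see [read_event_stream()]).
#' @param calls Call tibble for this session (may be empty).
#' @return A `dyad_session` object: a list with `meta`, `events`, `calls`,
#'   `retrieval_time` (NA if no retrieval) and `window_end`.
#' @details Rejection can only be coded while the infant is carried; a
#'   rejection event with no overlapping carry bout is a validation error.
#' @export
build_session <- function(meta, events, calls = NULL) {
  meta <- as_tibble(meta)
  stopifnot(nrow(meta) == 1)
  events <- if (is.null(events) || nrow(events) == 0) empty_events() else as_tibble(events)
  calls <- if (is.null(calls) || nrow(calls) == 0) empty_calls() else as_tibble(calls)
  if (nrow(events) > 0) validate_events(events)

  ret_events <- events$onset_s[events$behavior == "retrieval"]
  retrieval_time <- if (length(ret_events) > 0) min(ret_events) else NA_real_
  window_end <- if (is.na(retrieval_time)) {
    meta$nominal_duration
  } else {
    retrieval_time + meta$nominal_duration
  }
  # canonicalize to the bin grid so window_end and segment endpoints share
  # one floating-point representation
  window_end <- from_bins(to_bins(window_end))

  events <- events |>
    filter(.data$onset_s < window_end) |>
    mutate(offset_s = pmin(.data$offset_s, window_end)) |>
    arrange(.data$onset_s, .data$offset_s)
  calls <- calls |>
    filter(.data$onset_s < window_end) |>
    mutate(offset_s = pmin(.data$offset_s, window_end)) |>
    arrange(.data$onset_s)

  # Rejection must overlap a carry bout.
  rej <- filter(events, .data$behavior == "rejection")
  if (nrow(rej) > 0) {
    carry <- filter(events, .data$behavior == "carry_contact")
    ok <- vapply(seq_len(nrow(rej)), function(i) {
      any(carry$onset_s < rej$offset_s[i] & carry$offset_s > rej$onset_s[i])
    }, logical(1))
    if (!all(ok)) {
      abort(sprintf(
        "Session %s: rejection bout(s) at %s do not overlap any carrying bout.",
        meta$session_id, paste(rej$onset_s[!ok], collapse = ", ")))
    }
  }

  structure(
    list(meta = meta, events = events, calls = calls,
         retrieval_time = retrieval_time, window_end = as.numeric(window_end)),
    class = "dyad_session"
  )
}

#' @export
print.dyad_session <- function(x, ...) {
  cat(sprintf(
    "<dyad_session> %s  [%s, pnd %d, %s]\n  window [0, %.1f] s, retrieval %s, %d events, %d calls\n",
    x$meta$session_id, x$meta$caregiver_role, x$meta$pnd, x$meta$assay,
    x$window_end,
    if (is.na(x$retrieval_time)) "none" else sprintf("%.1f s", x$retrieval_time),
    nrow(x$events), nrow(x$calls)))
  invisible(x)
}

#' Build all sessions from event, call and metadata tables
#'
#' @param events Event tibble covering one or more sessions.
#' @param calls Call tibble (may be empty or NULL).
#' @param meta Metadata tibble, one row per session.
#' @return Named list of `dyad_session` objects, keyed by session_id.
#' @export
build_sessions <- function(events, calls, meta) {
  meta <- as_tibble(meta)
  calls <- if (is.null(calls)) empty_calls() else as_tibble(calls)
  sessions <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$session_id[i]
    build_session(meta[i, ],
                  filter(events, .data$session_id == sid),
                  filter(calls, .data$session_id == sid))
  })
  setNames(sessions, meta$session_id)
}

#' Write (and read back) a dyad summary table
#'
#' Writes per-session rows plus per-dyad aggregate rows to CSV. The `level`
#' column distinguishes the two. Values survive a read-back to 6 decimals.
#'
#' @param summaries Tibble of per-session summaries containing at least
#'   `session_id`, `caregiver_id`, `infant_id` and numeric measure columns.
#' @param path Output CSV path.
#' @return The written tibble (session rows + aggregate rows), invisibly.
#' @export
write_summary <- function(summaries, path) {
  summaries <- as_tibble(summaries)
  if (nrow(summaries) == 0) abort("Cannot write an empty summary table.")
  if (anyDuplicated(summaries$session_id)) {
    abort("Duplicate session_id keys in summary table.")
  }
  num_cols <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  dyad_rows <- summaries |>
    group_by(.data$caregiver_id, .data$infant_id) |>
    summarise(
      dplyr::across(dplyr::all_of(num_cols), ~ mean(.x, na.rm = TRUE)),
      n_sessions = dplyr::n(), .groups = "drop") |>
    mutate(session_id = NA_character_, level = "dyad")
  out <- summaries |>
    mutate(level = "session", n_sessions = 1L) |>
    bind_rows(dyad_rows) |>
    select("level", "session_id", "caregiver_id", "infant_id",
           dplyr::everything())
  readr::write_csv(out, path, na = "")
  invisible(out)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
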