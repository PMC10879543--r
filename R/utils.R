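# Internal helpers shared across modules.

# Width of the coding bin in seconds. Event times are snapped to this grid on
# ingestion; all interval arithmetic downstream runs on integer bin indices so
# the context partition is exact.
BIN_WIDTH <- 0.2

#' Snap times to the coding-bin grid
#'
#' Rounds to one decimal (round-half-even, as base R does) and then to the
#' nearest multiple of `bin_width`. Deterministic across platforms.
#'
#' @param x Numeric vector of times in seconds.
#' @param bin_width Grid step in seconds (default 0.2).
#' @return Numeric vector on the grid.
#' @keywords internal
snap_to_grid <- function(x, bin_width = BIN_WIDTH) {
  round(round(x, 1) / bin_width) * bin_width
}

# Convert grid seconds to integer bin index (exact for grid-snapped input).
to_bins <- function(x, bin_width = BIN_WIDTH) {
  as.integer(round(x / bin_width))
}

from_bins <- function(b, bin_width = BIN_WIDTH) {
  b * bin_width
}

# Deterministic substream seed derived from a master seed and a counter.
# Kept below 2^31 - 1 so set.seed() accepts it on all platforms.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 9973) %% 2147483587L)
}

#' The five social-context labels
#'
#' Closed set of mutually exclusive, collectively exhaustive session states:
#' alone before the first retrieval, carried without caregiver locomotion
#' (Holding), carried with locomotion (Transport), during/just after a
#' rejection bout, and alone after the first retrieval.
#'
#' @return Character vector of the five labels, in display order.
#' @export
context_levels <- function() {
  c("Alone_BeforeRET", "Holding", "Transport", "During_Rejection", "Alone_AfterRET")
}

#' Call-type vocabulary
#'
#' The closed call-type vocabulary used on ingestion, and the six-category
#' reduction used for per-context call-type proportions (chatter, chirp,
#' combination and other are lumped into `other`).
#'
#' @return Character vector of call types.
#' @export
call_types <- function() {
  c("phee", "twitter", "tsik", "trill", "chatter", "chirp", "cry",
    "combination", "other")
}

#' @rdname call_types
#' @export
call_type_groups <- function() {
  c("phee", "twitter", "tsik", "trill", "cry", "other")
}

# Map a raw call label to the six-category analysis grouping.
group_call_type <- function(call_type) {
  ifelse(call_type %in% c("phee", "twitter", "tsik", "trill", "cry"),
         call_type, "other")
}
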