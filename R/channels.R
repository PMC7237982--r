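#' Clinical channel registry
#'
#' All observation values are stored numerically. Consciousness uses the AVPU
#' ordinal coded 0 (Alert), 1 (Voice), 2 (Pain), 3 (Unresponsive);
#' supplemental oxygen is 0/1. Plausibility bounds are the default validation
#' limits; they can be overridden per call in [validate_cohort()].
#'
#' @return A tibble with one row per channel: `channel`, `unit`, `lo`, `hi`
#'   (plausibility bounds) and `normal` (the imputation-to-normal default,
#'   which scores zero points in every built-in score).
#' @export
ews_channels <- function() {
  if (!is.null(.ews_cache$channels)) return(.ews_cache$channels)
  .ews_cache$channels <- tibble::tribble(
    ~channel,           ~unit,          ~lo,  ~hi, ~normal,
    "respiratory_rate", "breaths/min",    0,   80,      14,
    "heart_rate",       "beats/min",      0,  300,      75,
    "systolic_bp",      "mm Hg",          0,  300,     120,
    "temperature",      "degC",          25,   45,      37,
    "spo2",             "%",              0,  100,      98,
    "supplemental_o2",  "0/1",            0,    1,       0,
    "consciousness",    "AVPU 0-3",       0,    3,       0,
    "wbc",              "10^3/uL",        0,  200,       8,
    "band_fraction",    "%",              0,  100,       0,
    "paco2",            "mm Hg",          0,  150,      40
  )
  .ews_cache$channels
}

.ews_cache <- new.env(parent = emptyenv())

#' @rdname ews_channels
#' @export
channel_names <- function() ews_channels()$channel

# AVPU letters <-> ordinal codes
avpu_levels <- c("A", "V", "P", "U")

avpu_to_code <- function(x) {
  out <- match(toupper(trimws(x)), avpu_levels) - 1L
  # numeric codes are accepted as-is
  num <- suppressWarnings(as.numeric(x))
  out[is.na(out)] <- num[is.na(out)]
  out
}

code_to_avpu <- function(code) avpu_levels[as.integer(code) + 1L]

#' Imputation-to-normal defaults
#'
#' The value assumed for a channel that has never been observed during the
#' time-at-risk interval. Every default scores zero points in every built-in
#' scoring system (an invariant the test suite enforces).
#'
#' @return Named numeric vector, one element per channel.
#' @export
normal_defaults <- function() {
  if (is.null(.ews_cache$defaults)) {
    ch <- ews_channels()
    .ews_cache$defaults <- stats::setNames(ch$normal, ch$channel)
  }
  .ews_cache$defaults
}
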