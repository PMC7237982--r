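#' Built-in scoring-system definitions
#'
#' The five points-based systems are stored as declarative band tables under
#' `inst/extdata/scores/`, one CSV per system with columns `channel`,
#' `criterion`, `lower`, `lower_open`, `upper`, `points`. A value belongs to
#' the band with the greatest satisfied lower bound (`value >= lower`, or
#' `value > lower` when `lower_open`); closed bounds therefore reproduce
#' half-open `[lower, upper)` bands, while open bounds express published
#' strict inequalities such as the SIRS heart-rate criterion (> 90).
#'
#' `criterion` groups channels that share one criterion: SIRS awards at most
#' one point for respiratory rate > 20 *or* PaCO2 < 32, and one for
#' WBC > 12 / < 4 *or* band forms > 10%. For the other systems each channel
#' is its own criterion.
#'
#' Aggregation is `sum_of_points` for NEWS, MEWS, qSOFA and SIRS and
#' `any_trigger` for BTF, whose red-zone criteria fire as a single 0/1 alarm.
#'
#' @param name One of `"NEWS"`, `"MEWS"`, `"BTF"`, `"qSOFA"`, `"SIRS"`.
#' @return An object of class `score_definition`: a list with `name`,
#'   `bands` (tibble), `aggregation`, `channels`, `max_value` and
#'   `default_thresholds`.
#' @export
#' @examples
#' qsofa <- builtin_definition("qSOFA")
#' qsofa$channels
builtin_definition <- function(name) {
  meta <- score_metadata()
  key <- names(meta)[match(toupper(name), toupper(names(meta)))]
  if (is.na(key))
    stop("unknown score '", name, "'; available: ",
         paste(names(meta), collapse = ", "), call. = FALSE)
  if (!is.null(.ews_cache$defs[[key]])) return(.ews_cache$defs[[key]])
  path <- system.file("extdata", "scores", paste0(tolower(key), ".csv"),
                      package = "ewsbench", mustWork = TRUE)
  def <- load_score_definition(path, name = key,
                               aggregation = meta[[key]]$aggregation,
                               default_thresholds = meta[[key]]$thresholds)
  if (is.null(.ews_cache$defs)) .ews_cache$defs <- list()
  .ews_cache$defs[[key]] <- def
  def
}

score_metadata <- function() {
  list(
    NEWS  = list(aggregation = "sum_of_points", thresholds = c(6L, 8L)),
    MEWS  = list(aggregation = "sum_of_points", thresholds = c(4L)),
    BTF   = list(aggregation = "any_trigger",   thresholds = c(1L)),
    qSOFA = list(aggregation = "sum_of_points", thresholds = c(2L)),
    SIRS  = list(aggregation = "sum_of_points", thresholds = c(2L))
  )
}

#' @rdname builtin_definition
#' @export
score_names <- function() names(score_metadata())

#' Load a score definition from a band-table CSV
#'
#' Users can define custom scores in the same file format as the built-in
#' tables (see [builtin_definition()]). The table is validated on load: for
#' every channel the bands must form a partition of the real line (lowest
#' band starts at `-Inf` with a closed bound; each band's `upper` must equal
#' the next band's `lower`).
#'
#' @param path CSV file with columns `channel`, `criterion` (optional,
#'   defaults to `channel`), `lower`, `lower_open` (optional, default FALSE),
#'   `upper`, `points`.
#' @param name Score name.
#' @param aggregation `"sum_of_points"` or `"any_trigger"`.
#' @param default_thresholds Integer alerting thresholds.
#' @export
load_score_definition <- function(path, name,
                                  aggregation = c("sum_of_points", "any_trigger"),
                                  default_thresholds = integer(0)) {
  aggregation <- match.arg(aggregation)
  bands <- readr::read_csv(path, col_types = readr::cols(
    channel = readr::col_character(),
    criterion = readr::col_character(),
    lower = readr::col_double(),
    lower_open = readr::col_logical(),
    upper = readr::col_double(),
    points = readr::col_integer()), progress = FALSE)
  if (!"criterion" %in% names(bands)) bands$criterion <- bands$channel
  if (!"lower_open" %in% names(bands)) bands$lower_open <- FALSE
  bands <- dplyr::arrange(bands, .data$channel, .data$lower)
  for (ch in unique(bands$channel)) {
    b <- bands[bands$channel == ch, ]
    if (!(is.infinite(b$lower[1]) && b$lower[1] < 0 && !b$lower_open[1]))
      stop("score ", name, ", channel ", ch,
           ": lowest band must start at -Inf (closed)", call. = FALSE)
    if (nrow(b) > 1 && any(b$upper[-nrow(b)] != b$lower[-1]))
      stop("score ", name, ", channel ", ch,
           ": bands do not chain (upper != next lower)", call. = FALSE)
    if (!is.infinite(b$upper[nrow(b)]))
      stop("score ", name, ", channel ", ch,
           ": highest band must end at +Inf", call. = FALSE)
    if (any(b$points < 0)) stop("negative points in score ", name, call. = FALSE)
  }
  if (aggregation == "any_trigger" && any(bands$points > 1))
    stop("any_trigger scores use 0/1 trigger flags", call. = FALSE)
  max_value <- if (aggregation == "any_trigger") 1L else {
    crit_max <- tapply(bands$points, bands$criterion, max)
    as.integer(sum(crit_max))
  }
  by_channel <- lapply(split(bands, bands$channel), function(b)
    list(lower = b$lower, lower_open = b$lower_open,
         points = as.integer(b$points)))
  structure(list(
    name = name, bands = bands, aggregation = aggregation,
    channels = unique(bands$channel),
    criteria = bands$criterion[match(unique(bands$channel), bands$channel)],
    by_channel = by_channel,
    max_value = max_value,
    default_thresholds = as.integer(default_thresholds)),
    class = "score_definition")
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s (%s), channels: %s, max %d\n",
              x$name, x$aggregation, paste(x$channels, collapse = ", "),
              x$max_value))
  invisible(x)
}

# Vectorized band lookup for one channel: points for each value.
band_points <- function(def, channel, values) {
  b <- def$by_channel[[channel]]
  if (is.null(b))
    stop("channel '", channel, "' is not used by score ", def$name,
         call. = FALSE)
  lim <- channel_bounds()
  j <- match(channel, names(lim$lo))
  if (!is.na(j) && any(!is.na(values) &
                       (values < lim$lo[j] | values > lim$hi[j])))
    stop("value out of domain for channel ", channel, call. = FALSE)
  # band with greatest satisfied lower bound; bands sorted by lower
  idx <- findInterval(values, b$lower)        # lower[idx] <= value
  on_bound <- idx >= 1 & !is.na(values) & values == b$lower[pmax(idx, 1L)] &
    b$lower_open[pmax(idx, 1L)]
  idx[on_bound] <- idx[on_bound] - 1L         # strict bound not satisfied
  b$points[idx]
}

channel_bounds <- function() {
  if (is.null(.ews_cache$bounds)) {
    ch <- ews_channels()
    .ews_cache$bounds <- list(lo = stats::setNames(ch$lo, ch$channel),
                              hi = stats::setNames(ch$hi, ch$channel))
  }
  .ews_cache$bounds
}

#' Points contributed by a single channel value
#'
#' @param def A [builtin_definition()] or [load_score_definition()] result.
#' @param channel Channel name; must be read by the score.
#' @param value Numeric value(s) within the channel's domain.
#' @return Integer points of the matching band (a 0/1 trigger flag for BTF).
#' @export
component_points <- function(def, channel, value) {
  as.integer(band_points(def, channel, value))
}

#' Total score for a complete channel state
#'
#' The caller supplies a value for every channel the score reads (after
#' imputation to normal); criteria grouping multiple channels contribute the
#' maximum of their member points.
#'
#' @param def A score definition.
#' @param state Named numeric vector or list mapping channel to current value.
#' @return Integer total (0/1 for any-trigger systems).
#' @export
total_score <- function(def, state) {
  state <- unlist(state)
  missing <- setdiff(def$channels, names(state))
  if (length(missing) > 0)
    stop("state is missing channel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  pts <- vapply(def$channels, function(ch) band_points(def, ch, state[[ch]]),
                numeric(1))
  per_crit <- tapply(pts, def$criteria, max)
  if (def$aggregation == "any_trigger") as.integer(any(per_crit > 0))
  else as.integer(sum(per_crit))
}
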