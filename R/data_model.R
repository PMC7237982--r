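#' Construct a ward-cohort object
#'
#' An `ews_cohort` bundles the four long tables the pipeline operates on:
#' encounter metadata, timestamped observations, unit-location intervals and
#' culture/antibiotic orders. Timestamps are timezone-naive POSIXct at minute
#' resolution (stored as UTC).
#'
#' @param encounters Tibble with columns `encounter_id`, `patient_id`, `age`,
#'   `admit_time`, `discharge_time`, `admitted_via_ed`, `death_time`
#'   (`NA` when the patient survived).
#' @param observations Tibble with `encounter_id`, `time`, `channel`, `value`
#'   (numeric; AVPU coded 0-3, supplemental O2 coded 0/1).
#' @param locations Tibble with `encounter_id`, `unit_class` (one of
#'   `ED`, `ward`, `ICU`, `labor_delivery`), `start`, `end`.
#' @param orders Tibble with `encounter_id`, `time`, `order_class` (one of
#'   `blood_culture_or_micro_culture`, `antibiotic`).
#' @return An object of class `ews_cohort`.
#' @export
ews_cohort <- function(encounters, observations, locations, orders) {
  obj <- list(
    encounters   = dplyr::arrange(tibble::as_tibble(encounters), .data$encounter_id),
    observations = dplyr::arrange(tibble::as_tibble(observations),
                                  .data$encounter_id, .data$time,
                                  .data$channel, .data$value),
    locations    = dplyr::arrange(tibble::as_tibble(locations),
                                  .data$encounter_id, .data$start),
    orders       = dplyr::arrange(tibble::as_tibble(orders),
                                  .data$encounter_id, .data$time)
  )
  structure(obj, class = "ews_cohort")
}

#' @export
print.ews_cohort <- function(x, ...) {
  cat(sprintf(
    "<ews_cohort> %d encounters, %d observations, %d location intervals, %d orders\n",
    nrow(x$encounters), nrow(x$observations), nrow(x$locations), nrow(x$orders)))
  invisible(x)
}

unit_classes <- c("ED", "ward", "ICU", "labor_delivery")
order_classes <- c("blood_culture_or_micro_culture", "antibiotic")

events_schema_cols <- c(
  "encounter_id", "patient_id", "age", "admit_time", "discharge_time",
  "admitted_via_ed", "death_time", "event_type", "time", "channel_or_class",
  "value", "interval_end")

parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(lubridate::force_tz(x, "UTC"))
  x <- as.character(x)
  x[!is.na(x) & x == ""] <- NA_character_
  lubridate::parse_date_time(x, orders = c("Ymd HMS", "Ymd HM", "Ymd"),
                             tz = "UTC", quiet = TRUE)
}

parse_value <- function(channel, value) {
  v <- rep(NA_real_, length(value))
  cons <- channel == "consciousness"
  o2 <- channel == "supplemental_o2"
  v[cons] <- avpu_to_code(value[cons])
  o2chr <- toupper(trimws(value[o2]))
  o2num <- suppressWarnings(as.numeric(o2chr))
  v[o2] <- ifelse(!is.na(o2num), as.numeric(o2num > 0),
                  as.numeric(o2chr %in% c("TRUE", "T", "YES")))
  other <- !cons & !o2
  v[other] <- suppressWarnings(as.numeric(value[other]))
  v
}

format_value <- function(channel, value) {
  out <- as.character(value)
  cons <- channel == "consciousness"
  out[cons] <- code_to_avpu(value[cons])
  o2 <- channel == "supplemental_o2"
  out[o2] <- ifelse(value[o2] > 0, "TRUE", "FALSE")
  out
}

#' Read a long-format events file into a cohort
#'
#' The file holds one row per event with an `event_type` discriminator
#' (`observation`, `location`, `order`); encounter metadata is repeated on
#' every row of its encounter. Consciousness accepts AVPU letters (A/V/P/U)
#' or codes 0-3; supplemental oxygen accepts TRUE/FALSE or 0/1. Temperatures
#' may be supplied in Fahrenheit with `fahrenheit = TRUE` and are converted
#' to Celsius.
#'
#' @param path File path.
#' @param format `"csv"` or `"parquet"` (default guessed from the extension).
#' @param fahrenheit Logical; interpret `temperature` values as Fahrenheit.
#' @return An [ews_cohort()].
#' @export
read_events <- function(path, format = c("auto", "csv", "parquet"),
                        fahrenheit = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.parquet$", path)) "parquet" else "csv"
  if (!file.exists(path)) stop("events file not found: ", path, call. = FALSE)
  raw <- if (format == "parquet") {
    tibble::as_tibble(arrow::read_parquet(path))
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  raw[] <- lapply(raw, as.character)
  missing_cols <- setdiff(events_schema_cols, names(raw))
  if (length(missing_cols) > 0)
    stop("events file schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  errs <- character(0)
  ts_cols <- c("time", "admit_time", "discharge_time")
  for (cc in ts_cols) {
    parsed <- suppressWarnings(parse_ts(raw[[cc]]))
    bad <- which(!is.na(raw[[cc]]) & raw[[cc]] != "" & is.na(parsed))
    if (length(bad) > 0)
      errs <- c(errs, sprintf("row %d: unparseable timestamp in %s: '%s'",
                              bad, cc, raw[[cc]][bad]))
  }
  is_obs <- raw$event_type == "observation"
  bad_chan <- which(is_obs & !(raw$channel_or_class %in% channel_names()))
  if (length(bad_chan) > 0)
    errs <- c(errs, sprintf("row %d: unknown channel '%s'",
                            bad_chan, raw$channel_or_class[bad_chan]))
  bad_loc <- which(raw$event_type == "location" &
                     !(raw$channel_or_class %in% unit_classes))
  if (length(bad_loc) > 0)
    errs <- c(errs, sprintf("row %d: unknown unit class '%s'",
                            bad_loc, raw$channel_or_class[bad_loc]))
  bad_ord <- which(raw$event_type == "order" &
                     !(raw$channel_or_class %in% order_classes))
  if (length(bad_ord) > 0)
    errs <- c(errs, sprintf("row %d: unknown order class '%s'",
                            bad_ord, raw$channel_or_class[bad_ord]))
  if (length(errs) > 0)
    stop("events file row errors:\n", paste(errs, collapse = "\n"), call. = FALSE)

  enc <- raw |>
    dplyr::distinct(.data$encounter_id, .keep_all = TRUE) |>
    dplyr::transmute(
      encounter_id = .data$encounter_id,
      patient_id = .data$patient_id,
      age = as.numeric(.data$age),
      admit_time = parse_ts(.data$admit_time),
      discharge_time = parse_ts(.data$discharge_time),
      admitted_via_ed = toupper(.data$admitted_via_ed) %in% c("TRUE", "T", "1"),
      death_time = parse_ts(.data$death_time))

  obs <- raw[is_obs, ] |>
    dplyr::transmute(
      encounter_id = .data$encounter_id,
      time = parse_ts(.data$time),
      channel = .data$channel_or_class,
      value = parse_value(.data$channel_or_class, .data$value))
  if (fahrenheit) {
    sel <- obs$channel == "temperature"
    obs$value[sel] <- (obs$value[sel] - 32) * 5 / 9
  }

  loc <- raw[raw$event_type == "location", ] |>
    dplyr::transmute(
      encounter_id = .data$encounter_id,
      unit_class = .data$channel_or_class,
      start = parse_ts(.data$time),
      end = parse_ts(.data$interval_end))

  ord <- raw[raw$event_type == "order", ] |>
    dplyr::transmute(
      encounter_id = .data$encounter_id,
      time = parse_ts(.data$time),
      order_class = .data$channel_or_class)

  ews_cohort(enc, obs, loc, ord)
}

#' Write a cohort to a long-format events file
#'
#' Inverse of [read_events()]: `read_events(write_events(x, p), p)` reproduces
#' `x` up to canonical ordering by (encounter_id, time, channel).
#'
#' @param cohort An [ews_cohort()].
#' @inheritParams read_events
#' @export
write_events <- function(cohort, path, format = c("auto", "csv", "parquet")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.parquet$", path)) "parquet" else "csv"
  fmt_ts <- function(x) ifelse(is.na(x), NA_character_,
                               format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  meta <- cohort$encounters |>
    dplyr::transmute(
      encounter_id = .data$encounter_id, patient_id = .data$patient_id,
      age = as.character(.data$age),
      admit_time = fmt_ts(.data$admit_time),
      discharge_time = fmt_ts(.data$discharge_time),
      admitted_via_ed = as.character(.data$admitted_via_ed),
      death_time = fmt_ts(.data$death_time))
  rows <- dplyr::bind_rows(
    cohort$observations |>
      dplyr::transmute(encounter_id = .data$encounter_id,
                       event_type = "observation", time = fmt_ts(.data$time),
                       channel_or_class = .data$channel,
                       value = format_value(.data$channel, .data$value),
                       interval_end = NA_character_),
    cohort$locations |>
      dplyr::transmute(encounter_id = .data$encounter_id,
                       event_type = "location", time = fmt_ts(.data$start),
                       channel_or_class = .data$unit_class,
                       value = NA_character_,
                       interval_end = fmt_ts(.data$end)),
    cohort$orders |>
      dplyr::transmute(encounter_id = .data$encounter_id,
                       event_type = "order", time = fmt_ts(.data$time),
                       channel_or_class = .data$order_class,
                       value = NA_character_, interval_end = NA_character_))
  out <- meta |>
    dplyr::left_join(rows, by = "encounter_id") |>
    dplyr::arrange(.data$encounter_id, .data$time, .data$channel_or_class)
  # encounters with no events still get one metadata-only row
  out <- out[, events_schema_cols]
  if (format == "parquet") arrow::write_parquet(out, path)
  else readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate cohort invariants
#'
#' Checks type invariants for every encounter: plausibility bounds per
#' channel, ordered and non-overlapping location intervals, admit before
#' discharge, death not after discharge, non-negative age. Violations are
#' returned as data, never raised.
#'
#' @param cohort An [ews_cohort()].
#' @param bounds Optional tibble like [ews_channels()] overriding the
#'   plausibility bounds.
#' @return Tibble with columns `encounter_id`, `field`, `rule`, `detail`;
#'   zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort, bounds = ews_channels()) {
  v <- list()
  add <- function(ids, field, rule, detail) {
    if (length(ids) > 0)
      v[[length(v) + 1]] <<- tibble::tibble(
        encounter_id = ids, field = field, rule = rule, detail = detail)
  }
  enc <- cohort$encounters
  add(enc$encounter_id[!is.na(enc$age) & enc$age < 0], "age", "age >= 0",
      "negative age")
  bad <- !is.na(enc$admit_time) & !is.na(enc$discharge_time) &
    enc$admit_time >= enc$discharge_time
  add(enc$encounter_id[bad], "admit_time", "admit_time < discharge_time",
      "admission not before discharge")
  bad <- !is.na(enc$death_time) & enc$death_time > enc$discharge_time
  add(enc$encounter_id[bad], "death_time", "death_time <= discharge_time",
      "death after discharge")

  obs <- dplyr::left_join(cohort$observations, bounds, by = "channel")
  bad <- is.na(obs$value) | obs$value < obs$lo | obs$value > obs$hi
  add(obs$encounter_id[bad], "value", "value within plausibility bounds",
      sprintf("%s = %s outside [%s, %s]", obs$channel[bad],
              format(obs$value[bad]), obs$lo[bad], obs$hi[bad]))
  unk <- !(cohort$observations$channel %in% bounds$channel)
  add(cohort$observations$encounter_id[unk], "channel", "known channel",
      paste("unknown channel", cohort$observations$channel[unk]))

  loc <- cohort$locations
  bad <- loc$start >= loc$end
  add(loc$encounter_id[bad], "location", "start < end", "empty or inverted interval")
  if (nrow(loc) > 1) {
    by_enc <- split(seq_len(nrow(loc)), loc$encounter_id)
    for (idx in by_enc) {
      if (length(idx) < 2) next
      s <- loc$start[idx]; e <- loc$end[idx]
      o <- order(s)
      s <- s[o]; e <- e[o]
      ov <- which(s[-1] < e[-length(e)])
      add(rep(loc$encounter_id[idx[1]], length(ov)), "location",
          "intervals non-overlapping",
          sprintf("interval %d overlaps interval %d", ov, ov + 1L))
    }
  }
  if (length(v) == 0)
    return(tibble::tibble(encounter_id = character(0), field = character(0),
                          rule = character(0), detail = character(0)))
  dplyr::bind_rows(v)
}

#' @describeIn validate_cohort Violations for a single encounter.
#' @param encounter_id Encounter to check.
#' @export
validate_encounter <- function(cohort, encounter_id,
                               bounds = ews_channels()) {
  sub <- subset_cohort(cohort, encounter_id)
  validate_cohort(sub, bounds = bounds)
}

#' Subset a cohort to a set of encounters
#' @param cohort An [ews_cohort()].
#' @param ids Encounter identifiers to keep.
#' @export
subset_cohort <- function(cohort, ids) {
  ews_cohort(
    encounters   = dplyr::filter(cohort$encounters, .data$encounter_id %in% ids),
    observations = dplyr::filter(cohort$observations, .data$encounter_id %in% ids),
    locations    = dplyr::filter(cohort$locations, .data$encounter_id %in% ids),
    orders       = dplyr::filter(cohort$orders, .data$encounter_id %in% ids))
}
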