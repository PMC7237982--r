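#' Hand-verifiable worked fixture
#'
#' A ten-encounter cohort built in code with every expectation computed by
#' hand from the band tables and rules: four planted inclusion violations
#' (a minor, a direct ICU admission, an ED discharge, a labor-and-delivery
#' stay), a ward death with an ICU transfer whose dyad falls after the
#' time-at-risk interval, qualifying and non-qualifying culture/antibiotic
#' dyads at the 71 h / 73 h / antibiotic-first boundaries, and a classic
#' qSOFA-positive presentation. The sidecar `expected` list freezes the
#' hand-computed inclusions, exclusion reasons, interval endpoints, labels,
#' infection onsets and per-score maxima used across the test suite.
#'
#' @return A list: `cohort` (an [ews_cohort()]) and `expected`.
#' @export
generate_worked_fixture <- function() {
  ts <- function(x) as.POSIXct(x, tz = "UTC")
  obs1 <- function(id, time, channel, value)
    tibble::tibble(encounter_id = id, time = ts(time), channel = channel,
                   value = value)
  normal_set <- function(id, time) {
    tibble::tibble(
      encounter_id = id, time = ts(time),
      channel = c("respiratory_rate", "heart_rate", "systolic_bp",
                  "temperature", "spo2", "supplemental_o2", "consciousness"),
      value = c(14, 75, 120, 37, 98, 0, 0))
  }
  enc <- function(id, pid, age, admit, discharge, via_ed = FALSE,
                  death = NA_character_) {
    tibble::tibble(encounter_id = id, patient_id = pid, age = age,
                   admit_time = ts(admit), discharge_time = ts(discharge),
                   admitted_via_ed = via_ed,
                   death_time = if (is.na(death)) ts(NA_character_) else ts(death))
  }
  loc <- function(id, unit, start, end)
    tibble::tibble(encounter_id = id, unit_class = unit,
                   start = ts(start), end = ts(end))
  ord <- function(id, time, class)
    tibble::tibble(encounter_id = id, time = ts(time), order_class = class)

  encounters <- dplyr::bind_rows(
    enc("F01", "P1", 60, "2024-03-01 08:00", "2024-03-03 10:00"),
    enc("F02", "P2", 70, "2024-03-01 06:00", "2024-03-05 12:00",
        death = "2024-03-05 12:00"),
    enc("F03", "P3", 55, "2024-03-01 09:00", "2024-03-02 09:00"),
    enc("F04", "P4", 65, "2024-03-01 08:00", "2024-03-06 08:00"),
    enc("F05", "P5", 66, "2024-03-01 08:00", "2024-03-06 08:00"),
    enc("F06", "P6", 48, "2024-03-01 08:00", "2024-03-04 08:00"),
    enc("F07", "P7", 17, "2024-03-01 08:00", "2024-03-02 08:00"),
    enc("F08", "P8", 52, "2024-03-01 08:00", "2024-03-05 08:00"),
    enc("F09", "P9", 41, "2024-03-01 08:00", "2024-03-01 14:00",
        via_ed = TRUE),
    enc("F10", "P10", 28, "2024-03-01 08:00", "2024-03-02 20:00"))

  locations <- dplyr::bind_rows(
    loc("F01", "ward", "2024-03-01 08:00", "2024-03-03 10:00"),
    loc("F02", "ward", "2024-03-01 06:00", "2024-03-01 12:00"),
    loc("F02", "ICU",  "2024-03-01 12:00", "2024-03-03 12:00"),
    loc("F02", "ward", "2024-03-03 12:00", "2024-03-05 12:00"),
    loc("F03", "ward", "2024-03-01 09:00", "2024-03-02 09:00"),
    loc("F04", "ward", "2024-03-01 08:00", "2024-03-06 08:00"),
    loc("F05", "ward", "2024-03-01 08:00", "2024-03-06 08:00"),
    loc("F06", "ward", "2024-03-01 08:00", "2024-03-04 08:00"),
    loc("F07", "ward", "2024-03-01 08:00", "2024-03-02 08:00"),
    loc("F08", "ICU",  "2024-03-01 08:00", "2024-03-03 08:00"),
    loc("F08", "ward", "2024-03-03 08:00", "2024-03-05 08:00"),
    loc("F09", "ED",   "2024-03-01 08:00", "2024-03-01 14:00"),
    loc("F10", "labor_delivery", "2024-03-01 08:00", "2024-03-02 20:00"))

  observations <- dplyr::bind_rows(
    normal_set("F01", "2024-03-01 08:00"),
    normal_set("F01", "2024-03-01 12:00"),
    normal_set("F01", "2024-03-01 16:00"),
    normal_set("F02", "2024-03-01 06:00"),
    obs1("F02", "2024-03-01 10:00", "respiratory_rate", 28),
    obs1("F02", "2024-03-01 10:00", "heart_rate", 120),
    obs1("F02", "2024-03-01 10:00", "systolic_bp", 85),
    obs1("F02", "2024-03-01 10:00", "temperature", 38.6),
    obs1("F02", "2024-03-01 10:00", "spo2", 89),
    obs1("F02", "2024-03-01 10:00", "supplemental_o2", 1),
    obs1("F02", "2024-03-01 10:00", "consciousness", 1),
    normal_set("F02", "2024-03-03 14:00"),  # post-ICU ward, outside interval
    normal_set("F03", "2024-03-01 09:00"),
    obs1("F03", "2024-03-01 15:00", "respiratory_rate", 24),
    obs1("F03", "2024-03-01 15:00", "systolic_bp", 95),
    obs1("F03", "2024-03-01 15:00", "consciousness", 1),
    normal_set("F04", "2024-03-01 08:30"),
    normal_set("F04", "2024-03-03 08:00"),
    normal_set("F05", "2024-03-01 08:30"),
    normal_set("F06", "2024-03-01 08:30"),
    normal_set("F07", "2024-03-01 09:00"),
    normal_set("F08", "2024-03-01 10:00"),   # charted in the ICU
    normal_set("F08", "2024-03-03 10:00"),   # post-ICU ward
    normal_set("F09", "2024-03-01 09:00"),   # ED vitals only
    normal_set("F10", "2024-03-01 10:00"))

  orders <- dplyr::bind_rows(
    ord("F02", "2024-03-02 09:00", "blood_culture_or_micro_culture"),
    ord("F02", "2024-03-02 10:00", "antibiotic"),
    ord("F04", "2024-03-01 10:00", "blood_culture_or_micro_culture"),
    ord("F04", "2024-03-04 09:00", "antibiotic"),   # 71 h later: qualifies
    ord("F05", "2024-03-01 10:00", "blood_culture_or_micro_culture"),
    ord("F05", "2024-03-04 11:00", "antibiotic"),   # 73 h later: no dyad
    ord("F06", "2024-03-01 12:00", "antibiotic"),
    ord("F06", "2024-03-01 22:00", "blood_culture_or_micro_culture"))

  cohort <- ews_cohort(encounters, observations, locations, orders)

  ts0 <- function(x) as.POSIXct(x, tz = "UTC")
  expected <- list(
    included_ids = c("F01", "F02", "F03", "F04", "F05", "F06"),
    exclusion_reasons = c(F07 = "age", F08 = "direct ICU admission",
                          F09 = "ED discharge", F10 = "labor_delivery"),
    intervals = tibble::tribble(
      ~encounter_id, ~start, ~end, ~end_reason,
      "F01", ts0("2024-03-01 08:00"), ts0("2024-03-03 10:00"), "discharge",
      "F02", ts0("2024-03-01 06:00"), ts0("2024-03-01 12:00"), "icu_transfer",
      "F03", ts0("2024-03-01 09:00"), ts0("2024-03-02 09:00"), "discharge",
      "F04", ts0("2024-03-01 08:30"), ts0("2024-03-06 08:00"), "discharge",
      "F05", ts0("2024-03-01 08:30"), ts0("2024-03-06 08:00"), "discharge",
      "F06", ts0("2024-03-01 08:30"), ts0("2024-03-04 08:00"), "discharge"),
    labels = tibble::tribble(
      ~encounter_id, ~died, ~icu_or_death, ~suspected_infection,
      "F01", FALSE, FALSE, FALSE,
      "F02", TRUE,  TRUE,  FALSE,   # dyad onset after the ICU transfer
      "F03", FALSE, FALSE, FALSE,
      "F04", FALSE, FALSE, TRUE,
      "F05", FALSE, FALSE, FALSE,
      "F06", FALSE, FALSE, TRUE),
    onsets = c(F04 = "2024-03-01 10:00", F06 = "2024-03-01 12:00"),
    # hand-traced per-score maxima over each time-at-risk interval
    max_scores = tibble::tribble(
      ~encounter_id, ~NEWS, ~MEWS, ~BTF, ~qSOFA, ~SIRS,
      "F01", 0L, 0L, 0L, 0L, 0L,
      "F02", 17L, 8L, 1L, 3L, 3L,
      "F03", 7L, 4L, 0L, 3L, 1L,
      "F04", 0L, 0L, 0L, 0L, 0L,
      "F05", 0L, 0L, 0L, 0L, 0L,
      "F06", 0L, 0L, 0L, 0L, 0L))
  list(cohort = cohort, expected = expected)
}
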