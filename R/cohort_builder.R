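vital_channels <- c("respiratory_rate", "heart_rate", "systolic_bp",
                    "temperature", "spo2", "supplemental_o2", "consciousness")

# exclusion rules, applied in this fixed order; the first failure is the reason
exclusion_order <- c("age", "labor_delivery", "direct ICU admission",
                     "died in ED", "ED discharge", "no qualifying vital sign")

#' Apply inclusion and exclusion rules
#'
#' Adults (age >= 18) with at least one vital sign charted in the ED or a
#' non-ICU ward are included. Exclusions, evaluated in a fixed order so the
#' recorded reason is reproducible: under 18; any labor-and-delivery location;
#' admitted directly to the ICU (first inpatient unit is ICU); died in the ED
#' before ward admission; discharged directly from the ED; no qualifying
#' vital sign.
#'
#' @param cohort An [ews_cohort()].
#' @return Tibble: `encounter_id`, `included` (logical), `reason` (`NA` when
#'   included, else the first failing rule).
#' @export
include_encounters <- function(cohort) {
  enc <- cohort$encounters
  loc <- cohort$locations
  obs <- cohort$observations

  first_unit <- loc |>
    dplyr::filter(.data$unit_class != "ED") |>
    dplyr::group_by(.data$encounter_id) |>
    dplyr::slice_min(.data$start, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("encounter_id", first_inpatient_unit = "unit_class")

  has_ld <- unique(loc$encounter_id[loc$unit_class == "labor_delivery"])
  ed_only <- vapply(split(loc$unit_class, loc$encounter_id),
                    function(u) all(u == "ED"), logical(1))
  ed_only_ids <- names(ed_only)[ed_only]

  # vital sign charted during an ED or ward interval
  qual <- obs[obs$channel %in% vital_channels, ]
  edw <- loc[loc$unit_class %in% c("ED", "ward"), ]
  qual_ids <- character(0)
  if (nrow(qual) > 0 && nrow(edw) > 0) {
    j <- dplyr::inner_join(qual, edw, by = "encounter_id",
                           relationship = "many-to-many")
    hit <- j$time >= j$start & j$time < j$end
    qual_ids <- unique(j$encounter_id[hit])
  }

  res <- enc |>
    dplyr::left_join(first_unit, by = "encounter_id") |>
    dplyr::mutate(
      fail_age = .data$age < 18,
      fail_ld = .data$encounter_id %in% has_ld,
      fail_icu = !is.na(.data$first_inpatient_unit) &
        .data$first_inpatient_unit == "ICU",
      fail_ed_death = .data$encounter_id %in% ed_only_ids &
        !is.na(.data$death_time),
      fail_ed_dc = .data$encounter_id %in% ed_only_ids &
        is.na(.data$death_time),
      fail_no_vitals = !(.data$encounter_id %in% qual_ids))
  fails <- cbind(res$fail_age, res$fail_ld, res$fail_icu,
                 res$fail_ed_death, res$fail_ed_dc, res$fail_no_vitals)
  first_fail <- apply(fails, 1, function(f) {
    w <- which(f)
    if (length(w) == 0) NA_character_ else exclusion_order[w[1]]
  })
  tibble::tibble(encounter_id = res$encounter_id,
                 included = is.na(first_fail),
                 reason = first_fail)
}

#' Build the first time-at-risk interval
#'
#' The interval runs from the first vital sign charted in the ED or a ward to
#' the earliest of the first ward/ED-to-ICU transfer, death, or discharge.
#' Ward periods after an ICU stay are never used: only the first interval is
#' analyzed.
#'
#' @param cohort An [ews_cohort()].
#' @param included Optional result of [include_encounters()]; only included
#'   encounters get an interval. Defaults to running the inclusion rules.
#' @return Tibble: `encounter_id`, `start`, `end`, `end_reason`
#'   (`icu_transfer`, `death` or `discharge`).
#' @export
build_time_at_risk <- function(cohort, included = include_encounters(cohort)) {
  ids <- included$encounter_id[included$included]
  enc <- cohort$encounters[cohort$encounters$encounter_id %in% ids, ]
  loc <- cohort$locations
  obs <- cohort$observations

  qual <- obs[obs$channel %in% vital_channels & obs$encounter_id %in% ids, ]
  edw <- loc[loc$unit_class %in% c("ED", "ward"), ]
  # first transfer into ICU from a non-ICU unit
  icu_first <- loc[loc$unit_class == "ICU", ] |>
    dplyr::group_by(.data$encounter_id) |>
    dplyr::summarise(icu_time = min(.data$start), .groups = "drop")

  j <- dplyr::inner_join(qual, edw, by = "encounter_id",
                         relationship = "many-to-many")
  j <- j[j$time >= j$start & j$time < j$end, ]
  # only vitals preceding the first ICU stay can open the first interval
  j <- dplyr::left_join(j, icu_first, by = "encounter_id")
  j <- j[is.na(j$icu_time) | j$time < j$icu_time, ]
  first_vital <- j |>
    dplyr::group_by(.data$encounter_id) |>
    dplyr::summarise(start = min(.data$time), .groups = "drop")

  out <- enc |>
    dplyr::inner_join(first_vital, by = "encounter_id") |>
    dplyr::left_join(icu_first, by = "encounter_id")
  end_candidates <- cbind(as.numeric(out$icu_time),
                          as.numeric(out$death_time),
                          as.numeric(out$discharge_time))
  which_end <- apply(end_candidates, 1, function(x) which.min(x))
  end <- apply(end_candidates, 1, function(x) min(x, na.rm = TRUE))
  stopifnot(all(is.finite(end)))
  tibble::tibble(
    encounter_id = out$encounter_id,
    start = out$start,
    end = as.POSIXct(end, origin = "1970-01-01", tz = "UTC"),
    end_reason = c("icu_transfer", "death", "discharge")[which_end])
}

#' Assign outcome and infection labels
#'
#' `died` marks in-hospital death; `icu_or_death` is the combined outcome of
#' ICU transfer or death; `suspected_infection` requires a dyad onset inside
#' the time-at-risk interval.
#'
#' @param cohort An [ews_cohort()].
#' @param intervals From [build_time_at_risk()].
#' @param onsets Tibble `encounter_id`, `infection_onset` (optional; from
#'   [find_infection_onsets()]). When omitted no infections are flagged.
#' @return Tibble: `encounter_id`, `died`, `icu_or_death`,
#'   `suspected_infection`, `infection_onset`, `outcome_time` (time of the
#'   first combined-outcome event, `NA` otherwise), plus `patient_id` and
#'   `admit_time` carried over for downstream deduplication.
#' @export
assign_labels <- function(cohort, intervals, onsets = NULL) {
  enc <- cohort$encounters
  icu_ids <- unique(cohort$locations$encounter_id[
    cohort$locations$unit_class == "ICU"])
  lab <- intervals |>
    dplyr::left_join(enc, by = "encounter_id") |>
    dplyr::mutate(
      died = !is.na(.data$death_time),
      icu_or_death = .data$died | .data$encounter_id %in% icu_ids,
      outcome_time = dplyr::if_else(
        .data$end_reason %in% c("icu_transfer", "death"), .data$end,
        as.POSIXct(NA, tz = "UTC")))
  if (is.null(onsets))
    onsets <- tibble::tibble(encounter_id = character(0),
                             infection_onset = as.POSIXct(character(0), tz = "UTC"))
  lab <- lab |>
    dplyr::left_join(onsets, by = "encounter_id") |>
    dplyr::mutate(
      suspected_infection = !is.na(.data$infection_onset) &
        .data$infection_onset >= .data$start &
        .data$infection_onset <= .data$end,
      infection_onset = dplyr::if_else(.data$suspected_infection,
                                       .data$infection_onset,
                                       as.POSIXct(NA, tz = "UTC")))
  lab[, c("encounter_id", "patient_id", "admit_time", "died", "icu_or_death",
          "suspected_infection", "infection_onset", "outcome_time")]
}

#' Keep one hospitalization per patient
#'
#' Used by the single-hospitalization sensitivity analysis: retains the
#' chronologically first encounter (by admission time) of each patient.
#'
#' @param labels A labeled cohort tibble containing `patient_id` and
#'   `admit_time` (e.g. from [assign_labels()]).
#' @return The input restricted to one row per patient.
#' @export
dedupe_patients <- function(labels) {
  labels |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_min(.data$admit_time, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

#' Cohort flow summary
#'
#' Counts per exclusion reason plus outcome and infection prevalences on the
#' included cohort, in the shape of a study flow / baseline table.
#'
#' @param included From [include_encounters()].
#' @param labels From [assign_labels()].
#' @return A list with `flow` (tibble of counts) and `prevalence` (tibble of
#'   rates on the included cohort).
#' @export
cohort_summary <- function(included, labels) {
  flow <- included |>
    dplyr::count(.data$included, .data$reason, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$included))
  prevalence <- tibble::tibble(
    n_included = nrow(labels),
    mortality = mean(labels$died),
    icu_or_death = mean(labels$icu_or_death),
    suspected_infection = mean(labels$suspected_infection))
  list(flow = flow, prevalence = prevalence)
}
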