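#' Suspected-infection dyad windows
#'
#' Pairing windows for the culture/antibiotic dyad: an antibiotic order up to
#' `antibiotic_after_culture_max` hours after a culture, or a culture up to
#' `culture_after_antibiotic_max` hours after an antibiotic, marks suspected
#' infection with onset at the first dyad element.
#'
#' @param antibiotic_after_culture_max Hours (default 72).
#' @param culture_after_antibiotic_max Hours (default 24).
#' @export
dyad_windows <- function(antibiotic_after_culture_max = 72,
                         culture_after_antibiotic_max = 24) {
  stopifnot(antibiotic_after_culture_max > 0,
            culture_after_antibiotic_max > 0)
  list(antibiotic_after_culture_max = antibiotic_after_culture_max,
       culture_after_antibiotic_max = culture_after_antibiotic_max)
}

#' Onset of suspected infection for one order stream
#'
#' Scans all culture/antibiotic pairs of one encounter. A pair qualifies when
#' the antibiotic follows the culture within the culture window (inclusive,
#' simultaneous orders qualify) or the culture follows the antibiotic within
#' the antibiotic window. The onset is the earliest first-element time over
#' all qualifying pairs.
#'
#' @param times POSIXct order times.
#' @param classes Character vector, `"blood_culture_or_micro_culture"` or
#'   `"antibiotic"`, parallel to `times`.
#' @param windows A [dyad_windows()].
#' @return POSIXct onset, or `NA` if no pair qualifies.
#' @export
find_infection_onset <- function(times, classes, windows = dyad_windows()) {
  cu <- sort(times[classes == "blood_culture_or_micro_culture"])
  ab <- sort(times[classes == "antibiotic"])
  if (length(cu) == 0 || length(ab) == 0) return(as.POSIXct(NA, tz = "UTC"))
  onset <- as.POSIXct(NA, tz = "UTC")
  for (ct in as.list(cu)) {
    d <- as.numeric(difftime(ab, ct, units = "hours"))
    # culture first: antibiotic within [0, w1]; antibiotic first: culture
    # within (0, w2]
    qual <- (d >= 0 & d <= windows$antibiotic_after_culture_max) |
      (d < 0 & -d <= windows$culture_after_antibiotic_max)
    if (any(qual)) {
      first_elem <- pmin(rep(ct, sum(qual)), ab[qual])
      cand <- min(first_elem)
      if (is.na(onset) || cand < onset) onset <- cand
    }
  }
  onset
}

#' Dyad onsets for a whole cohort
#'
#' @param cohort An [ews_cohort()].
#' @param windows A [dyad_windows()].
#' @return Tibble `encounter_id`, `infection_onset` (`NA` when no qualifying
#'   dyad exists anywhere in the encounter).
#' @export
find_infection_onsets <- function(cohort, windows = dyad_windows()) {
  ord <- cohort$orders
  if (nrow(ord) == 0)
    return(tibble::tibble(encounter_id = character(0),
                          infection_onset = as.POSIXct(character(0), tz = "UTC")))
  by_enc <- split(seq_len(nrow(ord)), ord$encounter_id)
  onsets <- vapply(by_enc, function(idx)
    as.numeric(find_infection_onset(ord$time[idx], ord$order_class[idx],
                                    windows)),
    numeric(1))
  tibble::tibble(
    encounter_id = names(by_enc),
    infection_onset = as.POSIXct(unname(onsets), origin = "1970-01-01",
                                 tz = "UTC"))
}

#' Flag suspected infection on a labeled cohort
#'
#' Computes dyad onsets over each whole encounter, then applies
#' [assign_labels()]: only an onset falling inside the time-at-risk interval
#' yields a suspected-infection hospitalization.
#'
#' @param cohort An [ews_cohort()].
#' @param intervals From [build_time_at_risk()].
#' @param windows A [dyad_windows()].
#' @return The [assign_labels()] tibble.
#' @export
flag_cohort <- function(cohort, intervals, windows = dyad_windows()) {
  assign_labels(cohort, intervals, find_infection_onsets(cohort, windows))
}
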