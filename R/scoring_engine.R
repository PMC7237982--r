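#' Event-driven score trajectory over a time-at-risk interval
#'
#' Starting from the imputation-to-normal state at the interval start, the
#' score is recalculated at every observation time: each new data element
#' replaces that channel's current value (last value carried forward) and the
#' total is recomputed. Observations outside the interval, on channels the
#' score does not read, or charted while the patient was in an ICU location
#' interval are ignored. Simultaneous observations (same minute, different
#' channels) are applied as one batch before a single recalculation;
#' same-minute duplicates of one channel keep the last row of the canonical
#' (encounter, time, channel, value) sort, so duplicate resolution does not
#' depend on input row order.
#'
#' @param cohort An [ews_cohort()].
#' @param encounter_id Encounter to score.
#' @param interval One-row tibble with `start`, `end` (from
#'   [build_time_at_risk()]), or a list with those elements.
#' @param def A [builtin_definition()].
#' @param staleness_hours Optional carry-forward cap: a value older than this
#'   reverts to the channel's normal default. `Inf` (the default) never
#'   expires values.
#' @return A `score_trajectory`: list with `encounter_id`, `score`, `points`
#'   (tibble of `time`, `value`, piecewise-constant between updates, first
#'   row at the interval start), `max_value` and `max_time` (first attainment
#'   of the maximum).
#' @export
compute_trajectory <- function(cohort, encounter_id, interval, def,
                               staleness_hours = Inf) {
  start <- interval$start[1]; end <- interval$end[1]
  if (is.na(start) || is.na(end) || start > end)
    stop("invalid time-at-risk interval", call. = FALSE)
  enc <- cohort$encounters[cohort$encounters$encounter_id == encounter_id, ]
  if (nrow(enc) == 1 && !is.na(enc$admit_time) &&
      (start < enc$admit_time - 1 || end > enc$discharge_time + 1))
    stop("interval outside encounter timeline", call. = FALSE)
  obs <- cohort$observations[cohort$observations$encounter_id == encounter_id, ]
  icu <- cohort$locations[cohort$locations$encounter_id == encounter_id &
                            cohort$locations$unit_class == "ICU", ]
  traj_core(obs$time, obs$channel, obs$value, start, end, def,
            icu_start = icu$start, icu_end = icu$end,
            staleness_hours = staleness_hours,
            encounter_id = encounter_id)
}

# Core trajectory computation on bare vectors (obs must be sorted by
# time, then channel; ties within a channel keep the last occurrence).
traj_core <- function(time, channel, value, start, end, def,
                      icu_start = NULL, icu_end = NULL,
                      staleness_hours = Inf, encounter_id = NA_character_) {
  keep <- channel %in% def$channels & time >= start & time <= end
  if (length(icu_start) > 0) {
    for (k in seq_along(icu_start))
      keep <- keep & !(time >= icu_start[k] & time < icu_end[k])
  }
  time <- time[keep]; channel <- channel[keep]; value <- value[keep]
  chan_idx <- match(channel, def$channels)
  # last duplicate wins per (time, channel)
  if (length(time) > 0) {
    key <- as.numeric(time) * (length(def$channels) + 1L) + chan_idx
    dup <- duplicated(key, fromLast = TRUE)
    time <- time[!dup]; chan_idx <- chan_idx[!dup]
    value <- value[!dup]
  }
  tnum <- as.numeric(time)
  all_num <- unique(c(as.numeric(start), sort(unique(tnum))))
  defaults <- normal_defaults()
  nt <- length(all_num)
  pts <- matrix(0L, nrow = nt, ncol = length(def$channels))
  for (j in seq_along(def$channels)) {
    ch <- def$channels[j]
    sel <- chan_idx == j
    v <- rep(defaults[[ch]], nt)
    if (any(sel)) {
      cht <- tnum[sel]; chv <- value[sel]
      idx <- findInterval(all_num, cht)
      have <- idx > 0
      v[have] <- chv[idx[have]]
      if (is.finite(staleness_hours)) {
        agesec <- all_num - c(-Inf, cht)[idx + 1]
        stale <- have & agesec > staleness_hours * 3600
        v[stale] <- defaults[[ch]]
      }
    }
    pts[, j] <- band_points(def, ch, v)
  }
  # per-criterion max, then aggregate
  crit_id <- match(def$criteria, unique(def$criteria))
  values <- integer(nt)
  for (g in unique(crit_id)) {
    cols <- which(crit_id == g)
    gmax <- pts[, cols[1]]
    for (cc in cols[-1]) gmax <- pmax(gmax, pts[, cc])
    values <- values + gmax
  }
  if (def$aggregation == "any_trigger") values <- as.integer(values > 0)
  max_value <- max(values)
  imax <- which.max(values)
  all_times <- .POSIXct(all_num, tz = "UTC")
  structure(list(
    encounter_id = encounter_id, score = def$name,
    points = tibble::new_tibble(list(time = all_times,
                                     value = as.integer(values)), nrow = nt),
    max_value = max_value, max_time = all_times[imax],
    interval_start = start, interval_end = end),
    class = "score_trajectory")
}

#' @export
print.score_trajectory <- function(x, ...) {
  cat(sprintf("<score_trajectory> %s, %s: %d updates, max %d at %s\n",
              x$encounter_id, x$score, nrow(x$points), x$max_value,
              format(x$max_time)))
  invisible(x)
}

#' Maximum score achieved during the interval
#'
#' @param traj A [compute_trajectory()] result.
#' @return Integer maximum of the trajectory; ties in time resolve to the
#'   earliest attainment for `max_time` (stored on the trajectory).
#' @export
max_score <- function(traj) {
  max(traj$points$value)
}

#' First threshold crossing and lead time
#'
#' @param traj A score trajectory.
#' @param threshold Integer alerting threshold (>= 1).
#' @param outcome_time Outcome timestamp, or `NA` if no outcome occurred.
#' @return One-row tibble: `encounter_id`, `score`, `threshold`,
#'   `first_crossing_time` (`NA` if the trajectory never reaches the
#'   threshold) and `lead_time_hours` (outcome minus crossing, present only
#'   when both exist).
#' @export
first_crossing <- function(traj, threshold, outcome_time = NA) {
  stopifnot(threshold >= 1)
  if (!is.na(outcome_time) && outcome_time < traj$interval_start)
    stop("outcome_time precedes the time-at-risk interval", call. = FALSE)
  hit <- which(traj$points$value >= threshold)
  ct <- if (length(hit) > 0) traj$points$time[hit[1]] else as.POSIXct(NA, tz = "UTC")
  lead <- if (length(hit) > 0 && !is.na(outcome_time))
    as.numeric(difftime(outcome_time, ct, units = "hours")) else NA_real_
  tibble::tibble(encounter_id = traj$encounter_id, score = traj$score,
                 threshold = as.integer(threshold),
                 first_crossing_time = ct, lead_time_hours = lead)
}

#' Censor the final hour before the outcome
#'
#' Used by the sensitivity analysis that drops data charted in the hour
#' immediately preceding the outcome: trajectory points at or after
#' `outcome_time - 1h` are removed and the maximum recomputed. If nothing
#' remains the constant imputation-to-normal trajectory is returned.
#'
#' @param traj A score trajectory.
#' @param outcome_time Outcome timestamp.
#' @return A censored `score_trajectory`.
#' @export
censor_final_hour <- function(traj, outcome_time) {
  cutoff <- outcome_time - 3600
  keep <- traj$points$time < cutoff
  pts <- traj$points[keep, ]
  if (nrow(pts) == 0)
    pts <- tibble::tibble(time = traj$interval_start, value = 0L)
  out <- traj
  out$points <- pts
  out$max_value <- max(pts$value)
  out$max_time <- pts$time[which(pts$value == out$max_value)[1]]
  out
}

#' Maximum scores for a whole cohort
#'
#' Convenience wrapper computing [compute_trajectory()] per encounter for one
#' or more scoring systems and returning the per-encounter maxima used by the
#' discrimination analyses.
#'
#' @param cohort An [ews_cohort()].
#' @param intervals Time-at-risk intervals from [build_time_at_risk()].
#' @param defs List of score definitions (default: all five built-ins).
#' @param censor_outcome_times Optional named vector/tibble of outcome times;
#'   when supplied, each trajectory is censored with [censor_final_hour()]
#'   before taking the maximum.
#' @param staleness_hours Passed to [compute_trajectory()].
#' @return Tibble: `encounter_id`, `score`, `max_value`, `max_time`.
#' @export
max_scores <- function(cohort, intervals, defs = lapply(score_names(), builtin_definition),
                       censor_outcome_times = NULL, staleness_hours = Inf) {
  if (inherits(defs, "score_definition")) defs <- list(defs)
  obs <- cohort$observations
  obs_split <- split(seq_len(nrow(obs)), obs$encounter_id)
  icu <- cohort$locations[cohort$locations$unit_class == "ICU", ]
  icu_split <- split(seq_len(nrow(icu)), icu$encounter_id)
  n_iv <- nrow(intervals)
  out_eid <- character(0); out_score <- character(0)
  out_max <- integer(0); out_maxt <- numeric(0)
  for (def in defs) {
    mv <- integer(n_iv); mt <- numeric(n_iv)
    for (i in seq_len(n_iv)) {
      eid <- intervals$encounter_id[i]
      oi <- obs_split[[eid]]
      ii <- icu_split[[eid]]
      tr <- traj_core(
        obs$time[oi], obs$channel[oi], obs$value[oi],
        intervals$start[i], intervals$end[i], def,
        icu_start = icu$start[ii], icu_end = icu$end[ii],
        staleness_hours = staleness_hours, encounter_id = eid)
      if (!is.null(censor_outcome_times)) {
        ot <- censor_outcome_times[[eid]]
        if (!is.null(ot) && !is.na(ot)) tr <- censor_final_hour(tr, ot)
      }
      mv[i] <- tr$max_value; mt[i] <- as.numeric(tr$max_time)
    }
    out_eid <- c(out_eid, intervals$encounter_id)
    out_score <- c(out_score, rep(def$name, n_iv))
    out_max <- c(out_max, mv); out_maxt <- c(out_maxt, mt)
  }
  tibble::tibble(encounter_id = out_eid, score = out_score,
                 max_value = out_max,
                 max_time = as.POSIXct(out_maxt, origin = "1970-01-01",
                                       tz = "UTC"))
}
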