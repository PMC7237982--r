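# Brute-force oracles and random-input builders shared across the suite.

# Full-rescan trajectory oracle: at every event time, rebuild the channel
# state from scratch by scanning the complete filtered history, then score it
# with total_score(). Independent of the incremental LOCF engine.
oracle_trajectory <- function(cohort, encounter_id, interval, def,
                              censor_time = NULL) {
  obs <- cohort$observations[cohort$observations$encounter_id == encounter_id, ]
  icu <- cohort$locations[cohort$locations$encounter_id == encounter_id &
                            cohort$locations$unit_class == "ICU", ]
  keep <- obs$channel %in% def$channels &
    obs$time >= interval$start[1] & obs$time <= interval$end[1]
  if (nrow(icu) > 0)
    for (k in seq_len(nrow(icu)))
      keep <- keep & !(obs$time >= icu$start[k] & obs$time < icu$end[k])
  obs <- obs[keep, ]
  obs <- obs[order(obs$time, obs$channel), ]
  times <- unique(c(interval$start[1], sort(unique(obs$time))))
  if (!is.null(censor_time)) {
    times <- times[times < censor_time - 3600]
    if (length(times) == 0)   # emptied: constant imputed-normal trajectory
      return(tibble::tibble(time = interval$start[1], value = 0L))
  }
  defaults <- normal_defaults()
  vals <- vapply(times, function(t) {
    state <- defaults
    hist <- obs[obs$time <= t, ]
    for (ch in unique(hist$channel)) {
      h <- hist[hist$channel == ch, ]
      state[[ch]] <- h$value[nrow(h)]   # last row after canonical sort
    }
    total_score(def, state[def$channels])
  }, numeric(1))
  tibble::tibble(time = times, value = as.integer(vals))
}

# O(n^2) all-pairs concordance oracle for the AUC.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# Random single-encounter cohort exercising every channel, optional mid-stay
# ICU interval, for engine/oracle property tests.
random_encounter <- function(id = "R1") {
  t0 <- as.POSIXct("2024-05-01 08:00", tz = "UTC")
  los_h <- runif(1, 24, 96)
  t_end <- t0 + round(los_h) * 3600
  chs <- channel_names()
  reg <- ews_channels()
  n_obs <- sample(5:40, 1)
  times <- t0 + round(runif(n_obs, 0, los_h) * 60) * 60
  channel <- sample(chs, n_obs, replace = TRUE)
  value <- vapply(channel, function(ch) {
    r <- reg[reg$channel == ch, ]
    if (ch == "consciousness") sample(0:3, 1)
    else if (ch == "supplemental_o2") sample(0:1, 1)
    else if (ch == "temperature") round(runif(1, 30, 42), 1)
    else round(runif(1, r$lo, r$hi))
  }, numeric(1))
  locations <- tibble::tibble(encounter_id = id, unit_class = "ward",
                              start = t0, end = t_end)
  if (runif(1) < 0.3) {
    icu_s <- t0 + round(los_h * 0.4) * 3600
    icu_e <- t0 + round(los_h * 0.6) * 3600
    locations <- tibble::tibble(
      encounter_id = id, unit_class = c("ward", "ICU", "ward"),
      start = c(t0, icu_s, icu_e), end = c(icu_s, icu_e, t_end))
  }
  cohort <- ews_cohort(
    encounters = tibble::tibble(
      encounter_id = id, patient_id = "P", age = 50, admit_time = t0,
      discharge_time = t_end, admitted_via_ed = FALSE,
      death_time = as.POSIXct(NA, tz = "UTC")),
    observations = tibble::tibble(encounter_id = id, time = times,
                                  channel = channel, value = value),
    locations = locations,
    orders = tibble::tibble(encounter_id = character(0),
                            time = as.POSIXct(character(0), tz = "UTC"),
                            order_class = character(0)))
  interval <- tibble::tibble(encounter_id = id, start = t0, end = t_end,
                             end_reason = "discharge")
  list(cohort = cohort, interval = interval)
}

expect_same_trajectory <- function(traj, oracle) {
  expect_equal(as.numeric(traj$points$time), as.numeric(oracle$time))
  expect_equal(traj$points$value, oracle$value)
}
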