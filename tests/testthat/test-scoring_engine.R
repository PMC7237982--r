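qsofa <- builtin_definition("qSOFA")
news <- builtin_definition("NEWS")

ts <- function(x) as.POSIXct(x, tz = "UTC")

one_enc_cohort <- function(obs, admit = "2024-01-01 08:00",
                           discharge = "2024-01-03 08:00") {
  ews_cohort(
    encounters = tibble::tibble(
      encounter_id = "E1", patient_id = "P1", age = 50,
      admit_time = ts(admit), discharge_time = ts(discharge),
      admitted_via_ed = FALSE, death_time = ts(NA_character_)),
    observations = obs,
    locations = tibble::tibble(encounter_id = "E1", unit_class = "ward",
                               start = ts(admit), end = ts(discharge)),
    orders = tibble::tibble(encounter_id = character(0),
                            time = ts(character(0)),
                            order_class = character(0)))
}
iv1 <- tibble::tibble(encounter_id = "E1", start = ts("2024-01-01 08:00"),
                      end = ts("2024-01-03 08:00"), end_reason = "discharge")

test_that("imputation to normal yields a constant-zero trajectory", {
  co <- one_enc_cohort(tibble::tibble(
    encounter_id = "E1", time = ts("2024-01-01 12:00"), channel = "wbc",
    value = 9))  # not a qSOFA channel
  tr <- compute_trajectory(co, "E1", iv1, qsofa)
  expect_equal(tr$points$value, 0L)
  expect_equal(tr$points$time, iv1$start)
  expect_equal(max_score(tr), 0L)
})

test_that("a single relevant event flips the score at its time, LOCF after", {
  co <- one_enc_cohort(tibble::tibble(
    encounter_id = "E1",
    time = ts(c("2024-01-01 14:00", "2024-01-02 02:00")),
    channel = c("respiratory_rate", "heart_rate"), value = c(24, 80)))
  tr <- compute_trajectory(co, "E1", iv1, qsofa)
  expect_equal(as.numeric(tr$points$time),
               as.numeric(ts(c("2024-01-01 08:00", "2024-01-01 14:00"))))
  expect_equal(tr$points$value, c(0L, 1L))  # RR 24 persists; HR not read
  expect_equal(tr$max_value, 1L)
  expect_equal(tr$max_time, ts("2024-01-01 14:00"))
})

test_that("simultaneous observations apply as one batch; last duplicate wins", {
  co <- one_enc_cohort(tibble::tibble(
    encounter_id = "E1",
    time = ts(c("2024-01-01 14:00", "2024-01-01 14:00", "2024-01-01 14:00")),
    channel = c("respiratory_rate", "systolic_bp", "systolic_bp"),
    value = c(24, 95, 120)))
  tr <- compute_trajectory(co, "E1", iv1, qsofa)
  # one recomputation: RR point; duplicate SBP readings resolve to the last
  # row of the canonical (time, channel, value) sort, i.e. 120, scoring 0
  expect_equal(tr$points$value, c(0L, 1L))
})

test_that("observations charted in the ICU are excluded from the trajectory", {
  co <- one_enc_cohort(tibble::tibble(
    encounter_id = "E1",
    time = ts(c("2024-01-01 12:00", "2024-01-02 12:00")),
    channel = "respiratory_rate", value = c(14, 30)))
  co$locations <- tibble::tibble(
    encounter_id = "E1", unit_class = c("ward", "ICU", "ward"),
    start = ts(c("2024-01-01 08:00", "2024-01-02 00:00", "2024-01-02 20:00")),
    end = ts(c("2024-01-02 00:00", "2024-01-02 20:00", "2024-01-03 08:00")))
  tr <- compute_trajectory(co, "E1", iv1, qsofa)
  expect_equal(max_score(tr), 0L)  # the RR=30 reading fell inside the ICU
})

test_that("max_score ties resolve to the earliest attainment", {
  co <- one_enc_cohort(tibble::tibble(
    encounter_id = "E1",
    time = ts(c("2024-01-01 10:00", "2024-01-01 12:00", "2024-01-01 14:00",
                "2024-01-01 16:00")),
    channel = "respiratory_rate", value = c(14, 24, 18, 24)))
  tr <- compute_trajectory(co, "E1", iv1, qsofa)
  expect_equal(tr$points$value, c(0L, 0L, 1L, 0L, 1L))
  expect_equal(tr$max_value, 1L)
  expect_equal(tr$max_time, ts("2024-01-01 12:00"))
})

test_that("first crossings and lead times follow the trajectory", {
  co <- one_enc_cohort(tibble::tibble(
    encounter_id = "E1", time = ts("2024-01-01 10:00"),
    channel = c("respiratory_rate", "systolic_bp"), value = c(24, 95)))
  tr <- compute_trajectory(co, "E1", iv1, qsofa)
  cr <- first_crossing(tr, 2L, outcome_time = ts("2024-01-01 15:18"))
  expect_equal(cr$first_crossing_time, ts("2024-01-01 10:00"))
  expect_equal(cr$lead_time_hours, 5.3)
  # never reaches threshold 3
  cr3 <- first_crossing(tr, 3L, outcome_time = ts("2024-01-01 15:18"))
  expect_true(is.na(cr3$first_crossing_time))
  expect_true(is.na(cr3$lead_time_hours))
  # constant-zero trajectory never crosses threshold 1
  tr0 <- compute_trajectory(one_enc_cohort(tibble::tibble(
    encounter_id = character(0), time = ts(character(0)),
    channel = character(0), value = numeric(0))), "E1", iv1, qsofa)
  expect_true(is.na(first_crossing(tr0, 1L)$first_crossing_time))
  expect_error(first_crossing(tr, 2L, ts("2024-01-01 06:00")), "precedes")
})

test_that("final-hour censoring drops late updates and recomputes the max", {
  mk <- function(obs_time) one_enc_cohort(tibble::tibble(
    encounter_id = "E1", time = ts(obs_time),
    channel = "respiratory_rate", value = 24))
  outcome <- ts("2024-01-02 12:00")
  tr_late <- compute_trajectory(mk("2024-01-02 11:30"), "E1", iv1, qsofa)
  cen <- censor_final_hour(tr_late, outcome)
  expect_equal(cen$max_value, 0L)
  tr_early <- compute_trajectory(mk("2024-01-02 10:00"), "E1", iv1, qsofa)
  expect_equal(censor_final_hour(tr_early, outcome)$max_value,
               tr_early$max_value)
  expect_lte(censor_final_hour(tr_late, outcome)$max_value,
             tr_late$max_value)
})

test_that("incremental engine matches the full-rescan oracle on random data", {
  defs <- lapply(score_names(), builtin_definition)
  set.seed(101)
  for (rep in 1:40) {
    re <- random_encounter()
    for (def in defs) {
      tr <- compute_trajectory(re$cohort, "R1", re$interval, def)
      expect_same_trajectory(tr, oracle_trajectory(re$cohort, "R1",
                                                   re$interval, def))
    }
  }
})

test_that("input row order does not affect trajectories", {
  set.seed(202)
  for (rep in 1:10) {
    re <- random_encounter()
    perm <- re$cohort
    idx <- sample(nrow(perm$observations))
    perm <- ews_cohort(perm$encounters, perm$observations[idx, ],
                       perm$locations, perm$orders)
    for (sc in c("NEWS", "SIRS")) {
      d <- builtin_definition(sc)
      t1 <- compute_trajectory(re$cohort, "R1", re$interval, d)
      t2 <- compute_trajectory(perm, "R1", re$interval, d)
      expect_equal(t1$points, t2$points)
    }
  }
})

test_that("adding an observation only changes the trajectory from its time on", {
  set.seed(303)
  for (rep in 1:10) {
    re <- random_encounter()
    t_new <- re$interval$start + round(runif(1, 1, 40)) * 3600
    extra <- tibble::tibble(encounter_id = "R1", time = t_new,
                            channel = "heart_rate", value = 140)
    co2 <- ews_cohort(re$cohort$encounters,
                      dplyr::bind_rows(re$cohort$observations, extra),
                      re$cohort$locations, re$cohort$orders)
    t1 <- compute_trajectory(re$cohort, "R1", re$interval, news)
    t2 <- compute_trajectory(co2, "R1", re$interval, news)
    before1 <- t1$points[t1$points$time < t_new, ]
    before2 <- t2$points[t2$points$time < t_new, ]
    expect_equal(before1, before2)
  }
})

test_that("an optional staleness cap reverts expired values to normal", {
  co <- one_enc_cohort(tibble::tibble(
    encounter_id = "E1",
    time = ts(c("2024-01-01 10:00", "2024-01-02 10:00")),
    channel = c("respiratory_rate", "systolic_bp"), value = c(24, 120)))
  tr_inf <- compute_trajectory(co, "E1", iv1, qsofa)
  expect_equal(tr_inf$points$value, c(0L, 1L, 1L))   # LOCF never expires
  tr_cap <- compute_trajectory(co, "E1", iv1, qsofa, staleness_hours = 12)
  expect_equal(tr_cap$points$value, c(0L, 1L, 0L))   # RR reverted by day 2
})
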