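#' Synthetic ward-cohort generator configuration
#'
#' Defaults emulate the statistical structure of a large multi-hospital
#' non-ICU inpatient cohort: ~2% mortality, ~12% ICU transfer or death, ~33%
#' suspected-infection prevalence, vitals charted every ~4 h with <1%
#' missingness versus high lab missingness (87% for band forms), and
#' deterioration signal concentrated in the channels the scores read, ramping
#' over the final 24 h before the outcome.
#'
#' The outcome model: each encounter has a latent severity `z ~ N(0,1)`;
#' the combined outcome (ICU transfer or death) follows a logistic link with
#' hospital-stratum intercept offsets and slope `severity_slope`; death among
#' outcome cases follows a second logistic with slope `death_slope`, so
#' deaths concentrate at high severity. Intercepts are calibrated numerically
#' so the marginal rates match the configured targets. Signal enters twice:
#' a persistent baseline shift proportional to `z` and, for outcome cases, a
#' linear ramp over the final `ramp_hours`; both are scaled per channel by
#' `signal_profile` (standardized effect sizes), so zero effect sizes yield a
#' pure-noise cohort. ICU transfers without death in the non-infected arm get
#' their ramp attenuated by `noninfected_icu_attenuation`, mimicking
#' low-acuity (e.g. elective) transfers.
#'
#' @param n_encounters Number of encounters to emit.
#' @param seed Integer seed; mandatory, the generator is fully reproducible.
#' @param mortality_rate,icu_or_death_rate,infection_prevalence Target
#'   marginal rates.
#' @param n_hospitals Number of strata; `hospital_effects` gives their
#'   log-odds offsets (recycled/truncated to `n_hospitals`).
#' @param hospital_effects Log-odds offsets per hospital stratum.
#' @param vitals_interval_hours Mean charting interval for vital signs.
#' @param channel_missingness Named per-channel missingness fractions.
#' @param signal_profile Named standardized effect sizes per channel.
#' @param severity_slope,death_slope Logistic slopes on latent severity.
#' @param noninfected_icu_attenuation Ramp multiplier for non-infected
#'   ICU-transfer-only cases.
#' @param ramp_hours Length of the pre-outcome deterioration ramp.
#' @param dyad_emission Probabilities of emitting a qualifying
#'   culture/antibiotic dyad in the infected and uninfected arms.
#' @param exclusion_fraction Fraction of encounters deliberately violating an
#'   inclusion rule (minors, direct-ICU admissions, ED discharges,
#'   labor-and-delivery stays, ED deaths) to exercise the cohort builder.
#' @param los_median_days,los_sdlog Log-normal length-of-stay parameters.
#' @return A validated config list of class `generator_config`.
#' @export
generator_config <- function(
    n_encounters = 1000, seed = 1,
    mortality_rate = 0.02, icu_or_death_rate = 0.12,
    infection_prevalence = 0.33,
    n_hospitals = 4, hospital_effects = c(-0.3, -0.1, 0.1, 0.3),
    vitals_interval_hours = 4,
    channel_missingness = c(respiratory_rate = 0.005, heart_rate = 0.005,
                            systolic_bp = 0.005, temperature = 0.005,
                            spo2 = 0.005, supplemental_o2 = 0.005,
                            consciousness = 0.005, wbc = 0.25,
                            band_fraction = 0.87, paco2 = 0.90),
    signal_profile = c(respiratory_rate = 1.0, heart_rate = 0.9,
                       systolic_bp = 0.9, temperature = 0.6, spo2 = 0.9,
                       supplemental_o2 = 0.7, consciousness = 0.6,
                       wbc = 0.7, band_fraction = 0.4, paco2 = 0),
    severity_slope = 1.2, death_slope = 1.2,
    noninfected_icu_attenuation = 0.4, ramp_hours = 24,
    dyad_emission = list(infected = 0.98, uninfected = 0.02),
    exclusion_fraction = 0.05,
    los_median_days = 2.5, los_sdlog = 0.6) {
  cfg <- as.list(environment())
  frac_fields <- c("mortality_rate", "icu_or_death_rate",
                   "infection_prevalence", "exclusion_fraction")
  for (f in frac_fields)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("generator config error: ", f, " must be a fraction in [0, 1]",
           call. = FALSE)
  if (!is.numeric(cfg$n_encounters) || cfg$n_encounters < 1)
    stop("generator config error: n_encounters must be positive", call. = FALSE)
  if (is.null(cfg$seed) || is.na(cfg$seed))
    stop("generator config error: seed is mandatory", call. = FALSE)
  if (any(!is.finite(cfg$signal_profile)))
    stop("generator config error: signal_profile has non-finite effect size",
         call. = FALSE)
  if (any(cfg$channel_missingness < 0 | cfg$channel_missingness > 1))
    stop("generator config error: channel_missingness must be fractions",
         call. = FALSE)
  cfg$hospital_effects <- rep_len(cfg$hospital_effects, cfg$n_hospitals)
  structure(cfg, class = "generator_config")
}

# intercept a such that mean over strata of E_z plogis(a + off + b z) hits the
# target rate
calibrate_intercept <- function(target, slope, offsets = 0) {
  marginal <- function(a) {
    mean(vapply(offsets, function(off)
      stats::integrate(function(z) stats::plogis(a + off + slope * z) *
                         stats::dnorm(z), -8, 8)$value, numeric(1)))
  }
  stats::uniroot(function(a) marginal(a) - target, c(-15, 10))$root
}

# intercept a_d such that E[p_outcome(z) * plogis(a_d + c z)] = target
calibrate_death_intercept <- function(target, a_out, b_out, offsets, c_death) {
  marginal <- function(a) {
    mean(vapply(offsets, function(off)
      stats::integrate(function(z)
        stats::plogis(a_out + off + b_out * z) *
          stats::plogis(a + c_death * z) * stats::dnorm(z),
        -8, 8)$value, numeric(1)))
  }
  stats::uniroot(function(a) marginal(a) - target, c(-15, 10))$root
}

round_minute <- function(t) {
  as.POSIXct(round(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

# per-channel generation parameters: baseline mean/sd, measurement noise,
# population scale (SD units for effect sizes) and abnormal direction
channel_gen_params <- function() {
  tibble::tribble(
    ~channel,           ~base_mean, ~base_sd, ~noise, ~scale, ~dir, ~digits,
    "respiratory_rate",       16.0,      2.0,    2.0,    4.0,    1,       0,
    "heart_rate",             78.0,      8.0,    6.0,   12.0,    1,       0,
    "systolic_bp",           122.0,     10.0,    8.0,   15.0,   -1,       0,
    "temperature",            36.8,     0.25,    0.3,    0.6,    1,       1,
    "spo2",                   97.0,      1.0,    1.2,    3.0,   -1,       0,
    "wbc",                     8.0,      2.0,    1.0,    4.0,    1,       1,
    "band_fraction",           2.0,      2.0,    1.5,    8.0,    1,       0,
    "paco2",                  40.0,      3.0,    2.0,    8.0,   -1,       0
  )
}

#' Generate a synthetic cohort with ground truth
#'
#' See [generator_config()] for the generative model. The emitted cohort
#' passes [validate_cohort()]; outcome, infection and exclusion structure is
#' returned as a ground-truth table so recovery tests can compare what the
#' pipeline estimates with what was planted.
#'
#' @param cfg A [generator_config()].
#' @return A list: `cohort` (an [ews_cohort()]) and `truth` (tibble with
#'   per-encounter latent severity, planted outcome and time, infection arm,
#'   ramp amplitude and any planted exclusion violation).
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n <- as.integer(cfg$n_encounters)
  eid <- sprintf("E%05d", seq_len(n))
  pid <- sprintf("P%05d", sample.int(max(1L, ceiling(n * 0.85)), n,
                                     replace = TRUE))
  hospital <- sample.int(cfg$n_hospitals, n, replace = TRUE)
  z <- stats::rnorm(n)

  # planted exclusion violations
  n_excl <- floor(cfg$exclusion_fraction * n)
  excl_types <- c("minor", "direct_icu", "ed_discharge", "labor_delivery",
                  "died_in_ed")
  excluded_design <- rep(NA_character_, n)
  if (n_excl > 0)
    excluded_design[sample.int(n, n_excl)] <-
      rep_len(excl_types, n_excl)
  clean <- is.na(excluded_design)

  # arms and outcomes (clean encounters only)
  a_inf <- calibrate_intercept(cfg$infection_prevalence, 0.5)
  infected <- stats::runif(n) < stats::plogis(a_inf + 0.5 * z) & clean
  a_out <- calibrate_intercept(cfg$icu_or_death_rate, cfg$severity_slope,
                               cfg$hospital_effects)
  p_out <- stats::plogis(a_out + cfg$hospital_effects[hospital] +
                           cfg$severity_slope * z)
  has_outcome <- stats::runif(n) < p_out & clean
  a_death <- calibrate_death_intercept(cfg$mortality_rate, a_out,
                                       cfg$severity_slope,
                                       cfg$hospital_effects, cfg$death_slope)
  dies <- has_outcome & stats::runif(n) < stats::plogis(a_death +
                                                          cfg$death_slope * z)
  outcome <- ifelse(dies, "death", ifelse(has_outcome, "icu", "none"))
  # per-patient heterogeneity in how strongly deterioration expresses itself
  amp <- ifelse(outcome == "icu" & !infected,
                cfg$noninfected_icu_attenuation, 1) *
    stats::rlnorm(n, -0.08, 0.4)

  admit <- round_minute(as.POSIXct("2024-01-01 00:00", tz = "UTC") +
                          stats::runif(n, 0, 364) * 86400)
  via_ed <- stats::runif(n) < 0.6
  los_days <- pmax(0.5, stats::rlnorm(n, log(cfg$los_median_days),
                                      cfg$los_sdlog))
  # the outcome ends the time-at-risk interval at a time drawn from the same
  # stay-length distribution as an uneventful discharge, so interval length
  # itself carries no outcome information: discrimination must come from the
  # planted channel signal, not from observation counts
  outcome_delay <- los_days

  gp <- channel_gen_params()
  eff <- cfg$signal_profile
  miss <- cfg$channel_missingness
  vital_ch <- c("respiratory_rate", "heart_rate", "systolic_bp",
                "temperature", "spo2")
  lab_ch <- c("wbc", "band_fraction", "paco2")
  g_mean <- stats::setNames(gp$base_mean, gp$channel)
  g_bsd <- stats::setNames(gp$base_sd, gp$channel)
  g_noise <- stats::setNames(gp$noise, gp$channel)
  g_scale <- stats::setNames(gp$scale, gp$channel)
  g_dir <- stats::setNames(gp$dir, gp$channel)
  g_dig <- stats::setNames(gp$digits, gp$channel)
  lims <- channel_bounds()
  rmin <- function(x) round(x / 60) * 60    # numeric seconds -> whole minutes

  obs_t <- vector("list", n); obs_c <- vector("list", n)
  obs_v <- vector("list", n)
  loc_e <- vector("list", n); loc_u <- vector("list", n)
  loc_s <- vector("list", n); loc_x <- vector("list", n)
  ord_e <- vector("list", n); ord_t <- vector("list", n)
  ord_c <- vector("list", n)
  age_v <- integer(n); dis_v <- numeric(n); death_v <- rep(NA_real_, n)
  via_v <- logical(n)
  truth_time <- rep(NA_real_, n)
  infection_onset <- rep(NA_real_, n)
  admit_n <- as.numeric(admit)

  for (i in seq_len(n)) {
    a0 <- admit_n[i]
    ev <- excluded_design[i]
    age_v[i] <- if (!is.na(ev) && ev == "minor") sample(8:17, 1) else
      if (!is.na(ev) && ev == "labor_delivery") sample(18:40, 1) else
        sample(18:95, 1)
    ed_end <- rmin(a0 + stats::runif(1, 2, 6) * 3600)

    if (!is.na(ev) && ev %in% c("ed_discharge", "died_in_ed")) {
      dis <- ed_end
      dis_v[i] <- dis
      if (ev == "died_in_ed") death_v[i] <- dis
      via_v[i] <- TRUE
      loc_e[[i]] <- eid[i]; loc_u[[i]] <- "ED"
      loc_s[[i]] <- a0; loc_x[[i]] <- dis
      vt <- sort(unique(rmin(a0 + stats::runif(2, 0.2, 3) * 3600)))
      nv <- length(vt)
      obs_t[[i]] <- rep(vt, length(vital_ch))
      obs_c[[i]] <- rep(vital_ch, each = nv)
      obs_v[[i]] <- unlist(lapply(vital_ch, function(ch)
        pmin(pmax(round(stats::rnorm(nv, g_mean[[ch]], g_noise[[ch]]),
                        g_dig[[ch]]), lims$lo[[ch]]), lims$hi[[ch]])))
      next
    }

    # ward timeline
    oc <- outcome[i]
    ot <- if (oc != "none") rmin(a0 + outcome_delay[i] * 86400) else NA_real_
    dis <- if (oc == "death") ot
      else if (oc == "icu")
        rmin(ot + stats::rlnorm(1, log(2), 0.5) * 86400 + 86400)
      else rmin(a0 + los_days[i] * 86400)
    if (oc == "death") death_v[i] <- ot
    truth_time[i] <- ot

    ward_start <- if (via_ed[i] && is.na(ev)) ed_end else a0
    via_v[i] <- via_ed[i] && is.na(ev)
    unit <- if (!is.na(ev) && ev == "labor_delivery") "labor_delivery" else "ward"
    lu <- character(0); ls <- numeric(0); lx <- numeric(0)
    if (via_ed[i] && is.na(ev)) {
      lu <- "ED"; ls <- a0; lx <- ward_start
    }
    if (!is.na(ev) && ev == "direct_icu") {
      icu_end <- rmin(ward_start + 86400)
      dis <- max(dis, rmin(icu_end + 43200))
      lu <- c(lu, "ICU", "ward")
      ls <- c(ls, ward_start, icu_end); lx <- c(lx, icu_end, dis)
    } else if (oc == "icu") {
      icu_end <- rmin(dis - 86400)
      lu <- c(lu, unit, "ICU", "ward")
      ls <- c(ls, ward_start, ot, icu_end); lx <- c(lx, ot, icu_end, dis)
    } else {
      lu <- c(lu, unit); ls <- c(ls, ward_start); lx <- c(lx, dis)
    }
    dis_v[i] <- dis
    loc_e[[i]] <- rep(eid[i], length(lu))
    loc_u[[i]] <- lu; loc_s[[i]] <- ls; loc_x[[i]] <- lx

    # observation schedule: jittered vitals cadence over the whole stay
    stay_h <- (dis - a0) / 3600
    k <- seq(0, stay_h, by = cfg$vitals_interval_hours)
    vt <- rmin(a0 + (k + c(0, stats::runif(length(k) - 1, -1, 1))) * 3600)
    vt <- sort(unique(pmin(pmax(vt, a0), dis)))
    # daily labs in the early morning
    nd <- max(1, ceiling(stay_h / 24))
    lt <- rmin(a0 + (seq_len(nd) - 1) * 86400 + stats::runif(nd, 4, 8) * 3600)
    lt <- lt[lt >= a0 & lt <= dis]

    ramp <- function(tt) {
      if (is.na(ot)) return(rep(0, length(tt)))
      pmax(0, 1 - (ot - tt) / 3600 / cfg$ramp_hours) * (tt <= ot)
    }
    inf_effect <- function(tt, onset) {
      if (is.na(onset)) return(rep(0, length(tt)))
      as.numeric(tt >= onset & tt <= onset + 48 * 3600)
    }

    # infection onset and dyad orders
    onset <- NA_real_
    emit_p <- if (infected[i]) cfg$dyad_emission$infected else
      cfg$dyad_emission$uninfected
    if (stats::runif(1) < emit_p) {
      horizon <- if (!is.na(ot)) ot else dis
      onset <- rmin(ward_start + stats::runif(1, 0.05, 0.6) *
                      (horizon - ward_start))
      ab_gap <- stats::runif(1, 0.5, 48) * 3600
      ord_e[[i]] <- rep(eid[i], 2)
      ord_t[[i]] <- rmin(c(onset, onset + ab_gap))
      ord_c[[i]] <- c("blood_culture_or_micro_culture", "antibiotic")
    } else if (stats::runif(1) < 0.08) {
      # isolated, non-qualifying order noise
      ord_e[[i]] <- eid[i]
      ord_t[[i]] <- rmin(ward_start + stats::runif(1, 1, 24) * 3600)
      ord_c[[i]] <- sample(order_classes, 1)
    }
    infection_onset[i] <- onset

    # numeric channels
    t_acc <- list(); c_acc <- list(); v_acc <- list()
    r_v <- ramp(vt)
    ie_v <- inf_effect(vt, onset)
    nv <- length(vt)
    for (ch in vital_ch) {
      keep <- stats::runif(nv) >= miss[[ch]]
      if (!any(keep)) next
      base <- stats::rnorm(1, g_mean[[ch]], g_bsd[[ch]])
      shift <- g_dir[[ch]] * g_scale[[ch]] * eff[[ch]] *
        (0.25 * z[i] + r_v[keep] * amp[i])
      inf_shift <- if (ch %in% c("temperature", "heart_rate"))
        g_dir[[ch]] * g_scale[[ch]] * eff[[ch]] * 0.6 * ie_v[keep] else 0
      val <- base + shift + inf_shift + stats::rnorm(sum(keep), 0, g_noise[[ch]])
      val <- pmin(pmax(round(val, g_dig[[ch]]), lims$lo[[ch]]), lims$hi[[ch]])
      t_acc[[ch]] <- vt[keep]; c_acc[[ch]] <- rep(ch, sum(keep))
      v_acc[[ch]] <- val
    }
    # consciousness and supplemental O2: bernoulli state channels
    p_alt <- pmin(0.95, eff[["consciousness"]] *
                    (r_v * amp[i] * 0.5 + pmax(0, 0.02 * z[i])))
    keep <- stats::runif(nv) >= miss[["consciousness"]]
    if (any(keep)) {
      alt <- stats::runif(sum(keep)) < p_alt[keep]
      lev <- ifelse(alt, sample(1:3, sum(keep), replace = TRUE,
                                prob = c(0.6, 0.3, 0.1)), 0)
      t_acc[["consciousness"]] <- vt[keep]
      c_acc[["consciousness"]] <- rep("consciousness", sum(keep))
      v_acc[["consciousness"]] <- as.numeric(lev)
    }
    p_o2 <- pmin(0.95, eff[["supplemental_o2"]] * r_v * amp[i] * 0.5)
    keep <- stats::runif(nv) >= miss[["supplemental_o2"]]
    if (any(keep)) {
      t_acc[["supplemental_o2"]] <- vt[keep]
      c_acc[["supplemental_o2"]] <- rep("supplemental_o2", sum(keep))
      v_acc[["supplemental_o2"]] <-
        as.numeric(stats::runif(sum(keep)) < p_o2[keep])
    }
    # labs
    if (length(lt) > 0) {
      r_l <- ramp(lt)
      ie_l <- inf_effect(lt, onset)
      for (ch in lab_ch) {
        keep <- stats::runif(length(lt)) >= miss[[ch]]
        if (!any(keep)) next
        base <- stats::rnorm(1, g_mean[[ch]], g_bsd[[ch]])
        shift <- g_dir[[ch]] * g_scale[[ch]] * eff[[ch]] *
          (0.25 * z[i] + r_l[keep] * amp[i])
        inf_shift <- if (ch %in% c("wbc", "band_fraction"))
          g_dir[[ch]] * g_scale[[ch]] * eff[[ch]] * 0.7 * ie_l[keep] else 0
        val <- base + shift + inf_shift +
          stats::rnorm(sum(keep), 0, g_noise[[ch]])
        val <- pmin(pmax(round(val, g_dig[[ch]]), lims$lo[[ch]]), lims$hi[[ch]])
        t_acc[[ch]] <- lt[keep]; c_acc[[ch]] <- rep(ch, sum(keep))
        v_acc[[ch]] <- val
      }
    }
    obs_t[[i]] <- unlist(t_acc, use.names = FALSE)
    obs_c[[i]] <- unlist(c_acc, use.names = FALSE)
    obs_v[[i]] <- unlist(v_acc, use.names = FALSE)
  }

  n_obs <- lengths(obs_t)
  observations <- tibble::tibble(
    encounter_id = rep(eid, n_obs),
    time = .POSIXct(unlist(obs_t, use.names = FALSE), tz = "UTC"),
    channel = unlist(obs_c, use.names = FALSE),
    value = unlist(obs_v, use.names = FALSE))
  locations <- tibble::tibble(
    encounter_id = unlist(loc_e, use.names = FALSE),
    unit_class = unlist(loc_u, use.names = FALSE),
    start = .POSIXct(unlist(loc_s, use.names = FALSE), tz = "UTC"),
    end = .POSIXct(unlist(loc_x, use.names = FALSE), tz = "UTC"))
  orders <- tibble::tibble(
    encounter_id = unlist(ord_e, use.names = FALSE),
    time = .POSIXct(unlist(ord_t, use.names = FALSE), tz = "UTC"),
    order_class = unlist(ord_c, use.names = FALSE))
  encounters <- tibble::tibble(
    encounter_id = eid, patient_id = pid, age = age_v,
    admit_time = admit, discharge_time = .POSIXct(dis_v, tz = "UTC"),
    admitted_via_ed = via_v, death_time = .POSIXct(death_v, tz = "UTC"))

  cohort <- ews_cohort(encounters, observations, locations, orders)
  truth <- tibble::tibble(
    encounter_id = eid, patient_id = pid, hospital = hospital, severity = z,
    outcome = ifelse(clean, outcome, "none"),
    outcome_time = .POSIXct(truth_time, tz = "UTC"),
    infected = infected, ramp_amplitude = ifelse(clean, amp, NA_real_),
    planted_infection_onset = .POSIXct(infection_onset, tz = "UTC"),
    excluded_design = excluded_design)
  list(cohort = cohort, truth = truth)
}
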