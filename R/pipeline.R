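#' Simulate a cohort and write it to disk
#'
#' Thin wrapper over [generate_cohort()] + [write_events()]: writes the
#' long-format events file and the ground-truth table next to it.
#'
#' @param cfg A [generator_config()] (the seed lives in the config).
#' @param events_path Output events file (`.csv` or `.parquet`).
#' @param truth_path Output ground-truth CSV (default: alongside events).
#' @return Invisibly, the list from [generate_cohort()].
#' @export
ews_simulate <- function(cfg, events_path,
                         truth_path = sub("\\.(csv|parquet)$", "_truth.csv",
                                          events_path)) {
  gen <- generate_cohort(cfg)
  write_events(gen$cohort, events_path)
  readr::write_csv(gen$truth, truth_path, na = "", progress = FALSE)
  invisible(gen)
}

#' Run the full evaluation pipeline
#'
#' Cohort construction, infection flagging, event-driven scoring and the
#' discrimination / efficiency / workload analyses, with results written as
#' tidy CSV and JSON into `out_dir`. Stage-by-stage counts and a hash of the
#' configuration are recorded in `run_log.json` for auditability.
#'
#' @param input An events file path or an [ews_cohort()].
#' @param out_dir Output directory (created if missing).
#' @param windows Dyad windows ([dyad_windows()]).
#' @param thresholds Named list of operating thresholds per score.
#' @param lead_time_thresholds Named integer vector of thresholds for the
#'   first-crossing / lead-time analysis on combined-outcome encounters.
#' @param ci_method,seed Passed to [auc_ci()].
#' @param sensitivity Run the three sensitivity analyses.
#' @param write_plots Also write efficiency-curve and AUC-grid figures (PNG).
#' @return Invisibly, a list with every computed table (`included`,
#'   `intervals`, `labels`, `summary`, `evaluation`, `crossings`, `log`).
#' @export
ews_run <- function(input, out_dir,
                    windows = dyad_windows(),
                    thresholds = list(NEWS = c(6L, 8L), SIRS = 2L,
                                      qSOFA = 2L, MEWS = 4L, BTF = 1L),
                    lead_time_thresholds = c(NEWS = 6L, qSOFA = 2L, SIRS = 2L),
                    ci_method = "delong", seed = 1L,
                    sensitivity = TRUE, write_plots = FALSE) {
  cohort <- if (inherits(input, "ews_cohort")) input else read_events(input)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  violations <- validate_cohort(cohort)
  included <- include_encounters(cohort)
  intervals <- build_time_at_risk(cohort, included)
  labels <- flag_cohort(cohort, intervals, windows)
  summ <- cohort_summary(included, labels)
  defs <- lapply(score_names(), builtin_definition)
  ev <- evaluate_all(cohort, intervals, labels, defs = defs,
                     thresholds = thresholds, ci_method = ci_method,
                     seed = seed, sensitivity = sensitivity)
  crossings <- compute_crossings(cohort, intervals, labels,
                                 lead_time_thresholds)

  cfg_hash <- rlang::hash(list(windows = windows, thresholds = thresholds,
                               lead_time_thresholds = lead_time_thresholds,
                               ci_method = ci_method, seed = seed,
                               sensitivity = sensitivity))
  log <- list(
    package_version = as.character(utils::packageVersion("ewsbench")),
    r_version = R.version.string,
    config_hash = cfg_hash,
    n_encounters_read = nrow(cohort$encounters),
    n_validation_violations = nrow(violations),
    n_included = sum(included$included),
    n_excluded = sum(!included$included),
    excluded_by_reason = as.list(table(included$reason[!included$included])),
    n_suspected_infection = sum(labels$suspected_infection),
    n_deaths = sum(labels$died),
    n_icu_or_death = sum(labels$icu_or_death))

  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f), na = "",
                                       progress = FALSE)
  w(included, "included.csv")
  w(intervals, "intervals.csv")
  w(labels, "labels.csv")
  w(summ$flow, "cohort_flow.csv")
  w(summ$prevalence, "prevalence.csv")
  w(ev$max_scores, "max_scores.csv")
  w(ev$discrimination, "discrimination.csv")
  w(ev$curves, "efficiency_curves.csv")
  w(ev$operating_points, "operating_points.csv")
  if (!is.null(ev$workload)) w(ev$workload, "workload.csv")
  w(crossings$records, "crossings.csv")
  w(crossings$summary, "lead_times.csv")
  if (!is.null(ev$sensitivity))
    for (nm in names(ev$sensitivity))
      w(ev$sensitivity[[nm]], paste0("discrimination_", nm, ".csv"))
  jsonlite::write_json(
    list(prevalence = summ$prevalence, discrimination = ev$discrimination),
    file.path(out_dir, "results.json"), dataframe = "rows", na = "null",
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  if (isTRUE(write_plots)) {
    ggplot2::ggsave(file.path(out_dir, "efficiency_curves.png"),
                    plot_efficiency_curves(ev$curves), width = 7, height = 5,
                    dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "discrimination.png"),
                    plot_discrimination(ev$discrimination), width = 8,
                    height = 5, dpi = 150)
  }
  invisible(list(included = included, intervals = intervals, labels = labels,
                 summary = summ, evaluation = ev, crossings = crossings,
                 log = log))
}

#' First-crossing records and lead-time summary
#'
#' For encounters that experienced the combined outcome, computes when each
#' score first reached its alerting threshold and the elapsed hours from that
#' crossing to the outcome.
#'
#' @param cohort An [ews_cohort()].
#' @param intervals From [build_time_at_risk()].
#' @param labels From [flag_cohort()].
#' @param thresholds Named integer vector, e.g. `c(NEWS = 6, qSOFA = 2)`.
#' @return A list: `records` (one row per outcome encounter and score) and
#'   `summary` (median and IQR of lead time per score).
#' @export
compute_crossings <- function(cohort, intervals, labels,
                              thresholds = c(NEWS = 6L, qSOFA = 2L, SIRS = 2L)) {
  out_enc <- labels[labels$icu_or_death & !is.na(labels$outcome_time), ]
  iv <- intervals[intervals$encounter_id %in% out_enc$encounter_id, ]
  recs <- list()
  for (sc in names(thresholds)) {
    def <- builtin_definition(sc)
    for (i in seq_len(nrow(iv))) {
      eid <- iv$encounter_id[i]
      tr <- compute_trajectory(cohort, eid, iv[i, ], def)
      ot <- out_enc$outcome_time[out_enc$encounter_id == eid]
      recs[[length(recs) + 1]] <- first_crossing(tr, thresholds[[sc]], ot)
    }
  }
  records <- if (length(recs) > 0) dplyr::bind_rows(recs) else
    tibble::tibble(encounter_id = character(0), score = character(0),
                   threshold = integer(0),
                   first_crossing_time = as.POSIXct(character(0), tz = "UTC"),
                   lead_time_hours = numeric(0))
  summary <- records |>
    dplyr::filter(!is.na(.data$lead_time_hours)) |>
    dplyr::group_by(.data$score, .data$threshold) |>
    dplyr::summarise(
      n_crossed = dplyr::n(),
      median_lead_hours = stats::median(.data$lead_time_hours),
      q1_lead_hours = stats::quantile(.data$lead_time_hours, 0.25),
      q3_lead_hours = stats::quantile(.data$lead_time_hours, 0.75),
      .groups = "drop")
  list(records = records, summary = summary)
}
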