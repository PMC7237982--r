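#' Area under the ROC curve (probability of concordance)
#'
#' Computed as the tie-corrected concordance estimator
#' (number of positive/negative pairs where the positive scores higher, plus
#' half the tied pairs, over all pairs), via midranks.
#'
#' @param scores Numeric (typically integer maximum score values).
#' @param labels Logical outcome labels; at least one `TRUE` and one `FALSE`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0)
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

#' AUC with a 95% confidence interval
#'
#' `"delong"` (default) uses the closed-form variance of the concordance
#' estimator from the positive/negative structural components; `"bootstrap"`
#' uses a stratified percentile interval.
#'
#' @inheritParams auc
#' @param method `"delong"` or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resamples.
#' @return Tibble with `auc`, `ci_low`, `ci_high`, `method`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   level = 0.95, boot = 2000, seed = NULL) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  a <- auc(scores, labels)
  if (method == "delong") {
    x <- scores[labels]; y <- scores[!labels]
    m <- length(x); n <- length(y)
    r_all <- rank(c(x, y))
    v10 <- (r_all[seq_len(m)] - rank(x)) / n          # placement of positives
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m  # placement of negatives
    v <- stats::var(v10) / m + stats::var(v01) / n
    z <- stats::qnorm(1 - (1 - level) / 2)
    lo <- max(0, a - z * sqrt(v)); hi <- min(1, a + z * sqrt(v))
  } else {
    if (!is.null(seed)) set.seed(seed)
    ip <- which(labels); ineg <- which(!labels)
    reps <- vapply(seq_len(boot), function(b) {
      idx <- c(sample(ip, length(ip), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      auc(scores[idx], labels[idx])
    }, numeric(1))
    qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    lo <- min(qs[1], a); hi <- max(qs[2], a)
  }
  tibble::tibble(auc = a, ci_low = lo, ci_high = hi, method = method)
}

#' Screening efficiency curve
#'
#' One point per achievable integer threshold: the sensitivity of the rule
#' "maximum score >= threshold" against the fraction of the cohort that rule
#' flags for screening. Both coordinates are non-decreasing as the threshold
#' drops; the curve is a step function with no interpolation.
#'
#' @inheritParams auc
#' @return Tibble `threshold`, `sensitivity`, `fraction_screened`, ordered by
#'   descending threshold.
#' @export
efficiency_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || !any(!labels))
    stop("efficiency curve undefined: labels contain a single class",
         call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tibble::tibble(
    threshold = thr,
    sensitivity = vapply(thr, function(c) mean(scores[labels] >= c), numeric(1)),
    fraction_screened = vapply(thr, function(c) mean(scores >= c), numeric(1)))
}

#' Operating point at a fixed threshold
#'
#' @inheritParams auc
#' @param threshold Alerting threshold for the rule `score >= threshold`.
#' @param score_name Optional score name carried into the result.
#' @return One-row tibble: `score`, `threshold`, `sensitivity`,
#'   `specificity`, `fraction_screened`.
#' @export
operating_point <- function(scores, labels, threshold, score_name = NA_character_) {
  labels <- as.logical(labels)
  if (!any(labels) || !any(!labels))
    stop("operating point undefined: labels contain a single class",
         call. = FALSE)
  flag <- scores >= threshold
  tibble::tibble(
    score = score_name, threshold = as.integer(threshold),
    sensitivity = sum(flag & labels) / sum(labels),
    specificity = sum(!flag & !labels) / sum(!labels),
    fraction_screened = mean(flag))
}

#' Workload comparison of two operating points
#'
#' Contrasts operating point A against B on the same cohort and outcome:
#' positive `additional_events_detected` means A catches more outcome events;
#' positive `fewer_screened` means A flags fewer patients.
#'
#' @param point_a,point_b One-row tibbles from [operating_point()].
#' @param n Cohort size.
#' @param n_events Number of outcome events (positives) in the cohort.
#' @return One-row tibble with the deltas and absolute counts.
#' @export
workload_comparison <- function(point_a, point_b, n, n_events) {
  stopifnot(nrow(point_a) == 1, nrow(point_b) == 1, n > 0, n_events >= 0)
  d_sens <- point_a$sensitivity - point_b$sensitivity
  d_screen <- point_a$fraction_screened - point_b$fraction_screened
  tibble::tibble(
    score_a = point_a$score, threshold_a = point_a$threshold,
    score_b = point_b$score, threshold_b = point_b$threshold,
    delta_sensitivity = d_sens,
    delta_fraction_screened = d_screen,
    additional_events_detected = d_sens * n_events,
    fewer_screened = -d_screen * n)
}

subgroup_names <- c("all", "suspected_infection", "no_suspected_infection")

subgroup_mask <- function(labels, subgroup) {
  switch(subgroup,
         all = rep(TRUE, nrow(labels)),
         suspected_infection = labels$suspected_infection,
         no_suspected_infection = !labels$suspected_infection)
}

#' Discrimination grid: score x outcome x subgroup
#'
#' AUC and CI of each score's maximum value for each outcome (death; ICU
#' transfer or death) in the overall cohort and the subgroups with and
#' without suspected infection. Cells whose subgroup is empty or single-class
#' are returned with `NA` AUC and `available = FALSE` rather than erroring.
#'
#' @param max_wide Tibble with `encounter_id` and one column of maximum score
#'   values per scoring system (see [scores_wide()]).
#' @param labels From [assign_labels()] / [flag_cohort()].
#' @param ci_method,seed Passed to [auc_ci()].
#' @return Tibble: `score`, `outcome`, `subgroup`, `auc`, `ci_low`,
#'   `ci_high`, `n`, `n_events`, `available`.
#' @export
discrimination_grid <- function(max_wide, labels, ci_method = "delong",
                                seed = NULL) {
  dat <- dplyr::inner_join(max_wide, labels, by = "encounter_id")
  scores <- intersect(score_names(), names(max_wide))
  missing <- setdiff(scores, names(dat))
  if (length(missing) > 0)
    stop("score column(s) lost in join (duplicated in labels?): ",
         paste(missing, collapse = ", "), call. = FALSE)
  grid <- expand.grid(score = scores, outcome = c("died", "icu_or_death"),
                      subgroup = subgroup_names, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    mask <- subgroup_mask(dat, g$subgroup)
    s <- dat[[g$score]][mask]
    y <- dat[[g$outcome]][mask]
    base <- tibble::tibble(score = g$score, outcome = g$outcome,
                           subgroup = g$subgroup, n = length(y),
                           n_events = sum(y))
    if (length(y) == 0 || !any(y) || all(y))
      return(dplyr::mutate(base, auc = NA_real_, ci_low = NA_real_,
                           ci_high = NA_real_, available = FALSE))
    ci <- auc_ci(s, y, method = ci_method, seed = seed)
    dplyr::mutate(base, auc = ci$auc, ci_low = ci$ci_low,
                  ci_high = ci$ci_high, available = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Pivot per-encounter maximum scores to wide form
#'
#' @param max_tbl Output of [max_scores()].
#' @return Tibble with `encounter_id` and one column per score.
#' @export
scores_wide <- function(max_tbl) {
  tidyr::pivot_wider(max_tbl[, c("encounter_id", "score", "max_value")],
                     names_from = "score", values_from = "max_value")
}

#' Full evaluation: discrimination, curves, operating points, sensitivity
#' analyses
#'
#' Runs the complete analysis grid on a scored, labeled cohort: the 5 x 2 x 3
#' discrimination grid, mortality efficiency curves per score, operating
#' points at the conventional thresholds (SIRS >= 2, qSOFA >= 2, NEWS >= 6,
#' NEWS >= 8), the workload comparisons of NEWS >= 6 vs SIRS >= 2 and
#' NEWS >= 8 vs qSOFA >= 2, and (optionally) the three sensitivity analyses:
#' complete-case (only encounters in which every channel of the score was
#' observed), final-hour censoring, and one hospitalization per patient.
#'
#' @param cohort An [ews_cohort()].
#' @param intervals From [build_time_at_risk()].
#' @param labels From [flag_cohort()].
#' @param defs Score definitions (default all five built-ins).
#' @param thresholds Named list of operating thresholds.
#' @param ci_method,seed Passed to [auc_ci()].
#' @param sensitivity Logical: run the three sensitivity analyses.
#' @return A list: `max_scores`, `discrimination`, `curves`,
#'   `operating_points`, `workload`, `auc_ranks`, and `sensitivity` (a list
#'   of discrimination grids, when requested).
#' @export
evaluate_all <- function(cohort, intervals, labels,
                         defs = lapply(score_names(), builtin_definition),
                         thresholds = list(NEWS = c(6L, 8L), SIRS = 2L,
                                           qSOFA = 2L, MEWS = 4L, BTF = 1L),
                         ci_method = "delong", seed = NULL,
                         sensitivity = TRUE) {
  max_tbl <- max_scores(cohort, intervals, defs)
  wide <- scores_wide(max_tbl)
  grid <- discrimination_grid(wide, labels, ci_method, seed)
  dat <- dplyr::inner_join(wide, labels, by = "encounter_id")

  curves <- dplyr::bind_rows(lapply(intersect(score_names(), names(wide)),
    function(sc) {
      dplyr::bind_rows(lapply(c("died", "icu_or_death"), function(oc) {
        if (!any(dat[[oc]]) || all(dat[[oc]])) return(NULL)
        dplyr::mutate(efficiency_curve(dat[[sc]], dat[[oc]]),
                      score = sc, outcome = oc, .before = 1)
      }))
    }))

  ops <- dplyr::bind_rows(lapply(names(thresholds), function(sc) {
    if (!sc %in% names(dat)) return(NULL)
    dplyr::bind_rows(lapply(thresholds[[sc]], function(th) {
      dplyr::bind_rows(lapply(c("died", "icu_or_death"), function(oc) {
        if (!any(dat[[oc]]) || all(dat[[oc]])) return(NULL)
        dplyr::mutate(operating_point(dat[[sc]], dat[[oc]], th, sc),
                      outcome = oc)
      }))
    }))
  }))

  workload <- NULL
  pick <- function(sc, th, oc) {
    r <- ops[ops$score == sc & ops$threshold == th & ops$outcome == oc, ]
    if (nrow(r) == 1) r else NULL
  }
  n <- nrow(dat); n_deaths <- sum(dat$died)
  a <- pick("NEWS", 6L, "died"); b <- pick("SIRS", 2L, "died")
  c_ <- pick("NEWS", 8L, "died"); d <- pick("qSOFA", 2L, "died")
  wl <- list()
  if (!is.null(a) && !is.null(b))
    wl$high_sensitivity <- workload_comparison(a, b, n, n_deaths)
  if (!is.null(c_) && !is.null(d))
    wl$high_specificity <- workload_comparison(c_, d, n, n_deaths)
  if (length(wl) > 0) workload <- dplyr::bind_rows(wl, .id = "comparison")

  ranks <- grid |>
    dplyr::filter(.data$available) |>
    dplyr::group_by(.data$outcome, .data$subgroup) |>
    dplyr::mutate(auc_rank = rank(-.data$auc, ties.method = "min")) |>
    dplyr::ungroup() |>
    dplyr::select("score", "outcome", "subgroup", "auc", "auc_rank")

  sens_res <- NULL
  if (isTRUE(sensitivity)) {
    sens_res <- list()
    # (1) complete-case per score: every channel observed within the interval
    obs_in <- dplyr::inner_join(cohort$observations, intervals,
                                by = "encounter_id")
    obs_in <- obs_in[obs_in$time >= obs_in$start & obs_in$time <= obs_in$end, ]
    cc_grid <- dplyr::bind_rows(lapply(defs, function(def) {
      seen <- obs_in[obs_in$channel %in% def$channels, ] |>
        dplyr::distinct(.data$encounter_id, .data$channel) |>
        dplyr::count(.data$encounter_id)
      ids <- seen$encounter_id[seen$n == length(def$channels)]
      sub <- dat[dat$encounter_id %in% ids, ]
      discrimination_grid(sub[, c("encounter_id", def$name)],
                          sub[, setdiff(names(sub), score_names())],
                          ci_method, seed)
    }))
    sens_res$complete_case <- cc_grid
    # (2) final-hour censoring
    ot <- stats::setNames(labels$outcome_time, labels$encounter_id)
    max_c <- max_scores(cohort, intervals, defs, censor_outcome_times = ot)
    sens_res$censor_final_hour <-
      discrimination_grid(scores_wide(max_c), labels, ci_method, seed)
    # (3) one hospitalization per patient
    lab1 <- dedupe_patients(labels)
    sens_res$single_encounter <-
      discrimination_grid(wide[wide$encounter_id %in% lab1$encounter_id, ],
                          lab1, ci_method, seed)
  }

  list(max_scores = max_tbl, discrimination = grid, curves = curves,
       operating_points = ops, workload = workload, auc_ranks = ranks,
       sensitivity = sens_res)
}
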