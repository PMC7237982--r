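test_that("AUC equals the all-pairs concordance oracle", {
  expect_equal(auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  expect_equal(auc(rep(2, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(auc(1:3, c(TRUE, TRUE, TRUE)), "single class")
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    s <- sample(0:8, n, replace = TRUE)
    y <- runif(n) < 0.4
    if (!any(y) || all(y)) next
    expect_equal(auc(s, y), oracle_auc(s, y))
  }
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  s <- sample(0:12, 400, replace = TRUE) + round(3 * (runif(400) < 0.3))
  y <- runif(400) < plogis(-2 + 0.3 * s)
  ours <- auc_ci(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci_low, ref_ci[1], tolerance = 1e-6)
  expect_equal(ours$ci_high, ref_ci[3], tolerance = 1e-6)
})

test_that("DeLong and bootstrap intervals agree on a moderate sample", {
  set.seed(31)
  s <- sample(0:10, 500, replace = TRUE) + round(2 * (runif(500) < 0.3))
  y <- runif(500) < plogis(-2.5 + 0.35 * s)
  d <- auc_ci(s, y, method = "delong")
  b <- auc_ci(s, y, method = "bootstrap", seed = 5)
  expect_lt(abs(d$ci_low - b$ci_low), 0.02)
  expect_lt(abs(d$ci_high - b$ci_high), 0.02)
  expect_true(b$ci_low <= b$auc && b$auc <= b$ci_high)
})

test_that("efficiency curve matches hand enumeration and is doubly monotone", {
  ec <- efficiency_curve(c(0, 1, 2), c(FALSE, FALSE, TRUE))
  expect_equal(ec$threshold, c(2, 1, 0))
  expect_equal(ec$sensitivity, c(1, 1, 1))
  expect_equal(ec$fraction_screened, c(1 / 3, 2 / 3, 1))

  ec2 <- efficiency_curve(rep(3, 4), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(nrow(ec2), 1L)
  expect_equal(ec2$sensitivity, 1)
  expect_equal(ec2$fraction_screened, 1)

  set.seed(41)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    s <- sample(0:15, n, replace = TRUE)
    y <- runif(n) < 0.3
    if (!any(y) || all(y)) next
    ec <- efficiency_curve(s, y)
    expect_true(all(diff(ec$sensitivity) >= 0))
    expect_true(all(diff(ec$fraction_screened) >= 0))
    expect_equal(ec$fraction_screened[nrow(ec)], 1)
    # operating points lie on the curve
    for (th in ec$threshold) {
      op <- operating_point(s, y, th)
      row <- ec[ec$threshold == th, ]
      expect_equal(op$sensitivity, row$sensitivity)
      expect_equal(op$fraction_screened, row$fraction_screened)
    }
  }
})

test_that("operating points reproduce a printed 2x2 table", {
  # TP=87, FN=13 among positives; FP=263, TN=637 among negatives
  s <- c(rep(1, 87), rep(0, 13), rep(1, 263), rep(0, 637))
  y <- c(rep(TRUE, 100), rep(FALSE, 900))
  op <- operating_point(s, y, 1)
  expect_equal(op$sensitivity, 0.87)
  expect_equal(op$fraction_screened, 0.35)
  expect_equal(op$specificity, 637 / 900)
  expect_equal(operating_point(s, y, 5)$sensitivity, 0)
  expect_equal(operating_point(s, y, 0)$fraction_screened, 1)
})

test_that("workload comparisons report deltas and absolute counts", {
  a <- operating_point(c(1, 1, 0, 0), c(TRUE, FALSE, TRUE, FALSE), 1, "A")
  expect_equal(workload_comparison(a, a, 100, 10)$additional_events_detected, 0)
  b <- a; b$sensitivity <- 0.63; a$sensitivity <- 0.74
  wc <- workload_comparison(a, b, 5000, 1000)
  expect_equal(wc$additional_events_detected, 110)
  b$fraction_screened <- 0.50; a$fraction_screened <- 0.36
  expect_equal(workload_comparison(a, b, 5000, 1000)$fewer_screened, 700)
})

test_that("the discrimination grid covers 5 scores x 2 outcomes x 3 subgroups", {
  g <- generate_cohort(generator_config(n_encounters = 600, seed = 3))
  iv <- build_time_at_risk(g$cohort)
  lab <- flag_cohort(g$cohort, iv)
  res <- evaluate_all(g$cohort, iv, lab, sensitivity = FALSE)
  expect_equal(nrow(res$discrimination), 30L)
  expect_true(all(res$discrimination$ci_low <= res$discrimination$auc,
                  na.rm = TRUE))
  expect_true(all(res$discrimination$auc <= res$discrimination$ci_high,
                  na.rm = TRUE))
  # empty or single-class subgroups are marked unavailable, not errors
  lab0 <- lab; lab0$suspected_infection <- FALSE
  lab0$died <- FALSE; lab0$icu_or_death <- FALSE
  grid0 <- discrimination_grid(scores_wide(res$max_scores), lab0)
  expect_true(all(!grid0$available))
  expect_true(all(is.na(grid0$auc)))
})

test_that("sensitivity analyses run and keep the grid shape", {
  g <- generate_cohort(generator_config(n_encounters = 500, seed = 13))
  iv <- build_time_at_risk(g$cohort)
  lab <- flag_cohort(g$cohort, iv)
  res <- evaluate_all(g$cohort, iv, lab, sensitivity = TRUE)
  expect_named(res$sensitivity,
               c("complete_case", "censor_final_hour", "single_encounter"))
  expect_equal(nrow(res$sensitivity$censor_final_hour), 30L)
  # censoring the final hour can only reduce each encounter's maximum
  ot <- setNames(lab$outcome_time, lab$encounter_id)
  m0 <- max_scores(g$cohort, iv, list(builtin_definition("NEWS")))
  m1 <- max_scores(g$cohort, iv, list(builtin_definition("NEWS")),
                   censor_outcome_times = ot)
  expect_true(all(m1$max_value <= m0$max_value))
  # dedup keeps at most one row per patient
  dd <- res$sensitivity$single_encounter
  expect_true(all(dd$n <= nrow(dedupe_patients(lab))))
})

test_that("sensitivity analyses preserve the mortality AUC rank ordering", {
  seeds <- 1:6
  grids <- list(main = list(), complete_case = list(),
                censor_final_hour = list(), single_encounter = list())
  for (s in seeds) {
    g <- generate_cohort(generator_config(n_encounters = 1200, seed = s))
    iv <- build_time_at_risk(g$cohort)
    lab <- flag_cohort(g$cohort, iv)
    res <- evaluate_all(g$cohort, iv, lab, sensitivity = TRUE)
    grids$main[[s]] <- res$discrimination
    for (nm in names(res$sensitivity))
      grids[[nm]][[s]] <- res$sensitivity[[nm]]
  }
  rank_of <- function(lst) {
    all_g <- dplyr::bind_rows(lst)
    d <- all_g[all_g$outcome == "died" & all_g$subgroup == "all" &
                 !is.na(all_g$auc), ]
    m <- stats::aggregate(auc ~ score, d, mean)
    m$score[order(-m$auc)]
  }
  main_order <- rank_of(grids$main)
  expect_equal(main_order[1], "NEWS")
  # a variant may lose scores entirely (complete-case SIRS is near-empty
  # under 87-90% lab missingness); the ordering of what remains must agree
  for (nm in c("complete_case", "censor_final_hour", "single_encounter")) {
    ord <- rank_of(grids[[nm]])
    expect_equal(ord, intersect(main_order, ord), label = nm)
  }
})
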