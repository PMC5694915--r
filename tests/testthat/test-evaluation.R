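test_that("AUROC follows the Mann-Whitney definition with half-credit ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.2), c(1, 1, -1)), 1.0)
  expect_equal(auroc(rep(0.5, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  expect_equal(auroc(c(0.8, 0.6, 0.4, 0.2), c(1, -1, 1, -1)), 0.75)
  expect_error(auroc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUROC agrees with the all-pairs oracle and pROC on random instances", {
  set.seed(13)
  for (case in 1:10) {
    n <- sample(20:200, 1)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    s <- round(runif(n), 2)               # rounding forces ties
    expect_equal(auroc(s, y), oracle_auroc(s, y), info = paste("case", case))
  }
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- c(1, -1, sample(c(-1, 1), 98, replace = TRUE))
  s <- round(runif(100), 2)
  expect_equal(auroc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("the break-even threshold equalizes sensitivity and precision", {
  be <- breakeven_threshold(c(0.9, 0.7, 0.3, 0.1), c(1, 1, -1, -1))
  expect_equal(be$threshold, 0.7)
  expect_equal(be$sensitivity, 1)
  expect_equal(be$precision, 1)
  expect_false(be$degenerate)

  anti <- breakeven_threshold(c(0.1, 0.2, 0.8, 0.9), c(1, 1, -1, -1))
  expect_true(anti$degenerate)

  set.seed(21)
  s <- runif(2000)
  y <- rep(c(1, -1), 1000)
  be2 <- breakeven_threshold(s, y)
  expect_lt(abs(be2$sensitivity - be2$precision), 0.05)
  expect_lt(abs(be2$sensitivity - 0.5), 0.1)

  expect_error(breakeven_threshold(c(0.1, 0.2), c(-1, -1)), "both classes")
})

test_that("no other cutpoint beats the break-even gap (exhaustive check)", {
  set.seed(8)
  for (case in 1:12) {
    n <- sample(6:30, 1)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    s <- round(runif(n), 1)
    be <- breakeven_threshold(s, y)
    for (cut in sort(unique(s))) {
      pred <- s >= cut
      sens <- sum(pred & y == 1) / sum(y == 1)
      prec <- if (sum(pred)) sum(pred & y == 1) / sum(pred) else NA
      if (!is.na(prec))
        expect_gte(abs(sens - prec) + 1e-12, be$gap)
    }
  }
})

test_that("prevalence adjustment reproduces the Bayes formulas", {
  pv <- adjust_predictive_values(0.66, 0.78, 0.42)
  expect_equal(round(pv$ppv, 2), 0.68)
  expect_equal(round(pv$npv, 2), 0.76)
  expect_equal(adjust_predictive_values(1, 1, 0.3), list(ppv = 1, npv = 1))
  expect_equal(round(adjust_predictive_values(0.76, 0.70, 0.24)$npv, 2), 0.90)
  # degenerate: a never-positive test at zero prevalence has undefined PPV
  expect_true(is.nan(adjust_predictive_values(0, 1, 0)$ppv))
})

test_that("adjustment at the sample prevalence equals the raw confusion matrix", {
  set.seed(31)
  s <- runif(300)
  y <- ifelse(runif(300) < plogis(4 * s - 2), 1, -1)
  thr <- 0.6
  pred <- s >= thr
  sens <- sum(pred & y == 1) / sum(y == 1)
  spec <- sum(!pred & y == -1) / sum(y == -1)
  pv <- adjust_predictive_values(sens, spec, mean(y == 1))
  expect_equal(pv$ppv, sum(pred & y == 1) / sum(pred))
  expect_equal(pv$npv, sum(!pred & y == -1) / sum(!pred))
  rep_row <- metrics_report(s, y, threshold = thr)
  expect_equal(rep_row$ppv, pv$ppv)
  expect_equal(rep_row$npv, pv$npv)
  expect_equal(rep_row$positive_lr, sens / (1 - spec))
})

test_that("summary statistics use the sample (n-1) standard deviation", {
  st <- summary_stats(c(0.82, 0.77, 0.82, 0.74, 0.75))
  expect_equal(round(st$mean, 2), 0.78)
  expect_equal(round(st$sd, 2), 0.04)
  expect_equal(st$min, 0.74)
  expect_equal(st$max, 0.82)
  expect_equal(summary_stats(rep(1, 3))$sd, 0)
  two <- summary_stats(c(0, 1))
  expect_equal(two$mean, 0.5)
  expect_equal(two$sd, sqrt(0.5), tolerance = 1e-12)
  expect_true(is.na(summary_stats(5)$sd))
})

test_that("reports are invariant to example order", {
  set.seed(41)
  s <- runif(120)
  y <- c(1, -1, sample(c(-1, 1), 118, replace = TRUE))
  a <- metrics_report(s, y)
  o <- sample(120)
  b <- metrics_report(s[o], y[o])
  expect_equal(a, b)
})

test_that("AUROC declines with lead time on a deteriorating cohort and is flat on a null one", {
  co <- simulate_cohort(sim_config(n_patients = 400, seed = 23))
  ex <- label_cohort(co$encounters, co$chart, co$interventions,
                     control_seed = 1, lead_times = c(1, 12))
  train_rows <- ex[is.na(ex$lead_time) | ex$lead_time == 0, ]
  sp <- split_dataset(train_rows, 0.9, seed = 1)
  fit <- hii_boost(sp$train, n_rounds = 40)
  test_all <- ex[ex$patient_id %in% sp$test$patient_id, ]
  lc <- leadtime_curve(fit, test_all, lead_times = c(1, 12))
  expect_equal(lc$lead_time, c(1, 12))
  expect_gt(lc$auroc[1], lc$auroc[2])

  single <- leadtime_curve(fit, test_all, lead_times = 1)
  expect_equal(nrow(single), 1)
  expect_warning(leadtime_curve(fit, test_all, lead_times = 7), "empty")
})

test_that("stratified reports cover the five age groups and masked feature subsets", {
  co <- simulate_cohort(sim_config(n_patients = 400, seed = 25))
  ex <- label_cohort(co$encounters, co$chart, co$interventions, control_seed = 1)
  fit <- hii_boost(ex, n_rounds = 40)
  ages <- stratified_report(fit, ex, strata = "age_group")
  expect_equal(nrow(ages), 5)
  st <- summary_stats(ages$auroc)
  expect_true(st$min <= st$mean && st$mean <= st$max)

  vitals <- feature_catalogue()$feature[feature_catalogue()$panel %in%
                                          c("vitals", "invasive_vitals")]
  subs <- stratified_report(fit, ex,
                            strata = list(vitals_only = vitals,
                                          all_features = c(
                                            catalogue_features(),
                                            composite_features())))
  expect_equal(subs$stratum, c("vitals_only", "all_features"))
  expect_gte(subs$auroc[2], subs$auroc[1] - 0.02)

  vent <- stratified_report(fit, ex, strata = "ventilated",
                            encounters = co$encounters)
  expect_equal(vent$stratum, c("ventilated", "not_ventilated"))

  first <- stratified_report(fit, ex, strata = "first_intervention",
                             interventions = co$interventions)
  expect_setequal(first$stratum, c("first_fluid_bolus", "first_vasoactive"))

  no_vaso <- co$interventions[co$interventions$kind == "fluid_bolus", ]
  expect_warning(stratified_report(fit, ex, strata = "first_intervention",
                                   interventions = no_vaso),
                 "skipped")
  expect_error(stratified_report(fit, ex, strata = "bogus"), "unknown stratum")
})

test_that("single-feature baselines detect constructed signal and nothing else", {
  co <- simulate_cohort(sim_config(n_patients = 400, seed = 27))
  ex <- label_cohort(co$encounters, co$chart, co$interventions, control_seed = 1)
  sp <- split_dataset(ex, 0.9, seed = 1)
  bl <- baseline_models(sp$train, n_rounds = 40)
  si_auc <- suppressWarnings(
    auroc(suppressWarnings(predict(bl$si, sp$test)), sp$test$label))
  expect_gt(si_auc, 0.5)

  # when only heart rate carries signal, an SBP-only model is at chance;
  # tested on an independent cohort from the same generator for resolution
  hr_only <- c(heart_rate = 2)
  co0 <- simulate_cohort(sim_config(n_patients = 400, seed = 29,
                                    effect_sizes = hr_only))
  ex0 <- label_cohort(co0$encounters, co0$chart, co0$interventions,
                      control_seed = 1)
  co1 <- simulate_cohort(sim_config(n_patients = 400, seed = 30,
                                    effect_sizes = hr_only))
  ex1 <- label_cohort(co1$encounters, co1$chart, co1$interventions,
                      control_seed = 2)
  bl0 <- baseline_models(ex0, n_rounds = 40)
  sbp_auc <- suppressWarnings(
    auroc(suppressWarnings(predict(bl0$sbp, ex1)), ex1$label))
  expect_lt(abs(sbp_auc - 0.5), 0.1)
})
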