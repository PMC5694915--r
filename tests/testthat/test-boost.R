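single_bin <- c(1 / 12, 20)

test_that("candidate thresholds sit at value midpoints, capped by the quantile grid", {
  d <- mk_train(list(glucose = c(1, 2, 3)), label = c(1, -1, 1))
  cand <- stump_candidates(d, "glucose", age_bins = single_bin)
  expect_equal(cand$thresholds[[1]], c(1.5, 2.5))

  big <- mk_train(list(glucose = seq_len(10000)), label = rep(c(1, -1), 5000))
  cand64 <- stump_candidates(big, "glucose", age_bins = single_bin,
                             max_thresholds = 64)
  expect_length(cand64$thresholds[[1]], 64)

  missing <- mk_train(list(glucose = rep(NA_real_, 4)),
                      label = c(1, 1, -1, -1))
  none <- stump_candidates(missing, "glucose", age_bins = single_bin)
  expect_length(none$thresholds[[1]], 0)
})

test_that("bins without data inherit the nearest populated bin's candidates", {
  d <- mk_train(list(heart_rate = c(100, 140, 90, 130)),
                label = c(-1, 1, -1, 1),
                age = c(0.5, 0.5, 0.6, 0.7))   # all in the infant bin
  cand <- stump_candidates(d, "heart_rate")     # five default bins
  expect_gt(length(cand$thresholds[[1]]), 0)
  for (b in 2:5) expect_equal(cand$thresholds[[b]], cand$thresholds[[1]])
})

test_that("stump scoring decomposes weight into W+, W-, W0 with Z = W0 + 2*sqrt(W+W-)", {
  st <- mk_one_stump_model(threshold = 100)$stumps[[1]]
  d_perfect <- mk_train(list(heart_rate = c(120, 130, 80, 90)),
                        label = c(1, 1, -1, -1))
  sc <- score_stump(st, d_perfect, d_perfect$label)
  expect_equal(sc$W_plus, 1)
  expect_equal(sc$W_minus, 0)
  expect_equal(sc$W_zero, 0)
  expect_equal(sc$Z, 0)

  d_absent <- mk_train(list(heart_rate = rep(NA_real_, 4)),
                       label = c(1, 1, -1, -1))
  sc0 <- score_stump(st, d_absent, d_absent$label)
  expect_equal(sc0$W_zero, 1)
  expect_equal(sc0$Z, 1)

  # right on 2, wrong on 1, abstains on 1, uniform weights
  d_mix <- mk_train(list(heart_rate = c(120, 130, 120, NA)),
                    label = c(1, 1, -1, -1))
  scm <- score_stump(st, d_mix, d_mix$label)
  expect_equal(scm$W_plus, 0.5)
  expect_equal(scm$W_minus, 0.25)
  expect_equal(scm$W_zero, 0.25)
  expect_equal(scm$Z, 0.25 + 2 * sqrt(0.125))
  expect_equal(scm$W_plus + scm$W_minus + scm$W_zero, 1)
})

test_that("separable one-feature data trains to zero error within a few rounds", {
  d <- mk_train(list(lactic_acid = c(30, 40, 35, 10, 12, 8)),
                label = c(1, 1, 1, -1, -1, -1))
  fit <- hii_boost(d, n_rounds = 5, age_bins = single_bin,
                   features = "lactic_acid")
  expect_lte(fit$n_rounds, 5)
  expect_equal(utils::tail(fit$diagnostics$train_error, 1), 0)
  expect_equal(fit$stumps[[1]]$direction[1], "high_is_unstable")
})

test_that("an informative half-missing feature beats complete noise, and abstained weights pass through round 1 unscaled", {
  set.seed(42)
  n <- 40
  y <- rep(c(1, -1), n / 2)
  informative <- ifelse(y == 1, 8, 2) + rnorm(n, 0, 0.3)
  informative[seq(1, n, by = 2)[1:10]] <- NA       # half of one class missing
  informative[seq(2, n, by = 2)[1:10]] <- NA
  noise <- rnorm(n)
  d <- mk_train(list(lactic_acid = informative, glucose = noise), label = y)
  fit <- hii_boost(d, n_rounds = 1, age_bins = single_bin)
  st <- fit$stumps[[1]]
  expect_equal(st$feature, "lactic_acid")
  # reweighting: h(x) = 0 on missing rows, so their weights pick up a factor
  # of exactly 1 and stay mutually equal after renormalization
  v_present <- if (st$direction[1] == "high_is_unstable")
    ifelse(informative > st$threshold[1], 1, -1)
  else ifelse(informative < st$threshold[1], 1, -1)
  v <- ifelse(is.na(informative), 0, v_present)
  w1 <- exp(-st$alpha * y * v) / sum(exp(-st$alpha * y * v))
  w1_abstained <- w1[is.na(informative)]
  expect_equal(max(w1_abstained), min(w1_abstained))
  expect_equal(sum(w1), 1)
})

test_that("training aborts when no feature is informative", {
  d <- mk_train(list(glucose = rep(100, 6)), label = c(1, 1, 1, -1, -1, -1))
  expect_error(hii_boost(d, age_bins = single_bin, features = "glucose"),
               "no informative feature")
})

test_that("the trainer matches the exhaustive brute-force oracle on tiny instances", {
  set.seed(7)
  for (case in 1:20) {
    n <- sample(4:8, 1)
    y <- c(1, -1, sample(c(-1, 1), n - 2, replace = TRUE))
    X <- cbind(glucose = sample(1:6, n, replace = TRUE) + 0L,
               lactic_acid = sample(1:6, n, replace = TRUE) + 0L)
    X <- X * 1.0
    if (case %% 2 == 0) X[sample(n, 2), "lactic_acid"] <- NA
    d <- mk_train(list(glucose = X[, 1], lactic_acid = X[, 2]), label = y)
    ora <- oracle_train(X, d$age, y, n_rounds = 3, edges = single_bin)
    fit <- tryCatch(
      hii_boost(d, n_rounds = 3, age_bins = single_bin,
                features = c("glucose", "lactic_acid")),
      error = function(e) NULL)
    if (is.null(fit)) {
      expect_length(ora, 0)
      next
    }
    expect_equal(length(fit$stumps), length(ora), info = paste("case", case))
    for (t in seq_along(ora)) {
      expect_equal(fit$stumps[[t]]$feature, ora[[t]]$feature,
                   info = paste("case", case, "round", t))
      expect_equal(fit$stumps[[t]]$threshold, ora[[t]]$threshold,
                   info = paste("case", case, "round", t))
      expect_equal(fit$stumps[[t]]$direction, ora[[t]]$direction,
                   info = paste("case", case, "round", t))
      expect_equal(fit$stumps[[t]]$alpha, ora[[t]]$alpha, tolerance = 1e-10,
                   info = paste("case", case, "round", t))
    }
  }
})

test_that("the trainer matches the oracle with two age bins", {
  set.seed(11)
  edges <- c(1 / 12, 6, 20)
  for (case in 1:8) {
    n <- 8
    y <- rep(c(1, -1), 4)
    age <- sample(c(2, 10), n, replace = TRUE)
    x <- sample(1:4, n, replace = TRUE) * 1.0
    d <- mk_train(list(heart_rate = x), label = y, age = age)
    ora <- oracle_train(cbind(heart_rate = x), age, y, n_rounds = 2,
                        edges = edges)
    fit <- tryCatch(hii_boost(d, n_rounds = 2, age_bins = edges,
                              features = "heart_rate"),
                    error = function(e) NULL)
    if (is.null(fit)) { expect_length(ora, 0); next }
    expect_equal(length(fit$stumps), length(ora))
    for (t in seq_along(ora)) {
      expect_equal(fit$stumps[[t]]$threshold, ora[[t]]$threshold,
                   info = paste("case", case))
      expect_equal(fit$stumps[[t]]$direction, ora[[t]]$direction,
                   info = paste("case", case))
      expect_equal(fit$stumps[[t]]$alpha, ora[[t]]$alpha, tolerance = 1e-10)
    }
  }
})

test_that("margins are additive in alpha and abstention contributes exactly zero", {
  m <- mk_one_stump_model(threshold = 100, alpha = 0.5)
  d <- mk_train(list(heart_rate = c(120, 80, NA)), label = c(1, -1, 1))
  expect_warning(mg <- predict(m, d, type = "margin"), "insufficient inputs")
  expect_equal(mg[1:2], c(0.5, -0.5))
  expect_true(is.na(mg[3]))

  # locality: removing measurements of an unused feature leaves margins alone
  d2 <- d[1:2, ]
  d2$glucose <- c(500, 400)
  expect_equal(predict(m, d2, type = "margin"), mg[1:2])

  no_age <- d[1:2, ]
  no_age$age <- NA
  expect_error(predict(m, no_age), "age")
})

test_that("the probability map is symmetric, monotone and bounded", {
  m <- mk_one_stump_model(alpha = 0)          # margin always 0
  d <- mk_train(list(heart_rate = c(120, 80)), label = c(1, -1))
  expect_equal(predict(m, d), c(0.5, 0.5))

  set.seed(1)
  alphas <- sort(runif(9, 0.1, 5))
  probs <- vapply(alphas, function(a) {
    mm <- mk_one_stump_model(alpha = a)
    predict(mm, mk_train(list(heart_rate = 120), label = 1))
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs > 0.5 & probs < 1))
})

test_that("selected features are ranked by summed vote weight, invariant to stump order", {
  co <- simulate_cohort(sim_config(n_patients = 150, seed = 21))
  ex <- label_cohort(co$encounters, co$chart, co$interventions, control_seed = 1)
  fit <- hii_boost(ex, n_rounds = 12)
  sf <- selected_features(fit)
  expect_equal(nrow(sf),
               length(unique(vapply(fit$stumps, `[[`, character(1), "feature"))))
  expect_true(all(diff(sf$alpha_total) <= 0))
  shuffled <- fit
  shuffled$stumps <- rev(fit$stumps)
  sf2 <- selected_features(shuffled)
  expect_equal(sf, sf2)
})

test_that("noise features stay unselected on separable toy data", {
  set.seed(5)
  n <- 60
  y <- rep(c(1, -1), n / 2)
  d <- mk_train(list(lactic_acid = ifelse(y == 1, 30, 10) + rnorm(n),
                     glucose = rnorm(n, 100, 10)), label = y)
  fit <- hii_boost(d, n_rounds = 8, age_bins = single_bin)
  expect_false("glucose" %in% selected_features(fit)$feature)
})

test_that("cross-validation folds are patient-level, stratified and seeded", {
  co <- simulate_cohort(sim_config(n_patients = 100, seed = 17))
  ex <- label_cohort(co$encounters, co$chart, co$interventions, control_seed = 1)
  cv <- cross_validate(ex, k = 10, seed = 4, n_rounds = 3)
  expect_length(cv$models, 10)
  expect_equal(nrow(cv$oof), nrow(ex))
  pos_per_fold <- table(cv$fold[ex$label == "unstable"])
  expect_lte(max(pos_per_fold) - min(pos_per_fold), 1)
  cv2 <- cross_validate(ex, k = 10, seed = 4, n_rounds = 3)
  expect_identical(cv$fold, cv2$fold)

  tiny <- mk_train(list(lactic_acid = c(30, 28, 9, 11)),
                   label = c(1, 1, -1, -1))
  tiny$patient_id <- paste0("P", 1:4)
  cv3 <- cross_validate(tiny, k = 2, seed = 1, n_rounds = 1,
                        age_bins = single_bin)
  expect_equal(as.integer(table(cv3$fold[tiny$label == 1])), c(1L, 1L))
  expect_error(cross_validate(tiny, k = 3, seed = 1), "class")
})

test_that("models serialize to structured text and round-trip bit-exactly", {
  co <- simulate_cohort(sim_config(n_patients = 80, seed = 19))
  ex <- label_cohort(co$encounters, co$chart, co$interventions, control_seed = 1)
  fit <- hii_boost(ex, n_rounds = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_hii_model(fit, path)
  back <- read_hii_model(path)
  expect_identical(back$stumps, fit$stumps)
  expect_identical(back$age_bins, fit$age_bins)
  expect_identical(back$operating_threshold, fit$operating_threshold)
  expect_identical(back$epsilon, fit$epsilon)
  sc_a <- suppressWarnings(predict(fit, ex))
  sc_b <- suppressWarnings(predict(back, ex))
  expect_identical(sc_a, sc_b)
  # a second write of the loaded model is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_hii_model(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the loader rejects a catalogue-hash mismatch", {
  co <- simulate_cohort(sim_config(n_patients = 80, seed = 19))
  ex <- label_cohort(co$encounters, co$chart, co$interventions, control_seed = 1)
  fit <- hii_boost(ex, n_rounds = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_hii_model(fit, path)
  txt <- readLines(path)
  txt <- sub(fit$catalogue$hash, "deadbeef", txt, fixed = TRUE)
  writeLines(txt, path)
  expect_error(read_hii_model(path), "hash mismatch")
})
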