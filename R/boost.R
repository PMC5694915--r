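# Boosting over age-conditioned decision stumps with abstention.
#
# Each weak classifier is a lookup table over age bins: within a bin it
# thresholds a single clinical feature and votes unstable (+1) or stable
# (-1); when the feature is missing it abstains (0), so sparsely measured
# labs contribute when present without imputation. Rounds minimize
# Z = W0 + 2*sqrt(W+ * W-), the expected exponential-loss normalizer of the
# confidence-rated construction, where W+/W-/W0 are the correctly voted,
# incorrectly voted and abstained weight. Because both vote directions are in
# the candidate set and W0 is fixed per feature, minimizing Z over a
# feature's per-bin (threshold, direction) choices is exactly per-bin
# weighted-edge maximization, which the trainer does with cumulative sums
# over value-sorted samples.

# label coercion to +/-1 (+1 = unstable)
label_to_pm1 <- function(label) {
  if (is.numeric(label)) {
    stopifnot(all(label %in% c(-1, 1)))
    return(as.numeric(label))
  }
  l <- as.character(label)
  stopifnot(all(l %in% c("stable", "unstable")))
  ifelse(l == "unstable", 1, -1)
}

# candidate thresholds for one bin: midpoints of consecutive distinct values,
# or quantile-grid midpoints when more than max_thresholds would result
cand_thresholds <- function(x, max_thresholds = 64) {
  u <- sort(unique(x[!is.na(x)]))
  if (length(u) < 2) return(numeric(0))
  if (length(u) - 1 <= max_thresholds)
    return((u[-1] + u[-length(u)]) / 2)
  qs <- stats::quantile(x[!is.na(x)],
                        probs = seq(0, 1, length.out = max_thresholds + 1),
                        names = FALSE, type = 7)
  unique((qs[-1] + qs[-length(qs)]) / 2)
}

#' Candidate stumps for one feature
#'
#' Per age bin, candidate thresholds are placed at midpoints between
#' consecutive distinct observed in-bin values (capped via a quantile grid at
#' `max_thresholds`), each in both vote directions. Bins with no usable data
#' (fewer than two distinct values) inherit the nearest populated bin's
#' candidate thresholds, so a trained stump is defined over every bin. A
#' feature with no usable data in any bin yields an empty candidate set and
#' can never be selected.
#'
#' @param data data.frame of labeled examples holding the feature column and
#'   an age column.
#' @param feature feature column name.
#' @param age_bins age-bin edges; see [default_age_bins()].
#' @param max_thresholds per-bin cap on candidate thresholds.
#' @param age_col name of the age column.
#' @return list with `feature`, `edges`, and `thresholds` (list of per-bin
#'   numeric vectors; `directions` are implicitly both for every threshold).
#' @export
stump_candidates <- function(data, feature, age_bins = default_age_bins(),
                             max_thresholds = 64, age_col = "age") {
  x <- data[[feature]]
  bin <- age_bin_index(data[[age_col]], age_bins)
  nb <- length(age_bins) - 1L
  thr <- lapply(seq_len(nb), function(b) cand_thresholds(x[bin == b], max_thresholds))
  pop <- which(vapply(thr, length, integer(1)) > 0)
  if (!length(pop))
    return(list(feature = feature, edges = age_bins,
                thresholds = rep(list(numeric(0)), nb)))
  for (b in seq_len(nb)) {
    if (!length(thr[[b]])) {
      nearest <- pop[which.min(abs(pop - b))]
      thr[[b]] <- thr[[nearest]]
    }
  }
  list(feature = feature, edges = age_bins, thresholds = thr)
}

# vote of a stump on (x, bin): +1 unstable, -1 stable, 0 abstain
stump_vote <- function(stump, x, bin) {
  v <- numeric(length(x))
  present <- !is.na(x)
  t <- stump$threshold[bin]
  high <- stump$direction[bin] == "high_is_unstable"
  v[present] <- ifelse(high[present],
                       ifelse(x[present] > t[present], 1, -1),
                       ifelse(x[present] < t[present], 1, -1))
  v
}

#' Score a stump against weighted samples
#'
#' Decomposes the (normalized) sample weight into `W_plus` (voted correctly),
#' `W_minus` (voted incorrectly) and `W_zero` (abstained), and returns the
#' weak-learner objective `Z = W_zero + 2*sqrt(W_plus * W_minus)`.
#'
#' @param stump a stump as stored in a fitted model: list with `feature`,
#'   `edges`, `threshold` (per bin), `direction` (per bin).
#' @param data data.frame with the stump's feature column and an age column.
#' @param label labels coercible to +/-1 (+1 = unstable).
#' @param weights sample weights summing to 1; default uniform.
#' @param age_col name of the age column.
#' @return list with `W_plus`, `W_minus`, `W_zero`, `Z`.
#' @export
score_stump <- function(stump, data, label, weights = NULL, age_col = "age") {
  y <- label_to_pm1(label)
  n <- length(y)
  w <- if (is.null(weights)) rep(1 / n, n) else weights
  stopifnot(abs(sum(w) - 1) < 1e-8)
  bin <- age_bin_index(data[[age_col]], stump$edges)
  v <- stump_vote(stump, data[[stump$feature]], bin)
  W_plus <- sum(w[v == y])
  W_minus <- sum(w[v == -y & v != 0])
  W_zero <- sum(w[v == 0])
  list(W_plus = W_plus, W_minus = W_minus, W_zero = W_zero,
       Z = W_zero + 2 * sqrt(W_plus * W_minus))
}

# search structure reused across rounds: per feature, per bin, sorted present
# rows, candidate thresholds and their cut positions
boost_prep <- function(X, bin, age_bins, max_thresholds) {
  nb <- length(age_bins) - 1L
  lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    thr <- lapply(seq_len(nb), function(b)
      cand_thresholds(x[bin == b & !is.na(x)], max_thresholds))
    pop <- which(vapply(thr, length, integer(1)) > 0)
    if (!length(pop)) return(NULL)
    for (b in seq_len(nb)) if (!length(thr[[b]]))
      thr[[b]] <- thr[[pop[which.min(abs(pop - b))]]]
    bins <- lapply(seq_len(nb), function(b) {
      rows <- which(bin == b & !is.na(x))
      rows <- rows[order(x[rows])]
      v <- x[rows]
      list(rows = rows, thr = thr[[b]],
           pos_le = findInterval(thr[[b]], v),
           pos_lt = findInterval(thr[[b]], v, left.open = TRUE))
    })
    bins
  })
}

# best per-bin (threshold, direction) for feature prep under weights wy;
# ties resolved toward the lowest threshold, then high_is_unstable
best_bin_choice <- function(pb, wy, w) {
  sw <- sum(w[pb$rows])
  if (!length(pb$thr))
    return(list(threshold = NA_real_, direction = "high_is_unstable",
                edge = 0, sw = sw))
  s <- sum(wy[pb$rows])
  cum <- cumsum(wy[pb$rows])
  cum_le <- ifelse(pb$pos_le > 0, cum[pmax(pb$pos_le, 1)], 0)
  cum_lt <- ifelse(pb$pos_lt > 0, cum[pmax(pb$pos_lt, 1)], 0)
  edge_high <- s - 2 * cum_le
  edge_low <- 2 * cum_lt - s
  t_all <- c(pb$thr, pb$thr)
  d_all <- rep(c("high_is_unstable", "low_is_unstable"), each = length(pb$thr))
  e_all <- c(edge_high, edge_low)
  best <- max(e_all)
  tied <- which(e_all >= best - 1e-12)
  pick <- tied[order(t_all[tied], d_all[tied] != "high_is_unstable")][1]
  list(threshold = t_all[pick], direction = d_all[pick],
       edge = e_all[pick], sw = sw)
}

#' Fit an abstaining boosted-stump model of hemodynamic instability
#'
#' Trains the boosting ensemble on labeled feature vectors. Per round the
#' trainer selects, over all features and their age-binned candidate
#' thresholds, the stump minimizing `Z = W0 + 2*sqrt(W+ * W-)`; its vote
#' weight is `alpha = 0.5 * log((W+ + eps) / (W- + eps))` with smoothing
#' `eps = 1/(2N)` by default. Sample weights are then multiplied by
#' `exp(-alpha * y * h(x))` — abstained samples keep their weight — and
#' renormalized. Training stops early when no candidate improves on
#' abstention-plus-chance (`Z >= 1 - 1e-6`); if that happens on the first
#' round no feature is informative and fitting aborts. Ties among equal-Z
#' candidates resolve to the lowest feature index, then lowest threshold,
#' then the high-is-unstable direction, so training is deterministic.
#'
#' The fitted probability is the additive-logistic map of the unnormalized
#' margin, `p = 1/(1 + exp(-2 F(x)))`, and the stored operating threshold is
#' the training break-even point (sensitivity = precision); both are
#' serialized with the model.
#'
#' @param data data.frame of labeled examples, e.g. from [label_cohort()]
#'   (controls plus at-onset unstable rows; lead-time rows should be held out
#'   for evaluation).
#' @param n_rounds maximum boosting rounds (default 100).
#' @param age_bins age-bin edges for the stump lookup tables.
#' @param features candidate feature columns; defaults to every catalogue or
#'   composite feature present in `data`.
#' @param max_thresholds per-bin candidate threshold cap.
#' @param epsilon smoothing for the vote weight; default `1/(2N)`. Set 0 for
#'   the textbook unsmoothed weights (separable data then yields infinite
#'   alpha).
#' @param label_col,age_col column names of the label ("stable"/"unstable" or
#'   +/-1) and age (years).
#' @return An object of class `hii_boost` with components `stumps`,
#'   `diagnostics` (per-round feature, Z, alpha, exponential loss, training
#'   error), `calibration`, `operating_threshold`, the frozen runtime
#'   `catalogue` (plausibility bounds, staleness horizons, hash) and fitting
#'   metadata. Methods: [predict.hii_boost()], `print`, `summary`, `coef`,
#'   `plot`, plus [selected_features()] and [explain()].
#' @export
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 120, seed = 3))
#' ex <- label_cohort(co$encounters, co$chart, co$interventions)
#' fit <- hii_boost(ex, n_rounds = 10)
#' print(fit)
#' head(predict(fit, ex))
hii_boost <- function(data, n_rounds = 100, age_bins = default_age_bins(),
                      features = NULL, max_thresholds = 64, epsilon = NULL,
                      label_col = "label", age_col = "age") {
  stopifnot(n_rounds >= 1, is.data.frame(data))
  if (is.null(features))
    features <- intersect(c(catalogue_features(), composite_features()),
                          names(data))
  stopifnot(length(features) >= 1, all(features %in% names(data)))
  y <- label_to_pm1(data[[label_col]])
  if (length(unique(y)) < 2) stop("both classes must be present for training")
  age <- data[[age_col]]
  if (anyNA(age)) stop("age must be present for every example")
  n <- length(y)
  if (is.null(epsilon)) epsilon <- 1 / (2 * n)
  X <- as.matrix(data[, features, drop = FALSE])
  bin <- age_bin_index(age, age_bins)
  nb <- length(age_bins) - 1L
  prep <- boost_prep(X, bin, age_bins, max_thresholds)

  w <- rep(1 / n, n)
  stumps <- list()
  diag_rows <- list()
  f_margin <- numeric(n)
  for (t in seq_len(n_rounds)) {
    wy <- w * y
    best <- NULL
    for (j in seq_along(prep)) {
      if (is.null(prep[[j]])) next
      choice <- lapply(prep[[j]], best_bin_choice, wy = wy, w = w)
      sw_tot <- sum(vapply(choice, `[[`, numeric(1), "sw"))
      edge <- sum(vapply(choice, `[[`, numeric(1), "edge"))
      W_plus <- max((sw_tot + edge) / 2, 0)
      W_minus <- max((sw_tot - edge) / 2, 0)
      W_zero <- max(1 - sw_tot, 0)
      Z <- W_zero + 2 * sqrt(W_plus * W_minus)
      if (is.null(best) || Z < best$Z - 1e-12) {
        best <- list(j = j, Z = Z, W_plus = W_plus, W_minus = W_minus,
                     W_zero = W_zero, choice = choice)
      }
    }
    if (is.null(best)) stop("no informative feature")
    if (best$Z >= 1 - 1e-6) {
      if (t == 1) stop("no informative feature")
      break
    }
    alpha <- 0.5 * log((best$W_plus + epsilon) / (best$W_minus + epsilon))
    stump <- list(
      feature = features[best$j],
      edges = age_bins,
      threshold = vapply(best$choice, `[[`, numeric(1), "threshold"),
      direction = vapply(best$choice, `[[`, character(1), "direction"),
      alpha = alpha
    )
    v <- stump_vote(stump, X[, best$j], bin)
    w <- w * exp(-alpha * y * v)
    w <- w / sum(w)
    f_margin <- f_margin + alpha * v
    stumps[[t]] <- stump
    diag_rows[[t]] <- data.frame(
      round = t, feature = stump$feature, Z = best$Z, alpha = alpha,
      exp_loss = mean(exp(-y * f_margin)),
      train_error = mean(y * f_margin <= 0)
    )
  }

  model <- structure(list(
    stumps = stumps,
    n_rounds = length(stumps),
    age_bins = age_bins,
    epsilon = epsilon,
    calibration = list(type = "logistic", scale = 2),
    operating_threshold = NA_real_,
    catalogue = list(
      features = c(catalogue_features(), composite_features()),
      plausibility = default_plausibility(),
      staleness = default_staleness(),
      hash = catalogue_hash()
    ),
    diagnostics = do.call(rbind, diag_rows),
    n = n, n_pos = sum(y == 1), n_neg = sum(y == -1),
    call = match.call()
  ), class = "hii_boost")

  p_train <- 1 / (1 + exp(-model$calibration$scale * f_margin))
  be <- breakeven_threshold(p_train, y)
  model$operating_threshold <- be$threshold
  model
}

#' Predict from an abstaining boosted-stump model
#'
#' Computes the ensemble margin `F(x) = sum_t alpha_t h_t(x)` — abstentions
#' contribute exactly zero — and maps it to the hemodynamic instability
#' probability `p = 1/(1 + exp(-scale * F))`. Age must be present for every
#' row; rows on which every stump abstains have no defensible score and
#' return `NA` with a warning (heart rate plus age is the documented minimum
#' input).
#'
#' @param object fitted [hii_boost()] model.
#' @param newdata data.frame with feature columns and an age column. Columns
#'   absent from `newdata` simply make their stumps abstain.
#' @param type `"prob"` (default), `"margin"`, or `"color"` (traffic-light
#'   band of the probability at the model's operating threshold).
#' @param age_col age column name.
#' @param ... unused.
#' @return numeric vector (or character vector for `type = "color"`).
#' @export
predict.hii_boost <- function(object, newdata, type = c("prob", "margin", "color"),
                              age_col = "age", ...) {
  type <- match.arg(type)
  age <- newdata[[age_col]]
  if (is.null(age) || anyNA(age)) stop("age must be present for every row")
  n <- nrow(newdata)
  margin <- numeric(n)
  voted <- rep(FALSE, n)
  for (st in object$stumps) {
    x <- if (st$feature %in% names(newdata)) newdata[[st$feature]]
         else rep(NA_real_, n)
    b <- age_bin_index(age, st$edges)
    v <- stump_vote(st, x, b)
    margin <- margin + st$alpha * v
    voted <- voted | v != 0
  }
  if (length(object$stumps) && any(!voted)) {
    warning(sprintf("insufficient inputs: all stumps abstain on %d row(s); returning NA",
                    sum(!voted)))
    margin[!voted] <- NA_real_
  }
  if (type == "margin") return(margin)
  p <- 1 / (1 + exp(-object$calibration$scale * margin))
  if (type == "prob") return(p)
  risk_color(p, default_color_bands(object))
}

#' Features selected by the ensemble
#'
#' Distinct features appearing in the fitted stumps, ranked by their summed
#' vote weight (the model's discriminative-importance order). Invariant to
#' stump order.
#'
#' @param model fitted [hii_boost()] model.
#' @return data.frame with `feature` and `alpha_total`, descending.
#' @export
selected_features <- function(model) {
  stopifnot(inherits(model, "hii_boost"))
  if (!length(model$stumps))
    return(data.frame(feature = character(0), alpha_total = numeric(0)))
  f <- vapply(model$stumps, `[[`, character(1), "feature")
  a <- vapply(model$stumps, `[[`, numeric(1), "alpha")
  tot <- tapply(abs(a), f, sum)
  out <- data.frame(feature = names(tot), alpha_total = as.numeric(tot))
  out <- out[order(-out$alpha_total, out$feature), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' @export
print.hii_boost <- function(x, ...) {
  cat("Abstaining boosted-stump model of hemodynamic instability\n")
  cat(sprintf("  %d rounds over %d selected feature(s); trained on %d examples (%d unstable / %d stable)\n",
              x$n_rounds, length(unique(vapply(x$stumps, `[[`, character(1), "feature"))),
              x$n, x$n_pos, x$n_neg))
  cat(sprintf("  operating threshold (break-even): %.3f\n", x$operating_threshold))
  invisible(x)
}

#' @export
summary.hii_boost <- function(object, ...) {
  sf <- selected_features(object)
  structure(list(model = object, selected = sf,
                 final = utils::tail(object$diagnostics, 1)),
            class = "summary.hii_boost")
}

#' @export
print.summary.hii_boost <- function(x, ...) {
  print(x$model)
  cat(sprintf("  final training exponential loss %.4f, training error %.4f\n",
              x$final$exp_loss, x$final$train_error))
  cat("\nSelected features by summed vote weight:\n")
  print(x$selected)
  invisible(x)
}

#' @export
coef.hii_boost <- function(object, ...) {
  if (!length(object$stumps))
    return(data.frame())
  nb <- length(object$age_bins) - 1L
  do.call(rbind, lapply(seq_along(object$stumps), function(t) {
    st <- object$stumps[[t]]
    data.frame(round = t, feature = st$feature, bin = seq_len(nb),
               age_lo = st$edges[-length(st$edges)], age_hi = st$edges[-1],
               threshold = st$threshold, direction = st$direction,
               alpha = st$alpha, stringsAsFactors = FALSE)
  }))
}

#' @export
plot.hii_boost <- function(x, ...) {
  sf <- selected_features(x)
  op <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(sf$alpha_total), names.arg = rev(sf$feature),
                    horiz = TRUE, las = 1, xlab = "summed vote weight",
                    main = "Feature importance", ...)
  invisible(x)
}

#' Patient-level stratified cross-validation
#'
#' Splits patients into `k` label-stratified folds of near-equal size (per
#' fold, class counts are within one example of the global proportion),
#' trains on each complement and returns the pooled out-of-fold scores for
#' evaluation.
#'
#' @param data labeled examples (one row per patient at the training
#'   reference time).
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param label_col label column name.
#' @param ... passed to [hii_boost()].
#' @return list with `models` (length `k`), `oof` (data.frame of pooled
#'   out-of-fold `score`, `label`, `fold`, `row`), and `fold` (per-row fold
#'   assignment).
#' @export
cross_validate <- function(data, k = 10, seed = 1L, label_col = "label", ...) {
  stopifnot(label_col %in% names(data))
  y <- label_to_pm1(data[[label_col]])
  pat <- if ("patient_id" %in% names(data)) data$patient_id else seq_len(nrow(data))
  upat <- unique(data.frame(pat = pat, y = y))
  if (any(duplicated(upat$pat))) stop("a patient carries conflicting labels")
  if (min(table(upat$y)) < k) stop("k exceeds the size of a class")
  fold_of <- with_seed(seed, {
    f <- integer(nrow(upat))
    for (cls in unique(upat$y)) {
      ids <- which(upat$y == cls)
      f[ids[sample.int(length(ids))]] <- rep_len(seq_len(k), length(ids))
    }
    f
  })
  fold <- fold_of[match(pat, upat$pat)]
  models <- vector("list", k)
  oof <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- data[fold != i, , drop = FALSE]
    te_idx <- which(fold == i)
    models[[i]] <- hii_boost(tr, label_col = label_col, ...)
    sc <- suppressWarnings(predict(models[[i]], data[te_idx, , drop = FALSE]))
    oof[[i]] <- data.frame(row = te_idx, fold = i, score = sc, label = y[te_idx])
  }
  oof <- do.call(rbind, oof)
  oof <- oof[order(oof$row), , drop = FALSE]
  row.names(oof) <- NULL
  list(models = models, oof = oof, fold = fold)
}
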