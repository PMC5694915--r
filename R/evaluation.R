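# Evaluation protocol: ROC analysis by lead time, break-even operating
# point, prevalence-adjusted predictive values, stratified reports and
# age-adjusted single-feature baselines.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, ties counted one half. Equivalent to trapezoidal
#' integration of the ROC curve.
#'
#' @param scores numeric scores (higher = more unstable). `NA` scores are
#'   dropped with a warning.
#' @param labels labels coercible to +/-1; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
#' @examples
#' auroc(c(0.8, 0.6, 0.4, 0.2), c(1, -1, 1, -1))  # 0.75
auroc <- function(scores, labels) {
  y <- label_to_pm1(labels)
  if (anyNA(scores)) {
    warning(sprintf("dropping %d NA score(s)", sum(is.na(scores))))
    y <- y[!is.na(scores)]
    scores <- scores[!is.na(scores)]
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Break-even operating threshold
#'
#' Scans the observed score cutpoints (predict unstable when
#' `score >= threshold`) and returns the one minimizing
#' `|sensitivity - precision|`; ties resolve to the lower threshold. Exact
#' equality is generally unattainable on a finite sample, so the attained
#' sensitivity and precision are returned too; a degenerate solution (at a
#' corner of the precision-recall curve) is flagged.
#'
#' @param scores numeric scores.
#' @param labels labels coercible to +/-1.
#' @return list with `threshold`, `sensitivity`, `precision`, `gap`,
#'   `degenerate`.
#' @export
breakeven_threshold <- function(scores, labels) {
  y <- label_to_pm1(labels)
  ok <- !is.na(scores)
  y <- y[ok]; scores <- scores[ok]
  n_pos <- sum(y == 1)
  if (n_pos == 0 || all(y == 1)) stop("both classes must be present")
  cand <- sort(unique(scores))
  o <- order(scores)
  ys <- y[o]; ss <- scores[o]
  n <- length(ys)
  # predicted positive at cutpoint c: scores >= c
  pos_ge <- rev(cumsum(rev(ys == 1)))   # positives with score >= ss[i]
  all_ge <- n - seq_len(n) + 1
  first_ge <- match(cand, ss)           # first index with score >= cand
  tp <- pos_ge[first_ge]
  pp <- all_ge[first_ge]
  sens <- tp / n_pos
  prec <- ifelse(pp > 0, tp / pp, NA_real_)
  if (all(is.na(prec))) stop("precision undefined at every cutpoint")
  gap <- abs(sens - prec)
  best <- which(gap <= min(gap, na.rm = TRUE) + 1e-12)[1]
  # the break-even can land on the empty corner of the PR curve (sens = 0,
  # e.g. anti-ranked scores); that operating point is flagged as degenerate
  list(threshold = cand[best], sensitivity = sens[best],
       precision = prec[best], gap = gap[best],
       degenerate = sens[best] == 0)
}

#' Prevalence-adjusted predictive values
#'
#' Bayes recomputation of PPV and NPV at a stated prevalence `pi` from
#' sensitivity and specificity:
#' `PPV = sens*pi / (sens*pi + (1-spec)*(1-pi))` and
#' `NPV = spec*(1-pi) / (spec*(1-pi) + (1-sens)*pi)`. A zero denominator
#' yields `NaN` (undefined), not an error.
#'
#' @param sensitivity,specificity,prevalence values in \[0, 1\].
#' @return list with `ppv` and `npv`.
#' @export
#' @examples
#' adjust_predictive_values(0.66, 0.78, 0.42)  # ppv ~0.68, npv ~0.76
adjust_predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence >= 0, prevalence <= 1)
  dp <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  dn <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  list(ppv = if (dp == 0) NaN else sensitivity * prevalence / dp,
       npv = if (dn == 0) NaN else specificity * (1 - prevalence) / dn)
}

#' Mean, sample SD, minimum and maximum
#'
#' Sample SD uses the n-1 denominator. With fewer than two values the SD is
#' returned as `NA` (undefined), the rest still computed.
#' @param values numeric vector.
#' @return list with `mean`, `sd`, `min`, `max`.
#' @export
summary_stats <- function(values) {
  stopifnot(length(values) >= 1, !anyNA(values))
  list(mean = mean(values),
       sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
       min = min(values), max = max(values))
}

#' Metrics at an operating threshold
#'
#' Confusion-matrix metrics (predict unstable when `score >= threshold`),
#' with PPV/NPV recomputed at `prevalence` (defaults to the sample
#' prevalence, in which case they equal the raw confusion-matrix values).
#' The positive likelihood ratio is `sens / (1 - spec)`.
#'
#' @param scores,labels as in [auroc()].
#' @param threshold operating threshold; default break-even.
#' @param prevalence prevalence for the predictive-value adjustment.
#' @param stratum optional label for the report row.
#' @return one-row data.frame (a `MetricsReport`): `stratum`, `n_pos`,
#'   `n_neg`, `auroc`, `threshold`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `positive_lr`, `prevalence_used`.
#' @export
metrics_report <- function(scores, labels, threshold = NULL,
                           prevalence = NULL, stratum = "all") {
  y <- label_to_pm1(labels)
  ok <- !is.na(scores)
  if (!all(ok)) warning(sprintf("dropping %d NA score(s)", sum(!ok)))
  y <- y[ok]; scores <- scores[ok]
  if (is.null(threshold)) threshold <- breakeven_threshold(scores, y)$threshold
  if (is.null(prevalence)) prevalence <- mean(y == 1)
  pred <- scores >= threshold
  sens <- sum(pred & y == 1) / sum(y == 1)
  spec <- sum(!pred & y == -1) / sum(y == -1)
  pv <- adjust_predictive_values(sens, spec, prevalence)
  data.frame(stratum = stratum, n_pos = sum(y == 1), n_neg = sum(y == -1),
             auroc = auroc(scores, y), threshold = threshold,
             sensitivity = sens, specificity = spec,
             ppv = pv$ppv, npv = pv$npv,
             positive_lr = if (spec < 1) sens / (1 - spec) else Inf,
             prevalence_used = prevalence,
             stringsAsFactors = FALSE)
}

#' AUROC as a function of prediction lead time
#'
#' Evaluates the model on feature vectors extracted `L` hours before
#' intervention onset for each requested lead time, against the control
#' examples (whose fixed random reference times are reused across lead
#' times). Empty strata are skipped with a warning.
#'
#' @param model fitted [hii_boost()] model.
#' @param examples labeled examples from [label_cohort()] built with
#'   `lead_times` covering the requested values (controls have
#'   `lead_time = NA`).
#' @param lead_times lead times in hours (default 1..12).
#' @return data.frame of [metrics_report()] rows, one per lead time, with a
#'   `lead_time` column.
#' @export
leadtime_curve <- function(model, examples, lead_times = 1:12) {
  ctl <- examples[examples$label == "stable", , drop = FALSE]
  out <- list()
  for (L in lead_times) {
    uns <- examples[examples$label == "unstable" &
                      !is.na(examples$lead_time) & examples$lead_time == L, ,
                    drop = FALSE]
    if (!nrow(uns) || !nrow(ctl)) {
      warning(sprintf("lead time %s h: empty stratum, skipped", L))
      next
    }
    sub <- rbind(uns, ctl)
    sc <- suppressWarnings(predict(model, sub))
    rep_row <- metrics_report(sc, sub$label, stratum = sprintf("lead_%dh", L))
    rep_row$lead_time <- L
    out[[length(out) + 1]] <- rep_row
  }
  do.call(rbind, out)
}

#' Stratified performance report
#'
#' Evaluates the model per stratum: the five age groups, the ventilated
#' flag, the kind of first intervention (controls are shared across
#' intervention strata), or feature subsets. Feature-subset strata are scored
#' by masking every other feature to missing at predict time — abstention
#' absorbs the rest, no retraining — with `retrain = TRUE` available as the
#' alternative mode.
#'
#' @param model fitted [hii_boost()] model.
#' @param examples labeled examples (at-onset unstable rows plus controls).
#' @param strata one of `"age_group"`, `"ventilated"`, `"first_intervention"`,
#'   or a named list of feature subsets, e.g.
#'   `list(vitals_only = c("heart_rate", ...))`.
#' @param encounters required for `"ventilated"` (supplies the flag) and
#'   `"first_intervention"` (via `interventions`).
#' @param interventions required for `"first_intervention"`.
#' @param retrain logical; refit per feature subset instead of masking.
#' @param ... passed to [hii_boost()] when `retrain = TRUE`.
#' @return data.frame of [metrics_report()] rows, one per non-empty stratum.
#' @export
stratified_report <- function(model, examples, strata = "age_group",
                              encounters = NULL, interventions = NULL,
                              retrain = FALSE, ...) {
  score_of <- function(sub, mdl = model) suppressWarnings(predict(mdl, sub))
  rows <- list()
  emit <- function(sub, name, mdl = model) {
    if (!nrow(sub) || length(unique(sub$label)) < 2) {
      warning(sprintf("stratum '%s' lacks both classes, skipped", name))
      return()
    }
    rows[[length(rows) + 1]] <<- metrics_report(score_of(sub, mdl), sub$label,
                                                stratum = name)
  }
  if (is.list(strata)) {
    feat_cols <- intersect(c(catalogue_features(), composite_features()),
                           names(examples))
    for (name in names(strata)) {
      keep <- strata[[name]]
      stopifnot(all(keep %in% feat_cols))
      if (retrain) {
        mdl <- hii_boost(examples, features = keep, ...)
        emit(examples, name, mdl)
      } else {
        sub <- examples
        mask <- setdiff(feat_cols, keep)
        sub[mask] <- NA_real_
        emit(sub, name)
      }
    }
  } else if (identical(strata, "age_group")) {
    edges <- default_age_bins()
    b <- age_bin_index(examples$age, edges)
    lab <- sprintf("age_%g_%g", edges[-length(edges)], edges[-1])
    for (k in seq_len(length(edges) - 1))
      emit(examples[b == k, , drop = FALSE], lab[k])
  } else if (identical(strata, "ventilated")) {
    stopifnot(!is.null(encounters))
    vent <- encounters$ventilated[match(examples$encounter_id,
                                        encounters$encounter_id)]
    emit(examples[vent %in% TRUE, , drop = FALSE], "ventilated")
    emit(examples[vent %in% FALSE, , drop = FALSE], "not_ventilated")
  } else if (identical(strata, "first_intervention")) {
    stopifnot(!is.null(interventions))
    first_kind <- vapply(split(interventions, interventions$encounter_id),
                         function(d) d$kind[which.min(as.numeric(d$time))],
                         character(1))
    kind <- first_kind[examples$encounter_id]
    ctl <- examples[examples$label == "stable", , drop = FALSE]
    for (k in c("fluid_bolus", "vasoactive")) {
      uns <- examples[examples$label == "unstable" & !is.na(kind) & kind == k, ,
                      drop = FALSE]
      emit(rbind(uns, ctl), paste0("first_", k))
    }
  } else stop("unknown stratum key: ", strata)
  do.call(rbind, rows)
}

#' Age-adjusted single-feature baseline models
#'
#' Fits the same boosting trainer restricted to systolic blood pressure only
#' (invasive and noninvasive columns) and to the shock index only, the two
#' conventional bedside comparators. Evaluated identically to the full model.
#'
#' @param data training examples.
#' @param ... passed to [hii_boost()].
#' @return list with `sbp` and `si` fitted models.
#' @export
baseline_models <- function(data, ...) {
  list(sbp = hii_boost(data, features = intersect(c("isbp", "nsbp"), names(data)), ...),
       si = hii_boost(data, features = "si", ...))
}
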