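# Streaming risk-score runtime: turn a live event sequence into a time
# series of HII probabilities, traffic-light colors and per-feature
# contributions. Strictly causal: a tick sees only events at or before it,
# filtered through the staleness gate.

#' Default traffic-light color bands
#'
#' The red cutpoint defaults to the model's operating (break-even) threshold
#' and the yellow cutpoint sits 0.1 below it (clamped to stay positive).
#' @param model optional fitted model supplying the operating threshold.
#' @param c1,c2 explicit cutpoints `0 < c1 < c2 < 1` overriding the defaults.
#' @return numeric vector `c(c1, c2)`.
#' @export
default_color_bands <- function(model = NULL, c1 = NULL, c2 = NULL) {
  if (is.null(c2))
    c2 <- if (!is.null(model) && is.finite(model$operating_threshold))
      model$operating_threshold else 0.6
  if (is.null(c1)) c1 <- max(c2 - 0.1, c2 / 2)
  c(c1, c2)
}

#' Map a probability to a risk color
#'
#' Green for `p < c1`, yellow for `c1 <= p < c2`, red for `p >= c2`
#' (boundaries belong to the higher-risk side).
#' @param p probabilities in \[0, 1\] (`NA` passes through).
#' @param bands cutpoints `c(c1, c2)` with `0 < c1 < c2 < 1`.
#' @return character vector of "green"/"yellow"/"red".
#' @export
risk_color <- function(p, bands) {
  stopifnot(length(bands) == 2, bands[1] > 0, bands[1] < bands[2], bands[2] < 1)
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p must lie in [0, 1]")
  ifelse(is.na(p), NA_character_,
         ifelse(p >= bands[2], "red",
                ifelse(p >= bands[1], "yellow", "green")))
}

#' Per-feature contributions to the margin
#'
#' Decomposes the ensemble margin into per-feature signed scores: each
#' feature's contribution is the sum of `alpha * vote` over its stumps, so
#' contributions always sum to the margin. Features whose stumps all abstain
#' are flagged missing rather than reported as zero — "no information" and
#' "actively neutral" are different clinical statements.
#'
#' @param model fitted [hii_boost()] model.
#' @param v one-row data.frame or named vector with feature values and age.
#' @param age_col age column/slot name.
#' @return data.frame with `feature`, `contribution`, `missing`, ordered by
#'   decreasing `abs(contribution)` (missing features last).
#' @export
explain <- function(model, v, age_col = "age") {
  stopifnot(inherits(model, "hii_boost"))
  if (!is.data.frame(v)) v <- as.data.frame(as.list(v))
  stopifnot(nrow(v) == 1)
  age <- v[[age_col]]
  if (is.null(age) || is.na(age)) stop("age must be present")
  feats <- unique(vapply(model$stumps, `[[`, character(1), "feature"))
  contrib <- stats::setNames(numeric(length(feats)), feats)
  nvotes <- stats::setNames(integer(length(feats)), feats)
  for (st in model$stumps) {
    x <- if (st$feature %in% names(v)) v[[st$feature]] else NA_real_
    vote <- stump_vote(st, x, age_bin_index(age, st$edges))
    contrib[st$feature] <- contrib[st$feature] + st$alpha * vote
    nvotes[st$feature] <- nvotes[st$feature] + (vote != 0)
  }
  out <- data.frame(feature = feats, contribution = as.numeric(contrib),
                    missing = nvotes == 0, stringsAsFactors = FALSE)
  out$contribution[out$missing] <- NA_real_
  out <- out[order(out$missing, -abs(out$contribution)), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Score a live event stream
#'
#' Replays one encounter's chart events and emits the hemodynamic instability
#' indicator on a fixed cadence: at each tick the staleness gate selects the
#' current value per feature (1-hour horizon for blood pressures and
#' ventilator parameters, 24 hours otherwise), composites are derived, and
#' the model produces a probability, color and top contributions. Ticks where
#' the minimum inputs — heart rate and age — are unavailable emit an explicit
#' no-output record rather than a silent skip. No future event influences any
#' tick.
#'
#' @param model fitted [hii_boost()] model.
#' @param events time-sorted chart events for one encounter.
#' @param age patient age in years.
#' @param cadence tick spacing in minutes (default 60; bedside deployments
#'   run at 1).
#' @param from,to tick range; defaults to the first and last event time.
#' @param bands color bands; defaults to [default_color_bands()] of the
#'   model.
#' @return data.frame (class `hii_series`): `time`, `hii`, `color`, `margin`,
#'   `available` (logical), `reason` (for no-output ticks), `top_feature` /
#'   `top_contribution` of the largest-magnitude voting feature, and `top3`
#'   (the three largest contributions as `feature:score`, `;`-joined).
#' @export
score_stream <- function(model, events, age, cadence = 60,
                         from = NULL, to = NULL, bands = NULL) {
  stopifnot(inherits(model, "hii_boost"), cadence > 0)
  if (nrow(events) && is.unsorted(as.numeric(events$time)))
    stop("events must be sorted by time")
  if (is.null(bands)) bands <- default_color_bands(model)
  if (is.null(from)) from <- if (nrow(events)) min(events$time) else stop("no events")
  if (is.null(to)) to <- max(events$time)
  ticks <- seq(from, to, by = cadence * 60)
  n <- length(ticks)
  out <- data.frame(
    time = ticks, hii = NA_real_, color = NA_character_, margin = NA_real_,
    available = FALSE, reason = NA_character_,
    top_feature = NA_character_, top_contribution = NA_real_,
    top3 = NA_character_,
    stringsAsFactors = FALSE
  )
  staleness <- model$catalogue$staleness
  for (i in seq_len(n)) {
    snap <- staleness_gate(events, ticks[i], staleness)
    if (is.na(snap[["heart_rate"]])) {
      out$reason[i] <- "minimum inputs unavailable (heart rate)"
      next
    }
    v <- as.data.frame(as.list(derive_composites(snap)))
    v$age <- age
    m <- suppressWarnings(predict(model, v, type = "margin"))
    if (is.na(m)) {
      out$reason[i] <- "insufficient inputs (all stumps abstain)"
      next
    }
    p <- 1 / (1 + exp(-model$calibration$scale * m))
    out$margin[i] <- m
    out$hii[i] <- p
    out$color[i] <- risk_color(p, bands)
    out$available[i] <- TRUE
    ex <- explain(model, v)
    ex <- ex[!ex$missing, , drop = FALSE]
    if (nrow(ex)) {
      out$top_feature[i] <- ex$feature[1]
      out$top_contribution[i] <- ex$contribution[1]
      k <- seq_len(min(3, nrow(ex)))
      out$top3[i] <- paste(sprintf("%s:%+.3f", ex$feature[k],
                                   ex$contribution[k]), collapse = ";")
    }
  }
  class(out) <- c("hii_series", "data.frame")
  out
}
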