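#' Age-dependent reference curves
#'
#' Normal ranges of pediatric vitals and laboratory values change as children
#' grow: an infant's resting heart rate of 140 bpm is unremarkable while the
#' same rate in a teenager is alarming. A `reference_curve` captures this as
#' piecewise-linear (age, mean, sd) knots; the cohort simulator samples
#' around these curves and shifts them during pre-intervention deterioration.
#'
#' @param feature canonical feature name.
#' @param age numeric vector of knot ages in years, strictly increasing.
#' @param mean,sd numeric vectors of the same length; `sd` strictly positive.
#' @return An object of class `reference_curve`.
#' @export
#' @examples
#' rc <- reference_curve("heart_rate", age = c(1, 10), mean = c(120, 80),
#'                       sd = c(15, 12))
#' reference_value(rc, 5.5)  # midpoint: mean 100, sd 13.5
reference_curve <- function(feature, age, mean, sd) {
  stopifnot(length(age) == length(mean), length(age) == length(sd),
            length(age) >= 1, all(diff(age) > 0), all(sd > 0),
            all(is.finite(age)), all(is.finite(mean)), all(is.finite(sd)))
  structure(list(feature = feature, age = as.numeric(age),
                 mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "reference_curve")
}

#' Evaluate a reference curve at an age
#'
#' Piecewise-linear interpolation between bracketing knots; ages beyond the
#' knot range clamp to the end knots. Evaluating exactly at a knot returns
#' that knot's (mean, sd).
#'
#' @param curve a [reference_curve()].
#' @param age age(s) in years; must be non-negative (pediatric range is
#'   1 month to 20 years).
#' @return A list with numeric vectors `mean` and `sd`.
#' @export
reference_value <- function(curve, age) {
  stopifnot(inherits(curve, "reference_curve"))
  if (any(!is.finite(age)) || any(age < 0))
    stop("age must be finite and non-negative")
  m <- stats::approx(curve$age, curve$mean, xout = age, rule = 2)$y
  s <- stats::approx(curve$age, curve$sd,   xout = age, rule = 2)$y
  list(mean = m, sd = s)
}

#' @export
print.reference_curve <- function(x, ...) {
  cat("Reference curve for", x$feature, "with", length(x$age), "knots\n")
  print(data.frame(age = x$age, mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Built-in pediatric reference curves
#'
#' Piecewise-linear curves for all 36 catalogue features with
#' pediatric-plausible knots at ages 1/12, 1, 5, 12 and 20 years. These are
#' simulator defaults chosen to be physiologically sensible, not normative
#' clinical ranges; each can be replaced via the `curves` argument of
#' [sim_config()].
#'
#' @return Named list of [reference_curve()] objects, one per catalogue
#'   feature.
#' @export
default_reference_curves <- function() {
  a5 <- c(1 / 12, 1, 5, 12, 20)
  k <- function(feature, mean, sd) {
    if (length(mean) == 1) mean <- rep(mean, 5)
    if (length(sd) == 1) sd <- rep(sd, 5)
    reference_curve(feature, a5, mean, sd)
  }
  curves <- list(
    k("heart_rate",       c(140, 120, 100, 85, 75),  c(15, 15, 12, 12, 10)),
    k("respiratory_rate", c(40, 30, 24, 18, 14),     c(8, 6, 5, 4, 3)),
    k("nsbp",             c(75, 90, 95, 110, 118),   c(10, 11, 11, 12, 12)),
    k("isbp",             c(75, 90, 95, 110, 118),   c(10, 11, 11, 12, 12)),
    k("ndbp",             c(45, 55, 58, 65, 70),     8),
    k("idbp",             c(45, 55, 58, 65, 70),     8),
    k("nmbp",             c(55, 67, 70, 80, 86),     9),
    k("imbp",             c(55, 67, 70, 80, 86),     9),
    k("temperature",      37, 0.5),
    k("spo2",             97, 2),
    k("sao2",             96, 3),
    k("ph",               7.38, 0.05),
    k("paco2",            40, 6),
    k("pao2",             95, 20),
    k("hco3",             c(22, 22, 23, 24, 24),     3),
    k("base_excess",      0, 3),
    k("fio2",             0.35, 0.10),
    k("mean_airway_pressure", c(8, 9, 10, 11, 12),   3),
    k("pf_ratio",         300, 80),
    k("glucose",          110, 25),
    k("chloride",         103, 4),
    k("bun",              12, 5),
    k("creatinine",       c(0.3, 0.3, 0.5, 0.7, 0.9), 0.2),
    k("potassium",        4.2, 0.5),
    k("sodium",           139, 3.5),
    k("alt",              28, 12),
    k("albumin",          3.8, 0.5),
    k("total_protein",    6.3, 0.7),
    k("wbc",              c(11, 10, 8.5, 7.5, 7),    3),
    k("rbc",              c(4.0, 4.4, 4.5, 4.7, 4.8), 0.5),
    k("hemoglobin",       c(11.5, 12, 12.5, 13.5, 14), 1.5),
    k("platelets",        c(300, 300, 280, 260, 250), 80),
    k("magnesium",        2.0, 0.3),
    k("inr",              13, 2),
    k("lactic_acid",      12, 5),
    k("urine_output",     c(2.5, 2.0, 1.5, 1.2, 1.0), 0.6)
  )
  names(curves) <- vapply(curves, function(x) x$feature, character(1))
  stopifnot(setequal(names(curves), catalogue_features()))
  curves[catalogue_features()]
}
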