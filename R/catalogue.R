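#' The 36-feature clinical catalogue
#'
#' Canonical names, units, panel membership, staleness class, default
#' plausibility bounds and default per-patient recording probabilities for the
#' 36 charted variables the model consumes. Age (years) is carried separately
#' on every feature vector and is never charted as an event. Three composite
#' features (`si`, `oi`, `osi`) are derived downstream and can be selected by
#' the classifier but are never ingested directly.
#'
#' Staleness classes: blood pressures and ventilator parameters expire after
#' 1 hour; laboratory values and the remaining vitals after 24 hours.
#' Plausibility bounds are deliberately permissive physiologic ranges; values
#' outside them are treated as missing. FiO2 is stored as a fraction in
#' \[0.21, 1\]; ingest accepts percentages and divides by 100 when the charted
#' value exceeds 1.
#'
#' @return A data.frame with one row per canonical feature: `feature`, `unit`,
#'   `panel` (abg, ventilator, invasive_vitals, vitals, bmp, cmp, cbc, other),
#'   `staleness_class` (`bp`, `ventilator`, `lab`, `vital`), `lower`/`upper`
#'   plausibility bounds, `record_prob` (default probability a patient ever
#'   has the feature recorded), `interval_h` (default mean inter-measurement
#'   interval, hours).
#' @export
#' @examples
#' cat <- feature_catalogue()
#' nrow(cat)           # 36
#' cat[cat$feature == "heart_rate", ]
feature_catalogue <- function() {
  f <- function(feature, unit, panel, stale, lower, upper, prob, interval)
    data.frame(feature = feature, unit = unit, panel = panel,
               staleness_class = stale, lower = lower, upper = upper,
               record_prob = prob, interval_h = interval,
               stringsAsFactors = FALSE)
  rbind(
    # arterial blood gas
    f("ph",            "pH",        "abg", "lab",   6.5,  8.0,  0.63, 8),
    f("hco3",          "mEq/L",     "abg", "lab",   1,    60,   0.63, 8),
    f("paco2",         "mmHg",      "abg", "lab",   5,    250,  0.63, 8),
    f("sao2",          "%",         "abg", "lab",   5,    100,  0.63, 8),
    f("base_excess",   "mEq/L",     "abg", "lab",  -40,   40,   0.63, 8),
    f("pao2",          "mmHg",      "abg", "lab",   10,   700,  0.63, 8),
    # ventilator parameters
    f("pf_ratio",      "mmHg",      "ventilator", "ventilator", 10, 700, 0.41, 24),
    f("fio2",          "fraction",  "ventilator", "ventilator", 0.21, 1.0, 0.76, 4),
    f("mean_airway_pressure", "cmH2O", "ventilator", "ventilator", 1, 60, 0.35, 4),
    # invasive vitals
    f("imbp",          "mmHg",      "invasive_vitals", "bp", 20, 250, 0.51, 1),
    f("isbp",          "mmHg",      "invasive_vitals", "bp", 30, 300, 0.51, 1),
    f("idbp",          "mmHg",      "invasive_vitals", "bp", 10, 200, 0.51, 1),
    # noninvasive vitals
    f("nmbp",          "mmHg",      "vitals", "bp",    20,  250, 0.98, 1),
    f("nsbp",          "mmHg",      "vitals", "bp",    30,  300, 0.98, 1),
    f("ndbp",          "mmHg",      "vitals", "bp",    10,  200, 0.98, 1),
    f("heart_rate",    "bpm",       "vitals", "vital", 20,  350, 1.00, 1),
    f("respiratory_rate", "bpm",    "vitals", "vital", 2,   150, 0.99, 1),
    f("spo2",          "%",         "vitals", "vital", 5,   100, 0.61, 1),
    f("temperature",   "Celsius",   "vitals", "vital", 25,  45,  0.99, 4),
    # basic metabolic panel
    f("glucose",       "mg/dl",     "bmp", "lab",     10,  2000, 0.74, 24),
    f("chloride",      "mEq/L",     "bmp", "lab",     50,  170,  0.72, 24),
    f("bun",           "mg/dl",     "bmp", "lab",     1,   300,  0.66, 24),
    f("creatinine",    "mg/dl",     "bmp", "lab",     0.05, 25,  0.66, 24),
    f("potassium",     "mEq/L",     "bmp", "lab",     1,   12,   0.78, 24),
    f("sodium",        "mEq/L",     "bmp", "lab",     90,  200,  0.77, 24),
    # comprehensive metabolic panel
    f("alt",           "U/L",       "cmp", "lab",     1,   10000, 0.18, 24),
    f("albumin",       "g/dl",      "cmp", "lab",     0.5, 7,    0.18, 24),
    f("total_protein", "g/dl",      "cmp", "lab",     1,   12,   0.18, 24),
    # complete blood count
    f("wbc",           "K/ul",      "cbc", "lab",     0.1, 200,  0.65, 24),
    f("rbc",           "M/ul",      "cbc", "lab",     0.5, 10,   0.65, 24),
    f("hemoglobin",    "g/dl",      "cbc", "lab",     1,   25,   0.68, 24),
    f("platelets",     "K/ul",      "cbc", "lab",     1,   2000, 0.65, 24),
    # additional tests
    f("magnesium",     "mg/dl",     "other", "lab",   0.1, 10,   0.26, 24),
    f("inr",           "seconds",   "other", "lab",   5,   200,  0.37, 24),
    f("lactic_acid",   "mg/dl",     "other", "lab",   1,   300,  0.14, 12),
    f("urine_output",  "ml/kg/h",   "other", "lab",   0,   50,   0.77, 2)
  )
}

#' @rdname feature_catalogue
#' @export
catalogue_features <- function() feature_catalogue()$feature

#' Composite (derived) feature names
#'
#' Shock index (`si` = HR/SBP), oxygenation index
#' (`oi` = MAP x FiO2 x 100 / PaO2) and oxygen saturation index
#' (`osi` = MAP x FiO2 x 100 / SpO2).
#' @return Character vector of the three derived slot names.
#' @export
composite_features <- function() c("si", "oi", "osi")

#' Default plausibility table
#'
#' Per-feature physiologically valid ranges. Charted values outside
#' \[lower, upper\] are treated as missing. The ranges are documented defaults
#' and can be overridden; they must remain total over the 36-feature
#' catalogue.
#'
#' @return data.frame with columns `feature`, `lower`, `upper`.
#' @export
default_plausibility <- function() {
  feature_catalogue()[, c("feature", "lower", "upper")]
}

#' Default staleness horizons (hours)
#'
#' Maximum age of a measurement before it is considered missing at scoring
#' time: 1 hour for blood pressures and ventilator parameters, 24 hours for
#' laboratory values and the remaining vital signs.
#'
#' @return Named numeric vector, hours, one entry per catalogue feature.
#' @export
default_staleness <- function() {
  cat <- feature_catalogue()
  h <- ifelse(cat$staleness_class %in% c("bp", "ventilator"), 1, 24)
  stats::setNames(h, cat$feature)
}

#' Feature-name alias map
#'
#' Maps common charting synonyms (case- and whitespace-insensitive) to
#' canonical catalogue names. Extend with a two-column (alias, canonical)
#' table, e.g. read from a site-specific file.
#'
#' @param extra optional data.frame with columns `alias`, `canonical`.
#' @return Named character vector: names are lower-cased aliases, values are
#'   canonical feature names.
#' @export
feature_aliases <- function(extra = NULL) {
  base <- c(
    hr = "heart_rate", "heart rate" = "heart_rate", pulse = "heart_rate",
    rr = "respiratory_rate", "resp rate" = "respiratory_rate",
    "respiration rate" = "respiratory_rate",
    temp = "temperature", sbp = "nsbp", dbp = "ndbp", mbp = "nmbp",
    "nibp systolic" = "nsbp", "nibp diastolic" = "ndbp", "nibp mean" = "nmbp",
    "abp systolic" = "isbp", "abp diastolic" = "idbp", "abp mean" = "imbp",
    "art ph" = "ph", "arterial ph" = "ph",
    bicarbonate = "hco3", "base excess" = "base_excess", abe = "base_excess",
    "map airway" = "mean_airway_pressure", paw = "mean_airway_pressure",
    "mean airway pressure" = "mean_airway_pressure",
    "pf" = "pf_ratio", "p/f ratio" = "pf_ratio",
    lactate = "lactic_acid", "lactic acid" = "lactic_acid",
    "urine output" = "urine_output", uo = "urine_output",
    "prothrombin time" = "inr", pt = "inr",
    haemoglobin = "hemoglobin", hgb = "hemoglobin",
    "total protein" = "total_protein",
    "blood urea nitrogen" = "bun"
  )
  cat_names <- catalogue_features()
  base <- c(base, stats::setNames(cat_names, cat_names))
  if (!is.null(extra)) {
    stopifnot(all(c("alias", "canonical") %in% names(extra)))
    add <- stats::setNames(as.character(extra$canonical),
                           tolower(trimws(as.character(extra$alias))))
    base[names(add)] <- add
  }
  base
}

#' Canonicalize feature names
#'
#' Lower-cases, trims whitespace and resolves aliases. Unknown names map to
#' `NA`.
#' @param x character vector of raw feature names.
#' @param aliases alias map from [feature_aliases()].
#' @return character vector of canonical names (NA where unknown).
#' @export
canonical_feature <- function(x, aliases = feature_aliases()) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(aliases[key])
  out[!(key %in% names(aliases))] <- NA_character_
  out
}

# Age bins used throughout: the five pediatric evaluation strata.
#' Default age-bin edges (years)
#'
#' Five strata: 1-12 months, 1-3, 3-6, 6-12 and 12-20 years. Stumps learn one
#' (threshold, direction) pair per bin; evaluation stratifies on the same
#' bins.
#' @return Numeric vector of 6 strictly increasing edges covering
#'   \[1/12, 20\] years.
#' @export
default_age_bins <- function() c(1 / 12, 1, 3, 6, 12, 20)

#' Map ages to age-bin indices
#'
#' Bins are left-closed, right-open except the last, which is closed:
#' \[e1, e2), ..., \[e_{k-1}, e_k\]. Ages outside the edge range clamp to the
#' first/last bin so a trained model can still score slightly out-of-range
#' ages.
#' @param age numeric vector, years.
#' @param edges bin edges as in [default_age_bins()].
#' @return integer vector of bin indices in 1..(length(edges)-1).
#' @export
age_bin_index <- function(age, edges = default_age_bins()) {
  stopifnot(is.numeric(age), all(diff(edges) > 0), length(edges) >= 2)
  i <- findInterval(age, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

# Vasoactive drugs whose initiation qualifies as a hemodynamic intervention.
#' @rdname find_onset
#' @export
vasoactive_drugs <- function() {
  c("dopamine", "dobutamine", "epinephrine", "norepinephrine",
    "neosynephrine", "vasopressin")
}

# internal: FNV-1a 64-bit-ish hash over a string, returned as hex. Used to
# fingerprint the frozen runtime catalogue inside serialized models.
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(s)
  # work in double precision; keep the accumulator below 2^49 by masking to
  # 32 bits after each step (sufficient as a change detector)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (as.numeric(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

catalogue_hash <- function(plausibility = default_plausibility(),
                           staleness = default_staleness()) {
  s <- paste(
    paste(plausibility$feature, plausibility$lower, plausibility$upper,
          sep = ":", collapse = ";"),
    paste(names(staleness), staleness, sep = ":", collapse = ";"),
    paste(composite_features(), collapse = ";"),
    sep = "|"
  )
  fnv1a_hash(s)
}
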