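# Shared fixture builders. All fixtures are generated in code.

t0 <- function() as.POSIXct("2021-03-01 00:00:00", tz = "UTC")

# chart events at hour offsets from t0()
mk_events <- function(feature, hours, value, source = "n/a",
                      encounter_id = "E1") {
  n <- max(length(hours), length(value))
  data.frame(encounter_id = rep_len(encounter_id, n),
             time = t0() + rep_len(hours, n) * 3600,
             feature = rep_len(feature, n),
             value = rep_len(value, n),
             source = rep_len(source, n),
             stringsAsFactors = FALSE)
}

mk_encounter <- function(encounter_id = "E1", patient_id = encounter_id,
                         admission_h = 0, discharge_h = 96, age = 5,
                         ventilated = FALSE, died = FALSE) {
  data.frame(encounter_id = encounter_id, patient_id = patient_id,
             admission_time = t0() + admission_h * 3600,
             discharge_time = t0() + discharge_h * 3600,
             age_years = age, ventilated = ventilated, died = died,
             stringsAsFactors = FALSE)
}

mk_intervention <- function(encounter_id = "E1", hours = 20,
                            kind = "fluid_bolus", rate = 15, drug = NA) {
  data.frame(encounter_id = encounter_id, time = t0() + hours * 3600,
             kind = kind,
             rate_ml_kg_h = ifelse(kind == "fluid_bolus", rate, NA_real_),
             drug = ifelse(kind == "vasoactive", drug, NA_character_),
             stringsAsFactors = FALSE)
}

empty_interventions <- function() {
  data.frame(encounter_id = character(0),
             time = as.POSIXct(character(0), tz = "UTC"),
             kind = character(0), rate_ml_kg_h = numeric(0),
             drug = character(0), stringsAsFactors = FALSE)
}

# small labeled training frame over arbitrary feature columns; labels +/-1
mk_train <- function(features, label, age = NULL) {
  df <- as.data.frame(features)
  df$label <- label
  df$age <- if (is.null(age)) rep(5, nrow(df)) else age
  df
}

# a one-stump model assembled by hand (single age bin over [1/12, 20])
mk_one_stump_model <- function(feature = "heart_rate", threshold = 100,
                               direction = "high_is_unstable", alpha = 0.5) {
  structure(list(
    stumps = list(list(feature = feature, edges = c(1 / 12, 20),
                       threshold = threshold, direction = direction,
                       alpha = alpha)),
    n_rounds = 1L, age_bins = c(1 / 12, 20), epsilon = 0,
    calibration = list(type = "logistic", scale = 2),
    operating_threshold = 0.5,
    catalogue = list(features = c(catalogue_features(), composite_features()),
                     plausibility = default_plausibility(),
                     staleness = default_staleness(),
                     hash = "fixture"),
    diagnostics = NULL, n = 0L, n_pos = 0L, n_neg = 0L, call = NULL
  ), class = "hii_boost")
}
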