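# Episode labeling: composite features, 24-hour last-value extraction,
# intervention-onset labeling with the exclusion rules, and the patient-level
# stratified train/test split.

#' Derive composite features (shock index, OI, OSI)
#'
#' Shock index SI = HR / SBP; oxygenation index
#' OI = (mean airway pressure x FiO2 x 100) / PaO2; oxygen saturation index
#' OSI = (mean airway pressure x FiO2 x 100) / SpO2, with FiO2 as a fraction.
#' A composite is missing whenever any constituent is missing; a zero
#' denominator yields missing (division guard). SBP source preference:
#' invasive when present, else noninvasive.
#'
#' @param v named numeric vector (or data.frame of such columns) holding the
#'   36 base features; missing slots are `NA`.
#' @return `v` with `si`, `oi`, `osi` slots added/overwritten.
#' @export
#' @examples
#' v <- setNames(rep(NA_real_, 3), c("heart_rate", "nsbp", "isbp"))
#' v[c("heart_rate", "nsbp")] <- c(120, 100)
#' derive_composites(v)[["si"]]  # 1.2
derive_composites <- function(v) {
  get1 <- function(nm) {
    if (is.data.frame(v)) {
      if (nm %in% names(v)) v[[nm]] else rep(NA_real_, nrow(v))
    } else {
      if (nm %in% names(v)) unname(v[[nm]]) else NA_real_
    }
  }
  guard <- function(x) ifelse(!is.na(x) & x == 0, NA_real_, x)
  sbp <- ifelse(!is.na(get1("isbp")), get1("isbp"), get1("nsbp"))
  si <- get1("heart_rate") / guard(sbp)
  num <- get1("mean_airway_pressure") * get1("fio2") * 100
  oi <- num / guard(get1("pao2"))
  osi <- num / guard(get1("spo2"))
  if (is.data.frame(v)) {
    v$si <- si; v$oi <- oi; v$osi <- osi
  } else {
    v[["si"]] <- si; v[["oi"]] <- oi; v[["osi"]] <- osi
  }
  v
}

# last value per feature among `events` rows with time in (ref - window, ref]
last_in_window <- function(events, reference_time, window_h) {
  feats <- catalogue_features()
  out <- stats::setNames(rep(NA_real_, length(feats)), feats)
  t <- as.numeric(events$time)
  r <- as.numeric(reference_time)
  ok <- t > r - window_h * 3600 & t <= r
  if (!any(ok)) return(out)
  ev <- events[ok, , drop = FALSE]
  o <- order(as.numeric(ev$time))
  ev <- ev[o, , drop = FALSE]
  last <- !duplicated(ev$feature, fromLast = TRUE)
  out[ev$feature[last]] <- ev$value[last]
  out
}

#' Extract a feature vector from an observation window
#'
#' Takes, per feature, the last measurement whose time lies in the half-open
#' window `(reference_time - window, reference_time]`; features with no
#' measurement in the window are missing. Composites (SI, OI, OSI) are
#' derived afterwards.
#'
#' @param events cleaned, reconciled chart events for one encounter.
#' @param reference_time POSIXct extraction anchor.
#' @param window window length in hours (default 24).
#' @param admission,discharge optional stay bounds; a reference time outside
#'   the stay is rejected.
#' @return Named numeric vector over the 36 features plus `si`, `oi`, `osi`.
#' @export
extract_window <- function(events, reference_time, window = 24,
                           admission = NULL, discharge = NULL) {
  stopifnot(window > 0)
  if (!is.null(admission) && reference_time < admission)
    stop("reference_time precedes admission")
  if (!is.null(discharge) && reference_time > discharge)
    stop("reference_time is after discharge")
  derive_composites(last_in_window(events, reference_time, window))
}

#' Find the onset of hemodynamic intervention
#'
#' The onset is the time of the earliest qualifying intervention: a fluid
#' bolus faster than `fluid_rate_threshold` ml/kg/h (colloid or crystalloid)
#' or initiation of a listed vasoactive drug. Fluid events at or below the
#' threshold never qualify. With no qualifying intervention the encounter is
#' a control candidate and `NA` is returned.
#'
#' @param interventions intervention rows for one encounter.
#' @param fluid_rate_threshold ml/kg/h; default 10.
#' @param drugs qualifying vasoactive drugs; default [vasoactive_drugs()].
#' @return POSIXct onset time, or `NA` if none qualifies.
#' @export
find_onset <- function(interventions, fluid_rate_threshold = 10,
                       drugs = vasoactive_drugs()) {
  if (!nrow(interventions))
    return(as.POSIXct(NA, tz = "UTC"))
  q <- (interventions$kind == "fluid_bolus" &
          !is.na(interventions$rate_ml_kg_h) &
          interventions$rate_ml_kg_h > fluid_rate_threshold) |
       (interventions$kind == "vasoactive" & interventions$drug %in% drugs)
  if (!any(q)) return(as.POSIXct(NA, tz = "UTC"))
  min(interventions$time[q])
}

#' Label a cohort and extract windowed feature vectors
#'
#' Applies the labeling protocol: only each patient's first admission is
#' kept; encounters whose onset falls within the first 6 hours of admission
#' are excluded entirely (instability on arrival is not predictable from PICU
#' data); encounters with a later qualifying intervention are labeled
#' unstable with features extracted at onset (and, optionally, at
#' `onset - L` hours for each requested lead time `L`); encounters with no
#' qualifying intervention are labeled stable with features extracted at a
#' seeded random reference time within the stay. Encounters with no charted
#' events or with age outside \[1/12, 20\] years are excluded. An exclusion
#' ledger (reason -> encounter count) is attached; ledger counts plus emitted
#' encounters always equal the input encounters.
#'
#' Control reference times are drawn uniformly over
#' \[admission + 24 h, discharge\] so a full window is available; stays
#' shorter than that use \[admission + 6 h, discharge\].
#'
#' @param encounters,events,interventions cleaned ingest tables.
#' @param control_seed seed for control reference-time draws.
#' @param lead_times optional vector of lead times (hours); for each unstable
#'   encounter an extra example is emitted at `onset - L` for each `L`.
#' @param window observation window, hours.
#' @param fluid_rate_threshold,drugs passed to [find_onset()].
#' @param exclusions character subset of
#'   `c("not_first_admission", "age_out_of_range", "early_instability",
#'   "no_charted_data")`; all active by default.
#' @return A data.frame of labeled examples (class `hii_examples`): ids,
#'   `label` ("stable"/"unstable"), `onset_time`, `reference_time`,
#'   `lead_time` (hours; 0 at onset, `NA` for controls), `age`, the 36
#'   features and `si`/`oi`/`osi`. Attribute `ledger` holds exclusion counts.
#' @export
label_cohort <- function(encounters, events, interventions,
                         control_seed = 1L, lead_times = NULL, window = 24,
                         fluid_rate_threshold = 10, drugs = vasoactive_drugs(),
                         exclusions = c("not_first_admission", "age_out_of_range",
                                        "early_instability", "no_charted_data")) {
  ledger <- c(not_first_admission = 0L, age_out_of_range = 0L,
              early_instability = 0L, no_charted_data = 0L)
  enc <- encounters[order(encounters$patient_id, encounters$admission_time), ,
                    drop = FALSE]
  if ("not_first_admission" %in% exclusions) {
    dup <- duplicated(enc$patient_id)
    ledger[["not_first_admission"]] <- sum(dup)
    enc <- enc[!dup, , drop = FALSE]
  }
  if ("age_out_of_range" %in% exclusions) {
    bad <- enc$age_years < 1 / 12 | enc$age_years > 20
    ledger[["age_out_of_range"]] <- sum(bad)
    enc <- enc[!bad, , drop = FALSE]
  }
  onset_by_enc <- lapply(split(interventions, interventions$encounter_id),
                         find_onset, fluid_rate_threshold = fluid_rate_threshold,
                         drugs = drugs)
  onset <- rep(as.POSIXct(NA, tz = "UTC"), nrow(enc))
  hit <- match(enc$encounter_id, names(onset_by_enc))
  has <- !is.na(hit)
  if (any(has)) onset[has] <- do.call(c, onset_by_enc[hit[has]])
  if ("early_instability" %in% exclusions) {
    early <- !is.na(onset) & onset < enc$admission_time + 6 * 3600
    ledger[["early_instability"]] <- sum(early)
    enc <- enc[!early, , drop = FALSE]
    onset <- onset[!early]
  }
  ev_ids <- unique(events$encounter_id)
  if ("no_charted_data" %in% exclusions) {
    none <- !enc$encounter_id %in% ev_ids
    ledger[["no_charted_data"]] <- sum(none)
    enc <- enc[!none, , drop = FALSE]
    onset <- onset[!none]
  }

  unstable <- !is.na(onset)
  # control reference times: seeded, drawn in (sorted) encounter order
  ref_ctl <- rep(as.POSIXct(NA, tz = "UTC"), nrow(enc))
  if (any(!unstable)) {
    adm <- as.numeric(enc$admission_time[!unstable])
    dis <- as.numeric(enc$discharge_time[!unstable])
    lo <- ifelse(dis >= adm + 24 * 3600, adm + 24 * 3600,
                 pmin(adm + 6 * 3600, dis))
    u <- with_seed(control_seed, stats::runif(length(adm)))
    ref_ctl[!unstable] <- as.POSIXct(round((lo + u * (dis - lo)) / 60) * 60,
                                     origin = "1970-01-01", tz = "UTC")
  }

  # assemble (encounter row, reference_time, lead_time) extraction requests
  req_row <- integer(0); req_ref <- numeric(0); req_lead <- numeric(0)
  for (i in seq_len(nrow(enc))) {
    if (unstable[i]) {
      lt <- c(0, lead_times)
      rf <- as.numeric(onset[i]) - lt * 3600
      keep <- rf >= as.numeric(enc$admission_time[i])
      req_row <- c(req_row, rep(i, sum(keep)))
      req_ref <- c(req_ref, rf[keep])
      req_lead <- c(req_lead, lt[keep])
    } else {
      req_row <- c(req_row, i)
      req_ref <- c(req_ref, as.numeric(ref_ctl[i]))
      req_lead <- c(req_lead, NA_real_)
    }
  }

  feats <- catalogue_features()
  ev_t <- as.numeric(events$time)
  ev_f <- match(events$feature, feats)
  ev_v <- events$value
  o <- order(events$encounter_id, ev_t)   # time-sorted within encounter
  ev_idx <- split(o, events$encounter_id[o])
  X <- matrix(NA_real_, nrow = length(req_row), ncol = length(feats),
              dimnames = list(NULL, feats))
  win_s <- window * 3600
  for (k in seq_along(req_row)) {
    idx <- ev_idx[[enc$encounter_id[req_row[k]]]]
    if (is.null(idx)) next
    t <- ev_t[idx]
    sel <- idx[t > req_ref[k] - win_s & t <= req_ref[k]]
    if (!length(sel)) next
    f <- ev_f[sel]
    last <- !duplicated(f, fromLast = TRUE)
    X[k, f[last]] <- ev_v[sel][last]
  }
  out <- data.frame(
    encounter_id = enc$encounter_id[req_row],
    patient_id = enc$patient_id[req_row],
    label = ifelse(unstable[req_row], "unstable", "stable"),
    onset_time = onset[req_row],
    reference_time = as.POSIXct(req_ref, origin = "1970-01-01", tz = "UTC"),
    lead_time = req_lead,
    age = enc$age_years[req_row],
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(X))
  out <- derive_composites(out)
  attr(out, "ledger") <- ledger
  attr(out, "emitted_encounters") <- nrow(enc)
  class(out) <- c("hii_examples", "data.frame")
  out
}

#' Patient-level stratified train/test split
#'
#' Splits labeled examples into a training(+cross-validation) set and a test
#' set at the patient level — no patient contributes to both — stratified by
#' label so class proportions match within rounding.
#'
#' @param examples labeled examples from [label_cohort()].
#' @param train_fraction proportion of patients per class assigned to
#'   training (default 0.9).
#' @param seed integer split seed.
#' @return list with elements `train` and `test`.
#' @export
split_dataset <- function(examples, train_fraction = 0.9, seed = 1L) {
  stopifnot(nrow(examples) >= 10, train_fraction > 0, train_fraction <= 1)
  pat <- unique(examples[, c("patient_id", "label")])
  if (any(duplicated(pat$patient_id)))
    stop("a patient carries conflicting labels")
  if (length(unique(pat$label)) < 2)
    stop("both classes must be present to split")
  train_pat <- with_seed(seed, {
    unlist(lapply(split(pat$patient_id, pat$label), function(ids) {
      n_tr <- round(train_fraction * length(ids))
      sample(ids, n_tr)
    }), use.names = FALSE)
  })
  tr <- examples[examples$patient_id %in% train_pat, , drop = FALSE]
  te <- examples[!examples$patient_id %in% train_pat, , drop = FALSE]
  if (!nrow(te)) warning("train_fraction leaves an empty test set")
  list(train = tr, test = te)
}

#' Export labeled examples as a delimited feature matrix
#'
#' One row per example, one column per feature, explicit `NA` token, with the
#' label and lead-time columns; the exclusion ledger is written alongside as
#' `<path>.ledger`.
#' @param examples from [label_cohort()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_examples <- function(examples, path) {
  df <- as.data.frame(examples)
  for (cl in c("onset_time", "reference_time"))
    df[[cl]] <- format(df[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  led <- attr(examples, "ledger")
  if (!is.null(led))
    utils::write.csv(data.frame(reason = names(led), count = as.integer(led)),
                     paste0(path, ".ledger"), row.names = FALSE)
  invisible(path)
}
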