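# Synthetic PICU cohort generation.
#
# The simulator emits the three ingest tables (encounters, chart events,
# interventions) with the statistical structure the pipeline assumes:
# age-dependent baseline physiology, per-feature recording sparsity,
# invasive/noninvasive blood-pressure co-occurrence, and a monotone
# pre-intervention drift toward the shock phenotype (tachycardia,
# hypotension, acidosis, oliguria, rising lactate) for unstable patients.

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-patient sub-stream seed, kept below 2^31 - 1
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483646) + 1L
}

sim_epoch <- function() as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

#' Default deterioration effect sizes
#'
#' Standardized drift magnitudes (units of the feature's age-specific SD)
#' reached at intervention onset for unstable patients. Signs follow the
#' physiology of compensated shock: heart rate and lactate rise; blood
#' pressures, pH, base excess and urine output fall. Features not listed do
#' not drift.
#' @return Named numeric vector of per-feature standardized drifts.
#' @export
default_effect_sizes <- function() {
  c(heart_rate = 2, nsbp = -1.5, isbp = -1.5, nmbp = -1.2, imbp = -1.2,
    ndbp = -1, idbp = -1, ph = -1.5, base_excess = -1.5,
    lactic_acid = 2, urine_output = -1.5)
}

#' Simulation configuration
#'
#' Defines the study conditions for a synthetic PICU cohort. Defaults follow
#' the cohort the model targets: 42% instability prevalence, ages 1 month to
#' 20 years uniform over five strata, per-feature recording probabilities at
#' the catalogue defaults, a 70/30 fluid-bolus/vasoactive intervention mix,
#' and a 24-hour linear deterioration ramp ending at intervention onset.
#'
#' @param n_patients number of patients (one encounter each).
#' @param unstable_fraction proportion of patients receiving a qualifying
#'   intervention, in \[0, 1\].
#' @param age_weights sampling weights over the five age strata of
#'   [default_age_bins()].
#' @param recording data.frame with columns `feature`, `record_prob`,
#'   `interval_h`: probability a patient ever has the feature recorded and
#'   mean inter-measurement interval in hours. Defaults from
#'   [feature_catalogue()].
#' @param effect_sizes named numeric vector of standardized drifts at onset;
#'   see [default_effect_sizes()]. Use `numeric(0)` (or all zeros) for a
#'   null cohort.
#' @param deterioration_duration hours before onset over which the drift
#'   ramps linearly from 0 to its full size; must be positive.
#' @param noise_sd_scale multiplier on the reference-curve SDs.
#' @param invasive_bp_prob per-patient probability of an arterial line
#'   (invasive blood pressure stream); invasive and noninvasive streams
#'   co-occur for these patients.
#' @param fluid_fraction proportion of interventions that are fluid boluses
#'   (the rest are vasoactive starts).
#' @param curves named list of [reference_curve()] objects; defaults to
#'   [default_reference_curves()].
#' @param seed integer; identical (config, seed) pairs reproduce identical
#'   cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 1000,
                       unstable_fraction = 0.42,
                       age_weights = rep(1, 5),
                       recording = feature_catalogue()[, c("feature", "record_prob", "interval_h")],
                       effect_sizes = default_effect_sizes(),
                       deterioration_duration = 24,
                       noise_sd_scale = 1,
                       invasive_bp_prob = 0.5,
                       fluid_fraction = 0.7,
                       curves = default_reference_curves(),
                       seed = 1L) {
  stopifnot(n_patients >= 1,
            unstable_fraction >= 0, unstable_fraction <= 1,
            length(age_weights) == length(default_age_bins()) - 1,
            all(age_weights >= 0), sum(age_weights) > 0,
            all(c("feature", "record_prob", "interval_h") %in% names(recording)),
            all(recording$record_prob >= 0 & recording$record_prob <= 1),
            all(recording$interval_h > 0),
            deterioration_duration > 0,
            noise_sd_scale >= 0,
            invasive_bp_prob >= 0, invasive_bp_prob <= 1,
            fluid_fraction >= 0, fluid_fraction <= 1)
  if (!setequal(recording$feature, catalogue_features()))
    stop("recording table must cover exactly the 36 catalogue features")
  es <- effect_sizes[names(effect_sizes) %in% catalogue_features()]
  if (length(effect_sizes) && !length(es) && any(effect_sizes != 0))
    stop("effect_sizes names must be canonical catalogue features")
  structure(list(
    n_patients = as.integer(n_patients),
    unstable_fraction = unstable_fraction,
    age_weights = age_weights / sum(age_weights),
    recording = recording,
    effect_sizes = es,
    deterioration_duration = deterioration_duration,
    noise_sd_scale = noise_sd_scale,
    invasive_bp_prob = invasive_bp_prob,
    fluid_fraction = fluid_fraction,
    curves = curves,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("PICU cohort simulation config\n")
  cat(sprintf("  patients: %d, unstable fraction: %.2f, seed: %d\n",
              x$n_patients, x$unstable_fraction, x$seed))
  cat(sprintf("  deterioration ramp: %g h, noise scale: %g, arterial line p: %g\n",
              x$deterioration_duration, x$noise_sd_scale, x$invasive_bp_prob))
  cat(sprintf("  drifting features: %s\n",
              paste(names(x$effect_sizes)[x$effect_sizes != 0], collapse = ", ")))
  invisible(x)
}

# which features a given patient can have recorded, with recording
# probability and cadence. Invasive BPs require an arterial line (drawn
# label-independently); every other feature records as an independent
# Bernoulli at its configured rate. Recording is deliberately independent of
# the label so that with zero effect sizes the two groups are exchangeable:
# presence patterns never carry outcome information in the simulator.
patient_recordable <- function(config, has_line, ventilated) {
  rec <- config$recording
  keep <- rep(TRUE, nrow(rec))
  inv <- rec$feature %in% c("imbp", "isbp", "idbp")
  keep[inv] <- has_line
  rec$record_prob[inv & keep] <- 1       # the line itself is the gate
  rec[keep, , drop = FALSE]
}

#' Simulate one patient's charted trajectory
#'
#' Samples per-feature event streams around the patient's age-specific
#' reference curves. When `onset` is given (an unstable patient), feature
#' means drift monotonically toward the shock direction over
#' `[onset - deterioration_duration, onset]`, scaled by the configured
#' standardized effect sizes; outside that window sampling is at baseline.
#' Events stop shortly after onset (the post-intervention course is not
#' modelled).
#'
#' @param patient one-row data.frame with `encounter_id`, `admission_time`,
#'   `discharge_time`, `age_years`, `ventilated`, and logical `has_line`.
#' @param onset intervention time (POSIXct) or `NULL` for a stable patient;
#'   must be at least 6 hours after admission.
#' @param config a [sim_config()].
#' @param seed integer sub-stream seed for this patient.
#' @return data.frame of chart events: `encounter_id`, `time`, `feature`,
#'   `value`, `source`.
#' @export
trajectory <- function(patient, onset, config, seed = config$seed) {
  core <- trajectory_core(
    adm = as.numeric(patient$admission_time),
    dis = as.numeric(patient$discharge_time),
    age = patient$age_years,
    has_line = isTRUE(patient$has_line),
    ventilated = isTRUE(patient$ventilated),
    onset = if (is.null(onset)) NULL else as.numeric(onset),
    config = config, seed = seed
  )
  src <- rep("n/a", length(core$feature))
  src[core$feature %in% c("isbp", "idbp", "imbp")] <- "invasive"
  src[core$feature %in% c("nsbp", "ndbp", "nmbp")] <- "noninvasive"
  data.frame(
    encounter_id = rep(patient$encounter_id, length(core$feature)),
    time = as.POSIXct(core$time, origin = "1970-01-01", tz = "UTC"),
    feature = core$feature,
    value = core$value,
    source = src,
    stringsAsFactors = FALSE
  )
}

# vector-level trajectory generator shared by trajectory() and
# simulate_cohort(); times in epoch seconds
trajectory_core <- function(adm, dis, age, has_line, ventilated, onset,
                            config, seed) {
  if (!is.null(onset)) {
    if (onset < adm + 6 * 3600)
      stop("onset must be at least 6 hours after admission")
    if (onset > dis) stop("onset must fall within the stay")
  }
  end_time <- if (is.null(onset)) dis else min(dis, onset + 6 * 3600)
  horizon_h <- (end_time - adm) / 3600
  rec <- patient_recordable(config, has_line, ventilated)
  plaus <- config$plaus_cache
  if (is.null(plaus)) {
    p <- default_plausibility()
    plaus <- list(lo = stats::setNames(p$lower, p$feature),
                  hi = stats::setNames(p$upper, p$feature))
  }
  es <- config$effect_sizes
  D <- config$deterioration_duration

  feats <- times <- vals <- vector("list", nrow(rec))
  with_seed(seed, {
    recorded <- stats::runif(nrow(rec)) <= rec$record_prob
    for (j in which(recorded)) {
      f <- rec$feature[j]
      iv <- rec$interval_h[j]
      n_max <- ceiling(horizon_h / iv * 3) + 5
      gaps <- stats::rexp(n_max, rate = 1 / iv)
      t_h <- stats::runif(1, 0, iv) + cumsum(c(0, gaps))
      t_h <- t_h[t_h <= horizon_h]
      if (!length(t_h)) next
      ref <- reference_value(config$curves[[f]], age)
      mu <- rep(ref$mean, length(t_h))
      sdv <- ref$sd * config$noise_sd_scale
      if (!is.null(onset) && f %in% names(es) && es[[f]] != 0) {
        onset_h <- (onset - adm) / 3600
        ramp <- pmin(pmax((t_h - (onset_h - D)) / D, 0), 1)
        mu <- mu + es[[f]] * ref$sd * ramp
      }
      v <- stats::rnorm(length(t_h), mu, sdv)
      v <- pmin(pmax(v, plaus$lo[[f]]), plaus$hi[[f]])
      feats[[j]] <- rep(f, length(t_h))
      times[[j]] <- adm + round(t_h * 60) * 60  # minute resolution
      vals[[j]] <- v
    }
  })
  list(feature = unlist(feats, use.names = FALSE),
       time = unlist(times, use.names = FALSE),
       value = unlist(vals, use.names = FALSE))
}

#' Simulate a synthetic PICU cohort
#'
#' Generates encounter demographics, charted observations and intervention
#' events for `config$n_patients` patients. Unstable patients (a
#' `round(unstable_fraction * n)` subset) receive exactly one qualifying
#' intervention — a fluid bolus above 10 ml/kg/h or a vasoactive start —
#' placed later than 6 hours after admission, preceded by the configured
#' physiological drift. Identical (config, seed) pairs reproduce identical
#' tables; each patient draws from its own deterministic sub-stream.
#'
#' @param config a [sim_config()].
#' @return An object of class `hii_cohort`: a list with data.frames
#'   `encounters`, `chart`, `interventions`, plus the `config`.
#' @export
#' @examples
#' co <- simulate_cohort(sim_config(n_patients = 30, seed = 7))
#' nrow(co$encounters)
#' table(co$interventions$kind)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  n_unstable <- round(config$unstable_fraction * n)
  if (config$unstable_fraction > 0 && n_unstable < 1)
    warning("unstable_fraction * n_patients < 1; generating an all-stable cohort")
  edges <- default_age_bins()

  cohort_draws <- with_seed(config$seed, {
    unstable <- rep(FALSE, n)
    if (n_unstable >= 1) unstable[sample.int(n, n_unstable)] <- TRUE
    stratum <- sample.int(length(edges) - 1, n, replace = TRUE,
                          prob = config$age_weights)
    age <- stats::runif(n, edges[stratum], edges[stratum + 1])
    ventilated <- stats::runif(n) < ifelse(unstable, 0.561, 0.285)
    died <- stats::runif(n) < ifelse(unstable, 0.060, 0.011)
    has_line <- stats::runif(n) < config$invasive_bp_prob
    onset_h <- stats::runif(n, 12, 72)                  # > 6 h by construction
    post_onset_h <- pmin(stats::rlnorm(n, log(10 * 24), 0.6), 45 * 24)
    los_h <- ifelse(unstable,
                    onset_h + post_onset_h,
                    pmin(pmax(stats::rlnorm(n, log(3 * 24), 0.6), 12), 45 * 24))
    kind <- ifelse(stats::runif(n) < config$fluid_fraction,
                   "fluid_bolus", "vasoactive")
    rate <- stats::runif(n, 11, 30)
    drug <- sample(vasoactive_drugs(), n, replace = TRUE)
    list(unstable = unstable, age = age, ventilated = ventilated, died = died,
         has_line = has_line, onset_h = onset_h, los_h = los_h,
         kind = kind, rate = rate, drug = drug)
  })

  d <- cohort_draws
  enc_id <- sprintf("E%05d", seq_len(n))
  admission <- sim_epoch() + (seq_len(n) - 1) * 6 * 3600
  discharge <- admission + round(d$los_h * 60) * 60
  encounters <- data.frame(
    encounter_id = enc_id,
    patient_id = sprintf("P%05d", seq_len(n)),
    admission_time = admission,
    discharge_time = discharge,
    age_years = d$age,
    ventilated = d$ventilated,
    died = d$died,
    stringsAsFactors = FALSE
  )

  iv <- which(d$unstable)
  interventions <- data.frame(
    encounter_id = enc_id[iv],
    time = admission[iv] + round(d$onset_h[iv] * 60) * 60,
    kind = d$kind[iv],
    rate_ml_kg_h = ifelse(d$kind[iv] == "fluid_bolus", d$rate[iv], NA_real_),
    drug = ifelse(d$kind[iv] == "vasoactive", d$drug[iv], NA_character_),
    stringsAsFactors = FALSE
  )

  p <- default_plausibility()
  config$plaus_cache <- list(lo = stats::setNames(p$lower, p$feature),
                             hi = stats::setNames(p$upper, p$feature))
  adm_num <- as.numeric(admission)
  onset_num <- rep(NA_real_, n)
  onset_num[iv] <- as.numeric(interventions$time)
  cores <- vector("list", n)
  for (i in seq_len(n)) {
    cores[[i]] <- trajectory_core(
      adm = adm_num[i], dis = as.numeric(discharge[i]), age = d$age[i],
      has_line = d$has_line[i], ventilated = d$ventilated[i],
      onset = if (d$unstable[i]) onset_num[i] else NULL,
      config = config, seed = patient_seed(config$seed, i))
  }
  counts <- vapply(cores, function(x) length(x$feature), integer(1))
  feature <- unlist(lapply(cores, `[[`, "feature"), use.names = FALSE)
  src <- rep("n/a", length(feature))
  src[feature %in% c("isbp", "idbp", "imbp")] <- "invasive"
  src[feature %in% c("nsbp", "ndbp", "nmbp")] <- "noninvasive"
  chart <- data.frame(
    encounter_id = rep(enc_id, counts),
    time = as.POSIXct(unlist(lapply(cores, `[[`, "time"), use.names = FALSE),
                      origin = "1970-01-01", tz = "UTC"),
    feature = feature,
    value = unlist(lapply(cores, `[[`, "value"), use.names = FALSE),
    source = src,
    stringsAsFactors = FALSE
  )
  config$plaus_cache <- NULL

  structure(list(encounters = encounters, chart = chart,
                 interventions = interventions, config = config),
            class = "hii_cohort")
}

#' @export
print.hii_cohort <- function(x, ...) {
  cat(sprintf("Synthetic PICU cohort: %d encounters, %d chart events, %d interventions\n",
              nrow(x$encounters), nrow(x$chart), nrow(x$interventions)))
  invisible(x)
}

#' Write a simulated cohort as delimited text
#'
#' Writes `encounters.csv`, `chart.csv` and `interventions.csv` to `dir`,
#' each prefixed with a `#`-commented provenance header recording the package
#' version and simulation seed. The files conform to the ingest schema of
#' [read_tables()].
#'
#' @param cohort an `hii_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hii_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("# hiiboost %s cohort_sim seed=%d n=%d",
                 as.character(utils::packageVersion("hiiboost")),
                 cohort$config$seed, cohort$config$n_patients)
  fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  paths <- file.path(dir, c("encounters.csv", "chart.csv", "interventions.csv"))
  enc <- cohort$encounters
  enc$admission_time <- fmt_time(enc$admission_time)
  enc$discharge_time <- fmt_time(enc$discharge_time)
  ch <- cohort$chart
  ch$time <- fmt_time(ch$time)
  itv <- cohort$interventions
  itv$time <- fmt_time(itv$time)
  for (p in seq_along(paths)) {
    con <- file(paths[p], "w")
    writeLines(hdr, con)
    utils::write.csv(list(enc, ch, itv)[[p]], con, row.names = FALSE,
                     quote = FALSE, na = "")
    close(con)
  }
  invisible(paths)
}
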