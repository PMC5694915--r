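# Clinical ingest: typed reading of the three raw tables, plausibility
# filtering, invasive/noninvasive blood-pressure reconciliation, and the
# measurement-staleness gate applied at scoring time.

parse_time_utc <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  # minute resolution throughout
  as.POSIXct(round(as.numeric(out) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

read_delim_guess <- function(path) {
  head1 <- readLines(path, n = 50)
  head1 <- head1[!startsWith(head1, "#")]
  sep <- if (grepl("\t", head1[1])) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = c("", "NA", "NaN"),
                    colClasses = "character")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
}

#' Read the raw encounter, chart-event and intervention tables
#'
#' Reads the three delimited text files (comma default, tab accepted;
#' `#`-prefixed provenance lines skipped), types and validates them,
#' normalizes timestamps to UTC minute resolution, and canonicalizes feature
#' names via the alias map. Rows that cannot be parsed — non-numeric values,
#' unknown feature names, unparseable timestamps — are dropped with a warning
#' and counted in the `drops` attribute; a missing required column is a hard
#' error naming the column.
#'
#' @param encounters_path,chart_path,interventions_path file paths.
#' @param aliases alias map from [feature_aliases()].
#' @return A list with typed data.frames `encounters`, `chart`,
#'   `interventions`; the `chart` element carries a `drops` attribute (named
#'   counts of dropped rows by reason).
#' @export
read_tables <- function(encounters_path, chart_path, interventions_path,
                        aliases = feature_aliases()) {
  enc <- read_delim_guess(encounters_path)
  require_columns(enc, c("encounter_id", "patient_id", "admission_time",
                         "discharge_time", "age_years"), "encounters")
  enc$admission_time <- parse_time_utc(enc$admission_time)
  enc$discharge_time <- parse_time_utc(enc$discharge_time)
  enc$age_years <- as.numeric(enc$age_years)
  enc$ventilated <- if ("ventilated" %in% names(enc))
    as.logical(enc$ventilated) else NA
  enc$died <- if ("died" %in% names(enc)) as.logical(enc$died) else NA
  bad <- enc$discharge_time <= enc$admission_time
  if (any(bad, na.rm = TRUE))
    stop("encounters with discharge_time <= admission_time: ",
         paste(enc$encounter_id[which(bad)], collapse = ", "))

  ch <- read_delim_guess(chart_path)
  require_columns(ch, c("encounter_id", "time", "feature", "value"), "chart")
  if (!"source" %in% names(ch)) ch$source <- "n/a"
  drops <- c(unknown_feature = 0L, non_numeric_value = 0L, bad_time = 0L)
  feat <- canonical_feature(ch$feature, aliases)
  if (anyNA(feat)) {
    bad_names <- unique(ch$feature[is.na(feat)])
    drops[["unknown_feature"]] <- sum(is.na(feat))
    warning("dropping rows with unknown feature name(s): ",
            paste(bad_names, collapse = ", "))
  }
  val <- suppressWarnings(as.numeric(ch$value))
  nn <- !is.na(ch$value) & is.na(val)
  if (any(nn)) {
    drops[["non_numeric_value"]] <- sum(nn)
    warning(sprintf("dropping %d chart row(s) with non-numeric values", sum(nn)))
  }
  tm <- suppressWarnings(parse_time_utc(ch$time))
  bt <- is.na(tm)
  if (any(bt)) {
    drops[["bad_time"]] <- sum(bt)
    warning(sprintf("dropping %d chart row(s) with unparseable timestamps", sum(bt)))
  }
  keep <- !is.na(feat) & !is.na(val) & !bt
  ch <- data.frame(encounter_id = ch$encounter_id[keep], time = tm[keep],
                   feature = feat[keep], value = val[keep],
                   source = ifelse(is.na(ch$source[keep]), "n/a", ch$source[keep]),
                   stringsAsFactors = FALSE)
  # FiO2 charted as a percentage is converted to a fraction
  pct <- ch$feature == "fio2" & ch$value > 1
  ch$value[pct] <- ch$value[pct] / 100
  ch <- ch[order(ch$encounter_id, ch$time), , drop = FALSE]
  row.names(ch) <- NULL
  attr(ch, "drops") <- drops

  itv <- read_delim_guess(interventions_path)
  require_columns(itv, c("encounter_id", "time", "kind"), "interventions")
  if (!"rate_ml_kg_h" %in% names(itv)) itv$rate_ml_kg_h <- NA
  if (!"drug" %in% names(itv)) itv$drug <- NA
  itv <- data.frame(encounter_id = itv$encounter_id,
                    time = parse_time_utc(itv$time),
                    kind = itv$kind,
                    rate_ml_kg_h = suppressWarnings(as.numeric(itv$rate_ml_kg_h)),
                    drug = tolower(trimws(as.character(itv$drug))),
                    stringsAsFactors = FALSE)
  bad_kind <- !itv$kind %in% c("fluid_bolus", "vasoactive")
  if (any(bad_kind)) stop("unknown intervention kind: ",
                          paste(unique(itv$kind[bad_kind]), collapse = ", "))
  if (any(itv$kind == "fluid_bolus" & is.na(itv$rate_ml_kg_h)))
    stop("fluid_bolus interventions require rate_ml_kg_h")
  bad_drug <- itv$kind == "vasoactive" & !itv$drug %in% vasoactive_drugs()
  if (any(bad_drug))
    stop("vasoactive interventions require a drug from: ",
         paste(vasoactive_drugs(), collapse = ", "))

  list(encounters = enc, chart = ch, interventions = itv)
}

#' Plausibility filter
#'
#' Removes chart events whose values fall outside the per-feature
#' physiologically valid range; downstream these become missing values. The
#' bounds table must cover every feature present (it is total over the
#' catalogue by default). Idempotent.
#'
#' @param events chart-event data.frame (`feature`, `value`, ...).
#' @param table plausibility table with `feature`, `lower`, `upper`; defaults
#'   to [default_plausibility()].
#' @return Filtered events; attribute `removed` holds per-feature removal
#'   counts.
#' @export
plausibility_filter <- function(events, table = default_plausibility()) {
  stopifnot(all(table$lower < table$upper))
  idx <- match(events$feature, table$feature)
  if (anyNA(idx))
    stop("plausibility table lacks bounds for: ",
         paste(unique(events$feature[is.na(idx)]), collapse = ", "))
  ok <- events$value >= table$lower[idx] & events$value <= table$upper[idx]
  removed <- table(factor(events$feature[!ok], levels = sort(unique(events$feature))))
  out <- events[ok, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "removed") <- removed[removed > 0]
  out
}

bp_components <- function() {
  list(sbp = c(invasive = "isbp", noninvasive = "nsbp"),
       dbp = c(invasive = "idbp", noninvasive = "ndbp"),
       mbp = c(invasive = "imbp", noninvasive = "nmbp"))
}

#' Reconcile invasive and noninvasive blood pressure
#'
#' When a noninvasive systolic/mean/diastolic pressure is charted within
#' `proximity` minutes of an invasive measurement of the same component in
#' the same encounter, the noninvasive reading is removed and the invasive
#' one used instead (an arterial line is the more reliable source). Invasive
#' events are never removed; a single-source stream passes unchanged.
#' Idempotent.
#'
#' @param events chart-event data.frame.
#' @param proximity window in minutes (default 20).
#' @return Events with superseded noninvasive BP rows removed.
#' @export
reconcile_bp <- function(events, proximity = 20) {
  stopifnot(proximity >= 0)
  drop <- rep(FALSE, nrow(events))
  for (comp in bp_components()) {
    ni <- which(events$feature == comp[["noninvasive"]])
    if (!length(ni)) next
    inv <- events[events$feature == comp[["invasive"]],
                  c("encounter_id", "time"), drop = FALSE]
    if (!nrow(inv)) next
    by_enc <- split(as.numeric(inv$time), inv$encounter_id)
    t_ni <- as.numeric(events$time[ni])
    enc_ni <- events$encounter_id[ni]
    for (k in seq_along(ni)) {
      ti <- by_enc[[enc_ni[k]]]
      if (is.null(ti)) next
      if (any(abs(ti - t_ni[k]) <= proximity * 60)) drop[ni[k]] <- TRUE
    }
  }
  out <- events[!drop, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Current-value snapshot under staleness rules
#'
#' For one encounter's events, returns the most recent value per feature
#' whose age at `now` is within the feature's staleness horizon (1 hour for
#' blood pressures and ventilator parameters, 24 hours for laboratory values
#' and other vitals); otherwise the feature is missing. Only events with
#' `time <= now` are considered — there is no lookahead. Simultaneous
#' duplicates resolve to the last row read.
#'
#' @param events chart events for a single encounter.
#' @param now POSIXct evaluation time.
#' @param staleness named vector of horizons in hours; defaults to
#'   [default_staleness()].
#' @param admission optional admission time; `now` earlier than it is
#'   rejected.
#' @return Named numeric vector over the 36 catalogue features (NA where
#'   missing).
#' @export
staleness_gate <- function(events, now, staleness = default_staleness(),
                           admission = NULL) {
  if (!is.null(admission) && now < admission)
    stop("evaluation time precedes admission")
  feats <- catalogue_features()
  out <- stats::setNames(rep(NA_real_, length(feats)), feats)
  if (!nrow(events)) return(out)
  horizon_s <- staleness[events$feature] * 3600
  age_s <- as.numeric(now) - as.numeric(events$time)
  ok <- age_s >= 0 & age_s <= horizon_s
  ev <- events[ok, , drop = FALSE]
  if (!nrow(ev)) return(out)
  o <- order(ev$time)                     # stable: ties keep file order
  ev <- ev[o, , drop = FALSE]
  last <- !duplicated(ev$feature, fromLast = TRUE)
  out[ev$feature[last]] <- ev$value[last]
  out
}
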