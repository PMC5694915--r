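# Structured-text (JSON) model serialization. Numeric fields are written as
# "%.17g" strings so a write/read cycle reproduces every double bit-exactly,
# and identical models always serialize to identical bytes.

num_out <- function(x) vapply(x, function(v)
  if (is.na(v)) "NA" else sprintf("%.17g", v), character(1))
num_in <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  out[s == "NA"] <- NA_real_
  out
}

MODEL_FORMAT_VERSION <- "hii_boost/1"

#' Serialize a fitted model to structured text
#'
#' Writes the stump ensemble, age bins, probability calibration, operating
#' threshold and a hash of the frozen runtime catalogue (plausibility bounds
#' and staleness horizons) as JSON. Doubles are encoded at full precision, so
#' the round trip is bit-exact and identical models produce byte-identical
#' files.
#'
#' @param model fitted [hii_boost()] model.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [read_hii_model()]
#' @export
write_hii_model <- function(model, path) {
  stopifnot(inherits(model, "hii_boost"))
  obj <- list(
    format = MODEL_FORMAT_VERSION,
    catalogue_hash = model$catalogue$hash,
    age_bins = num_out(model$age_bins),
    epsilon = num_out(model$epsilon),
    calibration = list(type = model$calibration$type,
                       scale = num_out(model$calibration$scale)),
    operating_threshold = num_out(model$operating_threshold),
    n_rounds = model$n_rounds,
    stumps = lapply(model$stumps, function(st) list(
      feature = st$feature,
      threshold = num_out(st$threshold),
      direction = st$direction,
      alpha = num_out(st$alpha)
    ))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a serialized model
#'
#' Rebuilds an `hii_boost` object from [write_hii_model()] output. The stored
#' catalogue hash must match the package's runtime catalogue (plausibility
#' bounds + staleness horizons); a mismatch means the model was trained
#' against different runtime rules and loading is refused.
#'
#' @param path file written by [write_hii_model()].
#' @return An `hii_boost` model.
#' @export
read_hii_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!identical(obj$format, MODEL_FORMAT_VERSION))
    stop("unsupported model format: ", obj$format)
  hash_now <- catalogue_hash()
  if (!identical(obj$catalogue_hash, hash_now))
    stop("catalogue hash mismatch: model was serialized against a different ",
         "feature catalogue (", obj$catalogue_hash, " vs ", hash_now, ")")
  age_bins <- num_in(unlist(obj$age_bins))
  stumps <- lapply(obj$stumps, function(st) list(
    feature = st$feature,
    edges = age_bins,
    threshold = num_in(unlist(st$threshold)),
    direction = unlist(st$direction),
    alpha = num_in(st$alpha)
  ))
  structure(list(
    stumps = stumps,
    n_rounds = obj$n_rounds,
    age_bins = age_bins,
    epsilon = num_in(obj$epsilon),
    calibration = list(type = obj$calibration$type,
                       scale = num_in(obj$calibration$scale)),
    operating_threshold = num_in(obj$operating_threshold),
    catalogue = list(
      features = c(catalogue_features(), composite_features()),
      plausibility = default_plausibility(),
      staleness = default_staleness(),
      hash = hash_now
    ),
    diagnostics = NULL,
    n = NA_integer_, n_pos = NA_integer_, n_neg = NA_integer_,
    call = NULL
  ), class = "hii_boost")
}
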