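# Per-analyte scale coefficients C_i, global bias delta, prediction and
# scoring against a truth panel, model persistence.

#' Fit per-analyte scale coefficients
#'
#' For each analyte the scalar `C_i` minimizing
#' `sum_s (C * K_s - B_{i,s})^2` has the closed form
#' `C_i = sum_s K_s B_{i,s} / sum_s K_s^2`; no iterative solver is needed.
#'
#' @param K Numeric vector of per-sample composite feature values.
#' @param conc Concentration matrix/data.frame (samples x analytes), rows
#'   aligned with `K`.
#' @return Named numeric vector of coefficients, one per analyte.
#' @export
fit_scale_coefficients <- function(K, conc) {
  conc <- as_conc_matrix(conc)
  if (length(K) != nrow(conc)) stop("K and concentrations have misaligned samples")
  if (all(K == 0)) stop("all-zero K")
  if (anyNA(conc)) stop("missing analyte values")
  drop(crossprod(K, conc)) / sum(K^2)
}

#' Estimate the global multiplicative bias
#'
#' The calibration systematically overpredicts by a few percent; the
#' correction is a single factor `(1 - delta)` shared by all analytes.
#' `delta = 1 - f*` where `f*` minimizes the *relative* squared error
#' `sum ((f * pred - truth) / truth)^2`, so high-concentration analytes do
#' not dominate. Closed form: with `r = pred / truth`,
#' `f* = sum(r) / sum(r^2)`.
#'
#' @param predicted Numeric vector/matrix of uncorrected predictions.
#' @param truth Matching true concentrations (all > 0).
#' @return delta (dimensionless; 0 for unbiased predictions).
#' @export
estimate_bias <- function(predicted, truth) {
  p <- as.numeric(predicted); tr <- as.numeric(truth)
  if (length(p) == 0) stop("empty input")
  if (length(p) != length(tr)) stop("shape mismatch")
  if (any(tr <= 0)) stop("truth values must be positive")
  r <- p / tr
  1 - sum(r) / sum(r^2)
}

#' Predict the full analyte panel from band features
#'
#' `B_i = C_i * K * (1 - delta)` for every panel analyte, with `K` evaluated
#' from the model's composite feature.
#'
#' @param model An `ftir_calibration` (see [ftir_calibrate()]) or any list
#'   with `composite`, `coefficients`, `delta` and optionally `panel`.
#' @param features Named numeric vector of feature values (or matrix,
#'   rows = samples).
#' @param warn_range Warn when predictions leave the panel's calibration
#'   ranges? Default `TRUE`.
#' @return Named numeric vector of concentrations in panel units (or a
#'   samples x analytes matrix).
#' @export
predict_panel <- function(model, features, warn_range = TRUE) {
  K <- evaluate_composite(model$composite, features)
  C <- model$coefficients
  out <- outer(K, C) * (1 - model$delta)
  rownames(out) <- if (is.matrix(features)) rownames(features) else NULL
  if (warn_range && !is.null(model$panel)) {
    pd <- model$panel
    lo <- pd$range_low[match(colnames(out), pd$analyte)]
    hi <- pd$range_high[match(colnames(out), pd$analyte)]
    bad <- sweep(out, 2, lo, "<") | sweep(out, 2, hi, ">")
    if (any(bad, na.rm = TRUE))
      warning(sprintf("%d prediction(s) fall outside the calibration concentration ranges",
                      sum(bad, na.rm = TRUE)))
  }
  if (is.matrix(features)) out else drop(out)
}

# round half away from zero (Table-style reporting; R's round() is
# round-half-even)
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Score predictions against a truth panel
#'
#' Per-analyte relative deviation `delta%_i = 100 |truth_i - pred_i| /
#' truth_i`, reported rounded half-away-from-zero to 2 decimals, with the
#' maximum over analytes as summary.
#'
#' @param pred Named numeric vector of predicted concentrations.
#' @param truth Named numeric vector of true concentrations (> 0), sharing
#'   analyte ids with `pred`.
#' @return A `data.frame` of class `prediction_report` with columns
#'   `analyte`, `true`, `found`, `delta_pct`; attribute `max_delta_pct`
#'   holds the summary maximum (unrounded deltas in attribute
#'   `delta_pct_raw`).
#' @export
score_predictions <- function(pred, truth) {
  ids <- intersect(names(pred), names(truth))
  if (length(ids) == 0) stop("no shared analyte ids")
  if (any(truth[ids] <= 0)) stop("truth values must be positive")
  d_raw <- 100 * abs(truth[ids] - pred[ids]) / truth[ids]
  rep_df <- data.frame(analyte = ids, true = as.numeric(truth[ids]),
                       found = as.numeric(pred[ids]),
                       delta_pct = round_half_away(as.numeric(d_raw), 2),
                       row.names = NULL)
  structure(rep_df, class = c("prediction_report", "data.frame"),
            max_delta_pct = max(d_raw), delta_pct_raw = as.numeric(d_raw))
}

#' @export
print.prediction_report <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf("max delta%%: %.4g\n", attr(x, "max_delta_pct")))
  invisible(x)
}

# ---- persistence -----------------------------------------------------------

term_to_list <- function(t) as.list(stats::setNames(as.integer(t), names(t)))

list_to_term <- function(l) {
  e <- as.integer(unlist(l))
  names(e) <- names(l)
  structure(e, class = "monomial_term")
}

#' Save a calibration model
#'
#' Serializes the model (terms, weights, scale, coefficients, delta, panel,
#' frozen bands, preprocessing options, provenance) as JSON at full double
#' precision, so [load_model()] reproduces every numeric field bit-exactly.
#'
#' @param model An `ftir_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ftir_calibration"))
  po <- model$preprocess
  doc <- list(
    format = "ftirserum-calibration",
    version = 1L,
    package_version = as.character(utils::packageVersion("ftirserum")),
    terms = lapply(model$composite$terms, term_to_list),
    weights = model$composite$weights,
    scale = model$composite$scale,
    coefficients = as.list(model$coefficients),
    delta = model$delta,
    panel = model$panel,
    bands = if (is.null(model$bands)) NULL else as.data.frame(model$bands),
    preprocess = if (is.null(po)) NULL else list(
      baseline_left = po$baseline_left, baseline_right = po$baseline_right,
      co2_region = if (is.null(po$co2_region)) NULL else as.numeric(po$co2_region),
      normalize = po$normalize,
      normalize_range = if (is.null(po$normalize_range)) NULL else
        as.numeric(po$normalize_range)),
    provenance = model$provenance
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a calibration model
#'
#' @param path Path written by [save_model()].
#' @return The restored `ftir_calibration`.
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "ftirserum-calibration")
    stop("not an ftirserum calibration file: ", path)
  # JSON integers deserialize as integer; all numeric fields are doubles
  coefs <- vapply(doc$coefficients, as.numeric, 0)
  panel <- if (is.null(doc$panel)) NULL else
    as.data.frame(lapply(as.data.frame(do.call(rbind, lapply(doc$panel, as.data.frame))),
                         utils::type.convert, as.is = TRUE))
  if (!is.null(panel)) {
    miss <- setdiff(panel$analyte, names(coefs))
    if (length(miss))
      stop("model file lacks coefficients for panel analyte(s): ",
           paste(miss, collapse = ", "))
  }
  bands <- if (is.null(doc$bands)) NULL else {
    b <- do.call(rbind, lapply(doc$bands, as.data.frame))
    b$index <- as.integer(b$index)
    for (col in c("center", "window_low", "window_high"))
      b[[col]] <- as.numeric(b[[col]])
    class(b) <- c("ftir_bands", "data.frame")
    b
  }
  po <- if (is.null(doc$preprocess)) NULL else {
    p <- doc$preprocess
    preprocess_options(
      baseline_left = p$baseline_left, baseline_right = p$baseline_right,
      co2_region = if (is.null(p$co2_region)) NULL else
        wn_range(p$co2_region[[1]], p$co2_region[[2]]),
      normalize = isTRUE(p$normalize),
      normalize_range = if (is.null(p$normalize_range)) NULL else
        wn_range(p$normalize_range[[1]], p$normalize_range[[2]]))
  }
  cf <- composite_feature(lapply(doc$terms, list_to_term),
                          as.numeric(unlist(doc$weights)),
                          scale = as.numeric(doc$scale))
  new_ftir_calibration(composite = cf, coefficients = coefs,
                       delta = as.numeric(doc$delta), panel = panel,
                       bands = bands, preprocess = po,
                       provenance = doc$provenance)
}
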