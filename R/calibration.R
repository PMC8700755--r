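# The ftir_calibration S3 class: end-to-end fitting from spectra +
# concentration design to a predictive model, with the usual modelling
# methods.

new_ftir_calibration <- function(composite, coefficients, delta,
                                 panel = NULL, bands = NULL,
                                 preprocess = NULL, provenance = NULL,
                                 training = NULL, call = NULL) {
  stopifnot(inherits(composite, "composite_feature"))
  coefficients <- unlist(coefficients)
  if (any(coefficients <= 0)) stop("scale coefficients must be positive")
  if (!is.numeric(delta) || delta < 0 || delta >= 0.5)
    stop("bias delta must lie in [0, 0.5)")
  structure(list(composite = composite, coefficients = coefficients,
                 delta = delta, panel = panel, bands = bands,
                 preprocess = preprocess, provenance = provenance,
                 training = training, call = call),
            class = "ftir_calibration")
}

#' Calibrate the serum panel model from spectra
#'
#' Runs the full calibration chain: replicate averaging and preprocessing,
#' band detection with frozen integration windows, extraction of band
#' absorbances (H) and areas (S), correlation screening of features and of
#' enumerated ratio terms against every analyte concentration, greedy
#' selection and reduced-gradient fitting of simplex weights into the
#' composite feature K, closed-form per-analyte scale coefficients `C_i`,
#' and the global multiplicative bias `delta`.
#'
#' @param spectra List of [ftir_spectrum()] objects with `meta$sample` set
#'   (replicates share a sample id), or a named list of already-averaged
#'   spectra.
#' @param concentrations Concentration matrix/data.frame, one row per
#'   sample (rownames = sample ids), one column per analyte.
#' @param config A [search_config()].
#' @param preprocess A [preprocess_options()] bundle, applied identically
#'   at prediction time.
#' @param bands Optional pre-computed band table ([detect_bands()] output);
#'   detected from the preprocessed calibration spectra when `NULL`.
#' @param min_prominence,min_presence Band detection settings passed to
#'   [detect_bands()].
#' @param reference_analyte Analyte whose concentrations (rescaled to unit
#'   mean) are the weight-fitting target. Default: the first column.
#' @param panel Optional panel definition `data.frame` (columns `analyte`,
#'   `name`, `units`, `range_low`, `range_high`) used for range warnings
#'   and reporting.
#' @return An object of class `ftir_calibration`.
#' @seealso [predict.ftir_calibration()], [save_model()], [reference_calibration()]
#' @examples
#' design <- study_design(noise_sd = 0, seed = 7)
#' lib <- make_band_library(n_bands = 15, seed = 7)
#' study <- simulate_dilution_study(design, lib)
#' fit <- ftir_calibrate(study$spectra, study$truth)
#' fit
#' @export
ftir_calibrate <- function(spectra, concentrations,
                           config = search_config(),
                           preprocess = preprocess_options(),
                           bands = NULL, min_prominence = 1e-3,
                           min_presence = 0.8,
                           reference_analyte = NULL, panel = NULL) {
  cl <- match.call()
  conc <- as_conc_matrix(concentrations)
  samples <- preprocess_samples(spectra, preprocess)
  if (!is.null(rownames(conc))) {
    miss <- setdiff(names(samples), rownames(conc))
    if (length(miss))
      stop("no concentrations for sample(s): ", paste(miss, collapse = ", "))
    conc <- conc[names(samples), , drop = FALSE]
  } else if (nrow(conc) != length(samples)) {
    stop("concentration rows do not match the number of samples")
  }
  if (is.null(bands))
    bands <- detect_bands(samples, min_prominence = min_prominence,
                          min_presence = min_presence)
  fm <- build_feature_matrix(samples, bands)
  scatter <- replicate_feature_scatter(spectra, bands, preprocess)
  feats <- screen_primary_features(fm, conc, config, rank_by = scatter)
  if (length(feats) == 0)
    stop("no features passed correlation screening (r > ",
         config$r_threshold, ")")
  terms <- enumerate_ratio_terms(feats, config)
  terms <- screen_terms(terms, fm[, feats, drop = FALSE], conc, config)
  if (length(terms) == 0)
    stop("no ratio terms passed correlation screening")
  if (is.null(reference_analyte)) reference_analyte <- colnames(conc)[1]
  target <- conc[, reference_analyte]
  target <- target / mean(target)
  composite <- select_and_fit_terms(terms, fm[, feats, drop = FALSE],
                                    target, config, noise = scatter)
  K <- evaluate_composite(composite, fm)
  coefs <- fit_scale_coefficients(K, conc)
  delta <- estimate_bias(outer(K, coefs), conc)
  if (delta < 0) delta <- 0   # relative-LS can land a hair below zero in-sample
  fitted_vals <- outer(K, coefs) * (1 - delta)
  training <- list(feature_matrix = fm, screened_features = feats,
                   n_candidate_terms = length(terms), K = K,
                   concentrations = conc, fitted = fitted_vals,
                   reference_analyte = reference_analyte,
                   objective = attr(composite, "objective"))
  new_ftir_calibration(composite = composite, coefficients = coefs,
                       delta = delta, panel = panel, bands = bands,
                       preprocess = preprocess,
                       provenance = list(config = unclass(config),
                                         n_samples = length(samples),
                                         n_bands = nrow(bands)),
                       training = training, call = cl)
}

#' @export
print.ftir_calibration <- function(x, ...) {
  cat("FTIR serum calibration model\n")
  cat(sprintf("  %d analytes, delta = %.4g\n", length(x$coefficients), x$delta))
  cat(sprintf("  composite feature: %d term(s)%s\n", length(x$composite$terms),
              if (x$composite$scale != 1)
                sprintf(" (scale %.4g)", x$composite$scale) else ""))
  for (i in seq_along(x$composite$terms))
    cat(sprintf("    %.6g * %s\n", x$composite$weights[i],
                format(x$composite$terms[[i]])))
  invisible(x)
}

#' @export
summary.ftir_calibration <- function(object, ...) {
  x <- object
  print(x)
  if (!is.null(x$bands))
    cat(sprintf("  bands: %d (centers %.6g-%.6g cm^-1)\n", nrow(x$bands),
                min(x$bands$center), max(x$bands$center)))
  if (!is.null(x$training)) {
    tr <- x$training
    cat("  screened features:", paste(tr$screened_features, collapse = ", "), "\n")
    cat(sprintf("  candidate terms after screening: %d\n", tr$n_candidate_terms))
    err <- 100 * abs(tr$fitted - tr$concentrations) / tr$concentrations
    cat(sprintf("  in-sample max relative error: %.4g%%\n", max(err)))
  }
  invisible(x)
}

#' @export
coef.ftir_calibration <- function(object, ...) object$coefficients

#' @export
fitted.ftir_calibration <- function(object, ...) object$training$fitted

#' @export
residuals.ftir_calibration <- function(object, ...) {
  if (is.null(object$training)) stop("model carries no training data")
  object$training$fitted - object$training$concentrations
}

#' Predict analyte concentrations
#'
#' Accepts raw spectra (replicates grouped by `meta$sample`, preprocessed
#' with the model's recorded options and integrated over its frozen band
#' windows), a named feature vector, or a feature matrix.
#'
#' @param object An `ftir_calibration`.
#' @param newdata List of [ftir_spectrum()]s, a named feature vector, or a
#'   feature matrix (rows = samples).
#' @param truth Optional named vector (single sample) of true
#'   concentrations; when given, a [score_predictions()] report is
#'   returned.
#' @param warn_range Warn on predictions outside the panel's calibration
#'   ranges. Default `TRUE`.
#' @param ... Unused.
#' @return Concentration vector/matrix, or a `prediction_report` when
#'   `truth` is supplied.
#' @export
predict.ftir_calibration <- function(object, newdata, truth = NULL,
                                     warn_range = TRUE, ...) {
  features <- if (is.list(newdata) && all(vapply(newdata, inherits, TRUE, "ftir_spectrum"))) {
    if (is.null(object$bands))
      stop("model carries no band windows; supply feature values directly")
    newdata <- lapply(seq_along(newdata), function(i) {
      s <- newdata[[i]]
      if (is.null(s$meta$sample)) s$meta$sample <- paste0("sample", i)
      s
    })
    samples <- preprocess_samples(newdata,
                                  if (is.null(object$preprocess))
                                    preprocess_options() else object$preprocess)
    build_feature_matrix(samples, object$bands)
  } else if (inherits(newdata, "ftir_spectrum")) {
    return(predict(object, list(newdata), truth = truth,
                   warn_range = warn_range, ...))
  } else newdata
  pred <- predict_panel(object, features, warn_range = warn_range)
  if (!is.null(truth)) {
    p <- if (is.matrix(pred)) {
      if (nrow(pred) != 1) stop("truth scoring needs a single sample")
      stats::setNames(pred[1, ], colnames(pred))
    } else pred
    return(score_predictions(p, truth))
  }
  pred
}

#' @export
plot.ftir_calibration <- function(x, ...) {
  if (is.null(x$training)) stop("model carries no training data")
  tru <- as.numeric(x$training$concentrations)
  fit <- as.numeric(x$training$fitted)
  graphics::plot(tru, fit, log = "xy",
                 xlab = "True concentration", ylab = "Predicted concentration",
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
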