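# Packaged reference calibration for the 38-analyte bovine control-serum
# panel: the reference scale coefficients, panel definition with
# calibration ranges and the pathological-serum test column, and the
# three-term composite feature over H20, H49, S2, S42, S49.

#' The packaged 38-analyte serum panel definition
#'
#' Analyte ids B1..B38 with names, units, calibration concentration ranges,
#' and the true/found concentrations (with reported delta%) of the
#' pathological control-serum test solution.
#'
#' @return A `data.frame` with columns `analyte`, `name`, `units`,
#'   `range_low`, `range_high`, `test_true`, `test_found`, `delta_pct`.
#' @export
serum_panel <- function() {
  path <- system.file("extdata", "serum_panel.csv", package = "ftirserum",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' The packaged per-analyte scale coefficients
#'
#' @return Named numeric vector `C_i` (B1..B38), in units of analyte
#'   concentration per unit of the composite feature K.
#' @export
serum_coefficients <- function() {
  path <- system.file("extdata", "serum_coefficients.csv",
                      package = "ftirserum", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tab$coefficient, tab$analyte)
}

#' The three-term reference composite feature
#'
#' `K = H20^2/S2^2 + H20*H49*S42/(S2*S49) + H49^2/(H20*S42*S49)`, where H20
#' and H49 are the absorbances of the bands at 1717 and 3903 cm^-1 and S2,
#' S42, S49 the areas of the bands at 616, 3750 and 3903 cm^-1. Stored as
#' simplex weights 1/3 with scale 3, which evaluates identically to the
#' plain unweighted sum.
#'
#' @return A [composite_feature()].
#' @export
reference_composite <- function() {
  t1 <- structure(c(H20 = 2L, S2 = -2L), class = "monomial_term")
  t2 <- structure(c(H20 = 1L, H49 = 1L, S42 = 1L, S2 = -1L, S49 = -1L),
                  class = "monomial_term")
  t3 <- structure(c(H49 = 2L, H20 = -1L, S42 = -1L, S49 = -1L),
                  class = "monomial_term")
  composite_feature(list(t1, t2, t3), rep(1 / 3, 3), scale = 3)
}

#' The packaged reference calibration model
#'
#' Combines [reference_composite()], the reference coefficients
#' [serum_coefficients()], the fixed bias `delta = 0.054` and the panel
#' definition into a ready `ftir_calibration`. The model carries no band
#' windows (the underlying raw spectra were never deposited), so prediction
#' requires feature values for H20, H49, S2, S42, S49 directly.
#'
#' @return An `ftir_calibration`.
#' @examples
#' m <- reference_calibration()
#' coef(m)[["B1"]]
#' @export
reference_calibration <- function() {
  new_ftir_calibration(composite = reference_composite(),
                       coefficients = serum_coefficients(),
                       delta = 0.054,
                       panel = serum_panel(),
                       provenance = list(source = "packaged reference tables"))
}

#' Fit a single shared K to a concentration panel by relative least squares
#'
#' Given per-analyte coefficients and true concentrations, finds the scalar
#' `K` minimizing `sum_i ((C_i (1 - delta) K - B_i) / B_i)^2`; closed form
#' `K = sum(u) / sum(u^2)` with `u_i = C_i (1 - delta) / B_i`. In a
#' lockstep design all analytes share one K, so this inverts the panel back
#' to the common feature value.
#'
#' @param coefficients Named `C_i` vector.
#' @param truth Named true concentrations (> 0), ids matching.
#' @param delta Bias; default 0.054.
#' @return The fitted scalar K.
#' @export
fit_shared_K <- function(coefficients, truth, delta = 0.054) {
  ids <- intersect(names(coefficients), names(truth))
  if (length(ids) == 0) stop("no shared analyte ids")
  if (any(truth[ids] <= 0)) stop("truth values must be positive")
  u <- coefficients[ids] * (1 - delta) / truth[ids]
  sum(u) / sum(u^2)
}

#' Internal-consistency checks of the packaged reference tables
#'
#' Recomputes, from the packaged coefficient and panel tables alone:
#' the per-analyte implied feature values `K_i = found_i / (C_i (1 -
#' 0.054))` and their coefficient of variation; the single shared K fitted
#' by relative least squares to the test-true concentrations of analytes
#' printed with >= 4 units (4+ significant digits, avoiding 2-decimal
#' rounding artifacts) and the maximum relative prediction error it
#' leaves; and the recomputed delta% for every row.
#'
#' @param min_true Threshold on the printed true value for the shared-K
#'   fit. Default 4.0.
#' @return A list: `K_values`, `K_cv_pct`, `K_shared`, `headline_analytes`,
#'   `headline_max_error_pct`, `delta_pct_recomputed`,
#'   `delta_pct_printed`, `delta_pct_matches`.
#' @export
validate_reference_tables <- function(min_true = 4.0) {
  panel <- serum_panel()
  C <- serum_coefficients()
  stopifnot(all(panel$analyte == names(C)))
  tru <- stats::setNames(panel$test_true, panel$analyte)
  fnd <- stats::setNames(panel$test_found, panel$analyte)
  delta <- 0.054
  K_i <- fnd / (C * (1 - delta))
  sub <- names(tru)[tru >= min_true]
  K <- fit_shared_K(C[sub], tru[sub], delta)
  pred <- C[sub] * (1 - delta) * K
  max_err <- max(100 * abs(pred - tru[sub]) / tru[sub])
  d_rec <- round_half_away(100 * abs(tru - fnd) / tru, 2)
  list(K_values = K_i,
       K_cv_pct = 100 * stats::sd(K_i) / mean(K_i),
       K_shared = K,
       headline_analytes = sub,
       headline_max_error_pct = max_err,
       delta_pct_recomputed = d_rec,
       delta_pct_printed = stats::setNames(panel$delta_pct, panel$analyte),
       delta_pct_matches = d_rec == stats::setNames(panel$delta_pct, panel$analyte))
}
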