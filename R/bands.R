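# Band detection and extraction of per-band absorbance (H) and area (S).

# Local maxima of a vector: strictly above the left neighbour, at least the
# right neighbour (plateaus credit their first point). Endpoints excluded.
local_maxima <- function(a) {
  n <- length(a)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[a[i] > a[i - 1] & a[i] >= a[i + 1]]
}

# Flanking local minima around peak index p (indices, endpoints allowed).
flanking_minima <- function(a, p) {
  n <- length(a)
  l <- p
  while (l > 1 && a[l - 1] <= a[l]) l <- l - 1
  r <- p
  while (r < n && a[r + 1] <= a[r]) r <- r + 1
  c(l, r)
}

# Topographic prominence proxy: peak height above the higher flanking minimum.
peak_prominence <- function(a, p) {
  fm <- flanking_minima(a, p)
  a[p] - max(a[fm[1]], a[fm[2]])
}

#' Detect stable absorption bands
#'
#' Finds absorption bands that persist across a set of preprocessed spectra:
#' local maxima whose prominence (height above the higher flanking minimum)
#' exceeds `min_prominence`, matched across spectra within `match_tol` and
#' kept when present in at least a fraction `min_presence` of the spectra.
#' Integration windows are the flanking local minima of the mean spectrum,
#' frozen into the descriptor so every sample is integrated over identical
#' bounds. Bands are indexed 1..n by ascending center wavenumber.
#'
#' @param spectra List of [ftir_spectrum()] objects on one common grid.
#' @param min_prominence Minimum prominence in AU. Default `1e-3`.
#' @param min_presence Minimum fraction of spectra in which a band must
#'   appear. Default `0.8`.
#' @param match_tol Cross-spectrum peak matching tolerance in cm^-1.
#'   Default 8 (two resolution elements at 4 cm^-1).
#' @return A `data.frame` with columns `index`, `center`, `window_low`,
#'   `window_high` (class `ftir_bands`).
#' @export
detect_bands <- function(spectra, min_prominence = 1e-3, min_presence = 0.8,
                         match_tol = 8) {
  if (!is.list(spectra) || length(spectra) == 0)
    stop("need at least one spectrum")
  stopifnot(all(vapply(spectra, inherits, TRUE, "ftir_spectrum")))
  grid <- spectra[[1]]$wavenumbers
  for (s in spectra[-1])
    if (length(s$wavenumbers) != length(grid) || any(s$wavenumbers != grid))
      stop("spectra must share a common wavenumber grid")

  # peak centers per spectrum
  peaks <- lapply(spectra, function(s) {
    idx <- local_maxima(s$absorbance)
    idx[vapply(idx, function(p) peak_prominence(s$absorbance, p), 0) >= min_prominence]
  })
  centers <- sort(unique(grid[unlist(peaks)]))
  if (length(centers) == 0) stop("no bands found above min_prominence")

  # greedy clustering of pooled centers within match_tol
  cluster <- cumsum(c(TRUE, diff(centers) > match_tol))
  cl_centers <- vapply(split(centers, cluster), stats::median, 0)

  # presence: fraction of spectra with a peak within match_tol of the cluster
  presence <- vapply(cl_centers, function(cc) {
    mean(vapply(peaks, function(p) any(abs(grid[p] - cc) <= match_tol), TRUE))
  }, 0)
  cl_centers <- cl_centers[presence >= min_presence]
  if (length(cl_centers) == 0) stop("no bands present in enough spectra")

  # freeze windows from the mean spectrum's flanking minima
  mean_ab <- rowMeans(vapply(spectra, `[[`, numeric(length(grid)), "absorbance"))
  rows <- lapply(cl_centers, function(cc) {
    p <- which.min(abs(grid - cc))
    # snap to the nearest local maximum of the mean spectrum within match_tol
    lm <- local_maxima(mean_ab)
    near <- lm[abs(grid[lm] - cc) <= match_tol]
    if (length(near)) p <- near[which.min(abs(grid[near] - cc))]
    fm <- flanking_minima(mean_ab, p)
    data.frame(center = grid[p], window_low = grid[fm[1]], window_high = grid[fm[2]])
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$center), , drop = FALSE]
  out <- out[order(out$center), , drop = FALSE]
  out <- data.frame(index = seq_len(nrow(out)), out, row.names = NULL)
  class(out) <- c("ftir_bands", "data.frame")
  out
}

as_band <- function(band) {
  if (is.data.frame(band)) {
    stopifnot(nrow(band) == 1)
    band <- as.list(band)
  }
  stopifnot(!is.null(band$window_low), !is.null(band$window_high))
  band
}

check_window <- function(s, band) {
  w <- s$wavenumbers
  if (band$window_low < w[1] || band$window_high > w[length(w)])
    stop(sprintf("band window [%.6g, %.6g] cm^-1%s lies outside the spectrum span [%.6g, %.6g]",
                 band$window_low, band$window_high,
                 if (!is.null(band$center)) sprintf(" (band at %.6g cm^-1)", band$center) else "",
                 w[1], w[length(w)]))
}

#' Band absorbance H
#'
#' Maximum absorbance of the (baseline-corrected) spectrum within a band's
#' frozen integration window.
#'
#' @param s An [ftir_spectrum()].
#' @param band A single band descriptor (one row of [detect_bands()] output
#'   or a list with `window_low`/`window_high`).
#' @return H in AU.
#' @export
band_absorbance <- function(s, band) {
  stopifnot(inherits(s, "ftir_spectrum"))
  band <- as_band(band)
  check_window(s, band)
  sel <- s$wavenumbers >= band$window_low & s$wavenumbers <= band$window_high
  max(s$absorbance[sel])
}

#' Band area S
#'
#' Trapezoidal integral of absorbance over the band's frozen window.
#'
#' @inheritParams band_absorbance
#' @return S in AU * cm^-1.
#' @export
band_area <- function(s, band) {
  stopifnot(inherits(s, "ftir_spectrum"))
  band <- as_band(band)
  check_window(s, band)
  sel <- which(s$wavenumbers >= band$window_low & s$wavenumbers <= band$window_high)
  w <- s$wavenumbers[sel]; a <- s$absorbance[sel]
  n <- length(w)
  if (n < 2) stop("band window contains fewer than 2 grid points")
  sum(diff(w) * (a[-1] + a[-n]) / 2)
}

#' Replicate-level feature scatter
#'
#' Empirical measurement precision of each band feature: every replicate
#' spectrum is preprocessed individually, features are extracted over the
#' frozen band windows, and the within-sample relative standard deviation
#' (sd / |mean|) is computed, then summarized as the median across
#' samples. Lower values mean the feature is read more precisely; used to
#' rank screened features in [screen_primary_features()] and candidate
#' terms in [select_and_fit_terms()].
#'
#' @param spectra Flat list of raw replicate [ftir_spectrum()]s with
#'   `meta$sample` set.
#' @param bands Band table from [detect_bands()].
#' @param opts A [preprocess_options()] bundle.
#' @return Named numeric vector of median feature-specific relative sd per
#'   feature, or `NULL` when no sample has 2 or more replicates.
#' @export
replicate_feature_scatter <- function(spectra, bands, opts = preprocess_options()) {
  ids <- vapply(spectra, function(s)
    if (is.null(s$meta$sample)) NA_character_ else as.character(s$meta$sample),
    character(1))
  if (anyNA(ids)) return(NULL)
  groups <- split(spectra, factor(ids, levels = unique(ids)))
  per_group <- lapply(groups, function(g) {
    if (length(g) < 2) return(NULL)
    proc <- lapply(g, preprocess_spectrum, opts = opts)
    fmg <- build_feature_matrix(proc, bands)
    apply(fmg, 2, function(v) stats::sd(v) / max(abs(mean(v)), .Machine$double.xmin))
  })
  per_group <- per_group[!vapply(per_group, is.null, TRUE)]
  if (length(per_group) == 0) return(NULL)
  apply(do.call(rbind, per_group), 2, stats::median)
}

#' Build the H/S feature matrix
#'
#' One row per sample spectrum, columns `H<i>` and `S<i>` for every band
#' `i`, computed with [band_absorbance()] and [band_area()].
#'
#' @param spectra Named list of preprocessed sample spectra (names or
#'   `meta$sample` become row names).
#' @param bands Band table from [detect_bands()].
#' @return Numeric matrix (class retains plain matrix) with feature ids as
#'   column names, ordered `H1, S1, H2, S2, ...` by band index.
#' @export
build_feature_matrix <- function(spectra, bands) {
  stopifnot(is.data.frame(bands), nrow(bands) >= 1)
  ids <- names(spectra)
  if (is.null(ids))
    ids <- vapply(seq_along(spectra), function(i) {
      id <- spectra[[i]]$meta$sample
      if (is.null(id)) paste0("sample", i) else as.character(id)
    }, character(1))
  feat_ids <- as.vector(rbind(paste0("H", bands$index), paste0("S", bands$index)))
  vals <- t(vapply(spectra, function(s) {
    row <- numeric(2 * nrow(bands))
    for (j in seq_len(nrow(bands))) {
      b <- bands[j, ]
      row[2 * j - 1] <- band_absorbance(s, b)
      row[2 * j] <- band_area(s, b)
    }
    row
  }, numeric(2 * nrow(bands))))
  dimnames(vals) <- list(ids, feat_ids)
  if (!all(is.finite(vals))) stop("non-finite feature values")
  vals
}
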