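# Spectrum container and preprocessing primitives.

#' Construct an FTIR spectrum
#'
#' The basic unit of all preprocessing: a wavenumber grid (cm^-1) with
#' matching absorbance values (AU). Wavenumbers are stored strictly
#' increasing; inputs given in descending instrument order are re-sorted and
#' the original orientation recorded in `meta`.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1, strictly
#'   monotonic (either direction), length >= 2.
#' @param absorbance Numeric vector of absorbances in AU, same length.
#' @param meta Named list of free-form annotations (sample id, dilution
#'   factor, replicate index, processing history).
#' @return An object of class `ftir_spectrum` with components `wavenumbers`,
#'   `absorbance` and `meta`.
#' @examples
#' s <- ftir_spectrum(c(500, 502, 504), c(0.1, 0.2, 0.1))
#' s
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length")
  if (length(wavenumbers) < 2)
    stop("a spectrum needs at least 2 points")
  if (!all(is.finite(wavenumbers)) || !all(is.finite(absorbance)))
    stop("all wavenumbers and absorbances must be finite")
  d <- diff(wavenumbers)
  if (all(d < 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
    meta$original_orientation <- "descending"
  } else if (any(d <= 0)) {
    stop("wavenumbers must be strictly monotonic (duplicates or mixed order found)")
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = meta),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("FTIR spectrum: %d points, %.1f-%.1f cm^-1\n",
              length(x$wavenumbers), min(x$wavenumbers), max(x$wavenumbers)))
  if (!is.null(x$meta$sample))
    cat("  sample:", x$meta$sample,
        if (!is.null(x$meta$replicate)) paste0("(replicate ", x$meta$replicate, ")"),
        "\n")
  if (!is.null(x$meta$processing))
    cat("  processing:", paste(x$meta$processing, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
plot.ftir_spectrum <- function(x, ..., xlab = expression(Wavenumber ~ (cm^-1)),
                               ylab = "Absorbance (AU)", type = "l") {
  graphics::plot(x$wavenumbers, x$absorbance, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Wavenumber range
#'
#' @param low,high Bounds in cm^-1 with `low < high`.
#' @return A `wn_range` object (named numeric of length 2).
#' @export
wn_range <- function(low, high) {
  low <- as.numeric(low); high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high) || low >= high)
    stop("wn_range requires finite low < high")
  structure(c(low = low, high = high), class = "wn_range")
}

# Index of the grid point nearest to w; ties broken toward lower wavenumber
# (which.min returns the first of tied minima on an increasing grid).
nearest_index <- function(s, w) {
  which.min(abs(s$wavenumbers - w))
}

in_span <- function(s, w) {
  w >= s$wavenumbers[1] & w <= s$wavenumbers[length(s$wavenumbers)]
}

note_step <- function(s, step) {
  s$meta$processing <- c(s$meta$processing, step)
  s
}

#' Read a spectrum from disk
#'
#' Reads the two-column CSV dialect (wavenumber, absorbance; header optional)
#' or a JCAMP-DX file with an AFFN `##XYDATA=(X++(Y..Y))` or
#' `##XYPOINTS=(XY..XY)` block. Descending instrument order is accepted and
#' re-sorted.
#'
#' @param path Path to the file.
#' @param format `"auto"` (by extension), `"csv"` or `"jcamp"`.
#' @param meta Extra annotations merged into the result's `meta`.
#' @return An [ftir_spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp"), meta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm|jcamp)$", tolower(path))) "jcamp" else "csv"
  }
  if (format == "csv") read_spectrum_csv(path, meta) else read_spectrum_jcamp(path, meta)
}

read_spectrum_csv <- function(path, meta = list()) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  tab <- utils::read.csv(path, header = has_header,
                         colClasses = "numeric", strip.white = TRUE)
  if (ncol(tab) < 2) stop("expected two numeric columns in ", path)
  if (anyNA(tab[[1]]) || anyNA(tab[[2]]))
    stop("unparseable numeric data in ", path)
  meta$source <- path
  ftir_spectrum(tab[[1]], tab[[2]], meta)
}

# Minimal JCAMP-DX reader: AFFN numbers only, honours XFACTOR/YFACTOR and
# DELTAX implied by FIRSTX/LASTX/NPOINTS.
read_spectrum_jcamp <- function(path, meta = list()) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    m <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE, value = TRUE)
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^##", name, "\\s*=\\s*"), "", m[1], ignore.case = TRUE)
  }
  num_ldr <- function(name, default = NA_real_) {
    v <- suppressWarnings(as.numeric(ldr(name)))
    if (is.na(v)) default else v
  }
  xf <- num_ldr("XFACTOR", 1); yf <- num_ldr("YFACTOR", 1)
  i_xy <- grep("^##XYDATA\\s*=", lines, ignore.case = TRUE)
  i_pts <- grep("^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  i_end <- grep("^##END\\s*=", lines, ignore.case = TRUE)
  block_after <- function(i) {
    stop_at <- c(grep("^##", lines), length(lines) + 1L)
    stop_at <- min(stop_at[stop_at > i], length(lines) + 1L)
    lines[seq(i + 1L, stop_at - 1L)]
  }
  if (length(i_xy) == 1) {
    body <- block_after(i_xy)
    w <- numeric(0); a <- numeric(0)
    for (ln in body) {
      ln <- trimws(ln)
      if (ln == "") next
      vals <- suppressWarnings(as.numeric(strsplit(ln, "[,;[:space:]]+")[[1]]))
      if (anyNA(vals) || length(vals) < 2)
        stop("unparseable JCAMP XYDATA line: ", ln)
      x0 <- vals[1] * xf
      ys <- vals[-1] * yf
      npt <- num_ldr("NPOINTS")
      dx <- num_ldr("DELTAX")
      if (is.na(dx)) {
        fx <- num_ldr("FIRSTX"); lx <- num_ldr("LASTX")
        if (!is.na(fx) && !is.na(lx) && !is.na(npt) && npt > 1)
          dx <- (lx - fx) / (npt - 1)
        else stop("JCAMP file lacks DELTAX and FIRSTX/LASTX/NPOINTS")
      }
      w <- c(w, x0 + dx * (seq_along(ys) - 1))
      a <- c(a, ys)
    }
  } else if (length(i_pts) == 1) {
    body <- block_after(i_pts)
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body[body != ""]),
                                                        "[,;[:space:]]+"))))
    if (anyNA(vals) || length(vals) %% 2 != 0)
      stop("unparseable JCAMP XYPOINTS block")
    w <- vals[seq(1, length(vals), by = 2)] * xf
    a <- vals[seq(2, length(vals), by = 2)] * yf
  } else {
    stop("no XYDATA or XYPOINTS block found in ", path)
  }
  meta$source <- path
  meta$title <- ldr("TITLE")
  ftir_spectrum(w, a, meta)
}

#' Write a spectrum to CSV
#'
#' Writes the same two-column dialect [read_spectrum()] consumes
#' (`wavenumber,absorbance` with a header). With `sidecar = TRUE` the meta
#' list is written next to it as `<path>.meta.json`.
#'
#' @param s An [ftir_spectrum()].
#' @param path Output CSV path.
#' @param sidecar Write the meta sidecar JSON? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, sidecar = FALSE) {
  stopifnot(inherits(s, "ftir_spectrum"))
  # %.17g preserves doubles exactly, so read -> write -> read round-trips
  tab <- data.frame(wavenumber = sprintf("%.17g", s$wavenumbers),
                    absorbance = sprintf("%.17g", s$absorbance))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  if (sidecar && length(s$meta))
    jsonlite::write_json(s$meta, paste0(path, ".meta.json"),
                         auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Average replicate spectra
#'
#' Pointwise mean over replicates sharing an identical wavenumber grid; the
#' standard presentation of triplicate acquisitions of one dried film.
#'
#' @param replicates List of [ftir_spectrum()] objects on one common grid.
#' @return A single averaged `ftir_spectrum`; `meta$n_replicates` records the
#'   replicate count and meta is inherited from the first replicate.
#' @export
average_replicates <- function(replicates) {
  if (!is.list(replicates) || length(replicates) == 0)
    stop("need at least one replicate spectrum")
  stopifnot(all(vapply(replicates, inherits, TRUE, "ftir_spectrum")))
  grid <- replicates[[1]]$wavenumbers
  for (r in replicates[-1]) {
    if (length(r$wavenumbers) != length(grid) || any(r$wavenumbers != grid))
      stop("replicates must share an identical wavenumber grid")
  }
  ab <- rowMeans(vapply(replicates, `[[`, numeric(length(grid)), "absorbance"))
  meta <- replicates[[1]]$meta
  meta$replicate <- NULL
  meta$n_replicates <- length(replicates)
  out <- ftir_spectrum(grid, ab, meta)
  note_step(out, sprintf("average_replicates(n=%d)", length(replicates)))
}

#' Two-point linear baseline correction
#'
#' Subtracts the straight line through the spectrum's values at two anchor
#' wavenumbers (taken at the nearest grid points) from the whole spectrum,
#' so the corrected absorbance at both anchors is exactly zero. Anchors
#' default to the first and last grid points.
#'
#' @param s An [ftir_spectrum()].
#' @param left,right Anchor wavenumbers in cm^-1 inside the grid span, with
#'   `left < right`. Defaults: the grid endpoints.
#' @return The corrected `ftir_spectrum`.
#' @export
baseline_correct_two_point <- function(s, left = NULL, right = NULL) {
  stopifnot(inherits(s, "ftir_spectrum"))
  w <- s$wavenumbers
  if (is.null(left)) left <- w[1]
  if (is.null(right)) right <- w[length(w)]
  if (left >= right) stop("baseline anchors require left < right")
  if (!in_span(s, left) || !in_span(s, right))
    stop("baseline anchors must lie inside the grid span")
  i1 <- nearest_index(s, left); i2 <- nearest_index(s, right)
  if (i1 == i2) stop("baseline anchors resolve to the same grid point")
  slope <- (s$absorbance[i2] - s$absorbance[i1]) / (w[i2] - w[i1])
  line <- s$absorbance[i1] + slope * (w - w[i1])
  s$absorbance <- s$absorbance - line
  note_step(s, sprintf("baseline_two_point(%.6g,%.6g)", w[i1], w[i2]))
}

#' Vector normalization
#'
#' Divides the whole spectrum by the Euclidean norm of its absorbances over
#' the stated wavenumber range, so the norm over that range becomes 1.
#'
#' @param s An [ftir_spectrum()].
#' @param range A [wn_range()]; default spans the whole grid.
#' @return The normalized `ftir_spectrum`.
#' @export
vector_normalize <- function(s, range = NULL) {
  stopifnot(inherits(s, "ftir_spectrum"))
  w <- s$wavenumbers
  if (is.null(range)) range <- wn_range(w[1], w[length(w)])
  sel <- w >= range["low"] & w <= range["high"]
  if (!any(sel)) stop("normalization range does not overlap the grid")
  nrm <- sqrt(sum(s$absorbance[sel]^2))
  if (nrm == 0) stop("cannot vector-normalize: zero norm within range")
  s$absorbance <- s$absorbance / nrm
  note_step(s, sprintf("vector_normalize(%.6g,%.6g)", range["low"], range["high"]))
}

#' Straight-line excision of a spectral region
#'
#' Replaces the absorbance inside `region` by the chord between the nearest
#' grid points at the region's boundaries; points outside are untouched.
#' Standard removal of the atmospheric CO2 doublet (~2280-2400 cm^-1).
#'
#' @param s An [ftir_spectrum()].
#' @param region A [wn_range()] strictly inside the grid span. Default the
#'   atmospheric CO2 stretch window 2280-2400 cm^-1.
#' @return The excised `ftir_spectrum`.
#' @export
excise_straight_line <- function(s, region = wn_range(2280, 2400)) {
  stopifnot(inherits(s, "ftir_spectrum"))
  w <- s$wavenumbers
  if (region["low"] <= w[1] || region["high"] >= w[length(w)])
    stop("excision region must lie strictly inside the grid span")
  i1 <- nearest_index(s, region["low"])
  i2 <- nearest_index(s, region["high"])
  inside <- which(w > w[i1] & w < w[i2])
  if (length(inside)) {
    slope <- (s$absorbance[i2] - s$absorbance[i1]) / (w[i2] - w[i1])
    s$absorbance[inside] <- s$absorbance[i1] + slope * (w[inside] - w[i1])
  }
  note_step(s, sprintf("excise(%.6g,%.6g)", region["low"], region["high"]))
}

#' Preprocessing options
#'
#' Bundle of preprocessing settings applied identically at calibration and
#' prediction time. The application order is fixed: average replicates,
#' two-point baseline correction, CO2 excision, then (optionally) vector
#' normalization.
#'
#' Vector normalization removes the overall spectral scale. In a pure
#' dilution design the scale *is* the concentration signal, so normalization
#' is off by default for calibration; enable it for data where film
#' thickness varies independently of composition.
#'
#' @param baseline_left,baseline_right Anchor wavenumbers (cm^-1) for the
#'   baseline; `NULL` uses the grid endpoints.
#' @param co2_region [wn_range()] excised by straight-line generation, or
#'   `NULL` to skip. Default 2280-2400 cm^-1.
#' @param normalize Apply vector normalization? Default `FALSE`.
#' @param normalize_range [wn_range()] for the norm; `NULL` = full span.
#' @return A list of class `preprocess_options`.
#' @export
preprocess_options <- function(baseline_left = NULL, baseline_right = NULL,
                               co2_region = wn_range(2280, 2400),
                               normalize = FALSE, normalize_range = NULL) {
  structure(list(baseline_left = baseline_left, baseline_right = baseline_right,
                 co2_region = co2_region, normalize = normalize,
                 normalize_range = normalize_range),
            class = "preprocess_options")
}

#' Preprocess one averaged spectrum
#'
#' Applies baseline correction, CO2 excision and optional normalization in
#' that fixed order (replicate averaging, if needed, happens before this via
#' [average_replicates()]). Each step is recorded in `meta$processing`.
#'
#' @param s An [ftir_spectrum()] (already replicate-averaged).
#' @param opts A [preprocess_options()] bundle.
#' @return The preprocessed `ftir_spectrum`.
#' @export
preprocess_spectrum <- function(s, opts = preprocess_options()) {
  stopifnot(inherits(s, "ftir_spectrum"), inherits(opts, "preprocess_options"))
  s <- baseline_correct_two_point(s, opts$baseline_left, opts$baseline_right)
  if (!is.null(opts$co2_region)) s <- excise_straight_line(s, opts$co2_region)
  if (isTRUE(opts$normalize)) s <- vector_normalize(s, opts$normalize_range)
  s
}

#' Group, average and preprocess replicate spectra
#'
#' Groups a flat list of spectra by `meta$sample`, averages each group and
#' runs [preprocess_spectrum()] on the averages.
#'
#' @param spectra List of [ftir_spectrum()] objects with `meta$sample` set.
#' @param opts A [preprocess_options()] bundle.
#' @return Named list of preprocessed spectra, one per sample, in order of
#'   first appearance.
#' @export
preprocess_samples <- function(spectra, opts = preprocess_options()) {
  ids <- vapply(spectra, function(s) {
    id <- s$meta$sample
    if (is.null(id)) stop("every spectrum needs meta$sample to group replicates")
    as.character(id)
  }, character(1))
  out <- lapply(split(spectra, factor(ids, levels = unique(ids))),
                function(g) preprocess_spectrum(average_replicates(g), opts))
  out[unique(ids)]
}
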