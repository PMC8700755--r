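# Synthetic serum-like FTIR dilution studies: Gaussian band library with
# Beer-Lambert linear mixing, known ground truth, reproducible substreams.

serum_template_centers <- c(616, 1080, 1171, 1242, 1394, 1453, 1536, 1650,
                            1717, 2872, 2920, 2957, 3280, 3750, 3903)
# stock-level amplitudes (AU) for the template bands; amide I dominates
serum_template_amps <- c(`616` = 0.35, `1080` = 0.55, `1171` = 0.40,
                         `1242` = 0.45, `1394` = 0.50, `1453` = 0.55,
                         `1536` = 0.85, `1650` = 1.00, `1717` = 0.45,
                         `2872` = 0.30, `2920` = 0.50, `2957` = 0.35,
                         `3280` = 0.80, `3750` = 0.25, `3903` = 0.20)
# characteristic Gaussian widths (cm^-1) of the named serum bands: sharp
# fingerprint modes, ~40 cm^-1 FWHM amides, and the broad amide A / O-H
# envelope at 3280
serum_template_sigmas <- c(`616` = 12, `1080` = 20, `1171` = 14,
                           `1242` = 16, `1394` = 12, `1453` = 12,
                           `1536` = 16, `1650` = 17, `1717` = 10,
                           `2872` = 10, `2920` = 12, `2957` = 10,
                           `3280` = 30, `3750` = 12, `3903` = 10)

#' Dilution study design
#'
#' The emulated protocol: a stock control-serum solution diluted by the
#' given factors, acquired in replicate, with additive white Gaussian
#' noise on absorbance and an optional per-sample linear baseline drift.
#' All analyte concentrations scale together (lockstep) unless
#' `jitter_sd > 0` breaks the proportionality.
#'
#' @param stock Named stock concentration vector; default twice the
#'   packaged panel's `range_high` (so the diluted levels span exactly the
#'   packaged calibration ranges).
#' @param dilution_factors Distinct factors > 1. Default `c(2, 3, 5, 7, 10)`.
#' @param replicates Spectra per level. Default 3.
#' @param noise_sd Absorbance noise sd in AU. Default `1e-4` (clean).
#' @param drift_amplitude Linear baseline drift amplitude in AU. Default 0.
#' @param jitter_sd Relative sd of per-analyte, per-level lockstep-breaking
#'   jitter. Default 0.
#' @param seed Integer master seed; every random draw flows from it via
#'   per-sample substreams.
#' @return A list of class `study_design`.
#' @export
study_design <- function(stock = NULL, dilution_factors = c(2, 3, 5, 7, 10),
                         replicates = 3, noise_sd = 1e-4,
                         drift_amplitude = 0, jitter_sd = 0, seed = 1L) {
  if (is.null(stock)) {
    p <- serum_panel()
    stock <- stats::setNames(2 * p$range_high, p$analyte)
  }
  stopifnot(all(stock > 0), all(dilution_factors > 1),
            !anyDuplicated(dilution_factors), replicates >= 1, noise_sd >= 0,
            drift_amplitude >= 0, jitter_sd >= 0)
  structure(list(stock = stock, dilution_factors = dilution_factors,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "study_design")
}

# deterministic substream seed below 2^31
substream_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) * 1000003 + i * 10007 + j * 101) %% 2147483629)
}

#' Generate a synthetic serum band library
#'
#' Builds `n_bands` Gaussian bands: the named serum template centers (616,
#' 1080, ..., 3903 cm^-1) plus randomized filler bands. With the default
#' `n_bands = 49`, fillers are allocated so the ascending band indexing
#' pins index 2 to 616, 20 to 1717, 42 to 3750 and 49 to 3903 cm^-1. Every
#' band's Beer-Lambert loadings reference 1-5 analytes, scaled so the band
#' reaches its drawn amplitude at stock concentration; every analyte gets
#' at least one nonzero loading.
#'
#' @param panel Panel `data.frame` (as [serum_panel()]) or character vector
#'   of analyte ids. Default: the packaged panel.
#' @param n_bands Total bands, at least the 15 template centers. Default 49.
#' @param seed Integer seed; the library is deterministic given it.
#' @param background_centers Optional centers (cm^-1, matched exactly)
#'   whose bands are flagged as concentration-independent background.
#' @return A `data.frame` of class `synthetic_band_library` with columns
#'   `center`, `sigma`, `amplitude`, `background`; attribute `loadings` is
#'   the bands x analytes Beer-Lambert coefficient matrix.
#' @export
make_band_library <- function(panel = NULL, n_bands = 49, seed = 1L,
                              background_centers = NULL) {
  if (is.null(panel)) panel <- serum_panel()
  if (is.data.frame(panel)) {
    analytes <- panel$analyte
    stock <- stats::setNames(2 * panel$range_high, analytes)
  } else {
    analytes <- as.character(panel)
    stock <- stats::setNames(rep(1, length(analytes)), analytes)
  }
  tc <- serum_template_centers
  if (n_bands < length(tc))
    stop("n_bands must be at least the ", length(tc), " template centers")
  set.seed(substream_seed(seed, 0L))
  n_fill <- n_bands - length(tc)
  # jittered even spacing within a zone, skipping slots near interior
  # template centers; deterministic given the seeded jitter draws
  draw_in <- function(n, lo, hi, avoid) {
    if (n == 0) return(numeric(0))
    inner <- avoid[avoid > lo & avoid < hi]
    slots <- seq(lo, hi, length.out = n + length(inner) + 2)
    slots <- slots[-c(1, length(slots))]
    if (length(inner))
      slots <- slots[vapply(slots, function(x) all(abs(x - inner) >= 12), TRUE)]
    while (length(slots) < n) {   # dense fallback, rarely needed
      slots <- seq(lo, hi, length.out = 2 * length(slots) + 3)
      slots <- slots[-c(1, length(slots))]
      if (length(inner))
        slots <- slots[vapply(slots, function(x) all(abs(x - inner) >= 12), TRUE)]
    }
    slots <- slots[seq_len(n)]
    gap <- if (n > 1) min(diff(slots)) else hi - lo
    slots + stats::runif(n, -1, 1) * min(4, gap / 4)
  }
  fillers <- if (n_bands == 49) {
    # allocation pinning indices 2/20/42/49 to 616/1717/3750/3903
    c(draw_in(1, 520, 600, tc),
      draw_in(10, 632, 1701, tc),
      draw_in(17, 1733, 3734, tc),
      draw_in(6, 3766, 3887, tc))
  } else if (n_fill > 0) {
    draw_in(n_fill, 632, 3734, tc)
  } else numeric(0)
  centers <- sort(c(tc, fillers))
  is_template <- centers %in% tc
  # template bands keep their characteristic widths; fillers draw theirs
  sigma <- stats::runif(length(centers), 4, 30)
  sigma[is_template] <- serum_template_sigmas[as.character(centers[is_template])]
  amplitude <- ifelse(is_template,
                      serum_template_amps[as.character(centers)],
                      exp(stats::runif(length(centers), log(0.02), log(0.8))))
  # assign 1-5 analytes per band; then guarantee every analyte is covered
  n_an <- length(analytes)
  picks <- lapply(seq_along(centers), function(j)
    sample.int(n_an, sample.int(min(5L, n_an), 1)))
  missing <- setdiff(seq_len(n_an), unique(unlist(picks)))
  for (i in missing) {
    j <- sample.int(length(centers), 1)
    picks[[j]] <- unique(c(picks[[j]], i))
  }
  loadings <- matrix(0, length(centers), n_an,
                     dimnames = list(NULL, analytes))
  for (j in seq_along(centers)) {
    share <- stats::runif(length(picks[[j]]))
    share <- share / sum(share)
    loadings[j, picks[[j]]] <- amplitude[j] * share / stock[picks[[j]]]
  }
  background <- centers %in% background_centers
  loadings[background, ] <- 0
  lib <- data.frame(center = centers, sigma = sigma, amplitude = amplitude,
                    background = background)
  attr(lib, "loadings") <- loadings
  class(lib) <- c("synthetic_band_library", "data.frame")
  lib
}

default_grid <- function() seq(500, 4000, by = 4)

#' Simulate one spectrum from the band library
#'
#' Beer-Lambert mixing: absorbance is the sum over bands of a Gaussian
#' profile times the loading-weighted analyte concentrations (background
#' bands contribute their fixed amplitude), plus an optional per-sample
#' linear baseline drift and i.i.d. Gaussian noise. The random draw is a
#' deterministic substream of `(design$seed, sample, replicate)`.
#'
#' @param conc Named concentration vector.
#' @param library A [make_band_library()] result.
#' @param design A [study_design()].
#' @param sample Integer sample index (seeds the substream).
#' @param replicate Integer replicate index.
#' @param meta Extra meta entries for the spectrum.
#' @return An [ftir_spectrum()] on the 500-4000 cm^-1 grid at 4 cm^-1 steps.
#' @export
simulate_spectrum <- function(conc, library, design, sample = 1L,
                              replicate = 1L, meta = list()) {
  stopifnot(inherits(library, "synthetic_band_library"),
            inherits(design, "study_design"), all(conc > 0))
  grid <- default_grid()
  loadings <- attr(library, "loadings")
  amp_eff <- as.numeric(loadings[, names(conc), drop = FALSE] %*% conc)
  amp_eff[library$background] <- library$amplitude[library$background]
  profiles <- exp(-outer(grid, library$center, "-")^2 /
                    matrix(2 * library$sigma^2, length(grid), nrow(library),
                           byrow = TRUE))
  ab <- as.numeric(profiles %*% amp_eff)
  set.seed(substream_seed(design$seed, sample, replicate))
  if (design$drift_amplitude > 0) {
    u <- stats::runif(2, -1, 1)
    ab <- ab + design$drift_amplitude *
      (u[1] + u[2] * (grid - grid[1]) / diff(range(grid)))
  }
  if (design$noise_sd > 0)
    ab <- ab + stats::rnorm(length(grid), 0, design$noise_sd)
  meta$replicate <- replicate
  ftir_spectrum(grid, ab, meta)
}

#' Simulate a full dilution study
#'
#' One concentration panel per dilution level (`stock / factor`, optionally
#' jittered per analyte to break the lockstep proportionality), each
#' acquired in `design$replicates` spectra ordered (level, replicate).
#'
#' @param design A [study_design()].
#' @param library A [make_band_library()] result.
#' @return List with `spectra` (flat list, `meta$sample = "dil<factor>"`),
#'   `truth` (levels x analytes concentration matrix) and `design`.
#' @export
simulate_dilution_study <- function(design, library) {
  stopifnot(inherits(design, "study_design"))
  ids <- paste0("dil", design$dilution_factors)
  n_an <- length(design$stock)
  truth <- matrix(NA_real_, length(ids), n_an,
                  dimnames = list(ids, names(design$stock)))
  spectra <- list()
  for (li in seq_along(design$dilution_factors)) {
    d <- design$dilution_factors[li]
    conc <- design$stock / d
    if (design$jitter_sd > 0) {
      set.seed(substream_seed(design$seed, li, 999L))
      conc <- conc * (1 + stats::rnorm(n_an, 0, design$jitter_sd))
      conc <- pmax(conc, design$stock * 1e-6)
    }
    truth[li, ] <- conc
    for (r in seq_len(design$replicates)) {
      spectra[[length(spectra) + 1L]] <-
        simulate_spectrum(conc, library, design, sample = li, replicate = r,
                          meta = list(sample = ids[li], dilution = d))
    }
  }
  list(spectra = spectra, truth = truth, design = design)
}

#' Write a simulated study to disk
#'
#' Emits the spectrum CSV dialect the readers consume (one file per
#' spectrum), a ground-truth CSV of per-level concentrations, and a design
#' manifest JSON.
#'
#' @param study A [simulate_dilution_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in study$spectra) {
    f <- file.path(dir, sprintf("%s_rep%d.csv", s$meta$sample, s$meta$replicate))
    write_spectrum(s, f)
    paths <- c(paths, f)
  }
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(data.frame(sample = rownames(study$truth), study$truth,
                              check.names = FALSE),
                   truth_path, row.names = FALSE, quote = FALSE)
  design_path <- file.path(dir, "design.json")
  jsonlite::write_json(unclass(study$design), design_path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(list(spectra = paths, truth = truth_path, design = design_path))
}
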