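# Shared builders for synthetic test inputs (everything generated in code).

# one Gaussian (or a sum of Gaussians) sampled on a grid
gaussian_spectrum <- function(centers, amps, sigmas, grid = seq(500, 4000, 4),
                              baseline = 0, meta = list()) {
  ab <- rep(baseline, length(grid))[seq_along(grid)]
  if (length(baseline) == 1) ab <- rep(baseline, length(grid))
  for (i in seq_along(centers))
    ab <- ab + amps[i] * exp(-(grid - centers[i])^2 / (2 * sigmas[i]^2))
  ftir_spectrum(grid, ab, meta)
}

# small fast dilution study (few bands) for pipeline tests
tiny_study <- function(seed = 7, noise_sd = 0, n_bands = 15, ...) {
  design <- study_design(noise_sd = noise_sd, seed = seed, ...)
  lib <- make_band_library(n_bands = n_bands, seed = seed)
  c(simulate_dilution_study(design, lib), list(library = lib))
}

# simple two-column csv on disk; returns the path
write_csv_spectrum <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(lines, file)
  file
}
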