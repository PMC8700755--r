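test_that("csv reader parses, re-sorts descending input and rejects duplicates", {
  f <- write_csv_spectrum(c("500,0.1", "502,0.2", "504,0.1"))
  s <- read_spectrum(f)
  expect_equal(s$wavenumbers, c(500, 502, 504))
  expect_equal(s$absorbance, c(0.1, 0.2, 0.1))

  f_rev <- write_csv_spectrum(c("504,0.1", "502,0.2", "500,0.1"))
  s_rev <- read_spectrum(f_rev)
  expect_equal(s_rev$wavenumbers, s$wavenumbers)
  expect_equal(s_rev$absorbance, s$absorbance)
  expect_identical(s_rev$meta$original_orientation, "descending")

  f_hdr <- write_csv_spectrum(c("wavenumber,absorbance", "500,0.1", "502,0.2"))
  expect_equal(read_spectrum(f_hdr)$absorbance, c(0.1, 0.2))

  f_dup <- write_csv_spectrum(c("500,0.1", "500,0.2", "504,0.1"))
  expect_error(read_spectrum(f_dup), "monotonic")
  expect_error(read_spectrum(write_csv_spectrum("500,0.1")), "2 points")
})

test_that("read -> write -> read round-trips bit-identically for csv", {
  set.seed(1)
  s <- ftir_spectrum(seq(500, 900, 4), rnorm(101) * pi)
  f <- tempfile(fileext = ".csv")
  write_spectrum(s, f)
  s2 <- read_spectrum(f)
  expect_identical(s2$wavenumbers, s$wavenumbers)
  expect_identical(s2$absorbance, s$absorbance)
})

test_that("minimal JCAMP-DX XYDATA and XYPOINTS blocks are read", {
  f <- tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=synthetic serum film",
               "##JCAMP-DX=4.24", "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
               "##XFACTOR=1", "##YFACTOR=0.001",
               "##FIRSTX=500", "##LASTX=516", "##NPOINTS=5", "##DELTAX=4",
               "##XYDATA=(X++(Y..Y))",
               "500 100 200 300", "512 400 500",
               "##END="), f)
  s <- read_spectrum(f)
  expect_equal(s$wavenumbers, c(500, 504, 508, 512, 516))
  expect_equal(s$absorbance, c(0.1, 0.2, 0.3, 0.4, 0.5))

  f2 <- tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=t", "##XYPOINTS=(XY..XY)",
               "500,0.1 504,0.2", "508,0.3", "##END="), f2)
  s2 <- read_spectrum(f2)
  expect_equal(s2$wavenumbers, c(500, 504, 508))
  expect_equal(s2$absorbance, c(0.1, 0.2, 0.3))
})

test_that("replicate averaging is the pointwise mean and demands one grid", {
  s1 <- ftir_spectrum(c(500, 502), c(0, 2))
  s2 <- ftir_spectrum(c(500, 502), c(2, 0))
  expect_equal(average_replicates(list(s1))$absorbance, s1$absorbance)
  avg <- average_replicates(list(s1, s2))
  expect_equal(avg$absorbance, c(1, 1))
  expect_identical(avg$meta$n_replicates, 2L)
  s3 <- ftir_spectrum(c(500, 504), c(1, 1))
  expect_error(average_replicates(list(s1, s3)), "grid")
  expect_error(average_replicates(list()), "at least one")
})

test_that("two-point baseline zeroes lines, is idempotent, preserves peak area", {
  g <- seq(1000, 2000, 1)
  lin <- ftir_spectrum(g, 0.2 + 3e-4 * (g - 1000))
  expect_equal(baseline_correct_two_point(lin)$absorbance, rep(0, length(g)))
  flat <- ftir_spectrum(g, rep(0.5, length(g)))
  expect_equal(baseline_correct_two_point(flat)$absorbance, rep(0, length(g)))

  # Gaussian on a ramp: after correction with anchors flanking the peak,
  # the trapezoid area over the window matches amplitude * sigma * sqrt(2*pi)
  amp <- 0.8; sig <- 12; ctr <- 1500
  ramp <- ftir_spectrum(g, 0.1 + 2e-4 * (g - 1000) +
                          amp * exp(-(g - ctr)^2 / (2 * sig^2)))
  bc <- baseline_correct_two_point(ramp, left = 1350, right = 1650)
  sel <- g >= 1350 & g <= 1650
  area <- sum(diff(g[sel]) * (bc$absorbance[sel][-1] +
                                bc$absorbance[sel][-sum(sel)]) / 2)
  expect_equal(area, amp * sig * sqrt(2 * pi), tolerance = 0.005)

  twice <- baseline_correct_two_point(baseline_correct_two_point(ramp))
  once <- baseline_correct_two_point(ramp)
  expect_equal(twice$absorbance, once$absorbance)

  expect_error(baseline_correct_two_point(lin, 900, 1500), "span")
  expect_error(baseline_correct_two_point(lin, 1500, 1200), "left < right")
})

test_that("vector normalization divides by the in-range Euclidean norm", {
  s <- ftir_spectrum(c(500, 502), c(3, 4))
  expect_equal(vector_normalize(s)$absorbance, c(0.6, 0.8))

  set.seed(2)
  r <- ftir_spectrum(seq(500, 600, 2), runif(51, 0.1, 1))
  n1 <- vector_normalize(r)
  n2 <- vector_normalize(ftir_spectrum(r$wavenumbers, 7.3 * r$absorbance))
  expect_equal(n1$absorbance, n2$absorbance)
  expect_equal(sqrt(sum(n1$absorbance^2)), 1, tolerance = 1e-12)

  rng <- wn_range(520, 560)
  nn <- vector_normalize(r, rng)
  sel <- r$wavenumbers >= 520 & r$wavenumbers <= 560
  expect_equal(sqrt(sum(nn$absorbance[sel]^2)), 1, tolerance = 1e-12)

  z <- ftir_spectrum(c(500, 502, 504), c(0, 0, 0))
  expect_error(vector_normalize(z), "zero norm")
})

test_that("straight-line excision replaces only the interior with the chord", {
  g <- seq(2000, 2600, 4)
  flat <- ftir_spectrum(g, rep(0.3, length(g)))
  expect_equal(excise_straight_line(flat)$absorbance, flat$absorbance)

  s <- gaussian_spectrum(c(2330, 2360), c(0.5, 0.4), c(8, 8), grid = g,
                         baseline = 0.05)
  ex <- excise_straight_line(s, wn_range(2280, 2400))
  out <- g < 2280 | g > 2400
  expect_identical(ex$absorbance[out], s$absorbance[out])
  i1 <- which.min(abs(g - 2280)); i2 <- which.min(abs(g - 2400))
  chord <- approx(g[c(i1, i2)], s$absorbance[c(i1, i2)], xout = g[i1:i2])$y
  expect_equal(ex$absorbance[i1:i2], chord)
  ex2 <- excise_straight_line(ex, wn_range(2280, 2400))
  expect_equal(ex2$absorbance, ex$absorbance)

  expect_error(excise_straight_line(s, wn_range(1900, 2100)), "inside")
})

test_that("preprocessing applies the fixed order and records it in meta", {
  study <- tiny_study(seed = 3)
  out <- preprocess_samples(study$spectra,
                            preprocess_options(normalize = TRUE))
  expect_named(out, rownames(study$truth))
  steps <- out[[1]]$meta$processing
  expect_match(steps[1], "average_replicates")
  expect_match(steps[2], "baseline_two_point")
  expect_match(steps[3], "excise")
  expect_match(steps[4], "vector_normalize")
})
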