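test_that("pearson correlation matches hand computation and validates input", {
  expect_equal(pearson_correlation(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_correlation(1:5, -(1:5)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 4)), 0.9820,
               tolerance = 1e-4)
  expect_error(pearson_correlation(1:3, 1:4), "length")
  expect_error(pearson_correlation(1:2, 2:3), "3 observations")
  expect_error(pearson_correlation(c(1, 1, 1), 1:3), "constant")
})

test_that("feature screening keeps proportional features, rejects noise", {
  conc <- c(dil2 = 1 / 2, dil3 = 1 / 3, dil5 = 1 / 5, dil7 = 1 / 7, dil10 = 1 / 10)
  targets <- outer(conc, c(B1 = 10, B2 = 0.5))   # lockstep panel
  set.seed(41)
  fm <- cbind(H1 = 3 * conc, S1 = runif(5), H2 = 80 * conc + rnorm(5, 0, 20))
  rownames(fm) <- names(conc)
  keep <- screen_primary_features(fm, targets, search_config())
  expect_identical(keep, "H1")

  # a pure-noise feature passes r > 0.999 with vanishing probability at n = 6
  set.seed(42)
  hits <- sum(replicate(400, {
    x <- seq_len(6); y <- rnorm(6)
    cor(x, y) > 0.999
  }))
  expect_identical(hits, 0L)

  # lockstep: what passes for one analyte passes for all
  fm2 <- cbind(H1 = 3 * conc, S1 = 7 * conc)
  rownames(fm2) <- names(conc)
  expect_identical(screen_primary_features(fm2, targets[, 1, drop = FALSE]),
                   screen_primary_features(fm2, targets[, 2, drop = FALSE]))

  const <- cbind(fm2, S2 = rep(1, 5))
  expect_warning(screen_primary_features(const, targets), "constant")
})

test_that("ratio-term enumeration matches brute-force counts", {
  cfg1 <- search_config(max_degree = 1, total_degree_cap = 1)
  expect_length(enumerate_ratio_terms("x", cfg1), 2)

  cfg2 <- search_config(max_degree = 2, total_degree_cap = 2)
  expect_length(enumerate_ratio_terms(c("a", "b"), cfg2), 12)

  # independent nested-loop count for all feature-set sizes <= 3, caps <= 4
  brute_count <- function(nf, d, cap) {
    cnt <- 0
    rng <- -d:d
    if (nf == 1) for (p in rng) {
      if (p != 0 && abs(p) <= cap) cnt <- cnt + 1
    }
    if (nf == 2) for (p in rng) for (q in rng) {
      t <- abs(p) + abs(q)
      if (t > 0 && t <= cap) cnt <- cnt + 1
    }
    if (nf == 3) for (p in rng) for (q in rng) for (r in rng) {
      t <- abs(p) + abs(q) + abs(r)
      if (t > 0 && t <= cap) cnt <- cnt + 1
    }
    cnt
  }
  for (nf in 1:3) for (d in 1:2) for (cap in 1:4) {
    cfg <- search_config(max_degree = d, total_degree_cap = cap)
    expect_length(enumerate_ratio_terms(letters[seq_len(nf)], cfg),
                  brute_count(nf, d, cap))
  }

  # canonical order is deterministic
  t1 <- enumerate_ratio_terms(c("a", "b"), cfg2)
  t2 <- enumerate_ratio_terms(c("a", "b"), cfg2)
  expect_identical(t1, t2)
})

test_that("all three reference composite terms appear in the enumeration", {
  feats <- c("H20", "H49", "S2", "S42", "S49")
  terms <- enumerate_ratio_terms(feats, search_config(max_degree = 2,
                                                      total_degree_cap = 5))
  key <- function(t) paste(sort(paste0(names(t), ":", t)), collapse = ",")
  keys <- vapply(terms, key, character(1))
  want <- vapply(reference_composite()$terms, key, character(1))
  expect_true(all(want %in% keys))
})

test_that("term screening keeps monotone-matching terms in canonical order", {
  conc <- c(1 / 2, 1 / 3, 1 / 5, 1 / 7, 1 / 10)
  fm <- cbind(H1 = 3 * conc, S1 = 5 * conc^2)
  rownames(fm) <- paste0("s", 1:5)
  targets <- outer(conc, c(B1 = 10, B2 = 2))
  terms <- enumerate_ratio_terms(colnames(fm),
                                 search_config(max_degree = 1,
                                               total_degree_cap = 2))
  kept <- screen_terms(terms, fm, targets, search_config())
  ids <- vapply(kept, format, character(1))
  expect_true("H1" %in% ids)                 # proportional to concentration
  expect_false("H1^-1" %in% ids)             # anti-monotone, r = -1
  expect_false("S1" %in% ids)                # quadratic in c, r < 0.999
  expect_true("H1^-1 * S1" %in% ids)         # degree-1 combination

  kept_b <- screen_terms(terms, fm, targets[, 2, drop = FALSE], search_config())
  expect_identical(ids, vapply(kept_b, format, character(1)))
})

test_that("term evaluation reports division by zero with context", {
  fm <- cbind(H1 = c(1, 0), S1 = c(2, 3))
  rownames(fm) <- c("a", "b")
  term <- structure(c(H1 = -1L, S1 = 1L), class = "monomial_term")
  expect_error(evaluate_term(term, fm), "division by zero.*b.*H1")
  expect_error(evaluate_term(structure(c(Q9 = 1L), class = "monomial_term"), fm),
               "missing feature")
})

test_that("simplex weight fitting matches brute-force and closed-form oracles", {
  # single term: weight exactly 1
  fm <- cbind(A = c(1, 2, 3, 5, 7))
  one <- fit_term_weights(list(structure(c(A = 1L), class = "monomial_term")),
                          fm, c(1, 2, 3, 5, 7))
  expect_identical(one$weights, 1)

  # term1 equals the target, term2 is orthogonal noise -> weights ~ (1, 0)
  set.seed(8)
  y <- c(1, 2, 3, 5, 7)
  noise <- residuals(lm(rnorm(5) ~ y))
  fm2 <- cbind(A = y, B = as.numeric(noise) + 10)
  terms2 <- list(structure(c(A = 1L), class = "monomial_term"),
                 structure(c(B = 1L), class = "monomial_term"))
  fit2 <- fit_term_weights(terms2, fm2, y)
  expect_equal(fit2$weights, c(1, 0), tolerance = 1e-6)

  # dense grid search over the 2-simplex agrees with the solver objective
  set.seed(9)
  fm3 <- cbind(A = runif(6, 0.5, 2), B = runif(6, 0.5, 2), C = runif(6, 0.5, 2))
  terms3 <- lapply(colnames(fm3), function(f)
    structure(stats::setNames(1L, f), class = "monomial_term"))
  y3 <- runif(6, 0.5, 2)
  fit3 <- fit_term_weights(terms3, fm3, y3)
  a <- rep(seq(0, 1, 1e-3), each = 1001)
  b <- rep(seq(0, 1, 1e-3), times = 1001)
  ok <- a + b <= 1
  a <- a[ok]; b <- b[ok]
  u <- fm3[, 1] - fm3[, 3]; v <- fm3[, 2] - fm3[, 3]; w <- fm3[, 3] - y3
  grid_obj <- sum(w^2) +
    a^2 * sum(u^2) + b^2 * sum(v^2) + 2 * a * b * sum(u * v) +
    2 * a * sum(u * w) + 2 * b * sum(v * w)
  expect_lte(attr(fit3, "objective"), min(grid_obj) + 1e-6)
  expect_gte(attr(fit3, "objective"), min(grid_obj) - 1e-6)

  # the fitted mixture is no worse than any single term (simplex vertices)
  for (j in 1:3) {
    vert <- sum((fm3[, j] - y3)^2)
    expect_lte(attr(fit3, "objective"), vert + 1e-12)
  }

  # reduced-gradient solver agrees with an independent KKT active-set solve
  kkt_best <- function(TT, y) {
    m <- ncol(TT); best <- Inf
    for (k in seq_len(2^m - 1)) {
      supp <- which(bitwAnd(k, 2^(seq_len(m) - 1)) > 0)
      Ts <- TT[, supp, drop = FALSE]
      A <- rbind(cbind(2 * crossprod(Ts), 1), c(rep(1, length(supp)), 0))
      sol <- tryCatch(solve(A, c(2 * crossprod(Ts, y), 1)),
                      error = function(e) NULL)
      if (is.null(sol)) next
      ws <- sol[seq_along(supp)]
      if (any(ws < -1e-12)) next
      best <- min(best, sum((Ts %*% ws - y)^2))
    }
    best
  }
  for (rep_i in 1:5) {
    set.seed(100 + rep_i)
    TT <- matrix(runif(8 * 4, 0.2, 3), 8, 4)
    colnames(TT) <- letters[1:4]
    yy <- runif(8, 0.2, 3)
    tt <- lapply(colnames(TT), function(f)
      structure(stats::setNames(1L, f), class = "monomial_term"))
    fit <- fit_term_weights(tt, TT, yy)
    expect_equal(attr(fit, "objective"), kkt_best(TT, yy), tolerance = 1e-8)
  }
})

test_that("composite evaluation is the scaled weighted term sum", {
  cf <- composite_feature(reference_composite()$terms, rep(1 / 3, 3))
  ones <- c(H20 = 1, H49 = 1, S2 = 1, S42 = 1, S49 = 1)
  expect_equal(evaluate_composite(cf, ones), 1)
  expect_equal(evaluate_composite(reference_composite(), ones), 3)

  terms <- lapply(c("A", "B", "C"), function(f)
    structure(stats::setNames(1L, f), class = "monomial_term"))
  cf2 <- composite_feature(terms, c(0.5, 0.5, 0))
  expect_equal(evaluate_composite(cf2, c(A = 2, B = 3, C = 4)), 2.5)

  expect_error(evaluate_composite(reference_composite(),
                                  c(H20 = 0, H49 = 1, S2 = 1, S42 = 1, S49 = 1)),
               "division by zero")
  expect_error(composite_feature(terms, c(0.5, 0.6, 0.2)), "sum to 1")
  expect_error(composite_feature(terms, c(0.9, 0.2, -0.1)), "nonnegative")
})

test_that("the fitted composite tracks concentration exactly on lockstep data", {
  study <- tiny_study(seed = 13, noise_sd = 0)
  fit <- ftir_calibrate(study$spectra, study$truth)
  K <- fit$training$K
  expect_gt(cor(K, study$truth[, 1]), 0.999999)
})
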