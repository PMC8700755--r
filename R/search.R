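# Composite-feature search: correlation screening of band features,
# enumeration of signed-exponent ratio terms, and simplex-constrained
# least-squares weight fitting by a reduced-gradient solver.
#
# The restriction to multiplication/division is deliberate: Pearson's r is
# invariant under positive affine maps of either argument, so adding terms
# or rescaling cannot create correlation that products and ratios cannot.

#' Search configuration
#'
#' @param r_threshold Pearson correlation a feature or term must exceed
#'   against every analyte concentration to be retained. Default 0.999.
#' @param max_degree Per-feature absolute exponent bound for ratio terms.
#'   Default 2.
#' @param total_degree_cap Bound on the sum of absolute exponents of a term.
#'   Default 5.
#' @param max_terms Maximum number of terms combined into the composite
#'   feature (greedy best-objective selection). Default 3.
#' @param max_features Cap on screened primary features carried into term
#'   enumeration, ranked by worst-case correlation across analytes.
#'   Default 5.
#' @param seed Integer seed for optional randomized restarts; the search
#'   itself is deterministic.
#' @return A list of class `search_config`.
#' @export
search_config <- function(r_threshold = 0.999, max_degree = 2,
                          total_degree_cap = 5, max_terms = 3,
                          max_features = 5, seed = 1L) {
  stopifnot(r_threshold > 0, r_threshold < 1, max_degree >= 1,
            total_degree_cap >= 1, max_terms >= 1, max_features >= 1)
  structure(list(r_threshold = r_threshold, max_degree = as.integer(max_degree),
                 total_degree_cap = as.integer(total_degree_cap),
                 max_terms = as.integer(max_terms),
                 max_features = as.integer(max_features),
                 seed = as.integer(seed)),
            class = "search_config")
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: requires equal lengths
#' >= 3 and non-constant inputs.
#'
#' @param x,y Numeric vectors.
#' @return r in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)
}

# Coerce concentration targets to a samples x analytes numeric matrix.
as_conc_matrix <- function(targets) {
  if (is.data.frame(targets)) targets <- as.matrix(targets)
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 1,
                                               dimnames = list(names(targets), "B1"))
  storage.mode(targets) <- "double"
  targets
}

# Minimum correlation of v against every analyte column.
min_cor_vs_targets <- function(v, conc) {
  if (stats::sd(v) == 0) return(-Inf)
  min(apply(conc, 2, function(b) stats::cor(v, b)))
}

#' Screen primary band features by correlation
#'
#' Keeps feature columns whose Pearson correlation with *every* analyte's
#' concentration exceeds `r_threshold`; constant columns are dropped with a
#' warning. At most `max_features` survivors are kept. By default survivors
#' are ranked by their worst-case (minimum) correlation across analytes;
#' when `rank_by` provides a per-feature measurement-noise score (e.g.
#' replicate-level relative scatter, lower is better), survivors are ranked
#' by it instead — with few calibration samples, correlation differences
#' among passing features are dominated by chance, while replicate scatter
#' measures which features are actually read precisely. Ties break by
#' column order.
#'
#' @param fm Feature matrix from [build_feature_matrix()].
#' @param targets Concentration matrix/data.frame (samples x analytes) with
#'   rows aligned to `fm`.
#' @param cfg A [search_config()].
#' @param rank_by Optional named numeric vector of per-feature noise scores
#'   (lower = more precise) used to rank survivors.
#' @return Character vector of retained feature ids.
#' @export
screen_primary_features <- function(fm, targets, cfg = search_config(),
                                    rank_by = NULL) {
  conc <- as_conc_matrix(targets)
  if (nrow(conc) != nrow(fm)) stop("feature matrix and targets have misaligned samples")
  if (!is.null(rownames(fm)) && !is.null(rownames(conc)) &&
      !all(rownames(fm) == rownames(conc)))
    stop("feature matrix and targets have misaligned samples")
  if (nrow(fm) < 3) stop("need at least 3 samples to screen by correlation")
  const <- apply(fm, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(fm)[const], collapse = ", "))
    fm <- fm[, !const, drop = FALSE]
  }
  rmin <- apply(fm, 2, min_cor_vs_targets, conc = conc)
  keep <- which(rmin > cfg$r_threshold)
  keep <- if (!is.null(rank_by)) {
    score <- rank_by[colnames(fm)[keep]]
    score[is.na(score)] <- Inf
    keep[order(score, keep)]
  } else {
    keep[order(-rmin[keep], keep)]
  }
  if (length(keep) > cfg$max_features) keep <- keep[seq_len(cfg$max_features)]
  colnames(fm)[sort(keep)]
}

#' Enumerate signed-exponent ratio terms
#'
#' All distinct monomials over the given features with per-feature integer
#' exponents in `[-max_degree, max_degree]` and total absolute degree at
#' most `total_degree_cap`, excluding the empty monomial. Order is
#' deterministic: lexicographic in the exponent vector over the features in
#' the order given.
#'
#' @param features Character vector of feature ids.
#' @param cfg A [search_config()].
#' @return List of terms; each term is a named integer vector of nonzero
#'   exponents (class `monomial_term`).
#' @export
enumerate_ratio_terms <- function(features, cfg = search_config()) {
  stopifnot(length(features) >= 1)
  d <- cfg$max_degree
  grid <- do.call(expand.grid,
                  c(rep(list(seq(-d, d)), length(features)),
                    KEEP.OUT.ATTRS = FALSE))
  tot <- rowSums(abs(grid))
  grid <- grid[tot > 0 & tot <= cfg$total_degree_cap, , drop = FALSE]
  # lexicographic order in the exponent vector, first feature most significant
  ord <- do.call(order, as.list(grid))
  grid <- grid[ord, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    e <- as.integer(grid[i, ])
    names(e) <- features
    structure(e[e != 0], class = "monomial_term")
  })
}

#' @export
format.monomial_term <- function(x, ...) {
  paste(vapply(seq_along(x), function(i) {
    if (x[i] == 1) names(x)[i] else sprintf("%s^%d", names(x)[i], x[i])
  }, character(1)), collapse = " * ")
}

#' @export
print.monomial_term <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate one ratio term on a feature matrix
#'
#' @param term A `monomial_term` (named integer exponents).
#' @param fm Feature matrix with the term's features as columns.
#' @return Numeric vector, one value per sample.
#' @export
evaluate_term <- function(term, fm) {
  miss <- setdiff(names(term), colnames(fm))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  out <- rep(1, nrow(fm))
  for (f in names(term)) {
    v <- fm[, f]
    if (term[[f]] < 0 && any(v == 0)) {
      bad <- if (is.null(rownames(fm))) which(v == 0)[1] else rownames(fm)[v == 0][1]
      stop(sprintf("division by zero evaluating term %s at sample %s (feature %s)",
                   format(term), bad, f))
    }
    out <- out * v^term[[f]]
  }
  out
}

#' Screen ratio terms by correlation with every analyte
#'
#' Retains terms whose evaluated per-sample vector correlates above
#' `r_threshold` with every analyte concentration; order of survivors is
#' the canonical enumeration order.
#'
#' @param terms List of `monomial_term`s.
#' @inheritParams screen_primary_features
#' @return List of retained terms.
#' @export
screen_terms <- function(terms, fm, targets, cfg = search_config()) {
  conc <- as_conc_matrix(targets)
  if (nrow(conc) != nrow(fm)) stop("feature matrix and targets have misaligned samples")
  keep <- vapply(terms, function(t) {
    v <- evaluate_term(t, fm)
    min_cor_vs_targets(v, conc) > cfg$r_threshold
  }, TRUE)
  terms[keep]
}

# Euclidean projection onto the probability simplex (Held et al. sort
# algorithm).
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

# Equality-constrained least squares on a support set: minimize |T w - y|^2
# s.t. sum(w) = 1, via the KKT system. Returns NULL if singular.
eq_constrained_ls <- function(TT, y) {
  m <- ncol(TT)
  A <- rbind(cbind(2 * crossprod(TT), rep(1, m)), c(rep(1, m), 0))
  b <- c(2 * crossprod(TT, y), 1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(sol)) NULL else sol[seq_len(m)]
}

#' Fit simplex-constrained term weights (reduced-gradient solver)
#'
#' Finds nonnegative weights summing to one that minimize the squared
#' deviation of the weighted term sum from the target vector. The solver is
#' projected reduced-gradient descent on the simplex: analytic gradient,
#' fixed step 1/L from the largest singular value of the term matrix, with
#' an Armijo backtracking fallback, declared converged when the objective
#' improves by less than `tol`. A final active-set polish solves the
#' equality-constrained least-squares problem on the positive support and
#' keeps it when feasible and at least as good. The problem is convex, so
#' the result is seed-independent.
#'
#' @param terms List of `monomial_term`s (length >= 1).
#' @param fm Feature matrix.
#' @param target Numeric target vector, one value per sample (the reference
#'   analyte's concentrations rescaled to unit mean in the calibration
#'   workflow).
#' @param cfg A [search_config()].
#' @param tol Convergence tolerance on objective improvement. Default 1e-12.
#' @param max_iter Iteration cap; default `max(10 * m^2, 500)` for `m` terms.
#' @param method `"reduced_gradient"` (default) runs the iterative solver
#'   with an active-set polish; `"active_set"` solves the convex QP exactly
#'   by enumerating active sets (requires few terms) — the closed-form
#'   route used internally to score candidate term sets.
#' @return A [composite_feature()] with attributes `objective`,
#'   `iterations` and `converged`.
#' @export
fit_term_weights <- function(terms, fm, target, cfg = search_config(),
                             tol = 1e-12, max_iter = NULL,
                             method = c("reduced_gradient", "active_set")) {
  method <- match.arg(method)
  m <- length(terms)
  stopifnot(m >= 1)
  TT <- vapply(terms, evaluate_term, numeric(nrow(fm)), fm = fm)
  TT <- matrix(TT, nrow = nrow(fm))
  if (any(apply(TT, 2, function(v) all(v == 0))))
    stop("degenerate all-zero term column")
  if (length(target) != nrow(fm)) stop("target length must match sample count")
  if (m == 1) {
    w <- 1
    obj <- sum((TT %*% w - target)^2)
    return(structure(composite_feature(terms, w),
                     objective = obj, iterations = 0L, converged = TRUE))
  }
  if (method == "active_set") {
    if (m > 12) stop("active_set method supports at most 12 terms")
    best <- NULL
    obj_fn <- function(w) sum((TT %*% w - target)^2)
    for (k in seq_len(2^m - 1)) {
      supp <- which(bitwAnd(k, 2^(seq_len(m) - 1)) > 0)
      ws <- eq_constrained_ls(TT[, supp, drop = FALSE], target)
      if (is.null(ws) || any(ws < -1e-12)) next
      w_try <- numeric(m)
      w_try[supp] <- pmax(ws, 0)
      w_try <- w_try / sum(w_try)
      f_try <- obj_fn(w_try)
      if (is.null(best) || f_try < best$f) best <- list(w = w_try, f = f_try)
    }
    return(structure(composite_feature(terms, best$w),
                     objective = best$f, iterations = 0L, converged = TRUE))
  }
  if (is.null(max_iter)) max_iter <- max(10L * m^2, 500L)
  obj_fn <- function(w) sum((TT %*% w - target)^2)
  grad_fn <- function(w) as.numeric(2 * crossprod(TT, TT %*% w - target))
  L <- 2 * max(svd(TT, nu = 0, nv = 0)$d)^2
  if (L == 0) stop("degenerate all-zero term matrix")
  w <- rep(1 / m, m)
  f <- obj_fn(w)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    g <- grad_fn(w)
    w_new <- project_simplex(w - g / L)
    f_new <- obj_fn(w_new)
    if (f_new > f - 1e-4 * sum(g * (w - w_new))) {
      # Armijo backtracking on the projection arc
      step <- 1 / L
      repeat {
        step <- step / 2
        w_new <- project_simplex(w - step * g)
        f_new <- obj_fn(w_new)
        if (f_new <= f || step < 1e-18) break
      }
    }
    if (f - f_new < tol) {
      w <- if (f_new < f) w_new else w
      f <- min(f, f_new)
      converged <- TRUE
      break
    }
    w <- w_new
    f <- f_new
  }
  # active-set polish: exact equality-constrained LS. For small m all
  # supports are enumerated (exact solve of the convex QP); otherwise only
  # the positive support of the iterate is tried.
  supports <- if (m <= 8) {
    lapply(seq_len(2^m - 1), function(k) which(bitwAnd(k, 2^(seq_len(m) - 1)) > 0))
  } else list(which(w > 1e-10))
  for (supp in supports) {
    ws <- eq_constrained_ls(TT[, supp, drop = FALSE], target)
    if (is.null(ws) || any(ws < -1e-12)) next
    w_try <- numeric(m)
    w_try[supp] <- pmax(ws, 0)
    w_try <- w_try / sum(w_try)
    f_try <- obj_fn(w_try)
    if (f_try <= f + 1e-15) {
      w <- w_try
      f <- f_try
      converged <- TRUE
    }
  }
  if (!converged)
    warning(sprintf("weight fit stopped at iteration cap (final gradient norm %.3g)",
                    sqrt(sum(grad_fn(w)^2))))
  structure(composite_feature(terms, w),
            objective = f, iterations = it, converged = converged)
}

#' Composite feature
#'
#' A weighted sum of ratio terms; evaluates to the shared feature K. Weights
#' lie on the probability simplex; `scale` carries any overall factor (so a
#' plain unweighted sum of `m` terms is weights `1/m` with `scale = m`).
#'
#' @param terms List of `monomial_term`s.
#' @param weights Nonnegative weights summing to 1 (tolerance 1e-9).
#' @param scale Overall positive scale factor. Default 1.
#' @return An object of class `composite_feature`.
#' @export
composite_feature <- function(terms, weights, scale = 1) {
  weights <- as.numeric(weights)
  if (length(terms) != length(weights))
    stop("terms and weights must have equal length")
  if (any(weights < -1e-12)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  stopifnot(scale > 0)
  structure(list(terms = terms, weights = pmax(weights, 0), scale = scale),
            class = "composite_feature")
}

#' @export
print.composite_feature <- function(x, digits = 6, ...) {
  cat("Composite feature K =",
      if (x$scale != 1) sprintf("%.6g * [", x$scale) else "", "\n")
  for (i in seq_along(x$terms))
    cat(sprintf("  %+.*g * %s\n", digits, x$weights[i], format(x$terms[[i]])))
  if (x$scale != 1) cat("]\n")
  invisible(x)
}

#' Evaluate the composite feature K
#'
#' `K = scale * sum_t w_t * prod_f value_f^exponent_{t,f}`.
#'
#' @param cf A [composite_feature()].
#' @param features Named numeric vector of feature values, or a feature
#'   matrix (rows = samples).
#' @return K (scalar, or one value per row of a matrix input).
#' @export
evaluate_composite <- function(cf, features) {
  stopifnot(inherits(cf, "composite_feature"))
  fm <- if (is.matrix(features)) features else
    matrix(features, nrow = 1, dimnames = list(NULL, names(features)))
  active <- cf$weights > 0
  vals <- rep(0, nrow(fm))
  for (i in which(active))
    vals <- vals + cf$weights[i] * evaluate_term(cf$terms[[i]], fm)
  out <- cf$scale * vals
  if (is.matrix(features)) out else as.numeric(out)
}

# leave-one-out PRESS of a term set: refit weights on n-1 samples (exact
# active-set solve), predict the held-out target value, accumulate squared
# prediction error
loo_press <- function(terms, fm, target, cfg) {
  n <- nrow(fm)
  press <- 0
  for (i in seq_len(n)) {
    fit_i <- fit_term_weights(terms, fm[-i, , drop = FALSE], target[-i],
                              cfg, method = "active_set")
    pred_i <- evaluate_composite(fit_i, fm[i, , drop = FALSE])
    press <- press + (pred_i - target[i])^2
  }
  press
}

# first-order propagated measurement variance of a fitted composite,
# summed over the design: dK/K = sum_f c_f df/f with
# c_f = sum_t (w_t T_t / K) e_tf, so var_rel = sum_f c_f^2 s_f^2 per
# sample; returns sum_s var_rel_s * K_s^2 (same scale as an SSE)
composite_noise_var <- function(cf, fm, noise) {
  K <- evaluate_composite(cf, fm)
  tot <- 0
  for (s in seq_len(nrow(fm))) {
    cs <- numeric(ncol(fm))
    names(cs) <- colnames(fm)
    for (t in seq_along(cf$terms)) {
      if (cf$weights[t] == 0) next
      Tt <- cf$scale * cf$weights[t] *
        evaluate_term(cf$terms[[t]], fm[s, , drop = FALSE])
      e <- cf$terms[[t]]
      cs[names(e)] <- cs[names(e)] + Tt * as.numeric(e)
    }
    sf <- noise[names(cs)]
    sf[is.na(sf)] <- 0
    tot <- tot + sum((cs * sf)^2)
  }
  tot
}

#' Greedy term selection by propagated uncertainty and leave-one-out error
#'
#' Selects the composite's terms in two stages. First the screened
#' candidates are ranked by the measurement uncertainty each term
#' propagates: to first order the relative error of a ratio term is
#' `sqrt(sum_f (e_f * scatter_f)^2)` over its exponents, so high-degree
#' terms on imprecise features score poorly; only the `pool_size` most
#' precise candidates are kept (without a `noise` estimate the ranking
#' falls back to total absolute degree — the same parsimony principle with
#' equal feature precision). Then forward selection runs within that pool:
#' each round refits the simplex weights for every candidate extension and
#' adds the term with the smallest leave-one-out PRESS (predicted residual
#' sum of squares), up to `cfg$max_terms` terms, stopping early when no
#' candidate improves the PRESS. PRESS rather than the in-sample objective
#' is used because with few calibration samples and up to three free
#' weights the in-sample fit cannot separate genuinely predictive terms
#' from noise-fitting ones. All ties break toward the earlier term in
#' canonical order. The returned composite is refit on all samples with
#' the reduced-gradient solver.
#'
#' @param terms Screened candidate terms.
#' @inheritParams fit_term_weights
#' @param tol Minimum PRESS improvement to accept another term.
#'   Default 1e-14.
#' @param noise Optional named per-feature relative measurement scatter
#'   (as from [replicate_feature_scatter()]) for the uncertainty ranking.
#' @param pool_size Candidate pool size after the uncertainty ranking.
#'   Default 25.
#' @return The fitted [composite_feature()] (attributes as in
#'   [fit_term_weights()], plus `press`).
#' @export
select_and_fit_terms <- function(terms, fm, target, cfg = search_config(),
                                 tol = 1e-14, noise = NULL, pool_size = 25) {
  stopifnot(length(terms) >= 1)
  if (nrow(fm) < 3) stop("need at least 3 samples for leave-one-out selection")
  score <- if (!is.null(noise)) {
    vapply(terms, function(t) {
      s <- noise[names(t)]
      s[is.na(s)] <- max(noise, na.rm = TRUE)
      sqrt(sum((as.numeric(t) * s)^2))
    }, 0)
  } else {
    vapply(terms, function(t) sum(abs(t)), 0)
  }
  pool <- order(score, seq_along(terms))[seq_len(min(pool_size, length(terms)))]
  terms <- terms[sort(pool)]
  # candidate score: LOO PRESS plus the composite's analytically propagated
  # measurement variance (rescaled from K units to target units) — the
  # empirical and model-based error estimates damp each other's selection
  # bias over many candidates
  cand_score <- function(set) {
    p <- loo_press(set, fm, target, cfg)
    if (is.null(noise)) return(p)
    fit_full <- fit_term_weights(set, fm, target, cfg, method = "active_set")
    K <- evaluate_composite(fit_full, fm)
    p + composite_noise_var(fit_full, fm, noise) * (mean(target) / mean(K))^2
  }
  chosen <- integer(0)
  best_score <- Inf
  repeat {
    if (length(chosen) >= cfg$max_terms) break
    cand <- rep(Inf, length(terms))
    for (j in seq_along(terms)) {
      if (j %in% chosen) next
      cand[j] <- cand_score(terms[c(chosen, j)])
    }
    j_best <- which.min(cand)
    if (!is.finite(cand[j_best]) || best_score - cand[j_best] <= tol) break
    chosen <- c(chosen, j_best)
    best_score <- cand[j_best]
  }
  if (length(chosen) == 0) {
    chosen <- 1L
    best_score <- cand_score(terms[1])
  }
  fit <- fit_term_weights(terms[chosen], fm, target, cfg)
  attr(fit, "press") <- best_score
  fit
}
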