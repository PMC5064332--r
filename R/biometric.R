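# Variance-component models for the classical twin design.
#
# Genetic theory fixes the cross-twin correlation of each latent factor:
# additive effects (A) correlate 1 in MZ and 0.5 in DZ pairs, dominance
# deviations (D) 1 and 0.25, shared environment (C) 1 in both, and the
# random environment (E) 0. With standardized components a2+c2+d2+e2 = 1 the
# implied liability correlations are
#   r_MZ = a2 + c2 + d2,   r_DZ = 0.5 a2 + c2 + 0.25 d2.

.MODEL_FREE <- list(
  ADE = c("a2", "d2"),
  ACE = c("a2", "c2"),
  AE  = "a2",
  CE  = "c2",
  DE  = "d2",
  E   = character(0)
)
.RMZ_COEF <- c(a2 = 1, c2 = 1, d2 = 1)
.RDZ_COEF <- c(a2 = 0.5, c2 = 1, d2 = 0.25)

#' Standardized twin variance components
#'
#' Constructor for a set of standardized variance proportions of the classical
#' twin model: additive genetic (`a2`), shared environment (`c2`), dominance
#' deviation (`d2`) and random environment (`e2`). Components must be
#' non-negative and sum to one. If `e2` is omitted it is set to the remainder
#' `1 - a2 - c2 - d2`.
#'
#' @param a2,c2,d2 Non-negative variance proportions.
#' @param e2 Random-environment proportion; defaults to the remainder.
#' @return A named numeric vector of class `"twin_components"`.
#' @examples
#' twin_components(a2 = 0.27, d2 = 0.25)   # e2 = 0.48
#' @export
twin_components <- function(a2 = 0, c2 = 0, d2 = 0, e2 = NULL) {
  if (is.null(e2)) e2 <- 1 - a2 - c2 - d2
  v <- c(a2 = a2, c2 = c2, d2 = d2, e2 = e2)
  if (any(!is.finite(v)) || any(v < -1e-12))
    stop("variance components must be finite and non-negative")
  if (abs(sum(v) - 1) > 1e-8)
    stop("variance components must sum to 1 (got ", format(sum(v)), ")")
  structure(pmax(v, 0), class = "twin_components")
}

#' @export
print.twin_components <- function(x, digits = 3, ...) {
  cat("Twin variance components:\n")
  print(round(unclass(x), digits))
  invisible(x)
}

as_twin_components <- function(x) {
  if (inherits(x, "twin_components")) return(x)
  x <- unlist(x)
  twin_components(a2 = x[["a2"]], c2 = x[["c2"]], d2 = x[["d2"]], e2 = x[["e2"]])
}

#' Model-implied MZ and DZ correlations
#'
#' Applies the classical cross-twin factor correlations to a set of variance
#' components: `r_mz = a2 + c2 + d2`, `r_dz = 0.5 a2 + c2 + 0.25 d2`.
#'
#' @param components A [twin_components] object (or named vector with
#'   elements `a2`, `c2`, `d2`, `e2`).
#' @return Named numeric vector `c(r_mz = , r_dz = )`.
#' @examples
#' expected_correlations(twin_components(a2 = 0.27, d2 = 0.25))
#' @export
expected_correlations <- function(components) {
  v <- as_twin_components(components)
  g <- v[c("a2", "c2", "d2")]
  c(r_mz = sum(.RMZ_COEF * g), r_dz = sum(.RDZ_COEF * g))
}

#' Variance components from path coefficients
#'
#' Squares standardized path coefficients (a, c, d, e) into variance
#' proportions, renormalizing so they sum exactly to one. The squares must
#' already sum to one within a rounding tolerance of 0.02, as when re-deriving
#' proportions from published coefficients rounded to two decimals.
#'
#' @param a,c,d,e Path coefficients (any sign; only squares are used).
#' @return A [twin_components] object.
#' @examples
#' variance_from_paths(0.52, 0, 0.50, 0.69)
#' @export
variance_from_paths <- function(a = 0, c = 0, d = 0, e = 0) {
  sq <- c(a, c, d, e)^2
  tot <- sum(sq)
  if (abs(tot - 1) > 0.02)
    stop("squared path coefficients sum to ", format(tot),
         "; expected 1 within rounding tolerance 0.02")
  sq <- sq / tot
  twin_components(a2 = sq[1], c2 = sq[2], d2 = sq[3], e2 = sq[4])
}

#' Observed MZ/DZ correlation pair
#'
#' Bundles the estimated MZ and DZ twin correlations with their standard
#' errors (and optionally pair counts) as input to model fitting.
#'
#' @param r_mz,r_dz Estimated correlations, `abs(r) < 1`.
#' @param se_mz,se_dz Positive standard errors.
#' @param n_mz,n_dz Optional pair counts.
#' @return A list of class `"correlation_pair"`.
#' @export
correlation_pair <- function(r_mz, r_dz, se_mz, se_dz, n_mz = NA_integer_, n_dz = NA_integer_) {
  if (abs(r_mz) >= 1 || abs(r_dz) >= 1)
    stop("correlations must satisfy abs(r) < 1")
  if (se_mz <= 0 || se_dz <= 0)
    stop("standard errors must be positive")
  structure(list(r_mz = r_mz, r_dz = r_dz, se_mz = se_mz, se_dz = se_dz,
                 n_mz = n_mz, n_dz = n_dz),
            class = "correlation_pair")
}

#' @export
print.correlation_pair <- function(x, digits = 3, ...) {
  cat(sprintf("MZ: r = %.*f (se %.*f, n = %s)\nDZ: r = %.*f (se %.*f, n = %s)\n",
              digits, x$r_mz, digits, x$se_mz, format(x$n_mz),
              digits, x$r_dz, digits, x$se_dz, format(x$n_dz)))
  invisible(x)
}

# Weighted least-squares solution for one free component along direction x,
# clipped to [lo, hi].
.wls_1d <- function(r, w, x, lo = 0, hi = 1) {
  t <- sum(w * r * x) / sum(w * x^2)
  min(max(t, lo), hi)
}

#' Closed-form solution of a saturated twin model
#'
#' Solves the ADE or ACE model exactly from a pair of observed correlations
#' (two statistics, two free genetic/shared parameters): for ADE,
#' `a2 = 4 r_dz - r_mz`, `d2 = 2 r_mz - 4 r_dz`; for ACE,
#' `a2 = 2 (r_mz - r_dz)`, `c2 = 2 r_dz - r_mz`; in both `e2 = 1 - r_mz`.
#' A negative component is clipped to zero (recorded in the `"boundary"`
#' attribute) and the remaining free component re-solved by least squares on
#' the two correlations.
#'
#' @param model `"ADE"` or `"ACE"`.
#' @param r_mz,r_dz Observed correlations.
#' @return A named vector `c(a2, c2, d2, e2)` with attribute `"boundary"`
#'   listing components clipped at zero.
#' @examples
#' solve_saturated("ADE", 0.40, 0.14)   # a2 = 0.16, d2 = 0.24, e2 = 0.60
#' @export
solve_saturated <- function(model = c("ADE", "ACE"), r_mz, r_dz) {
  model <- match.arg(model)
  free <- .MODEL_FREE[[model]]
  theta <- if (model == "ADE")
    c(a2 = 4 * r_dz - r_mz, d2 = 2 * r_mz - 4 * r_dz)
  else
    c(a2 = 2 * (r_mz - r_dz), c2 = 2 * r_dz - r_mz)
  boundary <- names(theta)[theta < 0]
  if (length(boundary)) {
    theta[boundary] <- 0
    keep <- setdiff(names(theta), boundary)
    for (j in keep) {
      x <- c(.RMZ_COEF[[j]], .RDZ_COEF[[j]])
      theta[j] <- .wls_1d(c(r_mz, r_dz), c(1, 1), x)
    }
  }
  out <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
  out[names(theta)] <- theta
  out["e2"] <- 1 - sum(theta)
  attr(out, "boundary") <- boundary
  out
}

#' Fit one twin variance-component model by constrained weighted least squares
#'
#' Minimizes the fit function
#' \deqn{\chi^2(\theta) = \left(\frac{r_{MZ} - \rho_{MZ}(\theta)}{se_{MZ}}\right)^2 +
#'       \left(\frac{r_{DZ} - \rho_{DZ}(\theta)}{se_{DZ}}\right)^2}
#' over the free variance proportions of the requested model, subject to
#' non-negativity and \eqn{a^2+c^2+d^2 \le 1}. Because the model-implied
#' correlations are linear in the proportions, the objective is a convex
#' quadratic and is solved exactly by active-set enumeration.
#'
#' Degrees of freedom follow the convention `df = 2 - (number of free
#' parameters not clipped at a boundary)`: a saturated model (ADE, ACE) with an
#' interior solution has `df = 0` and `chi2 = 0`; when a component is clipped
#' at zero the model effectively collapses to its reduced neighbour (e.g. ACE
#' to AE) and df increases accordingly.
#'
#' @param model One of `"ADE"`, `"ACE"`, `"AE"`, `"CE"`, `"DE"`, `"E"`.
#'   The ACDE model is not identified in the classical two-group design and is
#'   not offered.
#' @param corr A [correlation_pair].
#' @return An object of class `"twin_fit"`: list with elements `model`,
#'   `components` (named vector a2, c2, d2, e2), `chi2`, `df`, `p`,
#'   `boundary` (character vector of components clipped at zero), `free`,
#'   and `corr`.
#' @examples
#' corr <- correlation_pair(0.40, 0.14, 0.05, 0.05)
#' fit_model("ADE", corr)   # saturated: chi2 = 0
#' fit_model("AE", corr)
#' @export
fit_model <- function(model, corr) {
  model <- match.arg(model, names(.MODEL_FREE))
  stopifnot(inherits(corr, "correlation_pair"))
  free <- .MODEL_FREE[[model]]
  r <- c(corr$r_mz, corr$r_dz)
  w <- c(1 / corr$se_mz^2, 1 / corr$se_dz^2)
  k <- length(free)
  chi2_of <- function(theta) {
    rho <- c(sum(.RMZ_COEF[free] * theta), sum(.RDZ_COEF[free] * theta))
    sum(w * (r - rho)^2)
  }
  if (k == 0) {
    theta <- numeric(0)
  } else if (k == 1) {
    x <- c(.RMZ_COEF[[free]], .RDZ_COEF[[free]])
    theta <- setNames(.wls_1d(r, w, x), free)
  } else {
    x1 <- c(.RMZ_COEF[[free[1]]], .RDZ_COEF[[free[1]]])
    x2 <- c(.RMZ_COEF[[free[2]]], .RDZ_COEF[[free[2]]])
    X <- cbind(x1, x2)
    A <- t(X) %*% (w * X)
    b <- as.vector(t(X) %*% (w * r))
    cand <- list()
    th <- tryCatch(solve(A, b), error = function(e) NULL)
    if (!is.null(th) && all(th >= 0) && sum(th) <= 1) cand <- c(cand, list(th))
    # edges: each parameter at 0, and the a2+...=1 simplex face
    cand <- c(cand,
              list(c(0, .wls_1d(r, w, x2)),
                   c(.wls_1d(r, w, x1), 0)))
    tt <- sum(w * (r - x2) * (x1 - x2))
    den <- sum(w * (x1 - x2)^2)
    t_edge <- if (den > 0) min(max(tt / den, 0), 1) else 0
    cand <- c(cand, list(c(t_edge, 1 - t_edge)))
    vals <- vapply(cand, chi2_of, numeric(1))
    theta <- setNames(cand[[which.min(vals)]], free)
  }
  chi2 <- chi2_of(theta)
  if (chi2 < 1e-12) chi2 <- 0
  boundary <- names(theta)[theta <= 1e-12]
  comp <- c(a2 = 0, c2 = 0, d2 = 0, e2 = 0)
  comp[names(theta)] <- theta
  comp["e2"] <- 1 - sum(theta)
  df <- 2L - (k - length(boundary))
  p <- if (df == 0L) {
    if (chi2 < 1e-6) 1 else NA_real_
  } else {
    pchisq(chi2, df, lower.tail = FALSE)
  }
  structure(list(model = model, components = comp, chi2 = chi2, df = df,
                 p = p, boundary = boundary, free = free, corr = corr),
            class = "twin_fit")
}

#' @export
print.twin_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s model fit (weighted least squares on twin correlations)\n", x$model))
  print(round(x$components, digits))
  cat(sprintf("chi2 = %.*f, df = %d, p = %.2f", digits, x$chi2, x$df, x$p))
  if (length(x$boundary))
    cat("  [at boundary: ", paste(x$boundary, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Fit a set of twin models and tabulate the results
#'
#' @param corr A [correlation_pair].
#' @param models Character vector of model names (default all identified
#'   models, most to least parameterized).
#' @return A data frame with one row per model: components, `chi2`, `df`, `p`
#'   and a comma-separated `boundary` column.
#' @export
fit_all_models <- function(corr, models = c("ADE", "ACE", "AE", "CE", "DE", "E")) {
  fits <- lapply(models, fit_model, corr = corr)
  out <- data.frame(
    model = models,
    a2 = vapply(fits, function(f) f$components[["a2"]], numeric(1)),
    c2 = vapply(fits, function(f) f$components[["c2"]], numeric(1)),
    d2 = vapply(fits, function(f) f$components[["d2"]], numeric(1)),
    e2 = vapply(fits, function(f) f$components[["e2"]], numeric(1)),
    chi2 = vapply(fits, function(f) f$chi2, numeric(1)),
    df = vapply(fits, function(f) f$df, integer(1)),
    p = vapply(fits, function(f) f$p, numeric(1)),
    boundary = vapply(fits, function(f) paste(f$boundary, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "fits") <- fits
  out
}

#' Falconer broad-sense heritability
#'
#' Twice the difference between the MZ and DZ twin correlations,
#' `H2 = 2 (r_mz - r_dz)`.
#'
#' @param r_mz,r_dz Twin correlations, `abs(r) <= 1`. Vectorized.
#' @return Numeric heritability estimate(s).
#' @examples
#' falconer_heritability(0.40, 0.14)  # 0.52
#' @export
falconer_heritability <- function(r_mz, r_dz) {
  if (any(abs(c(r_mz, r_dz)) > 1))
    stop("correlations must lie in [-1, 1]")
  2 * (r_mz - r_dz)
}

#' Upper-tail chi-square probability
#'
#' @param x Non-negative statistic(s).
#' @param df Degrees of freedom (positive integer).
#' @return Upper-tail probability `P(X > x)`.
#' @examples
#' chi2_pvalue(2.6, 1)   # 0.11 to two decimals
#' @export
chi2_pvalue <- function(x, df) {
  if (any(x < 0)) stop("chi-square statistic must be non-negative")
  if (any(df < 1)) stop("df must be a positive integer")
  pchisq(x, df, lower.tail = FALSE)
}

#' Likelihood-ratio comparison of nested twin models
#'
#' Tests a reduced model against a full model fitted to the same correlation
#' pair: `delta_chi2 = chi2_reduced - chi2_full` (floored at zero) referred to
#' a chi-square with df equal to the difference in the models' nominal
#' free-parameter counts.
#'
#' @param full,reduced `"twin_fit"` objects; the reduced model's free
#'   parameters must be a proper subset of the full model's.
#' @return A list of class `"nested_test"` with `delta_chi2`, `df`, `p`.
#' @examples
#' corr <- correlation_pair(0.40, 0.14, 0.05, 0.05)
#' compare_nested(fit_model("ADE", corr), fit_model("AE", corr))
#' @export
compare_nested <- function(full, reduced) {
  stopifnot(inherits(full, "twin_fit"), inherits(reduced, "twin_fit"))
  ff <- full$free
  rf <- reduced$free
  if (!all(rf %in% ff) || length(rf) >= length(ff))
    stop("'", reduced$model, "' is not nested within '", full$model, "'")
  delta <- max(0, reduced$chi2 - full$chi2)
  df <- length(ff) - length(rf)
  structure(list(full = full$model, reduced = reduced$model,
                 delta_chi2 = delta, df = df, p = chi2_pvalue(delta, df)),
            class = "nested_test")
}

#' @export
print.nested_test <- function(x, ...) {
  cat(sprintf("%s vs %s: delta chi2 = %.3f, df = %d, p = %.2f\n",
              x$reduced, x$full, x$delta_chi2, x$df, x$p))
  invisible(x)
}
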