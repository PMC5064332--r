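# Two-stage polychoric correlation estimation for twin-pair ordinal tables.
#
# Stage 1: thresholds from the marginal cumulative proportions.
# Stage 2: one-dimensional maximum likelihood for the latent correlation,
# maximizing the multinomial log-likelihood sum(n_ij * log p_ij(tau, rho))
# where p_ij are standard bivariate normal rectangle probabilities.

#' Bivariate normal cell probabilities for an ordinal cross-classification
#'
#' Probability that a standard bivariate normal vector with correlation `rho`
#' falls in each rectangle of the grid defined by row and column thresholds
#' (padded with -Inf/+Inf).
#'
#' @param tau_rows,tau_cols Strictly increasing threshold vectors.
#' @param rho Latent correlation, `abs(rho) < 1`.
#' @return Matrix of dimension `(length(tau_rows)+1) x (length(tau_cols)+1)`
#'   whose entries are non-negative and sum to 1.
#' @examples
#' cell_probabilities(0, 0, 0.5)   # diagonal cells are each 1/3
#' @export
cell_probabilities <- function(tau_rows, tau_cols, rho) {
  for (tau in list(tau_rows, tau_cols)) {
    if (length(tau) >= 2 && any(diff(tau) <= 0))
      stop("thresholds must be strictly increasing")
    if (any(!is.finite(tau))) stop("thresholds must be finite")
  }
  tr <- c(-Inf, tau_rows, Inf)
  tc <- c(-Inf, tau_cols, Inf)
  nr <- length(tr)
  nc <- length(tc)
  cdf <- matrix(pbvnorm(rep(tr, times = nc), rep(tc, each = nr), rho), nr, nc)
  P <- cdf[-1, -1, drop = FALSE] - cdf[-nr, -1, drop = FALSE] -
    cdf[-1, -nc, drop = FALSE] + cdf[-nr, -nc, drop = FALSE]
  pmax(P, 0)
}

#' Thresholds from marginal category counts
#'
#' Standard-normal quantiles of the cumulative marginal proportions (stage 1
#' of two-stage polychoric estimation).
#'
#' @param counts Non-negative category counts with positive total.
#' @return Strictly increasing threshold vector of length `length(counts)-1`.
#' @examples
#' estimate_thresholds(c(63, 8, 14, 15))
#' @export
estimate_thresholds <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("need at least two categories")
  if (any(counts < 0) || sum(counts) <= 0) stop("counts must be non-negative with positive total")
  cum <- cumsum(counts)[-length(counts)] / sum(counts)
  if (any(cum <= 0) || any(cum >= 1))
    stop("a cumulative marginal proportion is 0 or 1; ",
         "collapse the empty category with an adjacent one before estimation")
  qnorm(cum)
}

#' Double-entered contingency table for one zygosity group
#'
#' Builds the K x K cross-classification of twin scores in which each pair is
#' entered twice, once as (score1, score2) and once as (score2, score1).
#' Twins within a pair are interchangeable, so symmetrizing removes the
#' arbitrary ordering; the table total is twice the pair count, which
#' [fit_polychoric] corrects for when computing standard errors.
#'
#' @param pairs Data frame with columns `zygosity`, `score1`, `score2`.
#' @param zygosity Optional `"MZ"` or `"DZ"` filter.
#' @param K Number of categories; defaults to `max(score) + 1` over the
#'   supplied records.
#' @return A symmetric K x K integer matrix with attributes `zygosity` and
#'   `n_pairs`.
#' @export
double_enter <- function(pairs, zygosity = NULL, K = NULL) {
  if (!is.null(zygosity)) pairs <- pairs[pairs$zygosity == zygosity, , drop = FALSE]
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no twin-pair records", if (!is.null(zygosity)) paste0(" of zygosity ", zygosity))
  s1 <- as.integer(pairs$score1)
  s2 <- as.integer(pairs$score2)
  if (is.null(K)) K <- max(s1, s2) + 1L
  tab <- .double_entry_counts(s1, s2, K)
  attr(tab, "zygosity") <- zygosity
  attr(tab, "n_pairs") <- nrow(pairs)
  tab
}

.double_entry_counts <- function(s1, s2, K) {
  idx <- c(s1 * K + s2, s2 * K + s1) + 1L
  m <- matrix(tabulate(idx, K * K), K, K, byrow = TRUE)
  dimnames(m) <- list(as.character(0:(K - 1)), as.character(0:(K - 1)))
  m
}

# Drop categories with an empty row AND column margin (their likelihood
# contribution is void); warns so no filtering is silent.
.drop_empty_categories <- function(tab) {
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping ", sum(!keep_r) + sum(!keep_c),
            " empty margin categor(ies) before polychoric estimation")
    tab2 <- tab[keep_r, keep_c, drop = FALSE]
    attributes(tab2)[c("zygosity", "n_pairs")] <- attributes(tab)[c("zygosity", "n_pairs")]
    tab <- tab2
  }
  tab
}

#' Polychoric correlation from an ordinal contingency table
#'
#' Two-stage estimator of the latent bivariate-normal correlation: row and
#' column thresholds are fixed at the normal quantiles of the marginal
#' cumulative proportions, then `rho` maximizes the multinomial
#' log-likelihood \eqn{\sum_{ij} n_{ij} \log p_{ij}(\tau, \rho)} over
#' `(-1, 1)` by one-dimensional optimization. Cell probabilities are floored
#' at 1e-30 inside the log-likelihood. The standard error comes from the
#' curvature of the profile log-likelihood at the optimum; for double-entered
#' tables the information is rescaled to the effective number of independent
#' pairs (`n_pairs`), not the doubled table total.
#'
#' @param tab Matrix of non-negative counts (rows: twin 1, columns: twin 2),
#'   e.g. from [double_enter]. At least two non-empty row and column
#'   categories are required; categories with empty margins are dropped with
#'   a warning.
#' @param n_pairs Effective number of independent observations. Defaults to
#'   the table's `n_pairs` attribute if present, else the table total.
#' @param interval Search interval for `rho` (default `c(-0.995, 0.995)`); an
#'   optimum at the interval end is flagged as a boundary estimate with a
#'   warning.
#' @return Object of class `"polychoric"`: list with `rho`, `se`, `tau_rows`,
#'   `tau_cols`, `loglik`, `n_pairs`, `zygosity`, `boundary`.
#' @examples
#' pairs <- simulate_twin_pairs(twin_components(a2 = 0.4), n_mz = 500,
#'                              n_dz = 500, seed = 2)
#' fit_polychoric(double_enter(pairs, "MZ"))
#' @export
fit_polychoric <- function(tab, n_pairs = NULL, interval = c(-0.995, 0.995)) {
  if (!is.matrix(tab) || any(tab < 0) || sum(tab) <= 0)
    stop("'tab' must be a matrix of non-negative counts with positive total")
  if (is.null(n_pairs)) {
    n_pairs <- attr(tab, "n_pairs")
    if (is.null(n_pairs)) n_pairs <- sum(tab)
  }
  tab <- .drop_empty_categories(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate table: need at least two non-empty row and column categories")
  tau_r <- estimate_thresholds(rowSums(tab))
  tau_c <- estimate_thresholds(colSums(tab))
  negll <- function(rho) {
    P <- pmax(cell_probabilities(tau_r, tau_c, rho), 1e-30)
    -sum(tab * log(P))
  }
  opt <- optimize(negll, interval, tol = 1e-7)
  rho <- opt$minimum
  boundary <- min(rho - interval[1], interval[2] - rho) < 1e-3
  if (boundary) {
    rho <- interval[which.min(abs(interval - rho))]
    warning("polychoric estimate at the search boundary (rho = ", rho, ")")
  }
  h <- 5e-4
  info <- (negll(rho - h) - 2 * negll(rho) + negll(rho + h)) / h^2
  infl <- sum(tab) / n_pairs   # 2 for double-entered tables
  se <- if (is.finite(info) && info > 0) sqrt(infl / info) else NA_real_
  structure(list(rho = rho, se = se, tau_rows = tau_r, tau_cols = tau_c,
                 loglik = -opt$objective, n_pairs = n_pairs,
                 zygosity = attr(tab, "zygosity"), boundary = boundary),
            class = "polychoric")
}

#' @export
print.polychoric <- function(x, digits = 3, ...) {
  cat(sprintf("Polychoric correlation%s: rho = %.*f (se %.*f), n_pairs = %d%s\n",
              if (!is.null(x$zygosity)) paste0(" [", x$zygosity, "]") else "",
              digits, x$rho, digits, x$se, x$n_pairs,
              if (x$boundary) " [boundary]" else ""))
  cat("thresholds (rows):", round(x$tau_rows, digits), "\n")
  invisible(x)
}

#' Per-zygosity polychoric correlations from twin-pair records
#'
#' Convenience wrapper: double-enters each zygosity group, fits the
#' polychoric correlation, and bundles the two estimates as a
#' [correlation_pair] ready for model fitting.
#'
#' @param pairs Data frame of twin-pair records.
#' @param K Number of categories (defaults to `max(score) + 1` pooled).
#' @return List with elements `mz` and `dz` (class `"polychoric"`) and
#'   `corr` (class `"correlation_pair"`).
#' @export
polychoric_by_zygosity <- function(pairs, K = NULL) {
  if (is.null(K)) K <- max(pairs$score1, pairs$score2) + 1L
  mz <- fit_polychoric(double_enter(pairs, "MZ", K))
  dz <- fit_polychoric(double_enter(pairs, "DZ", K))
  list(mz = mz, dz = dz,
       corr = correlation_pair(mz$rho, dz$rho, mz$se, dz$se, mz$n_pairs, dz$n_pairs))
}
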