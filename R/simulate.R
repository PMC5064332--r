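# Liability-threshold simulation of MZ/DZ twin-pair ordinal data.
#
# Each twin's phenotype is a standard-normal latent liability cut at fixed
# thresholds into K ordered categories. Within a pair the liabilities are
# bivariate normal with correlation r_MZ = a2 + c2 + d2 (MZ) or
# r_DZ = 0.5 a2 + c2 + 0.25 d2 (DZ).

#' Liability thresholds implied by category prevalences
#'
#' Standard-normal quantiles of the cumulative prevalences: with K categories
#' the K-1 thresholds are `qnorm(cumsum(p)[1:(K-1)])`.
#'
#' @param prevalences Probability vector over K >= 2 categories; all entries
#'   strictly positive and summing to 1 (tolerance 1e-8).
#' @return Strictly increasing numeric vector of length K-1.
#' @examples
#' liability_thresholds(c(0.63, 0.08, 0.14, 0.15))
#' @export
liability_thresholds <- function(prevalences) {
  p <- as.numeric(prevalences)
  if (length(p) < 2) stop("need at least two categories")
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all prevalences must be strictly positive")
  if (abs(sum(p) - 1) > 1e-8)
    stop("prevalences must sum to 1 (got ", format(sum(p)), ")")
  qnorm(cumsum(p)[-length(p)])
}

# Draw n pairs of liabilities with correlation r and cut at thresholds tau.
# Returns an n x 2 integer matrix of scores 0..K-1. Uses the current RNG
# stream (no reseeding) so callers control reproducibility.
.sim_pair_scores <- function(n, r, tau, method = "bivariate", components = NULL,
                             dz = FALSE) {
  if (method == "bivariate") {
    z1 <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  } else {
    # component-wise construction: separate A/C/D/E factor draws with the
    # classical cross-twin factor correlations (1/0.5 for A, 1/0.25 for D,
    # 1/1 for C, 0 for E); distributionally identical to the direct draw
    v <- components
    ra <- if (dz) c(0.5, 0.25) else c(1, 1)
    mix <- function(rf) {
      g <- rnorm(n)
      list(g, rf * g + sqrt(1 - rf^2) * rnorm(n))
    }
    A <- mix(ra[1]); D <- mix(ra[2]); C <- rnorm(n)
    z1 <- sqrt(v[["a2"]]) * A[[1]] + sqrt(v[["c2"]]) * C + sqrt(v[["d2"]]) * D[[1]] +
      sqrt(v[["e2"]]) * rnorm(n)
    z2 <- sqrt(v[["a2"]]) * A[[2]] + sqrt(v[["c2"]]) * C + sqrt(v[["d2"]]) * D[[2]] +
      sqrt(v[["e2"]]) * rnorm(n)
  }
  cbind(findInterval(z1, tau), findInterval(z2, tau))
}

#' Simulate ordinal twin-pair data under the liability-threshold model
#'
#' Draws `n_mz` monozygotic and `n_dz` dizygotic pairs. Each pair's latent
#' liabilities are standard bivariate normal with correlation
#' `r_mz = a2 + c2 + d2` or `r_dz = 0.5 a2 + c2 + 0.25 d2`, discretized at the
#' thresholds implied by `prevalences`. Thresholds are common to both twins
#' and both zygosity groups.
#'
#' @param components A [twin_components] object (must sum to 1).
#' @param prevalences Category prevalence vector (default the four-level
#'   depression severity distribution 63/8/14/15%).
#' @param n_mz,n_dz Number of MZ and DZ pairs (each >= 1).
#' @param seed Optional integer; if given, a master seed from which
#'   per-zygosity substreams are derived deterministically. If `NULL` the
#'   current RNG stream is used.
#' @param method `"bivariate"` draws the implied bivariate normal directly;
#'   `"pathwise"` sums separate A/C/D/E factor draws (distributionally
#'   equivalent, retained for didactic checks).
#' @return A data frame with columns `pair_id`, `zygosity` (`"MZ"`/`"DZ"`),
#'   `score1`, `score2` (integers in `0:(K-1)`).
#' @examples
#' pairs <- simulate_twin_pairs(twin_components(a2 = 0.27, d2 = 0.25),
#'                              n_mz = 200, n_dz = 200, seed = 1)
#' head(pairs)
#' @export
simulate_twin_pairs <- function(components,
                                prevalences = c(0.63, 0.08, 0.14, 0.15),
                                n_mz, n_dz, seed = NULL,
                                method = c("bivariate", "pathwise")) {
  method <- match.arg(method)
  v <- as_twin_components(components)
  if (n_mz < 1 || n_dz < 1) stop("n_mz and n_dz must each be >= 1")
  tau <- liability_thresholds(prevalences)
  rr <- expected_correlations(v)
  sub <- c(NA_integer_, NA_integer_)
  if (!is.null(seed)) {
    set.seed(seed)
    sub <- sample.int(.Machine$integer.max - 1L, 2L)
  }
  if (!is.na(sub[1])) set.seed(sub[1])
  mz <- .sim_pair_scores(n_mz, rr[["r_mz"]], tau, method, v)
  if (!is.na(sub[2])) set.seed(sub[2])
  dz <- .sim_pair_scores(n_dz, rr[["r_dz"]], tau, method, v, dz = TRUE)
  data.frame(
    pair_id = seq_len(n_mz + n_dz),
    zygosity = rep(c("MZ", "DZ"), c(n_mz, n_dz)),
    score1 = c(mz[, 1], dz[, 1]),
    score2 = c(mz[, 2], dz[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Pooled category frequencies of twin-pair scores
#'
#' Relative frequencies of the K categories pooled over both members of every
#' pair (each pair contributes two observations).
#'
#' @param pairs Data frame with `score1`, `score2` columns.
#' @param K Number of categories; defaults to `max(score) + 1`.
#' @return Probability vector of length K (sums to 1).
#' @export
observed_category_frequencies <- function(pairs, K = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0) stop("no twin-pair records supplied")
  s <- c(pairs$score1, pairs$score2)
  if (is.null(K)) K <- max(s) + 1L
  tabulate(s + 1L, K) / length(s)
}
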