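# Monte-Carlo power analysis for detecting genetic dominance: the probability
# that the df = 1 likelihood-ratio test rejects a (false) AE model in favour
# of ADE, when the generating truth contains dominance variance.

# One simulated study: generate pairs, estimate per-zygosity polychoric
# correlations, fit AE and ADE by constrained WLS, return the nested p-value.
.one_replicate_p <- function(v, rr, tau, K, n_mz, n_dz) {
  smz <- .sim_pair_scores(n_mz, rr[["r_mz"]], tau)
  sdz <- .sim_pair_scores(n_dz, rr[["r_dz"]], tau)
  emz <- fit_polychoric(.double_entry_counts(smz[, 1], smz[, 2], K), n_pairs = n_mz)
  edz <- fit_polychoric(.double_entry_counts(sdz[, 1], sdz[, 2], K), n_pairs = n_dz)
  corr <- correlation_pair(emz$rho, edz$rho, emz$se, edz$se, n_mz, n_dz)
  compare_nested(fit_model("ADE", corr), fit_model("AE", corr))$p
}

#' Simulated power to reject a false AE model
#'
#' Monte-Carlo estimate of the power of the df = 1 chi-square difference test
#' between the AE and ADE models, at a given truth, sample size and test
#' size. Each replicate simulates `n_mz + n_dz` pairs from the
#' liability-threshold model, estimates the two polychoric correlations
#' (double-entered tables), fits AE and ADE by constrained weighted least
#' squares, and rejects when the nested p-value is below `alpha`. Replicates
#' whose polychoric fit fails (degenerate small-sample tables) are resampled
#' and counted.
#'
#' With `d2 = 0` in the truth the routine estimates the empirical size of the
#' test, which should be close to `alpha`.
#'
#' @param truth A [twin_components] object (the generating composition).
#' @param prevalences Category prevalence vector (length K >= 2).
#' @param n_mz,n_dz Pairs per zygosity group in each replicate.
#' @param alpha Test size (default 0.05).
#' @param reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Optional integer seed.
#' @return Object of class `"power_result"`: `power`, `mc_se`
#'   (`sqrt(power (1 - power) / reps)`), `reps`, `n_mz`, `n_dz`, `alpha`,
#'   `n_resampled`.
#' @examples
#' \donttest{
#' power_reject_ae(twin_components(a2 = 0.3, d2 = 0.3), n_mz = 725,
#'                 n_dz = 724, reps = 200, seed = 7)
#' }
#' @export
power_reject_ae <- function(truth,
                            prevalences = c(0.63, 0.08, 0.14, 0.15),
                            n_mz, n_dz, alpha = 0.05, reps = 1000,
                            seed = NULL) {
  v <- as_twin_components(truth)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (reps < 100) stop("use at least 100 replicates")
  if (!is.null(seed)) set.seed(seed)
  tau <- liability_thresholds(prevalences)
  K <- length(prevalences)
  rr <- expected_correlations(v)
  rej <- logical(reps)
  n_resampled <- 0L
  for (i in seq_len(reps)) {
    repeat {
      p <- tryCatch(
        suppressWarnings(.one_replicate_p(v, rr, tau, K, n_mz, n_dz)),
        error = function(e) NULL
      )
      if (!is.null(p)) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 100L + reps)
        stop("too many degenerate replicates; increase the sample size")
    }
    rej[i] <- p < alpha
  }
  power <- mean(rej)
  structure(list(power = power,
                 mc_se = sqrt(power * (1 - power) / reps),
                 reps = reps, n_mz = n_mz, n_dz = n_dz, alpha = alpha,
                 n_resampled = n_resampled),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Power to reject AE: %.3f (MC se %.3f; %d reps; %d MZ + %d DZ pairs; alpha %.3g)\n",
              x$power, x$mc_se, x$reps, x$n_mz, x$n_dz, x$alpha))
  if (x$n_resampled > 0)
    cat(sprintf("  %d degenerate replicate(s) resampled\n", x$n_resampled))
  invisible(x)
}

#' Total pair count required for a target power
#'
#' Bisection over the total number of pairs (split equally between MZ and DZ)
#' on the simulated power curve. All evaluated points are pooled and smoothed
#' by isotonic regression (power is monotone in n) before each bisection
#' decision, which stabilizes the search against Monte-Carlo noise.
#'
#' @param target_power Target power in (0, 1).
#' @param truth,prevalences,alpha,reps,seed As in [power_reject_ae]; each
#'   evaluated sample size uses `reps` replicates on a deterministic
#'   sub-stream of `seed`.
#' @param n_bounds Length-2 vector of total pair counts bracketing the answer.
#' @param rel_tol Bisection stops when the bracket width is below
#'   `rel_tol * upper` (default 0.05) or 2 pairs.
#' @return Object of class `"required_n"`: `n_total` (smallest evaluated total
#'   meeting the target on the smoothed curve), `power`, `mc_se`, and the
#'   `evaluations` data frame.
#' @export
required_n <- function(target_power, truth,
                       prevalences = c(0.63, 0.08, 0.14, 0.15),
                       alpha = 0.05, reps = 500, seed = NULL,
                       n_bounds = c(500, 10000), rel_tol = 0.05) {
  if (target_power <= 0 || target_power >= 1) stop("target_power must be in (0, 1)")
  if (length(n_bounds) != 2 || n_bounds[1] >= n_bounds[2] || n_bounds[1] < 4)
    stop("'n_bounds' must be an increasing pair of total pair counts >= 4")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 64L)
  evals <- data.frame(n = integer(0), power = numeric(0), mc_se = numeric(0))
  k <- 0L
  eval_power <- function(n_total) {
    k <<- k + 1L
    n1 <- ceiling(n_total / 2)
    n2 <- n_total - n1
    pr <- power_reject_ae(truth, prevalences, n_mz = n1, n_dz = n2,
                          alpha = alpha, reps = reps, seed = subseeds[k])
    evals[nrow(evals) + 1L, ] <<- list(as.integer(n_total), pr$power, pr$mc_se)
    pr$power
  }
  smoothed <- function() {
    o <- order(evals$n)
    data.frame(n = evals$n[o], power = isoreg(evals$n[o], evals$power[o])$yf)
  }
  lo <- as.integer(n_bounds[1])
  hi <- as.integer(n_bounds[2])
  p_lo <- eval_power(lo)
  if (p_lo >= target_power) {
    return(structure(list(n_total = lo, power = p_lo,
                          mc_se = evals$mc_se[1], target_power = target_power,
                          evaluations = evals, seed = seed),
                     class = "required_n"))
  }
  p_hi <- eval_power(hi)
  if (p_hi < target_power)
    stop(sprintf("bracket failure: power is %.3f at n = %d and %.3f at n = %d, both below target %.2f",
                 p_lo, lo, p_hi, hi, target_power))
  while (hi - lo > max(2, rel_tol * hi) && k < 60L) {
    mid <- as.integer(round((lo + hi) / 2))
    eval_power(mid)
    sm <- smoothed()
    if (sm$power[sm$n == mid] >= target_power) hi <- mid else lo <- mid
  }
  sm <- smoothed()
  at_hi <- evals[evals$n == hi, ][1, ]
  structure(list(n_total = hi,
                 power = sm$power[sm$n == hi],
                 mc_se = at_hi$mc_se,
                 target_power = target_power,
                 evaluations = evals[order(evals$n), ],
                 seed = seed),
            class = "required_n")
}

#' @export
print.required_n <- function(x, ...) {
  cat(sprintf("Smallest total pair count reaching power %.2f: %d (smoothed power %.3f, MC se %.3f)\n",
              x$target_power, x$n_total, x$power, x$mc_se))
  invisible(x)
}
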