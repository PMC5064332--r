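# Shared fixtures and independent oracles built in code.

# All 64 combinations of the six questionnaire answer fields.
all_response_patterns <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), 6))
  names(g) <- c("ever_depressed", "postnatal_only", "gp_diagnosed",
                "psychiatrist_diagnosed", "defined_medication",
                "multiple_treated_episodes")
  g
}

# One canonical answer pattern per severity level.
response_for_level <- function(level) {
  r <- data.frame(ever_depressed = FALSE, postnatal_only = FALSE,
                  gp_diagnosed = FALSE, psychiatrist_diagnosed = FALSE,
                  defined_medication = FALSE, multiple_treated_episodes = FALSE)
  if (level >= 1) r$ever_depressed <- TRUE
  if (level >= 2) r$gp_diagnosed <- TRUE
  if (level >= 3) r$defined_medication <- TRUE
  r
}

# Exhaustive grid-search oracle for the polychoric correlation: maximizes the
# same multinomial log-likelihood over an explicit rho grid, independently of
# the optimizer under test.
grid_polychoric <- function(tab, step = 1e-3, lim = 0.999) {
  tau_r <- estimate_thresholds(rowSums(tab))
  tau_c <- estimate_thresholds(colSums(tab))
  grid <- seq(-lim, lim, by = step)
  ll <- vapply(grid, function(r) {
    P <- pmax(cell_probabilities(tau_r, tau_c, r), 1e-30)
    sum(tab * log(P))
  }, numeric(1))
  grid[which.max(ll)]
}

# Random ordinal twin-pair contingency table with known latent correlation.
random_poly_table <- function(K, rho, N = 5000) {
  p <- as.vector(stats::rgamma(K, 2)) ; p <- p / sum(p)
  tau <- liability_thresholds(p)
  P <- cell_probabilities(tau, tau, rho)
  tab <- round(P * N)
  tab[tab == 0 & P > 0] <- 1   # keep support
  tab
}

# Exhaustive grid-search oracle for the constrained WLS model fit.
grid_fit_chi2 <- function(model, corr, step = 1e-3) {
  free <- switch(model, ADE = c(1, 0.5, 1, 0.25), ACE = c(1, 0.5, 1, 1),
                 AE = c(1, 0.5), CE = c(1, 1), DE = c(1, 0.25), E = NULL)
  w <- c(1 / corr$se_mz^2, 1 / corr$se_dz^2)
  r <- c(corr$r_mz, corr$r_dz)
  if (is.null(free)) return(list(chi2 = sum(w * r^2), theta = numeric(0)))
  if (length(free) == 2) {
    t1 <- seq(0, 1, by = step)
    chi2 <- w[1] * (r[1] - free[1] * t1)^2 + w[2] * (r[2] - free[2] * t1)^2
    i <- which.min(chi2)
    return(list(chi2 = chi2[i], theta = t1[i]))
  }
  t1 <- seq(0, 1, by = step)
  best <- Inf; th <- c(NA, NA)
  for (a in t1) {
    t2 <- seq(0, 1 - a, by = step)
    chi2 <- w[1] * (r[1] - free[1] * a - free[3] * t2)^2 +
      w[2] * (r[2] - free[2] * a - free[4] * t2)^2
    i <- which.min(chi2)
    if (chi2[i] < best) { best <- chi2[i]; th <- c(a, t2[i]) }
  }
  list(chi2 = best, theta = th)
}
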