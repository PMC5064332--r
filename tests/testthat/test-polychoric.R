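test_that("bivariate normal CDF matches the mvtnorm oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(31)
  for (rho in c(-0.99, -0.9, -0.5, -0.1, 0.2, 0.6, 0.925, 0.99)) {
    h <- stats::runif(5, -2.5, 2.5)
    k <- stats::runif(5, -2.5, 2.5)
    ours <- pbvnorm(h, k, rho)
    oracle <- vapply(seq_along(h), function(i)
      mvtnorm::pmvnorm(upper = c(h[i], k[i]),
                       corr = matrix(c(1, rho, rho, 1), 2))[1], numeric(1))
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
  expect_equal(pbvnorm(Inf, 1.3, 0.7), pnorm(1.3))
  expect_equal(pbvnorm(-Inf, 1.3, 0.7), 0)
  expect_error(pbvnorm(0, 0, 1), "rho")
})

test_that("cell probabilities respect independence and the quadrant identity", {
  tau <- c(-0.5, 0.8)
  P0 <- cell_probabilities(tau, tau, 0)
  bands <- diff(pnorm(c(-Inf, tau, Inf)))
  expect_equal(P0, outer(bands, bands), tolerance = 1e-12)
  expect_equal(sum(P0), 1, tolerance = 1e-10)

  P <- cell_probabilities(0, 0, 0)
  expect_equal(as.vector(P), rep(0.25, 4))

  # P(X<0, Y<0; rho) = 1/4 + asin(rho)/(2*pi); at rho = 0.5 both diagonal
  # cells equal 1/3
  P5 <- cell_probabilities(0, 0, 0.5)
  expect_equal(P5[1, 1], 1 / 4 + asin(0.5) / (2 * pi), tolerance = 1e-10)
  expect_equal(diag(P5), rep(1 / 3, 2), tolerance = 1e-10)

  # margins equal the univariate band probabilities for any rho
  P7 <- cell_probabilities(tau, c(0.1), 0.7)
  expect_equal(rowSums(P7), bands, tolerance = 1e-9)
  expect_equal(colSums(P7), diff(pnorm(c(-Inf, 0.1, Inf))), tolerance = 1e-9)
  expect_error(cell_probabilities(c(1, 0), tau, 0.3), "increasing")
})

test_that("thresholds come from marginal cumulative proportions", {
  expect_equal(estimate_thresholds(c(50, 50)), 0)
  expect_equal(estimate_thresholds(c(63, 8, 14, 15)),
               c(0.3318533, 0.5533847, 1.0364334), tolerance = 1e-6)
  expect_equal(estimate_thresholds(c(85, 15)), 1.0364334, tolerance = 1e-6)
  expect_error(estimate_thresholds(c(0, 50, 50)), "collapse")
  expect_error(estimate_thresholds(c(50, 50, 0)), "collapse")
})

test_that("double entry produces symmetric tables with conserved totals", {
  one <- data.frame(pair_id = 1, zygosity = "MZ", score1 = 0, score2 = 3)
  tab <- double_enter(one, "MZ", K = 4)
  expect_equal(tab["0", "3"], 1)
  expect_equal(tab["3", "0"], 1)
  expect_equal(sum(tab), 2)

  set.seed(41)
  pairs <- simulate_twin_pairs(twin_components(a2 = 0.4), n_mz = 500, n_dz = 400,
                               seed = 41)
  for (z in c("MZ", "DZ")) {
    tab <- double_enter(pairs, z)
    expect_identical(tab, t(tab))
    expect_equal(sum(tab), 2 * sum(pairs$zygosity == z))
  }
  expect_error(double_enter(pairs[pairs$zygosity == "MZ", ], "DZ"), "DZ")
})

test_that("polychoric fit is invariant to the within-pair ordering", {
  pairs <- simulate_twin_pairs(twin_components(a2 = 0.5), n_mz = 800, n_dz = 1,
                               seed = 43)
  swapped <- pairs
  flip <- c(TRUE, FALSE)
  swapped[flip, c("score1", "score2")] <- swapped[flip, c("score2", "score1")]
  f1 <- fit_polychoric(double_enter(pairs, "MZ"))
  f2 <- fit_polychoric(double_enter(swapped, "MZ"))
  expect_equal(f1$rho, f2$rho)
  expect_equal(f1$se, f2$se)
})

test_that("fitted rho maximizes the likelihood and is self-consistent", {
  tau <- liability_thresholds(c(0.63, 0.08, 0.14, 0.15))
  tab <- round(cell_probabilities(tau, tau, 0.5) * 1e6)
  fit <- fit_polychoric(tab)
  expect_lt(abs(fit$rho - 0.5), 1e-2)

  # independence table -> rho ~ 0
  bands <- diff(pnorm(c(-Inf, tau, Inf)))
  tab0 <- round(outer(bands, bands) * 1e5)
  fit0 <- fit_polychoric(tab0)
  expect_lt(abs(fit0$rho), 0.01)

  # maximality: log-likelihood at the optimum >= at rho = 0
  ll_at <- function(tab, rho) {
    tr <- estimate_thresholds(rowSums(tab)); tc <- estimate_thresholds(colSums(tab))
    sum(tab * log(pmax(cell_probabilities(tr, tc, rho), 1e-30)))
  }
  expect_gte(fit$loglik, ll_at(tab, 0))
  set.seed(47)
  for (i in 1:5) {
    tab <- random_poly_table(K = sample(2:4, 1), rho = stats::runif(1, -0.8, 0.8))
    fit <- fit_polychoric(tab)
    expect_gte(fit$loglik, ll_at(tab, 0) - 1e-9)
  }
})

test_that("optimizer agrees with an exhaustive grid-search oracle", {
  set.seed(53)
  cases <- 100
  for (i in seq_len(cases)) {
    K <- sample(2:4, 1)
    rho <- stats::runif(1, -0.9, 0.9)
    tab <- random_poly_table(K, rho, N = sample(c(500, 5000, 50000), 1))
    fit <- suppressWarnings(fit_polychoric(tab))
    oracle <- grid_polychoric(tab)
    expect_lt(abs(fit$rho - oracle), 1e-3)
  }
})

test_that("fitted rho is monotone in the generating correlation", {
  tau <- liability_thresholds(c(0.63, 0.08, 0.14, 0.15))
  rhos <- seq(-0.6, 0.8, by = 0.2)
  fits <- vapply(rhos, function(r) {
    tab <- round(cell_probabilities(tau, tau, r) * 2e5)
    fit_polychoric(tab)$rho
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("degenerate tables are collapsed or rejected explicitly", {
  tab <- matrix(c(40, 10, 0, 10, 40, 0, 0, 0, 0), 3, 3)
  expect_warning(fit <- fit_polychoric(tab), "empty margin")
  expect_true(is.finite(fit$rho))
  expect_error(suppressWarnings(fit_polychoric(matrix(c(5, 0, 0, 0), 2, 2))),
               "degenerate")
  expect_error(fit_polychoric(matrix(-1, 2, 2)), "non-negative")
})

test_that("standard errors scale with the effective number of pairs", {
  pairs <- simulate_twin_pairs(twin_components(a2 = 0.4), n_mz = 2000, n_dz = 1,
                               seed = 59)
  tab <- double_enter(pairs, "MZ")
  fit <- fit_polychoric(tab)                      # n_pairs from attribute
  fit_raw <- fit_polychoric(unclass(tab[, ]), n_pairs = sum(tab))
  expect_equal(fit$rho, fit_raw$rho)
  # treating 2n double entries as independent understates se by sqrt(2)
  expect_equal(fit$se, fit_raw$se * sqrt(2), tolerance = 1e-6)
})
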