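test_that("expected correlations follow the classical factor covariances", {
  expect_equal(expected_correlations(twin_components(a2 = 1, e2 = 1e-9)),
               c(r_mz = 1, r_dz = 0.5), tolerance = 1e-6)
  expect_equal(expected_correlations(twin_components(d2 = 1, e2 = 1e-9)),
               c(r_mz = 1, r_dz = 0.25), tolerance = 1e-6)
  expect_equal(expected_correlations(twin_components(a2 = 0.27, d2 = 0.25)),
               c(r_mz = 0.52, r_dz = 0.1975))
})

test_that("squared path coefficients reproduce published variance estimates", {
  v <- variance_from_paths(0.52, 0, 0.50, 0.69)
  expect_equal(round(unclass(v), 2),
               c(a2 = 0.27, c2 = 0, d2 = 0.25, e2 = 0.48))
  expect_equal(round(v[["a2"]] + v[["d2"]], 2), 0.52)  # total genetic variance

  v2 <- variance_from_paths(0, 0, 0.58, 0.82)
  expect_equal(round(unclass(v2), 2),
               c(a2 = 0, c2 = 0, d2 = 0.33, e2 = 0.67))

  expect_equal(variance_from_paths(1, 0, 0, 0)[["a2"]], 1)
  expect_error(variance_from_paths(0.9, 0, 0.9, 0.9), "tolerance")
})

test_that("saturated models solve the correlation pair exactly", {
  v <- solve_saturated("ADE", 0.40, 0.14)
  expect_equal(unclass(v)[c("a2", "d2", "e2")],
               c(a2 = 0.16, d2 = 0.24, e2 = 0.60))
  expect_length(attr(v, "boundary"), 0)
  expect_equal(expected_correlations(twin_components(a2 = v[["a2"]], d2 = v[["d2"]])),
               c(r_mz = 0.40, r_dz = 0.14))

  v2 <- solve_saturated("ACE", 0.40, 0.30)
  expect_equal(unclass(v2)[c("a2", "c2", "e2")],
               c(a2 = 0.20, c2 = 0.20, e2 = 0.60))

  v3 <- solve_saturated("ACE", 0.40, 0.14)   # 2*0.14 - 0.40 < 0
  expect_equal(attr(v3, "boundary"), "c2")
  expect_equal(v3[["c2"]], 0)
  expect_error(solve_saturated("AE", 0.4, 0.2))
})

test_that("solving then predicting is the identity off the boundary", {
  set.seed(61)
  for (i in 1:50) {
    r_dz <- stats::runif(1, 0.05, 0.4)
    r_mz <- stats::runif(1, max(r_dz * 2.05, 0.1), min(0.95, 4 * r_dz * 0.99))
    if (r_mz <= 2 * r_dz || r_mz >= 4 * r_dz) next   # interior ADE region only
    v <- solve_saturated("ADE", r_mz, r_dz)
    expect_length(attr(v, "boundary"), 0)
    rr <- expected_correlations(twin_components(a2 = v[["a2"]], d2 = v[["d2"]]))
    expect_equal(unname(rr), c(r_mz, r_dz), tolerance = 1e-10)
  }
})

test_that("Falconer heritability doubles the correlation difference", {
  expect_equal(falconer_heritability(0.40, 0.14), 0.52)
  expect_equal(falconer_heritability(0.18, 0.06), 0.24)
  expect_equal(falconer_heritability(0.3, 0.3), 0)
  expect_error(falconer_heritability(1.2, 0), "\\[-1, 1\\]")
  # under the model, 2(r_mz - r_dz) = a2 + 1.5 d2
  set.seed(67)
  for (i in 1:25) {
    g <- stats::runif(3); g <- 0.9 * g / sum(g)
    v <- twin_components(a2 = g[1], c2 = g[2], d2 = g[3])
    rr <- expected_correlations(v)
    expect_equal(falconer_heritability(rr[["r_mz"]], rr[["r_dz"]]),
                 g[1] + 1.5 * g[3], tolerance = 1e-12)
  }
})

test_that("chi-square tail probabilities match numerical integration", {
  expect_equal(round(chi2_pvalue(2.6, 1), 2), 0.11)
  expect_equal(chi2_pvalue(0, 3), 1)
  expect_equal(round(chi2_pvalue(3.84, 1), 2), 0.05)
  oracle <- stats::integrate(function(x) stats::dchisq(x, 1), 2.6, Inf)$value
  expect_equal(chi2_pvalue(2.6, 1), oracle, tolerance = 1e-5)
  expect_error(chi2_pvalue(-1, 1), "non-negative")
})

test_that("the saturated ADE fit to the study correlations is exact", {
  corr <- correlation_pair(0.40, 0.14, 0.031, 0.038)
  fit <- fit_model("ADE", corr)
  expect_equal(fit$chi2, 0)
  expect_equal(fit$df, 0L)
  expect_length(fit$boundary, 0)
  expect_equal(fit$p, 1)
  expect_equal(unname(fit$components[c("a2", "d2", "e2")]), c(0.16, 0.24, 0.60))
})

test_that("ACE collapses onto AE when shared environment hits the boundary", {
  corr <- correlation_pair(0.40, 0.14, 0.031, 0.038)
  ace <- fit_model("ACE", corr)
  ae <- fit_model("AE", corr)
  expect_equal(ace$chi2, ae$chi2)
  expect_equal(ace$df, ae$df)
  expect_equal(ace$boundary, "c2")
  expect_equal(ace$components, ae$components)
})

test_that("the E model fits uncorrelated twins exactly", {
  corr <- correlation_pair(1e-12, 1e-12, 0.05, 0.05)
  fit <- fit_model("E", corr)
  expect_lt(fit$chi2, 1e-6)
  expect_equal(fit$df, 2L)
})

test_that("chi2 is non-increasing along nested chains and scale-invariant when saturated", {
  set.seed(71)
  for (i in 1:25) {
    r_dz <- stats::runif(1, -0.1, 0.5)
    r_mz <- stats::runif(1, r_dz, 0.9)
    corr <- correlation_pair(r_mz, r_dz, stats::runif(1, 0.02, 0.2),
                             stats::runif(1, 0.02, 0.2))
    chi2 <- vapply(c("ADE", "AE", "DE", "E"),
                   function(m) fit_model(m, corr)$chi2, numeric(1))
    expect_lte(chi2[["ADE"]], chi2[["AE"]] + 1e-12)
    expect_lte(chi2[["ADE"]], chi2[["DE"]] + 1e-12)
    expect_lte(chi2[["AE"]], chi2[["E"]] + 1e-12)
    expect_lte(chi2[["DE"]], chi2[["E"]] + 1e-12)
  }
  corr <- correlation_pair(0.40, 0.14, 0.05, 0.06)
  corr2 <- correlation_pair(0.40, 0.14, 0.05 * 3, 0.06 * 3)
  expect_equal(fit_model("ADE", corr)$chi2, fit_model("ADE", corr2)$chi2)
})

test_that("constrained optimizer matches the grid-search oracle", {
  set.seed(73)
  models <- c("ADE", "ACE", "AE", "CE", "DE", "E")
  for (i in 1:100) {
    r_dz <- stats::runif(1, -0.2, 0.6)
    r_mz <- stats::runif(1, -0.2, 0.9)
    corr <- correlation_pair(r_mz, r_dz, stats::runif(1, 0.05, 0.3),
                             stats::runif(1, 0.05, 0.3))
    m <- models[(i %% length(models)) + 1]
    fit <- fit_model(m, corr)
    oracle <- grid_fit_chi2(m, corr)
    # optimizer can only improve on the grid, and the grid is within its
    # resolution of the optimum
    expect_lte(fit$chi2, oracle$chi2 + 1e-10)
    expect_lte(oracle$chi2 - fit$chi2, 2e-3)
  }
})

test_that("nested comparisons respect the free-parameter hierarchy", {
  corr <- correlation_pair(0.40, 0.14, 0.031, 0.038)
  nt <- compare_nested(fit_model("ADE", corr), fit_model("DE", corr))
  expect_equal(nt$df, 1)
  expect_equal(nt$p, chi2_pvalue(nt$delta_chi2, 1))

  # perfectly AE-consistent data: ADE and AE both fit exactly
  corr0 <- correlation_pair(0.40, 0.20, 0.05, 0.05)
  nt0 <- compare_nested(fit_model("ADE", corr0), fit_model("AE", corr0))
  expect_equal(nt0$delta_chi2, 0)
  expect_equal(nt0$p, 1)

  expect_error(compare_nested(fit_model("ADE", corr), fit_model("CE", corr)),
               "not nested")
  expect_error(compare_nested(fit_model("AE", corr), fit_model("ADE", corr)),
               "not nested")
})
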