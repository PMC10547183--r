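test_that("Gaussian ML fit has the closed-form solution", {
  f <- fit_gaussian_1d(c(-1, 0, 1))
  expect_equal(f$mean, 0)
  expect_equal(f$variance, 2 / 3)  # ML (1/n) variance
  expect_equal(f$log_likelihood, -3 / 2 * log(2 * pi * 2 / 3) - 3 / 2)
  expect_error(fit_gaussian_1d(rep(2, 5)), "zero variance")
  set.seed(12)
  big <- fit_gaussian_1d(rnorm(1e5))
  expect_equal(big$mean, 0, tolerance = 0.02)
  expect_equal(big$variance, 1, tolerance = 0.02)
})

test_that("Landau fit collapses to the Gaussian member on normal data", {
  set.seed(7)
  y <- rnorm(1e4)
  fit <- fit_landau(y, J_nu = 1)
  expect_equal(fit$c, 1, tolerance = 0.1)
  expect_lt(fit$d, 0.02)            # at or near the 1e-3 floor
  expect_false(fit$bistable)
  expect_equal(fit$mu_nu, 0, tolerance = 0.05)
})

test_that("Landau fit recovers bistable parameters from sampled data", {
  set.seed(8)
  y <- rlandau(1e4, -4, 3, 1)
  fit <- fit_landau(y, J_nu = 1)
  expect_lt(abs(fit$c / -4 - 1), 0.15)
  expect_lt(abs(fit$d / 3 - 1), 0.15)
  expect_true(fit$bistable)
  expect_equal(fit$mu_nu, 0, tolerance = 0.1)
})

test_that("returned likelihood dominates both canonical starts", {
  set.seed(9)
  for (y in list(rnorm(300), rlandau(300, -3, 2, 1))) {
    fit <- fit_landau(y, J_nu = 1)
    ll_uni <- sum(landau_log_density_1d(y, 1, 1e-3, 1, mean(y)))
    ll_bi <- sum(landau_log_density_1d(y, -2, 1, 1, mean(y)))
    expect_gte(fit$log_likelihood, ll_uni - 1e-6)
    expect_gte(fit$log_likelihood, ll_bi - 1e-6)
  }
  expect_error(fit_landau(rep(1, 10), 1), "degenerate")
})

test_that("BIC differences follow the penalty arithmetic", {
  expect_equal(delta_bic_landau(10, 10, 16), -log(16))
  expect_equal(delta_bic_landau(0, 10, 16), 20 - log(16))
  expect_equal(delta_bic_mixture(10, 10, 16), -2 * log(16))
  expect_equal(delta_bic_mixture(0, 10, 16), 20 - 2 * log(16))
  for (n in c(1, 5, 100))
    expect_equal(delta_bic_mixture(3, 3, n), 2 * delta_bic_landau(3, 3, n))
  expect_error(delta_bic_landau(0, 0, 0), "n_samples")
})

test_that("well-separated bistability is detected at n = 16", {
  # mirrors the detectable regime: deep double well, small sample
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    y <- rlandau(16, -8, 2, 1)
    g <- fit_gaussian_1d(y)
    l <- fit_landau(y, J_nu = 1 / var(y))
    if (delta_bic_landau(g$log_likelihood, l$log_likelihood, 16) > 6)
      hits <- hits + 1
  }
  expect_gt(hits, 10)  # majority of seeds
})

test_that("mixture EM recovers a well-separated mixture", {
  set.seed(14)
  y <- c(rnorm(5000, -3), rnorm(5000, 3))
  m <- fit_mixture_1d(y)
  expect_equal(m$loc1, -3, tolerance = 0.15)
  expect_equal(m$loc2, 3, tolerance = 0.15)
  expect_equal(m$width, 1, tolerance = 0.05)
  expect_equal(m$weight, 0.5, tolerance = 0.025)
  expect_lte(m$loc1, m$loc2)
})

test_that("mixture handles degenerate two-point data", {
  y <- rep(c(-1, 1), 10)
  m <- fit_mixture_1d(y)
  expect_equal(m$loc1, -1, tolerance = 1e-6)
  expect_equal(m$loc2, 1, tolerance = 1e-6)
  expect_equal(m$weight, 0.5, tolerance = 1e-6)
})

test_that("mixture gains little on unimodal data", {
  set.seed(15)
  y <- rnorm(200)
  g <- fit_gaussian_1d(y)
  m <- fit_mixture_1d(y)
  expect_gte(m$log_likelihood, g$log_likelihood - 1e-8)  # nested family
  expect_lt(delta_bic_mixture(g$log_likelihood, m$log_likelihood, 200), 6)
})

test_that("mixture likelihood matches an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(16)
  y <- c(rnorm(150, -1.5, 0.8), rnorm(100, 1.2, 0.8))
  ours <- fit_mixture_1d(y)
  ref <- Mclust(y, G = 2, modelNames = "E", verbose = FALSE)
  expect_equal(ours$log_likelihood, ref$loglik, tolerance = 1e-4)
})

test_that("KS goodness of fit is calibrated and validates its inputs", {
  set.seed(17)
  u <- runif(1e4)
  ks <- ks_gof(u, punif)
  expect_gt(ks$p_value, 0.01)
  expect_lt(ks$statistic, 0.02)
  # self-comparison against the empirical CDF interpolant
  y <- sort(rnorm(50))
  ecdf_fun <- approxfun(y, seq_along(y) / length(y), yleft = 0, yright = 1)
  expect_lte(ks_gof(y, ecdf_fun)$statistic, 1 / 50 + 1e-12)
  expect_error(ks_gof(u, function(q) -q), "monotone")
  expect_error(ks_gof(u[1:5], punif), "at least 10")
})

test_that("single-group analysis is coherent end to end", {
  # two clusters along one gene direction: clearly bistable
  set.seed(18)
  n <- 20
  base <- matrix(rnorm(n * 5, sd = 0.3), n, 5)
  base[, 1] <- base[, 1] + rep(c(-2, 2), each = n / 2)
  g <- expression_group(base, group_label = "split")
  an <- analyze_group(g)
  expect_true(an$comparison$verdict_landau)
  expect_true(an$landau$bistable)
  expect_gt(an$comparison$delta_bic_landau, 6)
  expect_identical(an$comparison$dof_delta_landau, 1L)
  expect_identical(an$comparison$dof_delta_mixture, 2L)
  # verdicts track the threshold rule
  expect_identical(an$comparison$verdict_landau,
                   an$comparison$delta_bic_landau > an$comparison$threshold)

  # low-sample groups carry a warning note but still compute
  g8 <- expression_group(base[1:8, ], group_label = "small")
  an8 <- analyze_group(g8)
  expect_true(any(grepl("low sample size", an8$warnings)))
  expect_s3_class(an8$landau, "landau_fit")
})
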