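test_that("variance fractions follow the closed 2x2 form", {
  g <- group_with_cov2(matrix(c(2, 1, 1, 2), 2))
  ax <- principal_axis(g)
  s <- variance_fraction(ax, apply(g$values, 2, var))
  expect_equal(unname(s), c(0.75, 0.75), tolerance = 1e-10)
})

test_that("a dominant diagonal gene takes the whole fraction", {
  x <- cbind(g1 = c(0, 2, 4, 6), g2 = rep(1, 4), g3 = rep(2, 4))
  g <- expression_group(x)
  ax <- principal_axis(g)
  s <- variance_fraction(ax, apply(x, 2, var))
  expect_equal(unname(s[1]), 1, tolerance = 1e-12)
  expect_true(all(is.na(s[2:3])))  # zero-variance genes: undefined, not 0
})

test_that("|axis correlation| equals sqrt(s) on exact-eigenvector input", {
  set.seed(21)
  x <- matrix(rnorm(15 * 6), 15, 6) %*% diag(c(3, 1.5, 1, 1, 0.5, 0.2))
  g <- expression_group(x)
  ax <- principal_axis(g)
  s <- variance_fraction(ax, apply(x, 2, var))
  corr <- axis_correlation(g, ax)
  expect_equal(abs(corr), sqrt(s), tolerance = 1e-10)
  expect_true(all(s >= 0 & s <= 1))
  # sum rule: sum_i s_i Sigma_ii = lambda1
  expect_equal(sum(s * apply(x, 2, var)), ax$lambda1, tolerance = 1e-8)
})

test_that("perfectly aligned and orthogonal genes hit the correlation bounds", {
  x <- cbind(g1 = c(0, 2, 4, 6, 8), g2 = -c(0, 2, 4, 6, 8) / 2)
  g <- expression_group(x)
  ax <- principal_axis(g, orient_gene = "g1")
  corr <- axis_correlation(g, ax)
  expect_equal(unname(corr), c(1, -1), tolerance = 1e-10)
})

test_that("relevance table ranks by s and permutes with gene order", {
  set.seed(22)
  x <- matrix(rnorm(12 * 4), 12, 4) %*% diag(c(4, 2, 1, 0.5))
  colnames(x) <- c("a", "b", "c", "d")
  g <- expression_group(x)
  tab <- relevance_table(g, principal_axis(g))
  expect_identical(tab$rank, 1:4)
  expect_true(all(diff(tab$s) <= 0))
  # permuting columns permutes s identically
  perm <- c(3, 1, 4, 2)
  gp <- expression_group(x[, perm])
  tabp <- relevance_table(gp, principal_axis(gp))
  expect_equal(tabp$s[match(tab$gene_id, tabp$gene_id)], tab$s,
               tolerance = 1e-12)
  # threshold flag
  expect_identical(tab$highlight, !is.na(tab$s) & tab$s > 2 / 3)
})

test_that("gene marginal reduces to the Gaussian in the c = 1, d -> 0 limit", {
  ax <- make_axis(mean = c(1, -2, 0.5), loadings = c(2, 1, 2), lambda1 = 2)
  sig <- 2 * outer(ax$loadings, ax$loadings) + diag(c(0.5, 0.3, 0.4))
  fit <- list(c = 1, d = 1e-9, J_nu = 0.5, mu_nu = 0)
  gm <- gene_marginal(1, fit, ax, sig)
  ref <- dnorm(gm$x, ax$mean[1], sqrt(sig[1, 1]))
  expect_lt(max(abs(gm$density - ref)), 1e-4)
  # density integrates to 1 on its grid
  expect_equal(sum(diff(gm$x) * (gm$density[-1] + gm$density[-length(gm$density)]) / 2),
               1, tolerance = 1e-6)
})

test_that("zero-loading genes keep their residual Gaussian marginal", {
  ax <- make_axis(mean = c(0, 3), loadings = c(1, 0), lambda1 = 4)
  sig <- 4 * outer(ax$loadings, ax$loadings) + diag(c(0.2, 0.7))
  fit <- list(c = -4, d = 3, J_nu = 0.25, mu_nu = 0)
  gm <- gene_marginal(2, fit, ax, sig)
  expect_lt(max(abs(gm$density - dnorm(gm$x, 3, sqrt(0.7)))), 1e-6)
})

test_that("bimodal marginals agree with the two-step sampling oracle", {
  ax <- make_axis(mean = c(0.5, 1), loadings = c(0.9, sqrt(1 - 0.81)),
                  lambda1 = 1)
  sig <- 1 * outer(ax$loadings, ax$loadings) + diag(c(0.09, 0.15))
  fit <- list(c = -4, d = 3, J_nu = 1, mu_nu = 0)
  gm <- gene_marginal(1, fit, ax, sig, n_grid = 4001)
  set.seed(23)
  eta <- rlandau(2e4, fit$c, fit$d, fit$J_nu, fit$mu_nu)
  x1 <- ax$mean[1] + eta * ax$loadings[1] +
    rnorm(2e4, sd = sqrt(sig[1, 1] - ax$lambda1 * ax$loadings[1]^2))
  cdf_grid <- cumsum(c(0, diff(gm$x) * (gm$density[-1] + gm$density[-length(gm$density)]) / 2))
  cdf_fun <- approxfun(gm$x, pmin(cdf_grid / max(cdf_grid), 1),
                       yleft = 0, yright = 1)
  expect_gt(ks_gof(x1, cdf_fun)$p_value, 0.01)
})

test_that("negative residual variance is clamped only within round-off", {
  ax <- make_axis(mean = c(0, 0), loadings = c(1, 0), lambda1 = 2)
  sig <- diag(c(2 - 1e-12, 1))
  fit <- list(c = 1, d = 1e-3, J_nu = 0.5, mu_nu = 0)
  expect_warning(gene_marginal(1, fit, ax, sig), "clamped")
  sig2 <- diag(c(1, 1))  # residual variance -1: inconsistent input
  expect_error(suppressWarnings(gene_marginal(1, fit, ax, sig2)), "negative residual")
})
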