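test_that("config validation enforces stability and equilibration rules", {
  expect_error(sim_config(0, 0.1), "n_genes")
  expect_error(sim_config(10, -1), "alpha")
  expect_error(sim_config(10, 0.1, dt = 0.02), "stability guard")
  expect_warning(sim_config(91, 0.01, t_final = 20), "equilibration")
  expect_silent(sim_config(91, 0.01, t_final = 100))
  expect_error(sim_config(10, 0.1, weights = matrix(1, 3, 3)), "weights")
})

test_that("noise-free dynamics stay at the symmetric fixed point", {
  cfg <- sim_config(10, 0.5, t_final = 50, noise_scale = 0)
  expect_identical(unname(simulate_trial(cfg)), rep(0, 10))
})

test_that("ensembles are bitwise reproducible and stable in trial index", {
  cfg <- suppressWarnings(sim_config(5, 0.05, t_final = 5, n_samples = 6,
                                     seed = 99))
  e1 <- sample_ensemble(cfg)
  e2 <- sample_ensemble(cfg)
  expect_identical(e1$states, e2$states)
  # growing the ensemble does not reshuffle earlier trials
  cfg_big <- cfg; cfg_big$n_samples <- 9L
  e3 <- sample_ensemble(cfg_big)
  expect_identical(e3$states[1:6, ], e1$states)
  cfg_other <- cfg; cfg_other$seed <- 100L
  expect_false(identical(sample_ensemble(cfg_other)$states, e1$states))
})

test_that("uncoupled genes equilibrate to the OU stationary variance", {
  # alpha = 0: independent Ornstein-Uhlenbeck, stationary variance = 1/2
  cfg <- sim_config(4, 0, t_final = 20, n_samples = 2500, seed = 5)
  v <- apply(sample_ensemble(cfg)$states, 2, var)
  se <- 0.5 * sqrt(2 / 2500)
  expect_lt(abs(mean(v) - 0.5), 3 * se / sqrt(4))
  # permutation symmetry: all genes statistically exchangeable
  expect_lt(max(v) - min(v), 6 * se)
})

test_that("the mean-field critical point is 1/N and the Jacobian scan agrees", {
  expect_equal(mean_field_alpha_crit(91), 1 / 91)
  expect_equal(mean_field_alpha_crit(1), 1)
  expect_equal(mean_field_alpha_crit(10), 0.1)
  expect_error(mean_field_alpha_crit(0), "n_genes")
  expect_equal(drift_top_eigenvalue(2 / 91, 91), 1, tolerance = 1e-12)
  expect_equal(critical_alpha_scan(91), 1 / 91, tolerance = 1e-12)
  expect_equal(critical_alpha_scan(10), 0.1, tolerance = 1e-12)
})

test_that("supercritical coupling symmetry-breaks along a uniform axis", {
  # alpha = 2/N: by gene-permutation symmetry of the all-to-all network the
  # top axis has (nearly) equal loadings; projections split into two modes
  cfg <- suppressWarnings(sim_config(10, 0.2, t_final = 35, n_samples = 200,
                                     seed = 12))
  grp <- ensemble_as_group(sample_ensemble(cfg))
  ax <- principal_axis(grp)
  expect_lt(max(abs(ax$loadings)) - min(abs(ax$loadings)), 0.15)
  y <- axis_projection(grp, ax)
  fit <- fit_landau(y, ax$J_nu)
  expect_true(fit$bistable)
  expect_gt(delta_bic_landau(fit_gaussian_1d(y)$log_likelihood,
                             fit$log_likelihood, length(y)), 6)
})

test_that("detection power contrasts sub- and super-critical coupling", {
  cfg <- suppressWarnings(sim_config(10, 0.1, t_final = 35, n_samples = 16,
                                     seed = 8))
  curve <- detection_power(c(0.02, 0.2), cfg, n_trials = 10)
  expect_s3_class(curve, "detection_curve")
  expect_lte(curve$detection_fraction[1], 0.2)
  expect_gte(curve$detection_fraction[2], 0.7)
  expect_true(all(curve$stderr ==
    sqrt(curve$detection_fraction * (1 - curve$detection_fraction) / 10)))
})

test_that("the sub/super-critical contrast survives at n_genes = 1000", {
  # scaled-down twin of the small-network contrast: same pipeline, 1000
  # genes, reduced equilibration and trial count
  sub <- suppressWarnings(sim_config(1000, 0.5 / 1000, t_final = 20,
                                     n_samples = 16, seed = 31))
  sup <- suppressWarnings(sim_config(1000, 2 / 1000, t_final = 20,
                                     n_samples = 16, seed = 31))
  run_one <- function(cfg, t) {
    cfg$seed <- cfg$seed + t
    g <- ensemble_as_group(sample_ensemble(cfg))
    ax <- suppressWarnings(principal_axis(g))
    y <- axis_projection(g, ax)
    delta_bic_landau(fit_gaussian_1d(y)$log_likelihood,
                     fit_landau(y, ax$J_nu)$log_likelihood, length(y))
  }
  d_sub <- vapply(1:4, function(t) run_one(sub, t), numeric(1))
  d_sup <- vapply(1:4, function(t) run_one(sup, t), numeric(1))
  expect_lt(sum(d_sub > 6), 2)
  expect_gte(sum(d_sup > 6), 3)
})

test_that("ensemble converts to a labelled expression group", {
  cfg <- suppressWarnings(sim_config(3, 0.05, t_final = 5, n_samples = 4,
                                     seed = 2))
  g <- ensemble_as_group(sample_ensemble(cfg))
  expect_s3_class(g, "expression_group")
  expect_identical(g$gene_ids, c("g001", "g002", "g003"))
  expect_identical(g$sample_ids, c("s001", "s002", "s003", "s004"))
  expect_match(g$group_label, "alpha")
})
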