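#' Simulator configuration
#'
#' Parameters of the stochastic gene-network model
#' \deqn{dx_i/dt = -x_i + \alpha \sum_j w_{ij} \tanh(x_j) + \xi,}
#' integrated by Euler-Maruyama from `x(0) = 0` with additive Gaussian
#' noise of per-step increment `sqrt(dt) * noise_scale * z`.  With the
#' default all-to-all weights (`w_ij = 1`) the model has a supercritical
#' pitchfork transition to bistability at `alpha = 1/n_genes` (mean-field
#' theory; see [mean_field_alpha_crit()]).
#'
#' @param n_genes Number of genes (>= 1).
#' @param alpha Interaction strength (>= 0).
#' @param weights Optional `n_genes x n_genes` weight matrix; `NULL` (the
#'   default) means all-to-all unit weights, handled by a fast path.
#' @param dt Euler step (default `1e-3`); values above `0.01` are rejected
#'   as unstable for the default dynamics.
#' @param t_final Integration time (default 100).  The slowest relaxation
#'   time of the near-critical all-to-all model grows like `sqrt(n_genes)`,
#'   so `t_final` below `10 * sqrt(n_genes)` triggers an equilibration
#'   warning (allowed, for scaled-down experiments).
#' @param noise_scale Noise amplitude (default 1).
#' @param n_samples Ensemble size: number of independent trials.
#' @param seed Master seed; each trial uses an independent sub-stream
#'   derived from it, so ensembles are reproducible and earlier trials do
#'   not reshuffle when `n_samples` changes.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_genes, alpha, weights = NULL, dt = 1e-3,
                       t_final = 100, noise_scale = 1, n_samples = 100,
                       seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (alpha < 0) stop("alpha must be nonnegative")
  if (dt <= 0) stop("dt must be positive")
  if (dt > 0.01)
    stop("dt = ", dt, " exceeds the stability guard of 0.01 for the default dynamics")
  if (t_final <= 0) stop("t_final must be positive")
  if (t_final < 10 * sqrt(n_genes))
    warning(sprintf(
      "t_final = %g is below the equilibration rule t_final >= 10*sqrt(n_genes) = %g; samples may not be fully equilibrated",
      t_final, 10 * sqrt(n_genes)))
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (nrow(weights) != n_genes || ncol(weights) != n_genes)
      stop("weights must be an n_genes x n_genes matrix")
  }
  if (noise_scale < 0) stop("noise_scale must be nonnegative")
  structure(
    list(n_genes = as.integer(n_genes), alpha = alpha, weights = weights,
         dt = dt, t_final = t_final, noise_scale = noise_scale,
         n_samples = as.integer(n_samples), seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: %d genes, alpha = %.5g (alpha_crit = %.5g), dt = %g, t_final = %g, noise = %g, %d samples, seed = %d>\n",
              x$n_genes, x$alpha, 1 / x$n_genes, x$dt, x$t_final,
              x$noise_scale, x$n_samples, x$seed))
  invisible(x)
}

# Independent per-trial sub-stream seeds: a fixed multiplicative hash of the
# master seed and trial index, stable in the trial index so growing the
# ensemble never reshuffles earlier trials.
#' @noRd
trial_seed <- function(seed, trial) {
  s <- (as.double(seed) + as.double(trial) * 2654435761) %% 2147483629
  as.integer(s) + 1L
}

#' Run one simulation trial to its final state
#'
#' Integrates the network dynamics from `x(0) = 0` to `t_final` and returns
#' the final state vector.  With `noise_scale = 0` the origin is a fixed
#' point of the drift and the zero vector is returned exactly.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed for this trial; when `NULL` the current
#'   RNG state is used.
#' @return Named numeric vector of length `n_genes` (names `g001`, ...).
#' @export
simulate_trial <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(round(config$t_final / config$dt))
  x <- sim_trial_cpp(config$n_genes, config$alpha, config$dt, n_steps,
                     config$noise_scale, config$weights)
  names(x) <- gene_labels(config$n_genes)
  x
}

#' @noRd
gene_labels <- function(n) {
  sprintf(paste0("g%0", max(3L, nchar(n)), "d"), seq_len(n))
}

#' @noRd
sample_labels <- function(n) {
  sprintf(paste0("s%0", max(3L, nchar(n)), "d"), seq_len(n))
}

#' Sample an equilibrium ensemble
#'
#' Runs `n_samples` independent trials (independent noise streams derived
#' from the master seed) and collects the final states: the simulator's
#' stand-in for one group of expression samples.  Identical configurations
#' reproduce bitwise-identical ensembles.
#'
#' @param config A [sim_config()].
#' @return An object of class `"ensemble"`: list with `states`
#'   (`n_samples x n_genes` matrix) and `config`.
#' @export
sample_ensemble <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  states <- matrix(NA_real_, config$n_samples, config$n_genes,
                   dimnames = list(sample_labels(config$n_samples),
                                   gene_labels(config$n_genes)))
  for (k in seq_len(config$n_samples)) {
    states[k, ] <- simulate_trial(config, seed = trial_seed(config$seed, k))
  }
  structure(list(states = states, config = config), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble: %d samples x %d genes at alpha = %.5g>\n",
              nrow(x$states), ncol(x$states), x$config$alpha))
  invisible(x)
}

#' Convert an ensemble to an expression group
#'
#' Simulated states live on the model's own (already log-like) scale, so no
#' log transform is applied.
#'
#' @param ensemble An [sample_ensemble()] result.
#' @param group_label Label for the resulting group.
#' @return An [expression_group()].
#' @export
ensemble_as_group <- function(ensemble, group_label = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.null(group_label))
    group_label <- sprintf("alpha=%.6g", ensemble$config$alpha)
  expression_group(ensemble$states, group_label = group_label)
}

#' Mean-field critical interaction strength
#'
#' Linear stability of the symmetric fixed point `x = 0`: the drift Jacobian
#' is `-I + alpha * W`, and for all-to-all unit weights its top eigenvalue
#' `-1 + alpha * n_genes` crosses zero at
#' \deqn{\alpha_{crit} = 1/N_{genes}.}
#'
#' @param n_genes Number of genes (>= 1).
#' @return The critical interaction strength `1/n_genes`.
#' @export
mean_field_alpha_crit <- function(n_genes) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  1 / n_genes
}

#' Top eigenvalue of the noise-free drift Jacobian at the origin
#'
#' The Jacobian of the drift at `x = 0` is `-I + alpha * W` (the derivative
#' of `tanh` at 0 is 1).  Returns its largest real eigenvalue part, computed
#' numerically.
#'
#' @param alpha Interaction strength.
#' @param n_genes Number of genes.
#' @param weights Optional weight matrix; default all-to-all unit weights.
#' @return The top eigenvalue (real part).
#' @export
drift_top_eigenvalue <- function(alpha, n_genes, weights = NULL) {
  W <- if (is.null(weights)) matrix(1, n_genes, n_genes) else as.matrix(weights)
  J <- -diag(n_genes) + alpha * W
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Numerical scan for the bifurcation point
#'
#' Locates the interaction strength at which the top Jacobian eigenvalue of
#' the noise-free drift crosses zero, by root finding on
#' [drift_top_eigenvalue()].  For the default all-to-all network this
#' reproduces the mean-field value `1/n_genes` to near machine precision.
#'
#' @param n_genes Number of genes.
#' @param weights Optional weight matrix.
#' @param interval Search interval for `alpha`.
#' @return The critical `alpha`.
#' @export
critical_alpha_scan <- function(n_genes, weights = NULL,
                                interval = c(1e-8, 1)) {
  uniroot(function(a) drift_top_eigenvalue(a, n_genes, weights),
          interval, tol = 1e-15)$root
}

#' Detection-power experiment
#'
#' For each interaction strength, repeatedly (i) sample an equilibrium
#' ensemble, (ii) project it onto its first principal component, (iii) fit
#' the Gaussian and Landau models, and (iv) score a positive identification
#' when the BIC difference exceeds the threshold.  Returns the positive
#' fraction with its binomial standard error -- the power curve of the
#' detector across the transition.
#'
#' @param alpha_values Numeric vector of interaction strengths.
#' @param config A [sim_config()] used as template (`alpha` and `seed` are
#'   overridden per experiment).
#' @param n_trials Independent experiments per `alpha` (>= 1).
#' @param threshold BIC-difference threshold for a positive call (default 6).
#' @return An object of class `"detection_curve"`: a `data.frame` with
#'   columns `alpha`, `detection_fraction`, `stderr`, plus attributes
#'   `n_trials` and `n_samples_per_trial`.
#' @export
detection_power <- function(alpha_values, config, n_trials, threshold = 6) {
  stopifnot(inherits(config, "sim_config"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  frac <- numeric(length(alpha_values))
  for (a in seq_along(alpha_values)) {
    hits <- 0L
    for (t in seq_len(n_trials)) {
      cfg <- config
      cfg$alpha <- alpha_values[a]
      cfg$seed <- trial_seed(config$seed, a * 1000003 + t)
      ens <- sample_ensemble(cfg)
      grp <- ensemble_as_group(ens)
      axis <- suppressWarnings(principal_axis(grp))
      y <- axis_projection(grp, axis)
      gauss <- fit_gaussian_1d(y)
      landau <- fit_landau(y, axis$J_nu)
      dbic <- delta_bic_landau(gauss$log_likelihood, landau$log_likelihood,
                               length(y))
      if (dbic > threshold) hits <- hits + 1L
    }
    frac[a] <- hits / n_trials
  }
  out <- data.frame(alpha = alpha_values, detection_fraction = frac,
                    stderr = sqrt(frac * (1 - frac) / n_trials))
  attr(out, "n_trials") <- as.integer(n_trials)
  attr(out, "n_samples_per_trial") <- config$n_samples
  class(out) <- c("detection_curve", "data.frame")
  out
}
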