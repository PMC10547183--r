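#' @keywords internal
#' @noRd
check_landau_params <- function(c, d, J_nu) {
  if (!is.finite(c) || !is.finite(d) || !is.finite(J_nu))
    stop("Landau parameters must be finite")
  if (J_nu <= 0) stop("J_nu must be positive (got ", J_nu, ")")
  if (d < 0) stop("d must be nonnegative (got ", d, ")")
  if (c <= 0 && d == 0)
    stop("density is not normalizable for c <= 0 with d = 0")
  invisible(TRUE)
}

#' Log normalization constant of the 1-D Landau density
#'
#' Computes \eqn{\log Z_1} with
#' \deqn{Z_1 = \int_{-\infty}^{\infty}
#'   \exp\!\left[-\tfrac{c}{2} J_\nu y^2 - \tfrac{d}{4} J_\nu^2 y^4\right] dy,}
#' in closed form via exponentially scaled modified Bessel functions:
#' with \eqn{x = c^2/(8d)},
#' \deqn{Z_1 = \sqrt{c/(2 d J_\nu)}\; e^{x} K_{1/4}(x) \quad (c > 0),}
#' \deqn{Z_1 = \tfrac{\pi}{2}\sqrt{|c|/(d J_\nu)}\;
#'   e^{x}\left[I_{-1/4}(x) + I_{1/4}(x)\right] \quad (c < 0),}
#' and \eqn{Z_1 = 2\,\Gamma(5/4)\,(d J_\nu^2/4)^{-1/4}} at \eqn{c = 0}.
#' The scaled evaluation keeps the computation finite for arbitrarily deep
#' double wells, where \eqn{Z_1} itself can exceed floating-point range.
#'
#' @param c Quadratic shape coefficient (dimensionless); negative values give
#'   a double-well (bistable) density.
#' @param d Quartic coefficient, `d >= 0`; must be positive when `c <= 0`.
#' @param J_nu Inverse variance along the axis, positive.
#' @return `log(Z1)`, always finite.
#' @seealso [landau_normalization_1d()] for the constant itself.
#' @export
landau_log_normalization_1d <- function(c, d, J_nu) {
  check_landau_params(c, d, J_nu)
  if (d == 0) return(0.5 * log(2 * pi / (c * J_nu)))   # Gaussian limit
  x <- c^2 / (8 * d)
  if (c > 0) {
    if (x < 700) {
      0.5 * log(c / (2 * d * J_nu)) + log(besselK(x, 0.25, expon.scaled = TRUE))
    } else {
      # asymptotic series e^x K_a(x) ~ sqrt(pi/(2x)) (1 + (mu-1)/(8x)
      #   + (mu-1)(mu-9)/(2(8x)^2) + ...), mu = 4 a^2
      mu <- 0.25
      0.5 * log(c / (2 * d * J_nu)) + 0.5 * log(pi / (2 * x)) +
        log1p((mu - 1) / (8 * x) + (mu - 1) * (mu - 9) / (128 * x^2))
    }
  } else if (c < 0) {
    if (x < 700) {
      0.5 * log(-c / (d * J_nu)) + log(pi / 2) + 2 * x +
        log(besselI(x, -0.25, expon.scaled = TRUE) +
              besselI(x, 0.25, expon.scaled = TRUE))
    } else {
      # e^{-x} I_{\pm 1/4}(x) ~ (2 pi x)^{-1/2} (1 - (mu-1)/(8x)
      #   + (mu-1)(mu-9)/(2(8x)^2) - ...), mu = 4 a^2; same mu for +-1/4
      mu <- 0.25
      0.5 * log(-c / (d * J_nu)) + log(pi / 2) + 2 * x +
        log(2 / sqrt(2 * pi * x)) +
        log1p(-(mu - 1) / (8 * x) + (mu - 1) * (mu - 9) / (128 * x^2))
    }
  } else {
    log(2) + lgamma(1.25) - 0.25 * log(d * J_nu^2 / 4)
  }
}

#' Normalization constant of the 1-D Landau density
#'
#' The constant \eqn{Z_1} itself; see [landau_log_normalization_1d()] for the
#' closed form.  For deep double wells (large \eqn{c^2/8d}) the true constant
#' can exceed the double-precision range, in which case `Inf` is returned
#' with a warning; all internal likelihood computations use the log form and
#' never overflow.
#'
#' @inheritParams landau_log_normalization_1d
#' @return The positive normalization constant.
#' @export
landau_normalization_1d <- function(c, d, J_nu) {
  lz <- landau_log_normalization_1d(c, d, J_nu)
  if (lz > log(.Machine$double.xmax)) {
    warning("normalization constant exceeds double-precision range; ",
            "returning Inf -- use landau_log_normalization_1d()")
    return(Inf)
  }
  exp(lz)
}

#' Log density of the 1-D Landau distribution
#'
#' \deqn{\log p(y) = -\tfrac{c}{2} J_\nu (y-\mu_\nu)^2
#'   - \tfrac{d}{4} J_\nu^2 (y-\mu_\nu)^4 - \log Z_1.}
#' The Gaussian with variance \eqn{1/J_\nu} is the member \eqn{c = 1, d = 0};
#' bistability corresponds to \eqn{c < 0, d > 0}, with modes at
#' \eqn{\mu_\nu \pm \sqrt{-c/(d J_\nu)}}.
#'
#' @param y Numeric vector of axis coordinates.
#' @inheritParams landau_log_normalization_1d
#' @param mu_nu Center of the density along the axis.
#' @return Numeric vector of log densities.
#' @export
landau_log_density_1d <- function(y, c, d, J_nu, mu_nu = 0) {
  lz <- landau_log_normalization_1d(c, d, J_nu)
  z <- y - mu_nu
  -(c / 2) * J_nu * z^2 - (d / 4) * J_nu^2 * z^4 - lz
}

#' Modes of a Landau density
#'
#' For `c < 0` the density has two maxima at `mu_nu +- sqrt(-c/(d*J_nu))`;
#' otherwise the single maximum at `mu_nu`.
#' @param fit A [landau_fit][fit_landau] object or a list with elements
#'   `c`, `d`, `J_nu`, `mu_nu`.
#' @return Numeric vector of mode locations (length 1 or 2).
#' @export
landau_modes <- function(fit) {
  if (fit$c < 0 && fit$d > 0) {
    m <- sqrt(-fit$c / (fit$d * fit$J_nu))
    fit$mu_nu + c(-m, m)
  } else fit$mu_nu
}

#' CDF of the fitted 1-D Landau distribution
#'
#' Numerically integrated cumulative distribution.  Exploits the symmetry of
#' the density about `mu_nu` (CDF(mu_nu) = 1/2) and accumulates adaptive
#' quadrature between consecutive sorted evaluation points, so the result is
#' monotone by construction.
#'
#' @param y Numeric vector of evaluation points.
#' @param fit A [landau_fit][fit_landau] object, or any list with elements
#'   `c`, `d`, `J_nu`, `mu_nu`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
landau_cdf_1d <- function(y, fit) {
  c <- fit$c; d <- fit$d; J <- fit$J_nu; mu <- fit$mu_nu
  check_landau_params(c, d, J)
  lz <- landau_log_normalization_1d(c, d, J)
  dens <- function(t) {
    z <- t - mu
    exp(-(c / 2) * J * z^2 - (d / 4) * J^2 * z^4 - lz)
  }
  ord <- order(y)
  ys <- y[ord]
  out <- numeric(length(ys))
  # integrate outward from the center of symmetry through sorted points
  right <- ys >= mu
  acc <- 0.5; prev <- mu
  for (i in which(right)) {
    acc <- acc + integrate(dens, prev, ys[i], rel.tol = 1e-10,
                           abs.tol = 1e-12)$value
    prev <- ys[i]
    out[i] <- min(acc, 1)
  }
  acc <- 0.5; prev <- mu
  for (i in rev(which(!right))) {
    acc <- acc - integrate(dens, ys[i], prev, rel.tol = 1e-10,
                           abs.tol = 1e-12)$value
    prev <- ys[i]
    out[i] <- max(acc, 0)
  }
  res <- numeric(length(y))
  res[ord] <- out
  res
}

#' Draw samples from the 1-D Landau distribution
#'
#' Exact rejection sampling under a flat envelope over the effective support
#' (the region where the unnormalized density exceeds `exp(-40)` of its
#' maximum).  Intended for simulation studies and parameter-recovery tests;
#' acceptance is modest for deep wells but exact.
#'
#' @param n Number of draws.
#' @inheritParams landau_log_density_1d
#' @return Numeric vector of length `n`.
#' @export
rlandau <- function(n, c, d, J_nu, mu_nu = 0) {
  check_landau_params(c, d, J_nu)
  f <- function(z) -(c / 2) * J_nu * z^2 - (d / 4) * J_nu^2 * z^4
  # exponent maximum: at z = 0, or at the two wells when c < 0
  fmax <- if (c < 0 && d > 0) f(sqrt(-c / (d * J_nu))) else 0
  # support bound: f(z) - fmax <= -40
  g <- function(z) f(z) - fmax + 40
  zhi <- if (c < 0 && d > 0) sqrt(-c / (d * J_nu)) else 1 / sqrt(max(J_nu * abs(c), d))
  hi <- zhi + 1
  while (g(hi) > 0) hi <- hi * 2
  L <- uniroot(g, c(zhi, hi), tol = 1e-10)$root
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 100L)
    z <- runif(m, -L, L)
    keep <- log(runif(m)) < (f(z) - fmax)
    out <- c(out, z[keep])
  }
  out[seq_len(n)] + mu_nu
}
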