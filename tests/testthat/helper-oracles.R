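# Independent quadrature oracle for the 1-D Landau normalization, in log
# space: integrates exp(f(y) - max f) piecewise around the exponent maxima
# so narrow double-well peaks are never missed, then restores the shift.
landau_logZ_quad <- function(c, d, J) {
  f <- function(y) -(c / 2) * J * y^2 - (d / 4) * J^2 * y^4
  if (c < 0 && d > 0) {
    ys <- sqrt(-c / (d * J))
    M <- f(ys)
  } else {
    ys <- 0
    M <- 0
  }
  g <- function(y) f(y) - M + 80
  hi <- ys + 1
  while (g(hi) > 0) hi <- hi * 2
  L <- uniroot(g, c(ys, hi), tol = 1e-12)$root
  h <- function(y) exp(f(y) - M)
  tol <- list(rel.tol = 1e-12, abs.tol = 1e-300)
  if (c < 0 && d > 0) {
    # split at the well so adaptive quadrature resolves a narrow peak
    wdt <- min(sqrt(80 / (-c * J)), ys)
    total <-
      integrate(h, 0, ys - wdt, rel.tol = 1e-12, abs.tol = 1e-300)$value +
      integrate(h, ys - wdt, ys, rel.tol = 1e-12, abs.tol = 1e-300)$value +
      integrate(h, ys, L, rel.tol = 1e-12, abs.tol = 1e-300)$value
  } else {
    total <- integrate(h, 0, L, rel.tol = 1e-12, abs.tol = 1e-300)$value
  }
  M + log(2 * total)
}

# Build an expression group whose unbiased sample covariance is EXACTLY the
# given 2x2 matrix, using 3 samples assembled from an orthonormal frame.
group_with_cov2 <- function(sigma, mean2 = c(0, 0), label = "exact2") {
  eg <- eigen(sigma, symmetric = TRUE)
  u1 <- c(1, -1, 0) / sqrt(2)
  u2 <- c(1, 1, -2) / sqrt(6)
  xc <- sqrt(2 * eg$values[1]) * outer(u1, eg$vectors[, 1]) +
    sqrt(2 * eg$values[2]) * outer(u2, eg$vectors[, 2])
  x <- sweep(xc, 2, mean2, "+")
  dimnames(x) <- list(paste0("s", 1:3), c("gA", "gB"))
  expression_group(x, group_label = label)
}

# Multi-gene analogue: n samples, exact covariance lam1 * nu nu' + residual
# diagonal in the orthogonal complement; returns group plus the target axis.
make_axis <- function(mean, loadings, lambda1, gene_ids = NULL) {
  loadings <- loadings / sqrt(sum(loadings^2))
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(loadings))
  structure(list(mean = mean, loadings = loadings, lambda1 = lambda1,
                 J_nu = 1 / lambda1, gene_ids = gene_ids),
            class = "principal_axis")
}
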