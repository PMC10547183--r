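#' Fraction of each gene's variance along the bistable axis
#'
#' \deqn{s_i = \hat\nu_i^2 / (J_\nu \Sigma_{ii}) = \lambda_1 \hat\nu_i^2 / \Sigma_{ii},}
#' a number in `[0, 1]` giving the proportion of gene i's variance that lies
#' along the axis.  Genes with zero variance get `NA` (the fraction is
#' undefined, not zero).
#'
#' @param axis A [principal_axis()].
#' @param gene_variances Per-gene variances \eqn{\Sigma_{ii}} under the same
#'   (unbiased) covariance convention as the axis.
#' @return Numeric vector of fractions, one per gene.
#' @export
variance_fraction <- function(axis, gene_variances) {
  stopifnot(inherits(axis, "principal_axis"))
  if (length(gene_variances) != length(axis$loadings))
    stop("gene_variances length must match the number of loadings")
  s <- axis$lambda1 * axis$loadings^2 / gene_variances
  s[gene_variances <= 0] <- NA_real_
  s
}

#' Correlation of each gene with the projected coordinate
#'
#' Pearson correlation between each gene's expression and the sample
#' coordinates along the bistable axis.  When the axis is an exact
#' eigenvector of the covariance of the same data, `|corr| = sqrt(s)`
#' identically; the correlation is the more intuitive measure, the variance
#' fraction the one used for ranking.
#'
#' @param group An [expression_group()].
#' @param axis A [principal_axis()] for the same genes.
#' @return Numeric vector of correlations in `[-1, 1]`; `NA` for genes with
#'   zero variance.
#' @export
axis_correlation <- function(group, axis) {
  y <- axis_projection(group, axis)
  v <- apply(group$values, 2, var)
  out <- rep(NA_real_, ncol(group$values))
  ok <- v > 0
  out[ok] <- suppressWarnings(cor(group$values[, ok, drop = FALSE], y))
  out
}

#' Per-gene relevance table
#'
#' Combines the variance fraction, axis correlation, direction label, and
#' rank for every gene, ordered by decreasing `s` -- the table used to read
#' off which genes define the bistability.
#'
#' @param group An [expression_group()].
#' @param axis A [principal_axis()] computed from the group.
#' @param s_threshold Highlight threshold on the variance fraction
#'   (default `2/3`): genes above it are flagged in the `highlight` column.
#' @return A `data.frame` with columns `gene_id`, `s`, `axis_corr`,
#'   `direction` (`"up"`/`"down"` in the positive-axis state), `rank`,
#'   `highlight`.
#' @export
relevance_table <- function(group, axis, s_threshold = 2 / 3) {
  v <- apply(group$values, 2, var)
  s <- variance_fraction(axis, v)
  corr <- axis_correlation(group, axis)
  tab <- data.frame(
    gene_id = group$gene_ids,
    s = s,
    axis_corr = corr,
    direction = ifelse(axis$loadings >= 0, "up", "down"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$s, tab$gene_id), ]
  tab$rank <- seq_len(nrow(tab))
  tab$highlight <- !is.na(tab$s) & tab$s > s_threshold
  rownames(tab) <- NULL
  tab
}

#' Marginal density of one gene under the fitted Landau model
#'
#' The fitted model is a Landau density along the axis times a Gaussian in
#' the orthogonal directions.  Marginalizing all genes but gene i gives
#' \deqn{p(x_i) \propto \int N(x_i;\; \mu_i + \eta\,\hat\nu_i,\; \Sigma'_{ii})\,
#'   \exp\!\left[-\tfrac{c}{2} J_\nu (\eta-\mu_\nu)^2
#'              - \tfrac{d}{4} J_\nu^2 (\eta-\mu_\nu)^4\right] d\eta,}
#' where \eqn{\Sigma' = \Sigma - \lambda_1 \hat\nu \hat\nu^T} is the
#' covariance with the variance along the axis removed.  The eta integral is
#' evaluated by Gauss-Legendre quadrature (401 nodes over
#' `mu_nu +- 8*sqrt(lambda1)`) and the density is normalized on its grid.
#' A bimodal axis with a large loading on gene i produces a bimodal
#' marginal; a gene with zero loading keeps its plain Gaussian marginal
#' regardless of `c` and `d`.
#'
#' @param i Gene index (or gene id) to marginalize onto.
#' @param fit A [landau_fit][fit_landau].
#' @param axis The [principal_axis()] the fit was computed along.
#' @param covariance Unbiased sample covariance matrix of the group
#'   (genes x genes).
#' @param n_grid Number of evaluation points for the returned density.
#' @return An object of class `"gene_marginal"`: list with `x` (grid),
#'   `density`, `gene_id`, and `fun` (an interpolating density function).
#' @export
gene_marginal <- function(i, fit, axis, covariance, n_grid = 1001) {
  stopifnot(inherits(axis, "principal_axis"))
  if (is.character(i)) {
    i <- match(i, axis$gene_ids)
    if (is.na(i)) stop("gene id not found in axis")
  }
  nu_i <- axis$loadings[i]
  mu_i <- axis$mean[i]
  sig2_res <- covariance[i, i] - axis$lambda1 * nu_i^2   # Sigma'_ii
  if (sig2_res < 0) {
    if (sig2_res > -1e-10) {
      warning("residual variance slightly negative from round-off; clamped to 0")
      sig2_res <- 0
    } else {
      stop("negative residual variance for gene ", i,
           ": covariance and axis are inconsistent")
    }
  }
  half <- 8 * sqrt(axis$lambda1)
  gl <- pracma::gaussLegendre(401, fit$mu_nu - half, fit$mu_nu + half)
  eta <- gl$x
  z <- eta - fit$mu_nu
  w_eta <- gl$w * exp(-(fit$c / 2) * fit$J_nu * z^2 -
                        (fit$d / 4) * fit$J_nu^2 * z^4)
  centers <- mu_i + eta * nu_i
  span <- range(centers)
  sd_res <- sqrt(sig2_res)
  lo <- span[1] - 6 * max(sd_res, 1e-8)
  hi <- span[2] + 6 * max(sd_res, 1e-8)
  x <- seq(lo, hi, length.out = n_grid)
  if (sig2_res == 0) {
    # pushforward of the 1-D Landau density through x_i = mu_i + eta*nu_i
    if (abs(nu_i) < 1e-14) stop("gene has zero loading and zero residual variance")
    dens <- exp(landau_log_density_1d((x - mu_i) / nu_i, fit$c, fit$d,
                                      fit$J_nu, fit$mu_nu)) / abs(nu_i)
  } else {
    dens <- vapply(x, function(xx)
      sum(w_eta * dnorm(xx, centers, sd_res)), numeric(1))
  }
  # normalize on the grid (trapezoid)
  dx <- diff(x)
  mass <- sum(dx * (dens[-1] + dens[-length(dens)]) / 2)
  dens <- dens / mass
  structure(
    list(x = x, density = dens,
         gene_id = if (!is.null(axis$gene_ids)) axis$gene_ids[i] else i,
         fun = approxfun(x, dens, yleft = 0, yright = 0)),
    class = "gene_marginal")
}
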