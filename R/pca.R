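#' Dominant variance axis of an expression group
#'
#' Computes the first principal component of the group's sample covariance:
#' the candidate bistable dimension.  Near a continuous symmetry-breaking
#' transition, bistability is expected to appear along the direction of
#' largest variance, so all model comparison downstream happens along this
#' single axis.
#'
#' @param group An [expression_group()].
#' @param orient_gene Optional gene id; if given, the axis sign is chosen so
#'   that this gene's loading is positive.  By default the sign is fixed so
#'   that the largest-magnitude loading is positive (a deterministic
#'   convention; the orientation itself carries no statistical meaning).
#'
#' @return An object of class `"principal_axis"`: list with
#'   \item{mean}{per-gene sample mean (log units)}
#'   \item{loadings}{unit loading vector \eqn{\hat\nu}}
#'   \item{lambda1}{top eigenvalue \eqn{\lambda_1} of the unbiased sample
#'     covariance (log-units squared)}
#'   \item{J_nu}{\eqn{J_\nu = 1/\lambda_1}, the inverse variance along the
#'     axis; sets the scale of the Landau density}
#'   \item{gene_ids}{gene identifiers, in column order}
#'
#' @details The unbiased (n-1) covariance convention is used throughout the
#'   package: `lambda1` is the unbiased variance of the projected data and
#'   `J_nu = 1/lambda1`.  The decomposition is done by SVD of the centered
#'   data matrix, which is exact and efficient when there are many more genes
#'   than samples.  A warning is raised when the top two eigenvalues are
#'   nearly degenerate (the axis is then ill-determined).
#' @export
principal_axis <- function(group, orient_gene = NULL) {
  stopifnot(inherits(group, "expression_group"))
  x <- group$values
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc, nu = 0, nv = 1)
  lambda <- sv$d^2 / (n - 1)
  if (lambda[1] <= 0 || !any(abs(xc) > 0))
    stop("zero total variance: no principal axis is defined")
  if (length(lambda) > 1 && (lambda[1] - lambda[2]) < 1e-9 * lambda[1])
    warning("top two eigenvalues are nearly degenerate; ",
            "the bistable axis is ill-determined")
  nu <- drop(sv$v)
  # deterministic sign convention
  if (!is.null(orient_gene)) {
    j <- match(orient_gene, group$gene_ids)
    if (is.na(j)) stop("orient_gene '", orient_gene, "' not found in group")
    if (nu[j] < 0) nu <- -nu
  } else if (nu[which.max(abs(nu))] < 0) {
    nu <- -nu
  }
  nu <- nu / sqrt(sum(nu^2))
  structure(
    list(mean = mu, loadings = nu, lambda1 = lambda[1],
         J_nu = 1 / lambda[1], gene_ids = group$gene_ids),
    class = "principal_axis")
}

#' @export
print.principal_axis <- function(x, ...) {
  top <- order(abs(x$loadings), decreasing = TRUE)[seq_len(min(3, length(x$loadings)))]
  cat(sprintf("<principal_axis: lambda1 = %.4g, J_nu = %.4g; top loadings: %s>\n",
              x$lambda1, x$J_nu,
              paste(sprintf("%s (%.2f)", x$gene_ids[top], x$loadings[top]),
                    collapse = ", ")))
  invisible(x)
}

#' Project samples onto a principal axis
#'
#' Returns the centered coordinate \eqn{y_k = (x_k - \mu)\cdot\hat\nu} of
#' each sample along the axis.  When the axis was computed from the same
#' group, the projection has mean zero and unbiased variance `lambda1`.
#'
#' @param group An [expression_group()].
#' @param axis A [principal_axis()] with matching gene dimension.
#' @return Numeric vector of length `n_samples`, named by sample id.
#' @export
axis_projection <- function(group, axis) {
  stopifnot(inherits(group, "expression_group"),
            inherits(axis, "principal_axis"))
  if (ncol(group$values) != length(axis$loadings))
    stop("dimension mismatch: group has ", ncol(group$values),
         " genes but axis has ", length(axis$loadings), " loadings")
  y <- drop(sweep(group$values, 2, axis$mean) %*% axis$loadings)
  names(y) <- group$sample_ids
  y
}
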