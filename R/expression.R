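#' Construct an expression group
#'
#' An expression group is the unit of analysis: one group of samples (for
#' example, all individuals measured at one developmental timepoint) with
#' natural-log expression values for a common set of genes.
#'
#' @param values Numeric matrix, samples in rows and genes in columns, of
#'   natural-log expression values.  Use [log_transform()] first if the data
#'   are raw positive counts.
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   the column names of `values`).
#' @param sample_ids Character vector of unique sample identifiers (defaults
#'   to the row names of `values`).
#' @param group_label Single string labelling the group (e.g. `"day15"`).
#'
#' @return An object of class `"expression_group"`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `group_label`.
#'
#' @details At least 3 samples are required to define a covariance.  Groups
#'   with fewer than 10 samples are accepted but downstream reports carry a
#'   low-sample warning: with fewer than roughly 10 samples per group the
#'   bistable model is rarely statistically distinguishable from a Gaussian.
#'
#' @examples
#' x <- matrix(rnorm(30), nrow = 10, ncol = 3,
#'             dimnames = list(paste0("s", 1:10), c("a", "b", "c")))
#' g <- expression_group(x, group_label = "demo")
#' @export
expression_group <- function(values, gene_ids = colnames(values),
                             sample_ids = rownames(values),
                             group_label = "group") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-finite expression value at sample '%s', gene '%s'; ",
      sample_ids[bad[1]], gene_ids[bad[2]]),
      "missing values are not supported -- supply complete log-space data")
  }
  if (nrow(values) < 3L)
    stop("at least 3 samples are required to define a covariance (got ",
         nrow(values), ")")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) must equal ncol(values)")
  if (length(sample_ids) != nrow(values))
    stop("length(sample_ids) must equal nrow(values)")
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(
    list(values = values, gene_ids = as.character(gene_ids),
         sample_ids = as.character(sample_ids),
         group_label = as.character(group_label)[1]),
    class = "expression_group")
}

#' @export
print.expression_group <- function(x, ...) {
  cat(sprintf("<expression_group '%s': %d samples x %d genes>\n",
              x$group_label, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Natural-log transform of raw expression values
#'
#' All model fits operate on natural-log expression; fitted shape parameters
#' are only comparable across runs under this convention.
#'
#' @param raw Numeric matrix (or vector) of strictly positive raw values.
#' @return Elementwise natural logarithm, same shape as the input.
#' @examples
#' log_transform(matrix(c(1, exp(1), exp(2), 10), 2))
#' @export
log_transform <- function(raw) {
  raw <- if (is.matrix(raw)) raw else as.matrix(raw)
  bad <- which(!(is.finite(raw) & raw > 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    rn <- rownames(raw); cn <- colnames(raw)
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "non-positive value %g at row %s, column %s: raw expression must be strictly positive before log transform",
      raw[i, j],
      if (is.null(rn)) as.character(i) else sprintf("'%s'", rn[i]),
      if (is.null(cn)) as.character(j) else sprintf("'%s'", cn[j])))
  }
  log(raw)
}

#' Geometric-mean housekeeping normalization
#'
#' Rescales each sample by the geometric mean of a set of housekeeping genes,
#' so that the housekeeping geometric means are equal across samples (each
#' sample is divided by its housekeeping geometric mean over the grand
#' geometric mean).  This approximates the vendor-side normalization commonly
#' applied to targeted expression panels; it is off by default in the study
#' driver.
#'
#' @param raw Numeric matrix of strictly positive raw values, samples x genes.
#' @param housekeeping Column names or indices of the housekeeping genes.
#' @return Matrix of the same shape, normalized, still strictly positive.
#' @export
geometric_mean_normalize <- function(raw, housekeeping) {
  raw <- as.matrix(raw)
  hk <- raw[, housekeeping, drop = FALSE]
  if (any(!(is.finite(hk) & hk > 0)))
    stop("housekeeping values must be strictly positive")
  gm <- exp(rowMeans(log(hk)))           # per-sample geometric mean
  grand <- exp(mean(log(gm)))            # grand geometric mean
  factors <- gm / grand
  sweep(raw, 1, factors, "/")
}
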