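#' Read a delimited expression matrix
#'
#' Expects one header row of gene identifiers and a leading column of sample
#' identifiers, samples in rows and genes in columns.  The delimiter is
#' taken from the file extension (`.csv` comma, otherwise tab) unless given.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` to infer from the extension.
#' @return Numeric matrix with sample row names and gene column names.
#' @export
read_expression_matrix <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("non-numeric values in ", path,
         "; expected a samples x genes matrix with one id column")
  m
}

#' Write an expression matrix as TSV
#'
#' Full-precision (repr-faithful) formatting, so a write-then-read round
#' trip reproduces the values exactly.
#'
#' @param x Numeric matrix, samples x genes, with dimnames.
#' @param path Output file path.
#' @param sample_col Name of the leading sample-id column.
#' @export
write_expression_matrix <- function(x, path, sample_col = "sample_id") {
  df <- data.frame(format(rownames(x), justify = "none"),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(sample_col, colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Study manifest
#'
#' Declares the groups of a multi-group (for example per-timepoint) study
#' and the analysis configuration.
#'
#' @param groups Named list, one entry per group in analysis order.  Each
#'   entry is a file path (read with [read_expression_matrix()]), a numeric
#'   matrix (samples x genes), or an [expression_group()].
#' @param value_scale `"log"` if values are already natural-log transformed,
#'   `"raw"` to apply [log_transform()] (after optional normalization).
#' @param housekeeping_gene_ids Optional housekeeping genes for
#'   [geometric_mean_normalize()]; only used with `value_scale = "raw"`.
#' @param threshold BIC-difference threshold for verdicts (default 6).
#' @param d_min Lower bound for the quartic coefficient (default `1e-3`).
#' @param reference_gene_for_orientation Optional gene id whose loading is
#'   forced positive, fixing the axis orientation across groups.
#' @return An object of class `"study_manifest"`.
#' @export
study_manifest <- function(groups, value_scale = c("log", "raw"),
                           housekeeping_gene_ids = NULL, threshold = 6,
                           d_min = 1e-3,
                           reference_gene_for_orientation = NULL) {
  value_scale <- match.arg(value_scale)
  if (is.null(names(groups)) || anyDuplicated(names(groups)))
    stop("groups must be a named list with unique group labels")
  structure(
    list(groups = groups, value_scale = value_scale,
         housekeeping_gene_ids = housekeeping_gene_ids,
         threshold = threshold, d_min = d_min,
         reference_gene_for_orientation = reference_gene_for_orientation),
    class = "study_manifest")
}

#' @noRd
load_group <- function(spec, label, manifest) {
  if (inherits(spec, "expression_group")) {
    if (manifest$value_scale == "raw")
      stop("expression_group inputs must already be log-space")
    return(spec)
  }
  m <- if (is.character(spec)) read_expression_matrix(spec) else as.matrix(spec)
  if (manifest$value_scale == "raw") {
    if (!is.null(manifest$housekeeping_gene_ids))
      m <- geometric_mean_normalize(m, manifest$housekeeping_gene_ids)
    m <- log_transform(m)
  }
  expression_group(m, group_label = label)
}

#' Run a grouped study
#'
#' The per-timepoint workflow: for every group, load, optionally normalize
#' and log-transform, find the dominant variance axis, project, fit the
#' Gaussian, Landau and mixture models, compute BIC differences and
#' verdicts, and build the per-gene relevance table.  Also assembles an
#' across-group summary (standard deviation along PC1, BIC differences,
#' verdicts) -- the trajectory used to locate when a transition becomes
#' statistically visible.
#'
#' @param manifest A [study_manifest()].
#' @param out_dir Optional directory; when given, per-group JSON + TSV
#'   reports and the summary TSV are written there (deterministic content,
#'   no timestamps).
#' @return An object of class `"study_result"`: list with `groups` (named
#'   list of per-group results: `analysis`, `relevance`) and `summary`
#'   (data.frame).
#' @export
run_study <- function(manifest, out_dir = NULL) {
  stopifnot(inherits(manifest, "study_manifest"))
  labels <- names(manifest$groups)
  groups <- Map(function(spec, label) load_group(spec, label, manifest),
                manifest$groups, labels)
  gene_sets <- lapply(groups, `[[`, "gene_ids")
  ref <- gene_sets[[1]]
  for (k in seq_along(gene_sets)[-1]) {
    if (!identical(sort(gene_sets[[k]]), sort(ref))) {
      diff <- union(setdiff(gene_sets[[k]], ref), setdiff(ref, gene_sets[[k]]))
      stop("inconsistent gene sets across groups ('", labels[1], "' vs '",
           labels[k], "'); symmetric difference: ",
           paste(diff, collapse = ", "))
    }
  }
  results <- lapply(groups, function(g) {
    an <- analyze_group(g, threshold = manifest$threshold,
                        d_min = manifest$d_min,
                        orient_gene = manifest$reference_gene_for_orientation)
    rel <- relevance_table(g, an$axis)
    list(analysis = an, relevance = rel)
  })
  names(results) <- labels
  summary <- do.call(rbind, lapply(results, function(r) {
    a <- r$analysis
    data.frame(
      group = a$group_label, n_samples = a$n_samples,
      lambda1 = a$axis$lambda1, sd_pc1 = sqrt(a$axis$lambda1),
      c = a$landau$c, d = a$landau$d, mu_nu = a$landau$mu_nu,
      delta_bic_landau = a$comparison$delta_bic_landau,
      delta_bic_mixture = a$comparison$delta_bic_mixture,
      verdict_landau = a$comparison$verdict_landau,
      verdict_mixture = a$comparison$verdict_mixture,
      warnings = paste(a$warnings, collapse = "; "),
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  out <- structure(list(groups = results, summary = summary),
                   class = "study_result")
  if (!is.null(out_dir)) write_study_reports(out, out_dir)
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result>\n")
  print(x$summary[, c("group", "n_samples", "sd_pc1", "c", "d",
                      "delta_bic_landau", "delta_bic_mixture",
                      "verdict_landau")], digits = 4)
  invisible(x)
}

#' Write study reports to disk
#'
#' Per group: a JSON report (fit parameters, BIC differences, verdicts,
#' per-sample projected coordinates, warnings, and the log-scale
#' convention), a projection TSV, and a relevance TSV; plus one summary TSV
#' across groups.  Output is deterministic: identical inputs produce
#' byte-identical files.
#'
#' @param result A [run_study()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study_reports <- function(result, out_dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (label in names(result$groups)) {
    r <- result$groups[[label]]
    a <- r$analysis
    safe <- gsub("[^A-Za-z0-9._-]", "_", label)
    report <- list(
      group = a$group_label,
      n_samples = a$n_samples,
      value_convention = "natural-log expression; c and d are only comparable across runs under this convention",
      lambda1 = a$axis$lambda1,
      sd_pc1 = sqrt(a$axis$lambda1),
      J_nu = a$axis$J_nu,
      landau = a$landau[c("c", "d", "mu_nu", "log_likelihood", "bistable")],
      gaussian = a$gauss[c("mean", "variance", "log_likelihood")],
      mixture = a$mixture[c("loc1", "loc2", "width", "weight",
                            "log_likelihood")],
      delta_bic_landau = a$comparison$delta_bic_landau,
      delta_bic_mixture = a$comparison$delta_bic_mixture,
      threshold = a$comparison$threshold,
      verdict_landau = a$comparison$verdict_landau,
      verdict_mixture = a$comparison$verdict_mixture,
      projection = as.list(a$projection),
      warnings = a$warnings)
    jsonlite::write_json(report, file.path(out_dir, paste0(safe, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    proj <- data.frame(sample_id = names(a$projection),
                       projection = unname(a$projection),
                       stringsAsFactors = FALSE)
    write.table(format(proj, digits = 17, trim = TRUE),
                file.path(out_dir, paste0(safe, "_projection.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rel <- r$relevance
    rel$s <- format(rel$s, digits = 17, trim = TRUE)
    rel$axis_corr <- format(rel$axis_corr, digits = 17, trim = TRUE)
    write.table(rel, file.path(out_dir, paste0(safe, "_relevance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  s <- result$summary
  num <- vapply(s, is.numeric, logical(1))
  s[num] <- lapply(s[num], function(v) format(v, digits = 17, trim = TRUE))
  write.table(s, file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Pooled case/control analysis per stage
#'
#' For each case group (for example, successive disease stages), pools its
#' samples with the shared control group into one expression group, runs the
#' standard single-group analysis, and records the projected coordinates
#' labelled by their ground-truth origin.  Growing evidence of bimodality
#' across stages indicates a transition separating the case profiles from
#' the controls.
#'
#' @param control Control samples: matrix or [expression_group()]
#'   (log-space).
#' @param cases Named list of case groups in stage order, same gene universe.
#' @param threshold,d_min As in [analyze_group()].
#' @return Named list, one entry per stage: list with `analysis`
#'   (a `group_analysis`) and `membership` (data.frame of sample id,
#'   ground-truth group, projected coordinate).
#' @export
pooled_case_control_run <- function(control, cases, threshold = 6,
                                    d_min = 1e-3) {
  as_mat <- function(x) if (inherits(x, "expression_group")) x$values else as.matrix(x)
  ctrl <- as_mat(control)
  if (nrow(ctrl) == 0) stop("control group is empty")
  if (is.null(names(cases))) names(cases) <- paste0("stage", seq_along(cases))
  out <- list()
  for (stage in names(cases)) {
    cs <- as_mat(cases[[stage]])
    if (nrow(cs) == 0) stop("case group '", stage, "' is empty")
    if (!identical(sort(colnames(ctrl)), sort(colnames(cs))))
      stop("case group '", stage, "' does not share the control gene universe")
    cs <- cs[, colnames(ctrl), drop = FALSE]
    pooled <- rbind(ctrl, cs)
    rownames(pooled) <- make.unique(c(rownames(ctrl), rownames(cs)), sep = "_")
    grp <- expression_group(pooled, group_label = paste0("control+", stage))
    an <- analyze_group(grp, threshold = threshold, d_min = d_min)
    membership <- data.frame(
      sample_id = names(an$projection),
      group = rep(c("control", stage), c(nrow(ctrl), nrow(cs))),
      projection = unname(an$projection),
      stringsAsFactors = FALSE)
    out[[stage]] <- list(analysis = an, membership = membership)
  }
  out
}
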