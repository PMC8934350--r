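#' Construct an expression cohort
#'
#' Bundles a nonnegative genes-by-samples expression matrix with per-sample
#' normal/tumor labels. This is the input of the geometry stage, which
#' reduces the cohort to a single coordinate along the first principal
#' component of log2 fold-change space.
#'
#' @param values Numeric matrix, genes as rows, samples as columns, all
#'   entries `>= 0`.
#' @param labels Character vector, one of `"normal"`/`"tumor"` per sample.
#' @param gene_ids,sample_ids Optional identifiers; taken from `dimnames` or
#'   autogenerated when absent.
#' @return An `expression_cohort` (list with `values`, `gene_ids`,
#'   `sample_ids`, `labels`).
#' @export
expression_cohort <- function(values, labels, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (length(labels) != ncol(values)) {
    stop("need one label per sample (", ncol(values), " samples, ",
         length(labels), " labels)")
  }
  if (!all(labels %in% c("normal", "tumor"))) {
    stop("labels must be 'normal' or 'tumor'")
  }
  if (sum(labels == "normal") < 2 || sum(labels == "tumor") < 2) {
    stop("need at least 2 normal and 2 tumor samples")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and >= 0")
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, labels = labels),
            class = "expression_cohort")
}

#' Read an expression cohort from TSV files
#'
#' The expression file has genes as rows (first column gene id, header row of
#' sample ids); the label file has two columns (`sample_id`, `class` with
#' values `normal`/`tumor`).
#'
#' @param expr_path Expression matrix TSV.
#' @param labels_path Sample label TSV.
#' @return An `expression_cohort`.
#' @export
read_expression_cohort <- function(expr_path, labels_path) {
  expr <- read.delim(expr_path, check.names = FALSE)
  genes <- as.character(expr[[1]])
  mat <- as.matrix(expr[-1])
  rownames(mat) <- genes
  lab <- read.delim(labels_path, colClasses = "character")
  if (!all(c("sample_id", "class") %in% names(lab))) {
    stop("label file must have columns 'sample_id' and 'class'")
  }
  idx <- match(colnames(mat), lab$sample_id)
  if (anyNA(idx)) {
    stop("label missing for sample(s): ",
         paste(colnames(mat)[is.na(idx)], collapse = ", "))
  }
  expression_cohort(mat, labels = lab$class[idx])
}

#' Per-gene reference expression levels
#'
#' The reference level of a gene is the geometric mean of its expression
#' over the normal samples (after adding `pseudocount`); the log2 fold
#' changes taken against it are therefore exactly zero-mean over normals.
#' With `pseudocount = 0`, genes with any zero among the normal samples have
#' no usable reference and are returned as `NA` with a warning — downstream
#' steps exclude them.
#'
#' @param cohort An `expression_cohort`.
#' @param pseudocount Nonnegative scalar added to every value before the
#'   geometric mean; default 0.
#' @return Named numeric vector, one reference level per gene (`NA` =
#'   excluded).
#' @export
reference_levels <- function(cohort, pseudocount = 0) {
  stopifnot(inherits(cohort, "expression_cohort"), pseudocount >= 0)
  normals <- cohort$values[, cohort$labels == "normal", drop = FALSE] +
    pseudocount
  e_ref <- rep(NA_real_, nrow(normals))
  names(e_ref) <- cohort$gene_ids
  ok <- rowSums(normals == 0) == 0
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) with zero normal expression at pseudocount ",
            pseudocount, " excluded from the reference")
  }
  e_ref[ok] <- exp(rowMeans(log(normals[ok, , drop = FALSE])))
  e_ref
}

#' Log2 fold-change coordinates
#'
#' Maps expression to GE-space coordinates `ehat = log2((e + pseudocount) /
#' e_ref)`. Genes with `NA` reference (see [reference_levels()]) are dropped.
#' By construction the mean of `ehat` over normal samples is zero for every
#' retained gene, so the origin of GE space is the center of the normal
#' cloud.
#'
#' @param cohort An `expression_cohort`.
#' @param e_ref Reference levels from [reference_levels()].
#' @param pseudocount The same pseudocount used for `e_ref`.
#' @return Numeric matrix of log2 fold changes, retained genes x samples.
#' @export
log_fold_coordinates <- function(cohort, e_ref, pseudocount = 0) {
  stopifnot(inherits(cohort, "expression_cohort"))
  keep <- !is.na(e_ref)
  if (!any(keep)) stop("no genes with a valid reference level")
  ehat <- log2((cohort$values[keep, , drop = FALSE] + pseudocount) /
                 e_ref[keep])
  finite <- rowSums(!is.finite(ehat)) == 0
  if (any(!finite)) {
    # zeros outside the normal set still produce -Inf at pseudocount 0
    warning(sum(!finite), " gene(s) with non-finite log fold change ",
            "excluded (zero expression at pseudocount ", pseudocount, ")")
    ehat <- ehat[finite, , drop = FALSE]
  }
  if (nrow(ehat) == 0) stop("no genes with finite log fold changes")
  ehat
}

#' First principal axis of a log fold-change matrix
#'
#' Diagonalizes the sample covariance of `ehat` (samples as observations,
#' centered on the grand mean) and returns the leading unit eigenvector
#' `v1` — the "cancer axis" along which normal and tumor clouds separate —
#' together with the fraction of total variance it carries.
#'
#' Sign convention: if `labels` are supplied, `v1` is oriented so the mean
#' tumor projection is positive; otherwise the component of largest absolute
#' value is made positive (deterministic). Eigenvalue ties are broken the
#' same deterministic way.
#'
#' @param ehat Matrix from [log_fold_coordinates()], genes x samples.
#' @param labels Optional normal/tumor labels used to orient `v1`.
#' @return A list with `v1` (named unit vector over genes),
#'   `pc1_variance_fraction`, and `d_scale = max(abs(v1))`.
#' @export
principal_axis <- function(ehat, labels = NULL) {
  if (ncol(ehat) < 2) stop("need at least 2 samples")
  if (any(!is.finite(ehat))) stop("ehat must be finite")
  if (all(apply(ehat, 1, function(r) diff(range(r)) == 0))) {
    stop("no variance: all samples identical")
  }
  pc <- prcomp(t(ehat), center = TRUE, scale. = FALSE)
  v1 <- pc$rotation[, 1]
  ev <- pc$sdev^2
  # orient deterministically, then by tumor mean if labels are available
  peak <- which.max(abs(v1))
  if (v1[peak] < 0) v1 <- -v1
  if (!is.null(labels)) {
    x1 <- drop(crossprod(ehat, v1))
    if (mean(x1[labels == "tumor"]) < 0) v1 <- -v1
  }
  list(v1 = v1,
       pc1_variance_fraction = ev[1] / sum(ev),
       d_scale = max(abs(v1)))
}

#' Project a cohort onto PC1 and summarize its geometry
#'
#' Projections are uncentered dot products `x1 = ehat . v1`, so the origin
#' stays at the normal-cloud center. The normal radius `rn` is the r.m.s. of
#' normal projections about the origin; the tumor center `xbar1` is the mean
#' tumor projection; the tumor radius `rt` is the r.m.s. of tumor
#' projections about `xbar1`. `v1` is flipped if needed so `xbar1 > 0`.
#'
#' @param ehat Matrix from [log_fold_coordinates()].
#' @param labels Normal/tumor label per sample.
#' @param v1 Unit PC1 vector (e.g. from [principal_axis()]).
#' @param pc1_variance_fraction Optional, carried through to the result.
#' @return A `ge_geometry`: list with `v1`, `xbar1`, `rn`, `rt`, `d_scale`,
#'   `pc1_variance_fraction`, `x1` (per-sample projections), `labels`.
#' @export
project_and_summarize <- function(ehat, labels, v1,
                                  pc1_variance_fraction = NA_real_) {
  if (length(labels) != ncol(ehat)) {
    stop("label missing: need one label per sample")
  }
  if (abs(sqrt(sum(v1^2)) - 1) > 1e-9) stop("v1 must have unit norm")
  x1 <- drop(crossprod(ehat, v1))
  tumor <- labels == "tumor"
  if (mean(x1[tumor]) < 0) {
    v1 <- -v1
    x1 <- -x1
  }
  xbar1 <- mean(x1[tumor])
  structure(list(
    v1 = v1,
    xbar1 = xbar1,
    rn = sqrt(mean(x1[labels == "normal"]^2)),
    rt = sqrt(mean((x1[tumor] - xbar1)^2)),
    d_scale = max(abs(v1)),
    pc1_variance_fraction = pc1_variance_fraction,
    x1 = x1,
    labels = labels
  ), class = "ge_geometry")
}

#' One-call cohort geometry
#'
#' Runs the full geometry stage: reference levels, log2 fold-change
#' coordinates, PCA, projection and summary. The result holds the model
#' parameters the risk formulas consume: `xbar1`, `rn`, `rt` (hence the
#' minimal walk length, [minimal_walk_length()]) and the fluctuation scale
#' `d_scale = max |v1_i|`.
#'
#' @inheritParams reference_levels
#' @return A `ge_geometry`; see [project_and_summarize()].
#' @examples
#' spec <- cohort_spec(n_genes = 200, n_normal = 30, n_tumor = 30,
#'                     planted_xbar1 = 100, planted_rn = 10, planted_rt = 20,
#'                     seed = 1)
#' geom <- ge_geometry(generate_cohort(spec))
#' c(geom$xbar1, geom$rn, geom$rt)
#' @export
ge_geometry <- function(cohort, pseudocount = 0) {
  e_ref <- reference_levels(cohort, pseudocount)
  ehat <- log_fold_coordinates(cohort, e_ref, pseudocount)
  ax <- principal_axis(ehat, labels = cohort$labels)
  geom <- project_and_summarize(ehat, cohort$labels, ax$v1,
                                pc1_variance_fraction = ax$pc1_variance_fraction)
  geom$e_ref <- e_ref
  geom
}

#' @export
print.ge_geometry <- function(x, ...) {
  cat("<ge_geometry>\n",
      sprintf("  xbar1 = %.4g, rn = %.4g, rt = %.4g\n", x$xbar1, x$rn, x$rt),
      sprintf("  d_scale = %.4g, PC1 variance fraction = %.3f\n",
              x$d_scale, x$pc1_variance_fraction),
      sprintf("  minimal walk length R = %.4g\n",
              x$xbar1 - x$rn - x$rt), sep = "")
  invisible(x)
}
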