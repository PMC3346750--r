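#' Bundle gene and TF expression into a modelling-ready dataset
#'
#' An `expression_dataset` holds the two observed blocks of the two-layer
#' regulatory model: `X`, an N-samples-by-p-genes matrix of (log-)expression
#' for the regulated genes, and `R`, an N-by-d matrix for the known/putative
#' transcription factors. Gene and TF identifier sets must be disjoint so the
#' induced regulatory graph is bipartite and acyclic.
#'
#' @param X Numeric matrix or data frame, samples in rows, regulated genes in
#'   columns. Column names are used as gene identifiers.
#' @param R Numeric matrix or data frame of TF expression with the same rows
#'   as `X`; may have zero columns (pure latent-factor model). Column names
#'   are the TF identifiers.
#' @param sample_ids Optional character vector of sample identifiers;
#'   defaults to the row names of `X` or `S1..SN`.
#'
#' @return An object of class `expression_dataset` with elements `X`, `R`,
#'   `gene_ids`, `tf_ids` and `sample_ids`.
#' @export
#' @examples
#' sim <- simulate_grn_data(p = 6, d = 2, q = 1, N = 10, seed = 1)
#' ds <- sim$data
#' dim(ds$X)
expression_dataset <- function(X, R = NULL, sample_ids = NULL) {
  X <- as_expr_matrix(X, "X", "G")
  N <- nrow(X)
  if (is.null(R)) {
    R <- matrix(0, N, 0)
  } else {
    R <- as_expr_matrix(R, "R", "TF")
  }
  if (nrow(R) != N) {
    stop("X has ", N, " samples (rows) but R has ", nrow(R), call. = FALSE)
  }
  if (N < 2) stop("need at least 2 samples", call. = FALSE)
  if (ncol(X) < 1) stop("need at least 1 gene column in X", call. = FALSE)
  gene_ids <- colnames(X)
  tf_ids <- colnames(R)
  shared <- intersect(gene_ids, tf_ids)
  if (length(shared) > 0) {
    stop("gene and TF identifiers must be disjoint; shared: ",
         paste(utils::head(shared, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(tf_ids)) stop("duplicate TF identifiers", call. = FALSE)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(N))
  }
  rownames(X) <- sample_ids
  if (ncol(R) > 0) rownames(R) <- sample_ids
  structure(
    list(X = X, R = R, gene_ids = gene_ids, tf_ids = tf_ids,
         sample_ids = sample_ids),
    class = "expression_dataset"
  )
}

as_expr_matrix <- function(m, what, prefix) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix or data frame", call. = FALSE)
  }
  if (is.null(colnames(m)) && ncol(m) > 0) {
    colnames(m) <- sprintf("%s%04d", prefix, seq_len(ncol(m)))
  }
  m
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("<expression_dataset> ", length(x$sample_ids), " samples x ",
      length(x$gene_ids), " genes, ", length(x$tf_ids), " TFs\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) {
  c(length(x$sample_ids), length(x$gene_ids) + length(x$tf_ids))
}

# Subset samples by integer index; used by the cross-validation fold machinery.
subset_samples <- function(data, idx) {
  expression_dataset(
    X = data$X[idx, , drop = FALSE],
    R = if (ncol(data$R) > 0) data$R[idx, , drop = FALSE] else NULL,
    sample_ids = data$sample_ids[idx]
  )
}

check_finite_dataset <- function(data) {
  if (!all(is.finite(data$X)) || (ncol(data$R) > 0 && !all(is.finite(data$R)))) {
    stop("expression values must all be finite; impute missing values first ",
         "(see median_impute())", call. = FALSE)
  }
  invisible(data)
}

#' Split a combined expression matrix into TF and gene blocks
#'
#' Given a samples-by-features matrix covering both regulated genes and
#' transcription factors, partitions the columns by a TF identifier list:
#' listed features become the TF block `R`, everything else the gene block
#' `X`. TFs in the list that are absent from the matrix are dropped with a
#' warning, matching the common situation where a curated TF list covers
#' more genes than a given array measures.
#'
#' @param mat Numeric samples-by-features matrix with feature column names.
#' @param tf_ids Character vector of TF identifiers.
#' @return An [expression_dataset()].
#' @export
split_tf_genes <- function(mat, tf_ids) {
  mat <- as_expr_matrix(mat, "mat", "G")
  tf_ids <- unique(tf_ids)
  present <- tf_ids[tf_ids %in% colnames(mat)]
  absent <- setdiff(tf_ids, present)
  if (length(absent) > 0) {
    warning(length(absent), " TF identifier(s) absent from the matrix (e.g. ",
            paste(utils::head(absent, 3), collapse = ", "), ")", call. = FALSE)
  }
  if (length(present) == ncol(mat)) {
    stop("every feature is listed as a TF; no regulated genes remain",
         call. = FALSE)
  }
  gene_cols <- setdiff(colnames(mat), present)
  expression_dataset(
    X = mat[, gene_cols, drop = FALSE],
    R = if (length(present) > 0) mat[, present, drop = FALSE] else NULL,
    sample_ids = rownames(mat)
  )
}

#' Impute missing expression values with per-feature medians
#'
#' Replaces each missing entry by the median of the observed values in the
#' same feature (column), the imputation scheme commonly applied to
#' microarray expression compendia before model fitting.
#'
#' @param mat Numeric matrix, samples in rows, features in columns; missing
#'   values as `NA`.
#' @return The completed matrix.
#' @export
median_impute <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  stopifnot(is.matrix(mat))
  miss <- is.na(mat)
  if (!any(miss)) return(mat)
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    bad <- colnames(mat)[all_missing]
    if (is.null(bad)) bad <- which(all_missing)
    stop("feature(s) with no observed values: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (j in which(colSums(miss) > 0)) {
    mat[miss[, j], j] <- stats::median(mat[, j], na.rm = TRUE)
  }
  mat
}
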