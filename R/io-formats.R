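#' Read an expression matrix from TSV or GCT
#'
#' Both dialects are normalized to the package's internal orientation:
#' samples in rows, features (genes/TFs) in columns.
#'
#' The TSV dialect is a tab-delimited table whose header row holds feature
#' identifiers and whose first column holds sample identifiers. GCT 1.2
#' (Broad/GSEA) stores features in rows and samples in columns with a
#' `#1.2` version line and a dimension line; it is transposed on read and
#' the dimension line is validated. Missing values may be encoded as empty
#' cells or `NA` (case-insensitive); they are preserved as `NA` for
#' [median_impute()].
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"gct"`.
#' @return Numeric matrix, samples x features, with dimnames.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect, tsv = read_expr_tsv(path), gct = read_expr_gct(path))
}

split_fields <- function(line) {
  strsplit(sub("\r$", "", line), "\t", fixed = TRUE)[[1]]
}

parse_numeric_cells <- function(cells, path, line_no) {
  cells[cells == "" | toupper(cells) == "NA"] <- NA_character_
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !is.na(cells))
  if (length(bad) > 0) {
    stop("non-numeric cell '", cells[bad[1]], "' in ", path, " line ",
         line_no, call. = FALSE)
  }
  vals
}

read_expr_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(sub("\r$", "", lines))]
  if (length(lines) < 2) stop("expected a header plus at least one data row in ", path, call. = FALSE)
  header <- split_fields(lines[1])
  features <- header[-1]
  if (anyDuplicated(features)) {
    stop("duplicate feature identifiers in ", path, call. = FALSE)
  }
  n_feat <- length(features)
  rows <- lapply(seq.int(2, length(lines)), function(i) {
    cells <- split_fields(lines[i])
    if (length(cells) != n_feat + 1) {
      stop("ragged row: line ", i, " of ", path, " has ", length(cells),
           " fields, expected ", n_feat + 1, call. = FALSE)
    }
    cells
  })
  sample_ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers in ", path, call. = FALSE)
  mat <- do.call(rbind, lapply(seq_along(rows), function(i) {
    parse_numeric_cells(rows[[i]][-1], path, i + 1)
  }))
  dimnames(mat) <- list(sample_ids, features)
  mat
}

read_expr_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4 || sub("\r$", "", lines[1]) != "#1.2") {
    stop("not a GCT 1.2 file (missing '#1.2' version line): ", path, call. = FALSE)
  }
  dims <- suppressWarnings(as.integer(split_fields(lines[2])))
  if (length(dims) < 2 || anyNA(dims[1:2])) {
    stop("malformed GCT dimension line in ", path, call. = FALSE)
  }
  n_feat <- dims[1]; n_samp <- dims[2]
  header <- split_fields(lines[3])
  sample_ids <- header[-(1:2)]
  if (length(sample_ids) != n_samp) {
    stop("GCT dimension line claims ", n_samp, " samples but header has ",
         length(sample_ids), call. = FALSE)
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(sub("\r$", "", body))]
  if (length(body) != n_feat) {
    stop("GCT dimension line claims ", n_feat, " features but body has ",
         length(body), " rows", call. = FALSE)
  }
  features <- character(n_feat)
  mat <- matrix(NA_real_, n_feat, n_samp)
  for (i in seq_len(n_feat)) {
    cells <- split_fields(body[i])
    if (length(cells) != n_samp + 2) {
      stop("ragged row: line ", i + 3, " of ", path, call. = FALSE)
    }
    features[i] <- cells[1]
    mat[i, ] <- parse_numeric_cells(cells[-(1:2)], path, i + 3)
  }
  if (anyDuplicated(features)) stop("duplicate feature identifiers in ", path, call. = FALSE)
  dimnames(mat) <- list(features, sample_ids)
  t(mat)
}

#' Write an expression matrix as TSV
#'
#' Inverse of the `"tsv"` dialect of [read_expression_matrix()]: header row
#' of feature identifiers, first column of sample identifiers.
#'
#' @param mat Samples-by-features numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i],
            formatC(mat[i, ], format = "g", digits = 17)), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a plain-text transcription-factor list
#'
#' One identifier per line; blank lines and `#` comment lines are skipped.
#'
#' @param path File path.
#' @return Character vector of TF identifiers.
#' @export
read_tf_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(sub("\r$", "", readLines(path)))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read a GMT gene-set collection
#'
#' The GSEA GMT dialect: tab-delimited, one set per line, fields are
#' set name, description, then member gene identifiers. Trailing tabs and
#' CRLF line endings are tolerated.
#'
#' @param path File path.
#' @return Named list of character vectors (members per set).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line (need name + description): ", l, call. = FALSE)
    members <- f[-(1:2)]
    unique(members[nzchar(members)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in ", path, call. = FALSE)
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
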