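#' Random NCA connectivity mask
#'
#' Network component analysis requires each column of the p-by-L
#' connectivity matrix to contain at least L - 1 zeros for the
#' decomposition to be identifiable. When no network topology is known,
#' a random mask is used: in each column exactly L - 1 entries, chosen
#' uniformly at random, are fixed to zero.
#'
#' @param p Number of genes (rows); must exceed L - 1.
#' @param L Number of regulators (columns).
#' @param seed Integer seed.
#' @return Logical p-by-L matrix, `TRUE` where the entry may be nonzero.
#' @export
make_random_connectivity <- function(p, L, seed = 1) {
  stopifnot(L >= 1)
  if (p <= L - 1) stop("need p > L - 1 rows to place L - 1 zeros per column",
                       call. = FALSE)
  with_seed(substream_seed(seed, "nca-mask"), {
    mask <- matrix(TRUE, p, L)
    if (L > 1) {
      for (j in seq_len(L)) mask[sample.int(p, L - 1), j] <- FALSE
    }
    mask
  })
}

#' Check the NCA identifiability criteria
#'
#' Diagnoses whether a connectivity pattern supports a unique (up to
#' scaling) decomposition E = A P: (1) A has full column rank; (2) removing
#' any regulator together with the genes it connects to leaves a
#' full-column-rank submatrix; (3) the sample count is at least L, a
#' necessary condition for P to have full row rank. Ranks are evaluated on
#' a random realization of the masked matrix.
#'
#' @param mask Logical p-by-L connectivity mask.
#' @param N Number of samples.
#' @param seed Seed for the random realization.
#' @return List with logicals `full_column_rank`, `reduced_rank_ok`,
#'   `samples_ok`, and `all_pass`.
#' @export
check_nca_criteria <- function(mask, N, seed = 1) {
  p <- nrow(mask); L <- ncol(mask)
  A <- with_seed(substream_seed(seed, "nca-check"), {
    matrix(stats::rnorm(p * L), p, L) * mask
  })
  c1 <- qr(A)$rank == L
  c2 <- all(vapply(seq_len(L), function(j) {
    keep_rows <- !mask[, j]             # genes NOT connected to regulator j
    sub <- A[keep_rows, -j, drop = FALSE]
    if (L == 1) return(TRUE)
    qr(sub)$rank == L - 1
  }, logical(1)))
  c3 <- N >= L
  list(full_column_rank = c1, reduced_rank_ok = c2, samples_ok = c3,
       all_pass = c1 && c2 && c3)
}

#' Network component analysis by alternating least squares
#'
#' Decomposes a genes-by-samples expression matrix E into A P, where the
#' p-by-L connectivity matrix A has a frozen zero pattern (the network
#' structure, which NCA never alters) and P holds the L regulator activity
#' profiles. Fitting alternates full least squares for P with per-row
#' masked least squares for A until the relative change in reconstruction
#' error drops below `tol`. After convergence columns of A are rescaled to
#' unit norm with compensating row scaling of P, fixing the scaling
#' ambiguity.
#'
#' @param E Numeric p-by-N matrix (genes by samples).
#' @param mask Logical p-by-L connectivity mask (`TRUE` = free entry).
#' @param max_iter Maximum ALS sweeps.
#' @param tol Relative reconstruction-error change declaring convergence.
#' @param seed Seed for the random initialization of A's free entries.
#' @return Object of class `nca_model` with `A`, `P`, `mask`,
#'   `reconstruction_error_trace` (nonincreasing), `converged`.
#' @export
nca_decompose <- function(E, mask, max_iter = 200, tol = 1e-8, seed = 1) {
  stopifnot(is.matrix(E), is.matrix(mask), nrow(E) == nrow(mask))
  p <- nrow(E); N <- ncol(E); L <- ncol(mask)
  crit <- check_nca_criteria(mask, N, seed = seed)
  if (!crit$all_pass) {
    warning("connectivity mask fails the NCA identifiability criteria; ",
            "the decomposition may not be unique", call. = FALSE)
  }
  A <- with_seed(substream_seed(seed, "nca-init"), {
    matrix(stats::rnorm(p * L), p, L) * mask
  })
  err <- function(A, P) sum((E - A %*% P)^2)
  trace <- numeric(0)
  P <- NULL
  prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # fix A, solve P by full least squares
    AtA <- crossprod(A)
    P <- tryCatch(solve(AtA, crossprod(A, E)), error = function(e) {
      warning("singular system for P; ridge jitter added", call. = FALSE)
      solve(AtA + diag(1e-10, L), crossprod(A, E))
    })
    # fix P, solve each gene's row of A on its unmasked support
    PPt <- tcrossprod(P)
    PEt <- P %*% t(E)                    # L x p
    for (i in seq_len(p)) {
      s <- which(mask[i, ])
      if (length(s) == 0) next
      G <- PPt[s, s, drop = FALSE]
      b <- PEt[s, i]
      a <- tryCatch(solve(G, b), error = function(e) {
        warning("singular restricted system for A row ", i,
                "; ridge jitter added", call. = FALSE)
        solve(G + diag(1e-10, length(s)), b)
      })
      A[i, ] <- 0
      A[i, s] <- a
    }
    e <- err(A, P)
    trace <- c(trace, e)
    if (is.finite(prev) && abs(prev - e) <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- e
  }
  # resolve scaling ambiguity: unit-norm columns of A
  nrm <- sqrt(colSums(A^2))
  nz <- nrm > 0
  A[, nz] <- sweep(A[, nz, drop = FALSE], 2, nrm[nz], "/")
  P[nz, ] <- sweep(P[nz, , drop = FALSE], 1, nrm[nz], "*")
  structure(list(A = A, P = P, mask = mask,
                 reconstruction_error_trace = trace, converged = converged,
                 criteria = crit),
            class = "nca_model")
}

#' @export
print.nca_model <- function(x, ...) {
  cat("<nca_model>", nrow(x$A), "genes x", ncol(x$A), "regulators;",
      length(x$reconstruction_error_trace), "ALS sweeps; final error",
      format(utils::tail(x$reconstruction_error_trace, 1)), "\n")
  invisible(x)
}

#' Prune an NCA model to a target edge count
#'
#' Keeps the `target_edge_count` entries of A with the largest absolute
#' value and zeroes the rest (ties broken by row-then-column order), so
#' the NCA network can be compared against a sparse model with the same
#' edge budget.
#'
#' @param model An `nca_model`.
#' @param target_edge_count Number of edges to keep (0 <= target <=
#'   current nonzero count).
#' @return The pruned `nca_model`.
#' @export
prune_edges <- function(model, target_edge_count) {
  stopifnot(inherits(model, "nca_model"))
  if (target_edge_count < 0) stop("target edge count must be >= 0", call. = FALSE)
  A <- model$A
  nz <- which(A != 0)
  if (target_edge_count > length(nz)) {
    stop("target edge count ", target_edge_count, " exceeds current ",
         length(nz), call. = FALSE)
  }
  if (target_edge_count < length(nz)) {
    # order by |value| descending, ties by linear (row within column... )
    # index; column-major linear index equals (col-1)*p + row, so to break
    # ties by (row, column) order convert to row-major rank
    p <- nrow(A); Lc <- ncol(A)
    rows <- ((nz - 1) %% p) + 1
    cols <- ((nz - 1) %/% p) + 1
    ord <- order(-abs(A[nz]), rows, cols)
    drop_idx <- nz[ord][-seq_len(target_edge_count)]
    A[drop_idx] <- 0
  }
  model$A <- A
  model
}

#' Gene sets defined by an NCA model
#'
#' One set per regulator: the genes with a nonzero entry in the
#' corresponding column of A (after any pruning).
#'
#' @param model An `nca_model`.
#' @param gene_ids Gene identifiers, one per row of A.
#' @return Tibble with `source`, `type`, `size`, `members`, matching the
#'   layout of [extract_gene_sets()].
#' @export
nca_gene_sets <- function(model, gene_ids) {
  stopifnot(inherits(model, "nca_model"), length(gene_ids) == nrow(model$A))
  L <- ncol(model$A)
  tibble::tibble(
    source = sprintf("NCA%02d", seq_len(L)),
    type = "nca",
    size = colSums(model$A != 0),
    members = lapply(seq_len(L), function(j) gene_ids[model$A[, j] != 0]))
}
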