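# Derive an independent substream seed from a base seed and a label, so each
# component (restarts, folds, enrichment draws) is reproducible regardless of
# the order in which it is evaluated. Kept below 2^31 - 1.
substream_seed <- function(seed, label, index = 0L) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index * 31) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sparse_signs_matrix <- function(nrow, ncol, density, effect_scale) {
  m <- matrix(0, nrow, ncol)
  n_nonzero <- round(density * nrow * ncol)
  if (n_nonzero > 0) {
    pos <- sample.int(nrow * ncol, n_nonzero)
    m[pos] <- sample(c(-1, 1), n_nonzero, replace = TRUE) * effect_scale
  }
  m
}

#' Simulate expression data from the two-layer regulatory model
#'
#' Draws a dataset from the model's own generative process: TF expression
#' `R` and latent factors `Z` are i.i.d. standard normal (the upper-layer
#' nodes are mutually independent), the weight matrices `W` and `Lambda`
#' are sparse with nonzero positions drawn uniformly and magnitudes fixed
#' at `± effect_scale` (signs uniform, so support recovery is unambiguous),
#' and `X = R W' + Z Lambda' + 1 mu' + noise` with isotropic Gaussian noise
#' of standard deviation `sigma`. Gene and TF identifiers are synthesized
#' as zero-padded strings ("G0001", "TF001").
#'
#' @param p Number of regulated genes.
#' @param d Number of transcription factors (may be 0).
#' @param q Number of hidden factors (may be 0).
#' @param N Number of samples.
#' @param w_density,lambda_density Fraction of nonzero entries in `W` and
#'   `Lambda`, in \[0, 1\].
#' @param effect_scale Magnitude of nonzero weights.
#' @param sigma Noise standard deviation (>= 0).
#' @param mu Optional length-p intercept; defaults to i.i.d. N(0, 1).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with `data` (an [expression_dataset()]) and `truth`, a list
#'   holding the true `W`, `Lambda`, `mu`, `sigma2`, the latent matrix `Z`,
#'   and logical support masks `W_support`, `Lambda_support`.
#' @export
#' @examples
#' sim <- simulate_grn_data(p = 20, d = 3, q = 2, N = 50, seed = 7)
#' sim$data
simulate_grn_data <- function(p, d, q, N, w_density = 0.05,
                              lambda_density = 0.2, effect_scale = 1,
                              sigma = 0.5, mu = NULL, seed = 1) {
  stopifnot(p >= 1, d >= 0, q >= 0, N >= 2)
  if (w_density < 0 || w_density > 1 || lambda_density < 0 || lambda_density > 1) {
    stop("densities must lie in [0, 1]", call. = FALSE)
  }
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  with_seed(substream_seed(seed, "simulate"), {
    W <- sparse_signs_matrix(p, d, w_density, effect_scale)
    Lambda <- sparse_signs_matrix(p, q, lambda_density, effect_scale)
    if (is.null(mu)) mu <- stats::rnorm(p)
    stopifnot(length(mu) == p)
    R <- matrix(stats::rnorm(N * d), N, d)
    Z <- matrix(stats::rnorm(N * q), N, q)
    E <- matrix(stats::rnorm(N * p, sd = sigma), N, p)
    X <- E + matrix(mu, N, p, byrow = TRUE)
    if (d > 0) X <- X + tcrossprod(R, W)
    if (q > 0) X <- X + tcrossprod(Z, Lambda)
    gene_ids <- sprintf("G%04d", seq_len(p))
    tf_ids <- sprintf("TF%03d", seq_len(d))
    colnames(X) <- gene_ids
    if (d > 0) colnames(R) <- tf_ids
    data <- expression_dataset(X, if (d > 0) R else NULL,
                               sample_ids = sprintf("S%04d", seq_len(N)))
    truth <- list(W = W, Lambda = Lambda, mu = mu, sigma2 = sigma^2, Z = Z,
                  W_support = W != 0, Lambda_support = Lambda != 0)
    list(data = data, truth = truth)
  })
}

#' Build a gene-set category collection with planted signal
#'
#' Creates a desk-scale analogue of a GO-style collection for testing
#' enrichment: one "planted" category per hidden factor, equal to a seeded
#' 80% subsample of that factor's true support, plus `n_noise_categories`
#' categories of genes drawn uniformly at random. The universe is the full
#' gene identifier list.
#'
#' @param gene_ids Character vector of all gene identifiers.
#' @param truth The `truth` component of [simulate_grn_data()].
#' @param n_noise_categories Number of random categories to add.
#' @param noise_size_range Integer range for random-category sizes.
#' @param seed Integer seed.
#' @return List with `categories` (named list of member vectors) and
#'   `universe` (character vector).
#' @export
simulate_category_collection <- function(gene_ids, truth,
                                         n_noise_categories = 20,
                                         noise_size_range = c(5, 50),
                                         seed = 1) {
  q <- ncol(truth$Lambda)
  with_seed(substream_seed(seed, "categories"), {
    categories <- list()
    for (k in seq_len(q)) {
      support <- gene_ids[truth$Lambda_support[, k]]
      keep <- max(1, round(0.8 * length(support)))
      categories[[sprintf("PLANTED_H%02d", k)]] <-
        sort(sample(support, keep))
    }
    hi <- min(noise_size_range[2], length(gene_ids))
    lo <- min(noise_size_range[1], hi)
    for (j in seq_len(n_noise_categories)) {
      sz <- sample(seq.int(lo, hi), 1)
      categories[[sprintf("NOISE_%03d", j)]] <- sort(sample(gene_ids, sz))
    }
    list(categories = categories, universe = gene_ids)
  })
}

#' Write a simulated dataset to the pipeline's file formats
#'
#' Emits the same tab-delimited expression matrix, TF list, GMT collection
#' and truth archive that the command-line pipeline consumes, enabling
#' end-to-end tests without any downloads.
#'
#' @param sim Result of [simulate_grn_data()].
#' @param dir Output directory (created if needed).
#' @param collection Optional result of [simulate_category_collection()].
#' @return Named character vector of file paths, invisibly.
#' @export
write_simulated_files <- function(sim, dir, collection = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  full <- cbind(sim$data$X, sim$data$R)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    tf_list = file.path(dir, "tf_list.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_expression_tsv(full, paths[["expression"]])
  writeLines(c("# simulated TF identifiers", sim$data$tf_ids), paths[["tf_list"]])
  truth <- sim$truth
  jsonlite::write_json(
    list(version = 1L, W = truth$W, Lambda = truth$Lambda, mu = truth$mu,
         sigma2 = truth$sigma2),
    paths[["truth"]], digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  if (!is.null(collection)) {
    paths[["gmt"]] <- file.path(dir, "categories.gmt")
    write_gmt(collection$categories, paths[["gmt"]])
  }
  invisible(paths)
}
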