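#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted sparse regulatory model into an edge table
#'
#' One row per learned network edge (nonzero weight): regulators are the
#' TFs and the hidden factors (`H01`, `H02`, ...).
#'
#' @param x A `grn_fit` object.
#' @param ... Unused.
#' @return Tibble with columns `regulator`, `regulator_type` (`"tf"` or
#'   `"hidden"`), `gene`, `weight`.
#' @method tidy grn_fit
#' @export
tidy.grn_fit <- function(x, ...) {
  W <- x$params$W; Lambda <- x$params$Lambda
  rows <- list()
  if (ncol(W) > 0) {
    nz <- which(W != 0, arr.ind = TRUE)
    rows[[1]] <- tibble::tibble(
      regulator = x$tf_ids[nz[, 2]], regulator_type = "tf",
      gene = x$gene_ids[nz[, 1]], weight = W[nz])
  }
  if (ncol(Lambda) > 0) {
    nz <- which(Lambda != 0, arr.ind = TRUE)
    rows[[2]] <- tibble::tibble(
      regulator = sprintf("H%02d", nz[, 2]), regulator_type = "hidden",
      gene = x$gene_ids[nz[, 1]], weight = Lambda[nz])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(regulator = character(), regulator_type = character(),
                          gene = character(), weight = numeric())
  }
  dplyr::arrange(out, .data$regulator_type, .data$regulator, .data$gene)
}

#' One-row summary of a fitted model
#'
#' @param x A `grn_fit` object.
#' @param ... Unused.
#' @return Tibble with dimensions, penalty, edge counts, noise variance,
#'   final objective, iteration count, convergence flag, and the spread of
#'   final objectives across random restarts.
#' @method glance grn_fit
#' @export
glance.grn_fit <- function(x, ...) {
  tibble::tibble(
    n_genes = length(x$gene_ids), n_tfs = length(x$tf_ids), q = x$q,
    n_samples = x$n_samples, penalty = x$penalty,
    n_edges_tf = sum(x$params$W != 0),
    n_edges_hidden = sum(x$params$Lambda != 0),
    sigma2 = x$params$sigma2, objective = x$objective,
    n_iter = x$n_iter, converged = x$converged,
    restart_spread = diff(range(x$restart_objectives)))
}

#' Per-fold cross-validation results as a tibble
#'
#' @param x A `grn_cv` object.
#' @param ... Unused.
#' @return The per-fold tibble (`fold`, `model`, `test_loglik`, `n_test`).
#' @method tidy grn_cv
#' @export
tidy.grn_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation run
#'
#' @param x A `grn_cv` object.
#' @param ... Unused.
#' @return Tibble with the selected hyperparameters, mean test
#'   log-likelihood per model, and the pairwise Wilcoxon p-values.
#' @method glance grn_cv
#' @export
glance.grn_cv <- function(x, ...) {
  means <- tapply(x$folds$test_loglik, x$folds$model, mean)
  wp <- stats::setNames(x$wilcoxon$p_value,
                        paste0("p_", x$wilcoxon$comparison))
  tibble::as_tibble(c(
    list(n_folds = x$n_outer, selected_q = x$selected_q,
         selected_penalty = x$selected_penalty,
         mean_loglik_full = unname(means[["full"]]),
         mean_loglik_no_hidden = unname(means[["no_hidden"]]),
         mean_loglik_reference = unname(means[["reference"]])),
    as.list(wp)))
}

#' Plot per-fold out-of-sample log-likelihoods
#'
#' The model-comparison picture: one line per model across the outer
#' cross-validation folds.
#'
#' @param object A `grn_cv` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grn_cv
#' @export
autoplot.grn_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = .data$fold, y = .data$test_loglik,
                               colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = seq_len(object$n_outer)) +
    ggplot2::labs(x = "cross-validation fold",
                  y = "out-of-sample log-likelihood", colour = "model") +
    ggplot2::theme_minimal()
}

#' Plot the optimizer objective trace of a fit
#'
#' @param object A `grn_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot grn_fit
#' @export
autoplot.grn_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$trace) - 1,
                       objective = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "OWL-QN iteration", y = "penalized objective") +
    ggplot2::theme_minimal()
}

#' Plot enrichment results
#'
#' Calibrated p-value (as -log10, with exact zeros shown at the resolution
#' limit of the randomization) per gene set, coloured by FDR significance.
#'
#' @param object Tibble from [enrich_gene_sets()].
#' @param fdr_threshold Significance threshold for colouring.
#' @param B Null-draw count used (sets the floor for p = 0).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(object, fdr_threshold = 0.05, B = 1000, ...) {
  df <- dplyr::mutate(
    object,
    neg_log_p = -log10(pmax(.data$calibrated_p, 1 / (B + 1))),
    significant = .data$fdr_q < fdr_threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$source, .data$neg_log_p),
                                   y = .data$neg_log_p,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 calibrated p",
                  fill = paste0("FDR < ", fdr_threshold)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
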