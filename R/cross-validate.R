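#' Seeded cross-validation fold assignment
#'
#' Samples are shuffled with the given seed and cut into contiguous blocks;
#' remainder samples are spread one per fold, so fold sizes differ by at
#' most 1 and every sample lands in exactly one test fold.
#'
#' @param N Number of samples.
#' @param n_folds Number of folds (2 <= n_folds <= N).
#' @param seed Integer seed.
#' @return Integer vector of length `N` with fold labels in `1:n_folds`.
#' @export
make_folds <- function(N, n_folds, seed = 1) {
  stopifnot(n_folds >= 2, N >= n_folds)
  perm <- with_seed(substream_seed(seed, "folds"), sample.int(N))
  sizes <- rep(N %/% n_folds, n_folds)
  extra <- N %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  labels <- rep(seq_len(n_folds), sizes)
  out <- integer(N)
  out[perm] <- labels
  out
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided p-value for paired observations. Zero differences are dropped;
#' absolute differences are ranked with average ranks under ties. For 15 or
#' fewer nonzero differences the p-value is exact, computed by enumerating
#' all sign assignments of the ranks; above that a normal approximation
#' with continuity and tie corrections is used.
#'
#' @param a,b Equal-length numeric vectors (n >= 5), no missing values.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 5,
            !anyNA(a), !anyNA(b))
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (m <= 15) {
    # distribution of W+ over all 2^m equally likely sign assignments
    sums <- 0
    for (ri in r) sums <- as.numeric(outer(sums, c(0, ri), "+"))
    total <- length(sums)
    p_ge <- sum(sums >= w_pos - 1e-9) / total
    p_le <- sum(sums <= w_pos + 1e-9) / total
    return(min(1, 2 * min(p_ge, p_le)))
  }
  mean_w <- m * (m + 1) / 4
  ties <- table(r)
  var_w <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mean_w - sign(w_pos - mean_w) * 0.5) / sqrt(var_w)
  min(1, 2 * stats::pnorm(-abs(z)))
}

# largest penalty with a non-trivial solution: at W = 0, Lambda = 0,
# mu = gene means, sigma2 = pooled variance, the W-block gradient magnitude
# bounds the subgradient condition (the Lambda block is stationary at 0).
lambda_max_penalty <- function(data) {
  Xc <- sweep(data$X, 2, colMeans(data$X), "-")
  d <- ncol(data$R)
  if (d == 0) return(max(1, stats::sd(Xc)))
  Rc <- sweep(data$R, 2, colMeans(data$R), "-")
  s2 <- max(mean(Xc^2), 1e-12)
  max(abs(crossprod(Xc, Rc))) / s2
}

#' Default logarithmic penalty grid
#'
#' Eight points spaced logarithmically between `lambda_max / 100` and
#' `lambda_max`, where `lambda_max` is the smallest penalty at which the
#' zero-weights solution satisfies the L1 subgradient condition on the
#' training data (computed from the gradient at zero weights).
#'
#' @param data An [expression_dataset()].
#' @param n_points Grid size.
#' @return Increasing numeric vector of penalties.
#' @export
default_penalty_grid <- function(data, n_points = 8) {
  lmax <- lambda_max_penalty(data)
  exp(seq(log(lmax / 100), log(lmax), length.out = n_points))
}

inner_select <- function(train, penalty_grid, q_grid, n_inner, seed, ...) {
  folds <- make_folds(nrow(train$X), n_inner, seed = substream_seed(seed, "inner"))
  grid <- expand.grid(penalty = penalty_grid, q = q_grid)
  mean_ll <- vapply(seq_len(nrow(grid)), function(i) {
    lls <- vapply(seq_len(n_inner), function(k) {
      tr <- subset_samples(train, which(folds != k))
      te <- subset_samples(train, which(folds == k))
      fit <- grn_fit(tr, q = grid$q[i], penalty = grid$penalty[i],
                     seed = substream_seed(seed, "inner-fit", i * 100 + k), ...)
      out_of_sample_loglik(fit, te)
    }, numeric(1))
    mean(lls)
  }, numeric(1))
  best <- which.max(mean_ll)
  list(penalty = grid$penalty[best], q = grid$q[best],
       table = tibble::tibble(penalty = grid$penalty, q = grid$q,
                              mean_test_loglik = mean_ll))
}

#' Three-model comparison by nested cross-validation
#'
#' The evaluation protocol for the sparse regulatory model: samples are
#' split into `n_outer` folds; in each fold the three models are trained on
#' the remaining folds and scored by total out-of-sample log-likelihood on
#' the held-out fold. The compared models are the full model (TFs + hidden
#' factors), the no-hidden-factor model (q = 0), and the independent-genes
#' reference model ([fit_reference_model()]).
#'
#' Hyperparameters (penalty and q for the full model; penalty for the
#' no-hidden model) are chosen by `n_inner`-fold cross-validation on the
#' FIRST outer fold's training data — maximizing mean held-out
#' log-likelihood — and reused for the remaining folds; set
#' `retune_per_fold = TRUE` to repeat the inner search in every fold.
#' Pairwise model differences are tested with the paired exact Wilcoxon
#' signed-rank test over folds.
#'
#' @param data An [expression_dataset()].
#' @param penalty_grid Candidate L1 penalties (default
#'   [default_penalty_grid()]).
#' @param q_grid Candidate hidden-factor counts.
#' @param n_outer Outer folds (default 10).
#' @param n_inner Inner folds for hyperparameter selection (default 2).
#' @param retune_per_fold Repeat the inner search in every outer fold.
#' @param seed Integer seed controlling folds, restarts and selection.
#' @param ... Passed to [grn_fit()] (e.g. `n_restarts`, `max_iter`, `tol`).
#' @return Object of class `grn_cv`: `folds` (a tibble, one row per fold x
#'   model with the test log-likelihood), `selected_penalty`, `selected_q`,
#'   `selected_penalty_no_hidden`, `wilcoxon` (tibble of pairwise two-sided
#'   p-values), `fold_assignments`, and the inner-selection table.
#' @export
cross_validate <- function(data, penalty_grid = NULL, q_grid = c(0, 1, 3, 10),
                           n_outer = 10, n_inner = 2,
                           retune_per_fold = FALSE, seed = 1, ...) {
  stopifnot(inherits(data, "expression_dataset"))
  N <- nrow(data$X)
  stopifnot(N >= n_outer)
  if (is.null(penalty_grid)) penalty_grid <- default_penalty_grid(data)
  stopifnot(length(penalty_grid) >= 1, length(q_grid) >= 1)
  folds <- make_folds(N, n_outer, seed = seed)
  if (min(tabulate(folds, n_outer)) < 2 || N - max(tabulate(folds, n_outer)) < 2) {
    stop("folds must leave at least 2 samples on each side of the split",
         call. = FALSE)
  }
  sel <- NULL; sel_nh <- NULL; sel_table <- NULL
  rows <- list()
  for (k in seq_len(n_outer)) {
    train <- subset_samples(data, which(folds != k))
    test <- subset_samples(data, which(folds == k))
    if (k == 1 || retune_per_fold) {
      sel <- inner_select(train, penalty_grid, q_grid, n_inner,
                          seed = substream_seed(seed, "select", k), ...)
      sel_nh <- inner_select(train, penalty_grid, 0, n_inner,
                             seed = substream_seed(seed, "select-nh", k), ...)
      if (k == 1) sel_table <- sel$table
    }
    fit_full <- grn_fit(train, q = sel$q, penalty = sel$penalty,
                        seed = substream_seed(seed, "outer-full", k), ...)
    fit_nh <- grn_fit(train, q = 0, penalty = sel_nh$penalty,
                      seed = substream_seed(seed, "outer-nh", k), ...)
    fit_ref <- fit_reference_model(train)
    rows[[k]] <- tibble::tibble(
      fold = k,
      model = c("full", "no_hidden", "reference"),
      test_loglik = c(out_of_sample_loglik(fit_full, test),
                      out_of_sample_loglik(fit_nh, test),
                      out_of_sample_loglik(fit_ref, test)),
      n_test = nrow(test$X))
  }
  fold_tbl <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(fold_tbl, id_cols = "fold",
                             names_from = "model", values_from = "test_loglik")
  # the signed-rank comparison needs at least 5 paired folds
  wilcox_or_na <- function(a, b) {
    if (length(a) < 5) NA_real_ else wilcoxon_signed_rank(a, b)
  }
  wilcoxon <- tibble::tibble(
    comparison = c("full_vs_no_hidden", "no_hidden_vs_reference",
                   "full_vs_reference"),
    p_value = c(wilcox_or_na(wide$full, wide$no_hidden),
                wilcox_or_na(wide$no_hidden, wide$reference),
                wilcox_or_na(wide$full, wide$reference)))
  structure(
    list(folds = fold_tbl, fold_assignments = folds,
         selected_penalty = sel$penalty, selected_q = sel$q,
         selected_penalty_no_hidden = sel_nh$penalty,
         selection_table = sel_table, wilcoxon = wilcoxon,
         n_outer = n_outer, n_inner = n_inner, seed = seed),
    class = "grn_cv")
}

#' @export
print.grn_cv <- function(x, ...) {
  cat("<grn_cv>", x$n_outer, "outer folds; selected q =", x$selected_q,
      " penalty =", signif(x$selected_penalty, 4), "\n")
  s <- dplyr::summarise(dplyr::group_by(x$folds, .data$model),
                        mean_test_loglik = mean(.data$test_loglik))
  print(s)
  print(x$wilcoxon)
  invisible(x)
}

#' Write a cross-validation report
#'
#' Tab-delimited table with one row per fold and model (fold index, model
#' name, test log-likelihood) followed by a summary block of Wilcoxon
#' p-values as comment lines.
#'
#' @param cv A `grn_cv` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  stopifnot(inherits(cv, "grn_cv"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("fold", "model", "test_loglik"), collapse = "\t"), con)
  apply_rows <- sprintf("%d\t%s\t%.10g", cv$folds$fold, cv$folds$model,
                        cv$folds$test_loglik)
  writeLines(apply_rows, con)
  writeLines(sprintf("# selected_q\t%d", cv$selected_q), con)
  writeLines(sprintf("# selected_penalty\t%.10g", cv$selected_penalty), con)
  writeLines(sprintf("# wilcoxon\t%s\t%.10g", cv$wilcoxon$comparison,
                     cv$wilcoxon$p_value), con)
  invisible(path)
}
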