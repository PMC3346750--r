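#' Fit the sparse two-layer regulatory model
#'
#' Minimizes the L1-penalized negative log marginal likelihood with the
#' orthant-wise quasi-Newton optimizer ([owlqn_minimize()]). The exact
#' zeros in the fitted `W` and `Lambda` define the learned network edges.
#'
#' Columns of `X` and `R` are mean-centered before optimization (which
#' improves conditioning; the intercept absorbs residual offsets) and the
#' reported intercept is translated back to the original scale. The fit is
#' restarted `n_restarts` times from independent random initializations
#' (`W = 0`, `Lambda` entries i.i.d. N(0, 0.01), intercept at the gene
#' means, noise at the pooled variance) and the best objective is kept; the
#' spread of final objectives across restarts is reported as a convergence
#' diagnostic.
#'
#' By default each restart is solved pathwise: the optimizer is run over an
#' increasing penalty sequence ending at `penalty`, each stage warm-started
#' from the last. At small penalties the objective is nearly smooth and its
#' optimum essentially unique, so continuation steers every restart toward
#' the same basin and avoids the factor-collapse local optima that one-shot
#' fits at a large penalty can fall into.
#'
#' @param data An [expression_dataset()]; all entries must be finite.
#' @param q Number of hidden factors (>= 0).
#' @param penalty Nonnegative L1 weight on `W` and `Lambda`.
#' @param n_restarts Number of random restarts.
#' @param max_iter,tol,lbfgs_memory Optimizer controls, see
#'   [owlqn_minimize()].
#' @param warm_start Solve each restart along an increasing penalty path
#'   (`penalty / 27`, `penalty / 9`, `penalty / 3`, `penalty`), each stage
#'   warm-started from the previous solution. Ignored when `penalty = 0`.
#' @param seed Integer seed for the restart initializations.
#' @param scale_columns Also scale columns of `X`/`R` to unit variance
#'   before fitting (off by default; centering alone is the default
#'   preprocessing). With scaling on, the returned parameters describe the
#'   standardized data, the training transform is stored in the fit, and
#'   [out_of_sample_loglik()] applies it to test data; log-likelihoods are
#'   then only comparable among fits with the same scaling.
#' @return Object of class `grn_fit` holding `params` (a [grn_params()] on
#'   the original data scale), ids, the optimizer trace of the best
#'   restart, `restart_objectives`, and the fit configuration.
#' @export
#' @examples
#' sim <- simulate_grn_data(p = 15, d = 2, q = 1, N = 60, seed = 3)
#' fit <- grn_fit(sim$data, q = 1, penalty = 2, n_restarts = 2, seed = 3)
#' fit
grn_fit <- function(data, q, penalty, n_restarts = 10, max_iter = 500,
                    tol = 1e-7, lbfgs_memory = 10, seed = 1,
                    scale_columns = FALSE, warm_start = TRUE) {
  stopifnot(inherits(data, "expression_dataset"), q >= 0, penalty >= 0,
            n_restarts >= 1, max_iter >= 1, lbfgs_memory >= 1)
  check_finite_dataset(data)
  N <- nrow(data$X); p <- ncol(data$X); d <- ncol(data$R)
  mx <- colMeans(data$X)
  mr <- if (d > 0) colMeans(data$R) else numeric(0)
  Xc <- sweep(data$X, 2, mx, "-")
  Rc <- if (d > 0) sweep(data$R, 2, mr, "-") else data$R
  sx <- rep(1, p); sr <- rep(1, d)
  if (scale_columns) {
    sx <- pmax(apply(Xc, 2, stats::sd), 1e-12)
    Xc <- sweep(Xc, 2, sx, "/")
    if (d > 0) {
      sr <- pmax(apply(Rc, 2, stats::sd), 1e-12)
      Rc <- sweep(Rc, 2, sr, "/")
    }
  }
  cdata <- expression_dataset(Xc, if (d > 0) Rc else NULL,
                              sample_ids = data$sample_ids)
  pooled_var <- max(mean(Xc^2), 1e-12)
  mask <- penalty_mask(p, d, q)
  # overflowed trial points (huge Lambda or nu during a long line-search
  # step) evaluate to +Inf, which the optimizer treats as a rejected step
  loss <- function(theta) {
    tryCatch(negative_log_likelihood(unflatten_params(theta, p, d, q), cdata),
             error = function(e) Inf)
  }
  gradf <- function(theta) {
    flatten_gradient(nll_gradient(unflatten_params(theta, p, d, q), cdata))
  }
  best <- NULL
  restart_objectives <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    theta0 <- with_seed(substream_seed(seed, "fit-restart", r), {
      Lambda0 <- matrix(stats::rnorm(p * q, sd = 0.1), p, q)
      flatten_params(grn_params(matrix(0, p, d), Lambda0,
                                rep(0, p), pooled_var))
    })
    pens <- if (warm_start && penalty > 0) {
      penalty * c(1 / 27, 1 / 9, 1 / 3, 1)
    } else penalty
    th <- theta0
    res <- NULL
    for (l in pens) {
      res <- owlqn_minimize(loss, gradf, th, penalty = l, mask = mask,
                            memory = lbfgs_memory, max_iter = max_iter,
                            tol = tol)
      th <- res$par
    }
    restart_objectives[r] <- res$value
    if (is.null(best) || res$value < best$value) best <- res
  }
  params_c <- unflatten_params(best$par, p, d, q)
  if (scale_columns) {
    # model describes the standardized data; keep the transform for later
    W <- params_c$W; Lambda <- params_c$Lambda
    mu <- params_c$mu; sigma2 <- params_c$sigma2
  } else {
    # undo centering: translate the intercept back to the input scale
    W <- params_c$W
    Lambda <- params_c$Lambda
    mu <- mx + params_c$mu
    if (d > 0) mu <- mu - as.numeric(W %*% mr)
    sigma2 <- params_c$sigma2
  }
  out <- structure(
    list(params = grn_params(W, Lambda, mu, sigma2),
         transform = list(x_center = mx, x_scale = sx,
                          r_center = mr, r_scale = sr),
         gene_ids = data$gene_ids, tf_ids = data$tf_ids,
         q = q, penalty = penalty, seed = seed,
         objective = best$value, n_iter = best$n_iter,
         converged = best$converged, trace = best$trace,
         restart_objectives = restart_objectives,
         n_samples = N, scale_columns = scale_columns),
    class = "grn_fit")
  if (!best$converged) {
    warning("optimizer reached max_iter without meeting the convergence ",
            "criterion; best iterate returned", call. = FALSE)
  }
  out
}

#' @export
print.grn_fit <- function(x, ...) {
  cat("<grn_fit> p =", length(x$gene_ids), " d =", length(x$tf_ids),
      " q =", x$q, " penalty =", signif(x$penalty, 4), "\n")
  cat("  objective", format(x$objective), "(", x$n_iter, "iterations,",
      if (x$converged) "converged" else "not converged", ")\n")
  cat("  edges: W", sum(x$params$W != 0), " Lambda", sum(x$params$Lambda != 0),
      " sigma2 =", signif(x$params$sigma2, 4), "\n")
  invisible(x)
}

#' Fit the independent-genes reference model
#'
#' The bottom-rung comparison model: every non-TF gene is an independent
#' Gaussian with its own mean and variance (no upper layer at all). Means
#' and variances are maximum-likelihood estimates (variance denominator N),
#' with variances floored at `1e-8` times the pooled variance so constant
#' genes do not produce degenerate densities.
#'
#' @param data An [expression_dataset()].
#' @return Object of class `grn_reference` with `mean` and `variance`
#'   vectors over genes.
#' @export
fit_reference_model <- function(data) {
  stopifnot(inherits(data, "expression_dataset"), nrow(data$X) >= 2)
  check_finite_dataset(data)
  m <- colMeans(data$X)
  v <- colMeans(sweep(data$X, 2, m, "-")^2)
  floor_v <- 1e-8 * max(mean(v), .Machine$double.eps)
  structure(list(mean = m, variance = pmax(v, floor_v),
                 gene_ids = data$gene_ids),
            class = "grn_reference")
}

#' @export
print.grn_reference <- function(x, ...) {
  cat("<grn_reference> independent Gaussians over", length(x$mean), "genes\n")
  invisible(x)
}

#' Out-of-sample log-likelihood of held-out expression data
#'
#' Total log probability of the held-out gene expression given the held-out
#' TF expression, under a trained model with the latent factors integrated
#' out. The reference model ignores the TF block. This is the quantity used
#' to compare the full, no-hidden-factor and reference models by
#' cross-validation.
#'
#' @param model A `grn_fit`, [grn_params()], or `grn_reference` object.
#' @param test An [expression_dataset()] with the same genes (and TFs, for
#'   regression models) as the training data.
#' @return Scalar log-likelihood (higher is better).
#' @export
out_of_sample_loglik <- function(model, test) {
  stopifnot(inherits(test, "expression_dataset"))
  if (inherits(model, "grn_reference")) {
    if (!identical(model$gene_ids, test$gene_ids)) {
      stop("gene identifiers of model and test data differ", call. = FALSE)
    }
    return(sum(vapply(seq_along(model$mean), function(j) {
      sum(stats::dnorm(test$X[, j], model$mean[j],
                       sqrt(model$variance[j]), log = TRUE))
    }, numeric(1))))
  }
  if (inherits(model, "grn_fit")) {
    if (!identical(model$gene_ids, test$gene_ids) ||
        !identical(model$tf_ids, test$tf_ids)) {
      stop("gene/TF identifiers of model and test data differ", call. = FALSE)
    }
    if (isTRUE(model$scale_columns)) {
      tr <- model$transform
      Xs <- sweep(sweep(test$X, 2, tr$x_center, "-"), 2, tr$x_scale, "/")
      Rs <- if (ncol(test$R) > 0) {
        sweep(sweep(test$R, 2, tr$r_center, "-"), 2, tr$r_scale, "/")
      } else NULL
      test <- expression_dataset(Xs, Rs, sample_ids = test$sample_ids)
    }
    model <- model$params
  }
  stopifnot(inherits(model, "grn_params"))
  -negative_log_likelihood(model, test)
}

# ---- model archive ------------------------------------------------------

#' Save / load a fitted model archive
#'
#' The archive is a single self-describing JSON file holding the fitted
#' `W`, `Lambda`, `mu`, `sigma2`, the identifier lists, and fit metadata
#' (penalty, q, seed, objective trace), with a format version field.
#'
#' @param fit A `grn_fit` object.
#' @param path File path for the archive.
#' @return `write_grn_model()` returns `path` invisibly;
#'   `read_grn_model()` returns the reconstructed `grn_fit`.
#' @export
write_grn_model <- function(fit, path) {
  stopifnot(inherits(fit, "grn_fit"))
  obj <- list(
    format = "sparsegrn-model", version = 1L,
    gene_ids = fit$gene_ids, tf_ids = fit$tf_ids,
    W = fit$params$W, Lambda = fit$params$Lambda,
    mu = fit$params$mu, sigma2 = fit$params$sigma2,
    q = fit$q, penalty = fit$penalty, seed = fit$seed,
    objective = fit$objective, n_iter = fit$n_iter,
    converged = fit$converged, trace = fit$trace,
    restart_objectives = fit$restart_objectives,
    n_samples = fit$n_samples, scale_columns = fit$scale_columns,
    transform = fit$transform)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_grn_model
#' @param path File path of an archive written by `write_grn_model()`.
#' @export
read_grn_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "sparsegrn-model")) {
    stop("not a sparsegrn model archive: ", path, call. = FALSE)
  }
  p <- length(obj$gene_ids)
  as_mat <- function(m, ncols) {
    if (is.null(m) || length(m) == 0) return(matrix(0, p, 0))
    matrix(as.numeric(t(m)), p, ncols, byrow = TRUE)
  }
  W <- if (length(obj$tf_ids) > 0) as_mat(obj$W, length(obj$tf_ids)) else matrix(0, p, 0)
  Lambda <- if (obj$q > 0) as_mat(obj$Lambda, obj$q) else matrix(0, p, 0)
  structure(
    list(params = grn_params(W, Lambda, obj$mu, obj$sigma2),
         transform = lapply(obj$transform, as.numeric),
         gene_ids = as.character(obj$gene_ids),
         tf_ids = as.character(obj$tf_ids),
         q = obj$q, penalty = obj$penalty, seed = obj$seed,
         objective = obj$objective, n_iter = obj$n_iter,
         converged = obj$converged, trace = obj$trace,
         restart_objectives = obj$restart_objectives,
         n_samples = obj$n_samples, scale_columns = obj$scale_columns),
    class = "grn_fit")
}
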