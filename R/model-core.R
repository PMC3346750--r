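#' Parameters of the two-layer linear-Gaussian regulatory model
#'
#' The model writes a gene-expression vector x (length p) as
#' \deqn{x = W r + \Lambda z + \mu + \epsilon,}
#' where r (length d) is the observed TF expression, z (length q) is a
#' standard-normal latent factor, and \eqn{\epsilon \sim N(0, \sigma^2 I)}.
#' Integrating z out, x given r is Gaussian with mean \eqn{W r + \mu} and
#' covariance \eqn{C = \Lambda \Lambda^\top + \sigma^2 I}. The latent z is
#' never stored; all likelihood computations use the marginal.
#'
#' @param W p-by-d matrix of TF regulation weights (sign = activate/suppress);
#'   `d` may be 0 (pure probabilistic PCA).
#' @param Lambda p-by-q matrix of hidden-factor loadings; `q` may be 0
#'   (plain regression, no hidden variables).
#' @param mu Length-p intercept vector.
#' @param sigma2 Positive scalar, isotropic noise variance.
#' @return An object of class `grn_params`.
#' @export
grn_params <- function(W, Lambda, mu, sigma2) {
  W <- unname(as.matrix(W)); Lambda <- unname(as.matrix(Lambda))
  mu <- unname(as.numeric(mu)); sigma2 <- unname(sigma2)
  p <- length(mu)
  if (nrow(W) != p && ncol(W) > 0) stop("W must have ", p, " rows (one per gene)", call. = FALSE)
  if (nrow(W) != p) W <- matrix(0, p, 0)
  if (nrow(Lambda) != p && ncol(Lambda) > 0) stop("Lambda must have ", p, " rows", call. = FALSE)
  if (nrow(Lambda) != p) Lambda <- matrix(0, p, 0)
  if (!is.numeric(sigma2) || length(sigma2) != 1 || !is.finite(sigma2) || sigma2 <= 0) {
    stop("sigma2 must be a positive finite scalar", call. = FALSE)
  }
  structure(list(W = W, Lambda = Lambda, mu = mu, sigma2 = sigma2),
            class = "grn_params")
}

#' @export
print.grn_params <- function(x, ...) {
  cat("<grn_params> p =", length(x$mu), " d =", ncol(x$W),
      " q =", ncol(x$Lambda), " sigma2 =", signif(x$sigma2, 4), "\n")
  cat("  nonzero W:", sum(x$W != 0), " nonzero Lambda:", sum(x$Lambda != 0), "\n")
  invisible(x)
}

#' Dense marginal covariance of the model
#'
#' Returns \eqn{C = \Lambda \Lambda^\top + \sigma^2 I_p}, the p-by-p
#' covariance of gene expression given TF expression after integrating out
#' the latent factors. Intended for small p (diagnostics and tests); the
#' likelihood code never forms it, using [woodbury_terms()] instead.
#'
#' @param params A [grn_params()] object.
#' @return A p-by-p symmetric positive-definite matrix.
#' @export
marginal_covariance <- function(params) {
  p <- length(params$mu)
  C <- diag(params$sigma2, p)
  if (ncol(params$Lambda) > 0) C <- C + tcrossprod(params$Lambda)
  C
}

#' Low-rank terms for inverting the marginal covariance
#'
#' The p-by-p covariance \eqn{C = \Lambda\Lambda^\top + \sigma^2 I} is never
#' inverted directly. With the q-by-q matrix
#' \eqn{M = \sigma^2 I_q + \Lambda^\top \Lambda},
#' the Woodbury identity gives
#' \eqn{C^{-1} = \sigma^{-2}(I_p - \Lambda M^{-1} \Lambda^\top)} and
#' \eqn{\log|C| = (p-q)\log\sigma^2 + \log|M|}, so quadratic forms and the
#' log-determinant cost O(p q^2) instead of O(p^3).
#'
#' @param params A [grn_params()] object.
#' @return List with `M` (q-by-q; 0-by-0 when q = 0), its Cholesky factor
#'   `M_chol`, `M_inv`, and `log_det_C`.
#' @export
woodbury_terms <- function(params) {
  p <- length(params$mu)
  q <- ncol(params$Lambda)
  s2 <- params$sigma2
  if (q == 0) {
    return(list(M = matrix(0, 0, 0), M_chol = matrix(0, 0, 0),
                M_inv = matrix(0, 0, 0), log_det_C = p * log(s2)))
  }
  M <- diag(s2, q) + crossprod(params$Lambda)
  M_chol <- tryCatch(chol(M), error = function(e) {
    stop("M = sigma2*I + t(Lambda) %*% Lambda is numerically singular; ",
         "Lambda likely contains overflowed or NaN entries", call. = FALSE)
  })
  M_inv <- chol2inv(M_chol)
  list(M = M, M_chol = M_chol, M_inv = M_inv,
       log_det_C = (p - q) * log(s2) + 2 * sum(log(diag(M_chol))))
}

# Residual matrix T = X - R W^T - 1 mu^T (N x p), shared by NLL and gradient.
model_residuals <- function(params, data) {
  check_params_data(params, data)
  Tm <- sweep(data$X, 2, params$mu, "-")
  if (ncol(params$W) > 0) Tm <- Tm - tcrossprod(data$R, params$W)
  Tm
}

check_params_data <- function(params, data) {
  p <- length(params$mu)
  if (ncol(data$X) != p) {
    stop("gene axis mismatch: model has p = ", p, " genes, data has ",
         ncol(data$X), call. = FALSE)
  }
  if (ncol(params$W) != ncol(data$R)) {
    stop("TF axis mismatch: model has d = ", ncol(params$W),
         " TFs, data has ", ncol(data$R), call. = FALSE)
  }
  invisible(TRUE)
}

#' Negative log marginal likelihood
#'
#' Sum over samples of the negative log density of \eqn{x_n} given
#' \eqn{r_n}: the marginal is Gaussian with mean \eqn{W r_n + \mu} and
#' covariance \eqn{C = \Lambda\Lambda^\top + \sigma^2 I}; the latent factors
#' are integrated out analytically. Computed via [woodbury_terms()], so the
#' cost is O(N p (d + q)) and no p-by-p matrix is formed.
#'
#' @param params A [grn_params()] object.
#' @param data An [expression_dataset()] with matching dimensions.
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, data) {
  Tm <- model_residuals(params, data)
  N <- nrow(Tm); p <- ncol(Tm)
  wt <- woodbury_terms(params)
  s2 <- params$sigma2
  if (ncol(params$Lambda) > 0) {
    U <- Tm %*% params$Lambda                       # N x q
    quad <- (sum(Tm * Tm) - sum(U * (U %*% wt$M_inv))) / s2
  } else {
    quad <- sum(Tm * Tm) / s2
  }
  0.5 * (N * p * log(2 * pi) + N * wt$log_det_C + quad)
}

#' Analytic gradient of the negative log-likelihood
#'
#' Gradients with respect to `W`, `Lambda`, `mu`, and `nu = log(sigma2)`.
#' The noise is parameterized on the log scale so the optimizer works on an
#' unconstrained domain. All blocks are computed through the Woodbury
#' factorization in O(N p (d + q)) time.
#'
#' @inheritParams negative_log_likelihood
#' @return List with components `W` (p-by-d), `Lambda` (p-by-q), `mu`
#'   (length p), `nu` (scalar).
#' @export
nll_gradient <- function(params, data) {
  Tm <- model_residuals(params, data)
  N <- nrow(Tm); p <- ncol(Tm)
  q <- ncol(params$Lambda); d <- ncol(params$W)
  s2 <- params$sigma2
  wt <- woodbury_terms(params)
  if (q > 0) {
    U <- Tm %*% params$Lambda                       # N x q
    V <- (Tm - U %*% (wt$M_inv %*% t(params$Lambda))) / s2   # rows = C^{-1} t_n
    A <- params$Lambda %*% wt$M_inv                 # C^{-1} Lambda
    SA <- crossprod(Tm, Tm %*% A)                   # S A, p x q
    CinvSA <- (SA - params$Lambda %*% (wt$M_inv %*% crossprod(params$Lambda, SA))) / s2
    g_Lambda <- N * A - CinvSA
    tr_Cinv <- (p - q) / s2 + sum(diag(wt$M_inv))
  } else {
    V <- Tm / s2
    g_Lambda <- matrix(0, p, 0)
    tr_Cinv <- p / s2
  }
  g_W <- if (d > 0) -crossprod(V, data$R) else matrix(0, p, 0)
  g_mu <- -colSums(V)
  g_nu <- s2 * (N / 2 * tr_Cinv - 0.5 * sum(V * V))
  list(W = g_W, Lambda = g_Lambda, mu = g_mu, nu = g_nu)
}

#' L1-penalized objective
#'
#' The negative log marginal likelihood plus `penalty` times the L1 norm of
#' the regulatory weight blocks: \eqn{\lambda(\sum_{ij}|W_{ij}| +
#' \sum_{ik}|\Lambda_{ik}|)}. The intercept and the noise variance are not
#' penalized — sparsity has a biological reading only for edges.
#'
#' @inheritParams negative_log_likelihood
#' @param penalty Nonnegative L1 weight \eqn{\lambda}.
#' @return Scalar objective value.
#' @export
penalized_objective <- function(params, data, penalty) {
  if (!is.numeric(penalty) || length(penalty) != 1 || penalty < 0) {
    stop("penalty must be a single nonnegative number", call. = FALSE)
  }
  negative_log_likelihood(params, data) +
    penalty * (sum(abs(params$W)) + sum(abs(params$Lambda)))
}

#' Posterior over the latent factors for one sample
#'
#' Standard linear-Gaussian posterior: given observed gene expression `x`
#' and TF expression `r`, the latent factor z has mean
#' \eqn{M^{-1} \Lambda^\top (x - W r - \mu)} and covariance
#' \eqn{\sigma^2 M^{-1}}. Useful for reporting hidden-factor activities.
#'
#' @param params A [grn_params()] object.
#' @param r Length-d TF expression vector (ignored when d = 0).
#' @param x Length-p gene expression vector.
#' @return List with `mean` (length q) and `covariance` (q-by-q).
#' @export
posterior_latent <- function(params, r, x) {
  q <- ncol(params$Lambda)
  if (q == 0) return(list(mean = numeric(0), covariance = matrix(0, 0, 0)))
  resid <- x - params$mu
  if (ncol(params$W) > 0) resid <- resid - as.numeric(params$W %*% r)
  wt <- woodbury_terms(params)
  list(mean = as.numeric(wt$M_inv %*% crossprod(params$Lambda, resid)),
       covariance = params$sigma2 * wt$M_inv)
}

# ---- flatten / unflatten -----------------------------------------------
# Frozen layout of the optimization vector: W block (row-major over genes x
# TFs), Lambda block (row-major), mu block, then the scalar nu = log sigma2.
# The L1 mask covers exactly the W and Lambda blocks.

flatten_params <- function(params) {
  c(as.numeric(t(params$W)), as.numeric(t(params$Lambda)),
    params$mu, log(params$sigma2))
}

unflatten_params <- function(theta, p, d, q) {
  nW <- p * d; nL <- p * q
  W <- if (d > 0) matrix(theta[seq_len(nW)], p, d, byrow = TRUE) else matrix(0, p, 0)
  Lambda <- if (q > 0) matrix(theta[nW + seq_len(nL)], p, q, byrow = TRUE) else matrix(0, p, 0)
  mu <- theta[nW + nL + seq_len(p)]
  sigma2 <- exp(theta[nW + nL + p + 1])
  grn_params(W, Lambda, mu, sigma2)
}

flatten_gradient <- function(grad) {
  c(as.numeric(t(grad$W)), as.numeric(t(grad$Lambda)), grad$mu, grad$nu)
}

penalty_mask <- function(p, d, q) {
  c(rep(TRUE, p * (d + q)), rep(FALSE, p + 1))
}
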