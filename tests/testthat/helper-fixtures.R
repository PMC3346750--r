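# Shared helpers: small random fixtures and score functions.

random_params <- function(p, d, q, seed = 1, sigma2 = NULL) {
  set.seed(seed)
  grn_params(
    W = matrix(rnorm(p * d), p, d),
    Lambda = matrix(rnorm(p * q), p, q),
    mu = rnorm(p),
    sigma2 = if (is.null(sigma2)) runif(1, 0.3, 2) else sigma2)
}

random_dataset <- function(p, d, N, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(N * p), N, p)
  colnames(X) <- sprintf("G%03d", seq_len(p))
  R <- if (d > 0) {
    R <- matrix(rnorm(N * d), N, d)
    colnames(R) <- sprintf("TF%02d", seq_len(d))
    R
  } else NULL
  expression_dataset(X, R)
}

# dense-covariance oracle for the marginal Gaussian negative log-likelihood
nll_dense_oracle <- function(params, data) {
  C <- marginal_covariance(params)
  Tm <- sweep(data$X, 2, params$mu, "-")
  if (ncol(params$W) > 0) Tm <- Tm - tcrossprod(data$R, params$W)
  p <- ncol(Tm)
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  Ci <- solve(C)
  sum(apply(Tm, 1, function(t) {
    0.5 * (p * log(2 * pi) + ld + as.numeric(t %*% Ci %*% t))
  }))
}

central_fd_gradient <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
    (f(tp) - f(tm)) / (2 * h)
  }, numeric(1))
}

support_f1 <- function(estimated, truth) {
  tp <- sum(estimated & truth)
  fp <- sum(estimated & !truth)
  fn <- sum(!estimated & truth)
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# match estimated factor loadings to truth column by column (greedy over
# absolute correlation, i.e. up to sign and permutation); returns the
# matched absolute correlations
matched_column_cors <- function(L_est, L_true) {
  q <- ncol(L_true)
  cors <- abs(stats::cor(L_est, L_true))
  out <- numeric(q)
  used <- rep(FALSE, ncol(L_est))
  for (k in order(-apply(cors, 2, max))) {
    j <- which.max(ifelse(used, -Inf, cors[, k]))
    out[k] <- cors[j, k]
    used[j] <- TRUE
  }
  out
}
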