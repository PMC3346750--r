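test_that("marginal covariance is Lambda Lambda' + sigma2 I", {
  p0 <- grn_params(matrix(0, 2, 0), matrix(0, 2, 1), c(0, 0), 1)
  expect_equal(marginal_covariance(p0), diag(2))

  p1 <- grn_params(matrix(0, 2, 0), matrix(c(1, 1), 2, 1), c(0, 0), 0.5)
  expect_equal(marginal_covariance(p1), matrix(c(1.5, 1, 1, 1.5), 2))

  pars <- random_params(p = 6, d = 0, q = 2, seed = 3)
  C <- marginal_covariance(pars)
  ev_C <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev_LLt <- eigen(tcrossprod(pars$Lambda), symmetric = TRUE,
                  only.values = TRUE)$values
  expect_equal(min(ev_C), pars$sigma2 + min(ev_LLt), tolerance = 1e-10)
  expect_gt(min(ev_C), 0)
})

test_that("Woodbury terms reproduce the dense log-determinant", {
  p0 <- grn_params(matrix(0, 3, 0), matrix(0, 3, 0), rep(0, 3), 2)
  expect_equal(woodbury_terms(p0)$log_det_C, 3 * log(2))

  p1 <- grn_params(matrix(0, 2, 0), matrix(c(1, 1), 2, 1), c(0, 0), 0.5)
  wt <- woodbury_terms(p1)
  expect_equal(wt$M, matrix(2.5))
  expect_equal(wt$log_det_C, log(1.25))

  for (seed in 1:5) {
    pars <- random_params(p = 10, d = 0, q = 3, seed = seed)
    dense <- as.numeric(determinant(marginal_covariance(pars))$modulus)
    expect_equal(woodbury_terms(pars)$log_det_C, dense, tolerance = 1e-8)
  }
})

test_that("NLL matches the standard-normal density in the scalar case", {
  ds <- expression_dataset(matrix(0, 2, 1, dimnames = list(NULL, "G1")))
  pars <- grn_params(matrix(0, 1, 0), matrix(0, 1, 0), 0, 1)
  # two identical samples at the mean of a standard normal
  expect_equal(negative_log_likelihood(pars, ds), 2 * 0.5 * log(2 * pi))

  ds1 <- expression_dataset(matrix(c(1, 0), 2, 1, dimnames = list(NULL, "G1")))
  expect_equal(negative_log_likelihood(pars, ds1),
               2 * 0.5 * log(2 * pi) + 0.5)
})

test_that("NLL via Woodbury equals the dense-covariance oracle", {
  for (seed in 1:5) {
    pars <- random_params(p = 8, d = 2, q = 2, seed = seed)
    ds <- random_dataset(p = 8, d = 2, N = 5, seed = seed + 100)
    expect_equal(negative_log_likelihood(pars, ds),
                 nll_dense_oracle(pars, ds), tolerance = 1e-8)
  }
  # the q = 0 and d = 0 limits
  pars_q0 <- random_params(p = 6, d = 2, q = 0, seed = 8)
  ds_q0 <- random_dataset(p = 6, d = 2, N = 7, seed = 9)
  expect_equal(negative_log_likelihood(pars_q0, ds_q0),
               nll_dense_oracle(pars_q0, ds_q0), tolerance = 1e-8)
  pars_d0 <- random_params(p = 6, d = 0, q = 2, seed = 10)
  ds_d0 <- random_dataset(p = 6, d = 0, N = 7, seed = 11)
  expect_equal(negative_log_likelihood(pars_d0, ds_d0),
               nll_dense_oracle(pars_d0, ds_d0), tolerance = 1e-8)
})

test_that("dimension mismatches are reported by axis", {
  pars <- random_params(p = 4, d = 2, q = 1, seed = 1)
  expect_error(negative_log_likelihood(pars, random_dataset(5, 2, 4, 1)),
               "gene axis")
  expect_error(negative_log_likelihood(pars, random_dataset(4, 3, 4, 1)),
               "TF axis")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:4) {
    p <- 6; d <- 2; q <- 2
    pars <- random_params(p, d, q, seed = seed)
    ds <- random_dataset(p, d, N = 9, seed = seed + 50)
    f <- function(th) {
      negative_log_likelihood(unflatten_params(th, p, d, q), ds)
    }
    theta <- flatten_params(pars)
    g_an <- flatten_gradient(nll_gradient(pars, ds))
    g_fd <- central_fd_gradient(f, theta)
    expect_lt(max(abs(g_an - g_fd) / pmax(1, abs(g_fd))), 1e-5)
  }
})

test_that("gradient vanishes at closed-form stationary points", {
  # per-gene OLS with q = 0 and sigma2 at its MLE is stationary in W, mu
  set.seed(4)
  ds <- random_dataset(p = 4, d = 2, N = 30, seed = 4)
  X <- ds$X; R <- ds$R
  fits <- lapply(seq_len(4), function(j) stats::lm.fit(cbind(1, R), X[, j]))
  W <- t(vapply(fits, function(f) f$coefficients[-1], numeric(2)))
  mu <- vapply(fits, function(f) f$coefficients[1], numeric(1))
  s2 <- mean(vapply(fits, function(f) f$residuals, numeric(30))^2)
  g <- nll_gradient(grn_params(W, matrix(0, 4, 0), mu, s2), ds)
  expect_lt(max(abs(g$W)), 1e-8)
  expect_lt(max(abs(g$mu)), 1e-8)
  expect_lt(abs(g$nu), 1e-8)

  # Lambda = 0 is a symmetric stationary point of the loading gradient
  pars0 <- grn_params(matrix(0, 4, 2), matrix(0, 4, 2), colMeans(X), 1)
  g0 <- nll_gradient(pars0, ds)
  expect_true(all(g0$Lambda == 0))
})

test_that("penalized objective adds the L1 norm of W and Lambda only", {
  pars <- random_params(p = 5, d = 2, q = 1, seed = 6)
  ds <- random_dataset(p = 5, d = 2, N = 6, seed = 7)
  expect_equal(penalized_objective(pars, ds, 0),
               negative_log_likelihood(pars, ds))
  pars2 <- grn_params(matrix(2, 1, 1), matrix(-3, 1, 1), 0, 1)
  ds2 <- expression_dataset(matrix(c(0, 1), 2, 1, dimnames = list(NULL, "G1")),
                            matrix(c(0, 0), 2, 1, dimnames = list(NULL, "TF1")))
  expect_equal(penalized_objective(pars2, ds2, 1),
               negative_log_likelihood(pars2, ds2) + 5)
  # monotone nondecreasing in the penalty at fixed parameters
  lam_grid <- seq(0, 5, length.out = 11)
  vals <- vapply(lam_grid, function(l) penalized_objective(pars, ds, l),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(penalized_objective(pars, ds, -1), "nonnegative")
})

test_that("latent posterior matches the dense Bayesian oracle", {
  pars0 <- grn_params(matrix(0, 3, 0), matrix(0, 3, 2), rep(0, 3), 1)
  post0 <- posterior_latent(pars0, numeric(0), c(1, 2, 3))
  expect_equal(post0$mean, c(0, 0))
  expect_equal(post0$covariance, diag(2))

  pars <- random_params(p = 6, d = 2, q = 2, seed = 12)
  set.seed(13)
  r <- rnorm(2); x <- rnorm(6)
  post <- posterior_latent(pars, r, x)
  C <- marginal_covariance(pars)
  resid <- x - as.numeric(pars$W %*% r) - pars$mu
  mean_dense <- as.numeric(t(pars$Lambda) %*% solve(C, resid))
  expect_equal(post$mean, mean_dense, tolerance = 1e-8)

  # large noise pulls the posterior mean back to the prior
  pars_big <- grn_params(pars$W, pars$Lambda, pars$mu, 1e8)
  expect_lt(max(abs(posterior_latent(pars_big, r, x)$mean)), 1e-5)

  pars_q0 <- random_params(p = 4, d = 1, q = 0, seed = 14)
  post_q0 <- posterior_latent(pars_q0, 0.5, rnorm(4))
  expect_length(post_q0$mean, 0)
})

test_that("NLL is invariant to sign flips and column permutations of Lambda", {
  pars <- random_params(p = 7, d = 1, q = 3, seed = 15)
  ds <- random_dataset(p = 7, d = 1, N = 10, seed = 16)
  base <- negative_log_likelihood(pars, ds)
  flipped <- grn_params(pars$W, pars$Lambda %*% diag(c(-1, 1, -1)),
                        pars$mu, pars$sigma2)
  permuted <- grn_params(pars$W, pars$Lambda[, c(3, 1, 2)],
                         pars$mu, pars$sigma2)
  expect_equal(negative_log_likelihood(flipped, ds), base, tolerance = 1e-12)
  expect_equal(negative_log_likelihood(permuted, ds), base, tolerance = 1e-12)
})

test_that("flatten/unflatten round-trips and the mask covers W and Lambda", {
  pars <- random_params(p = 3, d = 2, q = 2, seed = 17)
  theta <- flatten_params(pars)
  back <- unflatten_params(theta, 3, 2, 2)
  expect_equal(back$W, pars$W)
  expect_equal(back$Lambda, pars$Lambda)
  expect_equal(back$mu, pars$mu)
  expect_equal(back$sigma2, pars$sigma2)
  mask <- penalty_mask(3, 2, 2)
  expect_equal(sum(mask), 3 * 4)
  expect_false(any(mask[(3 * 4 + 1):length(mask)]))
})
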