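test_that("unpenalized fit with q = 0 reduces to per-gene OLS", {
  sim <- simulate_grn_data(p = 8, d = 3, q = 0, N = 60, w_density = 0.3,
                           seed = 5)
  fit <- grn_fit(sim$data, q = 0, penalty = 0, n_restarts = 1,
                 max_iter = 2000, tol = 1e-12, seed = 2)
  X <- sim$data$X; R <- sim$data$R
  coefs <- t(vapply(seq_len(8), function(j) {
    stats::lm.fit(cbind(1, R), X[, j])$coefficients
  }, numeric(4)))
  expect_equal(fit$params$W, unname(coefs[, -1]), tolerance = 1e-6)
  expect_equal(fit$params$mu, unname(coefs[, 1]), tolerance = 1e-6)
  resid <- X - tcrossprod(R, fit$params$W) -
    matrix(fit$params$mu, 60, 8, byrow = TRUE)
  expect_equal(fit$params$sigma2, mean(resid^2), tolerance = 1e-6)
})

test_that("unpenalized fit with d = 0 recovers the PPCA closed form", {
  sim <- simulate_grn_data(p = 10, d = 0, q = 2, N = 150,
                           lambda_density = 1, seed = 9)
  fit <- grn_fit(sim$data, q = 2, penalty = 0, n_restarts = 2,
                 max_iter = 3000, tol = 1e-12, seed = 4)
  X <- sim$data$X
  S <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
  ev <- eigen(S, symmetric = TRUE)
  expect_equal(fit$params$sigma2, mean(ev$values[3:10]), tolerance = 1e-6)
  Q1 <- qr.Q(qr(fit$params$Lambda))
  Q2 <- ev$vectors[, 1:2]
  principal_angle <- acos(min(pmin(svd(crossprod(Q1, Q2))$d, 1)))
  expect_lt(principal_angle, 1e-3)
})

test_that("no-signal data with a large penalty yields an empty network", {
  sim <- simulate_grn_data(p = 6, d = 2, q = 1, N = 50, w_density = 0,
                           lambda_density = 0, sigma = 0.3, seed = 31)
  fit <- grn_fit(sim$data, q = 1, penalty = 500, n_restarts = 2, seed = 3)
  expect_true(all(fit$params$W == 0))
  expect_true(all(fit$params$Lambda == 0))
  expect_equal(fit$params$mu, unname(colMeans(sim$data$X)), tolerance = 0.05)
})

test_that("reference model uses per-gene Gaussian MLEs with a variance floor", {
  X <- cbind(G1 = c(0, 2, 0, 2), G2 = rep(5, 4))
  ds <- expression_dataset(X)
  ref <- fit_reference_model(ds)
  expect_equal(unname(ref$mean), c(1, 5))
  expect_equal(unname(ref$variance[1]), 1)       # MLE denominator N
  expect_gt(ref$variance[2], 0)                  # floored, not zero
  # held-out log-likelihood is the sum of univariate normal log-densities
  ds_test <- expression_dataset(cbind(G1 = c(0.5, 1.5), G2 = c(5, 6)))
  manual <- sum(stats::dnorm(c(0.5, 1.5), 1, 1, log = TRUE)) +
    sum(stats::dnorm(c(5, 6), 5, sqrt(ref$variance[2]), log = TRUE))
  expect_equal(out_of_sample_loglik(ref, ds_test), manual)
})

test_that("out-of-sample log-likelihood nests the simpler models", {
  sim <- simulate_grn_data(p = 6, d = 2, q = 2, N = 40, seed = 41)
  fit <- grn_fit(sim$data, q = 2, penalty = 5, n_restarts = 1, seed = 5)
  # evaluating the training data equals minus the training NLL
  expect_equal(out_of_sample_loglik(fit, sim$data),
               -negative_log_likelihood(fit$params, sim$data))
  # a full model with Lambda = 0 equals the no-hidden model with same W
  pars0 <- grn_params(fit$params$W, matrix(0, 6, 2), fit$params$mu,
                      fit$params$sigma2)
  pars_nh <- grn_params(fit$params$W, matrix(0, 6, 0), fit$params$mu,
                        fit$params$sigma2)
  expect_equal(negative_log_likelihood(pars0, sim$data),
               negative_log_likelihood(pars_nh, sim$data), tolerance = 1e-10)
  expect_error(out_of_sample_loglik(fit, random_dataset(6, 2, 5, 1)),
               "identifiers")
})

test_that("model archive round-trips through JSON", {
  sim <- simulate_grn_data(p = 5, d = 2, q = 1, N = 30, seed = 51)
  fit <- grn_fit(sim$data, q = 1, penalty = 3, n_restarts = 1, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_grn_model(fit, path)
  back <- read_grn_model(path)
  expect_equal(back$params$W, fit$params$W)
  expect_equal(back$params$Lambda, fit$params$Lambda)
  expect_equal(back$params$mu, fit$params$mu)
  expect_equal(back$params$sigma2, fit$params$sigma2)
  expect_equal(back$gene_ids, fit$gene_ids)
  expect_equal(back$penalty, fit$penalty)
  # archives evaluate identically
  expect_equal(out_of_sample_loglik(back, sim$data),
               out_of_sample_loglik(fit, sim$data))
})

test_that("support refit removes shrinkage while keeping exact zeros", {
  sim <- simulate_grn_data(p = 8, d = 3, q = 0, N = 80, w_density = 0.2,
                           seed = 61)
  fit <- grn_fit(sim$data, q = 0, penalty = 30, n_restarts = 1, seed = 7)
  Ws <- fit$params$W != 0
  ref <- refit_support(sim$data, Ws, matrix(FALSE, 8, 0), init = fit$params)
  expect_true(all(ref$W[!Ws] == 0))
  # refitted values equal restricted OLS
  for (j in which(rowSums(Ws) > 0)) {
    s <- which(Ws[j, ])
    ols <- stats::lm.fit(cbind(1, sim$data$R[, s, drop = FALSE]),
                         sim$data$X[, j])$coefficients
    expect_equal(ref$W[j, s], unname(ols[-1]), tolerance = 1e-5)
  }
})
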