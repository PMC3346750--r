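test_that("random connectivity has exactly L-1 zeros per column", {
  mask <- make_random_connectivity(5, 3, seed = 2)
  expect_equal(colSums(!mask), rep(2, 3))
  mask1 <- make_random_connectivity(5, 1, seed = 2)
  expect_true(all(mask1))
  expect_identical(make_random_connectivity(10, 4, seed = 7),
                   make_random_connectivity(10, 4, seed = 7))
  expect_error(make_random_connectivity(2, 4), "p > L - 1")
})

test_that("identifiability criteria detect block and degenerate structures", {
  # disjoint gene blocks: all criteria pass
  mask <- kronecker(diag(3) == 1, matrix(TRUE, 4, 1))
  crit <- check_nca_criteria(mask, N = 10)
  expect_true(crit$all_pass)
  # two regulators with identical full columns: removing one leaves no
  # rows to certify the other
  mask2 <- matrix(TRUE, 6, 2)
  crit2 <- check_nca_criteria(mask2, N = 10)
  expect_false(crit2$reduced_rank_ok)
  expect_false(check_nca_criteria(mask, N = 2)$samples_ok)
  # random masks agree with a dense-rank oracle on the column-rank check
  for (seed in 1:5) {
    m <- make_random_connectivity(50, 5, seed = seed)
    set.seed(seed + 500)
    A <- matrix(rnorm(250), 50, 5) * m
    expect_equal(check_nca_criteria(m, 100, seed = seed + 500)$full_column_rank,
                 qr(A)$rank == 5)
  }
})

test_that("ALS recovers a planted noise-free decomposition", {
  set.seed(111)
  p <- 40; L <- 4; N <- 60
  # a connectivity well above the minimal L-1 zeros per column: the
  # decomposition is then strongly pinned and ALS reaches the global
  # optimum quickly (minimally sparse masks converge much more slowly)
  mask <- matrix(FALSE, p, L)
  for (j in seq_len(L)) mask[sample.int(p, 12), j] <- TRUE
  expect_true(check_nca_criteria(mask, N)$all_pass)
  A_true <- matrix(rnorm(p * L), p, L) * mask
  A_true <- sweep(A_true, 2, sqrt(colSums(A_true^2)), "/")
  P_true <- matrix(rnorm(L * N), L, N)
  E <- A_true %*% P_true
  model <- nca_decompose(E, mask, seed = 4, max_iter = 500, tol = 1e-12)
  expect_lt(utils::tail(model$reconstruction_error_trace, 1), 1e-8 * sum(E^2))
  cosines <- abs(colSums(model$A * A_true))
  expect_true(all(cosines >= 0.999))
  # zero pattern conserved exactly
  expect_true(all(model$A[!mask] == 0))
  # error trace is nonincreasing
  expect_true(all(diff(model$reconstruction_error_trace) <= 1e-8))
})

test_that("all-true mask with L = 1 is rank-1 least squares", {
  set.seed(112)
  E <- matrix(rnorm(20 * 15), 20, 15)
  model <- nca_decompose(E, matrix(TRUE, 20, 1), seed = 5, max_iter = 500)
  sv <- svd(E)$d
  expect_equal(utils::tail(model$reconstruction_error_trace, 1),
               sum(sv[-1]^2), tolerance = 1e-6)
})

test_that("row permutation of E and mask permutes A identically", {
  set.seed(113)
  p <- 12; L <- 3
  mask <- matrix(FALSE, p, L)
  for (j in seq_len(L)) mask[sample.int(p, 4), j] <- TRUE
  A_true <- matrix(rnorm(p * L), p, L) * mask
  E <- A_true %*% matrix(rnorm(L * 30), L, 30)
  m1 <- nca_decompose(E, mask, seed = 7, max_iter = 500, tol = 1e-12)
  perm <- sample(p)
  m2 <- nca_decompose(E[perm, ], mask[perm, ], seed = 7,
                      max_iter = 500, tol = 1e-12)
  # a decomposable E stays decomposable under a joint row permutation:
  # both runs drive the reconstruction error to zero and respect the
  # permuted zero pattern
  expect_lt(utils::tail(m1$reconstruction_error_trace, 1), 1e-8 * sum(E^2))
  expect_lt(utils::tail(m2$reconstruction_error_trace, 1), 1e-8 * sum(E^2))
  expect_true(all(m2$A[!mask[perm, ]] == 0))
})

test_that("pruning keeps the largest-magnitude edges exactly", {
  set.seed(114)
  mask <- matrix(TRUE, 2, 2)
  model <- structure(list(A = matrix(c(3, 0.5, -1, 2), 2, 2), P = diag(2),
                          mask = mask, reconstruction_error_trace = 1,
                          converged = TRUE),
                     class = "nca_model")
  pruned <- prune_edges(model, 2)
  expect_equal(sum(pruned$A != 0), 2)
  expect_equal(pruned$A[1, 1], 3)
  expect_equal(pruned$A[2, 2], 2)
  same <- prune_edges(model, 4)
  expect_equal(same$A, model$A)
  expect_error(prune_edges(model, -1), ">= 0")
  expect_error(prune_edges(model, 5), "exceeds")
})
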