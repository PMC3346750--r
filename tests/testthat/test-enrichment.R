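test_that("gene sets are the exact nonzero supports of the fitted weights", {
  W <- matrix(c(0, 1.2, 0, 0, 0, -0.5, 0, 0), 4, 2)
  Lambda <- matrix(c(0, 0.3, 0, -0.2), 4, 1)
  pars <- grn_params(W, Lambda, rep(0, 4), 1)
  sets <- extract_gene_sets(pars, gene_ids = paste0("g", 1:4))
  hidden <- sets[sets$type == "hidden", ]
  expect_equal(hidden$members[[1]], c("g2", "g4"))
  tf <- sets[sets$type == "tf", ]
  expect_equal(tf$members[[1]], "g2")
  expect_equal(tf$members[[2]], "g2")
  expect_equal(sum(sets$size), sum(W != 0) + sum(Lambda != 0))
  # all-zero column yields an empty, flagged set
  pars0 <- grn_params(matrix(0, 4, 1), Lambda, rep(0, 4), 1)
  sets0 <- extract_gene_sets(pars0, gene_ids = paste0("g", 1:4))
  expect_equal(sets0$size[sets0$type == "tf"], 0)
})

test_that("fisher enrichment equals the hypergeometric tail", {
  universe <- paste0("g", 1:20)
  categ <- universe[1:5]
  gs <- universe[1:5]
  expect_equal(fisher_enrichment(gs, categ, universe), 1 / choose(20, 5))

  # overlap at the independence expectation is unremarkable
  u100 <- paste0("g", 1:100)
  expect_gt(fisher_enrichment(u100[1:10], u100[10:19], u100), 0.2)
  expect_equal(fisher_enrichment(character(0), categ, universe), 1)

  # enumeration oracle: sum of point masses at or beyond the observed overlap
  set.seed(101)
  for (rep in 1:5) {
    u <- paste0("g", 1:30)
    gs <- sample(u, 8)
    categ <- sample(u, 10)
    k <- length(intersect(gs, categ))
    oracle <- sum(vapply(k:8, function(i) {
      choose(10, i) * choose(20, 8 - i) / choose(30, 8)
    }, numeric(1)))
    expect_equal(fisher_enrichment(gs, categ, u), oracle, tolerance = 1e-12)
  }
})

test_that("best-category scan matches an exhaustive search", {
  set.seed(102)
  universe <- paste0("g", 1:60)
  categories <- lapply(1:50, function(i) sample(universe, sample(5:20, 1)))
  names(categories) <- sprintf("C%02d", 1:50)
  gs <- sample(universe, 12)
  res <- min_category_p(gs, categories, universe)
  oracle_p <- vapply(categories, function(cc) {
    fisher_enrichment(gs, cc, universe)
  }, numeric(1))
  expect_equal(res$raw_p, unname(min(oracle_p)))
  expect_equal(res$best_category,
               sort(names(oracle_p)[oracle_p == min(oracle_p)])[1])

  # a category identical to the gene set wins with the minimal p
  categories$EXACT <- gs
  res2 <- min_category_p(gs, categories, universe)
  expect_equal(res2$best_category, "EXACT")
})

test_that("calibrated p-values behave at the extremes and are multiples of 1/B", {
  set.seed(103)
  universe <- paste0("g", 1:50)
  categories <- lapply(1:10, function(i) sample(universe, 10))
  names(categories) <- sprintf("C%02d", 1:10)
  p0 <- calibrate_p(8, 0, categories, universe, B = 50, seed = 5)
  expect_equal(p0, 0)
  p1 <- calibrate_p(8, 1, categories, universe, B = 50, seed = 5)
  expect_equal(p1, 1)
  pm <- calibrate_p(8, 0.05, categories, universe, B = 50, seed = 5)
  expect_equal(pm * 50, round(pm * 50))
  # conservative variant never returns 0
  pc <- calibrate_p(8, 0, categories, universe, B = 50, seed = 5,
                    conservative = TRUE)
  expect_equal(pc, 1 / 51)
  expect_error(calibrate_p(51, 0.5, categories, universe, B = 10, seed = 1),
               "universe")
})

test_that("BH q-values match the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(104)
  for (rep in 1:3) {
    p <- runif(20)
    o <- order(p)
    m <- 20
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- numeric(m)
    oracle[o] <- pmin(q_sorted, 1)
    expect_equal(bh_fdr(p), oracle)
  }
  # monotone in the p-value ordering
  p <- runif(15)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("planted categories are detected and the pipeline is reproducible", {
  sim <- simulate_grn_data(p = 120, d = 0, q = 2, N = 50,
                           lambda_density = 0.25, seed = 105)
  coll <- simulate_category_collection(sim$data$gene_ids, sim$truth,
                                       n_noise_categories = 15, seed = 105)
  expect_equal(sum(startsWith(names(coll$categories), "PLANTED")), 2)
  sets <- tibble::tibble(
    source = c("H01", "H02"),
    members = list(sim$data$gene_ids[sim$truth$Lambda_support[, 1]],
                   sim$data$gene_ids[sim$truth$Lambda_support[, 2]]))
  res <- enrich_gene_sets(sets, coll$categories, universe = coll$universe,
                          B = 200, seed = 7)
  expect_equal(nrow(res), 2)
  expect_true(all(startsWith(res$best_category, "PLANTED")))
  expect_true(all(res$raw_p < 1e-6))
  expect_true(all(res$calibrated_p == 0))
  res2 <- enrich_gene_sets(sets, coll$categories, universe = coll$universe,
                           B = 200, seed = 7)
  expect_identical(res, res2)
})
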