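test_that("the generator is deterministic given a seed", {
  a <- generate_study(seed = 3L)
  b <- generate_study(seed = 3L)
  expect_identical(a$study$values, b$study$values)
  expect_identical(a$truth, b$truth)
  c2 <- generate_study(seed = 4L)
  expect_false(identical(a$study$values, c2$study$values))
})

test_that("parameter validation catches infeasible targets", {
  expect_error(synthetic_params(rho_in = 1.2), "rho_in")
  expect_error(synthetic_params(rho_switch = 0.3), "rho_switch")
  expect_error(synthetic_params(rho_in = 0.3, rho_switch = -0.9),
               "infeasible")
  expect_error(synthetic_params(n_genes = 100L), "exceed")
  expect_error(synthetic_params(periphery_loading = 1.5), "periphery_loading")
})

test_that("planted correlations hit their targets", {
  # shift = 0 isolates the correlation structure from differential expression
  p <- synthetic_params(shift = 0)
  sim <- generate_study(p, seed = 1L)
  tr <- sim$truth
  ctrl <- sim$study$values
  for (m in seq_along(p$module_sizes)) {
    mg <- names(tr$module)[tr$module == m]
    cc <- stats::cor(t(ctrl[mg, ]))
    expect_lt(abs(mean(cc[upper.tri(cc)]) - p$rho_in), 0.05)
  }
  # switch module: internally rho_in, anti-correlated with module 1
  swc <- stats::cor(t(ctrl[tr$switch_genes, ]))
  expect_lt(abs(mean(swc[upper.tri(swc)]) - p$rho_in), 0.05)
  m1 <- names(tr$module)[tr$module == 1L]
  cross <- stats::cor(t(ctrl[tr$switch_genes, ]), t(ctrl[m1, ]))
  expect_lt(abs(mean(cross) - p$rho_switch), 0.05)
  # periphery sits well below the module correlations
  pg <- tr$periphery_genes[1:120]
  core <- names(tr$module)[tr$module == length(p$module_sizes)][1:50]
  pc <- stats::cor(t(ctrl[pg, ]), t(ctrl[core, ]))
  expect_lt(mean(pc), 0.5)
  expect_gt(mean(pc), 0.1)
})

test_that("per-gene variances track the model-implied values", {
  sim <- generate_study(seed = 2L)
  sv <- apply(sim$study$values, 1L, stats::var)
  mv <- sim$truth$model_variance
  n <- ncol(sim$study$values)
  mc_sd <- mv * sqrt(2 / (n - 1))
  expect_gt(mean(abs(sv - mv) < 3 * mc_sd), 0.99)
})

test_that("planted shifts appear in the truth bookkeeping", {
  sim <- generate_study(seed = 5L)
  tr <- sim$truth
  expect_setequal(tr$deg_genes, names(tr$shift)[tr$shift != 0])
  expect_true(all(tr$switch_genes %in% tr$deg_genes))
  expect_equal(length(tr$switch_genes), tr$params$n_switch)
  expect_true(all(tr$shift[names(tr$module)[tr$module == 1L]] < 0))
  expect_true(all(tr$shift[tr$switch_genes] > 0))
})

test_that("synthetic interactomes are connected, simple and scale-free", {
  gi <- generate_interactome(n_nodes = 800L, seed = 6L)
  expect_true(igraph::is_connected(gi$graph))
  expect_true(igraph::is_simple(gi$graph))
  expect_gt(scale_free_fit(gi$graph)$signed_r2, 0.8)
  expect_length(gi$truth$proximal_a, gi$truth$set_size)
  # proximal sets are disjoint and pairwise adjacent by construction
  expect_length(intersect(gi$truth$proximal_a, gi$truth$proximal_b), 0)
  d <- igraph::distances(gi$graph, v = gi$truth$proximal_a,
                         to = gi$truth$proximal_b)
  expect_true(all(apply(d, 1L, min) == 1))
  expect_error(generate_interactome(n_nodes = 3L, attachment_m = 3L),
               "exceed")
})

test_that("fixtures are identical across calls", {
  a <- fixture_suite()
  b <- fixture_suite()
  expect_identical(a$two_block, b$two_block)
  expect_identical(igraph::as_edgelist(a$switch_toy$network$graph),
                   igraph::as_edgelist(b$switch_toy$network$graph))
})
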