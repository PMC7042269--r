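test_that("k-means recovers the two-block fixture exactly", {
  tb <- fixture_suite()$two_block
  km <- kmeans_modules(tb$values, k = 2, seed = 1L)
  # same partition up to label switching
  expect_equal(mclust::adjustedRandIndex(km$labels, tb$truth), 1)
  # labels are 1..k ordered by decreasing size
  expect_true(all(sort(unique(km$labels)) == seq_along(km$sizes)))
  expect_true(all(diff(km$sizes) <= 0))
})

test_that("k-means is deterministic given a seed", {
  set.seed(30)
  vals <- matrix(rnorm(300), 30, 10,
                 dimnames = list(paste0("g", 1:30), NULL))
  a <- kmeans_modules(vals, 3, seed = 7L)
  b <- kmeans_modules(vals, 3, seed = 7L)
  expect_identical(a$labels, b$labels)
  expect_identical(a$sse, b$sse)
})

test_that("scree SSE is monotone and the elbow finds planted k", {
  sim <- generate_study(synthetic_params(
    n_genes = 90L, n_cases = 20L, n_controls = 20L,
    module_sizes = c(30L, 30L, 30L), n_switch = 0L, n_periphery = 0L,
    shift = 0), seed = 5L)
  sc <- scree(sim$study$values, k_range = 1:6, seed = 2L)
  expect_true(all(diff(sc$table$sse) <= 1e-8))
  expect_equal(sc$elbow, 3L)
})

test_that("eigengene orients with the module mean and explains variance", {
  tb <- fixture_suite()$two_block
  block1 <- tb$values[1:5, ]
  eg <- eigengene(block1)
  # the block is a rank-1 pattern plus per-gene offsets; after z-scoring it
  # is exactly rank 1
  expect_equal(eg$var_explained[1L], 100, tolerance = 1e-8)
  expect_gt(stats::cor(eg$eigengene, rowMeans(scale(t(block1)))), 0.999)
  # membership of members is +/-1 in a rank-1 block
  mm <- vapply(1:5, function(i) module_membership(block1[i, ], eg$eigengene),
               numeric(1))
  expect_equal(abs(mm), rep(1, 5), tolerance = 1e-8)
  one <- eigengene(block1[1, , drop = FALSE])
  expect_equal(one$var_explained, 100)
})

test_that("eigengene condition test detects a shifted module", {
  set.seed(6)
  eg <- c(rnorm(15), rnorm(15) + 3)
  condition <- rep(c(0L, 1L), each = 15)
  ht <- eigengene_condition_test(eg, condition)
  expect_lt(ht$p, 1e-4)
  expect_equal(ht$direction, "up")
  flat <- eigengene_condition_test(rep(1, 30), condition)
  expect_equal(flat$p, 1)
})

test_that("hierarchical cross-check agrees on clean modules", {
  tb <- fixture_suite()$two_block
  labels <- stats::setNames(kmeans_modules(tb$values, 2)$labels,
                            rownames(tb$values))
  hc <- hierarchical_crosscheck(tb$values, labels)
  expect_equal(hc$ari, 1)
  expect_equal(unname(hc$module_jaccard), c(1, 1))
})

test_that("signature_overlap counts members and mean fold-change", {
  sets <- list(SIG1 = c("g1", "g2", "zz"), SIG2 = c("nope"))
  degs <- data.frame(gene = c("g1", "g2"), fc = c(2, 4))
  ov <- signature_overlap(c("g1", "g2", "g3"), sets, degs)
  expect_equal(ov$overlap, c(2, 0))
  expect_equal(ov$mean_fc[1], 3)
  expect_equal(ov$members[1], "g1,g2")
})

test_that("module_partition bundles labels, eigengenes and tests", {
  sim <- generate_study(synthetic_params(
    n_genes = 120L, n_cases = 15L, n_controls = 15L,
    module_sizes = c(40L, 40L), n_switch = 0L, n_periphery = 0L),
    seed = 9L)
  cc <- pearson_matrix(sim$study$values)
  net <- build_network(cc, percentile_threshold(cc, 95))
  part <- module_partition(sim$study, net, k = 2, seed = 3L)
  expect_s3_class(part, "module_partition")
  expect_equal(part$k, 2L)
  expect_equal(nrow(part$eigengenes), 2L)
  expect_length(part$membership, length(part$labels))
  # module genes correlate strongly with their own eigengene
  expect_gt(stats::median(abs(part$membership), na.rm = TRUE), 0.7)
  expect_length(part$condition_tests, 2L)
})
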