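test_that("edge shuffling preserves degree sequences in every replicate", {
  rg <- random_signed_graph(80L, 0.06, seed = 17L)
  net <- network_from_edges(rg$edges)
  for (s in 1:25) {
    shuf <- degree_preserving_shuffle(net, seed = s)
    expect_identical(shuf$nodes, net$nodes)
    expect_equal(shuf$degree, net$degree)
    expect_true(igraph::is_simple(shuf$graph))
    # multiset of edge weights is preserved
    expect_equal(sort(igraph::E(shuf$graph)$rho),
                 sort(igraph::E(net$graph)$rho))
  }
})

test_that("edge shuffling actually mixes the wiring", {
  set.seed(99)
  g <- igraph::sample_pa(100, m = 3, directed = FALSE)
  igraph::V(g)$name <- paste0("v", 1:100)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2], rho = 0.9)
  net <- network_from_edges(edges)
  shuf <- degree_preserving_shuffle(net, seed = 1L)
  key <- function(n) {
    e <- igraph::as_edgelist(n$graph, names = TRUE)
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  a <- key(net); b <- key(shuf)
  jac <- length(intersect(a, b)) / length(union(a, b))
  expect_lt(jac, 0.5)
  # reproducible under the same seed
  expect_identical(key(degree_preserving_shuffle(net, seed = 1L)), b)
})

test_that("a triangle admits no valid swap and returns unchanged", {
  edges <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                      rho = c(0.5, 0.6, 0.7))
  net <- network_from_edges(edges)
  shuf <- degree_preserving_shuffle(net, n_swaps = 500L, seed = 2L)
  key <- function(n) {
    e <- igraph::as_edgelist(n$graph, names = TRUE)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(key(shuf), key(net))
})

test_that("null_summary computes z and pseudo-count empirical p", {
  ns <- null_summary(8, c(1, 2, 3, 4), sided = "upper")
  expect_equal(ns$mean, 2.5)
  expect_equal(ns$z, (8 - 2.5) / stats::sd(1:4))
  expect_equal(ns$p_empirical, 1 / 5)
  expect_equal(ns$p, z_to_p(ns$z, "upper"))
  # degenerate null distribution
  flat <- null_summary(3, rep(3, 10))
  expect_equal(flat$z, 0)
  hi <- null_summary(5, rep(3, 10))
  expect_identical(hi$z, Inf)
  expect_lte(hi$p, 1 / 10)
})

test_that("set-overlap null matches hypergeometric moments", {
  universe <- sprintf("u%03d", 1:400)
  target <- universe[1:60]
  draw <- 50L
  ns <- geneset_overlap_null(universe, draw, target, observed = 20,
                             reps = 2000L, seed = 4L, sided = "upper")
  N <- 400; K <- 60; n <- draw
  hyper_mean <- n * K / N
  hyper_var <- n * K / N * (N - K) / N * (N - n) / (N - 1)
  mc_sd_mean <- sqrt(hyper_var / 2000)
  expect_lt(abs(ns$mean - hyper_mean), 3 * mc_sd_mean)
  # variance of a sample variance ~ 2 sigma^4 / (n - 1) for near-normal nulls
  expect_lt(abs(ns$sd^2 - hyper_var), 3 * sqrt(2 * hyper_var^2 / 1999))
  # exact calibration of the empirical p against phyper
  p_exact <- stats::phyper(20 - 1, K, N - K, n, lower.tail = FALSE)
  expect_lt(abs(ns$p_empirical - p_exact), 0.01)
})

test_that("switch_count_null sees the toy's observed count as exceptional", {
  toy <- fixture_suite()$switch_toy
  ns <- switch_count_null(toy$network, toy$labels, reps = 200L, seed = 3L)
  expect_equal(ns$observed, 1)
  expect_s3_class(ns, "null_summary")
  expect_equal(ns$reps, 200L)
  expect_true(all(ns$samples >= 0))
})

test_that("neighbor_shuffle_null returns calibrated two-sided machinery", {
  toy <- fixture_suite()$switch_toy
  res <- neighbor_shuffle_null("sw", toy$network,
                               target_set = c("e1", "e2", "a1"),
                               reps = 300L, seed = 5L)
  expect_equal(res$observed[["negative"]], 3)
  expect_equal(res$observed[["positive"]], 0)
  expect_s3_class(res$negative, "null_summary")
  # with 8 of 11 candidates drawn each replicate, nulls are large too
  expect_true(all(res$negative$samples <= 3))
  expect_error(neighbor_shuffle_null(character(0), toy$network, "e1"),
               "empty")
})

test_that("z_to_p covers all sidedness conventions", {
  expect_equal(z_to_p(1.96, "upper"), stats::pnorm(-1.96), tolerance = 1e-12)
  expect_equal(z_to_p(-1, "lower"), stats::pnorm(-1))
  expect_equal(z_to_p(2, "two"), 2 * stats::pnorm(-2))
})
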