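test_that("pearson_matrix matches cor() and drops constant genes", {
  set.seed(4)
  vals <- matrix(rnorm(50), 10, 5,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  expect_equal(pearson_matrix(vals), stats::cor(t(vals)))
  vals[4, ] <- 3
  expect_warning(cc <- pearson_matrix(vals), "zero.variance|constant")
  expect_false("g4" %in% rownames(cc))
  expect_error(pearson_matrix(vals[, 1:2]), "3 samples")
})

test_that("percentile_threshold is the quantile of |rho| over distinct pairs", {
  set.seed(8)
  vals <- matrix(rnorm(120), 12, 10)
  rownames(vals) <- paste0("g", 1:12)
  cc <- pearson_matrix(vals)
  v <- abs(cc[upper.tri(cc)])
  expect_equal(percentile_threshold(cc, 90),
               unname(stats::quantile(v, 0.9)))
  expect_equal(percentile_threshold(cc, 100), max(v))
})

test_that("build_network keeps strict exceedances with signed weights", {
  cc <- diag(3)
  rownames(cc) <- colnames(cc) <- c("a", "b", "c")
  cc["a", "b"] <- cc["b", "a"] <- -0.9
  cc["a", "c"] <- cc["c", "a"] <- 0.5
  cc["b", "c"] <- cc["c", "b"] <- 0.2
  net <- build_network(cc, 0.5)         # strict: the 0.5 pair is excluded
  expect_setequal(net$nodes, c("a", "b"))
  expect_equal(igraph::ecount(net$graph), 1)
  expect_equal(igraph::E(net$graph)$rho, -0.9)
  expect_warning(build_network(cc, 0.95), "empty|no ")
})

test_that("edge sets shrink monotonically as tau grows", {
  set.seed(12)
  vals <- matrix(rnorm(200), 20, 10)
  rownames(vals) <- paste0("g", 1:20)
  cc <- pearson_matrix(vals)
  taus <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  edge_key <- function(net) {
    if (!length(net$nodes)) return(character(0))
    el <- igraph::as_edgelist(net$graph, names = TRUE)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  prev <- NULL
  for (tau in taus) {
    cur <- edge_key(suppressWarnings(build_network(cc, tau)))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("scale_free_fit signs R2 by the slope and handles flat input", {
  # decaying: P(k) proportional to k^-2 over k = 1..6
  k <- 1:6
  pk <- k^-2 / sum(k^-2)
  deg <- rep(k, round(pk * 2000))
  fit <- scale_free_fit(stats::setNames(deg, seq_along(deg)))
  expect_gt(fit$signed_r2, 0.99)
  expect_equal(fit$alpha, 2, tolerance = 0.01)
  # increasing P(k): slope positive, so signed R2 < 0
  fit2 <- scale_free_fit(rep(1:5, times = c(1, 2, 4, 8, 16)))
  expect_lt(fit2$signed_r2, 0)
  expect_warning(one <- scale_free_fit(rep(3L, 10)), "distinct degrees")
  expect_true(is.nan(one$signed_r2))
})

test_that("sweep_thresholds recommends the smallest qualifying tau", {
  gi <- generate_interactome(n_nodes = 400L, seed = 3L)
  # turn the BA graph into a fake correlation matrix: adjacency scaled
  adj <- igraph::as_adjacency_matrix(gi$graph, sparse = FALSE)
  cc <- adj * 0.9
  diag(cc) <- 1
  sw <- suppressWarnings(sweep_thresholds(cc, percentiles = c(50, 90)))
  expect_s3_class(sw, "data.frame")
  expect_lte(sum(sw$recommended), 1)
  if (any(sw$recommended)) {
    ok <- !is.na(sw$signed_r2) & sw$signed_r2 > 0.8 &
      sw$giant_fraction >= 0.75
    expect_equal(which(sw$recommended), which(ok)[which.min(sw$tau[ok])])
  }
  expect_error(sweep_thresholds(cc, percentiles = numeric(0)), "grid")
})

test_that("network_from_edges preserves names and attributes", {
  toy <- fixture_suite()$switch_toy
  net <- toy$network
  expect_s3_class(net, "correlation_network")
  expect_equal(length(net$nodes), 12)
  expect_equal(unname(net$degree[["sw"]]), 8)
  expect_true(all(abs(igraph::E(net$graph)$rho) > net$tau))
})
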