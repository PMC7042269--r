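test_that("cartography matches the brute-force oracle on random graphs", {
  for (s in 1:10) {
    rg <- random_signed_graph(60L, 0.08, n_modules = 4L, seed = s)
    net <- network_from_edges(rg$edges)
    np <- network_parts(net)
    labels <- rg$labels[np$nodes]
    carto <- node_cartography(net, labels)
    oc <- oracle_cartography(np$nodes, np$edges, labels)
    i <- match(carto$gene, np$nodes)
    expect_equal(carto$k, unname(oc$k[i]), tolerance = 1e-12)
    expect_equal(carto$k_in, unname(oc$k_in[i]), tolerance = 1e-12)
    expect_equal(carto$apcc, unname(oc$apcc[i]), tolerance = 1e-12)
    expect_equal(carto$z_g, unname(oc$z_g[i]), tolerance = 1e-12)
    expect_equal(carto$k_pi, unname(oc$k_pi[i]), tolerance = 1e-12)
  }
})

test_that("the 12-node toy yields exactly its designed switch gene", {
  toy <- fixture_suite()$switch_toy
  carto <- node_cartography(toy$network, toy$labels)
  expect_identical(carto$gene[carto$switch], toy$expected_switch)
  sw <- carto[carto$gene == "sw", ]
  expect_equal(sw$k, 8)
  expect_equal(sw$k_in, 1)
  expect_lt(sw$apcc, 0)
  expect_lt(sw$z_g, 2.5)
  expect_gt(sw$k_pi, 0.8)
  expect_equal(sw$class, "fight-club")
  expect_equal(sw$region, "R4")
  tab <- extract_switch_genes(carto)
  expect_equal(tab$gene, "sw")
})

test_that("classification is invariant to module relabeling", {
  toy <- fixture_suite()$switch_toy
  relab <- c(`1` = 9L, `2` = 4L)[as.character(toy$labels)]
  names(relab) <- names(toy$labels)
  a <- node_cartography(toy$network, toy$labels)
  b <- node_cartography(toy$network, relab)
  expect_equal(a$z_g, b$z_g)
  expect_equal(a$class, b$class)
  expect_equal(a$switch, b$switch)
})

test_that("clusterphobic coefficient closed forms hold", {
  expect_equal(clusterphobic(5, 5), 0)   # all edges internal
  expect_equal(clusterphobic(0, 7), 1)   # all edges external
  expect_equal(clusterphobic(3, 6), 1 - 0.25)
})

test_that("hub classes split on degree and APCC as defined", {
  df <- data.frame(gene = letters[1:4], module = 1L,
                   k = c(3L, 10L, 10L, 10L), k_in = 1L,
                   apcc = c(-0.5, -0.2, 0.3, 0.8),
                   z_g = 0, k_pi = 0.9)
  cls <- classify_hubs(df)
  expect_equal(cls, c("none", "fight-club", "date", "party"))
})

test_that("role regions partition the (K_pi, z_g) plane", {
  df <- data.frame(gene = paste0("g", 1:6), module = 1L, k = 10L, k_in = 5L,
                   apcc = 0.1,
                   z_g = c(0, 0, 0, 0, 3, 3),
                   k_pi = c(0.01, 0.3, 0.7, 0.9, 0.1, 0.9))
  expect_equal(assign_regions(df), c("R1", "R2", "R3", "R4", "R5", "R7"))
})

test_that("positive-only networks cannot contain switch genes", {
  for (s in 1:5) {
    rg <- random_signed_graph(50L, 0.2, seed = s, rho_range = c(0.05, 1))
    net <- network_from_edges(rg$edges)
    labels <- rg$labels[net$nodes]
    carto <- node_cartography(net, labels)
    expect_equal(sum(carto$switch), 0)
    expect_false(any(carto$class == "fight-club"))
  }
})

test_that("accessor helpers agree with the cartography table", {
  toy <- fixture_suite()$switch_toy
  carto <- node_cartography(toy$network, toy$labels)
  expect_equal(apcc(toy$network, "sw"),
               carto$apcc[carto$gene == "sw"])
  expect_equal(within_module_degree(toy$network, toy$labels, "sw"),
               carto$z_g[carto$gene == "sw"])
})

test_that("switch_neighbor_report splits neighbors by correlation sign", {
  toy <- fixture_suite()$switch_toy
  rep <- switch_neighbor_report("sw", toy$network,
                                target_set = c("e1", "e2", "a1", "zzz"))
  expect_setequal(rep$negative_union, c("a1", paste0("e", 1:7)))
  expect_length(rep$positive_union, 0)
  expect_equal(rep$target_in_negative, 3)
  expect_equal(rep$per_gene$n_neg, 8)
  expect_equal(rep$per_gene$n_pos, 0)
})
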