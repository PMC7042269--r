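#' Parameters for the synthetic study generator
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: 3000 genes measured on 60 cases and 40 controls, two strongly
#' correlated core modules of 150 genes (a case-down "partner" module and a
#' case-up module), a 20-gene switch module anti-correlated with the partner
#' module, a 1300-gene weakly correlated "periphery" attached to the last
#' core module, and unstructured noise genes for the remainder.
#'
#' The periphery mirrors the large low-membership modules seen in real
#' co-expression networks: its correlations (about `periphery_loading *
#' sqrt(rho_in)` with the core, `periphery_loading^2` among themselves) form
#' a bulk of weak gene pairs well below the strong planted correlations, so a
#' high-percentile hard threshold lands in the gap between the two
#' populations and the planted structure survives thresholding intact.
#'
#' @param n_genes Total genes.
#' @param n_cases,n_controls Samples per class.
#' @param module_sizes Sizes of the core correlated modules; the first
#'   is the partner (case-down) module. May be `integer(0)` for a
#'   structure-free study.
#' @param n_switch Number of planted switch genes (the switch module).
#' @param n_periphery Number of weakly correlated periphery genes (all
#'   differentially expressed, mixed directions).
#' @param periphery_loading Loading of periphery genes on the last core
#'   module's factor, in `[0, 1)`; 0 makes them independent.
#' @param rho_in Within-module Pearson correlation target, in (0, 1).
#' @param rho_switch Planted switch/partner cross-correlation, in (-1, 0).
#' @param shift Case-vs-control log2 expression shift magnitude.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression level.
#' @return Named list of generator parameters.
#' @export
synthetic_params <- function(n_genes = 3000L, n_cases = 60L, n_controls = 40L,
                             module_sizes = c(150L, 150L), n_switch = 20L,
                             n_periphery = 1300L, periphery_loading = 0.35,
                             rho_in = 0.75, rho_switch = -0.65, shift = 1,
                             baseline_mean = 8, baseline_sd = 1) {
  p <- list(n_genes = n_genes, n_cases = n_cases, n_controls = n_controls,
            module_sizes = as.integer(module_sizes), n_switch = n_switch,
            n_periphery = n_periphery, periphery_loading = periphery_loading,
            rho_in = rho_in, rho_switch = rho_switch, shift = shift,
            baseline_mean = baseline_mean, baseline_sd = baseline_sd)
  if (rho_in <= 0 || rho_in >= 1) stop("rho_in must be in (0, 1)")
  if (n_switch > 0 && (rho_switch >= 0 || rho_switch <= -1))
    stop("rho_switch must be in (-1, 0)")
  if (n_switch > 0 && rho_switch^2 > rho_in^2 + 1e-12)
    stop("infeasible targets: need |rho_switch| <= rho_in ",
         "(switch loadings would exceed unit variance)")
  if (periphery_loading < 0 || periphery_loading >= 1)
    stop("periphery_loading must be in [0, 1)")
  if (sum(p$module_sizes) + n_switch + n_periphery > n_genes)
    stop("module, switch and periphery genes exceed n_genes")
  p
}

#' Generate a synthetic expression study with planted structure
#'
#' Latent-factor model: each core module `m` has a per-sample factor
#' `f_m ~ N(0, 1)`; a member gene is `sqrt(rho_in) * f_m + noise` with noise
#' variance `1 - rho_in`, so within-module correlations equal `rho_in` in
#' expectation. Planted switch genes load positively on the switch-module
#' factor and negatively on the partner module's factor (loadings chosen so
#' that switch-switch correlation is `rho_in` and switch-partner correlation
#' is `rho_switch < 0`), and carry a positive case shift while partner-module
#' genes carry a negative one. Periphery genes load `periphery_loading` on
#' the last core module's factor and carry case shifts of alternating sign;
#' the remaining genes are pure noise. A per-gene baseline places values on a
#' log2-like scale. Case shifts are added after the correlation structure, so
#' differential expression and network structure are independently tunable.
#'
#' @param params A [synthetic_params()] list.
#' @param seed RNG seed.
#' @return List with `study` (an [expression_study()]) and `truth`: planted
#'   `module` labels per gene (0 = unstructured or periphery; the switch
#'   module is the highest label), `shift` per gene (log2 units, case minus
#'   control), `deg_genes`, `switch_genes`, `periphery_genes`,
#'   `model_variance` (model-implied per-gene sample variance), and `params`.
#' @export
generate_study <- function(params = synthetic_params(), seed = 1L) {
  set.seed(seed)
  n <- params$n_cases + params$n_controls
  condition <- c(rep(0L, params$n_controls), rep(1L, params$n_cases))
  n_mod <- length(params$module_sizes)
  has_switch <- params$n_switch > 0L
  k_factors <- n_mod + as.integer(has_switch)
  fac <- if (k_factors) matrix(stats::rnorm(k_factors * n), k_factors, n) else NULL

  genes <- sprintf("G%05d", seq_len(params$n_genes))
  module <- integer(params$n_genes)
  shift <- numeric(params$n_genes)
  b <- sqrt(params$rho_in)
  noise_sd <- sqrt(1 - params$rho_in)

  vals <- matrix(stats::rnorm(params$n_genes * n, sd = 1), params$n_genes, n)
  pos <- 0L
  for (m in seq_len(n_mod)) {
    ix <- pos + seq_len(params$module_sizes[m])
    pos <- pos + params$module_sizes[m]
    module[ix] <- m
    vals[ix, ] <- b * matrix(fac[m, ], length(ix), n, byrow = TRUE) +
      noise_sd * vals[ix, ]
    shift[ix] <- if (m == 1L) -params$shift else params$shift
  }
  switch_genes <- character(0)
  if (has_switch) {
    ix <- pos + seq_len(params$n_switch)
    pos <- pos + params$n_switch
    module[ix] <- n_mod + 1L
    a <- if (n_mod >= 1L) abs(params$rho_switch) / b else 0
    cload <- sqrt(params$rho_in - a^2)
    f_sw <- fac[k_factors, ]
    load <- cload * matrix(f_sw, length(ix), n, byrow = TRUE)
    if (n_mod >= 1L)
      load <- load - a * matrix(fac[1L, ], length(ix), n, byrow = TRUE)
    vals[ix, ] <- load + noise_sd * vals[ix, ]
    shift[ix] <- params$shift
    switch_genes <- genes[ix]
  }
  periphery_genes <- character(0)
  if (params$n_periphery > 0L) {
    ix <- pos + seq_len(params$n_periphery)
    pos <- pos + params$n_periphery
    w <- if (n_mod >= 1L) params$periphery_loading else 0
    if (w > 0)
      vals[ix, ] <- w * matrix(fac[n_mod, ], length(ix), n, byrow = TRUE) +
        sqrt(1 - w^2) * vals[ix, ]
    shift[ix] <- params$shift * rep_len(c(1, -1), length(ix))
    periphery_genes <- genes[ix]
  }
  vals <- vals + outer(shift, condition)
  baseline <- stats::rnorm(params$n_genes, params$baseline_mean,
                           params$baseline_sd)
  vals <- vals + baseline
  dimnames(vals) <- list(genes, sprintf("S%03d", seq_len(n)))

  pq <- with(params, n_cases * n_controls / (n_cases + n_controls)^2)
  model_var <- 1 + shift^2 * pq
  study <- expression_study(vals, condition)
  truth <- list(module = stats::setNames(module, genes),
                shift = stats::setNames(shift, genes),
                deg_genes = genes[shift != 0],
                switch_genes = switch_genes,
                periphery_genes = periphery_genes,
                model_variance = stats::setNames(model_var, genes),
                params = params, seed = seed)
  list(study = study, truth = truth)
}

#' Generate a synthetic scale-free interactome with planted gene sets
#'
#' Builds a preferential-attachment (Barabasi-Albert) backbone, then plants
#' (a) a "proximal" pair of gene sets along a random matching of edges -- each
#' set holds one endpoint of every matched edge, so the two sets interleave
#' in the same neighborhood and their separation is negative -- and (b) a
#' "separated" pair placed in two mutually distant neighborhoods, giving
#' positive separation.
#'
#' @param n_nodes Number of nodes (default 2000).
#' @param attachment_m Edges added per new node (default 3).
#' @param set_size Size of each planted set (default 20).
#' @param seed RNG seed.
#' @return List with `graph` (igraph, node names `P0001`...) and `truth`:
#'   `proximal_a`, `proximal_b`, `separated_a`, `separated_b`, parameters.
#' @export
generate_interactome <- function(n_nodes = 2000L, attachment_m = 3L,
                                 set_size = 20L, seed = 1L) {
  if (n_nodes <= attachment_m) stop("n_nodes must exceed attachment_m")
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, power = 1, m = attachment_m,
                         directed = FALSE)
  igraph::V(g)$name <- sprintf("P%04d", seq_len(n_nodes))
  # proximal pair: a random matching of edges; A gets one endpoint, B the
  # other, so every A gene sits at distance 1 from a B gene
  el <- igraph::as_edgelist(g, names = TRUE)
  used <- character(0)
  prox_a <- character(0); prox_b <- character(0)
  for (i in sample.int(nrow(el))) {
    if (length(prox_a) >= set_size) break
    u <- el[i, 1L]; v <- el[i, 2L]
    if (u %in% used || v %in% used) next
    prox_a <- c(prox_a, u); prox_b <- c(prox_b, v)
    used <- c(used, u, v)
  }
  # separated pair: the set_size nodes nearest to each of two far-apart seeds
  d0 <- igraph::distances(g, v = igraph::V(g)$name[1L])[1L, ]
  u <- names(which.max(d0))
  du <- igraph::distances(g, v = u)[1L, ]
  v <- names(which.max(du))
  dv <- igraph::distances(g, v = v)[1L, ]
  sep_a <- names(sort(du))[seq_len(set_size)]
  sep_b <- setdiff(names(sort(dv)), sep_a)[seq_len(set_size)]
  list(graph = g,
       truth = list(proximal_a = prox_a, proximal_b = prox_b,
                    separated_a = sep_a, separated_b = sep_b,
                    n_nodes = n_nodes, attachment_m = attachment_m,
                    set_size = set_size, seed = seed))
}

#' Hand-checkable fixtures shared across the test suite
#'
#' Deterministic small objects: a 3-node path graph, a two-block expression
#' matrix with perfectly correlated blocks, and a 12-node network with module
#' labels in which exactly one node satisfies the switch-gene definition
#' (degree 8, one internal edge, all incident correlations negative).
#'
#' @param seed RNG seed for the randomized pieces.
#' @return Named list: `path3` (igraph), `two_block` (list `values`,
#'   `truth` labels), `switch_toy` (list `network`, `labels`,
#'   `expected_switch`).
#' @export
fixture_suite <- function(seed = 1L) {
  set.seed(seed)
  path3 <- igraph::make_graph(~ a - b - c)

  f1 <- stats::rnorm(8); f2 <- stats::rnorm(8)
  blk <- rbind(
    t(vapply(1:5, function(i) (0.5 + i / 4) * f1 + i, numeric(8))),
    t(vapply(1:5, function(i) (0.5 + i / 4) * f2 - i, numeric(8))))
  rownames(blk) <- sprintf("B%02d", 1:10)
  colnames(blk) <- sprintf("S%d", 1:8)
  two_block <- list(values = blk,
                    truth = stats::setNames(rep(1:2, each = 5), rownames(blk)))

  # 12-node switch toy. Module M1 = {sw, a1, a2, a3}; module M2 = {e1..e8}.
  # sw: one internal edge (negative) + 7 external negative edges -> degree 8,
  # k_in = 1, APCC < 0, z_g < 2.5 (internal degrees in M1 differ, sd > 0).
  # M2 nodes are positively tied among themselves.
  edges <- rbind(
    data.frame(from = "sw", to = "a1", rho = -0.4),
    data.frame(from = "a1", to = "a2", rho = 0.8),
    data.frame(from = "a2", to = "a3", rho = 0.8),
    data.frame(from = "sw", to = paste0("e", 1:7), rho = -0.7),
    data.frame(from = paste0("e", 1:7), to = paste0("e", c(2:7, 8)), rho = 0.9),
    data.frame(from = "e8", to = "e1", rho = 0.9))
  net <- network_from_edges(edges, tau = 0.3)
  labels <- stats::setNames(c(rep(1L, 4L), rep(2L, 8L)),
                            c("sw", paste0("a", 1:3), paste0("e", 1:8)))
  switch_toy <- list(network = net, labels = labels, expected_switch = "sw")

  list(path3 = path3, two_block = two_block, switch_toy = switch_toy)
}
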