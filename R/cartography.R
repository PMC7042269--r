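#' Node cartography of a correlation network
#'
#' Computes, for every network node: total degree `k`, internal degree `k_in`
#' (edges within the node's own module), the average Pearson correlation
#' coefficient with its first neighbors (APCC, the mean of the signed
#' correlations stored on its incident edges), the within-module degree
#' z-score `z_g`, the clusterphobic coefficient `K_pi = 1 - (k_in/k)^2`, the
#' date/party/fight-club hub class, the role region R1-R7 in the
#' `(K_pi, z_g)` plane, and the switch-gene flag.
#'
#' Hub classes (for nodes with degree > `hub_degree_min`): fight-club if
#' APCC < 0; date if 0 <= APCC < `apcc_cut`; party if APCC >= `apcc_cut`.
#' Switch genes are fight-club hubs in region R4: `z_g < zg_max` and
#' `K_pi > kpi_min` and APCC < 0.
#'
#' @param network A `correlation_network` (see [build_network()]).
#' @param labels Named module labels covering the network nodes.
#' @param hub_degree_min Hubs have degree strictly greater than this
#'   (default 5).
#' @param apcc_cut Date/party APCC boundary (default 0.5).
#' @param zg_max Hub/non-hub boundary on `z_g` (default 2.5).
#' @param kpi_min R4 boundary on `K_pi` (default 0.8, strict `>`).
#' @param sd_type `"population"` (default, Guimera-Amaral convention) or
#'   `"sample"` standard deviation for `z_g`.
#' @param nonhub_breaks,hub_breaks `K_pi` boundaries splitting the non-hub
#'   (R1-R4) and hub (R5-R7) bands of the role plane.
#' @return A `node_cartography` data.frame: `gene`, `module`, `k`, `k_in`,
#'   `apcc`, `z_g`, `k_pi`, `class`, `region`, `switch`.
#' @export
node_cartography <- function(network, labels, hub_degree_min = 5L,
                             apcc_cut = 0.5, zg_max = 2.5, kpi_min = 0.8,
                             sd_type = c("population", "sample"),
                             nonhub_breaks = c(0.05, 0.62, kpi_min),
                             hub_breaks = c(0.3, 0.75)) {
  sd_type <- match.arg(sd_type)
  g <- network$graph
  nodes <- network$nodes
  if (!all(nodes %in% names(labels)))
    stop("module labels must cover every network node")
  mod <- labels[nodes]
  ends <- igraph::as_edgelist(g, names = TRUE)
  rho <- igraph::E(g)$rho
  stats_df <- cartography_stats(nodes, mod, ends, rho, sd_type = sd_type)
  classify_and_flag(stats_df, hub_degree_min = hub_degree_min,
                    apcc_cut = apcc_cut, zg_max = zg_max, kpi_min = kpi_min,
                    nonhub_breaks = nonhub_breaks, hub_breaks = hub_breaks)
}

# Internal: vectorized k, k_in, APCC, z_g, K_pi from an edge list.
# Shared by node_cartography() and the edge-shuffle null (which reuses the
# original module labels on rewired edges).
cartography_stats <- function(nodes, mod, ends, rho,
                              sd_type = "population") {
  n <- length(nodes)
  ia <- match(ends[, 1L], nodes)
  ib <- match(ends[, 2L], nodes)
  k <- tabulate(ia, nbins = n) + tabulate(ib, nbins = n)
  internal <- mod[ia] == mod[ib]
  k_in <- tabulate(ia[internal], nbins = n) + tabulate(ib[internal], nbins = n)
  rho_sum <- numeric(n)
  rho_sum[seq_len(n)] <- 0
  add_a <- rowsum(rho, ia)
  add_b <- rowsum(rho, ib)
  rho_sum[as.integer(rownames(add_a))] <- rho_sum[as.integer(rownames(add_a))] + add_a[, 1L]
  rho_sum[as.integer(rownames(add_b))] <- rho_sum[as.integer(rownames(add_b))] + add_b[, 1L]
  apcc <- ifelse(k > 0, rho_sum / k, NA_real_)
  z_g <- numeric(n)
  for (m in unique(mod)) {
    ix <- which(mod == m)
    kin_m <- k_in[ix]
    mu <- mean(kin_m)
    sdv <- if (sd_type == "population")
      sqrt(mean((kin_m - mu)^2))
    else stats::sd(kin_m)
    z_g[ix] <- if (is.na(sdv) || sdv == 0) 0 else (kin_m - mu) / sdv
  }
  k_pi <- ifelse(k > 0, 1 - (k_in / k)^2, NA_real_)
  data.frame(gene = nodes, module = unname(mod), k = k, k_in = k_in,
             apcc = apcc, z_g = z_g, k_pi = k_pi,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Internal: zero-row cartography table, used when no network can be built.
empty_cartography <- function() {
  df <- data.frame(gene = character(0), module = integer(0), k = integer(0),
                   k_in = integer(0), apcc = numeric(0), z_g = numeric(0),
                   k_pi = numeric(0), class = character(0),
                   region = character(0), switch = logical(0),
                   stringsAsFactors = FALSE)
  class(df) <- c("node_cartography", "data.frame")
  df
}

# Internal: hub class, region and switch flag from the raw statistics.
classify_and_flag <- function(df, hub_degree_min = 5L, apcc_cut = 0.5,
                              zg_max = 2.5, kpi_min = 0.8,
                              nonhub_breaks = c(0.05, 0.62, 0.8),
                              hub_breaks = c(0.3, 0.75)) {
  hub <- df$k > hub_degree_min
  cls <- rep("none", nrow(df))
  cls[hub & df$apcc < 0] <- "fight-club"
  cls[hub & df$apcc >= 0 & df$apcc < apcc_cut] <- "date"
  cls[hub & df$apcc >= apcc_cut] <- "party"
  local_hub <- df$z_g >= zg_max
  region <- character(nrow(df))
  nb <- sort(nonhub_breaks)
  hb <- sort(hub_breaks)
  region[!local_hub] <- paste0("R", 1L +
    findInterval(df$k_pi[!local_hub], nb, left.open = TRUE))
  region[local_hub] <- paste0("R", 5L +
    findInterval(df$k_pi[local_hub], hb, left.open = TRUE))
  sw <- cls == "fight-club" & df$z_g < zg_max & df$k_pi > kpi_min
  df$class <- cls
  df$region <- region
  df$switch <- sw
  class(df) <- c("node_cartography", "data.frame")
  df
}

#' Average Pearson correlation with first neighbors (APCC)
#'
#' @param network A `correlation_network`.
#' @param gene Gene identifier (must have at least one neighbor).
#' @return Mean of the signed correlations on the gene's incident edges.
#' @export
apcc <- function(network, gene) {
  v <- match(gene, network$nodes)
  if (is.na(v)) stop("gene not in network: ", gene)
  eids <- igraph::incident(network$graph, v)
  if (!length(eids)) stop("gene has no neighbors: ", gene)
  mean(igraph::E(network$graph)$rho[eids])
}

#' Within-module degree z-score
#'
#' z-score of a node's internal degree against the internal-degree
#' distribution of its own module; 0 when the module's internal degrees are
#' all equal.
#'
#' @inheritParams node_cartography
#' @param gene Gene identifier.
#' @return `z_g`.
#' @export
within_module_degree <- function(network, labels, gene,
                                 sd_type = c("population", "sample")) {
  carto <- node_cartography(network, labels, sd_type = match.arg(sd_type))
  carto$z_g[match(gene, carto$gene)]
}

#' Clusterphobic coefficient
#'
#' `K_pi = 1 - (k_in / k)^2`: 0 when all of a node's edges are internal to
#' its module, approaching 1 as its edges become external.
#'
#' @param k_in Internal degree.
#' @param k Total degree (>= 1).
#' @return `K_pi` in `[0, 1]`.
#' @export
clusterphobic <- function(k_in, k) {
  if (any(k < 1)) stop("total degree must be >= 1")
  if (any(k_in > k | k_in < 0)) stop("need 0 <= k_in <= k")
  1 - (k_in / k)^2
}

#' Classify hubs from a cartography table
#'
#' @param carto A `node_cartography` data.frame (or any data.frame with `k`
#'   and `apcc` columns).
#' @inheritParams node_cartography
#' @return Character vector: "none", "date", "party", or "fight-club".
#' @export
classify_hubs <- function(carto, hub_degree_min = 5L, apcc_cut = 0.5) {
  classify_and_flag(carto[, c("gene", "module", "k", "k_in", "apcc", "z_g", "k_pi")],
                    hub_degree_min = hub_degree_min, apcc_cut = apcc_cut)$class
}

#' Assign cartography role regions
#'
#' @inheritParams classify_hubs
#' @inheritParams node_cartography
#' @return Character vector of regions "R1".."R7".
#' @export
assign_regions <- function(carto, zg_max = 2.5,
                           nonhub_breaks = c(0.05, 0.62, 0.8),
                           hub_breaks = c(0.3, 0.75)) {
  classify_and_flag(carto[, c("gene", "module", "k", "k_in", "apcc", "z_g", "k_pi")],
                    zg_max = zg_max, nonhub_breaks = nonhub_breaks,
                    hub_breaks = hub_breaks)$region
}

#' Extract switch genes from a cartography table
#'
#' Switch genes are fight-club hubs (degree > 5, APCC < 0) in region R4:
#' not local hubs (`z_g < 2.5`) with mostly external edges (`K_pi > 0.8`).
#'
#' @param carto A `node_cartography` data.frame.
#' @param degs Optional [deg_table()] to annotate the direction of
#'   differential expression.
#' @return data.frame of switch genes with their module, degree, APCC and
#'   (when available) DEG direction.
#' @export
extract_switch_genes <- function(carto, degs = NULL) {
  out <- carto[carto$switch, c("gene", "module", "k", "k_in", "apcc",
                               "z_g", "k_pi"), drop = FALSE]
  out$direction <- if (!is.null(degs))
    degs$direction[match(out$gene, degs$gene)] else NA_character_
  rownames(out) <- NULL
  out
}

#' Neighbor report for switch genes
#'
#' Splits each switch gene's network neighbors by edge sign and counts the
#' members of a target gene set (e.g. GWAS-region genes) among the unions of
#' positive and negative neighbors.
#'
#' @param switch_genes Character vector of switch genes.
#' @param network A `correlation_network`.
#' @param target_set Character vector of target genes.
#' @return List with `per_gene` (data.frame: `gene`, `n_pos`, `n_neg`,
#'   `target_pos`, `target_neg`), `positive_union`, `negative_union`,
#'   `target_in_positive`, `target_in_negative` (counts over the unions).
#' @export
switch_neighbor_report <- function(switch_genes, network, target_set = character(0)) {
  if (!length(switch_genes)) stop("switch gene list is empty")
  g <- network$graph
  ends <- igraph::as_edgelist(g, names = TRUE)
  rho <- igraph::E(g)$rho
  pos_u <- character(0); neg_u <- character(0)
  rows <- lapply(switch_genes, function(s) {
    hit <- ends[, 1L] == s | ends[, 2L] == s
    nb <- ifelse(ends[hit, 1L] == s, ends[hit, 2L], ends[hit, 1L])
    r <- rho[hit]
    pos <- nb[r > 0]; neg <- nb[r < 0]
    pos_u <<- union(pos_u, pos); neg_u <<- union(neg_u, neg)
    data.frame(gene = s, n_pos = length(pos), n_neg = length(neg),
               target_pos = length(intersect(pos, target_set)),
               target_neg = length(intersect(neg, target_set)),
               stringsAsFactors = FALSE)
  })
  list(per_gene = do.call(rbind, rows),
       positive_union = pos_u, negative_union = neg_u,
       target_in_positive = length(intersect(pos_u, target_set)),
       target_in_negative = length(intersect(neg_u, target_set)))
}
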