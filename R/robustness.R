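#' Average shortest path of a network
#'
#' Mean of the shortest-path lengths over all unordered pairs of nodes that
#' are connected; the fraction of unreachable pairs is reported alongside
#' (node removals can fragment the network, and disconnected pairs are
#' excluded from the mean rather than given an arbitrary length).
#'
#' @param network A `correlation_network` or an igraph graph.
#' @return List with `asp` (`NaN` when no pair is reachable) and
#'   `unreachable_frac`.
#' @export
average_shortest_path <- function(network) {
  g <- if (inherits(network, "correlation_network")) network$graph else network
  n <- igraph::vcount(g)
  if (n == 0L) stop("network is empty")
  if (n == 1L) return(list(asp = NaN, unreachable_frac = NA_real_))
  d <- igraph::distances(g)
  v <- d[upper.tri(d)]
  fin <- is.finite(v)
  list(asp = if (any(fin)) mean(v[fin]) else NaN,
       unreachable_frac = mean(!fin))
}

#' Node-removal robustness curve
#'
#' Removes nodes cumulatively in the given order, recomputing the average
#' shortest path after each removal.
#'
#' @param network A `correlation_network` or igraph graph.
#' @param order Character vector of node names to remove, in order.
#' @param strategy Label stored with the curve (e.g. "switch", "nonswitch",
#'   "random").
#' @return A `removal_curve` data.frame: `step` (0 = intact network),
#'   `removed_gene`, `frac_removed` (of the original node count), `asp`,
#'   `unreachable_frac`.
#' @export
removal_curve <- function(network, order, strategy = "custom") {
  g <- if (inherits(network, "correlation_network")) network$graph else network
  nodes <- igraph::V(g)$name
  missing <- setdiff(order, nodes)
  if (length(missing))
    stop("nodes not in network: ", paste(missing, collapse = ", "))
  n0 <- length(nodes)
  base <- average_shortest_path(g)
  rows <- list(data.frame(step = 0L, removed_gene = NA_character_,
                          frac_removed = 0, asp = base$asp,
                          unreachable_frac = base$unreachable_frac,
                          stringsAsFactors = FALSE))
  for (i in seq_along(order)) {
    g <- igraph::delete_vertices(g, order[i])
    a <- average_shortest_path(g)
    rows[[i + 1L]] <- data.frame(step = i, removed_gene = order[i],
                                 frac_removed = i / n0, asp = a$asp,
                                 unreachable_frac = a$unreachable_frac,
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "strategy") <- strategy
  class(out) <- c("removal_curve", "data.frame")
  out
}

#' Removal orders for the robustness comparison
#'
#' Builds the three node orders compared in the attack analysis:
#' (a) switch genes by decreasing degree, (b) the equally many highest-degree
#' non-switch nodes, and (c) equally many uniformly random nodes. Degree ties
#' are broken by lexicographic gene ID, so orders are deterministic given the
#' seed.
#'
#' @param carto A `node_cartography` data.frame.
#' @param seed RNG seed for the random order.
#' @return List with `switch`, `nonswitch`, `random` character vectors.
#' @export
removal_orders <- function(carto, seed = 1L) {
  sw <- carto[carto$switch, , drop = FALSE]
  sw <- sw[order(-sw$k, sw$gene), , drop = FALSE]
  n <- nrow(sw)
  ns <- carto[!carto$switch, , drop = FALSE]
  if (nrow(ns) < n) stop("fewer non-switch nodes than switch genes")
  ns <- ns[order(-ns$k, ns$gene), , drop = FALSE]
  set.seed(seed)
  rnd <- sample(carto$gene, n)
  list(switch = sw$gene, nonswitch = ns$gene[seq_len(n)], random = rnd)
}
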