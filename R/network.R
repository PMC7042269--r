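#' Pearson correlation matrix over genes
#'
#' @param values Numeric genes x samples matrix (e.g. the DEG submatrix of a
#'   study).
#' @return Symmetric gene x gene matrix of Pearson correlations with unit
#'   diagonal. Zero-variance genes are excluded with a warning (their
#'   correlations are undefined).
#' @export
pearson_matrix <- function(values) {
  if (ncol(values) < 3L) stop("need at least 3 samples")
  sds <- apply(values, 1L, stats::sd)
  zv <- sds == 0
  if (any(zv)) {
    warning(sum(zv), " zero-variance gene(s) excluded from correlation matrix")
    values <- values[!zv, , drop = FALSE]
  }
  stats::cor(t(values))
}

#' Percentile threshold of the correlation distribution
#'
#' The threshold is the stated percentile of the distribution of absolute
#' correlations over unordered gene pairs (each pair counted once, diagonal
#' excluded).
#'
#' @param correlations Square correlation matrix.
#' @param percentile Percentile in `(0, 100]` (default 98).
#' @return Threshold tau.
#' @export
percentile_threshold <- function(correlations, percentile = 98) {
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  v <- abs(correlations[upper.tri(correlations)])
  unname(stats::quantile(v, percentile / 100))
}

#' Build a hard-thresholded correlation network
#'
#' Draws an edge between two genes when the absolute Pearson correlation of
#' their expression profiles strictly exceeds `tau`; the signed correlation is
#' retained on the edge. Genes left without any edge are dropped from the
#' network.
#'
#' @param correlations Square signed correlation matrix with dimnames.
#' @param tau Correlation threshold in `(0, 1)`.
#' @return A `correlation_network`: list with `graph` (igraph with edge
#'   attribute `rho`), `tau`, `nodes`, and `degree` (named degree map).
#' @export
build_network <- function(correlations, tau) {
  if (tau < 0 || tau >= 1) stop("tau must be in [0, 1)")
  ix <- which(upper.tri(correlations) & abs(correlations) > tau, arr.ind = TRUE)
  genes <- rownames(correlations)
  if (nrow(ix) == 0L) {
    warning("no edge survives tau = ", tau, "; empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, tau = tau, nodes = character(0),
                          degree = numeric(0)),
                     class = "correlation_network"))
  }
  edges <- data.frame(from = genes[ix[, 1L]], to = genes[ix[, 2L]],
                      rho = correlations[ix], stringsAsFactors = FALSE)
  network_from_edges(edges, tau)
}

#' Build a correlation network directly from a signed edge list
#'
#' @param edges data.frame with columns `from`, `to`, `rho`.
#' @param tau Threshold to record on the object.
#' @return A `correlation_network` (see [build_network()]).
#' @export
network_from_edges <- function(edges, tau = NA_real_) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(rho = "first"))
  deg <- igraph::degree(g)
  structure(list(graph = g, tau = tau,
                 nodes = igraph::V(g)$name, degree = deg),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network: %d nodes, %d edges (tau = %s)\n",
              length(x$nodes), igraph::ecount(x$graph), format(x$tau)))
  invisible(x)
}

#' Scale-free topology fit
#'
#' Least-squares fit of `log P(k)` against `log k` over observed degrees.
#' The reported R-squared is multiplied by -1 when the slope is positive
#' (a network with more hubs than non-hubs is biologically implausible), so
#' that values near +1 indicate approximate scale-free (power-law decaying)
#' topology.
#'
#' @param network A `correlation_network`, an igraph graph, or a numeric
#'   degree vector.
#' @return List with `degrees`, `pk` (empirical degree distribution), `alpha`
#'   (negated slope, power-law exponent), `r2` (unsigned), and `signed_r2`
#'   (`NaN` when fewer than 2 distinct degrees are observed).
#' @export
scale_free_fit <- function(network) {
  deg <- if (inherits(network, "correlation_network")) network$degree
         else if (inherits(network, "igraph")) igraph::degree(network)
         else network
  deg <- deg[deg > 0]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / sum(tab)
  if (length(k) < 2L) {
    warning("fewer than 2 distinct degrees; scale-free fit undefined")
    return(list(degrees = k, pk = pk, alpha = NA_real_, r2 = NA_real_,
                signed_r2 = NaN))
  }
  fit <- stats::lm(log(pk) ~ log(k))
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  list(degrees = k, pk = pk, alpha = -slope, r2 = r2,
       signed_r2 = if (slope > 0) -r2 else r2)
}

#' Sweep candidate correlation thresholds
#'
#' Evaluates a grid of percentile thresholds and reports, for each, the
#' network size, edge count, number of connected components and the signed
#' scale-free R-squared. The recommended threshold is the smallest tau with
#' `signed_r2 > r2_min` whose giant component retains at least
#' `giant_fraction` of the network nodes -- a balance between scale-free
#' topology and connectivity.
#'
#' @param correlations Square signed correlation matrix.
#' @param percentiles Numeric grid of percentiles (default `seq(90, 99)`).
#' @param r2_min Signed R-squared requirement (default 0.8).
#' @param giant_fraction Minimum fraction of nodes in the giant component
#'   (default 0.75).
#' @return data.frame with columns `percentile`, `tau`, `n_nodes`, `n_edges`,
#'   `n_components`, `giant_fraction`, `signed_r2`, `recommended` (logical;
#'   at most one row). A warning is issued when no candidate qualifies.
#' @export
sweep_thresholds <- function(correlations, percentiles = seq(90, 99),
                             r2_min = 0.8, giant_fraction = 0.75) {
  if (!length(percentiles)) stop("percentile grid is empty")
  percentiles <- sort(percentiles)
  rows <- lapply(percentiles, function(p) {
    tau <- percentile_threshold(correlations, p)
    net <- suppressWarnings(build_network(correlations, min(tau, 1 - 1e-12)))
    comps <- if (length(net$nodes))
      igraph::components(net$graph) else list(no = 0L, csize = integer(0))
    gf <- if (length(net$nodes)) max(comps$csize) / length(net$nodes) else NA_real_
    sf <- suppressWarnings(scale_free_fit(net))
    data.frame(percentile = p, tau = tau, n_nodes = length(net$nodes),
               n_edges = igraph::ecount(net$graph),
               n_components = comps$no, giant_fraction = gf,
               signed_r2 = sf$signed_r2)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$signed_r2) & out$signed_r2 > r2_min &
    !is.na(out$giant_fraction) & out$giant_fraction >= giant_fraction
  out$recommended <- FALSE
  if (any(ok)) {
    out$recommended[which(ok)[which.min(out$tau[ok])]] <- TRUE
  } else {
    warning("no threshold satisfies both the scale-free and connectivity criteria")
  }
  out
}
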