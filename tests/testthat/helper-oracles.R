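# Brute-force reference implementations, written independently of the package
# internals: plain loops over edge lists and p-value vectors. Deliberately
# slow and obvious.

# Random signed graph as an edge data.frame (from, to, rho) plus random
# module labels. Nodes are letters-digits names to exercise name handling.
random_signed_graph <- function(n_nodes, p_edge, n_modules = 3L,
                                seed = 1L, rho_range = c(-1, 1)) {
  set.seed(seed)
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  edges <- data.frame(from = nodes[pairs[, 1L]], to = nodes[pairs[, 2L]],
                      rho = stats::runif(nrow(pairs), rho_range[1L],
                                         rho_range[2L]),
                      stringsAsFactors = FALSE)
  labels <- stats::setNames(sample.int(n_modules, n_nodes, replace = TRUE),
                            nodes)
  list(nodes = nodes, edges = edges, labels = labels)
}

# Per-node k, k_in, APCC, z_g (population sd), K_pi by direct loops.
oracle_cartography <- function(nodes, edges, labels) {
  k <- k_in <- rho_sum <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]; r <- edges$rho[i]
    k[a] <- k[a] + 1; k[b] <- k[b] + 1
    rho_sum[a] <- rho_sum[a] + r; rho_sum[b] <- rho_sum[b] + r
    if (labels[a] == labels[b]) {
      k_in[a] <- k_in[a] + 1; k_in[b] <- k_in[b] + 1
    }
  }
  apcc <- ifelse(k > 0, rho_sum / k, NA_real_)
  z_g <- stats::setNames(numeric(length(nodes)), nodes)
  for (m in unique(labels)) {
    members <- nodes[labels[nodes] == m]
    mu <- mean(k_in[members])
    sdv <- sqrt(mean((k_in[members] - mu)^2))
    z_g[members] <- if (sdv == 0) 0 else (k_in[members] - mu) / sdv
  }
  k_pi <- ifelse(k > 0, 1 - (k_in / k)^2, NA_real_)
  list(k = k, k_in = k_in, apcc = apcc, z_g = z_g, k_pi = k_pi)
}

# All-pairs shortest-path hop counts by Floyd-Warshall over the edge list.
oracle_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    d[a, b] <- 1; d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Mean shortest path over finite, distinct unordered pairs.
oracle_asp <- function(nodes, edges) {
  d <- oracle_distances(nodes, edges)
  v <- d[upper.tri(d)]
  v <- v[is.finite(v)]
  if (!length(v)) return(NaN)
  mean(v)
}

oracle_proximity <- function(s1, s2, dist) {
  mins <- vapply(s1, function(a) min(dist[a, s2]), numeric(1L))
  mins <- mins[is.finite(mins)]
  mean(mins)
}

oracle_separation <- function(a, b, dist) {
  excl_min <- function(x, set) {
    v <- dist[x, setdiff(set, x)]
    if (!length(v)) return(Inf)
    min(v)
  }
  pool <- function(s1, s2) {
    v <- c(vapply(s1, function(x) {
      dd <- dist[x, s2]
      dd[s2 == x] <- Inf
      min(dd)
    }, numeric(1L)), vapply(s2, function(x) {
      dd <- dist[x, s1]
      dd[s1 == x] <- Inf
      min(dd)
    }, numeric(1L)))
    mean(v[is.finite(v)])
  }
  within <- function(s) {
    v <- vapply(s, excl_min, numeric(1L), set = s)
    v <- c(v, v)                 # both directions pool identically
    v <- v[is.finite(v)]
    if (!length(v)) return(NaN)
    mean(v)
  }
  pool(a, b) - (within(a) + within(b)) / 2
}

# Benjamini-Hochberg by the explicit step-up definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# AUC by explicit pair counting with ties counted 1/2.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# A small expression study with planted shifts, for DEG unit tests.
toy_study <- function(n_genes = 60L, n_per_class = 12L, n_deg = 15L,
                      shift = 2, seed = 1L) {
  set.seed(seed)
  vals <- matrix(stats::rnorm(n_genes * 2L * n_per_class), n_genes,
                 dimnames = list(sprintf("T%03d", seq_len(n_genes)),
                                 sprintf("S%02d", seq_len(2L * n_per_class))))
  condition <- rep(c(0L, 1L), each = n_per_class)
  vals[seq_len(n_deg), condition == 1L] <-
    vals[seq_len(n_deg), condition == 1L] + shift
  list(study = expression_study(vals, condition),
       deg_genes = rownames(vals)[seq_len(n_deg)])
}

# Convert a package network to the plain (nodes, edges) form the oracles use.
network_parts <- function(network) {
  el <- igraph::as_edgelist(network$graph, names = TRUE)
  list(nodes = network$nodes,
       edges = data.frame(from = el[, 1L], to = el[, 2L],
                          rho = igraph::E(network$graph)$rho,
                          stringsAsFactors = FALSE))
}
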