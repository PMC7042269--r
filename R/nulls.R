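# Internal: assemble a null-model summary from an observed statistic and a
# vector of null replicates. The empirical p adds one pseudo-count:
# (#{null >= obs} + 1) / (reps + 1) for the upper side.
null_summary <- function(observed, samples, sided = c("upper", "lower", "two"),
                         seed = NA_integer_) {
  sided <- match.arg(sided)
  mu <- mean(samples)
  sdv <- stats::sd(samples)
  if (is.na(sdv) || sdv == 0) {
    z <- if (observed == mu) 0 else sign(observed - mu) * Inf
    p_norm <- if (observed == mu) {
      if (sided == "two") 1 else 0.5
    } else 1 / (length(samples))
    # sd = 0 with observed != mean: report p bounded by 1/reps
  } else {
    z <- (observed - mu) / sdv
    p_norm <- z_to_p(z, sided)
  }
  p_emp <- switch(sided,
    upper = (sum(samples >= observed) + 1) / (length(samples) + 1),
    lower = (sum(samples <= observed) + 1) / (length(samples) + 1),
    two = (min(sum(samples >= observed), sum(samples <= observed)) * 2 + 1) /
      (length(samples) + 1))
  structure(list(observed = observed, samples = samples, mean = mu, sd = sdv,
                 z = z, p = min(p_norm, 1), p_empirical = min(p_emp, 1),
                 sided = sided, reps = length(samples), seed = seed),
            class = "null_summary")
}

#' @export
print.null_summary <- function(x, ...) {
  cat(sprintf(paste0("null_summary (%d reps, %s-sided): observed = %.4g, ",
                     "null mean = %.4g, sd = %.4g, z = %.3g, p = %.3g ",
                     "(empirical %.3g)\n"),
              x$reps, x$sided, x$observed, x$mean, x$sd, x$z, x$p,
              x$p_empirical))
  invisible(x)
}

#' Normal-tail p-value for a z statistic
#'
#' @param z z-score (finite).
#' @param sided `"upper"`, `"lower"`, or `"two"`.
#' @return p-value.
#' @export
z_to_p <- function(z, sided = c("upper", "lower", "two")) {
  sided <- match.arg(sided)
  switch(sided,
         upper = stats::pnorm(z, lower.tail = FALSE),
         lower = stats::pnorm(z),
         two = 2 * stats::pnorm(-abs(z)))
}

#' Degree-preserving edge shuffle
#'
#' Randomizes a correlation network by repeated double-edge swaps, preserving
#' every node's degree exactly. Each edge's signed correlation travels with
#' its edge slot, so after a swap the original weight is carried by one of the
#' rewired endpoint pairs. Proposals creating self-loops or multi-edges are
#' rejected (a triangle, for instance, admits no valid swap and is returned
#' unchanged).
#'
#' @param network A `correlation_network`.
#' @param n_swaps Number of proposed swaps (default `10 * |E|`).
#' @param seed Optional RNG seed.
#' @return A rewired `correlation_network` with the same degree sequence.
#' @export
degree_preserving_shuffle <- function(network, n_swaps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- network$graph
  m <- igraph::ecount(g)
  if (m < 2L) stop("network needs at least 2 edges")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  el2 <- .double_edge_swap(el, as.integer(n_swaps))
  nodes <- network$nodes
  edges <- data.frame(from = nodes[el2[, 1L]], to = nodes[el2[, 2L]],
                      rho = igraph::E(g)$rho, stringsAsFactors = FALSE)
  out <- network_from_edges(edges, network$tau)
  # preserve the original node universe/order
  out$nodes <- nodes
  out$degree <- igraph::degree(out$graph)[nodes]
  out
}

#' Switch-count null: edge shuffling
#'
#' Repeatedly rewires the network with [degree_preserving_shuffle()] (module
#' labels and expression are untouched; only the wiring changes), recomputes
#' the cartography, and counts switch genes, yielding a z-score and one-sided
#' upper p-value for the observed switch count.
#'
#' @param network A `correlation_network`.
#' @param labels Named module labels covering the network nodes.
#' @param observed Observed switch count (computed from `network` when `NULL`).
#' @param reps Number of replicates (default 1000).
#' @param seed RNG seed.
#' @param ... Cartography thresholds passed to [node_cartography()].
#' @return A `null_summary` for the switch count.
#' @export
switch_count_null <- function(network, labels, observed = NULL, reps = 1000L,
                              seed = 1L, ...) {
  if (is.null(observed))
    observed <- sum(node_cartography(network, labels, ...)$switch)
  set.seed(seed)
  g <- network$graph
  nodes <- network$nodes
  mod <- labels[nodes]
  rho <- igraph::E(g)$rho
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  n_swaps <- as.integer(10L * nrow(el))
  counts <- integer(reps)
  for (r in seq_len(reps)) {
    el2 <- .double_edge_swap(el, n_swaps)
    ends <- cbind(nodes[el2[, 1L]], nodes[el2[, 2L]])
    st <- cartography_stats(nodes, mod, ends, rho)
    counts[r] <- sum(classify_and_flag(st, ...)$switch)
  }
  null_summary(observed, counts, sided = "upper", seed = seed)
}

#' Gene-set overlap null: random draws from the universe
#'
#' Draws `draw_size` genes uniformly without replacement from the universe
#' `reps` times and counts the overlap with a target set, yielding z and
#' p-value for an observed overlap (e.g. how many GWAS-region genes fall
#' among the DEGs).
#'
#' @param universe Character vector of all genes.
#' @param draw_size Number of genes drawn per replicate.
#' @param target_set Target gene set (subset of the universe).
#' @param observed Observed overlap count.
#' @param reps Replicates (default 1000).
#' @param seed RNG seed.
#' @param sided Test sidedness (default `"two"`: is the overlap different
#'   from chance).
#' @return A `null_summary`.
#' @export
geneset_overlap_null <- function(universe, draw_size, target_set, observed,
                                 reps = 1000L, seed = 1L, sided = "two") {
  if (draw_size > length(universe)) stop("draw_size exceeds universe size")
  extra <- setdiff(target_set, universe)
  if (length(extra)) stop("target genes outside the universe: ",
                          paste(utils::head(extra, 5L), collapse = ", "))
  set.seed(seed)
  is_target <- universe %in% target_set
  counts <- vapply(seq_len(reps), function(r)
    sum(is_target[sample.int(length(universe), draw_size)]), integer(1L))
  null_summary(observed, counts, sided = sided, seed = seed)
}

#' Neighbor-shuffle null for switch-gene target adjacency
#'
#' For each replicate, every switch gene's neighbor set is replaced by a
#' uniform draw of the same size from the non-switch network nodes, carrying
#' the original signed edge weights; the number of target-set members among
#' the unions of positive and of negative neighbors is then recounted.
#' Separate summaries are returned for the positive and negative counts.
#'
#' @param switch_genes Character vector of switch genes (non-empty).
#' @param network A `correlation_network`.
#' @param target_set Character vector of target genes (e.g. GWAS genes).
#' @param reps Replicates (default 1000).
#' @param seed RNG seed.
#' @return List with `positive` and `negative` `null_summary` objects and the
#'   observed counts.
#' @export
neighbor_shuffle_null <- function(switch_genes, network, target_set,
                                  reps = 1000L, seed = 1L) {
  if (!length(switch_genes)) stop("switch gene list is empty")
  obs <- switch_neighbor_report(switch_genes, network, target_set)
  candidates <- setdiff(network$nodes, switch_genes)
  g <- network$graph
  ends <- igraph::as_edgelist(g, names = TRUE)
  rho <- igraph::E(g)$rho
  signs <- lapply(switch_genes, function(s) {
    hit <- ends[, 1L] == s | ends[, 2L] == s
    rho[hit]
  })
  degs <- lengths(signs)
  if (any(degs > length(candidates)))
    stop("a switch gene's degree exceeds the number of candidate nodes")
  set.seed(seed)
  in_target <- stats::setNames(candidates %in% target_set, candidates)
  pos_counts <- integer(reps); neg_counts <- integer(reps)
  for (r in seq_len(reps)) {
    pos_u <- character(0); neg_u <- character(0)
    for (i in seq_along(switch_genes)) {
      nb <- candidates[sample.int(length(candidates), degs[i])]
      s <- signs[[i]]
      pos_u <- union(pos_u, nb[s > 0])
      neg_u <- union(neg_u, nb[s < 0])
    }
    pos_counts[r] <- sum(in_target[pos_u])
    neg_counts[r] <- sum(in_target[neg_u])
  }
  list(positive = null_summary(obs$target_in_positive, pos_counts,
                               sided = "upper", seed = seed),
       negative = null_summary(obs$target_in_negative, neg_counts,
                               sided = "upper", seed = seed),
       observed = c(positive = obs$target_in_positive,
                    negative = obs$target_in_negative))
}
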