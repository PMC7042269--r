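# Internal: map a gene list onto interactome vertices, reporting drops.
map_to_graph <- function(genes, graph) {
  nodes <- igraph::V(graph)$name
  mapped <- unique(genes[genes %in% nodes])
  list(mapped = mapped, n_input = length(unique(genes)),
       n_unmapped = length(unique(genes)) - length(mapped))
}

#' Interactome proximity between two gene lists
#'
#' Closest-distance proximity
#' `p(S1, S2) = mean over s1 in S1 of min over s2 in S2 of d(s1, s2)`,
#' where `d` is the shortest-path distance in hops. The measure is asymmetric
#' (normalized by the first list). Genes absent from the interactome are
#' dropped (counts reported); genes present in both lists contribute distance
#' 0; S1 genes with no finite distance to any mapped S2 gene are excluded from
#' the average.
#'
#' @param s1,s2 Character vectors of gene symbols.
#' @param graph An igraph interactome (see [read_interactome()]).
#' @param detail Return the full report instead of the bare value.
#' @return The proximity `p` (numeric), or, with `detail = TRUE`, a list with
#'   `p`, per-list mapping counts and the number of unreachable S1 genes.
#' @export
proximity <- function(s1, s2, graph, detail = FALSE) {
  m1 <- map_to_graph(s1, graph)
  m2 <- map_to_graph(s2, graph)
  if (!length(m1$mapped) || !length(m2$mapped))
    stop("a gene list maps to no interactome node")
  d <- igraph::distances(graph, v = m1$mapped, to = m2$mapped)
  mins <- apply(d, 1L, min)
  fin <- is.finite(mins)
  p <- if (any(fin)) mean(mins[fin]) else NaN
  if (!detail) return(p)
  list(p = p, n_s1 = m1$n_input, n_s1_unmapped = m1$n_unmapped,
       n_s2 = m2$n_input, n_s2_unmapped = m2$n_unmapped,
       n_unreachable = sum(!fin))
}

# Internal: symmetrized closest-distance average with self-exclusion, the
# form used inside the separation statistic. For each node of A the nearest
# node of B other than itself counts (and vice versa); the two direction sums
# are pooled and divided by |A| + |B|. With A = B this reduces exactly to the
# self-excluding within-set average, so s(A, A) = 0.
prox_sym_excl <- function(a, b, graph) {
  d <- igraph::distances(graph, v = a, to = b)
  if (length(a) == 1L && length(b) == 1L && a == b)
    stop("within-set distance undefined for a singleton set")
  excl <- outer(a, b, "==")
  d[excl] <- Inf
  mins_a <- apply(d, 1L, min)
  mins_b <- apply(d, 2L, min)
  v <- c(mins_a, mins_b)
  v <- v[is.finite(v)]
  if (!length(v)) return(NaN)
  mean(v)
}

#' Interactome separation of two gene lists
#'
#' `s(A, B) = p_AB - (p_AA + p_BB) / 2`, where `p_AB` is the symmetrized
#' closest-distance average over both directions and the within-set terms
#' `p_AA`, `p_BB` exclude each node itself (its nearest neighbor within its
#' own set must be another gene). `s < 0` means the two sets occupy the same
#' interactome neighborhood; `s >= 0` means they are topologically separated.
#'
#' @inheritParams proximity
#' @param detail Return the components alongside `s`.
#' @return `s` (numeric), or a list with `s`, `p_ab`, `p_aa`, `p_bb` and
#'   mapping counts when `detail = TRUE`.
#' @export
separation <- function(s1, s2, graph, detail = FALSE) {
  m1 <- map_to_graph(s1, graph)
  m2 <- map_to_graph(s2, graph)
  if (length(m1$mapped) < 2L || length(m2$mapped) < 2L)
    stop("each list needs at least 2 mapped genes for the within-set term")
  p_ab <- prox_sym_excl(m1$mapped, m2$mapped, graph)
  p_aa <- prox_sym_excl(m1$mapped, m1$mapped, graph)
  p_bb <- prox_sym_excl(m2$mapped, m2$mapped, graph)
  s <- p_ab - (p_aa + p_bb) / 2
  if (!detail) return(s)
  list(s = s, p_ab = p_ab, p_aa = p_aa, p_bb = p_bb,
       n_a_mapped = length(m1$mapped), n_b_mapped = length(m2$mapped))
}

# Internal: assign interactome nodes to logarithmic degree bins, merging bins
# upward until each holds at least min_per_bin candidates.
degree_bins <- function(graph, min_per_bin = 100L) {
  deg <- igraph::degree(graph)
  raw <- floor(log2(pmax(deg, 1)))
  lev <- sort(unique(raw))
  merged <- integer(length(lev))
  cur <- 1L
  count <- 0L
  for (i in seq_along(lev)) {
    merged[i] <- cur
    count <- count + sum(raw == lev[i])
    if (count >= min_per_bin && i < length(lev)) {
      cur <- cur + 1L
      count <- 0L
    }
  }
  # if the last bin ended up undersized, fold it into the previous one
  bin <- merged[match(raw, lev)]
  tab <- table(bin)
  if (length(tab) > 1L && tab[length(tab)] < min_per_bin)
    bin[bin == max(bin)] <- max(bin) - 1L
  stats::setNames(bin, names(deg))
}

#' Degree-matched random-set null for interactome proximity
#'
#' Repeatedly samples random node sets matching the size and degree
#' distribution of each input list (nodes are drawn within logarithmic degree
#' bins, merged until each bin holds at least `min_per_bin` candidates),
#' recomputes the proximity, and compares the observed value against this
#' reference distribution with a one-sided lower test (is the observed
#' proximity smaller than that of random sets?).
#'
#' @inheritParams proximity
#' @param reps Replicates (default 1000; at least 100).
#' @param seed RNG seed.
#' @param min_per_bin Minimum candidates per degree bin (default 100).
#' @return A `proximity_result`: list with `p_observed`, `null` (a
#'   `null_summary`), `separation` (`s(A, B)` when both lists have >= 2
#'   mapped genes, else `NA`) and mapping counts.
#' @export
degree_matched_null <- function(s1, s2, graph, reps = 1000L, seed = 1L,
                                min_per_bin = 100L) {
  if (reps < 100L) stop("need at least 100 replicates")
  m1 <- map_to_graph(s1, graph)
  m2 <- map_to_graph(s2, graph)
  if (!length(m1$mapped) || !length(m2$mapped))
    stop("a gene list maps to no interactome node")
  obs <- proximity(m1$mapped, m2$mapped, graph)
  bins <- degree_bins(graph, min_per_bin)
  by_bin <- split(names(bins), bins)
  set.seed(seed)
  draw_like <- function(mapped) {
    need <- table(bins[mapped])
    unlist(lapply(names(need), function(b) {
      pool <- by_bin[[b]]
      pool[sample.int(length(pool), need[[b]])]
    }), use.names = FALSE)
  }
  null_p <- vapply(seq_len(reps), function(r) {
    r1 <- draw_like(m1$mapped)
    r2 <- draw_like(m2$mapped)
    proximity(r1, r2, graph)
  }, numeric(1L))
  ns <- null_summary(obs, null_p, sided = "lower", seed = seed)
  sep <- if (length(m1$mapped) >= 2L && length(m2$mapped) >= 2L)
    separation(m1$mapped, m2$mapped, graph) else NA_real_
  structure(list(p_observed = obs, null = ns, separation = sep,
                 n_s1_mapped = length(m1$mapped),
                 n_s2_mapped = length(m2$mapped),
                 n_s1_unmapped = m1$n_unmapped, n_s2_unmapped = m2$n_unmapped),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("proximity_result: p = %.4g (null mean %.4g, z = %.3g, p-value = %.3g)\n",
              x$p_observed, x$null$mean, x$null$z, x$null$p))
  if (!is.na(x$separation))
    cat(sprintf("  separation s = %.4g (%s)\n", x$separation,
                if (x$separation < 0) "same neighborhood" else "separated"))
  invisible(x)
}
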