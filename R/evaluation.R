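#' Truth table for switch-gene disease specificity
#'
#' Labels each switch gene 1 when it belongs to at least one designated
#' disease-specific pathway set, and scores it by the number of disease
#' (e.g. GWAS-region) genes among its correlation-network neighbors: the more
#' disease interactors, the more confident the classifier that the gene is
#' disease-specific.
#'
#' @param switch_genes Character vector of switch genes (must be network
#'   nodes).
#' @param pathway_sets Named list of disease-specific pathway gene sets.
#' @param disease_set Character vector of disease genes used for the score.
#' @param network A `correlation_network`.
#' @return data.frame: `gene`, `label` (0/1), `score` (integer).
#' @export
build_truth_table <- function(switch_genes, pathway_sets, disease_set, network) {
  missing <- setdiff(switch_genes, network$nodes)
  if (length(missing))
    stop("switch genes absent from network: ", paste(missing, collapse = ", "))
  annotated <- unique(unlist(pathway_sets, use.names = FALSE))
  g <- network$graph
  score <- vapply(switch_genes, function(s) {
    nb <- igraph::V(g)$name[igraph::neighbors(g, s)]
    length(intersect(nb, disease_set))
  }, integer(1L))
  data.frame(gene = switch_genes,
             label = as.integer(switch_genes %in% annotated),
             score = score, row.names = NULL, stringsAsFactors = FALSE)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation, with tied scores contributing
#' 1/2 -- the appropriate convention for heavily tied integer scores. ROC
#' points are produced at every distinct score threshold.
#'
#' @param labels Binary labels (0/1), both classes present.
#' @param scores Numeric scores (higher = more positive).
#' @return List with `auc` and `roc` (data.frame `threshold`, `fpr`, `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  roc <- rbind(
    data.frame(threshold = Inf, fpr = 0, tpr = 0),
    do.call(rbind, lapply(thr, function(t) {
      pos <- scores >= t
      data.frame(threshold = t,
                 fpr = sum(pos & labels == 0L) / n0,
                 tpr = sum(pos & labels == 1L) / n1)
    })))
  list(auc = auc, roc = roc)
}

#' Over-representation test against annotation sets
#'
#' One-sided hypergeometric upper-tail test of the overlap between a query
#' gene list and each annotation set, against a stated gene universe, with
#' Benjamini-Hochberg adjustment across sets. A local replacement for web
#' enrichment services.
#'
#' @param query Character vector of query genes (non-empty, within the
#'   universe).
#' @param sets Named list of annotation gene sets.
#' @param universe Character vector of all considered genes.
#' @return data.frame per set: `set`, `set_size` (in-universe), `overlap`,
#'   `expected`, `odds_ratio`, `p`, `q`. Sets disjoint from the universe are
#'   skipped with a warning.
#' @export
overrepresentation <- function(query, sets, universe) {
  query <- unique(query)
  if (!length(query)) stop("query gene list is empty")
  out <- setdiff(query, universe)
  if (length(out)) stop("query genes outside the universe: ",
                        paste(utils::head(out, 5L), collapse = ", "))
  N <- length(unique(universe))
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    K <- length(set_u)
    if (K == 0L) {
      warning("set '", nm, "' is disjoint from the universe; skipped")
      return(NULL)
    }
    x <- length(intersect(query, set_u))
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    a <- x; b <- n - x; cc <- K - x; d <- N - K - b
    or <- (a * d) / max(b * cc, .Machine$double.eps)
    data.frame(set = nm, set_size = K, overlap = x,
               expected = n * K / N, odds_ratio = or, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(data.frame())
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  res
}
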