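# Internal: z-score each gene profile across samples. Zero-variance rows are
# returned as all-zero (flagged upstream).
zscore_rows <- function(values) {
  mu <- rowMeans(values)
  sd <- apply(values, 1L, stats::sd)
  z <- (values - mu) / ifelse(sd == 0, 1, sd)
  z[sd == 0, ] <- 0
  z
}

#' k-means gene modules under the 1 - correlation distance
#'
#' Genes are partitioned by k-means on their z-scored expression profiles.
#' On z-scored profiles the squared Euclidean distance between two genes
#' equals `2 * (n_samples - 1) * (1 - cor(x, y))`, so Euclidean k-means
#' minimizes the within-module `1 - correlation` objective while keeping the
#' classical convergence guarantees. The best of `n_restarts` random starts
#' (by SSE) is kept, and module labels are renumbered by decreasing size.
#'
#' @param values Numeric genes x samples matrix (network genes).
#' @param k Number of modules.
#' @param seed RNG seed for the restarts.
#' @param n_restarts Number of random starts (default 50).
#' @param centers Optional initial centers matrix (warm start); when given,
#'   a single run from these centers competes with the random restarts.
#' @return List with `labels` (named integer vector, 1 = largest module),
#'   `sizes`, `sse` (total within-cluster sum of squares on the z-scored
#'   profiles) and `zscored` (the z-scored matrix, reused downstream).
#' @export
kmeans_modules <- function(values, k, seed = 1L, n_restarts = 50L,
                           centers = NULL) {
  if (k > nrow(values)) stop("k exceeds the number of genes")
  z <- zscore_rows(values)
  if (k == 1L) {
    ctr <- colMeans(z)
    sse <- sum(sweep(z, 2L, ctr)^2)
    labels <- stats::setNames(rep(1L, nrow(z)), rownames(z))
    return(list(labels = labels, sizes = nrow(z), sse = sse, zscored = z,
                centers = matrix(ctr, nrow = 1L)))
  }
  uz <- unique(z)
  if (nrow(uz) <= k) {
    # degenerate input: at most k distinct profiles -> each its own module
    cl <- match(apply(z, 1L, paste, collapse = "\r"),
                apply(uz, 1L, paste, collapse = "\r"))
    fit <- list(cluster = cl, tot.withinss = 0, centers = uz)
    k_eff <- nrow(uz)
    ord <- order(tabulate(cl, nbins = k_eff), decreasing = TRUE)
    relabel <- match(seq_len(k_eff), ord)
    labels <- stats::setNames(relabel[cl], rownames(z))
    return(list(labels = labels,
                sizes = as.integer(table(factor(labels, levels = seq_len(k_eff)))),
                sse = 0, zscored = z, centers = uz[ord, , drop = FALSE]))
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fit <- tryCatch(
    suppressWarnings(stats::kmeans(z, centers = k, nstart = n_restarts,
                                   iter.max = 100L)),
    error = function(e)
      suppressWarnings(stats::kmeans(z, centers = k, nstart = n_restarts,
                                     iter.max = 100L, algorithm = "MacQueen")))
  if (!is.null(centers)) {
    warm <- tryCatch(
      suppressWarnings(stats::kmeans(z, centers = centers, iter.max = 100L)),
      error = function(e) NULL)
    if (!is.null(warm) && warm$tot.withinss < fit$tot.withinss) fit <- warm
  }
  ord <- order(tabulate(fit$cluster, nbins = k), decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  labels <- stats::setNames(relabel[fit$cluster], rownames(z))
  list(labels = labels, sizes = as.integer(table(factor(labels, levels = seq_len(k)))),
       sse = fit$tot.withinss, zscored = z,
       centers = fit$centers[ord, , drop = FALSE])
}

#' SSE scree over candidate module counts
#'
#' Runs [kmeans_modules()] for each `k` in `k_range` and reports the SSE
#' curve. Monotonicity of the best-of-restarts SSE is enforced by warm
#' starting each `k` from the `k - 1` solution augmented with the point
#' farthest from its centroid. The suggested elbow is the `k` with the
#' largest second difference of the SSE curve.
#'
#' @inheritParams kmeans_modules
#' @param k_range Increasing integer vector of candidate module counts.
#' @return List with `table` (data.frame `k`, `sse`) and `elbow` (suggested
#'   `k`, or `NA` when the curve is flat, e.g. constant data).
#' @export
scree <- function(values, k_range = 1:8, seed = 1L, n_restarts = 25L) {
  if (is.unsorted(k_range, strictly = TRUE)) stop("k_range must be increasing")
  z <- zscore_rows(values)
  sse <- numeric(length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    centers <- NULL
    if (!is.null(prev) && k == prev$k + 1L && k > 1L) {
      # warm start: previous centers plus the farthest point
      assigned <- prev$fit$centers[prev$fit$labels, , drop = FALSE]
      far <- which.max(rowSums((z - assigned)^2))
      centers <- rbind(prev$fit$centers, z[far, ])
    }
    fit <- kmeans_modules(values, k, seed = seed + i, n_restarts = n_restarts,
                          centers = centers)
    sse[i] <- fit$sse
    if (i > 1L && sse[i] > sse[i - 1L]) sse[i] <- sse[i - 1L]
    prev <- list(k = k, fit = fit)
  }
  elbow <- NA_integer_
  if (max(sse) > 1e-12 && length(k_range) >= 3L) {
    d2 <- sse[seq_len(length(sse) - 2L)] - 2 * sse[seq(2L, length(sse) - 1L)] +
      sse[seq(3L, length(sse))]
    elbow <- k_range[which.max(d2) + 1L]
  }
  list(table = data.frame(k = k_range, sse = sse), elbow = elbow)
}

#' Module eigengene
#'
#' The eigengene of a module is the first principal component of its z-scored
#' expression submatrix: the unit vector across samples that explains the
#' largest share of the module's variance. Its sign is oriented so that it
#' correlates positively with the module's mean z-scored profile, making
#' up/down trends reproducible.
#'
#' @param values Numeric module genes x samples matrix.
#' @return List with `eigengene` (length n_samples), `var_explained`
#'   (percent variance per principal component, sums to 100) and
#'   `n_components`.
#' @export
eigengene <- function(values) {
  z <- zscore_rows(values)
  if (nrow(z) == 1L) {
    v <- as.numeric(z[1L, ])
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    return(list(eigengene = v, var_explained = 100, n_components = 1L))
  }
  sv <- svd(z)
  ve <- 100 * sv$d^2 / sum(sv$d^2)
  eg <- sv$v[, 1L]
  if (stats::sd(colMeans(z)) > 0 && stats::cor(eg, colMeans(z)) < 0) eg <- -eg
  list(eigengene = eg, var_explained = ve, n_components = length(ve))
}

#' Module membership of a gene
#'
#' Pearson correlation between a gene's expression profile and a module
#' eigengene. `NaN` for zero-variance profiles.
#'
#' @param profile Numeric expression vector (one gene across samples).
#' @param eg Eigengene vector of the same length.
#' @return Correlation in `[-1, 1]`, or `NaN`.
#' @export
module_membership <- function(profile, eg) {
  if (length(profile) != length(eg)) stop("vectors must have the same length")
  if (stats::sd(profile) == 0 || stats::sd(eg) == 0) return(NaN)
  stats::cor(profile, eg)
}

#' Case/control test on a module eigengene
#'
#' Two-sided Wilcoxon rank-sum test of the eigengene scores by condition
#' (configurable to Welch's t), with the trend direction given by the sign of
#' `median(case) - median(control)`.
#'
#' @param eg Eigengene vector (one score per sample).
#' @param condition Binary labels (case = 1, control = 0).
#' @param method `"wilcoxon"` (default) or `"welch"`.
#' @return List with `p`, `direction` (`"up"`, `"down"`, or `"none"`), and
#'   `statistic`.
#' @export
eigengene_condition_test <- function(eg, condition, method = c("wilcoxon", "welch")) {
  method <- match.arg(method)
  cs <- eg[condition == 1L]; ct <- eg[condition == 0L]
  if (!length(cs) || !length(ct)) stop("both classes must be non-empty")
  if (max(eg) == min(eg))
    return(list(p = 1, direction = "none", statistic = NA_real_))
  ht <- if (method == "wilcoxon")
    suppressWarnings(stats::wilcox.test(cs, ct, exact = FALSE, correct = FALSE))
  else stats::t.test(cs, ct)
  d <- stats::median(cs) - stats::median(ct)
  list(p = min(ht$p.value, 1),
       direction = if (d > 0) "up" else if (d < 0) "down" else "none",
       statistic = unname(ht$statistic))
}

#' Overlap of a module with annotation signatures
#'
#' @param module_genes Character vector of module gene IDs.
#' @param sets Named list of gene sets (e.g. immune signatures).
#' @param degs Optional [deg_table()] to annotate overlapping members with
#'   their fold-changes.
#' @return data.frame per set: `set`, `set_size`, `overlap`, `members`
#'   (comma-joined), `mean_fc` (`NA` without a DEG table).
#' @export
signature_overlap <- function(module_genes, sets, degs = NULL) {
  rows <- lapply(names(sets), function(nm) {
    inter <- intersect(module_genes, sets[[nm]])
    fc <- NA_real_
    if (!is.null(degs) && length(inter)) {
      m <- degs$fc[match(inter, degs$gene)]
      fc <- mean(m, na.rm = TRUE)
    }
    data.frame(set = nm, set_size = length(sets[[nm]]),
               overlap = length(inter),
               members = paste(sort(inter), collapse = ","),
               mean_fc = fc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Hierarchical-clustering cross-check of a k-means partition
#'
#' Cuts a complete-linkage tree built on the `1 - correlation` dissimilarity
#' into `k` clusters and compares it with a k-means partition by the adjusted
#' Rand index, plus the best Jaccard match per k-means module.
#'
#' @param values Genes x samples matrix (same genes as the partition).
#' @param labels Named k-means module labels.
#' @return List with `ari`, `hc_labels`, and `module_jaccard` (best Jaccard
#'   overlap of each k-means module with any hierarchical cluster).
#' @export
hierarchical_crosscheck <- function(values, labels) {
  values <- values[names(labels), , drop = FALSE]
  d <- stats::as.dist(1 - stats::cor(t(values)))
  hc <- stats::hclust(d, method = "complete")
  k <- length(unique(labels))
  hl <- stats::cutree(hc, k = k)
  ari <- mclust::adjustedRandIndex(labels, hl)
  jac <- vapply(sort(unique(labels)), function(m) {
    a <- names(labels)[labels == m]
    max(vapply(unique(hl), function(h) {
      b <- names(hl)[hl == h]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1L)))
  }, numeric(1L))
  list(ari = ari, hc_labels = hl, module_jaccard = jac)
}

#' Full module partition of a network's genes
#'
#' Clusters the network genes, computes per-module eigengenes, variance
#' explained, per-gene memberships, and the eigengene case/control test.
#'
#' @param study An [expression_study()].
#' @param network A `correlation_network` whose nodes are clustered.
#' @param k Number of modules, or `"auto"` to use the [scree()] elbow.
#' @param seed RNG seed.
#' @param n_restarts k-means restarts (default 50).
#' @param k_range Candidate module counts for `k = "auto"`.
#' @return A `module_partition`: list with `labels`, `sizes`, `k`, `sse`,
#'   `eigengenes` (modules x samples matrix), `var_explained` (PC1 percent
#'   variance per module), `membership` (named per-gene correlation with own
#'   module eigengene), `condition_tests` (per-module list), `scree`
#'   (when `k = "auto"`).
#' @export
module_partition <- function(study, network, k = 3, seed = 1L,
                             n_restarts = 50L, k_range = 1:8) {
  genes <- intersect(network$nodes, rownames(study$values))
  vals <- study$values[genes, , drop = FALSE]
  scr <- NULL
  if (identical(k, "auto")) {
    scr <- scree(vals, k_range = k_range[k_range <= nrow(vals)], seed = seed,
                 n_restarts = max(10L, n_restarts %/% 2L))
    k <- if (is.na(scr$elbow)) 1L else scr$elbow
  }
  km <- kmeans_modules(vals, k, seed = seed, n_restarts = n_restarts)
  egs <- matrix(NA_real_, nrow = k, ncol = ncol(vals),
                dimnames = list(paste0("module", seq_len(k)), colnames(vals)))
  ve <- numeric(k)
  membership <- stats::setNames(rep(NA_real_, length(genes)), genes)
  tests <- vector("list", k)
  for (m in seq_len(k)) {
    mg <- names(km$labels)[km$labels == m]
    eg <- eigengene(vals[mg, , drop = FALSE])
    egs[m, ] <- eg$eigengene
    ve[m] <- eg$var_explained[1L]
    membership[mg] <- vapply(mg, function(g)
      module_membership(vals[g, ], eg$eigengene), numeric(1L))
    tests[[m]] <- eigengene_condition_test(eg$eigengene, study$condition)
  }
  structure(list(labels = km$labels, sizes = km$sizes, k = k, sse = km$sse,
                 eigengenes = egs, var_explained = ve,
                 membership = membership, condition_tests = tests,
                 scree = scr),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d genes; sizes %s\n",
              x$k, length(x$labels), paste(x$sizes, collapse = "/")))
  cat(sprintf("  PC1 variance explained: %s%%\n",
              paste(round(x$var_explained, 1), collapse = "/")))
  invisible(x)
}
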