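#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with the standard
#' defaults: 1% FDR for DEG calling, the 98th percentile of the absolute
#' correlation distribution for the network threshold, hubs at degree > 5,
#' date/party APCC boundary 0.5, switch region `z_g < 2.5` and `K_pi > 0.8`,
#' and 1000 randomization replicates.
#'
#' @param fdr_threshold DEG false-discovery-rate level.
#' @param correlation_percentile Percentile of `|rho|` defining the network
#'   threshold.
#' @param k_modules Number of k-means modules, or `"auto"` for the scree
#'   elbow.
#' @param n_restarts k-means restarts.
#' @param hub_degree_min Hub degree cutoff (strictly greater than).
#' @param apcc_date_party_cut Date/party APCC boundary.
#' @param switch_zg_max Switch-region `z_g` bound.
#' @param switch_kpi_min Switch-region `K_pi` bound (strict `>`).
#' @param n_null_reps Replicates for the randomization nulls.
#' @param rng_seed Master seed; each randomized stage derives its own stream
#'   from this seed and the stage name, so stages are reproducible
#'   independently of execution order.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fdr_threshold = 0.01, correlation_percentile = 98,
                            k_modules = 3, n_restarts = 50L,
                            hub_degree_min = 5L, apcc_date_party_cut = 0.5,
                            switch_zg_max = 2.5, switch_kpi_min = 0.8,
                            n_null_reps = 1000L, rng_seed = 1L) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            correlation_percentile > 0, correlation_percentile <= 100,
            identical(k_modules, "auto") || k_modules >= 1,
            hub_degree_min >= 0, switch_kpi_min >= 0, switch_kpi_min <= 1,
            n_null_reps >= 1)
  structure(list(fdr_threshold = fdr_threshold,
                 correlation_percentile = correlation_percentile,
                 k_modules = k_modules, n_restarts = as.integer(n_restarts),
                 hub_degree_min = as.integer(hub_degree_min),
                 apcc_date_party_cut = apcc_date_party_cut,
                 switch_zg_max = switch_zg_max,
                 switch_kpi_min = switch_kpi_min,
                 n_null_reps = as.integer(n_null_reps),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Derive a stage-specific seed from the master seed
#'
#' @param seed Master integer seed.
#' @param stage Stage name.
#' @return Integer seed (< 2^31), a deterministic function of both arguments.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) + 1009 * h) %% 2147483647)
}

#' Run the full switch-gene pipeline
#'
#' Executes every stage on an expression study: differential expression,
#' correlation-network construction at the configured percentile threshold,
#' module detection with eigengenes, node cartography and switch-gene
#' extraction, the edge-shuffle switch-count null, node-removal robustness
#' curves, and (when gene sets / an interactome are supplied) the gene-set
#' overlap null, the switch-neighbor report and null, and interactome
#' proximity/separation with a degree-matched null. When `out_dir` is given,
#' every stage's table is written as TSV (plus the network as a signed edge
#' list and GraphML) and a plain-text log records parameters and seeds.
#'
#' @param study An [expression_study()].
#' @param config A [pipeline_config()].
#' @param gene_sets Optional named list of gene sets; a set named `"gwas"`
#'   (case-insensitive) is used for the overlap and neighbor nulls.
#' @param interactome Optional igraph interactome; proximity is computed
#'   between the pipeline's switch genes and `proximity_set` on it.
#' @param proximity_set Optional character vector: second gene list for the
#'   proximity stage.
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with elements `degs`, `network`, `sweep`,
#'   `scale_free`, `partition`, `cartography`, `switch_genes`, `switch_null`,
#'   `robustness`, and (when inputs allow) `overlap_null`, `neighbor_null`,
#'   `proximity`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), gene_sets = NULL,
                         interactome = NULL, proximity_set = NULL,
                         out_dir = NULL) {
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  res <- list(config = config)

  say("deg: fitting per-gene models (fdr <= %g)", config$fdr_threshold)
  res$degs <- stage("deg", deg_table(study, config$fdr_threshold))
  calls <- call_degs(res$degs)
  deg_genes <- res$degs$gene[res$degs$deg]
  say("deg: %d DEGs (%d up / %d down)", length(deg_genes),
      length(calls$up), length(calls$down))
  finish_empty <- function(res, why) {
    say("pipeline: %s; no network structure, 0 switch genes", why)
    res$switch_genes <- extract_switch_genes(empty_cartography(), res$degs)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_tsv(res$degs, file.path(out_dir, "deg_table.tsv"))
      write_tsv(res$switch_genes, file.path(out_dir, "switch_genes.tsv"))
      writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    }
    invisible(res)
  }
  if (length(deg_genes) < 3L)
    return(finish_empty(res, sprintf("only %d DEGs (need >= 3 to correlate)",
                                     length(deg_genes))))

  say("network: correlations over %d DEGs, percentile %g",
      length(deg_genes), config$correlation_percentile)
  res$network <- stage("network", {
    cors <- pearson_matrix(study$values[deg_genes, , drop = FALSE])
    tau <- percentile_threshold(cors, config$correlation_percentile)
    net <- build_network(cors, tau)
    net
  })
  res$scale_free <- suppressWarnings(scale_free_fit(res$network))
  say("network: tau = %.4f; %d nodes, %d edges; signed R2 = %.3f",
      res$network$tau, length(res$network$nodes),
      igraph::ecount(res$network$graph), res$scale_free$signed_r2)
  if (!length(res$network$nodes))
    return(finish_empty(res, "no correlation exceeds the threshold"))

  say("cluster: k = %s, %d restarts", format(config$k_modules),
      config$n_restarts)
  res$partition <- stage("cluster",
    module_partition(study, res$network, k = config$k_modules,
                     seed = stage_seed(config$rng_seed, "cluster"),
                     n_restarts = config$n_restarts))
  say("cluster: %d modules, sizes %s; PC1 var %s%%", res$partition$k,
      paste(res$partition$sizes, collapse = "/"),
      paste(round(res$partition$var_explained, 1), collapse = "/"))

  say("cartography: hubs at degree > %d", config$hub_degree_min)
  res$cartography <- stage("cartography",
    node_cartography(res$network, res$partition$labels,
                     hub_degree_min = config$hub_degree_min,
                     apcc_cut = config$apcc_date_party_cut,
                     zg_max = config$switch_zg_max,
                     kpi_min = config$switch_kpi_min))
  res$switch_genes <- extract_switch_genes(res$cartography, res$degs)
  say("cartography: %d fight-club / %d date / %d party hubs; %d switch genes",
      sum(res$cartography$class == "fight-club"),
      sum(res$cartography$class == "date"),
      sum(res$cartography$class == "party"), nrow(res$switch_genes))

  say("nulls: switch-count edge shuffle, %d reps", config$n_null_reps)
  res$switch_null <- stage("nulls",
    switch_count_null(res$network, res$partition$labels,
                      observed = nrow(res$switch_genes),
                      reps = config$n_null_reps,
                      seed = stage_seed(config$rng_seed, "switch_null"),
                      hub_degree_min = config$hub_degree_min,
                      apcc_cut = config$apcc_date_party_cut,
                      zg_max = config$switch_zg_max,
                      kpi_min = config$switch_kpi_min))
  say("nulls: null mean %.2f sd %.2f, z = %.2f", res$switch_null$mean,
      res$switch_null$sd, res$switch_null$z)

  gwas <- NULL
  if (!is.null(gene_sets)) {
    hit <- grep("^gwas$", names(gene_sets), ignore.case = TRUE)
    if (length(hit)) gwas <- gene_sets[[hit[1L]]]
  }
  if (!is.null(gwas)) {
    say("nulls: DEG overlap with %d-gene target set", length(gwas))
    res$overlap_null <- stage("nulls",
      geneset_overlap_null(res$degs$gene, length(deg_genes),
                           intersect(gwas, res$degs$gene),
                           observed = length(intersect(gwas, deg_genes)),
                           reps = config$n_null_reps,
                           seed = stage_seed(config$rng_seed, "overlap_null")))
    if (nrow(res$switch_genes)) {
      res$neighbor_null <- stage("nulls",
        neighbor_shuffle_null(res$switch_genes$gene, res$network, gwas,
                              reps = config$n_null_reps,
                              seed = stage_seed(config$rng_seed,
                                                "neighbor_null")))
    }
  }

  say("robustness: removal curves")
  res$robustness <- stage("robustness", {
    n_sw <- nrow(res$switch_genes)
    if (n_sw == 0L) NULL else {
      orders <- removal_orders(res$cartography,
                               seed = stage_seed(config$rng_seed, "robustness"))
      lapply(stats::setNames(names(orders), names(orders)), function(o)
        removal_curve(res$network, orders[[o]], strategy = o))
    }
  })

  if (!is.null(interactome) && !is.null(proximity_set) &&
      nrow(res$switch_genes)) {
    say("proximity: degree-matched null, %d reps", config$n_null_reps)
    res$proximity <- stage("proximity",
      degree_matched_null(res$switch_genes$gene, proximity_set, interactome,
                          reps = max(100L, config$n_null_reps),
                          seed = stage_seed(config$rng_seed, "proximity")))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pipeline_outputs(res, out_dir)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  }
  invisible(res)
}

# Internal: serialize the result bundle as TSV tables (+ GraphML network).
write_pipeline_outputs <- function(res, out_dir) {
  write_tsv(res$degs, file.path(out_dir, "deg_table.tsv"))
  el <- igraph::as_edgelist(res$network$graph, names = TRUE)
  write_tsv(data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                       r = igraph::E(res$network$graph)$rho),
            file.path(out_dir, "network_edges.tsv"))
  igraph::write_graph(res$network$graph,
                      file.path(out_dir, "network.graphml"),
                      format = "graphml")
  write_tsv(data.frame(gene = names(res$partition$labels),
                       module = unname(res$partition$labels),
                       membership = unname(res$partition$membership)),
            file.path(out_dir, "partition.tsv"))
  eg <- data.frame(module = rownames(res$partition$eigengenes),
                   res$partition$eigengenes, check.names = FALSE)
  write_tsv(eg, file.path(out_dir, "eigengenes.tsv"))
  write_tsv(res$cartography, file.path(out_dir, "cartography.tsv"))
  write_tsv(res$switch_genes, file.path(out_dir, "switch_genes.tsv"))
  null_df <- data.frame(test = "switch_count",
                        observed = res$switch_null$observed,
                        null_mean = res$switch_null$mean,
                        null_sd = res$switch_null$sd,
                        z = res$switch_null$z, p = res$switch_null$p,
                        p_empirical = res$switch_null$p_empirical)
  if (!is.null(res$overlap_null)) {
    o <- res$overlap_null
    null_df <- rbind(null_df,
      data.frame(test = "deg_target_overlap", observed = o$observed,
                 null_mean = o$mean, null_sd = o$sd, z = o$z, p = o$p,
                 p_empirical = o$p_empirical))
  }
  if (!is.null(res$neighbor_null)) {
    for (side in c("positive", "negative")) {
      o <- res$neighbor_null[[side]]
      null_df <- rbind(null_df,
        data.frame(test = paste0("neighbor_", side), observed = o$observed,
                   null_mean = o$mean, null_sd = o$sd, z = o$z, p = o$p,
                   p_empirical = o$p_empirical))
    }
  }
  write_tsv(null_df, file.path(out_dir, "null_summaries.tsv"))
  if (!is.null(res$robustness)) {
    for (nm in names(res$robustness))
      write_tsv(res$robustness[[nm]],
                file.path(out_dir, paste0("robustness_", nm, ".tsv")))
  }
  if (!is.null(res$proximity)) {
    pr <- res$proximity
    write_tsv(data.frame(p_observed = pr$p_observed, null_mean = pr$null$mean,
                         null_sd = pr$null$sd, z = pr$null$z, p = pr$null$p,
                         separation = pr$separation,
                         n_s1_mapped = pr$n_s1_mapped,
                         n_s2_mapped = pr$n_s2_mapped),
              file.path(out_dir, "proximity.tsv"))
  }
  invisible(out_dir)
}
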