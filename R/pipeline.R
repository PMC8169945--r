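# End-to-end orchestration: network assembly -> core extraction ->
# per-feature subnetworks -> three-tool enrichment with semantic merging
# -> keyword permutation enrichment -> stratification -> overlap
# statistics -> summary report.

#' Pipeline configuration
#'
#' Inputs may be file paths (read with the package's readers) or in-memory
#' tibbles. All defaults mirror the documented analysis parameters:
#' score threshold 3, merged-term alpha 0.0166 (= 0.05/3, truncated),
#' at least 4 genes per retained term, block confirmation by at least 2 of
#' 3 tools, cluster counts 2..6, and 100,000 keyword simulations.
#'
#' @param ppi,seeds,corpus,dictionary inputs (paths or tibbles).
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes all artifact files there.
#' @param min_score edge retention threshold.
#' @param alpha merged-term significance threshold.
#' @param block_alpha per-tool block-confirmation threshold.
#' @param min_genes minimum genes per retained term.
#' @param min_tools minimum confirming tools per block.
#' @param tools enrichment tool configurations (see [ora_tools()]).
#' @param aspect annotation aspect used for functional profiles.
#' @param features clinical feature codes to slice; default: all codes
#'   observed in the seed table.
#' @param keyword_specs keyword panel (see [default_keyword_specs()]).
#' @param n_sims keyword permutation simulations.
#' @param mode profile value type, `"percent"` or `"count"`.
#' @param linkage agglomeration method.
#' @param k_range candidate cluster counts.
#' @param scales,n_boot multiscale bootstrap settings.
#' @param rng_seed mandatory integer seed for every stochastic stage.
#' @return an `hsp_config` list.
#' @export
pipeline_config <- function(ppi, seeds, corpus, dictionary, out_dir = NULL,
                            min_score = 3, alpha = bonferroni_alpha(),
                            block_alpha = 0.05, min_genes = 4, min_tools = 2,
                            tools = ora_tools(), aspect = "BP",
                            features = NULL,
                            keyword_specs = default_keyword_specs(),
                            n_sims = 1e5, mode = "percent",
                            linkage = "complete", k_range = 2:6,
                            scales = seq(0.5, 1.4, by = 0.1), n_boot = 1000,
                            rng_seed = 1L) {
  config <- structure(
    list(ppi = ppi, seeds = seeds, corpus = corpus, dictionary = dictionary,
         out_dir = out_dir, min_score = min_score, alpha = alpha,
         block_alpha = block_alpha, min_genes = min_genes,
         min_tools = min_tools, tools = tools, aspect = aspect,
         features = features, keyword_specs = keyword_specs,
         n_sims = n_sims, mode = mode, linkage = linkage, k_range = k_range,
         scales = scales, n_boot = n_boot, rng_seed = rng_seed),
    class = "hsp_config")
  validate_pipeline_config(config)
  config
}

validate_pipeline_config <- function(config) {
  with(config, {
    if (!is.numeric(min_score) || min_score < 0) config_error("`min_score` must be >= 0.")
    if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) config_error("`alpha` must be in (0, 1].")
    if (!is.numeric(block_alpha) || block_alpha <= 0 || block_alpha > 1) {
      config_error("`block_alpha` must be in (0, 1].")
    }
    if (!is_count(min_genes, 0)) config_error("`min_genes` must be a count.")
    if (!is_count(min_tools, 1)) config_error("`min_tools` must be a count >= 1.")
    if (length(tools) < min_tools) config_error("Need at least `min_tools` tool configurations.")
    if (!mode %in% c("percent", "count")) config_error("`mode` must be percent or count.")
    if (!is.numeric(n_sims) || n_sims < 100) config_error("`n_sims` must be >= 100.")
    if (!is_count(n_boot, 1)) config_error("`n_boot` must be a count >= 1.")
    if (is.null(rng_seed) || !is_count(abs(rng_seed))) {
      config_error("`rng_seed` is mandatory (stochastic stages must be seeded).")
    }
  })
  invisible(config)
}

#' Read / write a pipeline configuration as YAML
#'
#' Only path-based inputs and scalar parameters are serialized; a reloaded
#' configuration reproduces the run.
#'
#' @param path YAML file.
#' @return `read_pipeline_config()` returns an `hsp_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- if (!is.null(y$keyword_specs)) {
    imap(y$keyword_specs, ~keyword_spec(.y, unlist(.x)))
  } else default_keyword_specs()
  pipeline_config(
    ppi = y$ppi, seeds = y$seeds, corpus = y$corpus,
    dictionary = y$dictionary, out_dir = y$out_dir,
    min_score = y$min_score %||% 3,
    alpha = y$alpha %||% bonferroni_alpha(),
    block_alpha = y$block_alpha %||% 0.05,
    min_genes = y$min_genes %||% 4, min_tools = y$min_tools %||% 2,
    tools = y$tools %||% ora_tools(), aspect = y$aspect %||% "BP",
    features = y$features, keyword_specs = specs,
    n_sims = y$n_sims %||% 1e5, mode = y$mode %||% "percent",
    linkage = y$linkage %||% "complete",
    k_range = (y$k_min %||% 2):(y$k_max %||% 6),
    scales = y$scales %||% seq(0.5, 1.4, by = 0.1),
    n_boot = y$n_boot %||% 1000, rng_seed = y$rng_seed)
}

#' @param config an `hsp_config` whose inputs are file paths.
#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(is.character(config$ppi), is.character(config$seeds),
            is.character(config$corpus), is.character(config$dictionary))
  y <- list(ppi = config$ppi, seeds = config$seeds, corpus = config$corpus,
            dictionary = config$dictionary, out_dir = config$out_dir,
            min_score = config$min_score, alpha = config$alpha,
            block_alpha = config$block_alpha, min_genes = config$min_genes,
            min_tools = config$min_tools, tools = config$tools,
            aspect = config$aspect, features = config$features,
            keyword_specs = map(config$keyword_specs, "prefixes"),
            n_sims = config$n_sims, mode = config$mode,
            linkage = config$linkage,
            k_min = min(config$k_range), k_max = max(config$k_range),
            scales = config$scales, n_boot = config$n_boot,
            rng_seed = config$rng_seed)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}

load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

merged_enrichment_for <- function(genes, corpus, dictionary, config) {
  results <- map(config$tools, function(tool) {
    res <- suppressWarnings(
      run_ora(genes, corpus, tool = tool, aspect = config$aspect))
    classify_terms(res, dictionary)
  })
  merge_tool_results(results, alpha = config$alpha,
                     block_alpha = config$block_alpha,
                     min_genes = config$min_genes,
                     min_tools = config$min_tools)
}

#' Run the whole stratification pipeline
#'
#' Executes every stage on the configured inputs and returns the full
#' report bundle; when `out_dir` is set, also writes edge lists, GraphML,
#' merged terms, block profiles, the embedding, the dendrogram JSON,
#' cluster assignments, overlaps, keyword table and a plain-text summary.
#' All stochastic stages (keyword permutation, multiscale bootstrap) are
#' driven by `config$rng_seed`, so a rerun with the same configuration
#' reproduces every number.
#'
#' @param config an `hsp_config` from [pipeline_config()].
#' @return an `hsp_pipeline` list: `network`, `components`, `core`,
#'   `subnetworks`, `core_enrichment`, `profiles`, `stratification`,
#'   `cluster_enrichment`, `fold_changes`, `overlaps`, `overlap_p`,
#'   `keywords`, `summary`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  ppi <- load_input(config$ppi, read_ppi)
  seeds <- load_input(config$seeds, read_seeds)
  corpus <- load_input(config$corpus, read_go_corpus)
  dictionary <- load_input(config$dictionary, read_dictionary)

  inform(sprintf("Building global network from %d records (%d seeds), min score %d",
                 nrow(ppi), nrow(seeds), config$min_score))
  network <- build_global_network(ppi, seeds, min_score = config$min_score)
  components <- component_summary(network)
  core <- extract_core(network)
  inform(sprintf("Global: %d nodes / %d edges; core: %d nodes / %d edges",
                 nrow(network$nodes), nrow(network$edges),
                 nrow(core$nodes), nrow(core$edges)))

  features <- config$features %||%
    sort(unique(unlist(seeds$features)))
  subnetworks <- map(setNames(features, features), function(f) {
    extract_clinical_subnetwork(core, seeds, f)
  })
  subnetworks <- keep(subnetworks, ~nrow(.x$nodes) > 0)

  core_enrichment <- merged_enrichment_for(core$nodes$gene, corpus,
                                           dictionary, config)
  inform(sprintf("Core enrichment: %d merged terms in %d blocks",
                 nrow(core_enrichment$terms),
                 length(core_enrichment$blocks_kept)))

  sub_merges <- imap(subnetworks, function(net, label) {
    merged_enrichment_for(net$nodes$gene, corpus, dictionary, config)
  })
  profiles <- imap(sub_merges, function(mrg, label) {
    block_profile(mrg$terms, label = label)
  }) %>% bind_rows()
  if (length(unique(profiles$label)) < 2) {
    abort("Stage 'stratification' failed: fewer than two subnetworks have enrichment profiles.",
          class = "hspnet_stage_error")
  }

  strat <- run_stratification(profiles, mode = config$mode,
                              linkage = config$linkage,
                              k_range = config$k_range,
                              scales = config$scales, n_boot = config$n_boot,
                              rng_seed = config$rng_seed)

  ## per-cluster enrichment (union of member subnetwork nodes) vs the core
  clusters <- split(strat$assignments$label, strat$assignments$cluster)
  cluster_labels <- map_chr(clusters, ~paste(sort(.x), collapse = ""))
  cluster_enrichment <- map(clusters, function(members) {
    genes <- unique(unlist(map(subnetworks[members], ~.x$nodes$gene)))
    merged_enrichment_for(genes, corpus, dictionary, config)
  })
  names(cluster_enrichment) <- cluster_labels
  fold_changes <- imap(cluster_enrichment, function(mrg, label) {
    profile_fold_change(mrg$profile, core_enrichment$profile) %>%
      mutate(cluster = label, .before = 1)
  }) %>% bind_rows()

  ## node-set overlaps, within vs between clusters
  gene_sets <- map(subnetworks, ~.x$nodes$gene)
  overlaps <- pairwise_overlaps(gene_sets)
  assign_of <- setNames(strat$assignments$cluster, strat$assignments$label)
  overlaps <- overlaps %>%
    mutate(same_cluster = assign_of[.data$from] == assign_of[.data$to])
  overlap_p <- if (sum(overlaps$same_cluster) >= 2 &&
                   sum(!overlaps$same_cluster) >= 2) {
    overlap_ttest(overlaps$overlap_pct[overlaps$same_cluster],
                  overlaps$overlap_pct[!overlaps$same_cluster])
  } else NA_real_

  keywords <- keyword_enrichment(core_enrichment$terms$term_name,
                                 corpus$term_name,
                                 specs = config$keyword_specs,
                                 n_sims = config$n_sims,
                                 rng_seed = config$rng_seed)

  n_seeds_in <- sum(network$nodes$is_seed)
  summary <- list(
    global_nodes = nrow(network$nodes),
    global_edges = nrow(network$edges),
    seeds_retained = format_count_percentage(n_seeds_in, nrow(seeds)),
    main_component = format_count_percentage(components$main_component_nodes,
                                             max(1, nrow(network$nodes))),
    n_components = components$n_components,
    core_nodes = nrow(core$nodes),
    core_edges = nrow(core$edges),
    seeds_in_core = format_count_percentage(sum(core$nodes$is_seed),
                                            max(1, n_seeds_in)),
    merged_terms = nrow(core_enrichment$terms),
    best_k = strat$silhouette$best_k,
    main_branch_au = main_branch_au(strat$au),
    overlap_p = overlap_p,
    rng_seed = config$rng_seed
  )
  inform(sprintf("Stratification: best k = %d; root-split AU = %s",
                 summary$best_k,
                 paste(sprintf("%.2f", summary$main_branch_au), collapse = ", ")))

  result <- structure(
    list(network = network, components = components, core = core,
         subnetworks = subnetworks, core_enrichment = core_enrichment,
         profiles = profiles, stratification = strat,
         cluster_enrichment = cluster_enrichment,
         fold_changes = fold_changes, overlaps = overlaps,
         overlap_p = overlap_p, keywords = keywords, summary = summary,
         config = config),
    class = "hsp_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_network_edges(result$network, file.path(dir, "global_edges.tsv"))
  write_network_graphml(result$network, file.path(dir, "global.graphml"))
  write_network_edges(result$core, file.path(dir, "core_edges.tsv"))
  write_network_graphml(result$core, file.path(dir, "core.graphml"))
  readr::write_tsv(result$core_enrichment$terms,
                   file.path(dir, "merged_terms.tsv"))
  readr::write_tsv(result$core_enrichment$profile,
                   file.path(dir, "block_profile.tsv"))
  readr::write_tsv(result$profiles, file.path(dir, "subnetwork_profiles.tsv"))
  readr::write_tsv(result$stratification$embedding$scores,
                   file.path(dir, "embedding.tsv"))
  write_dendrogram_json(result$stratification$au,
                        file.path(dir, "dendrogram.json"))
  readr::write_tsv(result$stratification$assignments,
                   file.path(dir, "clusters.tsv"))
  readr::write_tsv(result$overlaps, file.path(dir, "overlaps.tsv"))
  readr::write_tsv(result$keywords, file.path(dir, "keywords.tsv"))
  readr::write_tsv(result$fold_changes, file.path(dir, "fold_changes.tsv"))
  summary_lines <- c(
    sprintf("global network: %d nodes, %d edges",
            result$summary$global_nodes, result$summary$global_edges),
    sprintf("seeds retained: %s", result$summary$seeds_retained),
    sprintf("main component: %s of nodes (%d components)",
            result$summary$main_component, result$summary$n_components),
    sprintf("core network: %d nodes, %d edges",
            result$summary$core_nodes, result$summary$core_edges),
    sprintf("seeds in core: %s", result$summary$seeds_in_core),
    sprintf("merged terms: %d", result$summary$merged_terms),
    sprintf("best k (silhouette): %d", result$summary$best_k),
    sprintf("root-split AU: %s",
            paste(sprintf("%.3f", result$summary$main_branch_au), collapse = ", ")),
    sprintf("within vs between overlap Welch p: %s",
            format(result$summary$overlap_p)),
    sprintf("rng seed: %d", result$summary$rng_seed))
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.hsp_pipeline <- function(x, ...) {
  cat("<hsp_pipeline>\n")
  cat(sprintf("  global: %d nodes / %d edges; core: %d nodes / %d edges\n",
              x$summary$global_nodes, x$summary$global_edges,
              x$summary$core_nodes, x$summary$core_edges))
  cat(sprintf("  merged terms: %d; best k: %d; root-split AU: %s\n",
              x$summary$merged_terms, x$summary$best_k,
              paste(sprintf("%.2f", x$summary$main_branch_au), collapse = ", ")))
  invisible(x)
}
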