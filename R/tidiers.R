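# broom-style tidiers for the package's result objects.

#' Tidy an `hsp_network` into its edge table
#'
#' @param x an `hsp_network`.
#' @param ... unused.
#' @return a tibble of scored edges.
#' @method tidy hsp_network
#' @export
tidy.hsp_network <- function(x, ...) {
  x$edges %>%
    mutate(n_publications = lengths(.data$publications),
           n_methods = lengths(.data$methods)) %>%
    select("gene_a", "gene_b", "score", "n_publications", "n_methods")
}

#' One-row summary of an `hsp_network`
#'
#' @param x an `hsp_network`.
#' @param ... unused.
#' @return a one-row tibble with node/edge/seed/hub counts.
#' @method glance hsp_network
#' @export
glance.hsp_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_seeds = sum(x$nodes$is_seed),
         n_test_seeds = sum(x$nodes$is_test_seed),
         n_iih = sum(x$nodes$seed_degree >= 2),
         min_score = x$min_score)
}

#' Tidy merged enrichment results into the term table
#'
#' @param x an `hsp_merge`.
#' @param ... unused.
#' @return the merged term tibble.
#' @method tidy hsp_merge
#' @export
tidy.hsp_merge <- function(x, ...) x$terms

#' One-row summary of merged enrichment results
#'
#' @param x an `hsp_merge`.
#' @param ... unused.
#' @return a one-row tibble.
#' @method glance hsp_merge
#' @export
glance.hsp_merge <- function(x, ...) {
  tibble(n_terms = nrow(x$terms), n_blocks = length(x$blocks_kept),
         alpha = x$params$alpha, min_genes = x$params$min_genes,
         min_tools = x$params$min_tools)
}

#' Tidy multiscale bootstrap results into the branch table
#'
#' @param x an `hsp_au`.
#' @param ... unused.
#' @return a tibble with one row per dendrogram branch (members collapsed
#'   to a single string).
#' @method tidy hsp_au
#' @export
tidy.hsp_au <- function(x, ...) {
  x$branches %>%
    mutate(members = map_chr(.data$members, paste, collapse = ",")) %>%
    select("branch", "members", "n_members", "bp", "au")
}

#' Tidy a stratification result into its cluster assignments
#'
#' @param x an `hsp_strat`.
#' @param ... unused.
#' @return tibble `label`, `cluster`.
#' @method tidy hsp_strat
#' @export
tidy.hsp_strat <- function(x, ...) x$assignments

#' One-row summary of a stratification result
#'
#' @param x an `hsp_strat`.
#' @param ... unused.
#' @return a one-row tibble with chosen k, silhouette and root-split AU.
#' @method glance hsp_strat
#' @export
glance.hsp_strat <- function(x, ...) {
  best <- x$silhouette$scores %>%
    filter(.data$k == x$silhouette$best_k)
  au2 <- main_branch_au(x$au)
  tibble(best_k = x$silhouette$best_k,
         mean_silhouette = best$mean_silhouette[1],
         au_main_1 = au2[1], au_main_2 = au2[2],
         pc1_var = x$embedding$var_explained[1],
         pc2_var = x$embedding$var_explained[2])
}

#' One-row summary of a pipeline run
#'
#' @param x an `hsp_pipeline`.
#' @param ... unused.
#' @return a one-row tibble of the headline counts and statistics.
#' @method glance hsp_pipeline
#' @export
glance.hsp_pipeline <- function(x, ...) {
  au2 <- x$summary$main_branch_au
  tibble(global_nodes = x$summary$global_nodes,
         global_edges = x$summary$global_edges,
         core_nodes = x$summary$core_nodes,
         core_edges = x$summary$core_edges,
         merged_terms = x$summary$merged_terms,
         best_k = x$summary$best_k,
         au_main_min = min(au2), overlap_p = x$summary$overlap_p)
}
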