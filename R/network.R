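# Evidence-scored PPI network assembly, inter-interactome-hub (IIH) core
# extraction and clinical slicing.
#
# A network is a plain list of two tibbles: `nodes` (gene, is_seed,
# is_test_seed, seed_degree) and `edges` (gene_a, gene_b, score,
# publications, methods), class "hsp_network". Global, core and clinical
# subnetworks are all this type; core/clinical extraction preserves node
# and edge attributes, so the subnetwork relation is a literal subset.

new_hsp_network <- function(nodes, edges, min_score = NA_integer_) {
  structure(list(nodes = nodes, edges = edges, min_score = min_score),
            class = "hsp_network")
}

empty_network <- function(min_score = NA_integer_) {
  new_hsp_network(
    nodes = tibble(gene = character(), is_seed = logical(),
                   is_test_seed = logical(), seed_degree = integer()),
    edges = tibble(gene_a = character(), gene_b = character(),
                   score = integer(), publications = list(), methods = list()),
    min_score = min_score)
}

#' Confidence score of one interaction
#'
#' The score is the number of distinct publications reporting the
#' interaction plus the number of distinct detection methods, a proxy for
#' replication in the curated literature. The minimum possible score is 2
#' (one publication, one method), which is exactly what the default
#' retention threshold of 3 removes.
#'
#' @param publications,methods character vectors of evidence identifiers
#'   (non-empty).
#' @return an integer score >= 2.
#' @export
#' @examples
#' score_interaction(c("p1", "p2"), "m1")
score_interaction <- function(publications, methods) {
  if (length(publications) == 0 || length(methods) == 0) {
    validation_error("Both evidence sets must be non-empty.")
  }
  length(unique(publications)) + length(unique(methods))
}

#' Score every record of a PPI table
#'
#' @param records a PPI tibble (`gene_a`, `gene_b`, list-columns
#'   `publications`, `methods`).
#' @return the input with an integer `score` column appended.
#' @export
score_interactions <- function(records) {
  if (any(lengths(records$publications) == 0) ||
      any(lengths(records$methods) == 0)) {
    validation_error("Every record needs at least one publication and one method id.")
  }
  records %>%
    mutate(score = map_int(.data$publications, ~length(unique(.x))) +
             map_int(.data$methods, ~length(unique(.x))))
}

#' Build the global seed-centred network
#'
#' Gene symbols are uppercased and whitespace-stripped, self-loops dropped,
#' and duplicate records for the same unordered pair merged by union of
#' their evidence sets *before* scoring (double-counting a replicated
#' record must not inflate its score). Edges scoring below `min_score` are
#' removed; seeds with no retained interaction are absent from the network.
#'
#' @param records PPI tibble (see [read_ppi()]).
#' @param seeds seed tibble (see [read_seeds()]); must be non-empty.
#' @param min_score retention threshold on the evidence score (default 3,
#'   i.e. interactions reported in one publication by one method are
#'   excluded).
#' @return an `hsp_network`.
#' @export
build_global_network <- function(records, seeds, min_score = 3) {
  if (nrow(seeds) == 0) validation_error("`seeds` must be non-empty.")
  if (anyDuplicated(normalize_gene(seeds$gene))) {
    validation_error("Seeds must be unique by gene.")
  }

  edges <- records %>%
    mutate(gene_a = normalize_gene(.data$gene_a),
           gene_b = normalize_gene(.data$gene_b))
  if (any(edges$gene_a == "" | edges$gene_b == "")) {
    validation_error("Gene symbols must be non-empty.")
  }
  edges <- edges %>%
    filter(.data$gene_a != .data$gene_b) %>%
    mutate(a = pmin(.data$gene_a, .data$gene_b),
           b = pmax(.data$gene_a, .data$gene_b)) %>%
    group_by(.data$a, .data$b) %>%
    summarise(publications = list(sort(unique(unlist(.data$publications)))),
              methods = list(sort(unique(unlist(.data$methods)))),
              .groups = "drop") %>%
    rename(gene_a = "a", gene_b = "b") %>%
    score_interactions() %>%
    filter(.data$score >= min_score) %>%
    select("gene_a", "gene_b", "score", "publications", "methods") %>%
    arrange(.data$gene_a, .data$gene_b)

  if (nrow(edges) == 0) {
    warn("No interaction survives the score filter; returning an empty network.")
    return(empty_network(min_score))
  }

  seed_tbl <- seeds %>%
    mutate(gene = normalize_gene(.data$gene))
  nodes <- tibble(gene = sort(unique(c(edges$gene_a, edges$gene_b)))) %>%
    left_join(seed_tbl %>% select("gene", "is_test_seed"), by = "gene") %>%
    mutate(is_seed = .data$gene %in% seed_tbl$gene,
           is_test_seed = coalesce(.data$is_test_seed, FALSE)) %>%
    select("gene", "is_seed", "is_test_seed")

  net <- new_hsp_network(nodes, edges, min_score)
  net$nodes$seed_degree <- compute_seed_degree(net)$seed_degree
  net
}

#' Seed degree of every node
#'
#' A node's seed degree is the number of *distinct* seed nodes adjacent to
#' it; nodes with seed degree >= 2 are the inter-interactome hubs (IIHs)
#' bridging two or more seed interactomes.
#'
#' @param network an `hsp_network` whose nodes carry seed flags.
#' @return a tibble `gene`, `seed_degree` in node order.
#' @export
compute_seed_degree <- function(network) {
  nodes <- network$nodes
  edges <- network$edges
  seed_set <- nodes$gene[nodes$is_seed]
  adj_pairs <- bind_rows(
    tibble(node = edges$gene_a, nb = edges$gene_b),
    tibble(node = edges$gene_b, nb = edges$gene_a)
  ) %>%
    filter(.data$nb %in% seed_set) %>%
    distinct() %>%
    count(.data$node, name = "seed_degree")
  nodes %>%
    select("gene") %>%
    left_join(adj_pairs, by = c(gene = "node")) %>%
    mutate(seed_degree = as.integer(coalesce(.data$seed_degree, 0L)))
}

induced_subnetwork <- function(network, keep_genes) {
  nodes <- network$nodes %>% filter(.data$gene %in% keep_genes)
  edges <- network$edges %>%
    filter(.data$gene_a %in% keep_genes & .data$gene_b %in% keep_genes)
  new_hsp_network(nodes, edges, network$min_score)
}

#' Extract the core network of inter-interactome hubs
#'
#' The core is the induced subgraph on the IIHs (seed degree >= 2; a seed
#' adjacent to two or more *other* seeds qualifies too) together with every
#' seed adjacent to at least one IIH. It is the most interconnected part of
#' the global network and the substrate for shared-function inference;
#' nodes interacting with a single seed are excluded.
#'
#' @param network the global `hsp_network`.
#' @return an `hsp_network` that is a subnetwork of the input (nodes,
#'   edges and attributes are preserved subsets).
#' @export
extract_core <- function(network) {
  nodes <- network$nodes
  iih <- nodes$gene[nodes$seed_degree >= 2]
  if (length(iih) == 0) {
    warn("No inter-interactome hub found; returning an empty core network.")
    return(empty_network(network$min_score))
  }
  edges <- network$edges
  nb_of_iih <- unique(c(edges$gene_b[edges$gene_a %in% iih],
                        edges$gene_a[edges$gene_b %in% iih]))
  seeds_in <- intersect(nodes$gene[nodes$is_seed], nb_of_iih)
  induced_subnetwork(network, union(iih, seeds_in))
}

#' Connected-component summary
#'
#' @param network an `hsp_network`.
#' @return a list with `n_components`, `main_component_nodes` (size of the
#'   largest component) and `components`, a tibble (`component`, `n_nodes`,
#'   `n_seeds`) sorted by decreasing size.
#' @export
component_summary <- function(network) {
  if (nrow(network$nodes) == 0) {
    return(list(n_components = 0L, main_component_nodes = 0L,
                components = tibble(component = integer(),
                                    n_nodes = integer(), n_seeds = integer())))
  }
  g <- as_igraph(network)
  comp <- igraph::components(g)
  tbl <- tibble(gene = igraph::V(g)$name,
                membership = comp$membership,
                is_seed = igraph::V(g)$is_seed) %>%
    group_by(.data$membership) %>%
    summarise(n_nodes = n(), n_seeds = sum(.data$is_seed), .groups = "drop") %>%
    arrange(desc(.data$n_nodes)) %>%
    mutate(component = row_number()) %>%
    select("component", "n_nodes", "n_seeds")
  list(n_components = as.integer(comp$no),
       main_component_nodes = as.integer(max(tbl$n_nodes)),
       components = tbl)
}

#' Extract the subnetwork of one clinical feature
#'
#' Takes the seeds carrying `feature` that are present in the core network,
#' adds all their core-network neighbours, and returns the induced
#' subgraph of the core on that node set.
#'
#' @param core the core `hsp_network`.
#' @param seeds seed tibble with the `features` list-column.
#' @param feature a single-letter clinical feature code.
#' @return an `hsp_network` (possibly empty, with a warning, when no core
#'   seed carries the feature).
#' @export
extract_clinical_subnetwork <- function(core, seeds, feature) {
  stopifnot(length(feature) == 1)
  seed_tbl <- seeds %>% mutate(gene = normalize_gene(.data$gene))
  carriers <- seed_tbl$gene[map_lgl(seed_tbl$features, ~feature %in% .x)]
  carriers <- intersect(carriers, core$nodes$gene[core$nodes$is_seed])
  if (length(carriers) == 0) {
    warn(sprintf("No core seed carries feature '%s'; returning an empty subnetwork.",
                 feature))
    return(empty_network(core$min_score))
  }
  edges <- core$edges
  nbs <- unique(c(edges$gene_b[edges$gene_a %in% carriers],
                  edges$gene_a[edges$gene_b %in% carriers]))
  induced_subnetwork(core, union(carriers, nbs))
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges %>% select("gene_a", "gene_b", "score"),
    directed = FALSE,
    vertices = network$nodes)
}

#' Write a network as a tab-separated edge list
#'
#' Columns: `gene_a`, `gene_b`, `score`, pipe-separated `publications` and
#' `methods`; directly importable into Cytoscape.
#'
#' @param network an `hsp_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_edges <- function(network, path) {
  network$edges %>%
    mutate(publications = collapse_set(.data$publications),
           methods = collapse_set(.data$methods)) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Write a network as GraphML with node attributes
#'
#' Node attributes `is_seed`, `is_test_seed`, `seed_degree` and the edge
#' `score` are carried along.
#'
#' @param network an `hsp_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @export
print.hsp_network <- function(x, ...) {
  cat(sprintf("<hsp_network> %d nodes (%d seeds, %d test seeds), %d edges\n",
              nrow(x$nodes), sum(x$nodes$is_seed & !x$nodes$is_test_seed),
              sum(x$nodes$is_test_seed), nrow(x$edges)))
  invisible(x)
}
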