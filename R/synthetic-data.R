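# Synthetic fixture generators.
#
# All three generators share one latent assignment (seed/interactor cluster
# membership, hub quota, per-seed features) drawn from `rng_seed`, then add
# their own randomness from a fixed offset of the same seed, so the PPI
# table, the annotation corpus and the clinical table are mutually
# consistent and each is reproducible on its own.

FEATURE_COUNT_WEIGHTS <- c(9, 18, 12, 7) # seeds with 1..4 features, 9:18:12:7

latent_state <- function(config) {
  withr::with_seed(config$rng_seed, {
    n_clusters <- length(config$planted_clusters)
    cl_sizes <- lengths(config$planted_clusters)
    seed_genes <- c(
      if (config$n_seeds > 0) sprintf("S%03d", seq_len(config$n_seeds)),
      if (config$n_test_seeds > 0) sprintf("T%03d", seq_len(config$n_test_seeds))
    )
    is_test <- rep(c(FALSE, TRUE), c(config$n_seeds, config$n_test_seeds))
    seed_cluster <- sample.int(n_clusters, length(seed_genes), replace = TRUE,
                               prob = cl_sizes / sum(cl_sizes))

    features <- lapply(seed_cluster, function(cl) {
      draw_features(config, cl)
    })

    if (config$n_interactors > 0) {
      interactor_genes <- sprintf("I%03d", seq_len(config$n_interactors))
      int_cluster <- sample.int(n_clusters, config$n_interactors,
                                replace = TRUE, prob = cl_sizes / sum(cl_sizes))
      n_iih <- round(config$iih_fraction * config$n_interactors)
      is_iih <- seq_len(config$n_interactors) <= n_iih
    } else {
      interactor_genes <- character()
      int_cluster <- integer()
      is_iih <- logical()
    }

    list(
      seeds = tibble(gene = seed_genes, is_test_seed = is_test,
                     cluster = seed_cluster, features = features),
      interactors = tibble(gene = interactor_genes, cluster = int_cluster,
                           is_iih = is_iih)
    )
  })
}

draw_features <- function(config, cl) {
  feats <- config$clinical_features
  own <- config$planted_clusters[[cl]]
  other <- setdiff(feats, own)
  n_max <- min(4, length(feats))
  n_feat <- sample.int(n_max, 1, prob = FEATURE_COUNT_WEIGHTS[seq_len(n_max)])
  if (length(other) == 0) {
    w <- rep(1, length(own))
    pool <- own
  } else {
    pool <- c(own, other)
    w <- c(rep(config$cluster_effect / length(own), length(own)),
           rep((1 - config$cluster_effect) / length(other), length(other)))
  }
  sort(sample(pool, n_feat, prob = w))
}

#' Generate a synthetic binary PPI table
#'
#' Emits one record per unordered gene pair with pipe-able publication and
#' detection-method evidence sets. Interactors attach to seeds by
#' preferential attachment (heavy-tailed seed degrees) under a hub quota:
#' a fraction `iih_fraction` of interactors is wired to at least two seeds
#' and, with probability `cluster_effect`, to seeds of its own planted
#' cluster. Evidence counts are 1 + Poisson, so a tunable share of records
#' has exactly one publication and one method and fails the score filter.
#'
#' @param config a [fixture_config()].
#' @return a tibble with columns `gene_a`, `gene_b`, and list-columns
#'   `publications`, `methods` (each a character vector of ids).
#' @export
generate_ppi_table <- function(config) {
  validate_fixture_config(config)
  latent <- latent_state(config)
  withr::with_seed(config$rng_seed + 1L, {
    seeds <- latent$seeds
    n_seed_total <- nrow(seeds)
    edges <- list()

    ## seed-seed edges: chain consecutive same-cluster seeds with
    ## probability seed_seed_prob; with no interactors, chain all seeds so
    ## the table is never empty.
    if (config$n_interactors == 0 && n_seed_total >= 2) {
      ord <- sample(seeds$gene)
      edges <- c(edges, map2(ord[-length(ord)], ord[-1], c))
    } else if (n_seed_total >= 2) {
      for (cl in seq_along(config$planted_clusters)) {
        members <- seeds$gene[seeds$cluster == cl]
        if (length(members) < 2) next
        members <- sample(members)
        take <- stats::runif(length(members) - 1) < config$seed_seed_prob
        edges <- c(edges, map2(members[-length(members)][take],
                               members[-1][take], c))
      }
    }

    ## interactor-seed edges
    if (config$n_interactors > 0 && n_seed_total > 0) {
      f <- config$iih_fraction
      target_edges <- n_seed_total * config$mean_partners_per_seed
      mean_k <- target_edges / config$n_interactors
      extra <- if (f > 0) max(0, (mean_k - (1 - f) - 2 * f) / f) else 0
      seed_deg <- setNames(rep(0, n_seed_total), seeds$gene)
      for (i in sample.int(config$n_interactors)) {
        gene <- latent$interactors$gene[i]
        cl <- latent$interactors$cluster[i]
        k <- if (latent$interactors$is_iih[i]) 2 + rpois(1, extra) else 1
        k <- min(k, n_seed_total)
        w_cl <- ifelse(seeds$cluster == cl, config$cluster_effect,
                       1 - config$cluster_effect)
        w <- (w_cl + 1e-9) * (seed_deg + 1)
        partners <- sample(seeds$gene, k, prob = w)
        seed_deg[partners] <- seed_deg[partners] + 1
        edges <- c(edges, map(partners, ~c(gene, .x)))
      }
    }

    if (length(edges) == 0) {
      return(tibble(gene_a = character(), gene_b = character(),
                    publications = list(), methods = list()))
    }

    gene_a <- map_chr(edges, 1)
    gene_b <- map_chr(edges, 2)
    n <- length(gene_a)
    method_pool <- sprintf("M%02d", 1:30)
    n_pub <- 1L + rpois(n, config$evidence_dist$pub_lambda)
    n_meth <- pmin(1L + rpois(n, config$evidence_dist$method_lambda), 30L)
    publications <- map(n_pub, ~sprintf("P%06d", sample.int(999999L, .x)))
    methods <- map(n_meth, ~sample(method_pool, .x))
    tibble(gene_a = gene_a, gene_b = gene_b,
           publications = publications, methods = methods)
  })
}

#' Generate a GO-style annotation corpus and semantic dictionary
#'
#' Terms are synthetic (`GO:0000001`, ...), each mapped to exactly one
#' semantic class and each class to exactly one functional block. Blocks
#' alternate affinity across the planted clusters; a term's annotated genes
#' are drawn preferentially (probability `cluster_effect`) from seeds and
#' hub interactors of the block's cluster, so clinical subnetworks of one
#' planted cluster enrich that cluster's blocks. A configurable fraction of
#' term names carries a keyword word (membrane, axon, ...); a small share
#' of terms falls into the "general"/"metabolism" classes that downstream
#' classification excludes.
#'
#' @param config a [fixture_config()].
#' @return a list with `corpus` (tibble: `term_id`, `term_name`, `aspect`,
#'   list-column `genes`) and `dictionary` (tibble: `term_id`,
#'   `semantic_class`, `block`).
#' @export
generate_annotation_corpus <- function(config) {
  validate_fixture_config(config)
  latent <- latent_state(config)
  withr::with_seed(config$rng_seed + 2L, {
    n_clusters <- length(config$planted_clusters)
    blocks <- sprintf("block_%02d", seq_len(config$n_blocks))
    block_cluster <- ((seq_len(config$n_blocks) - 1) %% n_clusters) + 1

    n_classes <- min(2L * config$n_blocks, config$n_go_terms)
    n_classes <- max(n_classes, config$n_blocks)
    class_block <- ((seq_len(n_classes) - 1) %% config$n_blocks) + 1
    classes <- sprintf("class_%03d", seq_len(n_classes))
    ## excluded-by-default classes live inside regular blocks
    special <- c("general", "metabolism")
    special_block <- rep_len(seq_len(config$n_blocks), length(special))

    n <- config$n_go_terms
    term_id <- sprintf("GO:%07d", seq_len(n))
    is_special <- stats::runif(n) < 0.08
    class_idx <- sample.int(n_classes, n, replace = TRUE)
    semantic_class <- ifelse(is_special,
                             sample(special, n, replace = TRUE),
                             classes[class_idx])
    block_idx <- ifelse(semantic_class == "general", special_block[1],
                 ifelse(semantic_class == "metabolism", special_block[2],
                        class_block[class_idx]))
    block <- blocks[block_idx]

    kw_words <- c("axon", "axonal", "cytoskeleton", "endosome", "endosomal",
                  "membrane", "microtubule", "vesicle", "vesicular",
                  "neuron", "neuronal", "projection")
    neutral <- c("chromatin", "ribosome", "lipid", "kinase", "phosphatase",
                 "organelle", "nuclear", "mitochondrial", "golgi",
                 "reticulum", "spindle", "histone", "ubiquitin",
                 "translation", "replication")
    verbs <- c("organization", "assembly", "regulation", "process",
               "localization", "biogenesis", "maturation", "remodeling")
    has_kw <- stats::runif(n) < config$keyword_freq
    noun <- ifelse(has_kw, sample(kw_words, n, replace = TRUE),
                   sample(neutral, n, replace = TRUE))
    term_name <- sprintf("%s %s %03d", noun,
                         sample(verbs, n, replace = TRUE), seq_len(n))
    aspect <- sample(c("BP", "CC"), n, replace = TRUE, prob = c(0.7, 0.3))

    universe <- bind_rows(
      latent$seeds %>%
        transmute(.data$gene, cluster = .data$cluster, core = TRUE),
      latent$interactors %>%
        transmute(.data$gene, cluster = .data$cluster, core = .data$is_iih)
    )
    genes <- map(block_idx, function(bi) {
      target_cl <- block_cluster[((bi - 1) %% config$n_blocks) + 1]
      w <- ifelse(universe$cluster == target_cl, config$cluster_effect,
                  1 - config$cluster_effect) + 1e-9
      w <- w * ifelse(universe$core, 4, 1)
      size <- min(max(3, rpois(1, config$mean_term_size)), nrow(universe))
      sort(sample(universe$gene, size, prob = w))
    })

    list(
      corpus = tibble(term_id = term_id, term_name = term_name,
                      aspect = aspect, genes = genes),
      dictionary = tibble(term_id = term_id,
                          semantic_class = semantic_class, block = block)
    )
  })
}

#' Generate the seed table with clinical-feature codes
#'
#' Each seed carries 1-4 single-letter feature flags, drawn preferentially
#' (probability `cluster_effect`) from its planted cluster's features, with
#' the 1:2:3:4-feature mix at proportions 9:18:12:7. Seeds sharing a
#' planted cluster therefore preferentially share features and, via the
#' other generators, interactors and annotations.
#'
#' @param config a [fixture_config()].
#' @return a tibble with columns `gene`, `is_test_seed` and list-column
#'   `features`.
#' @export
generate_clinical_annotations <- function(config) {
  validate_fixture_config(config)
  if (length(config$clinical_features) == 0) {
    config_error("`clinical_features` must contain at least one code.")
  }
  latent_state(config)$seeds %>%
    select("gene", "is_test_seed", "features")
}

#' Generate the full fixture bundle
#'
#' Convenience wrapper returning all four pipeline inputs from a single
#' configuration.
#'
#' @param config a [fixture_config()].
#' @return a list with `ppi`, `seeds`, `corpus`, `dictionary`.
#' @export
generate_fixture <- function(config) {
  validate_fixture_config(config)
  ann <- generate_annotation_corpus(config)
  list(ppi = generate_ppi_table(config),
       seeds = generate_clinical_annotations(config),
       corpus = ann$corpus,
       dictionary = ann$dictionary)
}
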