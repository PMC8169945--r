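#' Configuration for the synthetic pipeline fixtures
#'
#' Bundles every knob of the fixture generators. The defaults describe the
#' study conditions the pipeline is designed for: 66 disease seeds plus 17
#' test seeds, ~750 retained interactors, eleven functional blocks, the six
#' clinical-feature codes E/P/T/S/D/O with a planted \{T,S\} vs \{E,P,O,D\}
#' functional dichotomy, and evidence counts drawn as 1 + Poisson so that a
#' tunable fraction of interactions lacks replication (one publication and
#' one method) and is removed by the score filter.
#'
#' @param n_seeds number of disease seed genes.
#' @param n_test_seeds number of test seeds (contested disease association).
#' @param n_interactors number of non-seed interactor genes (may be 0).
#' @param mean_partners_per_seed target mean number of interactor partners
#'   per seed; controls total edge count.
#' @param iih_fraction fraction of interactors wired to at least two seeds
#'   (inter-interactome hub quota), in \[0, 1\].
#' @param n_go_terms number of annotation terms in the corpus.
#' @param n_blocks number of functional blocks (must be <= `n_go_terms`).
#' @param clinical_features single-letter clinical feature codes.
#' @param planted_clusters list of character vectors partitioning
#'   `clinical_features`; seeds, interactors and annotations are biased so
#'   features in the same group share functional structure.
#' @param cluster_effect probability mass directed at the own planted
#'   cluster when drawing features, interaction partners and annotations;
#'   0.5 means no planted structure, values near 1 a strong effect.
#' @param evidence_dist list with `pub_lambda` and `method_lambda`, the
#'   Poisson means of the (count - 1) publication/method evidence draws.
#' @param keyword_freq background frequency of keyword-bearing term names
#'   (e.g. containing "membrane", "axon") in the corpus.
#' @param mean_term_size mean number of genes annotated per term.
#' @param seed_seed_prob probability that two consecutive same-cluster seeds
#'   are directly connected.
#' @param rng_seed integer seed; identical config + seed give byte-identical
#'   fixtures.
#' @return a `fixture_config` list, validated.
#' @export
#' @examples
#' cfg <- fixture_config(n_seeds = 6, n_test_seeds = 0, n_interactors = 30,
#'                       n_go_terms = 40, rng_seed = 7)
fixture_config <- function(n_seeds = 66,
                           n_test_seeds = 17,
                           n_interactors = 746,
                           mean_partners_per_seed = 12,
                           iih_fraction = 0.25,
                           n_go_terms = 300,
                           n_blocks = 11,
                           clinical_features = c("E", "P", "T", "S", "D", "O"),
                           planted_clusters = list(c("T", "S"),
                                                   c("E", "P", "O", "D")),
                           cluster_effect = 0.9,
                           evidence_dist = list(pub_lambda = 1.2,
                                                method_lambda = 0.8),
                           keyword_freq = 0.1,
                           mean_term_size = 30,
                           seed_seed_prob = 0.3,
                           rng_seed = 1L) {
  config <- structure(
    list(n_seeds = n_seeds, n_test_seeds = n_test_seeds,
         n_interactors = n_interactors,
         mean_partners_per_seed = mean_partners_per_seed,
         iih_fraction = iih_fraction, n_go_terms = n_go_terms,
         n_blocks = n_blocks, clinical_features = clinical_features,
         planted_clusters = planted_clusters,
         cluster_effect = cluster_effect, evidence_dist = evidence_dist,
         keyword_freq = keyword_freq, mean_term_size = mean_term_size,
         seed_seed_prob = seed_seed_prob, rng_seed = rng_seed),
    class = "fixture_config")
  validate_fixture_config(config)
  config
}

validate_fixture_config <- function(config) {
  if (!inherits(config, "fixture_config")) {
    config_error("`config` must be created with fixture_config().")
  }
  with(config, {
    if (!is_count(n_seeds, min = 1)) config_error("`n_seeds` must be a count >= 1.")
    if (!is_count(n_test_seeds, min = 0)) config_error("`n_test_seeds` must be a count >= 0.")
    if (!is_count(n_interactors, min = 0)) config_error("`n_interactors` must be a count >= 0.")
    if (!is.numeric(mean_partners_per_seed) || mean_partners_per_seed <= 0) {
      config_error("`mean_partners_per_seed` must be a positive real.")
    }
    if (!is.numeric(iih_fraction) || iih_fraction < 0 || iih_fraction > 1) {
      config_error("`iih_fraction` must lie in [0, 1].")
    }
    if (!is_count(n_go_terms, min = 1)) config_error("`n_go_terms` must be a count >= 1.")
    if (!is_count(n_blocks, min = 1)) config_error("`n_blocks` must be a count >= 1.")
    if (n_blocks > n_go_terms) {
      config_error("`n_blocks` must not exceed `n_go_terms`.")
    }
    if (length(clinical_features) < 1) {
      config_error("`clinical_features` must contain at least one code.")
    }
    if (anyDuplicated(clinical_features)) {
      config_error("`clinical_features` must be unique codes.")
    }
    planted <- sort(unlist(planted_clusters))
    if (!identical(planted, sort(clinical_features))) {
      config_error("`planted_clusters` must partition `clinical_features` exactly.")
    }
    if (!is.numeric(cluster_effect) || cluster_effect < 0 || cluster_effect > 1) {
      config_error("`cluster_effect` must lie in [0, 1].")
    }
    if (!is.numeric(evidence_dist$pub_lambda) || evidence_dist$pub_lambda < 0 ||
        !is.numeric(evidence_dist$method_lambda) || evidence_dist$method_lambda < 0) {
      config_error("`evidence_dist` must give non-negative pub_lambda and method_lambda.")
    }
    if (!is.numeric(keyword_freq) || keyword_freq < 0 || keyword_freq > 1) {
      config_error("`keyword_freq` must lie in [0, 1].")
    }
    if (!is.numeric(seed_seed_prob) || seed_seed_prob < 0 || seed_seed_prob > 1) {
      config_error("`seed_seed_prob` must lie in [0, 1].")
    }
    if (!is_count(abs(rng_seed))) config_error("`rng_seed` must be an integer.")
  })
  invisible(config)
}
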