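# Prefix-wildcard keyword counting over enriched term names and a
# permutation-based enrichment test with a normal-tail p-value.

#' Keyword specification with prefix wildcards
#'
#' @param label keyword label (e.g. `"axon"`).
#' @param prefixes character vector of prefix patterns; a trailing `*` is
#'   allowed and stripped. Matching is case-insensitive on word prefixes.
#' @return a `keyword_spec` list.
#' @export
#' @examples
#' keyword_spec("axon", "axo*")
keyword_spec <- function(label, prefixes) {
  prefixes <- sub("\\*$", "", prefixes)
  if (any(!nzchar(prefixes))) {
    validation_error("Every keyword prefix must be non-empty.")
  }
  structure(list(label = label, prefixes = tolower(prefixes)),
            class = "keyword_spec")
}

#' The default keyword panel
#'
#' Axons, cytoskeleton, endosomes, membranes, microtubules, vesicles,
#' neurons and projections, matched as the word prefixes `axo*`,
#' `cytoskelet*`, `endos*`, `membrane*`, `microtubu*`, `vesic*`, `neuro*`
#' and `projection*` (the singular is included deliberately).
#'
#' @return a named list of [keyword_spec()] objects.
#' @export
default_keyword_specs <- function() {
  prefixes <- c(axon = "axo", cytoskeleton = "cytoskelet",
                endosome = "endos", membrane = "membrane",
                microtubule = "microtubu", vesicle = "vesic",
                neuron = "neuro", projection = "projection")
  imap(as.list(prefixes), ~keyword_spec(.y, .x))
}

#' Count term names matching a keyword
#'
#' A term counts at most once per keyword even when several of its words
#' match several prefixes.
#'
#' @param term_names character vector of term names.
#' @param spec a [keyword_spec()].
#' @return integer count of matching terms.
#' @export
#' @examples
#' count_keyword_matches(c("axon guidance", "axonal transport", "cell cycle"),
#'                       keyword_spec("axon", "axo*"))
count_keyword_matches <- function(term_names, spec) {
  if (length(term_names) == 0) return(0L)
  pattern <- paste0("\\b(", paste(stringr::str_escape(spec$prefixes),
                                  collapse = "|"), ")")
  sum(stringr::str_detect(tolower(term_names), pattern))
}

#' Keyword fold enrichment against a dictionary background
#'
#' Observed matching terms divided by the count expected from the
#' keyword's frequency in the dictionary: the enrichment-ratio formula
#' with terms in place of genes.
#'
#' @param observed matching terms in the result list.
#' @param n_result_terms total terms in the result list.
#' @param dict_matches matching terms in the dictionary.
#' @param dict_size total dictionary terms.
#' @return the positive fold enrichment.
#' @export
keyword_fold_enrichment <- function(observed, n_result_terms, dict_matches,
                                    dict_size) {
  if (dict_size <= 0 || n_result_terms <= 0) {
    validation_error("`dict_size` and `n_result_terms` must be positive.")
  }
  if (dict_matches == 0) {
    validation_error("`dict_matches` is zero: fold enrichment is undefined.")
  }
  observed / (n_result_terms * dict_matches / dict_size)
}

#' Permutation p-value for keyword enrichment
#'
#' Draws `n_sims` random term sets of size `n_result_terms` from the
#' dictionary names without replacement, counts keyword matches in each,
#' fits a normal null (mean mu, standard deviation sigma) to the simulated
#' counts and returns the upper-tail probability of the observed count
#' (with a 0.5 continuity correction by default, since counts are
#' discrete). When sigma is 0 the p-value is 0 if the observation exceeds
#' mu and 1 otherwise.
#'
#' @param dictionary_names character vector of dictionary term names.
#' @param n_result_terms number of terms drawn per simulation (must not
#'   exceed the dictionary size).
#' @param spec a [keyword_spec()].
#' @param observed the observed match count.
#' @param n_sims number of random simulations (>= 100; default 100,000).
#' @param rng_seed integer seed; identical seeds give identical p-values.
#' @param continuity apply the 0.5 continuity correction (default TRUE).
#' @return a single p-value.
#' @export
keyword_permutation_p <- function(dictionary_names, n_result_terms, spec,
                                  observed, n_sims = 1e5, rng_seed = 1L,
                                  continuity = TRUE) {
  n_dict <- length(dictionary_names)
  if (n_result_terms > n_dict) {
    validation_error("`n_result_terms` must not exceed the dictionary size.")
  }
  if (n_sims < 100) validation_error("`n_sims` must be at least 100.")
  match_ind <- stringr::str_detect(
    tolower(dictionary_names),
    paste0("\\b(", paste(stringr::str_escape(spec$prefixes), collapse = "|"), ")"))
  counts <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_sims),
           function(i) sum(match_ind[sample.int(n_dict, n_result_terms)]),
           integer(1))
  })
  mu <- mean(counts)
  sigma <- sd(counts)
  if (sigma == 0) return(if (observed > mu) 0 else 1)
  obs <- observed - if (continuity) 0.5 else 0
  pnorm(obs, mean = mu, sd = sigma, lower.tail = FALSE)
}

#' Keyword enrichment table over a merged term list
#'
#' Applies [count_keyword_matches()], [keyword_fold_enrichment()] and
#' [keyword_permutation_p()] for every keyword of the panel, using the
#' annotation corpus' term names as the dictionary background.
#'
#' @param term_names names of the enriched (merged) terms.
#' @param dictionary_names term names of the whole dictionary/corpus.
#' @param specs list of [keyword_spec()] objects.
#' @param n_sims simulations for the permutation p-value.
#' @param rng_seed integer seed.
#' @return a tibble: `keyword`, `n_matches`, `percent`, `dict_matches`,
#'   `fold_enrichment`, `p_value`.
#' @export
keyword_enrichment <- function(term_names, dictionary_names,
                               specs = default_keyword_specs(),
                               n_sims = 1e5, rng_seed = 1L) {
  n <- length(term_names)
  map(specs, function(spec) {
    obs <- count_keyword_matches(term_names, spec)
    dict_m <- count_keyword_matches(dictionary_names, spec)
    fold <- if (dict_m > 0 && n > 0) {
      keyword_fold_enrichment(obs, n, dict_m, length(dictionary_names))
    } else NA_real_
    p <- if (n > 0 && n <= length(dictionary_names)) {
      keyword_permutation_p(dictionary_names, n, spec, obs,
                            n_sims = n_sims, rng_seed = rng_seed)
    } else NA_real_
    tibble(keyword = spec$label, n_matches = obs,
           percent = if (n > 0) 100 * obs / n else NA_real_,
           dict_matches = dict_m, fold_enrichment = fold, p_value = p)
  }) %>% bind_rows()
}
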