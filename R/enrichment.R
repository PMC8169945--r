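# Over-representation analysis (ORA) in three tool-emulating
# configurations, semantic classification, cross-tool merging and the
# block-profile fold-change comparison.

ORA_TOOLS <- c(fisher_bonferroni = "fisher_bonferroni",
               binomial_bonferroni = "binomial_bonferroni",
               hypergeometric_fdr = "hypergeometric_fdr",
               gprofiler = "fisher_bonferroni",
               panther = "binomial_bonferroni",
               webgestalt = "hypergeometric_fdr")

#' The three emulated enrichment-tool configurations
#'
#' Fisher's one-tailed test and the hypergeometric test coincide for 2x2
#' over-representation, so both use the same upper-tail hypergeometric
#' kernel; the configurations differ in the multiple-testing correction
#' (Bonferroni vs Benjamini-Hochberg FDR) and, for the binomial
#' configuration, in the sampling model.
#'
#' @return a character vector of configuration labels.
#' @export
ora_tools <- function() {
  unname(unique(ORA_TOOLS[1:3]))
}

#' Enrichment ratio of observed over expected annotated query genes
#'
#' `ratio = ng / (ntg * nggo / ntag)`: the number of query genes annotated
#' to a term, divided by the count expected if the query drew annotations
#' at the background frequency. Equals 1 when query and background
#' annotation frequencies match.
#'
#' @param ng query genes annotated to the term.
#' @param ntg annotated query genes.
#' @param nggo background genes annotated to the term.
#' @param ntag annotated background genes.
#' @return the (vectorized) positive enrichment ratio.
#' @export
#' @examples
#' enrichment_ratio(8, 100, 40, 1000) # 2: twice the expected count
enrichment_ratio <- function(ng, ntg, nggo, ntag) {
  if (any(ntag <= 0) || any(nggo <= 0) || any(ntg <= 0)) {
    validation_error("ntg, nggo and ntag must all be positive (undefined ratio).")
  }
  ng / (ntg * nggo / ntag)
}

#' Over-representation analysis of a gene set
#'
#' For every corpus term overlapping the query, computes the raw upper-tail
#' p-value under the configured test (hypergeometric for the Fisher /
#' hypergeometric configurations, binomial with success probability
#' `nggo/ntag` for the binomial configuration), adjusts over all tested
#' terms with the configured correction, and attaches the enrichment
#' ratio. Query genes outside the annotated background are dropped with a
#' warning; terms with no query overlap are not reported.
#'
#' @param query character vector of gene symbols.
#' @param corpus annotation corpus tibble (`term_id`, `term_name`,
#'   `aspect`, list-column `genes`).
#' @param background optional background gene universe; default: all
#'   corpus-annotated genes.
#' @param tool one of `"fisher_bonferroni"`, `"binomial_bonferroni"`,
#'   `"hypergeometric_fdr"` (aliases `"gprofiler"`, `"panther"`,
#'   `"webgestalt"`).
#' @param aspect optional filter, `"BP"` or `"CC"`.
#' @return a tibble with one row per reported term: counts (`ng`, `ntg`,
#'   `nggo`, `ntag`), `p_raw`, `p_adjusted`, `enrichment_ratio`, `tool`.
#' @export
run_ora <- function(query, corpus, background = NULL,
                    tool = "fisher_bonferroni", aspect = NULL) {
  if (!tool %in% names(ORA_TOOLS)) {
    validation_error(sprintf("Unknown tool configuration '%s'.", tool))
  }
  tool_label <- unname(ORA_TOOLS[[tool]])
  if (!is.null(aspect)) corpus <- corpus %>% filter(.data$aspect %in% !!aspect)

  # default universe: all corpus-annotated genes; an explicit background
  # (an emulated tool's gene universe) is taken as given
  background <- if (is.null(background)) {
    unique(normalize_gene(unlist(corpus$genes)))
  } else {
    unique(normalize_gene(background))
  }
  ntag <- length(background)

  query <- unique(normalize_gene(query))
  unknown <- setdiff(query, background)
  if (length(unknown) > 0) {
    warn(sprintf("%d query gene(s) absent from the annotated background were excluded.",
                 length(unknown)))
  }
  query <- intersect(query, background)
  ntg <- length(query)

  empty <- tibble(term_id = character(), term_name = character(),
                  aspect = character(), ng = integer(), ntg = integer(),
                  nggo = integer(), ntag = integer(), p_raw = double(),
                  p_adjusted = double(), enrichment_ratio = double(),
                  tool = character())
  if (ntg == 0 || nrow(corpus) == 0) return(empty)

  res <- corpus %>%
    mutate(genes = map(.data$genes, ~intersect(normalize_gene(.x), background)),
           nggo = lengths(.data$genes),
           ng = map_int(.data$genes, ~length(intersect(.x, query)))) %>%
    filter(.data$ng >= 1, .data$nggo >= 1) %>%
    mutate(ntg = ntg, ntag = ntag)
  if (nrow(res) == 0) return(empty)

  p_raw <- if (tool_label == "binomial_bonferroni") {
    pbinom(res$ng - 1, res$ntg, res$nggo / res$ntag, lower.tail = FALSE)
  } else {
    phyper(res$ng - 1, res$nggo, res$ntag - res$nggo, res$ntg,
           lower.tail = FALSE)
  }
  method <- if (tool_label == "hypergeometric_fdr") "BH" else "bonferroni"

  res %>%
    mutate(p_raw = p_raw,
           p_adjusted = p.adjust(p_raw, method = method),
           enrichment_ratio = enrichment_ratio(.data$ng, .data$ntg,
                                               .data$nggo, .data$ntag),
           tool = tool_label) %>%
    select("term_id", "term_name", "aspect", "ng", "ntg", "nggo", "ntag",
           "p_raw", "p_adjusted", "enrichment_ratio", "tool") %>%
    arrange(.data$p_adjusted, .data$term_id)
}

#' Attach semantic classes and blocks to enrichment records
#'
#' Joins the two-level semantic dictionary (term -> class -> block) and
#' drops records whose class carries no functional specificity
#' (`"general"` and `"metabolism"` by default); the dropped count is
#' reported.
#'
#' @param records an ORA result tibble (see [run_ora()]).
#' @param dictionary tibble `term_id`, `semantic_class`, `block`.
#' @param exclude_classes semantic classes to drop.
#' @param unmapped policy for terms missing from the dictionary:
#'   `"drop"` (with a warning) or `"error"`.
#' @return the records with `semantic_class` and `block` columns.
#' @export
classify_terms <- function(records, dictionary,
                           exclude_classes = c("general", "metabolism"),
                           unmapped = c("drop", "error")) {
  unmapped <- match.arg(unmapped)
  out <- records %>%
    left_join(dictionary %>% select("term_id", "semantic_class", "block"),
              by = "term_id")
  missing <- is.na(out$semantic_class)
  if (any(missing)) {
    if (unmapped == "error") {
      validation_error(sprintf("%d term(s) missing from the dictionary.",
                               sum(missing)))
    }
    warn(sprintf("%d term(s) missing from the dictionary were dropped.",
                 sum(missing)))
    out <- out %>% filter(!is.na(.data$semantic_class))
  }
  n_excluded <- sum(out$semantic_class %in% exclude_classes)
  if (n_excluded > 0) {
    inform(sprintf("Dropped %d term(s) in excluded semantic classes (%s).",
                   n_excluded, paste(exclude_classes, collapse = ", ")))
  }
  out %>% filter(!.data$semantic_class %in% exclude_classes)
}

#' Merge classified enrichment results across tools
#'
#' Two-stage rule: a block is confirmed when at least `min_tools` tools
#' each report at least one term in it with `p_adjusted < block_alpha`
#' (each tool's native significance level); within confirmed blocks the
#' union of the tools' terms with `p_adjusted < alpha` and at least
#' `min_genes` contributing genes is retained, deduplicated by term id
#' (keeping the record with the smallest adjusted p, with the contributing
#' tools recorded). The merged term list defines the block profile.
#'
#' @param results list of classified ORA tibbles, one per tool.
#' @param alpha significance threshold for merged terms (default the
#'   three-tool threshold 0.0166, see [bonferroni_alpha()]).
#' @param block_alpha per-tool threshold for block confirmation.
#' @param min_genes minimum contributing genes per retained term.
#' @param min_tools minimum number of confirming tools per block.
#' @return an object of class `hsp_merge`: a list with `terms` (merged
#'   tibble with a `tools` column), `profile` (see [block_profile()]) and
#'   `blocks_kept`.
#' @export
merge_tool_results <- function(results, alpha = bonferroni_alpha(),
                               block_alpha = 0.05, min_genes = 4,
                               min_tools = 2) {
  all_rec <- bind_rows(results)
  empty_terms <- tibble(term_id = character(), term_name = character(),
                        aspect = character(), ng = integer(),
                        p_adjusted = double(), enrichment_ratio = double(),
                        semantic_class = character(), block = character(),
                        tools = character())
  if (nrow(all_rec) == 0) {
    out <- list(terms = empty_terms, profile = block_profile(empty_terms),
                blocks_kept = character(),
                params = list(alpha = alpha, block_alpha = block_alpha,
                              min_genes = min_genes, min_tools = min_tools))
    return(structure(out, class = "hsp_merge"))
  }

  blocks_kept <- all_rec %>%
    filter(.data$p_adjusted < block_alpha) %>%
    distinct(.data$block, .data$tool) %>%
    count(.data$block) %>%
    filter(.data$n >= min_tools) %>%
    pull(.data$block)

  candidates <- all_rec %>%
    filter(.data$block %in% blocks_kept,
           .data$p_adjusted < alpha,
           .data$ng >= min_genes)

  terms <- candidates %>%
    group_by(.data$term_id) %>%
    arrange(.data$p_adjusted, .data$tool, .by_group = TRUE) %>%
    mutate(tools = paste(sort(unique(.data$tool)), collapse = "|")) %>%
    slice(1) %>%
    ungroup() %>%
    select("term_id", "term_name", "aspect", "ng", "p_adjusted",
           "enrichment_ratio", "semantic_class", "block", "tools") %>%
    arrange(.data$block, .data$p_adjusted, .data$term_id)

  structure(list(terms = terms, profile = block_profile(terms),
                 blocks_kept = sort(blocks_kept),
                 params = list(alpha = alpha, block_alpha = block_alpha,
                               min_genes = min_genes, min_tools = min_tools)),
            class = "hsp_merge")
}

#' Block profile of a term list
#'
#' Counts terms per functional block and expresses them as percentages of
#' the total; the row unit of the stratification matrix.
#'
#' @param terms a tibble with a `block` column (e.g. merged terms).
#' @param label optional gene-set label column to attach.
#' @return tibble `block`, `n_terms`, `percent` (summing to 100).
#' @export
block_profile <- function(terms, label = NULL) {
  prof <- terms %>%
    count(.data$block, name = "n_terms") %>%
    mutate(percent = 100 * .data$n_terms / sum(.data$n_terms)) %>%
    arrange(.data$block)
  if (!is.null(label)) prof <- prof %>% mutate(label = label, .before = 1)
  prof
}

#' Fold change of a block profile against the core profile
#'
#' For each block, `(pct_cluster - pct_core) / pct_core`, clamped to
#' `[-clamp, clamp]`. A block absent from the cluster but present in the
#' core scores exactly -1; a block present in the cluster but absent from
#' the core is assigned `+clamp` (the division is undefined); a block
#' absent from both scores 0. Missing blocks on either side are treated as
#' 0%.
#'
#' @param cluster_profile,core_profile block-profile tibbles
#'   (see [block_profile()]).
#' @param clamp symmetric bound for display (default 25).
#' @return tibble `block`, `pct_cluster`, `pct_core`, `fold_change`.
#' @export
profile_fold_change <- function(cluster_profile, core_profile, clamp = 25) {
  full_join(cluster_profile %>% select("block", pct_cluster = "percent"),
            core_profile %>% select("block", pct_core = "percent"),
            by = "block") %>%
    mutate(pct_cluster = coalesce(.data$pct_cluster, 0),
           pct_core = coalesce(.data$pct_core, 0),
           fold_change = case_when(
             .data$pct_core > 0 ~
               pmax(pmin((.data$pct_cluster - .data$pct_core) / .data$pct_core,
                         clamp), -clamp),
             .data$pct_cluster > 0 ~ clamp,
             TRUE ~ 0
           )) %>%
    arrange(.data$block)
}

#' @export
print.hsp_merge <- function(x, ...) {
  cat(sprintf("<hsp_merge> %d merged terms across %d confirmed blocks\n",
              nrow(x$terms), length(x$blocks_kept)))
  invisible(x)
}
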