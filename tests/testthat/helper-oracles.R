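# Independent brute-force oracles, deliberately written in plain base R
# and kept free of the package's own code paths.

# Merge duplicate pairs by evidence union and score = |pubs| + |methods|.
oracle_merge_score <- function(ppi) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
  ks <- key(toupper(trimws(ppi$gene_a)), toupper(trimws(ppi$gene_b)))
  out <- list()
  for (i in seq_len(nrow(ppi))) {
    a <- toupper(trimws(ppi$gene_a[i])); b <- toupper(trimws(ppi$gene_b[i]))
    if (a == b) next
    k <- key(a, b)
    if (is.null(out[[k]])) out[[k]] <- list(pubs = character(), meths = character())
    out[[k]]$pubs <- union(out[[k]]$pubs, ppi$publications[[i]])
    out[[k]]$meths <- union(out[[k]]$meths, ppi$methods[[i]])
  }
  data.frame(pair = names(out),
             n_pubs = vapply(out, function(e) length(e$pubs), 1L),
             n_meths = vapply(out, function(e) length(e$meths), 1L),
             score = vapply(out, function(e) length(e$pubs) + length(e$meths), 1L),
             row.names = NULL)
}

# Distinct adjacent seeds per node, recounted from an edge table.
oracle_seed_degree <- function(edge_a, edge_b, seed_genes) {
  nodes <- union(edge_a, edge_b)
  sapply(nodes, function(n) {
    nb <- union(edge_b[edge_a == n], edge_a[edge_b == n])
    length(intersect(nb, seed_genes))
  })
}

# Connected components by hand-rolled BFS.
oracle_components <- function(edge_a, edge_b) {
  nodes <- union(edge_a, edge_b)
  if (length(nodes) == 0) return(integer())
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- union(edge_b[edge_a == v], edge_a[edge_b == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

# Exact upper-tail overlap probability by combinatorial counting.
oracle_hyper_upper <- function(ng, nggo, ntag, ntg) {
  ks <- seq(ng, min(ntg, nggo))
  sum(choose(nggo, ks) * choose(ntag - nggo, ntg - ks)) / choose(ntag, ntg)
}

# Same probability by literally enumerating every query subset (tiny n).
oracle_hyper_enumerate <- function(ng, nggo, ntag, ntg) {
  genes <- seq_len(ntag)
  term <- seq_len(nggo)
  subsets <- combn(ntag, ntg)
  mean(apply(subsets, 2, function(q) length(intersect(q, term)) >= ng))
}

# Naive complete-linkage agglomeration; returns merge heights and clades.
oracle_complete_linkage <- function(mat) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(rownames(mat))
  heights <- numeric(0)
  clades <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_h)
    clades <- c(clades, list(merged))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, clades = clades)
}

# Welch two-sample two-tailed t-test from first principles.
oracle_welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * pt(-abs(tstat), df)
}

# Character-scan keyword counter: word-by-word startsWith, no regex.
oracle_keyword_count <- function(names, prefixes) {
  sum(vapply(names, function(nm) {
    words <- strsplit(tolower(nm), "[^a-z]+")[[1]]
    any(vapply(prefixes, function(p) any(startsWith(words, p)), logical(1)))
  }, logical(1)))
}

# Small fixture configuration used across tests.
small_config <- function(rng_seed = 1, ...) {
  fixture_config(n_seeds = 8, n_test_seeds = 2, n_interactors = 40,
                 mean_partners_per_seed = 6, n_go_terms = 60, n_blocks = 4,
                 rng_seed = rng_seed, ...)
}

# Hand-built classified ORA record for merge tests.
fake_record <- function(term_id, block, tool, p_adjusted, ng = 5,
                        semantic_class = paste0("cls_", block)) {
  tibble::tibble(term_id = term_id, term_name = paste("name", term_id),
                 aspect = "BP", ng = ng, ntg = 50L, nggo = 10L, ntag = 500L,
                 p_raw = p_adjusted / 2, p_adjusted = p_adjusted,
                 enrichment_ratio = ng / (50 * 10 / 500),
                 tool = tool, semantic_class = semantic_class, block = block)
}
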