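# Network assembly, scoring, IIH/core extraction and slicing, checked
# against hand-rolled recount oracles.

rec <- function(a, b, pubs, meths) {
  tibble::tibble(gene_a = a, gene_b = b,
                 publications = list(pubs), methods = list(meths))
}

simple_seeds <- function(genes, test = rep(FALSE, length(genes))) {
  tibble::tibble(gene = genes, is_test_seed = test,
                 features = rep(list("E"), length(genes)))
}

test_that("interaction scores add distinct publications and methods", {
  expect_equal(score_interaction("pub1", "meth1"), 2)
  expect_equal(score_interaction(c("pub1", "pub2"), "meth1"), 3)
  expect_equal(score_interaction(c("p1", "p2", "p3"), c("m1", "m2")), 5)
  expect_equal(score_interaction(c("p1", "p1"), "m1"), 2) # duplicates ignored
  expect_error(score_interaction(character(), "m1"),
               class = "hspnet_validation_error")
})

test_that("duplicate pairs merge evidence before scoring and survive", {
  records <- dplyr::bind_rows(rec("A", "B", "p1", "m1"),
                              rec("B", "A", "p2", "m1"))
  net <- build_global_network(records, simple_seeds("A"))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$score, 3L)
  expect_setequal(net$edges$publications[[1]], c("p1", "p2"))
})

test_that("a single 1-publication 1-method record is filtered out", {
  records <- rec("A", "B", "p1", "m1")
  expect_warning(net <- build_global_network(records, simple_seeds("A")),
                 "empty network")
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 0)
})

test_that("the score filter removes exactly the unreplicated interactions", {
  for (s in 1:10) {
    ppi <- generate_ppi_table(small_config(rng_seed = s))
    merged <- oracle_merge_score(ppi)
    seeds <- generate_clinical_annotations(small_config(rng_seed = s))
    net <- suppressWarnings(build_global_network(ppi, seeds, min_score = 3))
    kept <- paste(net$edges$gene_a, net$edges$gene_b, sep = "~")
    removed <- setdiff(merged$pair, kept)
    expect_true(all(merged$n_pubs[merged$pair %in% removed] == 1 &
                      merged$n_meths[merged$pair %in% removed] == 1))
    expect_false(any(merged$n_pubs[merged$pair %in% kept] == 1 &
                       merged$n_meths[merged$pair %in% kept] == 1))
    expect_equal(nrow(net$edges), sum(merged$score >= 3))
  }
})

test_that("node and edge sets are invariant to record order and orientation", {
  ppi <- generate_ppi_table(small_config(rng_seed = 4))
  seeds <- generate_clinical_annotations(small_config(rng_seed = 4))
  net1 <- build_global_network(ppi, seeds)
  shuffled <- ppi[sample.int(nrow(ppi)), ]
  flip <- seq_len(nrow(shuffled)) %% 2 == 0
  tmp <- shuffled$gene_a[flip]
  shuffled$gene_a[flip] <- shuffled$gene_b[flip]
  shuffled$gene_b[flip] <- tmp
  net2 <- build_global_network(shuffled, seeds)
  expect_equal(net2$nodes, net1$nodes)
  expect_equal(net2$edges, net1$edges)
})

test_that("seed degrees equal an exhaustive adjacency recount", {
  cfg <- small_config(rng_seed = 8)
  net <- build_global_network(generate_ppi_table(cfg),
                              generate_clinical_annotations(cfg))
  oracle <- oracle_seed_degree(net$edges$gene_a, net$edges$gene_b,
                               net$nodes$gene[net$nodes$is_seed])
  expect_equal(setNames(net$nodes$seed_degree, net$nodes$gene),
               oracle[net$nodes$gene], ignore_attr = FALSE)
})

test_that("a minimal hub star yields a three-node core", {
  records <- dplyr::bind_rows(
    rec("H", "S1", c("p1", "p2"), "m1"),
    rec("H", "S2", c("p3", "p4"), "m2"),
    rec("X", "S1", c("p5", "p6"), "m3")) # single-seed interactor
  net <- build_global_network(records, simple_seeds(c("S1", "S2")))
  core <- extract_core(net)
  expect_setequal(core$nodes$gene, c("H", "S1", "S2"))
  expect_equal(nrow(core$edges), 2)
  expect_false("X" %in% core$nodes$gene)
})

test_that("the core equals a brute-force induced subgraph and is a subset", {
  cfg <- small_config(rng_seed = 12)
  net <- build_global_network(generate_ppi_table(cfg),
                              generate_clinical_annotations(cfg))
  core <- extract_core(net)
  seed_genes <- net$nodes$gene[net$nodes$is_seed]
  deg <- oracle_seed_degree(net$edges$gene_a, net$edges$gene_b, seed_genes)
  iih <- names(deg)[deg >= 2]
  nb_of_iih <- union(net$edges$gene_b[net$edges$gene_a %in% iih],
                     net$edges$gene_a[net$edges$gene_b %in% iih])
  keep <- union(iih, intersect(seed_genes, nb_of_iih))
  expect_setequal(core$nodes$gene, keep)
  in_keep <- net$edges$gene_a %in% keep & net$edges$gene_b %in% keep
  expect_equal(nrow(core$edges), sum(in_keep))
  # subset relation with attributes preserved
  expect_true(all(core$nodes$gene %in% net$nodes$gene))
  merged_back <- dplyr::semi_join(net$edges, core$edges,
                                  by = c("gene_a", "gene_b"))
  expect_equal(merged_back, core$edges)
  expect_equal(core$nodes,
               dplyr::semi_join(net$nodes, core$nodes, by = "gene"))
})

test_that("raising the score threshold never adds nodes or edges", {
  cfg <- small_config(rng_seed = 13)
  ppi <- generate_ppi_table(cfg)
  seeds <- generate_clinical_annotations(cfg)
  net3 <- suppressWarnings(build_global_network(ppi, seeds, min_score = 3))
  net4 <- suppressWarnings(build_global_network(ppi, seeds, min_score = 4))
  expect_true(all(net4$nodes$gene %in% net3$nodes$gene))
  expect_true(all(paste(net4$edges$gene_a, net4$edges$gene_b) %in%
                    paste(net3$edges$gene_a, net3$edges$gene_b)))
})

test_that("component summaries match a BFS recount", {
  empty <- suppressWarnings(
    build_global_network(rec("A", "B", "p", "m"), simple_seeds("A")))
  cs <- component_summary(empty)
  expect_equal(cs$n_components, 0L)
  expect_equal(cs$main_component_nodes, 0L)

  two <- build_global_network(
    dplyr::bind_rows(rec("A", "B", c("p1", "p2"), "m1"),
                     rec("C", "D", c("p3", "p4"), "m2")),
    simple_seeds(c("A", "C")))
  cs2 <- component_summary(two)
  expect_equal(cs2$n_components, 2L)
  expect_equal(cs2$main_component_nodes, 2L)

  cfg <- small_config(rng_seed = 14)
  net <- build_global_network(generate_ppi_table(cfg),
                              generate_clinical_annotations(cfg))
  oracle <- oracle_components(net$edges$gene_a, net$edges$gene_b)
  cs3 <- component_summary(net)
  expect_equal(cs3$n_components, length(unique(oracle)))
  expect_equal(cs3$main_component_nodes, max(table(oracle)),
               ignore_attr = TRUE)
  expect_equal(sum(cs3$components$n_nodes), nrow(net$nodes))
})

test_that("clinical slices take feature seeds in the core plus neighbours", {
  records <- dplyr::bind_rows(
    rec("H", "S1", c("p1", "p2"), "m1"),
    rec("H", "S2", c("p3", "p4"), "m2"),
    rec("K", "S1", c("p5", "p6"), "m3"),
    rec("K", "S2", c("p7", "p8"), "m4"))
  seeds <- tibble::tibble(gene = c("S1", "S2"),
                          is_test_seed = FALSE,
                          features = list("T", "E"))
  core <- extract_core(build_global_network(records, seeds))
  sub <- extract_clinical_subnetwork(core, seeds, "T")
  expect_setequal(sub$nodes$gene, c("S1", "H", "K"))
  expect_warning(emptysub <- extract_clinical_subnetwork(core, seeds, "O"),
                 "No core seed")
  expect_equal(nrow(emptysub$nodes), 0)

  # brute-force slice on a generated fixture
  cfg <- small_config(rng_seed = 15)
  fxseeds <- generate_clinical_annotations(cfg)
  net <- build_global_network(generate_ppi_table(cfg), fxseeds)
  corefx <- extract_core(net)
  for (f in c("T", "E")) {
    carriers <- fxseeds$gene[vapply(fxseeds$features, function(x) f %in% x,
                                    logical(1))]
    carriers <- intersect(carriers,
                          corefx$nodes$gene[corefx$nodes$is_seed])
    if (length(carriers) == 0) next
    nbs <- union(corefx$edges$gene_b[corefx$edges$gene_a %in% carriers],
                 corefx$edges$gene_a[corefx$edges$gene_b %in% carriers])
    slice <- extract_clinical_subnetwork(corefx, fxseeds, f)
    expect_setequal(slice$nodes$gene, union(carriers, nbs))
  }
})

test_that("networks export to edge lists and GraphML that re-load", {
  cfg <- small_config(rng_seed = 16)
  net <- build_global_network(generate_ppi_table(cfg),
                              generate_clinical_annotations(cfg))
  dir <- withr::local_tempdir()
  write_network_edges(net, file.path(dir, "edges.tsv"))
  tab <- readr::read_tsv(file.path(dir, "edges.tsv"),
                         show_col_types = FALSE)
  expect_equal(nrow(tab), nrow(net$edges))
  write_network_graphml(net, file.path(dir, "net.graphml"))
  g <- igraph::read_graph(file.path(dir, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
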