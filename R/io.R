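# Plain-text readers/writers for the pipeline's tab-separated formats.
# Evidence/gene/feature sets are pipe-separated in files and list-columns
# in memory; every writer round-trips through its reader without loss.

collapse_set <- function(x) map_chr(x, ~paste(.x, collapse = "|"))

split_set <- function(x) {
  map(x, ~if (is.na(.x) || .x == "") character() else strsplit(.x, "|", fixed = TRUE)[[1]])
}

#' Read / write a binary PPI table
#'
#' Columns: `gene_a`, `gene_b`, `publications`, `methods`; the evidence
#' columns hold pipe-separated identifier sets.
#'
#' @param path file path.
#' @return `read_ppi()` returns a tibble with list-columns `publications`
#'   and `methods`.
#' @export
read_ppi <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c")) %>%
    mutate(publications = split_set(.data$publications),
           methods = split_set(.data$methods))
}

#' @param ppi a PPI tibble as from [generate_ppi_table()].
#' @rdname read_ppi
#' @export
write_ppi <- function(ppi, path) {
  ppi %>%
    mutate(publications = collapse_set(.data$publications),
           methods = collapse_set(.data$methods)) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Read / write the seed table
#'
#' Columns: `gene`, `is_test_seed` (TRUE/FALSE), `features`
#' (pipe-separated single-letter codes).
#'
#' @param path file path.
#' @return `read_seeds()` returns a tibble with a `features` list-column.
#' @export
read_seeds <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = "c", is_test_seed = "l", features = "c")) %>%
    mutate(features = split_set(.data$features))
}

#' @param seeds a seed tibble as from [generate_clinical_annotations()].
#' @rdname read_seeds
#' @export
write_seeds <- function(seeds, path) {
  seeds %>%
    mutate(features = collapse_set(.data$features)) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Read / write the annotation corpus
#'
#' Columns: `term_id`, `term_name`, `aspect` (BP/CC), `genes`
#' (pipe-separated gene symbols).
#'
#' @param path file path.
#' @return `read_go_corpus()` returns a tibble with a `genes` list-column.
#' @export
read_go_corpus <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c")) %>%
    mutate(genes = split_set(.data$genes))
}

#' @param corpus a corpus tibble as from [generate_annotation_corpus()].
#' @rdname read_go_corpus
#' @export
write_go_corpus <- function(corpus, path) {
  corpus %>%
    mutate(genes = collapse_set(.data$genes)) %>%
    readr::write_tsv(path)
  invisible(path)
}

#' Read / write the semantic dictionary
#'
#' Columns: `term_id`, `semantic_class`, `block`.
#'
#' @param path file path.
#' @return `read_dictionary()` returns a tibble.
#' @export
read_dictionary <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"))
}

#' @param dictionary a dictionary tibble.
#' @rdname read_dictionary
#' @export
write_dictionary <- function(dictionary, path) {
  readr::write_tsv(dictionary, path)
  invisible(path)
}

#' Write a full fixture bundle to a directory
#'
#' Emits `ppi.tsv`, `seeds.tsv`, `go_corpus.tsv` and `dictionary.tsv`.
#'
#' @param fixture a list as returned by [generate_fixture()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ppi(fixture$ppi, file.path(dir, "ppi.tsv"))
  write_seeds(fixture$seeds, file.path(dir, "seeds.tsv"))
  write_go_corpus(fixture$corpus, file.path(dir, "go_corpus.tsv"))
  write_dictionary(fixture$dictionary, file.path(dir, "dictionary.tsv"))
  invisible(dir)
}

#' Read a full fixture bundle from a directory
#'
#' @param dir directory containing `ppi.tsv`, `seeds.tsv`, `go_corpus.tsv`,
#'   `dictionary.tsv`.
#' @return a list with `ppi`, `seeds`, `corpus`, `dictionary`.
#' @export
read_fixture <- function(dir) {
  list(ppi = read_ppi(file.path(dir, "ppi.tsv")),
       seeds = read_seeds(file.path(dir, "seeds.tsv")),
       corpus = read_go_corpus(file.path(dir, "go_corpus.tsv")),
       dictionary = read_dictionary(file.path(dir, "dictionary.tsv")))
}
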