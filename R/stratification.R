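# Clinical-subnetwork stratification: profile matrix, variance-scaled PCA,
# hierarchical clustering, silhouette-based cluster-count selection and
# set-overlap statistics. The multiscale bootstrap lives in bootstrap.R.

#' Assemble the subnetwork-by-block profile matrix
#'
#' Rows are gene-set labels (one clinical subnetwork each), columns the
#' union of all functional blocks, values the percentage or absolute count
#' of enriched terms per block; blocks absent from a subnetwork are 0.
#'
#' @param profiles a long tibble of labelled block profiles
#'   (`label`, `block`, `n_terms`, `percent`), e.g. bound rows of
#'   [block_profile()] outputs.
#' @param mode `"percent"` (rows sum to 100) or `"count"`.
#' @return a wide tibble, first column `label`, one column per block;
#'   attribute `mode` records the value type.
#' @export
build_profile_matrix <- function(profiles, mode = c("percent", "count")) {
  mode <- match.arg(mode)
  value_col <- if (mode == "percent") "percent" else "n_terms"
  wide <- profiles %>%
    select("label", "block", value = all_of(value_col)) %>%
    tidyr::pivot_wider(names_from = "block", values_from = "value",
                       values_fill = 0, names_sort = TRUE)
  if (nrow(wide) < 2) {
    validation_error("At least two subnetwork profiles are required.")
  }
  attr(wide, "mode") <- mode
  wide
}

profile_matrix_values <- function(pm) {
  mat <- as.matrix(pm[setdiff(names(pm), "label")])
  rownames(mat) <- pm$label
  mat
}

#' Variance-scaled two-dimensional PCA embedding
#'
#' PCA on column-centred (not variance-scaled) data; the first two
#' principal-component scores are multiplied elementwise by their
#' explained-variance fractions so that one unit of distance means the
#' same in either direction, making the embedding usable for Euclidean
#' clustering. Axis signs follow the convention that the
#' largest-magnitude loading is positive. If the data have rank < 2 the
#' second axis is all zeros (with a warning).
#'
#' @param pm a profile matrix from [build_profile_matrix()].
#' @return an `hsp_pca` object: `scores` (tibble `label`, `x`, `y`),
#'   `var_explained` (fractions v1 >= v2) and the sign-fixed `rotation`.
#' @export
pca_scale <- function(pm) {
  mat <- profile_matrix_values(pm)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    validation_error("PCA needs at least two rows and two columns.")
  }
  p <- prcomp(mat, center = TRUE, scale. = FALSE)
  v <- p$sdev^2 / sum(p$sdev^2)

  fix_sign <- function(scores, rot) {
    i <- which.max(abs(rot))
    if (rot[i] < 0) list(scores = -scores, rot = -rot)
    else list(scores = scores, rot = rot)
  }
  pc1 <- fix_sign(p$x[, 1], p$rotation[, 1])
  if (ncol(p$x) >= 2 && v[2] > 1e-12) {
    pc2 <- fix_sign(p$x[, 2], p$rotation[, 2])
    v2 <- v[2]
  } else {
    warn("Profile matrix has rank < 2; second embedding axis set to zero.")
    pc2 <- list(scores = rep(0, nrow(mat)), rot = rep(0, ncol(mat)))
    v2 <- 0
  }

  structure(list(
    scores = tibble(label = rownames(mat),
                    x = unname(pc1$scores * v[1]),
                    y = unname(pc2$scores * v2)),
    var_explained = c(v[1], v2),
    rotation = cbind(PC1 = pc1$rot, PC2 = pc2$rot)
  ), class = "hsp_pca")
}

embedding_matrix <- function(embedding) {
  if (inherits(embedding, "hsp_pca")) {
    mat <- as.matrix(embedding$scores[c("x", "y")])
    rownames(mat) <- embedding$scores$label
    mat
  } else if (is.data.frame(embedding)) {
    profile_matrix_values(embedding)
  } else {
    as.matrix(embedding)
  }
}

#' Hierarchically cluster embedded subnetworks
#'
#' Agglomerative clustering on the Euclidean distances of the scaled
#' embedding coordinates.
#'
#' @param embedding an `hsp_pca` object (or a labelled matrix).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return an `hclust` dendrogram.
#' @export
cluster_rows <- function(embedding, linkage = "complete") {
  mat <- embedding_matrix(embedding)
  if (nrow(mat) < 2) validation_error("Clustering needs at least two rows.")
  hclust(dist(mat), method = linkage)
}

#' Choose the number of clusters by mean silhouette width
#'
#' Cuts the dendrogram into k groups for every k in `k_range` and computes
#' the mean silhouette width on the scaled Euclidean distances; the best k
#' maximizes the mean, with ties resolved toward the smallest k.
#' Singleton clusters take the conventional silhouette width of 0. If all
#' points coincide the scores are undefined and the smallest k is returned
#' with a warning.
#'
#' @param embedding an `hsp_pca` object (or labelled matrix).
#' @param dendrogram the `hclust` object from [cluster_rows()].
#' @param k_range candidate cluster counts (default 2 to 6), clipped to
#'   `[2, n_rows - 1]`.
#' @return a list with `best_k` and `scores`
#'   (tibble `k`, `mean_silhouette`).
#' @export
select_k_silhouette <- function(embedding, dendrogram, k_range = 2:6) {
  mat <- embedding_matrix(embedding)
  d <- dist(mat)
  k_range <- k_range[k_range >= 2 & k_range <= nrow(mat) - 1]
  if (length(k_range) == 0) {
    validation_error("`k_range` must contain values in [2, n_rows - 1].")
  }
  if (max(d) == 0) {
    warn("All points coincide; silhouette is undefined, returning smallest k.")
    return(list(best_k = min(k_range),
                scores = tibble(k = k_range, mean_silhouette = NA_real_)))
  }
  scores <- map_dbl(k_range, function(k) {
    cl <- cutree(dendrogram, k = k)
    sil <- cluster::silhouette(cl, d)
    mean(sil[, "sil_width"])
  })
  list(best_k = k_range[which.max(scores)],
       scores = tibble(k = k_range, mean_silhouette = scores))
}

#' Directional overlap between two gene sets
#'
#' `100 * |A intersect B| / |A|`: the share of A's members also found in
#' B. Asymmetric by design — a value of 100 means A is a subset of B.
#'
#' @param a,b character vectors; `a` must be non-empty.
#' @return the percentage in \[0, 100\].
#' @export
#' @examples
#' directional_overlap(letters[1:23], letters[1:28]) # 100: a subset of b
directional_overlap <- function(a, b) {
  a <- unique(a)
  if (length(a) == 0) {
    validation_error("`a` must be non-empty: the directional overlap is undefined.")
  }
  100 * length(intersect(a, unique(b))) / length(a)
}

#' Welch t-test on within- vs between-cluster overlaps
#'
#' Two-sample, two-tailed t-test with unequal variances comparing the
#' protein-identity overlaps of subnetwork pairs inside one cluster with
#' those across clusters. When both groups have zero variance the p-value
#' degenerates to 1 for equal means and 0 otherwise.
#'
#' @param within_cluster_overlaps,between_cluster_overlaps numeric vectors
#'   (each of length >= 2) of directional overlap percentages.
#' @return the Welch p-value.
#' @export
overlap_ttest <- function(within_cluster_overlaps, between_cluster_overlaps) {
  w <- within_cluster_overlaps
  b <- between_cluster_overlaps
  if (length(w) < 2 || length(b) < 2) {
    validation_error("Both overlap lists need at least two values.")
  }
  if (sd(w) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(w), mean(b)))) 1 else 0)
  }
  t.test(w, b, var.equal = FALSE)$p.value
}

#' Pairwise directional overlaps of subnetwork node sets
#'
#' @param gene_sets named list of character vectors (subnetwork node
#'   sets).
#' @return tibble `from`, `to`, `n_common`, `overlap_pct` for every
#'   ordered pair of distinct non-empty sets.
#' @export
pairwise_overlaps <- function(gene_sets) {
  labels <- names(gene_sets)
  pairs <- expand.grid(from = labels, to = labels,
                       stringsAsFactors = FALSE) %>%
    filter(.data$from != .data$to)
  pairs %>%
    as_tibble() %>%
    mutate(n_common = map2_int(.data$from, .data$to, function(f, t) {
      length(intersect(unique(gene_sets[[f]]), unique(gene_sets[[t]])))
    }),
    overlap_pct = map2_dbl(.data$from, .data$to, function(f, t) {
      directional_overlap(gene_sets[[f]], gene_sets[[t]])
    }))
}

#' Run the full stratification stage
#'
#' Builds the profile matrix, embeds it with variance-scaled PCA, clusters
#' the embedding, selects the cluster count by silhouette, and attaches
#' multiscale-bootstrap AU/BP branch support (computed on the profile
#' matrix by default).
#'
#' @param profiles long tibble of labelled block profiles
#'   (see [build_profile_matrix()]).
#' @param mode `"percent"` or `"count"`.
#' @param linkage agglomeration method.
#' @param k_range candidate cluster counts.
#' @param scales bootstrap scale factors (see [multiscale_bootstrap_au()]).
#' @param n_boot bootstrap replicates per scale.
#' @param rng_seed integer seed for the bootstrap.
#' @param au_on `"matrix"` (resample profile-matrix columns; default) or
#'   `"embedding"` (resample the two embedding coordinates).
#' @return an `hsp_strat` object: `matrix`, `embedding`, `dendrogram`,
#'   `silhouette`, `au`, `assignments` (tibble `label`, `cluster` at the
#'   chosen k).
#' @export
run_stratification <- function(profiles, mode = "percent",
                               linkage = "complete", k_range = 2:6,
                               scales = seq(0.5, 1.4, by = 0.1),
                               n_boot = 1000, rng_seed = 1L,
                               au_on = c("matrix", "embedding")) {
  au_on <- match.arg(au_on)
  pm <- build_profile_matrix(profiles, mode = mode)
  emb <- pca_scale(pm)
  hc <- cluster_rows(emb, linkage = linkage)
  sil <- select_k_silhouette(emb, hc, k_range = k_range)
  au_input <- if (au_on == "matrix") pm else emb$scores %>%
    select("label", "x", "y")
  au <- multiscale_bootstrap_au(au_input, scales = scales, n_boot = n_boot,
                                linkage = linkage, rng_seed = rng_seed)
  assignments <- tibble(label = hc$labels,
                        cluster = unname(cutree(hc, k = sil$best_k)))
  structure(list(matrix = pm, embedding = emb, dendrogram = hc,
                 silhouette = sil, au = au, assignments = assignments),
            class = "hsp_strat")
}

#' @export
print.hsp_strat <- function(x, ...) {
  cat(sprintf("<hsp_strat> %d subnetworks, best k = %d\n",
              nrow(x$assignments), x$silhouette$best_k))
  invisible(x)
}
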