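# Profile matrix assembly, variance-scaled PCA, clustering, silhouette
# selection, bootstrap branch support and overlap statistics.

long_profiles <- function(mat) {
  # labelled matrix -> long (label, block, n_terms, percent) table
  tibble::tibble(label = rep(rownames(mat), ncol(mat)),
                 block = rep(colnames(mat), each = nrow(mat)),
                 n_terms = as.vector(mat),
                 percent = as.vector(mat))
}

planted_matrix <- function(noise = 0.2, seed = 1) {
  # rows T,S load on blocks 1-5; rows E,P,O,D on blocks 6-10
  set.seed(seed)
  base <- rbind(
    matrix(rep(c(18, 2), c(5, 5)), 2, 10, byrow = TRUE),
    matrix(rep(c(2, 18), c(5, 5)), 4, 10, byrow = TRUE))
  base <- base + matrix(rnorm(60, sd = noise), 6, 10)
  dimnames(base) <- list(c("T", "S", "E", "P", "O", "D"), paste0("b", 1:10))
  base
}

test_that("the profile matrix is the block union with zero fill", {
  profiles <- dplyr::bind_rows(
    tibble::tibble(label = "A", block = c("b1", "b2"), n_terms = c(3L, 1L),
                   percent = c(75, 25)),
    tibble::tibble(label = "B", block = c("b2", "b3"), n_terms = c(2L, 2L),
                   percent = c(50, 50)))
  pm <- build_profile_matrix(profiles, mode = "percent")
  expect_equal(names(pm), c("label", "b1", "b2", "b3"))
  expect_equal(pm$b1, c(75, 0))
  expect_equal(pm$b3, c(0, 50))
  expect_equal(rowSums(as.matrix(pm[-1])), c(100, 100), ignore_attr = TRUE)
  pmc <- build_profile_matrix(profiles, mode = "count")
  expect_equal(pmc$b2, c(1, 2))
  expect_error(build_profile_matrix(profiles[1:2, ]),
               class = "hspnet_validation_error")
})

test_that("duplicated rows coincide in the scaled embedding", {
  mat <- planted_matrix()
  mat[2, ] <- mat[1, ]
  emb <- pca_scale(build_profile_matrix(long_profiles(mat)))
  expect_equal(emb$scores$x[1], emb$scores$x[2], tolerance = 1e-9)
  expect_equal(emb$scores$y[1], emb$scores$y[2], tolerance = 1e-9)
})

test_that("rank-deficient data collapse onto the first axis with warning", {
  mat <- matrix(0, 4, 3, dimnames = list(paste0("r", 1:4), paste0("c", 1:3)))
  mat[, 1] <- c(1, 2, 3, 4)
  expect_warning(emb <- pca_scale(build_profile_matrix(long_profiles(mat))),
                 "rank")
  expect_equal(emb$var_explained[2], 0)
  expect_true(all(emb$scores$y == 0))
})

test_that("scaled coordinates equal a covariance eigendecomposition oracle", {
  set.seed(9)
  mat <- matrix(runif(66, 0, 30), 6, 11,
                dimnames = list(paste0("g", 1:6), paste0("b", 1:11)))
  emb <- pca_scale(build_profile_matrix(long_profiles(mat)))
  centred <- scale(mat, center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(centred))
  v <- eig$values / sum(eig$values)
  scores <- centred %*% eig$vectors[, 1:2]
  scaled <- cbind(scores[, 1] * v[1], scores[, 2] * v[2])
  expect_equal(as.matrix(dist(cbind(emb$scores$x, emb$scores$y))),
               as.matrix(dist(scaled)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(emb$var_explained, v[1:2], tolerance = 1e-8)
})

test_that("axis signs follow the largest-magnitude loading convention", {
  mat <- planted_matrix()
  emb <- pca_scale(build_profile_matrix(long_profiles(mat)))
  for (j in 1:2) {
    rot <- emb$rotation[, j]
    expect_gt(rot[which.max(abs(rot))], 0)
  }
})

test_that("dendrograms match a naive complete-linkage oracle", {
  two <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("x", "y")))
  hc2 <- cluster_rows(two)
  expect_equal(hc2$height, 5) # single merge at the euclidean distance

  mat <- planted_matrix(noise = 0.5, seed = 4)
  emb <- pca_scale(build_profile_matrix(long_profiles(mat)))
  hc <- cluster_rows(emb, linkage = "complete")
  coords <- cbind(emb$scores$x, emb$scores$y)
  rownames(coords) <- emb$scores$label
  oracle <- oracle_complete_linkage(coords)
  expect_equal(hc$height, oracle$heights, tolerance = 1e-9)
  # same clades, order-independent
  got <- list()
  for (i in seq_len(nrow(hc$merge))) {
    children <- hc$merge[i, ]
    leaves <- unlist(lapply(children, function(ch) {
      if (ch < 0) hc$labels[-ch] else got[[ch]]
    }))
    got[[i]] <- sort(leaves)
  }
  expect_setequal(got, oracle$clades)
})

test_that("silhouette selection recovers planted group counts", {
  # three tight, well-separated pairs
  pts <- rbind(matrix(c(0, 0, 0.1, 0), 2, 2, byrow = TRUE),
               matrix(c(10, 0, 10.1, 0), 2, 2, byrow = TRUE),
               matrix(c(0, 10, 0.1, 10), 2, 2, byrow = TRUE))
  rownames(pts) <- paste0("p", 1:6)
  hc <- cluster_rows(pts)
  sel <- select_k_silhouette(pts, hc, k_range = 2:5)
  expect_equal(sel$best_k, 3)
  # verify the chosen score by direct silhouette evaluation
  cl <- cutree(hc, 3)
  sil <- cluster::silhouette(cl, dist(pts))
  expect_equal(sel$scores$mean_silhouette[sel$scores$k == 3],
               mean(sil[, "sil_width"]))

  # two planted clusters in the profile geometry
  mat <- planted_matrix()
  emb <- pca_scale(build_profile_matrix(long_profiles(mat)))
  hc2 <- cluster_rows(emb)
  sel2 <- select_k_silhouette(emb, hc2, k_range = 2:5)
  expect_equal(sel2$best_k, 2)
})

test_that("identical points fall back to the smallest k with a warning", {
  pts <- matrix(1, 5, 2, dimnames = list(paste0("p", 1:5), NULL))
  hc <- cluster_rows(pts)
  expect_warning(sel <- select_k_silhouette(pts, hc, 2:4), "coincide")
  expect_equal(sel$best_k, 2)
})

test_that("silhouette selection is invariant to row order", {
  mat <- planted_matrix(noise = 0.5, seed = 8)
  perm <- sample(nrow(mat))
  run <- function(m) {
    emb <- pca_scale(build_profile_matrix(long_profiles(m)))
    hc <- cluster_rows(emb)
    sel <- select_k_silhouette(emb, hc)
    cl <- cutree(hc, sel$best_k)
    list(k = sel$best_k,
         part = unname(lapply(split(names(cl), cl), sort)))
  }
  a <- run(mat); b <- run(mat[perm, ])
  expect_equal(a$k, b$k)
  expect_setequal(a$part, b$part)
})

test_that("perfectly split blocks earn BP and AU of one", {
  mat <- rbind(matrix(c(5, 7, 6, 0, 0, 0), 3, 6, byrow = TRUE) +
                 matrix(runif(18, 0, 0.5), 3, 6),
               matrix(c(0, 0, 0, 6, 8, 5), 3, 6, byrow = TRUE) +
                 cbind(matrix(0, 3, 3), matrix(runif(9, 0, 0.5), 3, 3)))
  mat[1:3, 4:6] <- 0
  dimnames(mat) <- list(paste0("r", 1:6), paste0("c", 1:6))
  au <- multiscale_bootstrap_au(mat, n_boot = 100, rng_seed = 2)
  top <- main_branch_au(au)
  expect_equal(top, c(1, 1))
  idx <- au$branches$n_members %in% c(3)
  expect_true(all(au$branches$bp[idx] == 1))
  expect_true(all(au$branches$au >= 0 & au$branches$au <= 1))
})

test_that("pure-noise matrices rarely earn strong branch support", {
  frac <- vapply(1:20, function(s) {
    set.seed(s)
    m <- matrix(runif(72), 6, 12,
                dimnames = list(paste0("r", 1:6), paste0("c", 1:12)))
    au <- multiscale_bootstrap_au(m, n_boot = 100, rng_seed = s)
    deep <- au$branches[au$branches$n_members < 6, ]
    mean(deep$au < 0.95)
  }, numeric(1))
  expect_gt(mean(frac), 0.6)
})

test_that("the bootstrap is reproducible and scale-invariant in clustering", {
  mat <- planted_matrix(noise = 0.5, seed = 3)
  au1 <- multiscale_bootstrap_au(mat, n_boot = 100, rng_seed = 9)
  au2 <- multiscale_bootstrap_au(mat, n_boot = 100, rng_seed = 9)
  expect_identical(au1$branches$au, au2$branches$au)
  # multiplying every entry by a constant leaves assignments unchanged
  run_part <- function(m) {
    emb <- pca_scale(build_profile_matrix(long_profiles(m)))
    cutree(cluster_rows(emb), 2)
  }
  expect_equal(run_part(mat), run_part(mat * 3))
})

test_that("scales that do not straddle one are rejected", {
  mat <- planted_matrix()
  expect_error(multiscale_bootstrap_au(mat, scales = c(1.1, 1.2)),
               class = "hspnet_validation_error")
})

test_that("directional overlap is the asymmetric shared-node percentage", {
  a <- paste0("g", 1:28); b <- paste0("g", c(1:23, 40:50))
  expect_equal(round_half_up(directional_overlap(a, b), 1), 82.1)
  expect_equal(directional_overlap(paste0("g", 1:23), a), 100)
  expect_equal(directional_overlap("x", "y"), 0)
  expect_error(directional_overlap(character(), "y"),
               class = "hspnet_validation_error")
})

test_that("the overlap comparison uses Welch's unequal-variance test", {
  expect_equal(overlap_ttest(c(10, 20, 30), c(10, 20, 30)), 1.0)
  w <- c(90, 92, 91); b <- c(10, 11, 12)
  p <- overlap_ttest(w, b)
  expect_lt(p, 0.01)
  expect_equal(p, oracle_welch_p(w, b), tolerance = 1e-12)
  expect_equal(overlap_ttest(c(5, 5, 5), c(5, 5)), 1)
  expect_error(overlap_ttest(1, c(1, 2)), class = "hspnet_validation_error")
})

test_that("run_stratification recovers the planted bipartition", {
  mat <- planted_matrix(noise = 1, seed = 6)
  strat <- run_stratification(long_profiles(mat), mode = "percent",
                              n_boot = 100, rng_seed = 1)
  expect_equal(strat$silhouette$best_k, 2)
  part <- split(strat$assignments$label, strat$assignments$cluster)
  expect_true(any(vapply(part, setequal, logical(1), c("T", "S"))))
  expect_s3_class(glance(strat), "tbl_df")
  expect_equal(nrow(tidy(strat)), 6)
})
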