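# Multiscale bootstrap resampling with approximately unbiased (AU) branch
# support, in the style of pvclust: columns (features) are resampled with
# replacement at several scale factors r, the rows are re-clustered, and
# the per-branch recovery frequencies BP_r are extrapolated to the AU
# p-value through the two-parameter model
#   qnorm(BP_r) ~ -z*sqrt(r) - c/sqrt(r),   AU = pnorm(-z + c),
# fitted by weighted least squares (weights from the delta-method variance
# of qnorm(BP_hat)).

# Clade identity via leaf bitmasks: each internal node of an hclust merge
# tree maps to the integer whose set bits are its leaves. Limited to 31
# rows, far above the handful of clinical subnetworks clustered here.
clade_masks <- function(merge) {
  n_internal <- nrow(merge)
  masks <- integer(n_internal)
  for (i in seq_len(n_internal)) {
    left <- merge[i, 1]
    right <- merge[i, 2]
    ml <- if (left < 0) bitwShiftL(1L, -left - 1L) else masks[left]
    mr <- if (right < 0) bitwShiftL(1L, -right - 1L) else masks[right]
    masks[i] <- bitwOr(ml, mr)
  }
  masks
}

#' Multiscale bootstrap AU/BP support for dendrogram branches
#'
#' For each scale factor r, draws `n_boot` column resamples of size
#' `round(r * m)` (with replacement), re-clusters the rows and records how
#' often each branch (leaf subset) of the reference dendrogram reappears
#' (the bootstrap probability BP_r). The AU p-value extrapolates BP to
#' r -> -1 under the signed-distance/curvature model; branches never
#' recovered get AU = 0 and branches recovered in every replicate get
#' AU = 1. Scales that would leave fewer than two columns are skipped with
#' a warning.
#'
#' @param x a profile matrix from [build_profile_matrix()], a labelled
#'   data frame, or a numeric matrix (rows are clustered; at most 31
#'   rows).
#' @param scales scale factors straddling 1 (default 0.5 to 1.4 by 0.1).
#' @param n_boot bootstrap replicates per scale (default 1000).
#' @param linkage agglomeration method.
#' @param rng_seed integer seed; results are deterministic given the seed.
#' @return an `hsp_au` object: the reference `hclust`, `branches` (tibble
#'   `branch`, list-column `members`, `n_members`, `bp`, `au`; `bp` is the
#'   plain bootstrap probability at r = 1) and the full `bp_by_scale`
#'   matrix.
#' @export
multiscale_bootstrap_au <- function(x, scales = seq(0.5, 1.4, by = 0.1),
                                    n_boot = 1000, linkage = "complete",
                                    rng_seed = 1L) {
  mat <- if (is.data.frame(x)) profile_matrix_values(x) else as.matrix(x)
  n <- nrow(mat)
  m <- ncol(mat)
  if (n < 3) validation_error("Multiscale bootstrap needs at least three rows.")
  if (n > 31) validation_error("At most 31 rows are supported.")
  if (!any(scales < 1) || !any(scales > 1)) {
    validation_error("`scales` must straddle 1.0.")
  }

  base_hc <- hclust(dist(mat), method = linkage)
  base_masks <- clade_masks(base_hc$merge)
  sizes <- round(scales * m)
  usable <- sizes >= 2
  if (any(!usable)) {
    warn(sprintf("%d scale(s) yield < 2 columns and were skipped.", sum(!usable)))
  }
  scales <- scales[usable]
  sizes <- sizes[usable]

  bp <- withr::with_seed(rng_seed, {
    vapply(seq_along(scales), function(si) {
      hits <- integer(length(base_masks))
      for (b in seq_len(n_boot)) {
        cols <- sample.int(m, sizes[si], replace = TRUE)
        hc <- hclust(dist(mat[, cols, drop = FALSE]), method = linkage)
        boot_masks <- clade_masks(hc$merge)
        hits <- hits + (base_masks %in% boot_masks)
      }
      hits / n_boot
    }, numeric(length(base_masks)))
  })
  colnames(bp) <- sprintf("r=%.1f", scales)

  au <- vapply(seq_along(base_masks), function(i) {
    fit_au(bp[i, ], scales, n_boot)
  }, numeric(1))

  r1 <- which.min(abs(scales - 1))
  leaf_names <- base_hc$labels %||% as.character(seq_len(n))
  members <- map(base_masks, function(mask) {
    leaf_names[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0]
  })
  branches <- tibble(branch = seq_along(base_masks),
                     members = members,
                     n_members = map_int(members, length),
                     bp = bp[, r1],
                     au = au)
  structure(list(hclust = base_hc, branches = branches,
                 bp_by_scale = bp, scales = scales, n_boot = n_boot),
            class = "hsp_au")
}

fit_au <- function(bp_r, scales, n_boot) {
  if (all(bp_r >= 1)) return(1)
  if (all(bp_r <= 0)) return(0)
  eps <- 1 / (2 * n_boot)
  bp_c <- pmin(pmax(bp_r, eps), 1 - eps)
  y <- qnorm(bp_c)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- n_boot * dnorm(y)^2 / (bp_c * (1 - bp_c))
  fit <- stats::lm.wfit(X, y, w)
  z <- -fit$coefficients[1]
  cc <- -fit$coefficients[2]
  unname(pnorm(-z + cc))
}

#' AU support of the two branches below the dendrogram root
#'
#' Convenience accessor for the support of the top-level split; a child
#' that is a single leaf is trivially supported (AU = 1).
#'
#' @param au an `hsp_au` object.
#' @return a numeric vector of length 2.
#' @export
main_branch_au <- function(au) {
  merge <- au$hclust$merge
  root <- nrow(merge)
  vapply(merge[root, ], function(child) {
    if (child < 0) 1 else au$branches$au[child]
  }, numeric(1))
}

#' Write a dendrogram with branch support as nested JSON
#'
#' @param au an `hsp_au` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_json <- function(au, path) {
  hc <- au$hclust
  leaf_names <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1))
  build <- function(node) {
    if (node < 0) return(list(label = leaf_names[-node]))
    i <- node
    list(height = hc$height[i],
         au = au$branches$au[i],
         bp = au$branches$bp[i],
         children = list(build(hc$merge[i, 1]), build(hc$merge[i, 2])))
  }
  jsonlite::write_json(build(nrow(hc$merge)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.hsp_au <- function(x, ...) {
  cat(sprintf("<hsp_au> %d branches, %d boots x %d scales; root-split AU: %s\n",
              nrow(x$branches), x$n_boot, length(x$scales),
              paste(sprintf("%.2f", main_branch_au(x)), collapse = ", ")))
  invisible(x)
}
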