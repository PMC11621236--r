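#' Group white-matter analysis mask
#'
#' Averages subject white-matter probability maps, thresholds the average
#' at 50%, binarizes, and subtracts the seed ROIs dilated by a metric ball
#' so the seed signal and its immediate surroundings cannot leak into the
#' white-matter feature space.
#'
#' @param subject_wm_probmaps list of 3D probability arrays, co-registered
#'   on `grid`.
#' @param roi_masks list of logical/0-1 seed masks on the same grid.
#' @param grid a [vox_grid()].
#' @param dilation_mm dilation radius for the subtracted seed masks
#'   (default 4 mm).
#' @return logical 3D array.
#' @export
make_wm_mask <- function(subject_wm_probmaps, roi_masks, grid,
                         dilation_mm = 4) {
  stopifnot(length(subject_wm_probmaps) >= 1L)
  avg <- Reduce(`+`, subject_wm_probmaps) / length(subject_wm_probmaps)
  stopifnot(all(dim(avg) == grid$dim))
  wm <- avg >= 0.5
  for (roi in roi_masks) {
    wm <- wm & !dilate_mask(roi, grid, dilation_mm)
  }
  if (!any(wm)) stop("white-matter mask is empty after thresholding and ",
                     "seed subtraction (degenerate geometry)")
  wm
}

#' Extract tw-dFC series under a mask
#'
#' White-matter series are extracted after block-mean downsampling of the
#' tw-dFC volume by an integer factor (seed series are normally extracted
#' at native resolution with `factor = 1`). A downsampled voxel aggregates
#' the defined series of its in-mask children; blocks with no defined
#' in-mask child are dropped.
#'
#' @param twdfc a [compute_twdfc()] result.
#' @param mask logical 3D array on the tw-dFC grid.
#' @param factor positive integer downsampling factor (default 1; the
#'   pipeline uses 2 for white matter, e.g. 2 mm -> 4 mm).
#' @return list with `series` (n x W matrix), `voxels` (row order: linear
#'   voxel ids in the native grid for `factor = 1`, in the downsampled grid
#'   otherwise), `factor`, and `n_undefined` (in-mask voxels/blocks without
#'   any defined series).
#' @export
extract_series <- function(twdfc, mask, factor = 1L) {
  if (length(factor) != 1L || is.na(factor) || factor < 1 ||
      factor != as.integer(factor)) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  stopifnot(inherits(twdfc, "twdfc_image"), all(dim(mask) == twdfc$grid$dim))
  mask <- array(as.logical(mask), dim = twdfc$grid$dim)
  mask_lin <- which(mask)
  if (factor == 1L) {
    rows <- match(mask_lin, twdfc$voxels)
    keep <- !is.na(rows)
    series <- twdfc$values[rows[keep], , drop = FALSE]
    return(list(series = series, voxels = mask_lin[keep], factor = 1L,
                n_undefined = sum(!keep)))
  }
  # block id of every native voxel, in a ceil(dim/factor) downsampled grid
  dsdim <- as.integer(ceiling(twdfc$grid$dim / factor))
  in_mask <- match(twdfc$voxels, mask_lin)
  src <- twdfc$voxels[!is.na(in_mask)]
  vals <- twdfc$values[!is.na(in_mask), , drop = FALSE]
  ijk <- voxel_unlinear(twdfc$grid, src)
  blk <- cbind((ijk[, 1] - 1L) %/% factor,
               (ijk[, 2] - 1L) %/% factor,
               (ijk[, 3] - 1L) %/% factor)
  blk_id <- blk[, 3] * dsdim[1] * dsdim[2] + blk[, 2] * dsdim[1] +
    blk[, 1] + 1L
  blocks <- sort(unique(blk_id))
  grp <- match(blk_id, blocks)
  W <- ncol(vals)
  inc <- Matrix::sparseMatrix(i = grp, j = seq_along(grp), x = 1,
                              dims = c(length(blocks), length(grp)))
  defined <- !is.na(vals)
  v0 <- vals; v0[!defined] <- 0
  sums <- as.matrix(inc %*% v0)
  cnts <- as.matrix(inc %*% (defined * 1))
  series <- sums / cnts
  series[cnts == 0] <- NA_real_
  keep <- rowSums(cnts) > 0
  n_mask_blocks <- length(unique((function(m) {
    ijk <- voxel_unlinear(twdfc$grid, m)
    ((ijk[, 3] - 1L) %/% factor) * dsdim[1] * dsdim[2] +
      ((ijk[, 2] - 1L) %/% factor) * dsdim[1] + ((ijk[, 1] - 1L) %/% factor) + 1L
  })(mask_lin)))
  list(series = series[keep, , drop = FALSE], voxels = blocks[keep],
       factor = factor, n_undefined = n_mask_blocks - sum(keep))
}

#' Seed-to-white-matter connectivity fingerprint
#'
#' Row i, column j holds the Fisher r-to-z transformed Pearson correlation
#' between seed voxel i's and white-matter voxel j's tw-dFC series.
#' Correlations are clamped to +/-(1 - 1e-7) before `atanh`; undefined
#' correlations (zero-variance series) are set to 0 and counted.
#'
#' @param roi_series,wm_series matrices (voxels x windows) with identical
#'   window counts >= 3, as returned by [extract_series()] (pass the
#'   `$series` element or the list itself).
#' @return object of class `connectivity_fingerprint`: list with `matrix`
#'   (Fisher-z), `roi_voxels`, `wm_voxels`, `n_undefined`.
#' @export
fingerprint <- function(roi_series, wm_series) {
  roi_vox <- NULL; wm_vox <- NULL
  if (is.list(roi_series) && !is.null(roi_series$series)) {
    roi_vox <- roi_series$voxels; roi_series <- roi_series$series
  }
  if (is.list(wm_series) && !is.null(wm_series$series)) {
    wm_vox <- wm_series$voxels; wm_series <- wm_series$series
  }
  if (ncol(roi_series) != ncol(wm_series)) {
    stop("seed and white-matter series must share the window axis")
  }
  if (ncol(roi_series) < 3L) stop("need at least 3 common windows")
  r <- suppressWarnings(stats::cor(t(roi_series), t(wm_series)))
  und <- sum(is.na(r))
  if (und > 0L) {
    message(und, " undefined correlation(s) set to 0 in fingerprint")
    r[is.na(r)] <- 0
  }
  lim <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -lim), lim))
  structure(list(matrix = z, roi_voxels = roi_vox, wm_voxels = wm_vox,
                 n_undefined = und),
            class = "connectivity_fingerprint")
}

#' k-means partition of fingerprint rows
#'
#' Standard Lloyd k-means on Euclidean distance between Fisher-z rows.
#' Each initialization draws k distinct data rows as starting centroids;
#' the solution with the smallest within-cluster sum of squares over
#' `n_init` initializations is returned. Assignment ties go to the lowest
#' centroid index and empty clusters are re-seeded at the point farthest
#' from its centroid, so results are deterministic given `seed`.
#'
#' @param fp a [fingerprint()] or a plain numeric matrix of row features.
#' @param k number of clusters (2 <= k <= rows).
#' @param n_init number of random initializations (default 100).
#' @param seed integer seed.
#' @param max_iter Lloyd iteration cap per initialization.
#' @return object of class `roi_partition`: list with `labels` (integer in
#'   1..k per row), `k`, `wcss`, `voxels` (row identities if known).
#' @export
kmeans_partition <- function(fp, k, n_init = 100L, seed = 1L,
                             max_iter = 100L) {
  X <- if (inherits(fp, "connectivity_fingerprint")) fp$matrix else as.matrix(fp)
  voxels <- if (inherits(fp, "connectivity_fingerprint")) fp$roi_voxels else NULL
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (k > nrow(X)) stop("k exceeds the number of data rows")
  if (nrow(unique(X)) < k) stop("fewer distinct rows than clusters")
  init <- with_seed(seed, t(replicate(n_init,
                                      sample.int(nrow(X), k))))
  init <- matrix(as.integer(init), nrow = n_init)
  res <- kmeans_lloyd_cpp(X, init, as.integer(max_iter))
  structure(list(labels = as.integer(res$labels) + 1L, k = k,
                 wcss = res$wcss, voxels = voxels),
            class = "roi_partition")
}

#' @export
print.roi_partition <- function(x, ...) {
  cat("roi_partition: k =", x$k, "over", length(x$labels),
      "voxels; sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' Voxel-pair co-assignment matrix of a partition
#'
#' Entry (i, j) is 1 when voxels i and j share a cluster, 0 otherwise;
#' the diagonal is 1. Invariant under cluster relabelling.
#'
#' @param partition a [kmeans_partition()] result or an integer label vector.
#' @return symmetric 0/1 matrix.
#' @export
coassignment <- function(partition) {
  labels <- if (inherits(partition, "roi_partition")) partition$labels
  else as.integer(partition)
  outer(labels, labels, `==`) * 1
}

#' Group consensus partition
#'
#' Subject-level binary co-assignment matrices are averaged into a group
#' matrix whose entry (i, j) is the fraction of subjects assigning voxels
#' i and j to the same cluster; k-means on the rows of this matrix yields
#' the group partition.
#'
#' @param partitions list of subject partitions over the same voxel list
#'   ([kmeans_partition()] results or label vectors).
#' @param k group-level cluster count.
#' @param n_init,seed,max_iter forwarded to [kmeans_partition()].
#' @return a `roi_partition` with an extra element `q` (the group
#'   co-assignment matrix).
#' @export
consensus <- function(partitions, k, n_init = 100L, seed = 1L,
                      max_iter = 100L) {
  stopifnot(length(partitions) >= 1L)
  labs <- lapply(partitions, function(p) {
    if (inherits(p, "roi_partition")) p$labels else as.integer(p)
  })
  n <- length(labs[[1]])
  if (!all(vapply(labs, length, integer(1)) == n)) {
    stop("partitions cover inconsistent voxel lists")
  }
  vox <- NULL
  for (p in partitions) {
    if (inherits(p, "roi_partition") && !is.null(p$voxels)) {
      if (is.null(vox)) vox <- p$voxels
      else if (!identical(vox, p$voxels)) {
        stop("partitions cover inconsistent voxel lists")
      }
    }
  }
  q <- Reduce(`+`, lapply(labs, coassignment)) / length(labs)
  part <- kmeans_partition(q, k, n_init = n_init, seed = seed,
                           max_iter = max_iter)
  part$voxels <- vox
  part$q <- q
  part
}
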