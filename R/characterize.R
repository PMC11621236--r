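#' Percentage overlap of a cluster with an atlas nucleus
#'
#' `100 * |cluster intersect nucleus| / |nucleus|`: the share of the
#' nucleus volume captured by the connectivity-defined cluster.
#'
#' @param cluster_mask,nucleus_mask logical/0-1 arrays on one grid.
#' @return percentage in [0, 100].
#' @export
percent_overlap <- function(cluster_mask, nucleus_mask) {
  stopifnot(length(cluster_mask) == length(nucleus_mask))
  nn <- sum(nucleus_mask != 0)
  if (nn == 0L) stop("empty nucleus mask")
  100 * sum(cluster_mask != 0 & nucleus_mask != 0) / nn
}

#' Overlap table between atlas nuclei and connectivity clusters
#'
#' Rows are atlas nuclei (trimmed to the seed ROI when one is supplied),
#' columns are clusters; entries are the percentage of each nucleus volume
#' falling in each cluster. With nuclei restricted to the ROI each row
#' sums to 100.
#'
#' @param cluster_labels integer 3D label array (0 = background).
#' @param atlas_labels integer 3D label array of nuclei.
#' @param roi_mask optional logical array; nuclei are intersected with it.
#' @return numeric matrix nuclei x clusters (percent).
#' @export
overlap_table <- function(cluster_labels, atlas_labels, roi_mask = NULL) {
  if (!is.null(roi_mask)) {
    atlas_labels <- atlas_labels * (roi_mask != 0)
  }
  nuclei <- sort(unique(atlas_labels[atlas_labels > 0]))
  clusters <- sort(unique(cluster_labels[cluster_labels > 0]))
  out <- matrix(0, length(nuclei), length(clusters),
                dimnames = list(paste0("nucleus_", nuclei),
                                paste0("cluster_", clusters)))
  for (a in seq_along(nuclei)) {
    for (b in seq_along(clusters)) {
      out[a, b] <- percent_overlap(cluster_labels == clusters[b],
                                   atlas_labels == nuclei[a])
    }
  }
  out
}

#' Maximum probability maps from individual parcellations
#'
#' Each individual cluster is relabelled to the group cluster it overlaps
#' best (highest Dice; many-to-one allowed), binarized, and averaged over
#' subjects, giving the probability of each voxel being assigned to each
#' group cluster.
#'
#' @param individual_labels list of integer 3D label arrays (0 =
#'   background), one per subject.
#' @param group_labels integer 3D label array.
#' @return list with `prob` (list of probability arrays, one per group
#'   cluster, values in [0, 1] summing to <= 1 per voxel) and
#'   `n_unmatched` (individual clusters with zero Dice to every group
#'   cluster, which contribute nothing).
#' @export
mpm <- function(individual_labels, group_labels) {
  gl <- sort(unique(group_labels[group_labels > 0]))
  acc <- lapply(gl, function(g) array(0, dim = dim(group_labels)))
  names(acc) <- paste0("cluster_", gl)
  n_unmatched <- 0L
  for (il in individual_labels) {
    stopifnot(all(dim(il) == dim(group_labels)))
    for (ic in sort(unique(il[il > 0]))) {
      dsc <- vapply(gl, function(g) dice(il == ic, group_labels == g),
                    numeric(1))
      if (max(dsc) == 0) { n_unmatched <- n_unmatched + 1L; next }
      tgt <- which.max(dsc)  # ties: lowest group index
      acc[[tgt]] <- acc[[tgt]] + (il == ic)
    }
  }
  if (n_unmatched > 0L) {
    message(n_unmatched, " individual cluster(s) matched no group cluster")
  }
  list(prob = lapply(acc, function(a) a / length(individual_labels)),
       n_unmatched = n_unmatched)
}

#' Whole-brain connectivity map of a cluster's mean tw-dFC time course
#'
#' Averages the tw-dFC series over the cluster's voxels and correlates it
#' with the tw-dFC series of every indexed voxel; correlations are Fisher
#' r-to-z transformed (clamped at |r| = 1 - 1e-7).
#'
#' @param twdfc a [compute_twdfc()] result.
#' @param cluster_mask logical 3D array (or vector of linear voxel ids)
#'   selecting the cluster's voxels; they must carry defined series.
#' @return 3D array of Fisher-z values; voxels without tw-dFC are `NA`.
#' @export
cluster_timecourse_map <- function(twdfc, cluster_mask) {
  ids <- if (is.array(cluster_mask) || is.logical(cluster_mask)) {
    which(cluster_mask != 0)
  } else as.integer(cluster_mask)
  rows <- match(ids, twdfc$voxels)
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0L) stop("cluster has no voxels with tw-dFC series")
  sub <- twdfc$values[rows, , drop = FALSE]
  mean_tc <- colMeans(sub, na.rm = TRUE)
  if (!any(is.finite(mean_tc))) stop("cluster mean time course is undefined")
  ok_w <- is.finite(mean_tc)
  vals <- twdfc$values[, ok_w, drop = FALSE]
  r <- suppressWarnings(as.numeric(stats::cor(t(vals), mean_tc[ok_w],
                                              use = "pairwise.complete.obs")))
  lim <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -lim), lim))
  out <- array(NA_real_, dim = twdfc$grid$dim)
  out[twdfc$voxels] <- z
  out
}

#' Winner-takes-all labelling of per-cluster connectivity maps
#'
#' Each voxel is assigned to the cluster whose map value is largest; ties
#' go to the lowest cluster index; voxels where no map is positive stay
#' background (0). `NA` values never win.
#'
#' @param z_maps list (>= 2) of 3D arrays on one grid.
#' @return integer 3D label array.
#' @export
winner_takes_all <- function(z_maps) {
  stopifnot(length(z_maps) >= 2L)
  d <- dim(z_maps[[1]])
  stopifnot(all(vapply(z_maps, function(m) all(dim(m) == d), logical(1))))
  stacked <- vapply(z_maps, as.numeric, numeric(prod(d)))
  stacked[is.na(stacked)] <- -Inf
  best <- max.col(stacked, ties.method = "first")
  bestval <- stacked[cbind(seq_len(nrow(stacked)), best)]
  best[bestval <= 0] <- 0L
  array(as.integer(best), dim = d)
}

#' One-sample permutation t-test with max-statistic FWE correction
#'
#' Voxelwise one-sample t statistics against zero; the null distribution
#' is built by random sign-flipping of whole subject maps, and family-wise
#' error corrected p-values are the proportion of permutations (the
#' unpermuted labelling included, so p >= 1/(n_perm + 1)) whose maximum
#' |t| over the analysis mask reaches the voxel's |t|.
#'
#' @param maps subjects x voxels matrix, or a list of 3D arrays plus
#'   `mask`.
#' @param mask logical 3D array when `maps` is a list of volumes.
#' @param n_perm number of random sign-flip permutations (default 5000).
#' @param alpha FWE threshold for the significance mask (default 0.001).
#' @param seed integer seed.
#' @return list with `t`, `p_fwe`, `sig` (each a vector over columns, or a
#'   3D array when volumes were supplied; zero-variance voxels are `NA`
#'   and excluded from the max statistic), plus `n_perm`, `alpha`.
#' @export
permutation_onesample <- function(maps, mask = NULL, n_perm = 5000L,
                                  alpha = 0.001, seed = 1L) {
  as_vol <- FALSE
  if (is.list(maps)) {
    stopifnot(!is.null(mask))
    d <- dim(maps[[1]])
    sel <- which(mask != 0)
    maps <- t(vapply(maps, function(m) as.numeric(m)[sel], numeric(length(sel))))
    as_vol <- TRUE
  }
  n <- nrow(maps); V <- ncol(maps)
  if (n < 2L) stop("need at least 2 subjects")
  ok <- apply(maps, 2, function(x) stats::sd(x) > 0 && all(is.finite(x)))
  X <- maps[, ok, drop = FALSE]
  if (ncol(X) == 0L) stop("no voxel has non-zero variance")
  signs <- with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                                  n_perm, n))
  signs <- rbind(rep(1, n), signs)  # unpermuted labelling included
  ss <- colSums(X^2)                # invariant under sign flips
  tstat_all <- function(S) {
    m <- (S %*% X) / n
    v <- (matrix(ss, nrow(S), length(ss), byrow = TRUE) - n * m^2) / (n - 1)
    v[v < 0] <- 0
    m / sqrt(v / n)
  }
  tmat <- tstat_all(signs)
  t_obs <- tmat[1, ]
  maxnull <- apply(abs(tmat), 1, max)
  p <- vapply(abs(t_obs), function(tv) mean(maxnull >= tv), numeric(1))
  expand <- function(v) { out <- rep(NA_real_, V); out[ok] <- v; out }
  t_full <- expand(t_obs); p_full <- expand(p)
  sig_full <- expand(as.numeric(p <= alpha))
  if (as_vol) {
    tovol <- function(v) {
      a <- array(NA_real_, dim = d); a[sel] <- v; a
    }
    return(list(t = tovol(t_full), p_fwe = tovol(p_full),
                sig = tovol(sig_full), n_perm = n_perm, alpha = alpha))
  }
  list(t = t_full, p_fwe = p_full, sig = sig_full,
       n_perm = n_perm, alpha = alpha)
}

#' Voxelwise lateralization index
#'
#' `LI = (Z_left - Z_right) / (Z_left + Z_right)` wherever the denominator
#' magnitude exceeds `eps`; other voxels are masked out (`NA`). Positive
#' values mean stronger left-seed connectivity. The two maps must already
#' be in voxelwise correspondence; with mirrored geometries pass the right
#' map through [mirror_x()] first so homotopic locations align.
#'
#' @param zl,zr 3D arrays of Fisher-z connectivity (left and right seed).
#' @param eps denominator guard (default 1e-6).
#' @return list with `li` (3D array) and `valid` (logical array).
#' @export
lateralization <- function(zl, zr, eps = 1e-6) {
  stopifnot(all(dim(zl) == dim(zr)))
  den <- zl + zr
  valid <- is.finite(den) & abs(den) > eps
  li <- array(NA_real_, dim = dim(zl))
  li[valid] <- (zl[valid] - zr[valid]) / den[valid]
  list(li = li, valid = valid)
}
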