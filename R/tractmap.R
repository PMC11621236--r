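#' Voxels traversed by a streamline
#'
#' Collects the unique voxels whose centre cells are crossed by the
#' polyline. Each segment is traversed exactly: the parameter values where
#' it crosses a cell boundary plane are enumerated and the containing cell
#' of every interval midpoint is recorded, so no cell is skipped however
#' obliquely the segment clips it. Portions outside the grid are dropped.
#'
#' @param s numeric n x 3 matrix of world coordinates (mm), n >= 2.
#' @param grid a [vox_grid()].
#' @return sorted integer vector of linear (column-major) voxel ids;
#'   may be empty if the streamline lies entirely outside the grid.
#' @export
voxelize_streamline <- function(s, grid) {
  s <- as.matrix(s)
  if (nrow(s) < 2L || ncol(s) != 3L) {
    stop("degenerate streamline: need at least 2 points in 3D")
  }
  # continuous 0-based voxel coordinates; cell v spans [v-0.5, v+0.5)
  pc <- solve(grid$affine, rbind(t(s), 1))[1:3, , drop = FALSE]
  cells <- list()
  for (i in seq_len(ncol(pc) - 1L)) {
    a <- pc[, i]; b <- pc[, i + 1L]
    d <- b - a
    tt <- c(0, 1)
    for (ax in 1:3) {
      if (abs(d[ax]) < .Machine$double.eps) next
      lo <- min(a[ax], b[ax]); hi <- max(a[ax], b[ax])
      planes <- seq(ceiling(lo - 0.5), floor(hi + 0.5)) + 0.5
      planes <- planes[planes > lo & planes < hi]
      if (length(planes)) tt <- c(tt, (planes - a[ax]) / d[ax])
    }
    tt <- sort(unique(tt))
    mid <- (tt[-length(tt)] + tt[-1]) / 2
    vox <- floor(a + outer(d, mid) + 0.5)  # 3 x m, 0-based
    cells[[i]] <- t(vox)
  }
  idx0 <- unique(do.call(rbind, cells))
  keep <- idx0[, 1] >= 0 & idx0[, 1] < grid$dim[1] &
    idx0[, 2] >= 0 & idx0[, 2] < grid$dim[2] &
    idx0[, 3] >= 0 & idx0[, 3] < grid$dim[3]
  idx0 <- idx0[keep, , drop = FALSE]
  if (nrow(idx0) == 0L) return(integer(0))
  sort(unique(voxel_linear(grid, idx0 + 1L)))
}

#' Build a traversal index for a streamline set
#'
#' Maps every voxel to the streamlines traversing it (whose count is the
#' track density N_v) and every streamline to its two endpoint voxels (the
#' voxels containing the first and last polyline points). Streamlines whose
#' endpoints fall outside the grid are excluded and counted.
#'
#' @param ss a [streamline_set()] (or list of n x 3 matrices); non-empty.
#' @param grid a [vox_grid()].
#' @return an object of class `traversal_index` with elements
#'   \describe{
#'     \item{voxels}{integer vector of linear voxel ids with N_v >= 1}
#'     \item{voxel_streamlines}{list, parallel to `voxels`, of integer
#'       vectors of streamline ids}
#'     \item{n_v}{integer vector of streamline counts per voxel}
#'     \item{endpoints}{S x 2 matrix of linear voxel ids (first, last)}
#'     \item{streamline_voxels}{list of traversed voxel ids per streamline}
#'     \item{kept}{ids of retained streamlines (w.r.t. the input set)}
#'     \item{n_excluded}{streamlines dropped for out-of-grid endpoints}
#'   }
#' @export
build_traversal_index <- function(ss, grid) {
  if (length(ss) == 0L) stop("empty streamline set")
  firstlast <- t(vapply(ss, function(s) c(s[1, ], s[nrow(s), ]),
                        numeric(6)))
  epA <- world_to_voxel(grid, firstlast[, 1:3, drop = FALSE])
  epB <- world_to_voxel(grid, firstlast[, 4:6, drop = FALSE])
  keep <- !is.na(epA[, 1]) & !is.na(epB[, 1])
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message(n_excluded, " streamline(s) excluded: endpoint outside grid")
  }
  if (!any(keep)) stop("all streamlines have endpoints outside the grid")
  kept <- which(keep)
  svox <- lapply(ss[kept], voxelize_streamline, grid = grid)
  vox_all <- unlist(svox, use.names = FALSE)
  sl_all <- rep.int(seq_along(kept), lengths(svox))
  o <- order(vox_all, sl_all)
  vox_all <- vox_all[o]; sl_all <- sl_all[o]
  voxels <- unique(vox_all)
  voxel_streamlines <- split(sl_all, factor(vox_all, levels = voxels))
  names(voxel_streamlines) <- NULL
  endpoints <- cbind(voxel_linear(grid, epA[kept, , drop = FALSE]),
                     voxel_linear(grid, epB[kept, , drop = FALSE]))
  structure(list(voxels = voxels,
                 voxel_streamlines = voxel_streamlines,
                 n_v = lengths(voxel_streamlines),
                 endpoints = endpoints,
                 streamline_voxels = svox,
                 kept = kept,
                 n_excluded = n_excluded,
                 grid = grid),
            class = "traversal_index")
}

#' @export
print.traversal_index <- function(x, ...) {
  cat("traversal_index:", nrow(x$endpoints), "streamlines over",
      length(x$voxels), "voxels (max N_v =", max(x$n_v), ")\n")
  invisible(x)
}

#' Track-weight a scalar map
#'
#' Redistributes a scalar volume onto white matter: for each streamline the
#' scalar is sampled (nearest voxel) at the polyline's own points and
#' averaged along the track; each traversed voxel then receives the mean of
#' that per-streamline statistic over all streamlines crossing it. Voxels
#' traversed by no streamline are background (0).
#'
#' @param ss a [streamline_set()].
#' @param scalar 3D array on `grid`.
#' @param grid a [vox_grid()].
#' @param index optional precomputed [build_traversal_index()] for `ss`.
#' @return 3D array of track-weighted values.
#' @export
track_weight_scalar_map <- function(ss, scalar, grid, index = NULL) {
  stopifnot(all(dim(scalar) == grid$dim))
  if (is.null(index)) index <- build_traversal_index(ss, grid)
  kept <- index$kept
  track_mean <- rep(NA_real_, length(kept))
  for (i in seq_along(kept)) {
    idx <- world_to_voxel(grid, ss[[kept[i]]])
    idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
    if (nrow(idx) == 0L) next
    vals <- scalar[voxel_linear(grid, idx)]
    vals <- vals[!is.na(vals)]
    if (length(vals)) track_mean[i] <- mean(vals)
  }
  n_dropped <- sum(is.na(track_mean))
  if (n_dropped > 0L) {
    message(n_dropped, " streamline(s) contributed no scalar samples")
  }
  out <- array(0, dim = grid$dim)
  vals <- vapply(index$voxel_streamlines, function(ids) {
    v <- track_mean[ids]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  out[index$voxels] <- vals
  out
}
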