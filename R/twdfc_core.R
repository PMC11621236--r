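#' Sliding-window specification
#'
#' Rectangular, partially overlapping windows over a BOLD time series.
#'
#' @param length_tp window length in timepoints (>= 2).
#' @param stride_tp timepoints between consecutive window starts (>= 1).
#'   The default of 1 gives maximal temporal resolution.
#' @return object of class `window_spec`.
#' @export
window_spec <- function(length_tp, stride_tp = 1L) {
  length_tp <- as.integer(length_tp); stride_tp <- as.integer(stride_tp)
  if (is.na(length_tp) || length_tp < 2L) stop("length_tp must be >= 2")
  if (is.na(stride_tp) || stride_tp < 1L) stop("stride_tp must be >= 1")
  structure(list(length_tp = length_tp, stride_tp = stride_tp),
            class = "window_spec")
}

#' Enumerate sliding windows
#'
#' @param n_timepoints length of the series.
#' @param spec a [window_spec()].
#' @return integer matrix with columns `start`, `end` (1-based, inclusive);
#'   `floor((n - L)/stride) + 1` rows, every window fully inside the series.
#' @export
make_windows <- function(n_timepoints, spec) {
  n <- as.integer(n_timepoints)
  if (spec$length_tp > n) stop("window length exceeds series length")
  starts <- seq.int(1L, n - spec$length_tp + 1L, by = spec$stride_tp)
  cbind(start = starts, end = starts + spec$length_tp - 1L)
}

# Windowed Pearson correlation between paired columns of two T x S
# matrices, computed with cumulative sums. Returns a W x S matrix;
# windows where either series has zero variance are NA.
rolling_cor <- function(A, B, spec) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  W <- make_windows(nrow(A), spec)
  L <- spec$length_tp
  pad <- function(M) rbind(0, apply(M, 2, cumsum))
  wsum <- function(cs) cs[W[, 2] + 1L, , drop = FALSE] -
    cs[W[, 1], , drop = FALSE]
  Sa <- wsum(pad(A));  Sb <- wsum(pad(B))
  Saa <- wsum(pad(A * A)); Sbb <- wsum(pad(B * B)); Sab <- wsum(pad(A * B))
  va <- L * Saa - Sa^2
  vb <- L * Sbb - Sb^2
  # guard tiny negative values from cancellation
  va[va < 0] <- 0; vb[vb < 0] <- 0
  num <- L * Sab - Sa * Sb
  den <- sqrt(va) * sqrt(vb)
  r <- ifelse(den > 0, num / den, NA_real_)
  r <- pmin(pmax(r, -1), 1)
  r <- matrix(r, nrow = nrow(W))
  attr(r, "window_starts") <- W[, 1]
  r
}

#' Windowed endpoint functional connectivity of one streamline
#'
#' Pearson correlation between the BOLD series of the two endpoint voxels,
#' restricted to each sliding window. Windows in which either endpoint
#' series has zero variance are flagged undefined (`NA`).
#'
#' @param bold 4D array (x, y, z, time).
#' @param endpoints either a length-2 vector of linear voxel ids or a
#'   2 x 3 matrix of 1-based voxel indices.
#' @param spec a [window_spec()].
#' @param grid the [vox_grid()] of `bold` (needed for index endpoints).
#' @return numeric vector of per-window correlations with attribute
#'   `window_starts`.
#' @export
windowed_endpoint_fc <- function(bold, endpoints, spec, grid = NULL) {
  d <- dim(bold)
  stopifnot(length(d) == 4L)
  if (is.matrix(endpoints)) {
    stopifnot(!is.null(grid))
    endpoints <- voxel_linear(grid, endpoints)
  }
  stopifnot(length(endpoints) == 2L, all(endpoints >= 1L),
            all(endpoints <= prod(d[1:3])))
  bm <- matrix(bold, nrow = prod(d[1:3]))
  r <- rolling_cor(cbind(bm[endpoints[1], ]), cbind(bm[endpoints[2], ]), spec)
  structure(as.numeric(r), window_starts = attr(r, "window_starts"))
}

#' Track-weighted dynamic functional connectivity
#'
#' For every voxel v traversed by at least one streamline and every sliding
#' window t, the tw-dFC value is the mean over traversing streamlines of
#' the windowed endpoint correlation FC_i(t). Undefined correlations
#' (zero-variance windows) are excluded from the average; a voxel-window
#' with no defined contribution is `NA`. Because every voxel traversed only
#' by streamline i carries exactly FC_i, connectivity dynamics at the
#' endpoints are propagated along the whole streamline.
#'
#' @param bold 4D array (x, y, z, time).
#' @param index a [build_traversal_index()] on the same grid.
#' @param spec a [window_spec()].
#' @return object of class `twdfc_image`: a list with `values` (V x W
#'   matrix over indexed voxels), `voxels` (linear ids), `n_v`,
#'   `window_starts`, `spec`, `grid`.
#' @export
compute_twdfc <- function(bold, index, spec) {
  if (!inherits(index, "traversal_index")) stop("index must be a traversal_index")
  if (length(index$voxels) == 0L) stop("empty traversal index")
  d <- dim(bold)
  stopifnot(length(d) == 4L, all(d[1:3] == index$grid$dim))
  bm <- matrix(bold, nrow = prod(d[1:3]))
  A <- t(bm[index$endpoints[, 1], , drop = FALSE])
  B <- t(bm[index$endpoints[, 2], , drop = FALSE])
  fc <- rolling_cor(A, B, spec)          # W x S
  starts <- attr(fc, "window_starts")
  S <- ncol(fc)
  V <- length(index$voxels)
  inc <- Matrix::sparseMatrix(
    i = rep.int(seq_len(V), index$n_v),
    j = unlist(index$voxel_streamlines, use.names = FALSE),
    x = 1, dims = c(V, S))
  defined <- !is.na(fc)
  fc0 <- fc; fc0[!defined] <- 0
  sums <- as.matrix(inc %*% t(fc0))
  cnts <- as.matrix(inc %*% t(defined * 1))
  vals <- sums / cnts
  vals[cnts == 0] <- NA_real_
  # exact pass-through for single-streamline voxels (bit-identical series)
  single <- which(index$n_v == 1L)
  if (length(single)) {
    sid <- vapply(index$voxel_streamlines[single], `[`, integer(1), 1L)
    vals[single, ] <- t(fc[, sid, drop = FALSE])
  }
  structure(list(values = vals, voxels = index$voxels, n_v = index$n_v,
                 window_starts = starts, spec = spec, grid = index$grid),
            class = "twdfc_image")
}

#' @export
print.twdfc_image <- function(x, ...) {
  cat("twdfc_image:", nrow(x$values), "voxels x", ncol(x$values),
      "windows (length", x$spec$length_tp, ", stride", x$spec$stride_tp, ")\n")
  invisible(x)
}

#' Write a tw-dFC image as a 4D NIfTI volume with a JSON sidecar
#'
#' The 4th dimension indexes windows; undefined voxel-windows are written
#' as 0 with the voxel mask derivable from N_v in the sidecar, which also
#' records the window specification and start indices.
#'
#' @param x a `twdfc_image`.
#' @param path output `.nii` path; the sidecar replaces the extension
#'   with `.json`.
#' @param datatype NIfTI storage type (default `"float"`).
#' @return `path`, invisibly.
#' @export
write_twdfc <- function(x, path, datatype = "float") {
  vol <- twdfc_as_array(x)
  vol[is.na(vol)] <- 0
  write_image(vol, path, grid = x$grid, datatype = datatype)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(window = unclass(x$spec), window_starts = x$window_starts,
         voxels = x$voxels, n_v = x$n_v),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Materialize a tw-dFC image as a dense 4D array
#'
#' @param x a `twdfc_image`.
#' @return 4D array (x, y, z, window); non-indexed voxels are `NA`.
#' @export
twdfc_as_array <- function(x) {
  d <- c(x$grid$dim, ncol(x$values))
  out <- array(NA_real_, dim = d)
  nxyz <- prod(x$grid$dim)
  for (w in seq_len(ncol(x$values))) {
    out[x$voxels + (w - 1L) * nxyz] <- x$values[, w]
  }
  out
}
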