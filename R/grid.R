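#' Voxel grid geometry
#'
#' A grid couples an array dimension with a NIfTI-style affine mapping
#' 0-based voxel coordinates to world coordinates in millimetres (RAS).
#' All package functions index voxels 1-based (R convention); the affine
#' follows the NIfTI convention, i.e. world = affine %*% c(i-1, j-1, k-1, 1).
#'
#' @param dim integer vector of length 3, voxels per axis.
#' @param affine 4x4 voxel-to-world matrix. Defaults to isotropic voxels of
#'   size `voxel_size_mm` centred on the origin, so the mid-sagittal plane
#'   (x = 0 mm) lies halfway along the first axis.
#' @param voxel_size_mm scalar voxel edge length, used only when `affine`
#'   is not supplied.
#' @return an object of class `vox_grid` with elements `dim`, `affine`,
#'   `voxel_mm` (edge lengths per axis).
#' @export
vox_grid <- function(dim, affine = NULL, voxel_size_mm = 2) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 1L))
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_size_mm, 3), 1))
    affine[1:3, 4] <- -voxel_size_mm * (dim - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(identical(base::dim(affine), c(4L, 4L)))
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps) {
    stop("grid affine is not invertible")
  }
  voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(dim = dim, affine = affine, voxel_mm = voxel_mm),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat("vox_grid:", paste(x$dim, collapse = " x "),
      "voxels,", paste(signif(x$voxel_mm, 3), collapse = " x "), "mm\n")
  invisible(x)
}

#' Convert world coordinates (mm) to 1-based voxel indices
#'
#' A point belongs to the voxel whose centre cell contains it; half-open
#' cell boundaries are resolved by rounding half up (`floor(x + 0.5)`),
#' which keeps the assignment deterministic across platforms.
#'
#' @param grid a [vox_grid()].
#' @param pts n x 3 matrix of world coordinates.
#' @return n x 3 integer matrix of 1-based voxel indices; rows falling
#'   outside the grid contain `NA`.
#' @export
world_to_voxel <- function(grid, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  v0 <- solve(grid$affine, pts)[1:3, , drop = FALSE]
  idx <- floor(v0 + 0.5) + 1  # 1-based
  idx <- t(idx)
  bad <- idx[, 1] < 1 | idx[, 1] > grid$dim[1] |
    idx[, 2] < 1 | idx[, 2] > grid$dim[2] |
    idx[, 3] < 1 | idx[, 3] > grid$dim[3]
  idx[bad, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

#' Convert 1-based voxel indices to world coordinates of voxel centres
#' @param grid a [vox_grid()].
#' @param idx n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- as.matrix(idx)
  t(grid$affine %*% rbind(t(idx) - 1, 1))[, 1:3, drop = FALSE]
}

# Linear (column-major) voxel id from an n x 3 index matrix.
voxel_linear <- function(grid, idx) {
  as.integer((idx[, 3] - 1L) * grid$dim[1] * grid$dim[2] +
               (idx[, 2] - 1L) * grid$dim[1] + idx[, 1])
}

# Inverse of voxel_linear: n x 3 matrix of 1-based indices.
voxel_unlinear <- function(grid, lin) {
  lin0 <- lin - 1L
  nxy <- grid$dim[1] * grid$dim[2]
  k <- lin0 %/% nxy
  j <- (lin0 %% nxy) %/% grid$dim[1]
  i <- lin0 %% grid$dim[1]
  cbind(i, j, k) + 1L
}

#' Mirror a volume about the mid-sagittal plane
#'
#' Reverses the first (x) axis of a 3D array. For grids whose affine is
#' symmetric about x = 0 (the default [vox_grid()] layout) this maps every
#' voxel onto its homotopic counterpart, which is how left/right maps are
#' brought into correspondence before lateralization analysis.
#'
#' @param vol 3D array.
#' @return array of the same dimension with the x axis reversed.
#' @export
mirror_x <- function(vol) {
  stopifnot(length(dim(vol)) == 3L)
  vol[dim(vol)[1]:1, , , drop = FALSE]
}

#' Dilate a binary mask by a metric ball
#'
#' @param mask logical/0-1 3D array.
#' @param grid the [vox_grid()] the mask lives on.
#' @param radius_mm ball radius in millimetres.
#' @return logical array: voxels whose centre lies within `radius_mm` of
#'   the centre of any mask voxel.
#' @export
dilate_mask <- function(mask, grid, radius_mm) {
  stopifnot(radius_mm >= 0)
  m <- array(as.logical(mask), dim = grid$dim)
  if (!any(m) || radius_mm == 0) return(m)
  # offsets of voxel centres within the ball
  r_vox <- floor(radius_mm / grid$voxel_mm)
  off <- as.matrix(expand.grid(i = -r_vox[1]:r_vox[1],
                               j = -r_vox[2]:r_vox[2],
                               k = -r_vox[3]:r_vox[3]))
  dmm <- sqrt(colSums((t(off) * grid$voxel_mm)^2))
  off <- off[dmm <= radius_mm + 1e-9, , drop = FALSE]
  idx <- which(m, arr.ind = TRUE)
  out <- array(FALSE, dim = grid$dim)
  for (r in seq_len(nrow(off))) {
    shifted <- idx + matrix(off[r, ], nrow(idx), 3, byrow = TRUE)
    keep <- shifted[, 1] >= 1 & shifted[, 1] <= grid$dim[1] &
      shifted[, 2] >= 1 & shifted[, 2] <= grid$dim[2] &
      shifted[, 3] >= 1 & shifted[, 3] <= grid$dim[3]
    out[shifted[keep, , drop = FALSE]] <- TRUE
  }
  out
}

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's state afterwards. All randomized operations in the
# package route their seeds through this helper so no stage depends on (or
# disturbs) global randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n child seeds (< 2^31) from a master seed.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
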