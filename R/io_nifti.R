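#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with `data` (numeric array), `affine` (4x4 voxel-to-world
#'   matrix), `grid` (a [vox_grid()] over the spatial axes) and `tr_s`
#'   (repetition time in seconds for 4D data, otherwise `NA`).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI-1 file: ",
                                           path, " (", conditionMessage(e), ")"))
  data <- array(as.numeric(img), dim = dim(img))
  affine <- RNifti::xform(img)
  affine <- matrix(as.numeric(affine), 4, 4)
  tr <- NA_real_
  if (length(dim(data)) >= 4L) {
    tr <- as.numeric(RNifti::niftiHeader(img)$pixdim[5])
  }
  list(data = data, affine = affine,
       grid = vox_grid(dim(data)[1:3], affine = affine), tr_s = tr)
}

#' Write a NIfTI-1 volume
#'
#' Round-trips data, affine and (for 4D data) the repetition time.
#'
#' @param data numeric array (3D or 4D).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid a [vox_grid()] supplying the affine; alternatively pass
#'   `affine` directly.
#' @param affine 4x4 voxel-to-world matrix (overrides `grid`).
#' @param tr_s repetition time in seconds, stored in pixdim for 4D data.
#' @param datatype NIfTI storage type, default `"double"` so synthetic
#'   data round-trips exactly; use `"float"` for compact files.
#' @return `path`, invisibly.
#' @export
write_image <- function(data, path, grid = NULL, affine = NULL, tr_s = NULL,
                        datatype = "double") {
  if (is.null(affine)) {
    if (is.null(grid)) stop("supply either grid or affine")
    affine <- grid$affine
  }
  d <- dim(data)
  stopifnot(length(d) %in% c(3L, 4L))
  voxmm <- sqrt(colSums(affine[1:3, 1:3]^2))
  pixdim <- c(-1, voxmm, if (length(d) == 4L) max(0, tr_s %||% 0) else 0,
              0, 0, 0)[1:8]
  pixdim <- c(pixdim, rep(0, 8 - length(pixdim)))
  hdr <- RNifti::niftiHeader(list(
    dim = c(length(d), d, rep(1L, 7 - length(d))),
    pixdim = pixdim,
    datatype = if (datatype == "double") 64L else 16L))
  img <- RNifti::asNifti(data, reference = hdr, datatype = datatype)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
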