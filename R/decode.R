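#' Mask a map with a grey-matter mask
#'
#' Zeroes the map outside the mask. Warns when the mask removes all of the
#' map's support.
#'
#' @param map 3D array.
#' @param gm_mask logical/0-1 array on the same grid; must be non-empty.
#' @return 3D array.
#' @export
gm_mask_map <- function(map, gm_mask) {
  stopifnot(all(dim(map) == dim(gm_mask)))
  if (!any(gm_mask != 0)) stop("empty grey-matter mask")
  out <- map * (gm_mask != 0)
  if (any(map != 0, na.rm = TRUE) && !any(out != 0, na.rm = TRUE)) {
    warning("mask does not intersect the map support; result is all zero")
  }
  out
}

#' Track-weight a set of term maps
#'
#' Applies [track_weight_scalar_map()] to every term map with a common
#' template streamline set, converting activation-style maps into
#' white-matter maps comparable with track-weighted connectivity maps.
#'
#' @param terms named list of 3D arrays on `grid`.
#' @param template a [streamline_set()] (non-empty).
#' @param grid a [vox_grid()].
#' @return named list of track-weighted 3D arrays.
#' @export
track_weight_terms <- function(terms, template, grid) {
  if (length(template) == 0L) stop("empty template streamline set")
  index <- build_traversal_index(template, grid)
  lapply(terms, track_weight_scalar_map, ss = template, grid = grid,
         index = index)
}

#' Rank term maps by spatial correlation with a connectivity map
#'
#' Pearson correlation over in-mask voxels between the connectivity map and
#' every term map, sorted descending (ties broken by term name). Terms with
#' zero variance in the mask are excluded with a message.
#'
#' @param conn_map 3D array (e.g. a group preferential connectivity map).
#' @param tw_terms named list of 3D arrays on the same grid.
#' @param mask optional logical array restricting the correlation domain;
#'   defaults to voxels where `conn_map` is finite.
#' @param top_n maximum number of terms returned (default 20).
#' @return data frame with columns `term`, `r`, `rank`.
#' @export
rank_terms <- function(conn_map, tw_terms, mask = NULL, top_n = 20L) {
  stopifnot(length(tw_terms) >= 1L)
  if (is.null(names(tw_terms)) || any(names(tw_terms) == "")) {
    stop("tw_terms must be a named list")
  }
  if (is.null(mask)) mask <- is.finite(conn_map)
  sel <- which(mask != 0 & is.finite(conn_map))
  x <- conn_map[sel]
  if (stats::sd(x) == 0) stop("connectivity map has zero variance in mask")
  rs <- vapply(tw_terms, function(tm) {
    stopifnot(all(dim(tm) == dim(conn_map)))
    y <- tm[sel]
    if (!all(is.finite(y)) || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  dropped <- sum(is.na(rs))
  if (dropped > 0L) {
    message(dropped, " term map(s) excluded (zero variance or NA in mask)")
    rs <- rs[!is.na(rs)]
  }
  ord <- order(-rs, names(rs))
  out <- data.frame(term = names(rs)[ord], r = as.numeric(rs[ord]),
                    row.names = NULL)
  out <- utils::head(out, top_n)
  out$rank <- seq_len(nrow(out))
  out
}

#' Merge per-subject streamline sets into a template tractogram
#'
#' Downsamples every subject's set to at most `per_subject_n` streamlines
#' (uniformly at random, deterministic given `seed`) and concatenates
#' them, the usual way a group template tractogram is assembled for
#' track-weighting term maps.
#'
#' @param sets list of [streamline_set()]s.
#' @param per_subject_n streamlines retained per subject.
#' @param seed integer seed.
#' @return a [streamline_set()].
#' @export
merge_streamline_sets <- function(sets, per_subject_n, seed = 1L) {
  stopifnot(length(sets) >= 1L, per_subject_n >= 1L)
  seeds <- spawn_seeds(seed, length(sets))
  merged <- list()
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    keep <- if (length(s) > per_subject_n) {
      sort(with_seed(seeds[i], sample.int(length(s), per_subject_n)))
    } else seq_along(s)
    merged <- c(merged, unclass(s)[keep])
  }
  streamline_set(merged)
}

#' Synthetic term maps with a known best match
#'
#' Fabricates a term-map set for decoding experiments: one "planted" term
#' per requested cluster, built by smoothing the indicator of that
#' cluster's target territories (both hemispheres), plus smoothed random
#' blob distractors. All maps are synthetic stand-ins for database-derived
#' activation maps.
#'
#' @param scene a [build_scene()] result.
#' @param n_distractors number of random distractor maps (default 19).
#' @param fwhm_mm smoothing applied to all maps (default 4 mm).
#' @param seed integer seed for the distractors.
#' @return named list of 3D arrays: `planted_cluster<c>` for every planted
#'   cluster and `distractor<i>` for the rest.
#' @export
synthetic_term_maps <- function(scene, n_distractors = 19L, fwhm_mm = 4,
                                seed = 1L) {
  grid <- scene$grid
  k <- scene$config$k_true
  terms <- list()
  for (c in seq_len(k)) {
    ind <- (scene$target_regions$left[[c]] |
              scene$target_regions$right[[c]]) * 1
    terms[[sprintf("planted_cluster%d", c)]] <-
      smooth_bold(ind, fwhm_mm, grid)
  }
  blobs <- with_seed(seed, {
    lapply(seq_len(n_distractors), function(i) {
      n_blob <- sample(2:5, 1)
      a <- array(0, dim = grid$dim)
      ctr <- cbind(round(stats::runif(n_blob, 3, grid$dim[1] - 2)),
                   round(stats::runif(n_blob, 3, grid$dim[2] - 2)),
                   round(stats::runif(n_blob, 3, grid$dim[3] - 2)))
      # anchor one blob on the tractogram so every distractor is live
      # after track-weighting (a term map disjoint from the template
      # carries no decodable signal at all)
      wm <- which(scene$wm_mask, arr.ind = TRUE)
      ctr[1, ] <- wm[sample.int(nrow(wm), 1L), ]
      a[ctr] <- stats::runif(n_blob, 0.5, 1.5)
      # distractors share the planted terms' spatial scale so ranking
      # reflects location, not smoothness
      smooth_bold(a, fwhm_mm, grid)
    })
  })
  names(blobs) <- sprintf("distractor%02d", seq_len(n_distractors))
  c(terms, blobs)
}
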