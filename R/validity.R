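#' Mean silhouette score of a partition
#'
#' For each point, `a` is its mean distance to the other members of its
#' cluster and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`, averaged over points. Singleton
#' clusters contribute 0, as does the degenerate case `a = b = 0`. The
#' score lies in [-1, 1] and grows with cluster segregation. Euclidean
#' distance matches the k-means objective; individual-level scores are
#' computed on Fisher-z fingerprint rows and group-level scores on group
#' co-assignment rows.
#'
#' @param features numeric matrix (points x features), a
#'   [fingerprint()], or a precomputed `dist` object.
#' @param partition a [kmeans_partition()] result or integer label vector.
#' @return scalar mean silhouette.
#' @export
silhouette_score <- function(features, partition) {
  labels <- if (inherits(partition, "roi_partition")) partition$labels
  else as.integer(partition)
  k <- length(unique(labels))
  if (k < 2L) stop("silhouette requires at least 2 clusters")
  D <- if (inherits(features, "dist")) as.matrix(features)
  else {
    X <- if (inherits(features, "connectivity_fingerprint")) features$matrix
    else as.matrix(features)
    stopifnot(nrow(X) == length(labels))
    as.matrix(stats::dist(X))
  }
  stopifnot(nrow(D) == length(labels))
  ulab <- sort(unique(labels))
  sizes <- table(factor(labels, levels = ulab))
  # mean distance from every point to every cluster
  member <- outer(labels, ulab, `==`) * 1
  sums <- D %*% member                       # n x k total distance
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], ulab)
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1L)
    b <- min(sums[i, -ci] / sizes[-ci])
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m
  }
  mean(s)
}

#' Normalized variation of information between two partitions
#'
#' VI = H(p1) + H(p2) - 2 I(p1, p2) with natural logarithms, normalized by
#' log(N) so the distance between the single-cluster partition and the
#' all-singletons partition is exactly 1. Zero iff the partitions are equal
#' up to relabelling; symmetric; obeys the triangle inequality (before and
#' after the fixed normalization).
#'
#' @param p1,p2 partitions over the same voxel list ([kmeans_partition()]
#'   results or label vectors).
#' @return scalar in [0, 1].
#' @export
nvi <- function(p1, p2) {
  l1 <- if (inherits(p1, "roi_partition")) p1$labels else as.integer(p1)
  l2 <- if (inherits(p2, "roi_partition")) p2$labels else as.integer(p2)
  if (length(l1) != length(l2)) stop("partitions have mismatched lengths")
  n <- length(l1)
  if (n < 2L) stop("need at least 2 points")
  tab <- table(l1, l2) / n
  pr <- rowSums(tab); pc <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / (pr[row(tab)[nz]] * pc[col(tab)[nz]])))
  vi <- ent(pr) + ent(pc) - 2 * mi
  max(0, vi) / log(n)
}

#' Split-half stability of the consensus partition
#'
#' In each resample the subjects are split into two disjoint random halves
#' (the larger half takes the extra subject when the count is odd), a
#' consensus partition is computed per half at the requested k, and the
#' normalized variation of information between the two halves is recorded.
#' Low values mean the group solution does not depend on which subjects
#' entered it.
#'
#' @param partitions list of subject partitions over one voxel list.
#' @param k cluster count under evaluation.
#' @param n_resamples number of split-half iterations (default 100).
#' @param seed master seed; each resample and each consensus derive their
#'   own stream from it.
#' @param n_init k-means initializations per consensus.
#' @return numeric vector of `n_resamples` nVI values.
#' @export
splithalf_nvi <- function(partitions, k, n_resamples = 100L, seed = 1L,
                          n_init = 100L) {
  n <- length(partitions)
  if (n < 4L) stop("split-half resampling needs at least 4 subjects")
  seeds <- spawn_seeds(seed, 3L * n_resamples)
  vapply(seq_len(n_resamples), function(r) {
    perm <- with_seed(seeds[3L * r - 2L], sample.int(n))
    h1 <- perm[seq_len(ceiling(n / 2))]
    h2 <- setdiff(perm, h1)
    c1 <- consensus(partitions[h1], k, n_init = n_init,
                    seed = seeds[3L * r - 1L])
    c2 <- consensus(partitions[h2], k, n_init = n_init,
                    seed = seeds[3L * r])
    nvi(c1, c2)
  }, numeric(1))
}

#' Compare a validity score across cluster numbers
#'
#' One-way ANOVA with Tukey's HSD post hoc over per-k score samples
#' (e.g. subject silhouettes or split-half nVI values).
#'
#' @param scores_by_k named list of numeric vectors, one per k (>= 2
#'   groups of >= 2 values each).
#' @param alpha significance level used to flag pairs (default 0.05).
#' @return list with `anova` (data frame: F, df, p) and `tukey` (data
#'   frame: pair, diff, p_adj, significant).
#' @export
compare_k <- function(scores_by_k, alpha = 0.05) {
  stopifnot(length(scores_by_k) >= 2L)
  if (any(vapply(scores_by_k, length, integer(1)) < 2L)) {
    stop("every k group needs at least 2 scores")
  }
  df <- data.frame(
    score = unlist(scores_by_k, use.names = FALSE),
    k = factor(rep(names(scores_by_k),
                   vapply(scores_by_k, length, integer(1)))))
  if (all(vapply(scores_by_k, stats::var, numeric(1)) == 0)) {
    stop("zero within-group variance everywhere: F is undefined")
  }
  fit <- stats::aov(score ~ k, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$k
  list(anova = data.frame(F = an[["F value"]][1],
                          df_between = an[["Df"]][1],
                          df_within = an[["Df"]][2],
                          p = an[["Pr(>F)"]][1]),
       tukey = data.frame(pair = rownames(tk),
                          diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          significant = tk[, "p adj"] < alpha,
                          row.names = NULL))
}

#' Dice coefficient between two binary volumes
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty sets are identical (1);
#' empty versus non-empty is 0.
#'
#' @param a,b logical/0-1 arrays of one shape, or integer vectors of
#'   voxel ids.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  if (is.array(a) || is.logical(a)) {
    stopifnot(length(a) == length(b))
    na <- sum(a != 0); nb <- sum(b != 0)
    ni <- sum(a != 0 & b != 0)
  } else {
    a <- unique(a); b <- unique(b)
    na <- length(a); nb <- length(b); ni <- length(intersect(a, b))
  }
  if (na + nb == 0L) return(1)
  2 * ni / (na + nb)
}

#' Match clusters across two partitions and average their Dice overlap
#'
#' Greedy matching on descending pairwise Dice: the best-overlapping pair
#' is matched first, each cluster is used at most once, and ties go to the
#' lowest index pair. Used to identify corresponding clusters between
#' datasets (or between an individual and the group) and to summarize
#' reproducibility as the mean Dice over matched pairs.
#'
#' @param partition_a,partition_b partitions on a common voxel set: either
#'   integer label vectors/3D label arrays (0 = background).
#' @return list with `pairs` (data frame: cluster_a, cluster_b, dice),
#'   `average_dice`, and `unmatched` (labels left over when cluster counts
#'   differ).
#' @export
match_and_average_dice <- function(partition_a, partition_b) {
  la <- if (inherits(partition_a, "roi_partition")) partition_a$labels
  else as.integer(partition_a)
  lb <- if (inherits(partition_b, "roi_partition")) partition_b$labels
  else as.integer(partition_b)
  stopifnot(length(la) == length(lb))
  ka <- sort(unique(la[la > 0])); kb <- sort(unique(lb[lb > 0]))
  dm <- outer(seq_along(ka), seq_along(kb),
              Vectorize(function(i, j) dice(la == ka[i], lb == kb[j])))
  pairs <- data.frame(cluster_a = integer(), cluster_b = integer(),
                      dice = numeric())
  usedA <- logical(length(ka)); usedB <- logical(length(kb))
  for (step in seq_len(min(length(ka), length(kb)))) {
    d <- dm
    d[usedA, ] <- -Inf; d[, usedB] <- -Inf
    best <- which(d == max(d), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    usedA[best[1]] <- TRUE; usedB[best[2]] <- TRUE
    pairs <- rbind(pairs, data.frame(cluster_a = ka[best[1]],
                                     cluster_b = kb[best[2]],
                                     dice = dm[best[1], best[2]]))
  }
  list(pairs = pairs,
       average_dice = mean(pairs$dice),
       unmatched = list(a = ka[!usedA], b = kb[!usedB]))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; 1 for identical partitions (up to
#' relabelling), about 0 for independent ones.
#'
#' @param p1,p2 partitions over the same voxel list.
#' @return scalar (can be slightly negative for anti-correlated
#'   partitions).
#' @export
ari <- function(p1, p2) {
  l1 <- if (inherits(p1, "roi_partition")) p1$labels else as.integer(p1)
  l2 <- if (inherits(p2, "roi_partition")) p2$labels else as.integer(p2)
  stopifnot(length(l1) == length(l2))
  tab <- table(l1, l2)
  n <- length(l1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
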