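test_that("white-matter mask thresholding follows the 50% rule", {
  grid <- tiny_grid(10, 2)
  full <- array(1, grid$dim)
  empty_roi <- array(FALSE, grid$dim)
  expect_true(all(make_wm_mask(list(full), list(empty_roi), grid)))
  low <- array(0.4, grid$dim)
  expect_error(make_wm_mask(list(low), list(empty_roi), grid), "empty")
  # averaging across subjects happens before thresholding
  mixed <- make_wm_mask(list(array(0.2, grid$dim), array(0.9, grid$dim)),
                        list(empty_roi), grid)
  expect_true(all(mixed))  # mean 0.55 >= 0.5
})

test_that("series extraction at factor 1 is the identity on defined voxels", {
  scene <- small_scene()
  tw <- subject_twdfc(scene, 1, small_spec())
  ex <- extract_series(tw, scene$roi_left, factor = 1)
  expect_equal(ex$voxels, which(scene$roi_left))
  expect_equal(ex$n_undefined, 0)
  rows <- match(ex$voxels, tw$voxels)
  expect_identical(ex$series, tw$values[rows, ])
  expect_error(extract_series(tw, scene$roi_left, factor = 1.5),
               "positive integer")
  expect_error(extract_series(tw, scene$roi_left, factor = 0),
               "positive integer")
})

test_that("block downsampling equals brute-force block means", {
  scene <- small_scene()
  tw <- subject_twdfc(scene, 1, small_spec())
  mask <- array(TRUE, scene$grid$dim)
  ex <- extract_series(tw, mask, factor = 2)
  vol <- twdfc_as_array(tw)
  f <- 2L
  dd <- ceiling(scene$grid$dim / f)
  for (b in ex$voxels[seq(1, length(ex$voxels), by = 23)]) {
    b0 <- b - 1L
    bk <- b0 %/% (dd[1] * dd[2])
    bj <- (b0 %% (dd[1] * dd[2])) %/% dd[1]
    bi <- b0 %% dd[1]
    xs <- (bi * f + 1):min((bi + 1) * f, scene$grid$dim[1])
    ys <- (bj * f + 1):min((bj + 1) * f, scene$grid$dim[2])
    zs <- (bk * f + 1):min((bk + 1) * f, scene$grid$dim[3])
    block <- vol[xs, ys, zs, , drop = FALSE]
    oracle <- apply(block, 4, mean, na.rm = TRUE)
    row <- match(b, ex$voxels)
    expect_equal(ex$series[row, ], oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # constant 2x2x2 block collapses to its value
  tw2 <- tw
  tw2$values[] <- 7
  ex2 <- extract_series(tw2, mask, factor = 2)
  expect_true(all(ex2$series == 7))
})

test_that("fingerprints are Fisher-z transformed endpoint correlations", {
  set.seed(31)
  roi <- matrix(rnorm(5 * 40), 5)
  wm <- matrix(rnorm(7 * 40), 7)
  fp <- fingerprint(roi, wm)
  oracle <- atanh(pmin(pmax(cor(t(roi), t(wm)), -(1 - 1e-7)), 1 - 1e-7))
  expect_lt(max(abs(fp$matrix - oracle)), 1e-12)
  # closed forms: r = 0 -> 0, r = 0.5 -> atanh(0.5)
  x <- rnorm(100)
  y <- as.numeric(scale(x)) * 0.5 +
    as.numeric(scale(residuals(lm(rnorm(100) ~ x)))) * sqrt(0.75)
  fp2 <- fingerprint(rbind(x), rbind(y, x))
  expect_equal(fp2$matrix[1, 1], atanh(cor(x, y)), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_error(fingerprint(roi[, 1:2], wm[, 1:2]), "3 common windows|window")
  # zero-variance series become 0 with a message
  roi0 <- roi; roi0[1, ] <- 5
  expect_message(fp3 <- fingerprint(roi0, wm), "undefined")
  expect_true(all(fp3$matrix[1, ] == 0))
})

test_that("fingerprints are invariant to a joint window permutation", {
  set.seed(32)
  roi <- matrix(rnorm(4 * 30), 4)
  wm <- matrix(rnorm(6 * 30), 6)
  perm <- sample(30)
  f1 <- fingerprint(roi, wm)$matrix
  f2 <- fingerprint(roi[, perm], wm[, perm])$matrix
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("k-means recovers well-separated row blocks and is deterministic", {
  set.seed(33)
  centers <- matrix(rnorm(3 * 8, sd = 10), 3)
  X <- centers[rep(1:3, each = 20), ] + matrix(rnorm(60 * 8, sd = 0.5), 60)
  p1 <- kmeans_partition(X, 3, n_init = 25, seed = 7)
  p2 <- kmeans_partition(X, 3, n_init = 25, seed = 7)
  expect_identical(p1$labels, p2$labels)
  expect_equal(ari(p1, rep(1:3, each = 20)), 1)
  # independent check: stats::kmeans reaches the same optimum here
  km <- stats::kmeans(X, 3, nstart = 25)
  expect_equal(ari(p1, km$cluster), 1)
  expect_equal(p1$wcss, km$tot.withinss, tolerance = 1e-8)
})

test_that("k-means honours duplication invariance and degenerate k", {
  set.seed(34)
  centers <- matrix(rnorm(3 * 4, sd = 10), 3)
  X <- centers[rep(1:3, each = 4), ] + matrix(rnorm(12 * 4, sd = 0.3), 12)
  p <- kmeans_partition(X, 3, n_init = 20, seed = 1)
  pdup <- kmeans_partition(rbind(X, X), 3, n_init = 20, seed = 1)
  expect_equal(ari(rep(p$labels, 2), pdup$labels), 1)
  # k = number of distinct rows: singletons, zero WCSS
  psing <- kmeans_partition(X, 12, n_init = 5, seed = 2)
  expect_equal(psing$wcss, 0)
  expect_equal(length(unique(psing$labels)), 12)
  expect_error(kmeans_partition(X, 13, n_init = 2, seed = 1), "exceeds")
  expect_error(kmeans_partition(matrix(1, 5, 2), 2, seed = 1), "distinct")
})

test_that("co-assignment matrices are binary, symmetric and label-invariant", {
  labels <- c(1L, 1L, 2L, 3L, 2L)
  q <- coassignment(labels)
  expect_true(all(diag(q) == 1))
  expect_identical(q, t(q))
  expect_true(all(q %in% c(0, 1)))
  relabelled <- c(2L, 3L, 1L)[labels]
  expect_identical(coassignment(relabelled), q)
})

test_that("consensus reproduces a shared partition and averages co-assignment", {
  labels <- rep(1:2, each = 3)
  relab <- 3L - labels
  cons <- consensus(list(labels, relab, labels), k = 2, n_init = 10, seed = 3)
  expect_equal(ari(cons, labels), 1)
  # hand-computed group matrix for two independent partitions of 6 voxels
  p1 <- c(1L, 1L, 1L, 2L, 2L, 2L)
  p2 <- c(1L, 2L, 1L, 2L, 1L, 2L)
  cons2 <- consensus(list(p1, p2), k = 2, n_init = 10, seed = 4)
  oracle <- (coassignment(p1) + coassignment(p2)) / 2
  expect_identical(cons2$q, oracle)
  expect_error(consensus(list(p1, p2[1:5]), k = 2), "inconsistent")
})

test_that("consensus finds the majority partition in a noisy cohort", {
  set.seed(35)
  base <- rep(1:2, each = 10)
  parts <- lapply(1:20, function(s) {
    lab <- base
    flip <- sample(20, 2)  # 90% agreement
    lab[flip] <- 3L - lab[flip]
    sample(2L)[lab]        # random relabelling
  })
  cons <- consensus(parts, k = 2, n_init = 50, seed = 5)
  expect_gte(ari(cons, base), 0.9)
})
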