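test_that("window enumeration follows the closed form", {
  expect_equal(nrow(make_windows(100, window_spec(55, 1))), 46)
  expect_equal(nrow(make_windows(55, window_spec(55, 1))), 1)
  w <- make_windows(10, window_spec(4, 3))
  expect_equal(w[, "start"], c(1, 4, 7))
  expect_equal(w[, "end"], c(4, 7, 10))
  # exactness of floor((n - L)/stride) + 1 over a parameter sweep
  for (n in c(10, 17, 55)) for (L in c(2, 5, n)) for (st in c(1, 2, 3)) {
    w <- make_windows(n, window_spec(L, st))
    expect_equal(nrow(w), floor((n - L) / st) + 1)
    expect_true(all(w[, "end"] <= n))
  }
  expect_error(make_windows(10, window_spec(11, 1)), "exceeds")
})

test_that("endpoint FC is exact for identical and negated series", {
  d <- c(3, 3, 3, 40)
  bold <- array(rnorm(prod(d)), d)
  x <- rnorm(40)
  bold[1, 1, 1, ] <- x
  bold[2, 1, 1, ] <- x
  bold[3, 1, 1, ] <- -x
  spec <- window_spec(10, 2)
  same <- windowed_endpoint_fc(bold, c(1L, 2L), spec)
  neg <- windowed_endpoint_fc(bold, c(1L, 3L), spec)
  expect_equal(as.numeric(same), rep(1, length(same)), tolerance = 1e-12)
  expect_equal(as.numeric(neg), rep(-1, length(neg)), tolerance = 1e-12)
})

test_that("endpoint FC matches direct per-window correlation to 1e-12", {
  d <- c(4, 4, 4, 60)
  bold <- array(twdfc:::with_seed(5, rnorm(prod(d))), d)
  spec <- window_spec(12, 3)
  fc <- windowed_endpoint_fc(bold, c(7L, 29L), spec)
  bm <- matrix(bold, nrow = 64)
  W <- make_windows(60, spec)
  direct <- vapply(seq_len(nrow(W)), function(w)
    cor(bm[7, W[w, 1]:W[w, 2]], bm[29, W[w, 1]:W[w, 2]]), numeric(1))
  expect_equal(as.numeric(fc), direct, tolerance = 1e-12)
})

test_that("zero-variance windows are flagged undefined", {
  d <- c(2, 2, 2, 30)
  bold <- array(rnorm(prod(d)), d)
  bold[1, 1, 1, 1:15] <- 2  # flat first half
  fc <- windowed_endpoint_fc(bold, c(1L, 2L), window_spec(5, 1))
  expect_true(all(is.na(fc[1:11])))
  expect_true(all(!is.na(fc[12:26])))
})

test_that("tw-dFC equals the brute-force double loop and respects bounds", {
  grid <- tiny_grid(10, 2)
  ss <- streamline_set(random_streamlines(30, grid, seed = 6))
  idx <- build_traversal_index(ss, grid)
  Tn <- 80
  bold <- array(twdfc:::with_seed(7, rnorm(prod(grid$dim) * Tn)),
                c(grid$dim, Tn))
  spec <- window_spec(15, 4)
  tw <- compute_twdfc(bold, idx, spec)
  expect_true(all(tw$values >= -1 & tw$values <= 1, na.rm = TRUE))
  bm <- matrix(bold, nrow = prod(grid$dim))
  W <- make_windows(Tn, spec)
  oracle <- matrix(NA_real_, length(idx$voxels), nrow(W))
  for (vi in seq_along(idx$voxels)) {
    sl <- idx$voxel_streamlines[[vi]]
    for (w in seq_len(nrow(W))) {
      fcs <- vapply(sl, function(i) {
        a <- bm[idx$endpoints[i, 1], W[w, 1]:W[w, 2]]
        b <- bm[idx$endpoints[i, 2], W[w, 1]:W[w, 2]]
        suppressWarnings(cor(a, b))
      }, numeric(1))
      oracle[vi, w] <- mean(fcs, na.rm = TRUE)
    }
  }
  expect_equal(tw$values, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a voxel's series is the mean of its streamlines' FC series", {
  # two streamlines sharing one voxel: construct explicitly
  grid <- tiny_grid(8, 2)
  c1 <- voxel_to_world(grid, rbind(c(2, 4, 4), c(4, 4, 4), c(6, 4, 4)))
  c2 <- voxel_to_world(grid, rbind(c(4, 2, 4), c(4, 4, 4), c(4, 6, 4)))
  ss <- streamline_set(list(c1, c2))
  idx <- build_traversal_index(ss, grid)
  Tn <- 50
  bold <- array(twdfc:::with_seed(8, rnorm(prod(grid$dim) * Tn)),
                c(grid$dim, Tn))
  spec <- window_spec(10, 5)
  tw <- compute_twdfc(bold, idx, spec)
  fc1 <- windowed_endpoint_fc(bold, idx$endpoints[1, ], spec)
  fc2 <- windowed_endpoint_fc(bold, idx$endpoints[2, ], spec)
  shared <- twdfc:::voxel_linear(grid, cbind(4, 4, 4))
  vi <- match(shared, tw$voxels)
  expect_equal(tw$values[vi, ], (as.numeric(fc1) + as.numeric(fc2)) / 2,
               tolerance = 1e-12)
})

test_that("single-streamline voxels carry the streamline's series bit-identically", {
  scene <- small_scene()
  tw <- subject_twdfc(scene, 1, small_spec())
  singles <- which(scene$index$n_v == 1L)
  expect_gt(length(singles), 0)
  bm <- matrix(scene$bold[[1]], nrow = prod(scene$grid$dim))
  picked <- singles[round(seq(1, length(singles), length.out = 12))]
  for (vi in picked) {
    sid <- scene$index$voxel_streamlines[[vi]]
    fc <- windowed_endpoint_fc(scene$bold[[1]],
                               scene$index$endpoints[sid, ], small_spec())
    expect_identical(tw$values[vi, ], as.numeric(fc))
  }
  # voxels sharing one streamline share the series exactly
  sids <- vapply(scene$index$voxel_streamlines[singles], `[`, integer(1), 1)
  dup <- sids[duplicated(sids)][1]
  vset <- singles[sids == dup]
  expect_gt(length(vset), 1)
  for (v in vset[-1]) {
    expect_identical(tw$values[vset[1], ], tw$values[v, ])
  }
})

test_that("empty traversal index is rejected", {
  grid <- tiny_grid(8, 2)
  bold <- array(rnorm(prod(grid$dim) * 20), c(grid$dim, 20))
  expect_error(compute_twdfc(bold, list(), window_spec(5, 1)),
               "traversal_index")
})

test_that("tw-dFC volumes round-trip through NIfTI with a sidecar", {
  tmp <- withr::local_tempfile(fileext = ".nii")
  grid <- tiny_grid(8, 2)
  ss <- streamline_set(random_streamlines(5, grid, seed = 15, margin_mm = -3))
  idx <- build_traversal_index(ss, grid)
  bold <- array(rnorm(prod(grid$dim) * 30), c(grid$dim, 30))
  tw <- compute_twdfc(bold, idx, window_spec(10, 2))
  write_twdfc(tw, tmp)
  back <- read_image(tmp)
  expect_equal(dim(back$data), c(grid$dim, ncol(tw$values)))
  vi <- tw$voxels[1]
  expect_equal(back$data[arrayInd(vi, grid$dim)[1],
                         arrayInd(vi, grid$dim)[2],
                         arrayInd(vi, grid$dim)[3], ],
               unname(tw$values[1, ]), tolerance = 1e-6)
  side <- jsonlite::read_json(sub("\\.nii$", ".json", tmp),
                              simplifyVector = TRUE)
  expect_equal(side$window$length_tp, 10)
  expect_equal(side$n_v, idx$n_v)
})
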