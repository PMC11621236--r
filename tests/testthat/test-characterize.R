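test_that("percentage overlap covers the closed-form cases", {
  d <- c(5, 5, 5)
  nucleus <- array(FALSE, d); nucleus[1:10] <- TRUE
  inside <- array(FALSE, d); inside[1:20] <- TRUE
  expect_equal(percent_overlap(inside, nucleus), 100)  # nucleus subset
  disjoint <- array(FALSE, d); disjoint[21:30] <- TRUE
  expect_equal(percent_overlap(disjoint, nucleus), 0)
  half <- array(FALSE, d); half[6:15] <- TRUE          # overlap 5 of 10
  expect_equal(percent_overlap(half, nucleus), 50)
  expect_error(percent_overlap(inside, array(FALSE, d)), "empty nucleus")
})

test_that("ROI-trimmed overlap table rows sum to 100", {
  scene <- small_scene()
  res <- overlap_table(scene$truth_left, scene$atlas_labels,
                       roi_mask = scene$roi_left)
  expect_equal(unname(rowSums(res)), rep(100, nrow(res)), tolerance = 1e-9)
  # offset partitions must produce genuinely mixed rows
  expect_gt(sum(res > 0 & res < 100), 0)
})

test_that("maximum probability maps average matched individual clusters", {
  d <- c(6, 6, 2)
  group <- array(0L, d); group[1:3, , ] <- 1L; group[4:6, , ] <- 2L
  # all subjects identical (one relabelled) -> probabilities are 0/1
  swapped <- array(0L, d); swapped[1:3, , ] <- 2L; swapped[4:6, , ] <- 1L
  res <- mpm(list(group, group, swapped), group)
  expect_equal(res$prob$cluster_1, (group == 1) * 1)
  expect_equal(res$prob$cluster_2, (group == 2) * 1)
  # half the subjects assign a voxel to cluster 1, half to cluster 2
  shift <- array(0L, d); shift[1:4, , ] <- 1L; shift[5:6, , ] <- 2L
  res2 <- mpm(list(group, shift), group)
  expect_equal(res2$prob$cluster_1[4, 1, 1], 0.5)
  expect_equal(res2$prob$cluster_2[4, 1, 1], 0.5)
  # an individual cluster with zero Dice to every group cluster is left
  # unmatched and counted
  gpart <- array(0L, d); gpart[2:3, , ] <- 1L; gpart[4:6, , ] <- 2L
  stray <- gpart; stray[1, , ] <- 3L  # lives entirely in group background
  expect_message(res3 <- mpm(list(stray), gpart), "no group cluster")
  expect_equal(res3$n_unmatched, 1L)
})

test_that("cluster time-course maps equal a per-voxel correlation oracle", {
  scene <- small_scene()
  tw <- subject_twdfc(scene, 1, small_spec())
  cl <- scene$truth_left == 1
  z <- cluster_timecourse_map(tw, cl)
  rows <- match(which(cl), tw$voxels)
  mean_tc <- colMeans(tw$values[rows, ])
  picked <- tw$voxels[seq(1, length(tw$voxels), by = 97)]
  for (v in picked) {
    r <- cor(tw$values[match(v, tw$voxels), ], mean_tc)
    expect_equal(z[v], atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)),
                 tolerance = 1e-12)
  }
  # voxels without tw-dFC stay NA
  expect_true(is.na(z[1]))
  # a cluster voxel correlates strongly with its own mean
  expect_gt(min(z[which(cl)], na.rm = TRUE), 0)
  expect_error(cluster_timecourse_map(tw, array(FALSE, scene$grid$dim)),
               "no voxels")
})

test_that("winner-takes-all follows the argmax with deterministic ties", {
  d <- c(3, 3, 1)
  m1 <- array(0.3, d); m2 <- array(0.1, d)
  expect_true(all(winner_takes_all(list(m1, m2)) == 1L))
  # tie at equal values goes to the lowest cluster index
  m2[1, 1, 1] <- 0.3
  expect_equal(winner_takes_all(list(m1, m2))[1, 1, 1], 1L)
  # non-positive everywhere stays background
  expect_true(all(winner_takes_all(list(array(-1, d), array(0, d))) == 0L))
  # random maps against an explicit argmax oracle
  set.seed(51)
  maps <- lapply(1:4, function(i) array(rnorm(27), c(3, 3, 3)))
  wta <- winner_takes_all(maps)
  stacked <- sapply(maps, as.numeric)
  oracle <- apply(stacked, 1, which.max)
  oracle[apply(stacked, 1, max) <= 0] <- 0L
  expect_equal(as.integer(wta), as.integer(oracle))
  # assigned voxels are partitioned: disjoint and exhaustive over
  # positive-argmax voxels
  expect_setequal(which(wta > 0), which(apply(stacked, 1, max) > 0))
})

test_that("permutation t-test is antisymmetric and exact in structure", {
  set.seed(52)
  maps <- matrix(rnorm(10 * 50), 10)
  res <- permutation_onesample(maps, n_perm = 200, seed = 9)
  resneg <- permutation_onesample(-maps, n_perm = 200, seed = 9)
  expect_equal(res$t, -resneg$t, tolerance = 1e-12)
  expect_equal(res$p_fwe, resneg$p_fwe, tolerance = 1e-12)
  # p-values live in [1/(n_perm+1), 1] and decrease with |t|
  expect_gte(min(res$p_fwe), 1 / 201)
  expect_lte(max(res$p_fwe), 1)
  o <- order(abs(res$t))
  expect_true(all(diff(res$p_fwe[o]) <= 1e-12))
  # determinism
  res2 <- permutation_onesample(maps, n_perm = 200, seed = 9)
  expect_identical(res$p_fwe, res2$p_fwe)
  # zero-variance voxels are excluded as NA
  maps0 <- cbind(maps, 1)
  res0 <- permutation_onesample(maps0, n_perm = 100, seed = 1)
  expect_true(is.na(res0$t[51]))
})

test_that("strong constant signal survives FWE thresholding at alpha 0.001", {
  set.seed(53)
  maps <- matrix(rnorm(20 * 80, mean = 0, sd = 0.1), 20)
  maps[, 1:10] <- maps[, 1:10] + 1  # planted signal voxels
  res <- permutation_onesample(maps, n_perm = 2000, alpha = 0.001, seed = 2)
  expect_true(all(res$sig[1:10] == 1))
  expect_true(all(res$sig[11:80] == 0))
})

test_that("lateralization index reproduces its closed forms and guards", {
  d <- c(2, 2, 2)
  z2 <- array(0.2, d); z6 <- array(0.6, d)
  li <- lateralization(z2, z6)
  expect_equal(unique(as.numeric(li$li)), -0.5)
  expect_equal(unique(as.numeric(lateralization(z6, z6)$li)), 0)
  expect_equal(unique(as.numeric(lateralization(z2, array(0, d))$li)), 1)
  # masked where the denominator vanishes
  guard <- lateralization(z2, -z2)
  expect_true(all(is.na(guard$li)))
  expect_true(all(!guard$valid))
})

test_that("mirroring maps homotopic voxels onto each other", {
  scene <- small_scene()
  expect_identical(mirror_x(scene$roi_left), scene$roi_right)
  expect_identical(mirror_x(mirror_x(scene$truth_left)), scene$truth_left)
  # world coordinates flip sign in x on the centred grid
  g <- scene$grid
  w <- voxel_to_world(g, matrix(c(3, 5, 7), 1))
  wm <- voxel_to_world(g, matrix(c(g$dim[1] + 1 - 3, 5, 7), 1))
  expect_equal(w[1], -wm[1])
})
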