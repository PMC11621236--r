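test_that("silhouette approaches 1 for tight far blobs and 0 for degenerate data", {
  set.seed(41)
  # separation 20x the within-blob spread
  X <- rbind(matrix(rnorm(40 * 3, sd = 1), 40),
             matrix(rnorm(40 * 3, mean = 20 * sqrt(3), sd = 1), 40))
  lab <- rep(1:2, each = 40)
  expect_gte(silhouette_score(X, lab), 0.95)
  # all points identical: a = b = 0 convention gives 0
  same <- matrix(1, 10, 3)
  expect_equal(silhouette_score(same, rep(1:2, 5)), 0)
  expect_error(silhouette_score(X, rep(1L, 80)), "2 clusters")
})

test_that("silhouette of a random split of one blob is near zero", {
  set.seed(42)
  X <- matrix(rnorm(500 * 4), 500)
  lab <- sample(rep(1:2, 250))
  expect_lt(abs(silhouette_score(X, lab)), 0.1)
})

test_that("silhouette matches the reference implementation on generic data", {
  skip_if_not_installed("cluster")
  set.seed(43)
  X <- matrix(rnorm(60 * 5), 60)
  lab <- sample(1:3, 60, replace = TRUE)
  ours <- silhouette_score(X, lab)
  ref <- mean(cluster::silhouette(lab, dist(X))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("nVI closed forms and hand-enumerated contingency agree", {
  # identical partitions (any relabelling) -> 0
  p <- c(1L, 1L, 2L, 3L, 3L, 2L, 1L, 2L)
  expect_equal(nvi(p, c(2L, 3L, 1L)[p]), 0)
  # one cluster vs all singletons on N points -> VI = log N -> nVI = 1
  expect_equal(nvi(rep(1L, 8), 1:8), 1)
  # brute-force contingency computation on 8 points
  set.seed(44)
  p1 <- sample(1:2, 8, replace = TRUE)
  p2 <- sample(1:2, 8, replace = TRUE)
  n <- 8
  h <- function(p) {
    f <- table(p) / n
    -sum(f * log(f))
  }
  mi <- 0
  for (a in unique(p1)) for (b in unique(p2)) {
    pab <- sum(p1 == a & p2 == b) / n
    if (pab > 0) mi <- mi + pab * log(pab / (mean(p1 == a) * mean(p2 == b)))
  }
  expect_equal(nvi(p1, p2), (h(p1) + h(p2) - 2 * mi) / log(n),
               tolerance = 1e-12)
  expect_error(nvi(1:4, 1:5), "mismatch")
})

test_that("nVI behaves as a metric on random partitions", {
  set.seed(45)
  for (rep in 1:100) {
    n <- 30
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    cc <- sample(1:3, n, replace = TRUE)
    dab <- nvi(a, b); dbc <- nvi(b, cc); dac <- nvi(a, cc)
    expect_gte(dab, 0)
    expect_equal(dab, nvi(b, a))
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("adjusted Rand index matches the reference implementation", {
  skip_if_not_installed("mclust")
  set.seed(46)
  for (rep in 1:20) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(ari(1:10, 10:1), 1)
})

test_that("split-half nVI is zero for unanimous cohorts and deterministic", {
  p <- rep(1:3, each = 5)
  parts <- replicate(8, p, simplify = FALSE)
  v <- splithalf_nvi(parts, k = 3, n_resamples = 10, seed = 2, n_init = 10)
  expect_equal(v, rep(0, 10))
  v2 <- splithalf_nvi(parts, k = 3, n_resamples = 10, seed = 2, n_init = 10)
  expect_identical(v, v2)
  expect_error(splithalf_nvi(parts[1:3], 3), "4 subjects")
})

test_that("split-half nVI detects mixed sub-populations", {
  set.seed(47)
  pa <- rep(1:2, each = 10)
  pb <- rep(c(1L, 2L), 10)  # interleaved: different planted partition
  parts <- c(replicate(6, pa, simplify = FALSE),
             replicate(6, pb, simplify = FALSE))
  v <- splithalf_nvi(parts, k = 2, n_resamples = 25, seed = 3, n_init = 20)
  expect_gt(median(v), 0)
})

test_that("ANOVA and Tukey HSD match a hand calculation and flag separations", {
  # hand-computed one-way ANOVA on a small textbook-style table
  g1 <- c(1, 2, 3); g2 <- c(2, 3, 4); g3 <- c(6, 7, 8)
  all <- c(g1, g2, g3)
  ssb <- 3 * sum((c(mean(g1), mean(g2), mean(g3)) - mean(all))^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  res <- compare_k(list(k2 = g1, k3 = g2, k4 = g3))
  expect_equal(res$anova$F, f_hand, tolerance = 1e-10)
  expect_equal(res$anova$df_between, 2)
  expect_equal(res$anova$df_within, 6)
  # identical groups: F small, p large
  set.seed(48)
  base <- rnorm(30)
  res0 <- compare_k(list(a = base, b = base + 0, c = base))
  expect_gt(res0$anova$p, 0.9)
  # 5-sd separation: Tukey p < 0.001
  res5 <- compare_k(list(a = rnorm(20), b = rnorm(20, mean = 5)))
  expect_lt(res5$tukey$p_adj[1], 0.001)
  expect_true(res5$tukey$significant[1])
  expect_error(compare_k(list(a = c(1, 1), b = c(2, 2))), "undefined")
})

test_that("Dice handles closed forms and empty-set conventions", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0)         # empty vs non-empty
  expect_equal(dice(b, b), 1)         # empty vs empty: identical
  a8 <- array(FALSE, c(4, 4, 4)); b8 <- a8
  a8[1:8] <- TRUE; b8[5:12] <- TRUE   # |a|=|b|=8, overlap 4
  expect_equal(dice(a8, b8), 0.5)
  expect_equal(dice(c(1, 2, 3), c(4, 5, 6)), 0)
})

test_that("cluster matching recovers swaps and penalizes shifts", {
  lab <- array(0L, c(6, 6, 1))
  lab[1:3, , 1] <- 1L; lab[4:6, , 1] <- 2L
  swapped <- array(0L, c(6, 6, 1))
  swapped[1:3, , 1] <- 2L; swapped[4:6, , 1] <- 1L
  m <- match_and_average_dice(lab, swapped)
  expect_equal(m$average_dice, 1)
  expect_equal(m$pairs$cluster_b[m$pairs$cluster_a == 1], 2)
  shifted <- array(0L, c(6, 6, 1))
  shifted[2:4, , 1] <- 1L; shifted[c(5:6, 1), , 1] <- 2L
  m2 <- match_and_average_dice(lab, shifted)
  expect_lt(m2$average_dice, 1)
  expect_gt(m2$average_dice, 0)
})

test_that("greedy Dice matching usually equals the optimal assignment", {
  set.seed(49)
  mismatches <- 0
  trials <- 60
  for (t in seq_len(trials)) {
    # pairs of similar parcellations (relabelled + 20% disagreement), the
    # regime cluster matching is used in; greedy may only tie or lose to
    # the exhaustive optimum, and must match it almost always
    k <- sample(2:4, 1)
    la <- sample(1:k, 30, replace = TRUE)
    lb <- sample(1:k)[la]
    flip <- sample(30, 6)
    lb[flip] <- sample(1:k, 6, replace = TRUE)
    greedy <- match_and_average_dice(la, lb)$average_dice
    # brute force over all bijections
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      }
      out
    }
    best <- max(vapply(perms(1:k), function(p) {
      mean(vapply(1:k, function(i) dice(la == i, lb == p[i]), numeric(1)))
    }, numeric(1)))
    if (abs(greedy - best) > 1e-12) mismatches <- mismatches + 1
    expect_lte(greedy, best + 1e-12)
  }
  expect_lte(mismatches / trials, 0.05)
})
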