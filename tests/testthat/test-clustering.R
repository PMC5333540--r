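test_that("length groups split at 500 and 1000 bp", {
  expect_equal(assign_length_group(c(1, 499, 500, 750, 999, 1000, 5000)),
               c("small", "small", "medium", "medium", "medium", "long",
                 "long"))
  expect_error(assign_length_group(0))
})

test_that("the cluster-count rule follows the piecewise definition", {
  expect_true(is.na(choose_cluster_count(1)))
  expect_true(is.na(choose_cluster_count(2)))
  expect_equal(choose_cluster_count(3), 2L)
  expect_equal(choose_cluster_count(7), 2L)
  expect_equal(choose_cluster_count(9), 2L)
  expect_equal(choose_cluster_count(10), 4L)
  expect_equal(choose_cluster_count(50), 4L)
  expect_equal(choose_cluster_count(100), 4L)
  expect_equal(choose_cluster_count(101), 5L)
  expect_equal(choose_cluster_count(110), 6L)   # half away from zero
  expect_equal(choose_cluster_count(120), 6L)
  expect_equal(choose_cluster_count(300), 10L)  # capped
  expect_error(choose_cluster_count(0))
  # total on n >= 1, never above 10
  ks <- vapply(1:5000, choose_cluster_count, 1L)
  expect_true(all(is.na(ks[1:2])))
  expect_true(all(ks[-(1:2)] <= 10L, na.rm = TRUE))
})

test_that("profile normalization resamples, scales, and drops zeros", {
  ramp_long <- seq(0, 10, length.out = 2000)
  ramp_short <- seq(0, 3, length.out = 200)
  flat <- rep(4, 700)
  zero <- rep(0, 300)
  expect_warning(
    mat <- normalize_profiles(list(a = ramp_long, b = ramp_short,
                                   c = flat, z = zero), n_bins = 50L),
    "all-zero")
  expect_equal(dim(mat), c(3L, 50L))
  expect_equal(attr(mat, "excluded"), "z")
  expect_equal(mat["c", ], rep(1, 50L), ignore_attr = TRUE)
  # a linear ramp of any length resamples to the same ramp
  grid <- seq(0, 1, length.out = 50L)
  expect_equal(mat["a", ], grid, ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(mat["b", ], grid, ignore_attr = TRUE, tolerance = 1e-8)
  # independent interpolation oracle at a random profile
  set.seed(3)
  y <- rpois(137, 5)
  m <- normalize_profiles(list(p = y), n_bins = 60L)
  oracle <- approx(seq(0, 1, length.out = 137), y,
                   xout = seq(0, 1, length.out = 60))$y
  expect_equal(m["p", ], oracle / max(oracle), ignore_attr = TRUE)
})

test_that("correlation K-means recovers planted profile families", {
  set.seed(42)
  bins <- 80L
  x <- seq(0, 1, length.out = bins)
  bell <- function() dnorm(x, 0.5, 0.15) + rnorm(bins, 0, 0.05)
  spike <- function() exp(-8 * x) + exp(-8 * (1 - x)) +
    rnorm(bins, 0, 0.05)
  mat <- rbind(t(replicate(10, bell())), t(replicate(10, spike())))
  rownames(mat) <- paste0("p", 1:20)
  cl <- kmeans_correlation(mat, 2L, seed = 1L)
  truth <- rep(1:2, each = 10L)
  expect_equal(adjusted_rand(cl$assignments, truth), 1)

  # duplicated rows share a label; k = n gives zero total distance
  dup <- mat[c(1, 1, 11, 11), ]
  rownames(dup) <- paste0("d", 1:4)
  cl2 <- kmeans_correlation(dup, 2L, seed = 1L)
  expect_equal(cl2$assignments[["d1"]], cl2$assignments[["d2"]])
  expect_equal(cl2$assignments[["d3"]], cl2$assignments[["d4"]])
  cl3 <- kmeans_correlation(mat[1:4, ], 4L, seed = 1L)
  expect_equal(sort(unname(cl3$assignments)), 1:4)
  expect_lt(cl3$tot_within, 1e-8)

  expect_error(kmeans_correlation(mat[1:3, ], 5L), "exceeds")
  flatrow <- rbind(mat[1:3, ], flat = rep(1, bins))
  expect_warning(kmeans_correlation(flatrow, 2L), "zero-variance")

  # row order only permutes labels at a fixed seed
  perm <- sample(nrow(mat))
  cl4 <- kmeans_correlation(mat[perm, ], 2L, seed = 1L)
  expect_equal(adjusted_rand(cl4$assignments[rownames(mat)],
                             cl$assignments), 1)
})

test_that("cluster summaries report medians and junction imbalance", {
  bins <- 60L
  x <- seq(0, 1, length.out = bins)
  balanced <- exp(-6 * x) + exp(-6 * (1 - x))
  onesided <- exp(-6 * x)
  mat <- rbind(b1 = balanced, b2 = balanced * 0.9 + 0.01,
               u1 = onesided, u2 = onesided * 1.1 + 0.01)
  mat <- mat / apply(mat, 1, max)
  cl <- kmeans_correlation(mat, 2L, seed = 7L)
  lengths <- c(b1 = 500, b2 = 560, u1 = 600, u2 = 560)
  sm <- summarize_clusters(cl, mat, lengths)
  bal_cluster <- cl$assignments[["b1"]]
  expect_false(sm$unbalanced[sm$cluster == bal_cluster])
  expect_true(sm$unbalanced[sm$cluster != bal_cluster])
  expect_equal(sm$n_members, c(2L, 2L))
  # a cluster of identical profiles has that profile as its mean
  mp <- attr(sm, "mean_profiles")
  expect_equal(cor(mp[bal_cluster, ], balanced), 1, tolerance = 1e-6)
  # median of member lengths {500, 560, 600}: check both clusters
  expect_equal(sm$median_length_bp[sm$cluster == bal_cluster], 530)
  expect_equal(sm$median_length_bp[sm$cluster != bal_cluster], 580)
})

test_that("group-wise clustering separates length families on all circles", {
  # three families whose profile shapes track length, as observed for
  # real circles: short = covered throughout (central mass), medium =
  # broad dome, long = coverage only near the back-splice junction
  bins <- 100L
  x <- seq(0, 1, length.out = bins)
  shapes <- list(function() dnorm(x, 0.5, 0.12),
                 function() dnorm(x, 0.5, 0.35),
                 function() exp(-10 * x) + exp(-10 * (1 - x)))
  lens <- c(300, 700, 1500)
  for (s in 1:5) {
    set.seed(s)
    profiles <- list()
    lengths <- numeric(0)
    for (f in 1:3) for (i in 1:12) {
      id <- sprintf("f%d_%d", f, i)
      profiles[[id]] <- pmax(0, shapes[[f]]() * runif(1, 0.8, 1.2) +
                               rnorm(bins, 0, 0.1))
      lengths[id] <- lens[f] + sample(-20:20, 1)
    }
    cl <- cluster_coverage_profiles(profiles, lengths, seed = 11L)
    expect_equal(cl$all$k, 4L)        # 36 circles -> 4 clusters
    expect_equal(cl$small$n_circles, 12L)
    expect_equal(cl$medium$n_circles, 12L)
    expect_equal(cl$long$n_circles, 12L)
    truth <- rep(1:3, each = 12L)
    names(truth) <- names(profiles)
    ari <- adjusted_rand(cl$all$assignments[names(truth)], truth)
    expect_gte(ari, 0.8)
  }
})
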