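test_that("a planted far outlier is removed, and nothing else", {
  set.seed(21)
  ball <- matrix(rnorm(600), 200, 3)
  ball <- ball / pmax(sqrt(rowSums(ball^2)), 1)   # inside the unit ball
  pts <- rbind(ball, c(100, 0, 0))
  cl <- labeled_cloud(pts, c(rep(0L, 200), 1L))
  res <- statistical_outlier_removal(cl, k_neighbors = 16L, std_ratio = 2)
  expect_equal(res$removed_indices, 201L)
  expect_equal(nrow(res$kept$points), 200L)
  expect_equal(res$kept$labels, rep(0L, 200))
})

test_that("a uniform grid loses nothing when neighbour distances are constant", {
  g <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4))
  cl <- labeled_cloud(g)
  # every grid point has at least 3 axis neighbours at unit distance, so the
  # mean 3-NN distance is constant and the threshold clears every point
  res <- statistical_outlier_removal(cl, k_neighbors = 3L, std_ratio = 3)
  expect_length(res$removed_indices, 0L)
})

test_that("outlier removal is idempotent on the constructed fixture", {
  g <- as.matrix(expand.grid(x = 0:5, y = 0:5, z = 0:5))
  pts <- rbind(g, c(60, 60, 60))
  first <- statistical_outlier_removal(labeled_cloud(pts), 3L, 2)
  expect_equal(first$removed_indices, nrow(pts))
  second <- statistical_outlier_removal(first$kept, 3L, 2)
  expect_length(second$removed_indices, 0L)
})

test_that("the filter matches a brute-force all-pairs implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    m <- sample(50:400, 1)
    k <- sample(c(4L, 8L, 16L), 1)
    pts <- matrix(rnorm(3 * m, sd = sample(1:3, 1)), m, 3)
    d_oracle <- brute_knn_meandist(pts, k)
    removed_oracle <- which(d_oracle > mean(d_oracle) + 2 * sd(d_oracle))
    res <- statistical_outlier_removal(labeled_cloud(pts), k, 2)
    expect_equal(res$removed_indices, removed_oracle)
  }
  expect_error(statistical_outlier_removal(random_cloud(10), 16L), "points")
})

test_that("normalization centres, scales to unit radius, and inverts", {
  cl <- labeled_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  nm <- normalize_cloud(cl)
  expect_equal(nm$cloud$points, rbind(c(-1, 0, 0), c(1, 0, 0)),
               ignore_attr = TRUE)
  rc <- random_cloud(40, seed = 2)
  nm2 <- normalize_cloud(rc)
  expect_equal(denormalize_points(nm2$cloud$points, nm2$transform),
               rc$points, tolerance = 1e-9)
  # idempotence
  again <- normalize_cloud(nm2$cloud)
  expect_equal(again$cloud$points, nm2$cloud$points, tolerance = 1e-9)
  # degenerate single point
  one <- normalize_cloud(labeled_cloud(matrix(c(3, 4, 5), 1, 3)))
  expect_equal(as.vector(one$cloud$points), c(0, 0, 0))
  expect_equal(one$transform$scale, 1)
})

test_that("fixed-size resampling down-samples distinctly and up-samples from originals", {
  big <- random_cloud(8192, seed = 3)
  down <- resample_fixed(big, 4096L, seed = 1)
  expect_equal(nrow(down$points), 4096L)
  expect_equal(anyDuplicated(down$points), 0L)

  small <- random_cloud(1000, seed = 4)
  up <- resample_fixed(small, 4096L, seed = 1)
  expect_equal(nrow(up$points), 4096L)
  key_small <- apply(small$points, 1, paste, collapse = ",")
  key_up <- apply(up$points, 1, paste, collapse = ",")
  expect_true(all(key_up %in% key_small))

  same <- resample_fixed(small, 1000L, seed = 1)
  expect_setequal(apply(same$points, 1, paste, collapse = ","), key_small)
})

test_that("rotation is an isometry about the vertical axis", {
  cl <- labeled_cloud(rbind(c(1, 0, 0), c(-1, 0, 0)), c(1L, 0L))
  expect_equal(augment_rotation(cl, angle = 0)$points, cl$points,
               tolerance = 1e-12)
  rot <- augment_rotation(cl, angle = pi)
  expect_equal(rot$points[1, ], c(x = -1, y = 0, z = 0), tolerance = 1e-12)
  expect_identical(rot$labels, cl$labels)

  rc <- random_cloud(60, seed = 5)
  r2 <- augment_rotation(rc, seed = 8)
  expect_equal(as.matrix(dist(r2$points)), as.matrix(dist(rc$points)),
               tolerance = 1e-9)
  expect_equal(r2$points[, 3], rc$points[, 3])   # z untouched
})

test_that("jitter is clipped and has the requested spread", {
  cl <- random_cloud(4096, seed = 6)
  p0 <- augment_params(jitter_sigma = 0, jitter_clip = 0.05)
  expect_equal(augment_jitter(cl, p0, seed = 1)$points, cl$points)
  p <- augment_params(jitter_sigma = 0.01, jitter_clip = 0.05)
  jc <- augment_jitter(cl, p, seed = 2)
  off <- jc$points - cl$points
  expect_lte(max(abs(off)), 0.05)
  expect_lt(abs(sd(off) - 0.01) / 0.01, 0.1)      # sigma << clip regime
  expect_error(augment_params(jitter_sigma = 0.1, jitter_clip = 0.01),
               "jitter_clip")
})

test_that("Gaussian noise is unclipped and adds its variance", {
  cl <- random_cloud(10000, seed = 7)
  p0 <- augment_params(noise_sigma = 0)
  expect_equal(augment_noise(cl, p0, seed = 1)$points, cl$points)
  p <- augment_params(noise_sigma = 0.5)
  nz <- augment_noise(cl, p, seed = 3)
  expect_equal(nrow(nz$points), nrow(cl$points))
  v_in <- apply(cl$points, 2, var)
  v_out <- apply(nz$points, 2, var)
  expect_equal(v_out, v_in + 0.25, tolerance = 0.05)
  expect_identical(nz$labels, cl$labels)
})

test_that("augmentation expands a manifest exactly four-fold", {
  d <- withr::local_tempdir()
  m <- generate_dataset(3L, d, seed = 30, points_total = 256L)
  aug <- build_augmented(m, augment_params(seed = 1))
  expect_equal(nrow(aug), 12L)
  expect_true(all(file.exists(aug$path)))
  for (id in unique(aug$origin_id)) {
    expect_setequal(aug$variant[aug$origin_id == id],
                    c("original", "rotated", "jittered", "noised"))
  }
  one <- build_augmented(m[1, , drop = FALSE], augment_params(seed = 1))
  expect_equal(nrow(one), 4L)
  expect_equal(unique(one$origin_id), m$origin_id[1])
})
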