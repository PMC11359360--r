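test_that("farthest point sampling matches the greedy max-min oracle", {
  # m = 1 returns the start index
  set.seed(10)
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(farthest_point_sample(pts, 1, start_index = 4L), 4L)

  # unit-square corners: starting at (0,0), the second pick is (1,1)
  sq <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0)
  expect_equal(farthest_point_sample(sq, 2, start_index = 1L), c(1L, 4L))

  # oracle equivalence on 50 random points, m = 8
  set.seed(11)
  p50 <- matrix(rnorm(150), 50, 3)
  expect_equal(farthest_point_sample(p50, 8), brute_fps(p50, 8))

  # exhaustive greedy oracle on all instance sizes up to 64
  for (n in c(8, 17, 33, 64)) {
    pts <- matrix(runif(3 * n), n, 3)
    m <- max(2L, n %/% 4L)
    st <- sample.int(n, 1)
    expect_equal(farthest_point_sample(pts, m, st), brute_fps(pts, m, st))
  }
  expect_error(farthest_point_sample(sq, 9), "exceeds")
})

test_that("ball grouping matches a brute-force range query", {
  set.seed(12)
  pts <- matrix(rnorm(300), 100, 3)
  cents <- c(3L, 50L, 99L)
  K <- 12L
  r <- 0.8
  grp <- group_neighbors(pts, cents, r, K)
  expect_equal(dim(grp$indices), c(K, length(cents)))
  for (j in seq_along(cents)) {
    d <- sqrt(colSums((t(pts) - pts[cents[j], ])^2))
    inball <- which(d <= r)
    expected <- inball[order(d[inball])]
    take <- min(K, length(expected))
    got <- grp$indices[, j]
    expect_equal(d[got[seq_len(take)]], sort(d[inball])[seq_len(take)])
    if (take < K) expect_true(all(got[(take + 1):K] == expected[1]))
    # relative coordinates are neighbour minus centroid
    rel <- grp$relative[, (j - 1) * K + seq_len(K)]
    expect_equal(rel, t(pts[got, ]) - pts[cents[j], ], ignore_attr = TRUE)
  }
})

test_that("grouping handles the whole cloud and isolated centroids", {
  set.seed(13)
  pts <- matrix(rnorm(24), 8, 3)
  all_grp <- group_neighbors(pts, 1:8, Inf, 8L)
  for (j in 1:8) expect_setequal(all_grp$indices[, j], 1:8)

  iso <- rbind(matrix(rnorm(21), 7, 3), c(100, 100, 100))
  grp <- group_neighbors(iso, 8L, 0.5, 4L)
  expect_true(all(grp$indices == 8L))
  expect_equal(grp$relative[, 1:4], matrix(0, 3, 4), ignore_attr = TRUE)
})

test_that("interpolation weights are a proper convex combination", {
  set.seed(14)
  coarse <- matrix(rnorm(30), 10, 3)
  fine <- rbind(coarse[c(2, 7), ], matrix(rnorm(15), 5, 3))
  w <- three_nn_weights(fine, coarse)
  expect_true(all(w$w >= 0))
  expect_equal(colSums(w$w), rep(1, nrow(fine)))

  feats <- matrix(rnorm(5 * 10), 5, 10)
  interp <- interpolate_features(feats, coarse, fine)
  # a fine point coincident with a coarse point takes that feature
  expect_equal(interp[, 1], feats[, 2], tolerance = 1e-6)
  expect_equal(interp[, 2], feats[, 7], tolerance = 1e-6)
  # constant features interpolate to the constant everywhere
  const <- matrix(5, 2, 10)
  expect_equal(interpolate_features(const, coarse, fine),
               matrix(5, 2, nrow(fine)), tolerance = 1e-9)
})

test_that("the stage schedule follows the printed 4x point / channel chain", {
  cfg <- model_config()   # 4096-point, full-width configuration
  sch <- config_schedule(cfg)
  expect_equal(sch$points, c(4096L, 1024L, 256L, 64L, 16L))
  expect_equal(sch$channels, c(64L, 128L, 256L, 512L, 1024L))
  expect_error(model_config(n_points = 1000), "divisible")
})

test_that("set abstraction reduces points 4x and carries the stage widths", {
  set.seed(15)
  model <- cphnet_new(tiny_config(), seed = 2)
  coords <- matrix(rnorm(256 * 3), 256, 3)
  coords <- coords / max(sqrt(rowSums(coords^2)))
  feats <- cra_mlp(t(coords), model$lift)
  s1 <- set_abstraction(feats, coords, model$sa[[1]])
  expect_equal(dim(s1$features), c(16L, 64L))
  expect_equal(dim(s1$coords), c(64L, 3L))
  s2 <- set_abstraction(s1$features, s1$coords, model$sa[[2]])
  expect_equal(dim(s2$features), c(32L, 16L))
})

test_that("a point permutation fixing the start index leaves stage output unchanged", {
  set.seed(16)
  model <- cphnet_new(tiny_config(), seed = 3)
  coords <- matrix(rnorm(256 * 3), 256, 3)
  feats <- matrix(rnorm(8 * 256), 8, 256)
  out1 <- set_abstraction(feats, coords, model$sa[[1]])
  perm <- c(1L, sample(2:256))
  out2 <- set_abstraction(feats[, perm], coords[perm, ], model$sa[[1]])
  expect_equal(out2$coords, out1$coords, tolerance = 1e-12)
  expect_equal(out2$features, out1$features, tolerance = 1e-8)
})

test_that("feature propagation fuses skips at the requested width", {
  set.seed(17)
  model <- cphnet_new(tiny_config(), seed = 4)
  coarse_c <- matrix(rnorm(12), 4, 3)
  fine_c <- matrix(rnorm(48), 16, 3)
  coarse_f <- matrix(rnorm(128 * 4), 128, 4)
  skip <- matrix(rnorm(64 * 16), 64, 16)
  out <- feature_propagation(coarse_f, coarse_c, fine_c, skip, model$fp[[4]])
  expect_equal(dim(out), c(64L, 16L))
})

test_that("the forward pass emits per-point probability rows summing to 1", {
  set.seed(18)
  model <- cphnet_new(tiny_config(), seed = 5)
  cl <- tiny_training_set(1)[[1]]
  prob <- cphnet_forward(model, cl)
  expect_equal(dim(prob), c(1L, 256L, 2L))
  expect_true(max(abs(rowSums(prob[1, , ]) - 1)) < 1e-6)

  # identical clouds in a batch give identical outputs
  probs <- cphnet_forward(model, list(cl, cl))
  expect_identical(probs[1, , ], probs[2, , ])

  # wrong point count directs the user to resampling
  small <- labeled_cloud(matrix(rnorm(30), 10, 3))
  expect_error(cphnet_forward(model, small), "resample_fixed")
})

test_that("ablation switches control module presence as in the 8-way grid", {
  for (cra in c(TRUE, FALSE)) for (pesa in c(TRUE, FALSE)) {
    m <- cphnet_new(tiny_config(cra = cra, pesa = pesa), seed = 1)
    expect_equal(!is.null(m$sa[[1]]$block$se), cra)
    expect_equal(!is.null(m$sa[[1]]$pesa), pesa)
    p <- cphnet_forward(m, matrix(rnorm(256 * 3), 256, 3))
    expect_true(all(is.finite(p)))
  }
})

test_that("a full-width forward pass of one 4096-point cloud stays under 5 s", {
  set.seed(19)
  model <- cphnet_new(model_config(), seed = 6)
  coords <- matrix(rnorm(4096 * 3), 4096, 3)
  coords <- coords / max(sqrt(rowSums(coords^2)))
  prob <- NULL
  # steady-state timing: best of two passes, after a warm-up and a gc so
  # allocator state from earlier tests does not leak into the measurement
  invisible(cphnet_forward(cphnet_new(tiny_config(), seed = 1),
                           matrix(rnorm(768), 256, 3)))   # warm code paths
  gc(FALSE)
  times <- vapply(1:2, function(i) {
    t0 <- proc.time()[["elapsed"]]
    prob <<- cphnet_forward(model, coords)
    proc.time()[["elapsed"]] - t0
  }, numeric(1))
  expect_lt(min(times), 5)
  expect_true(max(abs(rowSums(prob[1, , ]) - 1)) < 1e-6)
})
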