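test_that("seedling generation honours the point budget and labels both classes", {
  b <- generate_seedling(scene_spec(points_total = 1024L, outlier_rate = 0,
                                    seed = 2))
  expect_equal(nrow(b$cloud$points), 1024L)
  expect_setequal(unique(b$cloud$labels), c(0L, 1L))
})

test_that("generation is bit-reproducible under a fixed seed", {
  s <- scene_preset("cluttered", points_total = 1024L, seed = 9)
  a <- generate_scene(s)
  b <- generate_scene(s)
  expect_identical(a$cloud$points, b$cloud$points)
  expect_identical(a$cloud$labels, b$cloud$labels)
  expect_identical(a$truth_masks, b$truth_masks)
})

test_that("a near-degenerate stem radius keeps stem points on the spine", {
  # with zero curvature and no branches the spine is the vertical axis, so
  # every stem point must lie within the tube radius of it
  r <- 1e-4
  b <- generate_seedling(scene_spec(stem_radius = r, stem_curvature = 0,
                                    leaf_count = 0L, points_total = 512L,
                                    outlier_rate = 0, seed = 4))
  stem <- b$cloud$points[b$truth_masks$stem, , drop = FALSE]
  expect_gt(nrow(stem), 0)
  expect_lt(max(sqrt(stem[, 1]^2 + stem[, 2]^2)), r + 1e-8)
  expect_error(scene_spec(stem_radius = 0), "positive")
})

test_that("masks partition the points and agree with the labels", {
  b <- generate_scene(scene_preset("cluttered", points_total = 2048L, seed = 3))
  idx <- sort(unname(unlist(b$truth_masks)))
  expect_equal(idx, seq_len(2048L))                 # partition, no overlap
  expect_equal(sort(b$truth_masks$stem), which(b$cloud$labels == 1L))
})

test_that("the outlier budget is honoured exactly", {
  b <- generate_scene(scene_spec(outlier_rate = 0.05, points_total = 2000L,
                                 seed = 6))
  expect_length(b$truth_masks$outlier, round(0.05 * 2000))
})

test_that("two-plant scenes have two separated stem components", {
  b <- generate_scene(scene_preset("two_plant", points_total = 4096L, seed = 8))
  stem <- b$cloud$points[b$truth_masks$stem, , drop = FALSE]
  hc <- hclust(dist(stem), method = "single")
  comp <- cutree(hc, h = 2 * b$spec$stem_radius)
  # the two largest single-linkage components dominate the stem points
  expect_gte(length(unique(comp)), 2)
  top2 <- sort(table(comp), decreasing = TRUE)[1:2]
  expect_gt(sum(top2) / nrow(stem), 0.95)
})

test_that("without wall or table the scene stays near the plant axis", {
  b <- generate_scene(scene_spec(points_total = 2048L, seed = 5))
  keep <- setdiff(seq_len(2048L), b$truth_masks$outlier)
  radial <- sqrt(b$cloud$points[keep, 1]^2 + b$cloud$points[keep, 2]^2)
  expect_lt(max(radial), 0.35)
})

test_that("the early-growth preset is stem-scarce", {
  b <- generate_scene(scene_preset("early", points_total = 4096L, seed = 11))
  expect_lt(mean(b$cloud$labels == 1L), 0.05)
  expect_gt(sum(b$cloud$labels == 1L), 0)
})

test_that("scene generation at 4096 points is fast", {
  t0 <- proc.time()[["elapsed"]]
  generate_scene(scene_preset("branchy", points_total = 4096L, seed = 12))
  expect_lt(proc.time()[["elapsed"]] - t0, 1)
})

test_that("generate_dataset writes files, distinct origins, deterministically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(5L, d1, seed = 13, points_total = 256L)
  m2 <- generate_dataset(5L, d2, seed = 13, points_total = 256L)
  expect_equal(nrow(m1), 5L)
  expect_length(unique(m1$origin_id), 5L)
  expect_true(all(file.exists(m1$path)))
  expect_identical(m1$origin_id, m2$origin_id)
  expect_identical(readLines(m1$path[1]), readLines(m2$path[1]))
  m3 <- generate_dataset(1L, withr::local_tempdir(), seed = 1,
                         points_total = 256L)
  expect_equal(nrow(m3), 1L)
})
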