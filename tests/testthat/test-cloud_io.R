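test_that("xyzl text parses coordinates and labels", {
  f <- withr::local_tempfile(fileext = ".xyzl")
  writeLines(c("0 0 0 1", "1 0 0 0", "0 1 0 1"), f)
  cl <- read_cloud(f, format = "xyzl")
  expect_equal(nrow(cl$points), 3L)
  expect_equal(cl$labels, c(1L, 0L, 1L))
  expect_equal(cl$points[2, ], c(x = 1, y = 0, z = 0))
})

test_that("xyz file without a label column yields a label-free cloud", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 2 3"), f)
  cl <- read_cloud(f)
  expect_null(cl$labels)
  expect_equal(nrow(cl$points), 2L)
})

test_that("PLY and xyzl encodings of one cloud read identically", {
  cl <- random_cloud(20, seed = 3)
  f1 <- withr::local_tempfile(fileext = ".ply")
  f2 <- withr::local_tempfile(fileext = ".xyzl")
  write_cloud(cl, f1)
  write_cloud(cl, f2)
  a <- read_cloud(f1)
  b <- read_cloud(f2)
  expect_equal(a$points, b$points)
  expect_equal(a$labels, b$labels)
})

test_that("round trips hold for every format on random fixtures", {
  for (seed in 1:3) {
    cl <- random_cloud(30, seed = seed)
    for (fmt in c("ply", "pcd", "xyzl")) {
      f <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_cloud(cl, f, format = fmt)
      back <- read_cloud(f, format = fmt)
      expect_equal(back$points, cl$points, tolerance = 1e-6)
      expect_identical(back$labels, cl$labels)
    }
  }
  # label-free round trip
  cl <- random_cloud(10, seed = 9, labels = FALSE)
  f <- withr::local_tempfile(fileext = ".ply")
  write_cloud(cl, f)
  expect_null(read_cloud(f)$labels)
})

test_that("colorized PLY writes green stems and blue others", {
  cl <- labeled_cloud(rbind(c(0, 0, 0), c(1, 1, 1)), c(1L, 0L))
  f <- withr::local_tempfile(fileext = ".ply")
  write_cloud(cl, f, colorize = TRUE)
  lines <- readLines(f)
  body <- lines[(match("end_header", lines) + 1):length(lines)]
  expect_match(body[1], "0 255 0$")   # stem -> green
  expect_match(body[2], "0 0 255$")   # other -> blue
  # colorize requires labels
  nolab <- labeled_cloud(rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(write_cloud(nolab, f, colorize = TRUE), "labelled")
})

test_that("malformed records raise parse errors naming the element", {
  f <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 2",
               "property double x", "property double y", "property double z",
               "end_header", "0 0 0", "1 oops"), f)
  expect_error(read_cloud(f), "record 2")
  expect_error(read_cloud("does_not_exist.ply"), "not found")
  f2 <- withr::local_tempfile(fileext = ".bin")
  writeLines("x", f2)
  expect_error(read_cloud(f2), "format")
})

test_that("manifests reject duplicates and empty origins", {
  expect_error(dataset_manifest("a.ply", "", "original"), "non-empty")
  expect_error(dataset_manifest(c("a.ply", "b.ply"), c("o1", "o1"),
                                c("original", "original")), "duplicate")
  m <- fake_manifest(3, c("original", "rotated"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(m, f)
  expect_equal(read_manifest(f), m, ignore_attr = TRUE)
})

test_that("grouped 4:1 split of 298 origins x 4 variants gives 952/240", {
  m <- fake_manifest(298, c("original", "rotated", "jittered", "noised"))
  sp <- split_grouped(m, "4:1", seed = 7)
  expect_equal(nrow(sp$train), 952L)
  expect_equal(nrow(sp$test), 240L)
  expect_equal(sp$ratio, 0.8)
})

test_that("split sizes follow floor of the train fraction on origins", {
  m <- fake_manifest(5)
  sp <- split_grouped(m, "4:1", seed = 1)
  expect_equal(nrow(sp$train), 4L)
  expect_equal(nrow(sp$test), 1L)
  expect_error(split_grouped(fake_manifest(1), 0.8), "2 origins")
  expect_error(split_grouped(m, 1.2), "ratio")
})

test_that("splits are deterministic and never separate variants of an origin", {
  m <- fake_manifest(12, c("original", "rotated", "jittered", "noised"))
  a <- split_grouped(m, 0.8, seed = 42)
  b <- split_grouped(m, 0.8, seed = 42)
  expect_identical(a$train, b$train)
  expect_identical(a$test, b$test)
  for (i in 1:100) {
    n_or <- sample(2:20, 1)
    vs <- sample(c("original", "rotated", "jittered", "noised"),
                 sample(1:4, 1))
    mm <- fake_manifest(n_or, vs)
    sp <- split_grouped(mm, runif(1, 0.3, 0.9), seed = i)
    expect_equal(nrow(sp$train) + nrow(sp$test), nrow(mm))
    expect_length(intersect(unique(sp$train$origin_id),
                            unique(sp$test$origin_id)), 0)
  }
})

test_that("grouped k-fold partitions origins into near-equal folds", {
  m <- fake_manifest(10)
  folds <- kfold_grouped(m, k = 5, seed = 3)
  expect_length(folds, 5)
  val_origins <- lapply(folds, function(f) unique(f$test$origin_id))
  expect_true(all(lengths(val_origins) == 2))
  expect_setequal(unlist(val_origins), unique(m$origin_id))
  expect_equal(anyDuplicated(unlist(val_origins)), 0L)

  sizes <- sort(lengths(lapply(kfold_grouped(fake_manifest(298), 5, 1),
                               function(f) unique(f$test$origin_id))),
                decreasing = TRUE)
  expect_equal(sizes, c(60, 60, 60, 59, 59))
  expect_error(kfold_grouped(fake_manifest(3), k = 5), "exceeds")
})
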