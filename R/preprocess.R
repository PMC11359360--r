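#' Statistical outlier removal
#'
#' The classic point-cloud statistical filter: every point's mean distance
#' to its `k` nearest neighbours (self excluded) is computed; points whose
#' mean distance exceeds the global mean plus `std_ratio` standard
#' deviations are removed. Labels follow the kept points.
#'
#' @param cloud a [labeled_cloud()].
#' @param k_neighbors number of neighbours (default 16).
#' @param std_ratio multiplier on the standard deviation of the mean
#'   neighbour distances (default 2).
#' @return list with `kept` (the filtered cloud) and `removed_indices`
#'   (indices into the input cloud).
#' @export
statistical_outlier_removal <- function(cloud, k_neighbors = 16L,
                                        std_ratio = 2.0) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  k <- as.integer(k_neighbors)
  if (k < 1L) stopf("k_neighbors must be >= 1")
  if (std_ratio <= 0) stopf("std_ratio must be positive")
  m <- n_points(cloud)
  if (m <= k) stopf("cloud has %d points, need more than k = %d", m, k)
  d <- cpp_knn_meandist(cloud$points, k)
  threshold <- mean(d) + std_ratio * sd(d)
  removed <- which(d > threshold)
  keep <- setdiff(seq_len(m), removed)
  kept <- labeled_cloud(cloud$points[keep, , drop = FALSE],
                        cloud$labels[keep],
                        origin_id = cloud$origin_id, variant = cloud$variant)
  list(kept = kept, removed_indices = removed)
}

#' Normalize a cloud to the unit sphere
#'
#' Centres the centroid at the origin and scales the maximum radius to 1;
#' the transform is recorded and invertible. A single-point (or otherwise
#' degenerate) cloud is centred with scale 1.
#'
#' @param cloud a [labeled_cloud()].
#' @return list with `cloud` (normalized) and `transform`
#'   (`list(center, scale)` such that original = normalized * scale + center).
#' @export
normalize_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  center <- colMeans(cloud$points)
  centered <- sweep(cloud$points, 2, center)
  r <- sqrt(max(rowSums(centered^2)))
  scale <- if (r > 0) r else 1
  out <- labeled_cloud(centered / scale, cloud$labels,
                       origin_id = cloud$origin_id, variant = cloud$variant)
  list(cloud = out, transform = list(center = center, scale = scale))
}

#' @rdname normalize_cloud
#' @param points M x 3 matrix of normalized coordinates.
#' @param transform transform record from `normalize_cloud`.
#' @return `denormalize_points`: the coordinates in the original frame.
#' @export
denormalize_points <- function(points, transform) {
  sweep(points * transform$scale, 2, transform$center, `+`)
}

#' Resample a cloud to a fixed size
#'
#' Downsampling uses farthest-point sampling (distinct indices); upsampling
#' keeps every original point and draws the remainder uniformly with
#' replacement. Labels follow their points.
#'
#' @param cloud a [labeled_cloud()].
#' @param n_points target size (the network input size, typically 4096).
#' @param seed seed for the FPS start / upsampling draws.
#' @return a [labeled_cloud()] with exactly `n_points` points.
#' @export
resample_fixed <- function(cloud, n_points = 4096L, seed = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  m <- nrow(cloud$points)
  n <- as.integer(n_points)
  idx <- if (m >= n) {
    start <- with_seed(seed, sample.int(m, 1L))
    cpp_fps(cloud$points, n, start)
  } else {
    extra <- with_seed(seed, sample.int(m, n - m, replace = TRUE))
    c(seq_len(m), extra)
  }
  labeled_cloud(cloud$points[idx, , drop = FALSE], cloud$labels[idx],
                origin_id = cloud$origin_id, variant = cloud$variant)
}

#' Augmentation parameters
#'
#' Defaults (normalized units): jitter sigma 0.01 clipped at 0.05; unclipped
#' Gaussian noise sigma 0.02; rotation about the vertical axis over
#' \[0, 2*pi). Jitter and Gaussian noise are distinct augmentations: jitter
#' is clipped per coordinate, noise is not.
#'
#' @param jitter_sigma,jitter_clip jitter standard deviation and clip bound.
#' @param noise_sigma Gaussian noise standard deviation.
#' @param seed master seed for [build_augmented()].
#' @return an `augment_params` list.
#' @export
augment_params <- function(jitter_sigma = 0.01, jitter_clip = 0.05,
                           noise_sigma = 0.02, seed = 1L) {
  if (jitter_sigma < 0 || noise_sigma < 0) stopf("sigmas must be >= 0")
  if (jitter_clip < jitter_sigma)
    stopf("jitter_clip must be at least jitter_sigma")
  structure(list(jitter_sigma = jitter_sigma, jitter_clip = jitter_clip,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "augment_params")
}

#' Random rotation about the vertical axis
#'
#' One angle drawn uniformly from \[0, 2*pi) rotates the whole cloud about
#' the vertical (z) axis through its centroid, preserving gravity
#' orientation and all pairwise distances.
#'
#' @param cloud a [labeled_cloud()].
#' @param seed seed for the angle draw.
#' @param angle optional fixed angle in radians (overrides the draw).
#' @return the rotated [labeled_cloud()] (variant `"rotated"`).
#' @export
augment_rotation <- function(cloud, seed = 1L, angle = NULL) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  theta <- angle %||% with_seed(seed, runif(1, 0, 2 * pi))
  center <- colMeans(cloud$points)
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3)
  pts <- sweep(sweep(cloud$points, 2, center) %*% rot, 2, center, `+`)
  labeled_cloud(pts, cloud$labels, origin_id = cloud$origin_id,
                variant = "rotated")
}

#' Random clipped jitter
#'
#' Adds i.i.d. Gaussian offsets to every coordinate, each clipped to
#' `+/- jitter_clip`.
#'
#' @param cloud a [labeled_cloud()].
#' @param params an [augment_params()].
#' @param seed seed for the offsets.
#' @return the jittered [labeled_cloud()] (variant `"jittered"`).
#' @export
augment_jitter <- function(cloud, params = augment_params(), seed = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  m <- n_points(cloud)
  off <- with_seed(seed, matrix(rnorm(3 * m, sd = params$jitter_sigma), m, 3))
  off <- pmin(pmax(off, -params$jitter_clip), params$jitter_clip)
  labeled_cloud(cloud$points + off, cloud$labels,
                origin_id = cloud$origin_id, variant = "jittered")
}

#' Additive Gaussian noise
#'
#' Unclipped i.i.d. Gaussian perturbation of every coordinate.
#'
#' @inheritParams augment_jitter
#' @return the perturbed [labeled_cloud()] (variant `"noised"`).
#' @export
augment_noise <- function(cloud, params = augment_params(), seed = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  m <- n_points(cloud)
  off <- with_seed(seed, matrix(rnorm(3 * m, sd = params$noise_sigma), m, 3))
  labeled_cloud(cloud$points + off, cloud$labels,
                origin_id = cloud$origin_id, variant = "noised")
}

#' Expand a manifest four-fold by augmentation
#'
#' Every original entry is read from disk and written back in three
#' augmented variants (rotated, jittered, noised) beside it, so the
#' augmented manifest holds exactly 4x the originals. Per-entry seeds derive
#' deterministically from `params$seed`.
#'
#' @param manifest a [dataset_manifest()] of `"original"` entries.
#' @param params an [augment_params()].
#' @param out_dir directory for the augmented files; defaults to each
#'   source file's directory.
#' @return the expanded [dataset_manifest()].
#' @export
build_augmented <- function(manifest, params = augment_params(),
                            out_dir = NULL) {
  orig <- manifest[manifest$variant == "original", , drop = FALSE]
  if (nrow(orig) == 0L) stopf("manifest has no original entries")
  rows <- vector("list", 4L * nrow(orig))
  for (i in seq_len(nrow(orig))) {
    cloud <- read_cloud(orig$path[i], origin_id = orig$origin_id[i])
    dir_i <- out_dir %||% dirname(orig$path[i])
    stem_name <- tools::file_path_sans_ext(basename(orig$path[i]))
    ext <- tools::file_ext(orig$path[i])
    sd_i <- derive_seed(params$seed, i)
    variants <- list(
      rotated = augment_rotation(cloud, seed = derive_seed(sd_i, 1L)),
      jittered = augment_jitter(cloud, params, seed = derive_seed(sd_i, 2L)),
      noised = augment_noise(cloud, params, seed = derive_seed(sd_i, 3L)))
    rows[[4L * i - 3L]] <- data.frame(path = orig$path[i],
                                      origin_id = orig$origin_id[i],
                                      variant = "original", split = "")
    j <- 1L
    for (v in names(variants)) {
      path_v <- file.path(dir_i, sprintf("%s_%s.%s", stem_name, v, ext))
      write_cloud(variants[[v]], path_v)
      rows[[4L * i - 3L + j]] <- data.frame(path = path_v,
                                            origin_id = orig$origin_id[i],
                                            variant = v, split = "")
      j <- j + 1L
    }
  }
  all_rows <- do.call(rbind, rows)
  dataset_manifest(all_rows$path, all_rows$origin_id, all_rows$variant,
                   all_rows$split)
}
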