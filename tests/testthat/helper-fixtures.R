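# Shared fixture builders. Everything is generated in code at test time.

# Random labelled cloud on the unit sphere.
random_cloud <- function(m = 50L, seed = 1L, labels = TRUE) {
  set.seed(seed)
  pts <- matrix(rnorm(3 * m), m, 3)
  labeled_cloud(pts, if (labels) as.integer(runif(m) > 0.7),
                origin_id = sprintf("fix%d", seed))
}

# Manifest of n_origins x length(variants) synthetic entries (no files).
fake_manifest <- function(n_origins, variants = "original") {
  ids <- rep(sprintf("o%03d", seq_len(n_origins)), each = length(variants))
  vs <- rep(variants, n_origins)
  dataset_manifest(path = sprintf("%s_%s.ply", ids, vs),
                   origin_id = ids, variant = vs)
}

# Brute-force mean k-NN distance (the independent oracle for the
# statistical outlier filter).
brute_knn_meandist <- function(pts, k) {
  d <- as.matrix(dist(pts))
  diag(d) <- Inf
  unname(apply(d, 1, function(row) mean(sort(row)[seq_len(k)])))
}

# Brute-force greedy farthest-point sampling oracle.
brute_fps <- function(pts, m, start = 1L) {
  d <- as.matrix(dist(pts))
  picked <- start
  for (j in seq_len(m - 1L)) {
    mind <- apply(d[, picked, drop = FALSE], 1, min)
    mind[picked] <- -Inf
    picked <- c(picked, unname(which.max(mind)))
  }
  picked
}

# A tiny model configuration that keeps unit tests fast.
tiny_config <- function(n_points = 256L, ...) {
  model_config(n_points = n_points, channels = c(8L, 16L, 32L, 64L, 128L),
               k_group = 8L, ...)
}

# Small labelled training clouds at the network input size.
tiny_training_set <- function(n = 6L, n_points = 256L, seed = 5L) {
  lapply(seq_len(n), function(i) {
    b <- generate_seedling(scene_spec(points_total = 512L,
                                      seed = seed + i))
    prepare_clouds(list(b$cloud), n_points = n_points, seed = seed + i)[[1]]
  })
}
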