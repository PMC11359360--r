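#' Model configuration
#'
#' The architecture schedule of the hierarchical encoder/decoder. The four
#' set-abstraction stages each retain 25% of the points, so from the default
#' 4096 input points the point chain is 4096 -> 1024 -> 256 -> 64 -> 16 and
#' the channel chain is 64 -> 128 -> 256 -> 512 -> 1024 (the first entry is
#' the width of the per-point lifting perceptron). Decoder widths mirror the
#' encoder. `cra` and `pesa` are the ablation switches; with both off the
#' model is the plain single-scale set-abstraction baseline.
#'
#' @param n_points input cloud size; must be divisible by 256 (= 4^4).
#' @param channels length-5 channel schedule.
#' @param k_group neighbours per grouping ball.
#' @param radii length-4 ball radii per stage, in normalized units.
#' @param se_reduction squeeze-excitation and query/key reduction ratio.
#' @param cra enable the channel-residual attention perceptrons.
#' @param pesa enable position-enhanced self-attention after each stage.
#' @param decoder_channels length-4 feature-propagation output widths,
#'   coarsest first; defaults to the mirror of the encoder schedule.
#' @param head_dropout dropout probability on the final per-point features
#'   during training (0 disables).
#' @param num_classes output classes (2: other, stem).
#' @return a `model_config` list.
#' @export
model_config <- function(n_points = 4096L,
                         channels = c(64L, 128L, 256L, 512L, 1024L),
                         k_group = 32L,
                         radii = c(0.1, 0.2, 0.4, 0.8),
                         se_reduction = 4L,
                         cra = TRUE, pesa = TRUE,
                         decoder_channels = NULL,
                         head_dropout = 0,
                         num_classes = 2L) {
  n_points <- as.integer(n_points)
  if (length(channels) != 5L) stopf("channels must list 5 widths (4 stages + lift)")
  if (length(radii) != 4L) stopf("radii must list 4 ball radii")
  if (n_points %% 256L != 0L)
    stopf("n_points must be divisible by 256 (four 4x reductions), got %d",
          n_points)
  decoder_channels <- if (is.null(decoder_channels)) rev(channels[1:4])
                      else as.integer(decoder_channels)
  if (length(decoder_channels) != 4L)
    stopf("decoder_channels must list 4 widths (coarsest first)")
  if (any(c(channels, decoder_channels) %% se_reduction != 0L))
    stopf("all channel widths must be divisible by se_reduction")
  structure(list(n_points = n_points, channels = as.integer(channels),
                 k_group = as.integer(k_group), radii = radii,
                 se_reduction = as.integer(se_reduction),
                 cra = isTRUE(cra), pesa = isTRUE(pesa),
                 decoder_channels = decoder_channels,
                 head_dropout = head_dropout,
                 num_classes = as.integer(num_classes)),
            class = "model_config")
}

#' Point/channel schedule of a configuration
#'
#' @param config a [model_config()].
#' @return list with `points` (stage point counts, length 5) and `channels`.
#' @export
config_schedule <- function(config) {
  list(points = config$n_points %/% 4L^(0:4), channels = config$channels)
}

#' Farthest point sampling
#'
#' Greedy max-min subsampling: each new pick maximizes its minimum distance
#' to the points already chosen.
#'
#' @param coords N x 3 coordinate matrix.
#' @param m number of points to pick (<= N).
#' @param start_index 1-based index of the first pick.
#' @return integer vector of `m` unique 1-based indices; the first equals
#'   `start_index`.
#' @export
farthest_point_sample <- function(coords, m, start_index = 1L) {
  coords <- as.matrix(coords)
  if (m > nrow(coords)) stopf("m = %d exceeds %d points", m, nrow(coords))
  cpp_fps(coords, as.integer(m), as.integer(start_index))
}

#' Ball-query neighbourhood grouping
#'
#' For every centroid, up to `K` points within `radius`, nearest first; a
#' neighbourhood with fewer than `K` in-ball points is padded by repeating
#' its nearest member (the centroid itself when isolated, making all its
#' relative coordinates zero).
#'
#' @param coords N x 3 coordinate matrix.
#' @param centroid_indices 1-based centroid indices.
#' @param radius ball radius.
#' @param K neighbours per centroid.
#' @return list with `indices` (K x M matrix of 1-based point indices) and
#'   `relative` (3 x (M*K) matrix of neighbour-minus-centroid coordinates,
#'   the K columns of each centroid contiguous).
#' @export
group_neighbors <- function(coords, centroid_indices, radius, K) {
  coords <- as.matrix(coords)
  if (K < 1L) stopf("K must be >= 1")
  idx <- cpp_ball_group(coords, as.integer(centroid_indices), radius,
                        as.integer(K))
  flat <- as.vector(idx)
  centers <- t(coords[centroid_indices, , drop = FALSE])
  rel <- t(coords[flat, , drop = FALSE]) -
    centers[, rep(seq_along(centroid_indices), each = K), drop = FALSE]
  list(indices = idx, relative = rel)
}

#' Inverse-distance interpolation weights
#'
#' Three nearest coarse points per fine point with weights
#' `w_j = 1 / (d_j + eps)` normalized to sum 1.
#'
#' @param fine_coords n x 3 matrix of target coordinates.
#' @param coarse_coords m x 3 matrix of source coordinates.
#' @param eps distance offset guarding against division by zero.
#' @return list with `idx` (3 x n indices into the coarse set) and `w`
#'   (3 x n nonnegative weights, columns summing to 1).
#' @export
three_nn_weights <- function(fine_coords, coarse_coords, eps = 1e-8) {
  nn <- cpp_three_nn(as.matrix(fine_coords), as.matrix(coarse_coords))
  w <- 1 / (nn$dist + eps)
  w <- sweep(w, 2, colSums(w), `/`)
  list(idx = nn$idx, w = w)
}

#' Interpolate coarse features onto finer points
#'
#' @param coarse_features C x m feature matrix.
#' @param coarse_coords m x 3 coordinates of the features.
#' @param fine_coords n x 3 target coordinates.
#' @return C x n interpolated features (a convex combination of the three
#'   nearest coarse features per fine point).
#' @export
interpolate_features <- function(coarse_features, coarse_coords, fine_coords) {
  w <- three_nn_weights(fine_coords, coarse_coords)
  ag_reset()
  ag_interp(ag_const(as.matrix(coarse_features)), w$idx, w$w)$value
}

# --- stage construction ----------------------------------------------------

new_sa_stage <- function(c_in, c_out, radius, K, config) {
  stage <- new.env(parent = emptyenv())
  stage$block <- cra_mlp_module(c_in + 3L, c_out, config$se_reduction,
                                use_cra = config$cra)
  stage$pesa <- if (config$pesa) pesa_module(c_out, config$se_reduction)
  stage$radius <- radius
  stage$K <- K
  class(stage) <- "sa_stage"
  stage
}

new_fp_stage <- function(c_in, c_out, config) {
  stage <- new.env(parent = emptyenv())
  stage$block <- cra_mlp_module(c_in, c_out, config$se_reduction,
                                use_cra = config$cra)
  class(stage) <- "fp_stage"
  stage
}

#' Build a segmentation network
#'
#' Assembles the per-point lifting perceptron, four set-abstraction stages
#' (farthest-point sampling to 25% of the points, ball-query grouping,
#' shared CRA-MLP, max pooling, optional PESA on the stage output), four
#' feature-propagation stages with U-Net-style encoder skips, and the
#' per-point classification head. Weight initialization is seeded.
#'
#' @param config a [model_config()].
#' @param seed seed for weight initialization.
#' @return a `cphnet_model`.
#' @export
cphnet_new <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  ch <- config$channels
  with_seed(seed, {
    model <- new.env(parent = emptyenv())
    model$config <- config
    model$lift <- cra_mlp_module(3L, ch[1], config$se_reduction,
                                 use_cra = config$cra)
    model$sa <- lapply(1:4, function(s)
      new_sa_stage(ch[s], ch[s + 1], config$radii[s], config$k_group, config))
    # decoder j = 4..1: (incoming width + skip ch[j]) -> decoder width
    dec <- config$decoder_channels
    model$fp <- vector("list", 4L)
    incoming <- ch[5]
    for (j in 4:1) {
      model$fp[[j]] <- new_fp_stage(incoming + ch[j], dec[5L - j], config)
      incoming <- dec[5L - j]
    }
    model$head <- nn_linear(dec[4], config$num_classes)
    class(model) <- "cphnet_model"
    model
  })
}

#' @export
print.cphnet_model <- function(x, ...) {
  sch <- config_schedule(x$config)
  np <- sum(vapply(module_params(x), function(p) length(p$value), numeric(1)))
  cat(sprintf("<cphnet_model> points %s | channels %s | CRA %s | PESA %s | %.3f M parameters\n",
              paste(sch$points, collapse = "-"),
              paste(sch$channels, collapse = "-"),
              x$config$cra, x$config$pesa, np / 1e6))
  invisible(x)
}

# Forward of one set-abstraction stage on ag nodes.
sa_forward <- function(stage, x, coords, training) {
  n <- nrow(coords)
  if (n %% 4L != 0L) stopf("stage input of %d points is not divisible by 4", n)
  m <- n %/% 4L
  cidx <- cpp_fps(coords, m, 1L)
  grp <- group_neighbors(coords, cidx, stage$radius, stage$K)
  gathered <- ag_gather_cols(x, as.vector(grp$indices))
  h <- forward_cra(stage$block,
                   ag_concat_rows(gathered, ag_const(grp$relative)), training)
  pooled <- ag_group_maxpool(h, stage$K)
  ccoords <- coords[cidx, , drop = FALSE]
  if (!is.null(stage$pesa)) {
    pooled <- forward_pesa(stage$pesa, pooled, ag_const(t(ccoords)),
                           training)$out
  }
  list(features = pooled, coords = ccoords)
}

#' Run one set-abstraction stage
#'
#' Numeric wrapper around the encoder stage: centroids are selected by
#' farthest-point sampling (points / 4), neighbourhoods grouped within the
#' stage radius, relative coordinates concatenated to the gathered
#' features, the shared perceptron applied and max-pooled per group, and
#' (when the model enables it) PESA applied to the pooled features.
#'
#' @param features C x N numeric feature map.
#' @param coords N x 3 stage coordinates.
#' @param stage a stage from a [cphnet_new()] model (`model$sa[[s]]`).
#' @param training use batch statistics (TRUE) or running statistics.
#' @return list with `features` (C' x N/4) and `coords` (N/4 x 3).
#' @export
set_abstraction <- function(features, coords, stage, training = FALSE) {
  ag_reset()
  res <- sa_forward(stage, ag_const(as.matrix(features)), as.matrix(coords),
                    training)
  list(features = res$features$value, coords = res$coords)
}

fp_forward <- function(stage, coarse, coarse_coords, fine_coords, skip,
                       training) {
  w <- three_nn_weights(fine_coords, coarse_coords)
  interp <- ag_interp(coarse, w$idx, w$w)
  forward_cra(stage$block, ag_concat_rows(interp, skip), training)
}

#' Run one feature-propagation stage
#'
#' Inverse-distance interpolation of the coarse features onto the finer
#' point set, concatenation with the encoder skip features of matching
#' resolution, and the stage's pointwise perceptron.
#'
#' @param coarse_features C x m coarse feature map.
#' @param coarse_coords m x 3 coarse coordinates.
#' @param fine_coords n x 3 target coordinates.
#' @param skip_features C_skip x n encoder features at the fine resolution.
#' @param stage a stage from a [cphnet_new()] model (`model$fp[[j]]`).
#' @param training use batch statistics (TRUE) or running statistics.
#' @return C_out x n numeric feature map.
#' @export
feature_propagation <- function(coarse_features, coarse_coords, fine_coords,
                                skip_features, stage, training = FALSE) {
  ag_reset()
  fp_forward(stage, ag_const(as.matrix(coarse_features)),
             as.matrix(coarse_coords), as.matrix(fine_coords),
             ag_const(as.matrix(skip_features)), training)$value
}

# Full forward on one cloud; coords N x 3 (normalized). Returns the
# classes x N probability node (the tape stays live for backward).
cphnet_forward_node <- function(model, coords, training = FALSE) {
  cfg <- model$config
  if (nrow(coords) != cfg$n_points)
    stopf("cloud has %d points but the model expects %d; use resample_fixed()",
          nrow(coords), cfg$n_points)
  ag_reset()
  feats <- vector("list", 5L)
  crds <- vector("list", 5L)
  feats[[1]] <- forward_cra(model$lift, ag_const(t(coords)), training)
  crds[[1]] <- coords
  for (s in 1:4) {
    res <- sa_forward(model$sa[[s]], feats[[s]], crds[[s]], training)
    feats[[s + 1]] <- res$features
    crds[[s + 1]] <- res$coords
  }
  y <- feats[[5]]
  for (j in 4:1) {
    y <- fp_forward(model$fp[[j]], y, crds[[j + 1]], crds[[j]], feats[[j]],
                    training)
  }
  y <- ag_dropout(y, cfg$head_dropout, training)
  logits <- forward_linear(model$head, y)
  ag_colsoftmax(logits)
}

#' Per-point class probabilities
#'
#' Runs the network over one or more clouds in evaluation mode (running
#' batch-norm statistics; deterministic for fixed weights). Every cloud
#' must have exactly `config$n_points` points in normalized coordinates
#' (see [normalize_cloud()] and [resample_fixed()]).
#'
#' @param model a [cphnet_new()] model.
#' @param clouds a [labeled_cloud()], a list of them, or an N x 3 matrix.
#' @return batch x n_points x num_classes array of probabilities; each
#'   per-point row sums to 1.
#' @export
cphnet_forward <- function(model, clouds) {
  stopifnot(inherits(model, "cphnet_model"))
  if (inherits(clouds, "labeled_cloud")) clouds <- list(clouds)
  if (is.matrix(clouds)) clouds <- list(labeled_cloud(clouds))
  cfg <- model$config
  out <- array(NA_real_, c(length(clouds), cfg$n_points, cfg$num_classes))
  for (b in seq_along(clouds)) {
    cl <- clouds[[b]]
    coords <- if (inherits(cl, "labeled_cloud")) cl$points else as.matrix(cl)
    prob <- cphnet_forward_node(model, coords, training = FALSE)
    out[b, , ] <- t(prob$value)
  }
  out
}

#' Predicted labels for one cloud
#'
#' @param model a [cphnet_new()] model.
#' @param coords N x 3 normalized coordinates (N = `config$n_points`).
#' @return integer vector of 0/1 predicted labels.
#' @export
cphnet_predict <- function(model, coords) {
  prob <- cphnet_forward_node(model, as.matrix(coords), training = FALSE)
  max.col(t(prob$value)) - 1L
}
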