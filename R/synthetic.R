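#' Parametric description of a synthetic seedling scene
#'
#' The generator emulates the structure of scanned pumpkin-seedling scenes:
#' a curved stem (optionally branched) rising out of potting soil, drooping
#' leaves attached near the apex, primitive clutter (soil disk, pot shell,
#' wall and table planes), and uniform outlier noise. Coordinates are in a
#' z-up frame with the soil surface at z = 0 and stem lengths of roughly
#' 0.2-0.5 scene units.
#'
#' @param stem_length stem length in scene units.
#' @param stem_radius stem tube radius.
#' @param stem_curvature lateral amplitude of the cubic spine curve.
#' @param branches number of side branches (labelled stem as well).
#' @param leaf_count number of leaves.
#' @param leaf_radius major radius of the elliptical leaf patch.
#' @param leaf_droop droop angle of the leaves, degrees from horizontal.
#' @param soil_density,pot_density,wall_density,table_density relative
#'   point-density multipliers for the clutter surfaces; 0 switches a
#'   surface off.
#' @param outlier_rate fraction of points placed uniformly in the 1.5x
#'   inflated bounding box; must lie in \[0, 0.2\].
#' @param points_total number of points in the generated cloud (>= 256).
#' @param plants number of plants (>= 2 places non-overlapping pots).
#' @param seed integer seed; generation is bit-reproducible.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(stem_length = 0.3, stem_radius = 0.008,
                       stem_curvature = 0.05, branches = 0L,
                       leaf_count = 2L, leaf_radius = 0.08, leaf_droop = 50,
                       soil_density = 1, pot_density = 1,
                       wall_density = 0, table_density = 0,
                       outlier_rate = 0.02, points_total = 4096L,
                       plants = 1L, seed = 1L) {
  if (stem_length <= 0 || stem_radius <= 0)
    stopf("stem length and radius must be positive")
  if (outlier_rate < 0 || outlier_rate > 0.2)
    stopf("outlier_rate must lie in [0, 0.2]")
  if (points_total < 256L) stopf("points_total must be at least 256")
  dens <- c(soil_density, pot_density, wall_density, table_density)
  if (any(dens < 0)) stopf("densities must be nonnegative")
  if (plants < 1L) stopf("plants must be >= 1")
  structure(list(stem_length = stem_length, stem_radius = stem_radius,
                 stem_curvature = stem_curvature, branches = as.integer(branches),
                 leaf_count = as.integer(leaf_count), leaf_radius = leaf_radius,
                 leaf_droop = leaf_droop,
                 soil_density = soil_density, pot_density = pot_density,
                 wall_density = wall_density, table_density = table_density,
                 outlier_rate = outlier_rate,
                 points_total = as.integer(points_total),
                 plants = as.integer(plants), seed = as.integer(seed)),
            class = "scene_spec")
}

#' Scene presets
#'
#' Named parameter bundles covering the evaluation scenarios the method is
#' stressed against: `simple` (one plant, soil and pot), `branchy`
#' (multi-branch stem), `cluttered` (wall, table and extra outliers),
#' `two_plant` (two potted plants) and `early` (early-growth seedling whose
#' stem holds under 5\% of the points, the class-imbalance stressor).
#'
#' @param preset preset name.
#' @param ... overrides passed to [scene_spec()].
#' @return a `scene_spec`.
#' @export
scene_preset <- function(preset = c("simple", "branchy", "cluttered",
                                    "two_plant", "early"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    simple = list(),
    branchy = list(branches = 2L, leaf_count = 4L, stem_curvature = 0.08),
    cluttered = list(wall_density = 1, table_density = 1, outlier_rate = 0.05),
    two_plant = list(plants = 2L),
    early = list(stem_length = 0.12, stem_radius = 0.004, leaf_count = 2L,
                 leaf_radius = 0.1, stem_curvature = 0.02))
  do.call(scene_spec, utils::modifyList(args, list(...)))
}

# --- surface samplers ------------------------------------------------------

# Cubic spine of one stem: returns a function t in [0,1] -> 3D point, plus
# the apex. Lateral offsets are cubic polynomials scaled by the curvature
# amplitude; the base sits below the soil surface when soil is present so
# the soil/stem boundary is ambiguous, as in real pot scans.
make_spine <- function(spec, base) {
  cx <- spec$stem_curvature * (runif(2, -1, 1))
  cy <- spec$stem_curvature * (runif(2, -1, 1))
  L <- spec$stem_length
  z0 <- base[3]
  function(t) {
    cbind(base[1] + cx[1] * t^2 + cx[2] * t^3,
          base[2] + cy[1] * t^2 + cy[2] * t^3,
          z0 + L * t)
  }
}

sample_tube <- function(n, spine, radius) {
  if (n <= 0) return(matrix(numeric(0), 0, 3))
  t <- runif(n)
  phi <- runif(n, 0, 2 * pi)
  r <- radius * sqrt(runif(n))  # fill the tube, denser shell near surface
  p <- spine(t)
  p[, 1] <- p[, 1] + r * cos(phi)
  p[, 2] <- p[, 2] + r * sin(phi)
  p
}

sample_leaf <- function(n, attach, droop_deg, azimuth, radius) {
  if (n <= 0) return(matrix(numeric(0), 0, 3))
  # uniform sample of an ellipse (major radius, minor 0.6x), drooped about
  # the horizontal axis and swung to the azimuth, petiole at the attach point
  u <- sqrt(runif(n))
  v <- runif(n, 0, 2 * pi)
  ex <- radius * u * cos(v) + radius  # shift so the leaf extends outward
  ey <- 0.6 * radius * u * sin(v)
  droop <- droop_deg * pi / 180
  x1 <- ex * cos(droop)
  z1 <- -ex * sin(droop)
  rot <- cbind(x1 * cos(azimuth) - ey * sin(azimuth),
               x1 * sin(azimuth) + ey * cos(azimuth),
               z1)
  sweep(rot, 2, attach, `+`) + matrix(rnorm(3 * n, sd = 0.002), n, 3)
}

sample_disk <- function(n, center, radius, jitter = 0.002) {
  if (n <= 0) return(matrix(numeric(0), 0, 3))
  r <- radius * sqrt(runif(n))
  phi <- runif(n, 0, 2 * pi)
  cbind(center[1] + r * cos(phi), center[2] + r * sin(phi),
        center[3] + rnorm(n, sd = jitter))
}

sample_cylinder_shell <- function(n, center, radius, z0, z1) {
  if (n <= 0) return(matrix(numeric(0), 0, 3))
  phi <- runif(n, 0, 2 * pi)
  z <- runif(n, z0, z1)
  cbind(center[1] + radius * cos(phi), center[2] + radius * sin(phi), z)
}

sample_plane_patch <- function(n, origin, e1, e2, w1, w2) {
  if (n <= 0) return(matrix(numeric(0), 0, 3))
  a <- runif(n, 0, w1)
  b <- runif(n, 0, w2)
  sweep(outer(a, e1) + outer(b, e2), 2, origin, `+`) +
    matrix(rnorm(3 * n, sd = 0.002), n, 3)
}

# Allocate n points over surfaces proportionally to area x density, exact
# total by largest remainder.
allocate_counts <- function(n, weights) {
  if (sum(weights) <= 0) stopf("no surface has positive density")
  raw <- n * weights / sum(weights)
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

pot_radius <- function(spec) max(0.1, 1.3 * spec$leaf_radius)

# Build the per-surface sampler table for one scene. Each element:
# list(name, label, weight, fun(n) -> n x 3 matrix).
scene_surfaces <- function(spec, with_clutter) {
  prad <- pot_radius(spec)
  pot_depth <- 0.08
  offsets <- if (spec$plants == 1L) {
    matrix(c(0, 0), 1, 2)
  } else {
    # non-overlapping pots on a line, spaced by 2.4 pot radii
    cbind((seq_len(spec$plants) - (spec$plants + 1) / 2) * 2.4 * prad, 0)
  }
  surf <- list()
  soil_on <- with_clutter && spec$soil_density > 0
  for (p in seq_len(spec$plants)) {
    base <- c(offsets[p, 1], offsets[p, 2],
              if (soil_on) -0.1 * spec$stem_length else 0)
    spine <- make_spine(spec, base)
    apex <- drop(spine(1))
    stem_area <- 2 * pi * spec$stem_radius * spec$stem_length
    surf[[length(surf) + 1]] <- list(
      name = "stem", label = 1L, weight = stem_area,
      fun = local({
        sp <- spine; r <- spec$stem_radius
        function(n) sample_tube(n, sp, r)
      }))
    if (spec$branches > 0L) {
      for (b in seq_len(spec$branches)) {
        t0 <- runif(1, 0.35, 0.8)
        az <- runif(1, 0, 2 * pi)
        babs <- drop(spine(t0))
        blen <- 0.45 * spec$stem_length
        brad <- 0.7 * spec$stem_radius
        bdir <- c(cos(az) * 0.7, sin(az) * 0.7, 0.7)
        bspine <- local({
          b0 <- babs; d <- bdir * blen
          function(t) cbind(b0[1] + d[1] * t, b0[2] + d[2] * t, b0[3] + d[3] * t)
        })
        surf[[length(surf) + 1]] <- list(
          name = "stem", label = 1L, weight = 2 * pi * brad * blen,
          fun = local({
            sp <- bspine; r <- brad
            function(n) sample_tube(n, sp, r)
          }))
      }
    }
    if (spec$leaf_count > 0L) {
      leaf_area <- pi * spec$leaf_radius * 0.6 * spec$leaf_radius
      for (l in seq_len(spec$leaf_count)) {
        az <- 2 * pi * (l - 1) / spec$leaf_count + runif(1, -0.3, 0.3)
        attach <- apex - c(0, 0, runif(1, 0, 0.1 * spec$stem_length))
        surf[[length(surf) + 1]] <- list(
          name = "leaf", label = 0L, weight = leaf_area,
          fun = local({
            at <- attach; dr <- spec$leaf_droop; a <- az; rad <- spec$leaf_radius
            function(n) sample_leaf(n, at, dr, a, rad)
          }))
      }
    }
    if (with_clutter && spec$soil_density > 0) {
      surf[[length(surf) + 1]] <- list(
        name = "soil", label = 0L,
        weight = spec$soil_density * pi * prad^2,
        fun = local({
          ctr <- c(base[1], base[2], 0); r <- prad
          function(n) sample_disk(n, ctr, r)
        }))
    }
    if (with_clutter && spec$pot_density > 0) {
      surf[[length(surf) + 1]] <- list(
        name = "pot", label = 0L,
        weight = spec$pot_density * 2 * pi * prad * pot_depth,
        fun = local({
          ctr <- base; r <- 1.1 * prad; d <- pot_depth
          function(n) sample_cylinder_shell(n, ctr, r, -d, 0)
        }))
    }
  }
  span <- max(2 * spec$stem_length, 0.5)
  if (with_clutter && spec$wall_density > 0) {
    surf[[length(surf) + 1]] <- list(
      name = "wall", label = 0L, weight = spec$wall_density * span^2,
      fun = local({
        s <- span
        function(n) sample_plane_patch(n, c(-0.6 * s, -s / 2, -0.1), c(0, 1, 0),
                                       c(0, 0, 1), s, s)
      }))
  }
  if (with_clutter && spec$table_density > 0) {
    surf[[length(surf) + 1]] <- list(
      name = "table", label = 0L, weight = spec$table_density * span^2,
      fun = local({
        s <- span
        function(n) sample_plane_patch(n, c(-s / 2, -s / 2, -0.1), c(1, 0, 0),
                                       c(0, 1, 0), s, s)
      }))
  }
  surf
}

generate_bundle <- function(spec, with_clutter) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    n_out <- if (with_clutter) round(spec$outlier_rate * spec$points_total) else 0L
    n_surf <- spec$points_total - n_out
    surf <- scene_surfaces(spec, with_clutter)
    counts <- allocate_counts(n_surf, vapply(surf, `[[`, numeric(1), "weight"))
    pts <- vector("list", length(surf))
    for (i in seq_along(surf)) pts[[i]] <- surf[[i]]$fun(counts[i])
    points <- do.call(rbind, pts)
    labels <- rep.int(vapply(surf, `[[`, integer(1), "label"), counts)
    names_per_point <- rep.int(vapply(surf, `[[`, character(1), "name"), counts)
    if (n_out > 0L) {
      lo <- apply(points, 2, min)
      hi <- apply(points, 2, max)
      mid <- (lo + hi) / 2
      half <- pmax((hi - lo) / 2 * 1.5, 1e-3)
      out_pts <- sapply(1:3, function(d) runif(n_out, mid[d] - half[d], mid[d] + half[d]))
      if (n_out == 1L) out_pts <- matrix(out_pts, 1, 3)
      points <- rbind(points, out_pts)
      labels <- c(labels, rep.int(0L, n_out))
      names_per_point <- c(names_per_point, rep.int("outlier", n_out))
    }
    masks <- split(seq_len(nrow(points)), names_per_point)
    cloud <- labeled_cloud(points, labels,
                           origin_id = sprintf("scene_seed%d", spec$seed))
    structure(list(cloud = cloud, spec = spec, truth_masks = masks),
              class = "scene_bundle")
  })
}

#' Generate a synthetic seedling (plant only)
#'
#' Samples points on the curved stem tube (label 1) and the drooping leaf
#' patches (label 0) without any clutter or outliers. Deterministic under
#' the scene spec's seed.
#'
#' @param spec a [scene_spec()].
#' @return a `scene_bundle`: list with `cloud` ([labeled_cloud()]), `spec`
#'   and `truth_masks`, named index sets partitioning the points.
#' @export
generate_seedling <- function(spec) generate_bundle(spec, with_clutter = FALSE)

#' Generate a full synthetic scene
#'
#' As [generate_seedling()] plus soil, pot, wall and table clutter (label 0)
#' at the scene spec's densities and a fraction `outlier_rate` of uniform outlier
#' points in the 1.5x inflated bounding box. With `plants >= 2`,
#' non-overlapping potted plants are placed side by side.
#'
#' @param spec a [scene_spec()].
#' @return a `scene_bundle`.
#' @export
generate_scene <- function(spec) generate_bundle(spec, with_clutter = TRUE)

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("<scene_bundle> %d points; masks: %s\n", n_points(x$cloud),
              paste(sprintf("%s=%d", names(x$truth_masks),
                            lengths(x$truth_masks)), collapse = ", ")))
  invisible(x)
}

#' Default scene sampler
#'
#' Draws a preset uniformly from the five scenarios of [scene_preset()] and
#' perturbs the morphology parameters, so a sampled dataset spans
#' multi-branch, multi-pot, noisy and two-plant scenes.
#'
#' @param seed seed for the sampled spec (also stored in it).
#' @param points_total points per scene.
#' @return a `scene_spec`.
#' @export
default_spec_sampler <- function(seed, points_total = 4096L) {
  with_seed(derive_seed(seed, 17L), {
    preset <- sample(c("simple", "branchy", "cluttered", "two_plant", "early"), 1)
    scene_preset(preset,
                 stem_length = runif(1, 0.8, 1.2) *
                   if (preset == "early") 0.12 else 0.3,
                 stem_radius = runif(1, 0.8, 1.2) *
                   if (preset == "early") 0.004 else 0.008,
                 leaf_droop = runif(1, 35, 65),
                 outlier_rate = if (preset == "cluttered") 0.05 else
                   runif(1, 0, 0.03),
                 points_total = points_total,
                 seed = seed)
  })
}

#' Generate a dataset of synthetic scenes
#'
#' Writes `n_origins` scenes (variant `"original"`) as labelled PLY files
#' plus a manifest table. Scene specs come from `spec_sampler(seed_i)`,
#' where per-scene seeds derive deterministically from `seed`.
#'
#' @param n_origins number of scenes.
#' @param out_dir output directory (created if missing).
#' @param spec_sampler function(seed) returning a [scene_spec()].
#' @param seed master seed.
#' @param points_total points per scene, passed to the default sampler.
#' @return the [dataset_manifest()], invisibly written to
#'   `file.path(out_dir, "manifest.tsv")`.
#' @export
generate_dataset <- function(n_origins, out_dir,
                             spec_sampler = default_spec_sampler,
                             seed = 1L, points_total = 4096L) {
  if (n_origins < 1L) stopf("n_origins must be >= 1")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(n_origins)
  ids <- sprintf("scene_%04d", seq_len(n_origins))
  for (i in seq_len(n_origins)) {
    sd_i <- derive_seed(seed, i)
    spec <- if (identical(spec_sampler, default_spec_sampler)) {
      spec_sampler(sd_i, points_total = points_total)
    } else {
      spec_sampler(sd_i)
    }
    bundle <- generate_scene(spec)
    bundle$cloud$origin_id <- ids[i]
    paths[i] <- file.path(out_dir, paste0(ids[i], ".ply"))
    write_cloud(bundle$cloud, paths[i], format = "ply")
  }
  manifest <- dataset_manifest(paths, ids, rep("original", n_origins))
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  manifest
}
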