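#' Desk-scale synthetic benchmark
#'
#' The package's end-to-end study at desk scale: generate labelled
#' synthetic seedling scenes spanning the simple / branchy / cluttered /
#' two-plant / early-growth scenarios, split 4:1 grouped by scene, train
#' the full network (CRA-MLP + PESA + hybrid CE/Dice loss) at reduced
#' widths, and evaluate on the held-out scenes. With `with_baseline = TRUE`
#' the attention-free baseline (plain perceptrons, cross-entropy loss) is
#' trained identically for the ablation direction check.
#'
#' @param seed master seed for generation, splitting and training.
#' @param n_origins number of generated scenes.
#' @param n_points network input size.
#' @param epochs training epochs.
#' @param channels reduced channel schedule.
#' @param decoder_channels decoder widths (kept wider than the encoder
#'   mirror so per-point discrimination at full resolution does not
#'   bottleneck at the narrow end of the reduced schedule).
#' @param k_group neighbours per grouping ball.
#' @param sor apply statistical outlier removal during preparation; off by
#'   default so the generated outlier noise is part of the benchmark's
#'   stress conditions.
#' @param out_dir where generated scenes are written.
#' @param verbose per-epoch progress.
#' @return list with `full` and (optionally) `baseline` evaluation results
#'   (each with `report`, `loss`, `counts`), the two `cphnet_fit`s, and the
#'   split sizes.
#' @export
synthetic_benchmark <- function(seed = 1L, n_origins = 120L,
                                n_points = 1024L, epochs = 30L,
                                channels = c(16L, 32L, 64L, 128L, 256L),
                                decoder_channels = c(128L, 96L, 64L, 64L),
                                k_group = 16L, sor = FALSE,
                                out_dir = file.path(tempdir(), "cphnet_bench"),
                                verbose = FALSE, with_baseline = TRUE) {
  manifest <- generate_dataset(n_origins, out_dir, seed = seed,
                               points_total = 2L * n_points)
  split <- split_grouped(manifest, "4:1", seed = derive_seed(seed, 1L))
  tr <- prepare_clouds(split$train, n_points, seed = derive_seed(seed, 2L),
                       sor = sor)
  te <- prepare_clouds(split$test, n_points, seed = derive_seed(seed, 3L),
                       sor = sor)
  mk_cfg <- function(cra, pesa) {
    model_config(n_points = n_points, channels = channels, k_group = k_group,
                 cra = cra, pesa = pesa, decoder_channels = decoder_channels)
  }
  tr_seed <- derive_seed(seed, 4L)
  # one cloud per optimizer step and a higher peak rate than the full-scale
  # defaults: at desk scale (tens of scenes, tens of epochs) the update
  # count, not the data volume, limits convergence
  mk_tr <- function(loss) {
    train_config(batch_size = 1L, lr_init = 5e-3, epochs = epochs,
                 seed = tr_seed, loss = loss, val_every = 5L)
  }
  full_fit <- train(tr, mk_cfg(TRUE, TRUE), mk_tr("hce"),
                    loss_config(), val_data = te, verbose = verbose)
  full_ev <- evaluate_model(full_fit$model, te, "hce", loss_config())
  out <- list(full = full_ev, full_fit = full_fit,
              n_train = length(tr), n_test = length(te))
  if (with_baseline) {
    base_fit <- train(tr, mk_cfg(FALSE, FALSE), mk_tr("ce"),
                      loss_config(), val_data = te, verbose = verbose)
    out$baseline <- evaluate_model(base_fit$model, te, "ce", loss_config())
    out$baseline_fit <- base_fit
  }
  out
}

#' Segment a cloud with a trained model
#'
#' Reads a cloud of any size, normalizes and resamples it to the model's
#' input size, predicts per-point labels, maps them back to the original
#' resolution through the nearest resampled point, and optionally writes a
#' green/blue colorized PLY.
#'
#' @param fit a `cphnet_fit` or a checkpoint path.
#' @param cloud a [labeled_cloud()] or a file path.
#' @param out_path optional output PLY (colorized).
#' @param seed resampling seed.
#' @return the input cloud with predicted labels (all original points).
#' @export
segment_cloud <- function(fit, cloud, out_path = NULL, seed = 1L) {
  if (is.character(fit)) fit <- load_checkpoint(fit)
  model <- if (inherits(fit, "cphnet_model")) fit else fit$model
  if (is.character(cloud)) cloud <- read_cloud(cloud)
  norm <- normalize_cloud(cloud)
  rs <- resample_fixed(norm$cloud, model$config$n_points, seed = seed)
  pred <- cphnet_predict(model, rs$points)
  back <- cpp_nearest(norm$cloud$points, rs$points)
  out <- labeled_cloud(cloud$points, pred[back], origin_id = cloud$origin_id,
                       variant = cloud$variant)
  if (!is.null(out_path)) write_cloud(out, out_path, format = "ply",
                                      colorize = TRUE)
  out
}

#' Run configuration
#'
#' Reads (or defaults) the nested configuration driving [run_pipeline()]:
#' sections `scene` (generator), `filter`, `augment`, `split`, `model`,
#' `train`, `loss` and `output`.
#'
#' @param path YAML file; `NULL` gives the defaults.
#' @param overrides named list merged over the file values.
#' @return a validated `run_config` list.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    scene = list(n_origins = 20L, points_total = 2048L),
    filter = list(enabled = FALSE, k_neighbors = 16L, std_ratio = 2.0),
    augment = list(enabled = TRUE, jitter_sigma = 0.01, jitter_clip = 0.05,
                   noise_sigma = 0.02),
    split = list(ratio = "4:1"),
    model = list(n_points = 1024L, channels = c(16L, 32L, 64L, 128L, 256L),
                 k_group = 16L, cra = TRUE, pesa = TRUE),
    train = list(batch_size = 6L, lr_init = 1e-3, lr_min = 1e-5,
                 epochs = 10L, momentum = 0.9, loss = "hce", folds = 5L),
    loss = list(weight_ce = 0.5, weight_dice = 0.5, epsilon = 1e-5),
    seed = 1L,
    output = list(dir = "cphnet_run"))
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  cfg <- utils::modifyList(cfg, overrides)
  # schema check before any stage runs
  mcfg <- do.call(model_config, cfg$model)
  tcfg <- do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  lcfg <- do.call(loss_config, cfg$loss)
  structure(list(raw = cfg, model_cfg = mcfg, tr_cfg = tcfg,
                 loss_cfg = lcfg), class = "run_config")
}

#' Run the full pipeline
#'
#' generate -> (filter) -> augment -> split -> train -> evaluate, writing
#' every artifact (clouds, manifests, checkpoint, metrics) under the
#' configured output directory. Rerunning with the same configuration and
#' seed reproduces the same manifests and counts.
#'
#' @param config a [run_config()] (or a YAML path passed to it).
#' @return list with the manifests, split sizes, the `cphnet_fit` and the
#'   held-out [metric_report()].
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- run_config(config)
  cfg <- config$raw
  out_dir <- cfg$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scenes_dir <- file.path(out_dir, "scenes")
  manifest <- generate_dataset(cfg$scene$n_origins, scenes_dir,
                               seed = cfg$seed,
                               points_total = cfg$scene$points_total)
  if (isTRUE(cfg$filter$enabled)) {
    for (i in seq_len(nrow(manifest))) {
      cl <- read_cloud(manifest$path[i], origin_id = manifest$origin_id[i])
      kept <- statistical_outlier_removal(cl, cfg$filter$k_neighbors,
                                          cfg$filter$std_ratio)$kept
      write_cloud(kept, manifest$path[i])
    }
  }
  if (isTRUE(cfg$augment$enabled)) {
    ap <- augment_params(cfg$augment$jitter_sigma, cfg$augment$jitter_clip,
                         cfg$augment$noise_sigma, seed = cfg$seed)
    manifest <- build_augmented(manifest, ap)
    write_manifest(manifest, file.path(out_dir, "manifest_augmented.tsv"))
  }
  split <- split_grouped(manifest, cfg$split$ratio,
                         seed = derive_seed(cfg$seed, 1L))
  write_manifest(dataset_manifest(c(split$train$path, split$test$path),
                                  c(split$train$origin_id, split$test$origin_id),
                                  c(split$train$variant, split$test$variant),
                                  c(split$train$split, split$test$split)),
                 file.path(out_dir, "manifest_split.tsv"))
  tr <- prepare_clouds(split$train, config$model_cfg$n_points,
                       seed = derive_seed(cfg$seed, 2L))
  te <- prepare_clouds(split$test, config$model_cfg$n_points,
                       seed = derive_seed(cfg$seed, 3L))
  fit <- train(tr, config$model_cfg, config$tr_cfg, config$loss_cfg,
               val_data = te)
  save_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))
  ev <- evaluate_model(fit$model, te, config$tr_cfg$loss, config$loss_cfg)
  metrics <- data.frame(mIoU = ev$report$miou, mP = ev$report$mp,
                        mR = ev$report$mr, mF1 = ev$report$mf1,
                        speed = ev$report$speed)
  write.table(metrics, file.path(out_dir, "metrics.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  list(manifest = manifest, n_train = nrow(split$train),
       n_test = nrow(split$test), fit = fit, report = ev$report,
       out_dir = out_dir)
}
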