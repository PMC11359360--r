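#' Training configuration
#'
#' Defaults follow the experimental settings: batch size 6, Adam with
#' first-moment coefficient 0.9, initial learning rate 1e-3 decaying to
#' 1e-5 over 150 epochs, 5 folds for cross-validation.
#'
#' @param batch_size clouds per optimizer step.
#' @param lr_init,lr_min maximum and minimum learning rates.
#' @param epochs training epochs.
#' @param momentum Adam first-moment decay coefficient.
#' @param seed training seed (shuffles, point permutations).
#' @param folds folds for [cross_validate()].
#' @param loss `"ce"`, `"dice"` or `"hce"`.
#' @param val_every evaluate the validation set every this many epochs
#'   (the final epoch is always evaluated).
#' @param rotate_each_epoch apply a fresh random vertical-axis rotation to
#'   every training cloud each epoch (on-the-fly augmentation; off by
#'   default, where augmentation is expected to come from the offline
#'   [build_augmented()] pipeline).
#' @param resample_each_epoch when training clouds carry more points than
#'   the network input size, draw a fresh uniform subset every epoch
#'   instead of fixing one subsample up front.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 6L, lr_init = 1e-3, lr_min = 1e-5,
                         epochs = 150L, momentum = 0.9, seed = 1L,
                         folds = 5L, loss = c("hce", "ce", "dice"),
                         val_every = 1L, rotate_each_epoch = FALSE,
                         resample_each_epoch = FALSE) {
  if (lr_min > lr_init) stopf("lr_min must not exceed lr_init")
  if (epochs < 1L) stopf("epochs must be >= 1")
  if (batch_size < 1L) stopf("batch_size must be >= 1")
  structure(list(batch_size = as.integer(batch_size), lr_init = lr_init,
                 lr_min = lr_min, epochs = as.integer(epochs),
                 momentum = momentum, seed = as.integer(seed),
                 folds = as.integer(folds), loss = match.arg(loss),
                 val_every = as.integer(val_every),
                 rotate_each_epoch = isTRUE(rotate_each_epoch),
                 resample_each_epoch = isTRUE(resample_each_epoch)),
            class = "train_config")
}

#' Cosine learning-rate schedule
#'
#' Decays from `lr_init` at epoch 0 to `lr_min` at the final epoch along a
#' half cosine; monotone non-increasing.
#'
#' @param epoch 0-based epoch index.
#' @param config a [train_config()].
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, config) {
  n <- config$epochs
  if (epoch < 0 || epoch >= n) stopf("epoch must lie in [0, %d)", n)
  if (n == 1L) return(config$lr_init)
  frac <- epoch / (n - 1)
  config$lr_min + 0.5 * (config$lr_init - config$lr_min) * (1 + cos(pi * frac))
}

adam_step <- function(params, lr, beta1, t, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$m)) {
      p$m <- g * 0
      p$v <- g * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * g
    p$v <- beta2 * p$v + (1 - beta2) * g * g
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    p$grad <- NULL
  }
}

#' Prepare clouds for the network
#'
#' Reads every manifest entry (or takes clouds directly), optionally
#' applies statistical outlier removal, normalizes to the unit sphere and
#' resamples to the network input size.
#'
#' @param x a [dataset_manifest()] (or split side) or list of
#'   [labeled_cloud()] objects.
#' @param n_points network input size.
#' @param seed resampling seed.
#' @param sor apply [statistical_outlier_removal()] first.
#' @return list of normalized, fixed-size [labeled_cloud()]s.
#' @export
prepare_clouds <- function(x, n_points = 4096L, seed = 1L, sor = FALSE) {
  clouds <- if (inherits(x, "dataset_manifest") || is.data.frame(x)) {
    lapply(seq_len(nrow(x)), function(i)
      read_cloud(x$path[i], origin_id = x$origin_id[i], variant = x$variant[i]))
  } else if (inherits(x, "labeled_cloud")) list(x) else x
  lapply(seq_along(clouds), function(i) {
    cl <- clouds[[i]]
    if (sor) cl <- statistical_outlier_removal(cl)$kept
    cl <- normalize_cloud(cl)$cloud
    resample_fixed(cl, n_points, seed = derive_seed(seed, i))
  })
}

#' Train a segmentation network
#'
#' Seeded training loop: per epoch the cloud order and each cloud's point
#' order are reshuffled, clouds are processed in batches with gradients
#' averaged per batch, and Adam updates the weights under the cosine
#' learning-rate schedule. Histories are reproducible for a fixed seed.
#'
#' @param train_data list of prepared [labeled_cloud()]s (see
#'   [prepare_clouds()]); must contain both classes.
#' @param model_cfg a [model_config()].
#' @param tr_cfg a [train_config()].
#' @param loss_cfg a [loss_config()].
#' @param val_data optional validation clouds for the per-epoch metrics.
#' @param verbose print one line per epoch.
#' @return a `cphnet_fit` list with `model`, `history` (data frame with
#'   epoch, lr, train_loss, val_loss, val_miou) and the configs.
#' @export
train <- function(train_data, model_cfg = model_config(),
                  tr_cfg = train_config(), loss_cfg = loss_config(),
                  val_data = NULL, verbose = FALSE) {
  labs <- unlist(lapply(train_data, `[[`, "labels"))
  if (is.null(labs)) stopf("training clouds must be labelled")
  if (length(unique(labs)) < 2L)
    stopf("training data contains a single class; cannot train a segmenter")
  model <- cphnet_new(model_cfg, seed = tr_cfg$seed)
  params <- module_params(model)
  n <- length(train_data)
  history <- data.frame(epoch = seq_len(tr_cfg$epochs) - 1L, lr = NA_real_,
                        train_loss = NA_real_, val_loss = NA_real_,
                        val_miou = NA_real_)
  t_step <- 0L
  with_seed(tr_cfg$seed, {
    for (epoch in seq_len(tr_cfg$epochs) - 1L) {
      lr <- lr_schedule(epoch, tr_cfg)
      order <- sample.int(n)
      losses <- numeric(0)
      b <- 1L
      while (b <= n) {
        batch <- order[b:min(b + tr_cfg$batch_size - 1L, n)]
        for (i in batch) {
          cl <- train_data[[i]]
          np <- model_cfg$n_points
          perm <- if (tr_cfg$resample_each_epoch && nrow(cl$points) > np) {
            sample.int(nrow(cl$points), np)
          } else {
            sample.int(nrow(cl$points))
          }
          pts <- cl$points[perm, , drop = FALSE]
          if (tr_cfg$rotate_each_epoch) {
            theta <- runif(1, 0, 2 * pi)
            rot <- matrix(c(cos(theta), sin(theta), 0,
                            -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
            pts <- pts %*% rot
          }
          prob <- cphnet_forward_node(model, pts, training = TRUE)
          loss <- ag_loss(prob, cl$labels[perm] + 1L, tr_cfg$loss, loss_cfg)
          losses <- c(losses, loss$value)
          ag_backward(ag_scale(loss, 1 / length(batch)))
        }
        t_step <- t_step + 1L
        adam_step(params, lr, tr_cfg$momentum, t_step)
        b <- b + tr_cfg$batch_size
      }
      history$lr[epoch + 1L] <- lr
      history$train_loss[epoch + 1L] <- mean(losses)
      if (!is.null(val_data) &&
          (epoch %% tr_cfg$val_every == 0L || epoch == tr_cfg$epochs - 1L)) {
        ev <- evaluate_model(model, val_data, tr_cfg$loss, loss_cfg)
        history$val_loss[epoch + 1L] <- ev$loss
        history$val_miou[epoch + 1L] <- ev$report$miou
      }
      if (verbose)
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  val mIoU %s",
                        epoch, lr, history$train_loss[epoch + 1L],
                        history$val_loss[epoch + 1L],
                        ifelse(is.na(history$val_miou[epoch + 1L]), "-",
                               sprintf("%.1f%%", history$val_miou[epoch + 1L]))))
    }
  })
  structure(list(model = model, history = history, model_cfg = model_cfg,
                 tr_cfg = tr_cfg, loss_cfg = loss_cfg),
            class = "cphnet_fit")
}

#' Evaluate a model on labelled clouds
#'
#' Runs the network in evaluation mode, accumulates dataset-global
#' confusion counts and reports the class-averaged metrics plus the mean
#' loss and inference speed.
#'
#' @param model a [cphnet_new()] model.
#' @param clouds list of prepared labelled clouds.
#' @param loss_name,loss_cfg loss reported alongside the metrics.
#' @return list with `report` ([metric_report()]), `loss` and `counts`.
#' @export
evaluate_model <- function(model, clouds, loss_name = "hce",
                           loss_cfg = loss_config()) {
  counts <- NULL
  losses <- numeric(length(clouds))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_along(clouds)) {
    cl <- clouds[[i]]
    prob <- cphnet_forward_node(model, cl$points, training = FALSE)
    losses[i] <- ag_loss(prob, cl$labels + 1L, loss_name, loss_cfg)$value
    pred <- max.col(t(prob$value)) - 1L
    cc <- confusion(pred, cl$labels, model$config$num_classes)
    counts <- if (is.null(counts)) cc else add_counts(counts, cc)
  }
  elapsed <- max(proc.time()[["elapsed"]] - t0, 1e-9)
  list(report = metric_report(counts, elapsed, length(clouds)),
       loss = mean(losses), counts = counts)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration, all parameter values, the
#' batch-norm running statistics and the training history; loading rebuilds
#' the model and restores them, reproducing evaluation results exactly.
#'
#' @param fit a `cphnet_fit` (or a bare model) to save.
#' @param path checkpoint file.
#' @return `load_checkpoint`: a `cphnet_fit` with the restored model.
#' @export
save_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "cphnet_model")) fit else fit$model
  state <- list(
    config = model$config,
    params = lapply(module_params(model), `[[`, "value"),
    bn = lapply(module_bn_stats(model), function(b)
      list(mean = b$running_mean, var = b$running_var)),
    history = if (inherits(fit, "cphnet_fit")) fit$history,
    tr_cfg = if (inherits(fit, "cphnet_fit")) fit$tr_cfg,
    loss_cfg = if (inherits(fit, "cphnet_fit")) fit$loss_cfg)
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  model <- cphnet_new(state$config, seed = 1L)
  params <- module_params(model)
  stopifnot(length(params) == length(state$params))
  for (i in seq_along(params)) params[[i]]$value <- state$params[[i]]
  bns <- module_bn_stats(model)
  stopifnot(length(bns) == length(state$bn))
  for (i in seq_along(bns)) {
    bns[[i]]$running_mean <- state$bn[[i]]$mean
    bns[[i]]$running_var <- state$bn[[i]]$var
  }
  structure(list(model = model, history = state$history,
                 model_cfg = state$config, tr_cfg = state$tr_cfg,
                 loss_cfg = state$loss_cfg),
            class = "cphnet_fit")
}

#' Grouped k-fold cross-validation
#'
#' Folds come from [kfold_grouped()] so augmentation variants of one
#' specimen never straddle a fold boundary; every origin is validated
#' exactly once. Reports per-fold metrics and their mean.
#'
#' @param manifest a [dataset_manifest()] whose files exist on disk.
#' @param model_cfg,tr_cfg,loss_cfg configurations (see [train()]);
#'   `tr_cfg$folds` sets k.
#' @param sor apply statistical outlier removal during preparation.
#' @return list with `fits` (per-fold `cphnet_fit`s), `fold_reports`,
#'   `mean_metrics` and `pooled_report` (metrics of the summed counts).
#' @export
cross_validate <- function(manifest, model_cfg = model_config(),
                           tr_cfg = train_config(), loss_cfg = loss_config(),
                           sor = FALSE) {
  folds <- kfold_grouped(manifest, tr_cfg$folds, seed = tr_cfg$seed)
  fits <- vector("list", length(folds))
  reports <- vector("list", length(folds))
  pooled <- NULL
  for (f in seq_along(folds)) {
    tr <- prepare_clouds(folds[[f]]$train, model_cfg$n_points,
                         seed = derive_seed(tr_cfg$seed, f), sor = sor)
    va <- prepare_clouds(folds[[f]]$test, model_cfg$n_points,
                         seed = derive_seed(tr_cfg$seed, 100L + f), sor = sor)
    fits[[f]] <- train(tr, model_cfg, tr_cfg, loss_cfg, val_data = va)
    ev <- evaluate_model(fits[[f]]$model, va, tr_cfg$loss, loss_cfg)
    reports[[f]] <- ev$report
    pooled <- if (is.null(pooled)) ev$counts else add_counts(pooled, ev$counts)
  }
  mean_metrics <- c(miou = mean(vapply(reports, `[[`, numeric(1), "miou")),
                    mp = mean(vapply(reports, `[[`, numeric(1), "mp")),
                    mr = mean(vapply(reports, `[[`, numeric(1), "mr")),
                    mf1 = mean(vapply(reports, `[[`, numeric(1), "mf1")))
  list(fits = fits, fold_reports = reports, mean_metrics = mean_metrics,
       pooled_report = metric_report(pooled))
}
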