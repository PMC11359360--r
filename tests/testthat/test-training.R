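test_that("the cosine schedule hits its endpoints and midpoint", {
  cfg <- train_config(epochs = 151L)
  expect_equal(lr_schedule(0, cfg), 1e-3)
  expect_equal(lr_schedule(150, cfg), 1e-5)
  expect_equal(lr_schedule(75, cfg), (1e-3 + 1e-5) / 2, tolerance = 1e-12)
  lrs <- vapply(0:150, lr_schedule, numeric(1), config = cfg)
  expect_true(all(diff(lrs) <= 0))
  expect_error(lr_schedule(151, cfg), "epoch")
  expect_equal(lr_schedule(0, train_config(epochs = 1L)), 1e-3)
})

test_that("a short training run produces a finite, reproducible history", {
  clouds <- tiny_training_set(6)
  cfg <- tiny_config()
  tcfg <- train_config(batch_size = 2L, epochs = 3L, seed = 7L, loss = "hce")
  fit1 <- train(clouds, cfg, tcfg, loss_config())
  expect_s3_class(fit1, "cphnet_fit")
  expect_equal(nrow(fit1$history), 3L)
  expect_true(all(is.finite(fit1$history$train_loss)))
  expect_true(all(diff(fit1$history$lr) <= 0))

  fit2 <- train(clouds, cfg, tcfg, loss_config())
  expect_identical(fit1$history$train_loss, fit2$history$train_loss)
})

test_that("training refuses unlabelled or single-class data", {
  clouds <- tiny_training_set(2)
  clouds[[1]]$labels <- rep(0L, 256)
  clouds[[2]]$labels <- rep(0L, 256)
  expect_error(train(clouds, tiny_config(), train_config(epochs = 1L)),
               "single class")
  nolab <- lapply(tiny_training_set(2), function(cl) {
    cl$labels <- NULL
    cl
  })
  expect_error(train(nolab, tiny_config(), train_config(epochs = 1L)),
               "labelled")
})

test_that("optimization reduces the training loss on the default synthetic set", {
  set.seed(42)
  clouds <- lapply(1:20, function(i) {
    b <- generate_scene(default_spec_sampler(i, points_total = 1024L))
    prepare_clouds(list(b$cloud), n_points = 512L, seed = i)[[1]]
  })
  fit <- train(clouds, tiny_config(n_points = 512L),
               train_config(batch_size = 2L, lr_init = 5e-3, epochs = 11L,
                            seed = 42L, loss = "hce"), loss_config())
  expect_lt(fit$history$train_loss[11], fit$history$train_loss[1])
})

test_that("checkpoints round-trip the evaluation metrics exactly", {
  clouds <- tiny_training_set(4)
  fit <- train(clouds, tiny_config(),
               train_config(batch_size = 2L, epochs = 2L, seed = 3L),
               loss_config(), val_data = clouds[1:2])
  ev1 <- evaluate_model(fit$model, clouds[1:2])
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  restored <- load_checkpoint(f)
  ev2 <- evaluate_model(restored$model, clouds[1:2])
  expect_identical(ev2$report$miou, ev1$report$miou)
  expect_identical(ev2$loss, ev1$loss)
  expect_identical(restored$history, fit$history)
})

test_that("grouped cross-validation validates every origin exactly once", {
  d <- withr::local_tempdir()
  manifest <- generate_dataset(6L, d, seed = 9, points_total = 512L)
  cv <- cross_validate(manifest, tiny_config(),
                       train_config(batch_size = 2L, epochs = 2L, seed = 5L,
                                    folds = 3L))
  expect_length(cv$fits, 3L)
  expect_length(cv$fold_reports, 3L)
  folds <- kfold_grouped(manifest, 3L, seed = 5L)
  vo <- unlist(lapply(folds, function(f) unique(f$test$origin_id)))
  expect_setequal(vo, manifest$origin_id)
  expect_equal(anyDuplicated(vo), 0L)
  expect_true(all(is.finite(cv$mean_metrics)))
  expect_s3_class(cv$pooled_report, "metric_report")
})
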