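test_that("learning-rate schedule halves per period from the initial rate", {
  cfg <- train_config(initial_lr = 1e-4, lr_halving_period = 2L)
  expect_equal(learning_rate_schedule(0, cfg), 1e-4)
  expect_equal(learning_rate_schedule(1, cfg), 1e-4)
  expect_equal(learning_rate_schedule(2, cfg), 5e-5)
  expect_equal(learning_rate_schedule(3, cfg), 5e-5)
  expect_equal(learning_rate_schedule(4, cfg), 2.5e-5)
  # non-increasing
  lrs <- vapply(0:10, learning_rate_schedule, 0, cfg = cfg)
  expect_true(all(diff(lrs) <= 0))
})

test_that("train_config applies the ablation variants", {
  full <- desk_train_config()
  m1 <- desk_train_config(variant = "model_I")
  m2 <- desk_train_config(variant = "model_II")
  expect_true(full$model$use_fusion)
  expect_false(m1$model$use_fusion)
  expect_equal(m2$loss$lambda1, 1)
  expect_equal(m2$loss$lambda2, 0.1)
  expect_equal(full$loss$lambda2, 1)
})

test_that("full-scale defaults carry the reference training protocol", {
  cfg <- train_config()
  expect_equal(cfg$initial_lr, 1e-4)
  expect_equal(cfg$lr_halving_period, 2L)
  expect_equal(cfg$log_every, 10L)
  expect_equal(cfg$checkpoint_every, 1000L)
  expect_equal(cfg$patch_shape, c(128L, 128L, 64L))
  expect_equal(cfg$loss$gamma, 2)
  expect_equal(cfg$loss$class_weights, c(0.1, 1, 1, 1))
})

make_tiny_dataset <- function(n, seed = 21L) {
  root <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    "cases")
  generate_dataset(n, root, small_spec(), seed = seed)
}

tiny_cfg <- function(steps, seed = 1L, ...) {
  train_config(steps = steps, batch_size = 1L, patch_shape = c(16L, 16L, 16L),
               patches_per_case = 2L, initial_lr = 1e-3, seed = seed,
               model = network_config(encoder_levels = 2L, base_filters = 2L),
               ...)
}

test_that("one training step yields a finite loss and a loadable checkpoint", {
  man <- make_tiny_dataset(1)
  out_dir <- withr::local_tempdir()
  cfg <- tiny_cfg(1L, checkpoint_every = 1L)
  fit <- train_model(man, cfg, out_dir = out_dir)
  expect_true(is.finite(fit$history$loss[1]))
  expect_true(file.exists(fit$checkpoint))
  model <- load_checkpoint(fit$checkpoint)
  expect_s3_class(model, "mtvnet_model")
  expect_true(file.exists(file.path(out_dir, "history.csv")))
})

test_that("training is reproducible under a fixed seed", {
  man <- make_tiny_dataset(2)
  fit1 <- train_model(man, tiny_cfg(6L, seed = 5L))
  fit2 <- train_model(man, tiny_cfg(6L, seed = 5L))
  expect_identical(fit1$history$loss, fit2$history$loss)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_error(train_model(character(0), tiny_cfg(1L)), "empty")
})

test_that("short training reduces the loss on tiny phantoms", {
  man <- make_tiny_dataset(2)
  fit <- train_model(man, tiny_cfg(30L, log_every = 1L))
  h <- fit$history
  expect_lt(mean(tail(h$loss, 5)), mean(head(h$loss, 5)))
})

test_that("prediction on a single-patch volume reduces to one forward pass", {
  man <- make_tiny_dataset(1)
  case <- read_case(man$dir[1])
  model <- build_network(network_config(encoder_levels = 2L, base_filters = 2L),
                         seed = 9)
  pred <- predict_volume(model, case$image, patch_shape = c(32L, 32L, 32L),
                         overlap = 0L)
  vol <- normalize_volume(case$image)
  direct <- decode_onehot(forward_pass(model, vol$data)$mask_probs)
  expect_identical(pred, direct)
  expect_true(all(pred %in% c(0L, 1L, 2L, 4L)))
})

test_that("overlap averaging keeps labels inside the valid set", {
  man <- make_tiny_dataset(1)
  case <- read_case(man$dir[1])
  model <- build_network(network_config(encoder_levels = 2L, base_filters = 2L),
                         seed = 9)
  pred <- predict_volume(model, case$image, patch_shape = c(16L, 16L, 16L),
                         overlap = 8L)
  expect_equal(dim(pred), dim(case$labels))
  expect_true(all(pred %in% c(0L, 1L, 2L, 4L)))
})

test_that("evaluate_dataset scores perfect predictions perfectly and applies the ET rule", {
  man <- make_tiny_dataset(1)
  case <- read_case(man$dir[1])

  # oracle model: feed ground truth as prediction through the metrics path
  m <- case_metrics(case$labels, case$labels, case = "oracle")
  expect_equal(m$dice, rep(1, 3))

  # post-processing changes ET only, when ET is sub-threshold
  pred <- case$labels
  post <- postprocess_enhancing_tumor(pred, threshold = sum(pred == 4L) + 1)
  m_pre <- case_metrics(case$labels, pred)
  m_post <- case_metrics(case$labels, post)
  expect_equal(m_pre[m_pre$region != "ET", c("dice", "hausdorff95")],
               m_post[m_post$region != "ET", c("dice", "hausdorff95")])
  expect_false(isTRUE(all.equal(m_pre$dice[m_pre$region == "ET"],
                                m_post$dice[m_post$region == "ET"])))

  # empty-ET ground truth with empty-ET prediction scores 1 by convention
  no_et <- case$labels
  no_et[no_et == 4L] <- 1L
  m_empty <- case_metrics(no_et, no_et)
  expect_equal(m_empty$dice[m_empty$region == "ET"], 1)
})
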