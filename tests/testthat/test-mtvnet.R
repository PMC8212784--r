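test_that("config validation enforces the head-channel relation", {
  expect_error(network_config(distance_channels = 4L), "num_classes - 1")
  expect_error(network_config(encoder_levels = 1L), ">= 2")
  cfg <- network_config()
  expect_equal(cfg$distance_channels, 3L)
  expect_equal(cfg$num_classes, 4L)
})

test_that("fusion block preserves shape for random shapes and channels", {
  withr::with_seed(7, {
    for (rep in 1:4) {
      C <- sample(2:5, 1)
      shp <- c(sample(4:8, 3, replace = TRUE), C)
      x <- array(rnorm(prod(shp)), dim = shp)
      params <- fusion_block_params(C, seed = rep)
      y <- multi_depth_fusion_block(x, params)
      expect_equal(dim(y), shp)
      expect_true(all(is.finite(y)))
    }
  })
})

test_that("zero-weight fusion block is the identity (pure residual)", {
  x <- array(rnorm(6 * 6 * 6 * 3), dim = c(6, 6, 6, 3))
  params <- fusion_block_params(3, init = "zero", use_norm = FALSE)
  y <- multi_depth_fusion_block(x, params, use_norm = FALSE)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("identity-kernel fusion block doubles non-negative input", {
  # with exact-identity conv units: F(x) = avg(x, x) = x, so
  # y = x + avg(F(F(x)), x) = 2x for x >= 0
  x <- array(abs(rnorm(5 * 5 * 5 * 2)), dim = c(5, 5, 5, 2))
  params <- fusion_block_params(2, init = "identity", use_norm = FALSE)
  y <- multi_depth_fusion_block(x, params, use_norm = FALSE)
  expect_equal(y, 2 * x, tolerance = 1e-12)
})

test_that("fusion block rejects a channel mismatch", {
  params <- fusion_block_params(3)
  x <- array(rnorm(4^3 * 2), dim = c(4, 4, 4, 2))
  expect_error(multi_depth_fusion_block(x, params), "channels")
})

test_that("built network has the contracted head channels and fewer params without fusion", {
  cfg <- network_config(encoder_levels = 2L, base_filters = 4L)
  model <- build_network(cfg, seed = 1)
  expect_equal(ncol(model$params[["mask.head.w"]]), 4L)
  expect_equal(ncol(model$params[["dist.head.w"]]), 3L)

  ablated <- build_network(network_config(encoder_levels = 2L, base_filters = 4L,
                                          use_fusion = FALSE), seed = 1)
  expect_lt(n_parameters(ablated), n_parameters(model))
})

test_that("forward pass satisfies the output invariants and shape contract", {
  cfg <- network_config(encoder_levels = 2L, base_filters = 4L)
  model <- build_network(cfg, seed = 2)
  x <- withr::with_seed(3, array(rnorm(16^3 * 4), dim = c(16, 16, 16, 4)))
  out <- forward_pass(model, x)
  expect_equal(dim(out$mask_probs), c(16L, 16L, 16L, 4L))
  expect_equal(dim(out$dist_pred), c(16L, 16L, 16L, 3L))
  sums <- apply(out$mask_probs, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(out$dist_pred > 0 & out$dist_pred < 1))

  # evaluation-mode determinism
  out2 <- forward_pass(model, x)
  expect_identical(out$mask_probs, out2$mask_probs)

  # fully convolutional: doubling input doubles output
  x2 <- withr::with_seed(4, array(rnorm(32 * 16 * 16 * 4), dim = c(32, 16, 16, 4)))
  out3 <- forward_pass(model, x2)
  expect_equal(dim(out3$mask_probs)[1:3], c(32L, 16L, 16L))

  expect_error(forward_pass(model, array(0, dim = c(15, 16, 16, 4))),
               "divisible")
})

test_that("analytic gradients match finite differences through the whole graph", {
  cfg <- network_config(encoder_levels = 2L, base_filters = 2L)
  model <- build_network(cfg, seed = 3)
  x <- withr::with_seed(5, array(rnorm(8^3 * 4), dim = c(8, 8, 8, 4)))
  labs <- random_labels(c(8L, 8L, 8L), seed = 6)
  oh <- unclass(encode_labels_onehot(labs))
  dt <- unclass(ground_truth_distance_maps(encode_labels_onehot(labs)))
  lc <- loss_config()

  loss_of <- function(params) {
    tp <- mtvnet:::tp_new()
    pid <- mtvnet:::tp_register_params(tp, params)
    xid <- mtvnet:::tp_leaf(tp, x)
    heads <- mtvnet:::mtv_graph(tp, pid, cfg, xid)
    lm <- mtvnet:::op_focal_softmax(tp, heads$mask, oh, lc$gamma,
                                    lc$class_weights, lc$eps)
    ld <- mtvnet:::op_sigmoid_mse(tp, heads$dist, dt, "mean")
    lt <- mtvnet:::op_wsum2(tp, lm, ld, 1, 1)
    list(tp = tp, pid = pid, lt = lt, val = mtvnet:::tp_value(tp, lt))
  }
  r <- loss_of(model$params)
  grads <- mtvnet:::tp_backward(r$tp, r$lt)
  withr::with_seed(8, {
    for (nm in sample(names(model$params), 6)) {
      g <- grads[[r$pid[[nm]]]]
      expect_false(is.null(g), info = nm)
      i <- sample(length(model$params[[nm]]), 1)
      f <- function(v) {
        p <- model$params
        p[[nm]][i] <- v
        loss_of(p)$val
      }
      eps <- 1e-6
      v0 <- model$params[[nm]][i]
      num <- (f(v0 + eps) - f(v0 - eps)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4, info = nm)
    }
  })
})
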