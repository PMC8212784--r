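#' Network configuration
#'
#' Architecture hyperparameters of the multi-task V-Net: a shared encoder of
#' \code{encoder_levels} resolution levels (filters doubling per level,
#' 3x3x3 convolutions, strided 2x2x2 downsampling, a multi-depth fusion block
#' in front of each downsampling layer) feeding two structurally parallel
#' decoders with transposed-convolution upsampling and skip connections from
#' the matching encoder level. The mask head emits softmax probabilities over
#' the 4 label channels; the distance head emits sigmoid outputs over the 3
#' foreground classes.
#'
#' @param input_channels number of input modalities (4: FLAIR, T1, T1-CE, T2).
#' @param num_classes mask-head channels (4: background, necrosis, edema,
#'   enhancing).
#' @param distance_channels distance-head channels; must equal
#'   \code{num_classes - 1}.
#' @param encoder_levels number of resolution levels (>= 2).
#' @param base_filters filters at the first level; doubled at each level.
#' @param use_fusion include the multi-depth fusion blocks (FALSE gives the
#'   fusion-ablated variant, "Model I").
#' @param use_norm batch normalization after every convolution.
#' @return object of class \code{network_config}.
#' @export
network_config <- function(input_channels = 4L, num_classes = 4L,
                           distance_channels = num_classes - 1L,
                           encoder_levels = 4L, base_filters = 16L,
                           use_fusion = TRUE, use_norm = TRUE) {
  if (distance_channels != num_classes - 1L)
    stop_mtv("distance_channels (%d) must equal num_classes - 1 (%d)",
             distance_channels, num_classes - 1L)
  if (encoder_levels < 2L) stop_mtv("encoder_levels must be >= 2")
  if (base_filters < 1L) stop_mtv("base_filters must be >= 1")
  structure(list(input_channels = as.integer(input_channels),
                 num_classes = as.integer(num_classes),
                 distance_channels = as.integer(distance_channels),
                 encoder_levels = as.integer(encoder_levels),
                 base_filters = as.integer(base_filters),
                 use_fusion = isTRUE(use_fusion),
                 use_norm = isTRUE(use_norm)),
            class = "network_config")
}

# parameter names of one conv(+norm) unit
cbr_param_names <- function(name, use_norm) {
  n <- c(paste0(name, ".w"), paste0(name, ".b"))
  if (use_norm) n <- c(n, paste0(name, ".gamma"), paste0(name, ".beta"))
  n
}

# He-initialized parameters for one conv(+norm) unit
init_cbr <- function(K, cin, cout, use_norm, zero = FALSE) {
  fan_in <- K^3 * cin
  w <- if (zero) matrix(0, fan_in, cout) else
    matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  p <- list(w = w, b = numeric(cout))
  if (use_norm) p <- c(p, list(gamma = rep(1, cout), beta = numeric(cout)))
  p
}

fusion_unit_names <- c("f1c1", "f1c2", "f1c3", "f2c1", "f2c2", "f2c3", "g")

# ordered table of every conv unit in the architecture:
# name, kernel, cin, cout, norm (upconv rows use kernel = 0 marker)
layer_table <- function(cfg) {
  L <- cfg$encoder_levels
  Fl <- cfg$base_filters * 2L^(seq_len(L) - 1L)
  rows <- list()
  add <- function(name, K, cin, cout, norm = cfg$use_norm)
    rows[[length(rows) + 1L]] <<- list(name = name, K = K, cin = cin,
                                       cout = cout, norm = norm)
  for (l in seq_len(L)) {
    cin <- if (l == 1L) cfg$input_channels else Fl[l]
    add(sprintf("enc%d.conv", l), 3L, cin, Fl[l])
    if (cfg$use_fusion) {
      for (u in fusion_unit_names)
        add(sprintf("enc%d.fus.%s", l, u), 3L, Fl[l], Fl[l])
    } else {
      add(sprintf("enc%d.conv2", l), 3L, Fl[l], Fl[l])
    }
    if (l < L) add(sprintf("down%d", l), 2L, Fl[l], Fl[l + 1L])
  }
  for (h in c("mask", "dist")) {
    for (l in rev(seq_len(L - 1L))) {
      add(sprintf("%s.up%d", h, l), 0L, Fl[l + 1L], Fl[l])     # transposed conv
      add(sprintf("%s.conv%d", h, l), 3L, 2L * Fl[l], Fl[l])
    }
    nc <- if (h == "mask") cfg$num_classes else cfg$distance_channels
    add(sprintf("%s.head", h), 1L, Fl[1L], nc, norm = FALSE)
  }
  rows
}

#' Build the multi-task network
#'
#' Initializes all convolution, transposed-convolution and normalization
#' parameters (He-style, from a seeded generator) for the architecture
#' described by \code{config}.
#'
#' @param config a [network_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class \code{mtvnet_model}: list with \code{config},
#'   \code{params} (named list of arrays) and \code{seed}.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  stopifnot(inherits(config, "network_config"))
  params <- with_seed(seed, {
    p <- list()
    for (row in layer_table(config)) {
      K <- if (row$K == 0L) 2L else row$K
      unit <- init_cbr(K, row$cin, row$cout, row$norm)
      for (nm in names(unit)) p[[paste0(row$name, ".", nm)]] <- unit[[nm]]
    }
    p
  })
  structure(list(config = config, params = params, bn_stats = list(),
                 seed = as.integer(seed)),
            class = "mtvnet_model")
}

#' Number of trainable parameters
#' @param model an \code{mtvnet_model}.
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' @export
print.mtvnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("mtvnet_model: %d levels, base %d filters, fusion %s, ",
                     "%d parameters\n"),
              cfg$encoder_levels, cfg$base_filters,
              if (cfg$use_fusion) "on" else "off", n_parameters(x)))
  invisible(x)
}

# register all params as tape leaves; returns name -> node id
tp_register_params <- function(tp, params) {
  ids <- vector("list", length(params))
  names(ids) <- names(params)
  for (nm in names(params)) ids[[nm]] <- tp_leaf(tp, params[[nm]])
  ids
}

# conv (+ optional norm) + optional ReLU; `ctx` carries norm mode and stats
tp_cbr <- function(tp, pid, name, x_id, K, stride = 1L, pad = (K - 1L) %/% 2L,
                   use_norm = TRUE, act = TRUE, ctx = NULL) {
  y <- op_conv(tp, x_id, pid[[paste0(name, ".w")]], pid[[paste0(name, ".b")]],
               K, stride, pad)
  if (use_norm)
    y <- op_batchnorm(tp, y, pid[[paste0(name, ".gamma")]],
                      pid[[paste0(name, ".beta")]], name = name, ctx = ctx)
  if (act) y <- op_relu(tp, y)
  y
}

# fusion sub-network F(x) = avg(conv(conv(x)), conv(x)) built from three
# conv units named <base>c1, <base>c2 (the two-conv branch) and <base>c3
tp_fusion_F <- function(tp, pid, base, x_id, use_norm, ctx = NULL) {
  deep <- tp_cbr(tp, pid, paste0(base, "c2"),
                 tp_cbr(tp, pid, paste0(base, "c1"), x_id, 3L,
                        use_norm = use_norm, ctx = ctx),
                 3L, use_norm = use_norm, ctx = ctx)
  shallow <- tp_cbr(tp, pid, paste0(base, "c3"), x_id, 3L,
                    use_norm = use_norm, ctx = ctx)
  op_avg2(tp, deep, shallow)
}

# multi-depth fusion block: y = x + avg(F2(F1(x)), conv_g(x))
tp_fusion_block <- function(tp, pid, prefix, x_id, use_norm, ctx = NULL) {
  f1 <- tp_fusion_F(tp, pid, paste0(prefix, ".f1"), x_id, use_norm, ctx)
  f2 <- tp_fusion_F(tp, pid, paste0(prefix, ".f2"), f1, use_norm, ctx)
  g <- tp_cbr(tp, pid, paste0(prefix, ".g"), x_id, 3L, use_norm = use_norm,
              ctx = ctx)
  op_add(tp, x_id, op_avg2(tp, f2, g))
}

# full forward graph; returns mask/dist logit node ids
mtv_graph <- function(tp, pid, cfg, x_id, ctx = NULL) {
  L <- cfg$encoder_levels
  skips <- vector("list", L)
  cur <- x_id
  for (l in seq_len(L)) {
    cur <- tp_cbr(tp, pid, sprintf("enc%d.conv", l), cur, 3L,
                  use_norm = cfg$use_norm, ctx = ctx)
    cur <- if (cfg$use_fusion)
      tp_fusion_block(tp, pid, sprintf("enc%d.fus", l), cur, cfg$use_norm, ctx)
    else
      tp_cbr(tp, pid, sprintf("enc%d.conv2", l), cur, 3L,
             use_norm = cfg$use_norm, ctx = ctx)
    skips[[l]] <- cur
    if (l < L)
      cur <- tp_cbr(tp, pid, sprintf("down%d", l), cur, 2L, stride = 2L,
                    pad = 0L, use_norm = cfg$use_norm, ctx = ctx)
  }
  heads <- list()
  for (h in c("mask", "dist")) {
    cur <- skips[[L]]
    for (l in rev(seq_len(L - 1L))) {
      up <- op_upconv(tp, cur, pid[[sprintf("%s.up%d.w", h, l)]],
                      pid[[sprintf("%s.up%d.b", h, l)]])
      if (cfg$use_norm)
        up <- op_batchnorm(tp, up, pid[[sprintf("%s.up%d.gamma", h, l)]],
                           pid[[sprintf("%s.up%d.beta", h, l)]],
                           name = sprintf("%s.up%d", h, l), ctx = ctx)
      up <- op_relu(tp, up)
      cur <- op_concat(tp, up, skips[[l]])
      cur <- tp_cbr(tp, pid, sprintf("%s.conv%d", h, l), cur, 3L,
                    use_norm = cfg$use_norm, ctx = ctx)
    }
    heads[[h]] <- tp_cbr(tp, pid, sprintf("%s.head", h), cur, 1L, pad = 0L,
                         use_norm = FALSE, act = FALSE)
  }
  heads
}

check_patch_dims <- function(shp, levels) {
  div <- 2L^(levels - 1L)
  if (any(shp %% div != 0L))
    stop_mtv(paste0("input spatial shape (%s) must be divisible by ",
                    "2^(encoder_levels-1) = %d in every axis"),
             paste(shp, collapse = "x"), div)
}

as_patch_array <- function(patch) {
  if (inherits(patch, "multimodal_volume")) patch <- patch$data
  if (length(dim(patch)) != 4L)
    stop_mtv("patch must be a (D,H,W,C) array")
  patch
}

#' Forward pass through the network
#'
#' Runs one 4-channel patch through the model and returns both heads:
#' softmax class probabilities (4 channels, summing to 1 at every voxel) and
#' sigmoid distance-map predictions (3 channels in (0,1)). Deterministic for
#' fixed weights and input.
#'
#' Normalization layers use the running statistics accumulated during
#' training (evaluation mode); for an untrained model they fall back to the
#' statistics of the input itself.
#'
#' @param model an \code{mtvnet_model}.
#' @param patch (D,H,W,4) array (or \code{multimodal_volume}); spatial dims
#'   must be divisible by \code{2^(encoder_levels-1)}.
#' @return list with \code{mask_probs} (D,H,W,4) and \code{dist_pred}
#'   (D,H,W,3).
#' @export
forward_pass <- function(model, patch) {
  stopifnot(inherits(model, "mtvnet_model"))
  patch <- as_patch_array(patch)
  check_patch_dims(dim(patch)[1:3], model$config$encoder_levels)
  tp <- tp_new()
  pid <- tp_register_params(tp, model$params)
  x_id <- tp_leaf(tp, patch)
  ctx <- list(training = FALSE, stats = model$bn_stats)
  heads <- mtv_graph(tp, pid, model$config, x_id, ctx)
  mask_logits <- tp_value(tp, heads$mask)
  dist_logits <- tp_value(tp, heads$dist)
  list(mask_probs = softmax_channels(mask_logits),
       dist_pred = 1 / (1 + exp(-dist_logits)))
}

#' Parameters of a standalone multi-depth fusion block
#'
#' The block contains seven 3x3x3 convolution units: two fusion
#' sub-networks \eqn{F_i(x) = avg(conv(conv(x)), conv(x))} (three units
#' each) and one outer convolution on the residual input path.
#'
#' @param channels feature channels of the block.
#' @param init \code{"he"} (random), \code{"zero"} (all weights and biases
#'   zero, so the block reduces to the identity), or \code{"identity"}
#'   (center-tap kernels, so each conv unit passes non-negative input
#'   through unchanged).
#' @param use_norm include normalization parameters.
#' @param seed seed for random initialization.
#' @return named list of parameter arrays.
#' @export
fusion_block_params <- function(channels, init = c("he", "zero", "identity"),
                                use_norm = TRUE, seed = 1L) {
  init <- match.arg(init)
  with_seed(seed, {
    p <- list()
    for (u in fusion_unit_names) {
      unit <- init_cbr(3L, channels, channels, use_norm, zero = init != "he")
      if (init == "identity") {
        # center tap of the 3x3x3 kernel: offset (1,1,1) of channel c -> c
        center <- 1L + 3L * (1L + 3L * 1L)
        for (c in seq_len(channels)) unit$w[center + 27L * (c - 1L) + 1L, c] <- 1
      }
      for (nm in names(unit)) p[[paste0("fus.", u, ".", nm)]] <- unit[[nm]]
    }
    p
  })
}

#' Apply a multi-depth fusion block
#'
#' Computes \eqn{y = x + avg(F_2(F_1(x)), conv_g(x))} with
#' \eqn{F_i(x) = avg(conv(conv(x)), conv(x))}; all convolutions are 3x3x3,
#' stride 1, each followed by (optional) normalization and ReLU. Output
#' shape and channel count equal those of the input.
#'
#' @param x (D,H,W,C) feature array.
#' @param params block parameters from [fusion_block_params()].
#' @param use_norm apply normalization inside the conv units.
#' @return (D,H,W,C) array.
#' @export
multi_depth_fusion_block <- function(x, params, use_norm = TRUE) {
  stopifnot(length(dim(x)) == 4L)
  C <- dim(x)[4]
  if (nrow(params[["fus.g.w"]]) != 27L * C)
    stop_mtv("fusion block configured for %d channels but input has %d",
             nrow(params[["fus.g.w"]]) / 27L, C)
  tp <- tp_new()
  pid <- tp_register_params(tp, params)
  x_id <- tp_leaf(tp, x)
  y_id <- tp_fusion_block(tp, pid, "fus", x_id, use_norm)
  tp_value(tp, y_id)
}
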