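#' Training configuration
#'
#' Optimization settings of the multi-task training loop. Defaults follow
#' the reference training protocol: Adam, initial learning rate 1e-4 halved
#' after every two traversals of the training set, per-traversal shuffling,
#' loss and mean-Dice logging every 10 steps, checkpoints (with sample
#' prediction/ground-truth exports) every 1000 steps. The \code{variant}
#' field selects the ablation builds: \code{"model_I"} removes the
#' multi-depth fusion blocks; \code{"model_II"} down-weights the distance
#' task (\eqn{\lambda_1 = 1, \lambda_2 = 0.1}).
#'
#' @param steps number of optimization steps.
#' @param batch_size patches per step.
#' @param patch_shape training patch size (voxels).
#' @param patches_per_case patches counted per case per traversal (defines
#'   the traversal length for the learning-rate schedule).
#' @param initial_lr initial learning rate (> 0).
#' @param lr_halving_period traversals between halvings (>= 1).
#' @param shuffle reshuffle the case order each traversal.
#' @param tumor_fraction fraction of training patches forced to intersect
#'   tumor.
#' @param log_every steps between history records.
#' @param checkpoint_every steps between checkpoints.
#' @param bn_freeze_step step after which batch-norm statistics are frozen
#'   and training continues against the stored running averages, so the
#'   network optimizes the exact function used at inference
#'   (\code{Inf} = never freeze).
#' @param seed master seed for shuffling, patch sampling and initialization.
#' @param loss a [loss_config()].
#' @param model a [network_config()].
#' @param variant \code{"full"}, \code{"model_I"} or \code{"model_II"}.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(steps = 500000L, batch_size = 1L,
                         patch_shape = c(128L, 128L, 64L),
                         patches_per_case = 1L,
                         initial_lr = 1e-4, lr_halving_period = 2L,
                         shuffle = TRUE, tumor_fraction = 0.5,
                         log_every = 10L, checkpoint_every = 1000L,
                         bn_freeze_step = Inf,
                         seed = 1L, loss = loss_config(),
                         model = network_config(),
                         variant = c("full", "model_I", "model_II"),
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8) {
  variant <- match.arg(variant)
  if (initial_lr <= 0) stop_mtv("initial_lr must be > 0")
  if (lr_halving_period < 1) stop_mtv("lr_halving_period must be >= 1")
  if (variant == "model_I") model$use_fusion <- FALSE
  if (variant == "model_II") { loss$lambda1 <- 1; loss$lambda2 <- 0.1 }
  structure(list(steps = as.integer(steps), batch_size = as.integer(batch_size),
                 patch_shape = as.integer(patch_shape),
                 patches_per_case = as.integer(patches_per_case),
                 initial_lr = initial_lr,
                 lr_halving_period = as.integer(lr_halving_period),
                 shuffle = isTRUE(shuffle), tumor_fraction = tumor_fraction,
                 log_every = as.integer(log_every),
                 checkpoint_every = as.integer(checkpoint_every),
                 bn_freeze_step = bn_freeze_step,
                 seed = as.integer(seed), loss = loss, model = model,
                 variant = variant, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A reduced configuration (3 levels, 4 base filters, 32^3 patches, larger
#' learning rate, a few hundred steps) sized so the full multi-task model
#' trains on synthetic phantoms in minutes on one CPU. The architecture and
#' objective are identical to the full-scale defaults; only capacity, patch
#' size and schedule are reduced.
#'
#' @param steps,batch_size,initial_lr,seed,variant,... overrides passed to
#'   [train_config()].
#' @return a \code{train_config}.
#' @export
desk_train_config <- function(steps = 300L, batch_size = 1L,
                              initial_lr = 2e-3, seed = 1L,
                              variant = "full", ...) {
  train_config(steps = steps, batch_size = batch_size,
               patch_shape = c(32L, 32L, 32L), patches_per_case = 20L,
               initial_lr = initial_lr, lr_halving_period = 2L,
               checkpoint_every = 1000L, bn_freeze_step = 150L, seed = seed,
               model = network_config(encoder_levels = 3L, base_filters = 4L),
               variant = variant, ...)
}

#' Learning-rate schedule
#'
#' Step decay: \eqn{lr = lr_0 \cdot 0.5^{\lfloor traversals / period
#' \rfloor}} — the rate halves after every \code{lr_halving_period} complete
#' traversals of the training set.
#'
#' @param traversals_completed non-negative count of completed traversals.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
learning_rate_schedule <- function(traversals_completed, cfg) {
  stopifnot(traversals_completed >= 0)
  cfg$initial_lr * 0.5^(traversals_completed %/% cfg$lr_halving_period)
}

# mean foreground Dice of an argmax segmentation against one-hot truth,
# the scalar monitored during training
batch_mean_dice <- function(y_true, probs) {
  pred <- decode_onehot(probs)
  gt <- decode_onehot(y_true)
  vals <- vapply(c(1L, 2L, 4L), function(v) {
    cc <- confusion_counts(gt == v, pred == v)
    dice_score(cc)
  }, 0)
  mean(vals)
}

adam_state_new <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

load_training_cases <- function(manifest) {
  dirs <- if (is.data.frame(manifest)) manifest$dir
          else if (is.character(manifest) && length(manifest) == 1L &&
                   dir.exists(manifest) &&
                   length(list.files(manifest, pattern = "\\.nii")) == 0L)
            list.dirs(manifest, recursive = FALSE)
          else as.character(manifest)
  if (length(dirs) == 0L) stop_mtv("empty training manifest")
  lapply(dirs, function(d) {
    case <- read_case(d)
    if (is.null(case$labels))
      stop_mtv("training case '%s' has no segmentation", basename(d))
    list(image = normalize_volume(case$image),
         onehot = encode_labels_onehot(case$labels),
         dir = d)
  })
}

# forward + backward for one patch; returns losses, monitor, grads by name
# and the updated running normalization statistics
train_step_single <- function(params, cfg, img_patch, mask_patch, dist_patch,
                              bn_stats = list(), bn_frozen = FALSE) {
  tp <- tp_new()
  pid <- tp_register_params(tp, params)
  x_id <- tp_leaf(tp, img_patch)
  ctx <- new.env(parent = emptyenv())
  ctx$training <- TRUE
  ctx$frozen <- bn_frozen
  ctx$stats <- bn_stats
  ctx$momentum <- 0.9
  heads <- mtv_graph(tp, pid, cfg$model, x_id, ctx)
  lc <- cfg$loss
  l_mask <- op_focal_softmax(tp, heads$mask, mask_patch, lc$gamma,
                             lc$class_weights, lc$eps)
  l_dist <- op_sigmoid_mse(tp, heads$dist, dist_patch, lc$distance_reduction)
  l_tot <- op_wsum2(tp, l_mask, l_dist, lc$lambda1, lc$lambda2)
  grads_by_id <- tp_backward(tp, l_tot)
  grads <- setNames(lapply(names(pid), function(nm) grads_by_id[[pid[[nm]]]]),
                    names(pid))
  probs <- softmax_channels(tp_value(tp, heads$mask))
  list(loss = tp_value(tp, l_tot), l_mask = tp_value(tp, l_mask),
       l_dist = tp_value(tp, l_dist), grads = grads,
       mean_dice = batch_mean_dice(mask_patch, probs),
       bn_stats = ctx$stats)
}

#' Train the multi-task network
#'
#' CPU training loop: per-traversal shuffling of the case order, random
#' tumor-biased patch sampling, Adam updates under the step-decay
#' learning-rate schedule, loss/mean-Dice logging every \code{log_every}
#' steps, and periodic checkpoints with sample prediction and ground-truth
#' exports. Distance-map regression targets are computed on the fly from
#' each mask patch. Aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param manifest data.frame from [generate_dataset()], a vector of case
#'   directories, or a root directory of cases.
#' @param cfg a [train_config()].
#' @param out_dir optional run directory for checkpoints, sample exports and
#'   the history log.
#' @param verbose print progress lines at logging steps.
#' @return list with \code{model} (trained \code{mtvnet_model}),
#'   \code{history} (data.frame: step, traversal, lr, loss, loss_mask,
#'   loss_dist, mean_dice) and \code{checkpoint} (path or NULL).
#' @export
train_model <- function(manifest, cfg = desk_train_config(), out_dir = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  cases <- load_training_cases(manifest)
  n_cases <- length(cases)
  check_patch_dims(cfg$patch_shape, cfg$model$encoder_levels)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  model <- build_network(cfg$model, seed = cfg$seed)
  state <- adam_state_new(model$params)
  history <- list()
  ckpt_path <- NULL

  traversal_len <- n_cases * cfg$patches_per_case
  with_seed(cfg$seed + 1L, {
    queue <- integer(0)
    traversals <- 0L
    samples_drawn <- 0L
    for (step in seq_len(cfg$steps)) {
      lr <- learning_rate_schedule(traversals, cfg)
      batch_losses <- c(); batch_mask <- c(); batch_dist <- c(); batch_md <- c()
      grad_acc <- NULL
      for (b in seq_len(cfg$batch_size)) {
        if (length(queue) == 0L) {
          queue <- rep(seq_len(n_cases), cfg$patches_per_case)
          if (cfg$shuffle) queue <- sample(queue)
        }
        ci <- queue[1L]; queue <- queue[-1L]
        case <- cases[[ci]]
        pp <- extract_patches(case$image, case$onehot, cfg$patch_shape,
                              mode = "random", n_patches = 1L,
                              tumor_fraction = cfg$tumor_fraction,
                              seed = sample.int(.Machine$integer.max - 1L, 1L))[[1]]
        dist_true <- ground_truth_distance_maps(pp$mask)
        res <- train_step_single(model$params, cfg, pp$image, pp$mask,
                                 unclass(dist_true), model$bn_stats,
                                 bn_frozen = step > cfg$bn_freeze_step)
        model$bn_stats <- res$bn_stats
        if (!is.finite(res$loss))
          stop_mtv("non-finite loss at step %d (mask %g, dist %g); aborting",
                   step, res$l_mask, res$l_dist)
        batch_losses <- c(batch_losses, res$loss)
        batch_mask <- c(batch_mask, res$l_mask)
        batch_dist <- c(batch_dist, res$l_dist)
        batch_md <- c(batch_md, res$mean_dice)
        if (is.null(grad_acc)) grad_acc <- res$grads
        else for (nm in names(grad_acc))
          grad_acc[[nm]] <- grad_acc[[nm]] + res$grads[[nm]]
        samples_drawn <- samples_drawn + 1L
        if (samples_drawn %% traversal_len == 0L) traversals <- traversals + 1L
      }
      for (nm in names(grad_acc))
        grad_acc[[nm]] <- grad_acc[[nm]] / cfg$batch_size
      upd <- adam_update(model$params, grad_acc, state, lr,
                         cfg$beta1, cfg$beta2, cfg$adam_eps)
      model$params <- upd$params
      state <- upd$state

      if (step %% cfg$log_every == 0L || step == 1L || step == cfg$steps) {
        rec <- data.frame(step = step, traversal = traversals, lr = lr,
                          loss = mean(batch_losses),
                          loss_mask = mean(batch_mask),
                          loss_dist = mean(batch_dist),
                          mean_dice = mean(batch_md))
        history[[length(history) + 1L]] <- rec
        if (verbose)
          message(sprintf("step %5d lr %.2e loss %.4f (mask %.4f dist %.4f) dice %.3f",
                          step, lr, rec$loss, rec$loss_mask, rec$loss_dist,
                          rec$mean_dice))
      }
      if (!is.null(out_dir) &&
          (step %% cfg$checkpoint_every == 0L || step == cfg$steps)) {
        ckpt_path <- file.path(out_dir, sprintf("checkpoint_%06d.rds", step))
        save_checkpoint(model, ckpt_path)
        pp_last <- cases[[1L]]
        ex <- extract_patches(pp_last$image, pp_last$onehot, cfg$patch_shape,
                              mode = "random", n_patches = 1L,
                              tumor_fraction = 1, seed = step)[[1]]
        out <- forward_pass(model, ex$image)
        saveRDS(list(step = step, pred = decode_onehot(out$mask_probs),
                     gt = decode_onehot(ex$mask)),
                file.path(out_dir, sprintf("sample_%06d.rds", step)))
      }
    }
  })
  history <- do.call(rbind, history)
  if (!is.null(out_dir))
    write.csv(history, file.path(out_dir, "history.csv"), row.names = FALSE)
  list(model = model, history = history, checkpoint = ckpt_path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the architecture configuration alongside the
#' parameter arrays, so a load rebuilds a usable model without external
#' information.
#'
#' @param model an \code{mtvnet_model}.
#' @param path file path (.rds).
#' @return \code{save_checkpoint}: the path, invisibly;
#'   \code{load_checkpoint}: the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mtvnet_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mtvnet_model"))
  model
}

#' Patch-tiled full-volume prediction
#'
#' Tiles the volume with an overlapping grid of patches, averages the
#' per-voxel softmax probabilities over all patches covering a voxel, takes
#' the argmax (ties broken toward the lower channel index) and maps channel
#' 3 back to label 4.
#'
#' @param model an \code{mtvnet_model} (or a checkpoint path).
#' @param volume a \code{multimodal_volume}.
#' @param patch_shape patch size; defaults to the whole volume when it fits
#'   the divisibility constraint.
#' @param overlap voxel overlap between adjacent patches per axis.
#' @param normalize apply per-channel Z-score before inference.
#' @return integer label array (values in \{0, 1, 2, 4\}) of the volume's
#'   spatial shape.
#' @export
predict_volume <- function(model, volume, patch_shape = c(32L, 32L, 32L),
                           overlap = 8L, normalize = TRUE) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "mtvnet_model"), inherits(volume, "multimodal_volume"))
  if (normalize) volume <- normalize_volume(volume)
  shp <- dim(volume$data)[1:3]
  patch_shape <- as.integer(pmin(patch_shape, shp))
  check_patch_dims(patch_shape, model$config$encoder_levels)
  stride <- pmax(patch_shape - as.integer(overlap), 1L)
  patches <- extract_patches(volume, NULL, patch_shape, mode = "grid",
                             stride = stride)
  prob_sum <- array(0, dim = c(shp, model$config$num_classes))
  cover <- array(0, dim = shp)
  for (pp in patches) {
    out <- forward_pass(model, pp$image)
    i1 <- pp$origin + 1L; i2 <- pp$origin + patch_shape
    prob_sum[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3], ] <-
      prob_sum[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3], , drop = FALSE] +
      out$mask_probs
    cover[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] <-
      cover[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3]] + 1
  }
  probs <- prob_sum / as.numeric(cover)  # channel-recycled over voxels
  decode_onehot(probs)
}

#' Evaluate a model over a dataset
#'
#' Predicts every case, computes the ET/WT/TC metrics before and after the
#' enhancing-tumor post-processing rule, and returns the per-case table.
#' Cases without ground truth are skipped with a warning.
#'
#' @param model an \code{mtvnet_model} or checkpoint path.
#' @param case_dirs character vector of BraTS-layout case directories (or a
#'   manifest data.frame with a \code{dir} column).
#' @param postprocess also report post-processed metrics.
#' @param et_threshold ET voxel-count threshold of the rule.
#' @param patch_shape,overlap passed to [predict_volume()].
#' @param csv optional path; per-case table written as CSV.
#' @return data.frame of per-case, per-region metrics with a
#'   \code{postprocessed} flag column.
#' @export
evaluate_dataset <- function(model, case_dirs, postprocess = TRUE,
                             et_threshold = 500,
                             patch_shape = c(32L, 32L, 32L), overlap = 8L,
                             csv = NULL) {
  if (is.character(model) && length(model) == 1L && file.exists(model))
    model <- load_checkpoint(model)
  if (is.data.frame(case_dirs)) case_dirs <- case_dirs$dir
  rows <- list()
  for (d in case_dirs) {
    case <- read_case(d)
    if (is.null(case$labels)) {
      warning(sprintf("case '%s' has no ground truth; skipped", basename(d)))
      next
    }
    pred <- predict_volume(model, case$image, patch_shape, overlap)
    m <- case_metrics(case$labels, pred, spacing = case$image$spacing,
                      case = basename(d))
    m$postprocessed <- FALSE
    rows[[length(rows) + 1L]] <- m
    if (postprocess) {
      mp <- case_metrics(case$labels,
                         postprocess_enhancing_tumor(pred, et_threshold),
                         spacing = case$image$spacing, case = basename(d))
      mp$postprocessed <- TRUE
      rows[[length(rows) + 1L]] <- mp
    }
  }
  res <- do.call(rbind, rows)
  if (!is.null(csv)) write.csv(res, csv, row.names = FALSE)
  res
}
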