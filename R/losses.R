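#' Loss configuration
#'
#' Settings of the multi-task objective: the weighted categorical focal loss
#' of the mask head, the squared-error loss of the distance head, and their
#' weighted combination \eqn{L = \lambda_1 L_{mask} + \lambda_2 L_{dist}}.
#' Defaults follow the training setup used throughout the package:
#' \eqn{\gamma = 2}, background class weight 0.1 with all foreground class
#' weights 1.0, and \eqn{\lambda_1 = \lambda_2 = 1}.
#'
#' @param gamma focusing exponent (>= 0).
#' @param class_weights per-channel weights (background, necrosis, edema,
#'   enhancing).
#' @param lambda1,lambda2 scaling factors of the mask and distance losses.
#' @param distance_reduction \code{"mean"} (patch-size stable, default) or
#'   \code{"sum"} over voxels for the distance loss.
#' @param eps probability clipping floor applied before the logarithm.
#' @return object of class \code{loss_config}.
#' @export
loss_config <- function(gamma = 2, class_weights = c(0.1, 1, 1, 1),
                        lambda1 = 1, lambda2 = 1,
                        distance_reduction = c("mean", "sum"), eps = 1e-7) {
  distance_reduction <- match.arg(distance_reduction)
  if (gamma < 0) stop_mtv("gamma must be >= 0")
  if (any(class_weights < 0)) stop_mtv("class weights must be >= 0")
  if (lambda1 < 0 || lambda2 < 0) stop_mtv("lambdas must be >= 0")
  structure(list(gamma = gamma, class_weights = as.numeric(class_weights),
                 lambda1 = lambda1, lambda2 = lambda2,
                 distance_reduction = distance_reduction, eps = eps),
            class = "loss_config")
}

#' Weighted categorical focal loss
#'
#' Per-voxel term \eqn{-W_t (1 - p_t)^\gamma \log p_t} where \eqn{p_t} is the
#' predicted probability of the true class \eqn{t} and \eqn{W_t} its class
#' weight, averaged over voxels. With \eqn{\gamma = 0} and unit weights this
#' is exactly categorical cross-entropy; for \eqn{\gamma > 0} easy voxels
#' (large \eqn{p_t}) are down-weighted, countering the extreme
#' background/tumor class imbalance. Probabilities are clipped to
#' \code{[eps, 1 - eps]} before the logarithm.
#'
#' @param y_true one-hot ground truth, (D,H,W,C).
#' @param y_prob softmax probabilities, same shape, summing to 1 per voxel.
#' @param cfg a [loss_config()].
#' @return scalar loss (non-negative).
#' @export
categorical_focal_loss <- function(y_true, y_prob, cfg = loss_config()) {
  if (!identical(dim(y_true), dim(y_prob)))
    stop_mtv("shape mismatch: y_true %s vs y_prob %s",
             paste(dim(y_true), collapse = "x"),
             paste(dim(y_prob), collapse = "x"))
  shp <- dim(y_true)
  C <- shp[length(shp)]
  nv <- prod(shp) / C
  Y <- matrix(y_true, nrow = nv, ncol = C)
  P <- matrix(y_prob, nrow = nv, ncol = C)
  pt <- pmin(pmax(rowSums(P * Y), cfg$eps), 1 - cfg$eps)
  wt <- as.numeric(Y %*% cfg$class_weights[seq_len(C)])
  mean(-wt * (1 - pt)^cfg$gamma * log(pt))
}

#' Distance-map regression loss
#'
#' Squared differences between the predicted and ground-truth normalized
#' distance maps, aggregated over all voxels and channels (mean by default,
#' sum via \code{cfg$distance_reduction}).
#'
#' @param d_pred predicted distance maps (sigmoid outputs), (D,H,W,3).
#' @param d_true ground-truth distance maps, same shape.
#' @param cfg a [loss_config()].
#' @return scalar loss; zero iff the inputs are equal.
#' @export
distance_map_loss <- function(d_pred, d_true, cfg = loss_config()) {
  if (!identical(dim(d_pred), dim(d_true)))
    stop_mtv("shape mismatch: d_pred %s vs d_true %s",
             paste(dim(d_pred), collapse = "x"),
             paste(dim(d_true), collapse = "x"))
  r <- d_pred - d_true
  if (cfg$distance_reduction == "mean") mean(r * r) else sum(r * r)
}

#' Combined multi-task loss
#'
#' \eqn{\lambda_1 L_{mask} + \lambda_2 L_{dist}}. Setting
#' \eqn{\lambda_2 = 0} gives the single-task (mask-only) limit used in
#' ablations; \eqn{\lambda_1 = 1, \lambda_2 = 0.1} is the down-weighted
#' auxiliary-task variant ("Model II").
#'
#' @param l_mask,l_dist finite scalar losses.
#' @param cfg a [loss_config()].
#' @return scalar.
#' @export
combined_loss <- function(l_mask, l_dist, cfg = loss_config()) {
  if (!is.finite(l_mask) || !is.finite(l_dist))
    stop_mtv("loss components must be finite (got %g, %g)", l_mask, l_dist)
  cfg$lambda1 * l_mask + cfg$lambda2 * l_dist
}
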