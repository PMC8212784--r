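# Shared fixtures built in code at test time.

# small phantom spec sized for fast tests
small_spec <- function(seed = 1L, ...) {
  phantom_spec(volume_shape = c(32L, 32L, 32L), subregion_radii = c(8, 5, 3),
               seed = seed, ...)
}

# random BraTS label volume
random_labels <- function(shp = c(6L, 6L, 6L), seed = 1L) {
  withr::with_seed(seed, {
    array(sample(c(0L, 1L, 2L, 4L), prod(shp), replace = TRUE,
                 prob = c(0.7, 0.1, 0.1, 0.1)), dim = shp)
  })
}

# random binary mask
random_mask <- function(shp, p = 0.3, seed = 1L) {
  withr::with_seed(seed, array(runif(prod(shp)) < p, dim = shp))
}

# brute-force distance from every voxel to the nearest TRUE voxel
brute_force_distance <- function(mask, spacing = c(1, 1, 1)) {
  shp <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  out <- array(Inf, dim = shp)
  if (nrow(idx) == 0) return(out)
  for (i in seq_len(shp[1])) for (j in seq_len(shp[2])) for (k in seq_len(shp[3])) {
    d2 <- ((i - idx[, 1]) * spacing[1])^2 + ((j - idx[, 2]) * spacing[2])^2 +
      ((k - idx[, 3]) * spacing[3])^2
    out[i, j, k] <- sqrt(min(d2))
  }
  out
}

# directed-percentile Hausdorff oracle built on the brute-force distances
brute_force_hd95 <- function(gt, pred, spacing = c(1, 1, 1), percentile = 95) {
  if (!any(gt) || !any(pred)) return(NA_real_)
  d_to_gt <- brute_force_distance(gt, spacing)
  d_to_pred <- brute_force_distance(pred, spacing)
  max(quantile(d_to_gt[pred], percentile / 100, names = FALSE),
      quantile(d_to_pred[gt], percentile / 100, names = FALSE))
}

# central finite-difference gradient of f at x, on a subset of entries
numeric_gradient <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, 0)
}
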