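#' Euclidean distance transform of a binary mask
#'
#' For every voxel, the exact Euclidean distance to the nearest \code{TRUE}
#' voxel, computed by the separable lower-envelope algorithm with anisotropic
#' voxel spacing. \code{Inf} everywhere when the mask is empty.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing (length 3), default unit.
#' @return numeric 3D array of distances.
#' @export
distance_to_mask <- function(mask, spacing = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L)
  sq <- .edt_squared(as.logical(mask), as.integer(dim(mask)),
                     as.numeric(spacing))
  sqrt(sq)
}

#' Ground-truth distance maps for the distance-regression decoder
#'
#' For each of the three foreground classes (necrosis, edema, enhancing
#' tumor), computes the interior Euclidean distance transform: 0 at every
#' voxel outside the class; inside the class, the distance to the nearest
#' non-class voxel. Each channel is then divided by its own maximum so the
#' deepest interior voxel maps to 1 — matching the (0,1) range of the
#' network's sigmoid-activated distance head. A class absent from the mask
#' yields an all-zero channel.
#'
#' @param mask a 4-channel one-hot mask (channels background, necrosis,
#'   edema, enhancing).
#' @param spacing voxel spacing used for the distances; default unit
#'   (isotropic voxel units).
#' @param normalize divide each channel by its maximum (default TRUE).
#' @return D x H x W x 3 array in [0, 1] (foreground channels only), class
#'   \code{distance_map_set}.
#' @export
ground_truth_distance_maps <- function(mask, spacing = c(1, 1, 1),
                                       normalize = TRUE) {
  shp <- dim(mask)
  stopifnot(length(shp) == 4L, shp[4] == 4L)
  out <- array(0, dim = c(shp[1:3], 3L))
  for (c in 1:3) {
    cls <- mask[, , , c + 1L] > 0
    if (!any(cls)) next
    if (all(cls)) { out[, , , c] <- 1; next }  # no non-class voxel anywhere
    d <- distance_to_mask(!cls, spacing)     # distance to nearest non-class voxel
    d[!cls] <- 0
    if (normalize) {
      m <- max(d)
      if (m > 0) d <- d / m
    }
    out[, , , c] <- d
  }
  structure(out, class = c("distance_map_set", "array"))
}
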