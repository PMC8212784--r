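#' Stack four modality volumes into a multimodal volume
#'
#' Combines the four co-registered MRI contrasts into one 4-channel volume
#' with fixed channel order FLAIR, T1, T1-CE, T2 (channel axis last), the
#' layout used throughout the pipeline.
#'
#' @param flair,t1,t1ce,t2 single-channel 3D arrays of identical shape.
#' @param spacing voxel spacing in mm (length 3).
#' @param affine optional 4 x 4 affine carried through NIfTI I/O.
#' @return object of class \code{multimodal_volume}: list with \code{data}
#'   (D x H x W x 4 array), \code{spacing}, \code{affine},
#'   \code{modalities}.
#' @export
stack_modalities <- function(flair, t1, t1ce, t2, spacing = c(1, 1, 1),
                             affine = NULL) {
  vols <- list(flair = flair, t1 = t1, t1ce = t1ce, t2 = t2)
  shapes <- lapply(vols, dim)
  if (any(vapply(shapes, length, 1L) != 3L))
    stop_mtv("all modalities must be 3D arrays")
  if (!all(vapply(shapes, identical, TRUE, shapes[[1]])))
    stop_mtv("modality shapes differ: %s",
             paste(vapply(shapes, function(s) paste(s, collapse = "x"), ""),
                   collapse = " vs "))
  data <- array(c(flair, t1, t1ce, t2), dim = c(shapes[[1]], 4L))
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine,
                 modalities = c("flair", "t1", "t1ce", "t2")),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("multimodal_volume: %dx%dx%d voxels, channels %s, spacing %s mm\n",
              d[1], d[2], d[3], paste(x$modalities, collapse = "/"),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' Z-score standardization of one modality
#'
#' \eqn{\hat X = (X - \bar X) / \sigma}, with mean and standard deviation
#' computed over the whole volume by default, or over nonzero (brain) voxels
#' only when \code{nonzero_only = TRUE}. A constant volume (zero sd) returns
#' all zeros with a warning.
#'
#' @param volume single-channel 3D array.
#' @param nonzero_only compute the statistics over nonzero voxels only; the
#'   transformation is still applied to every voxel.
#' @return standardized array of the same shape.
#' @export
zscore_normalize <- function(volume, nonzero_only = FALSE) {
  if (length(volume) == 0) stop_mtv("empty volume")
  vals <- if (nonzero_only) volume[volume != 0] else volume
  if (length(vals) < 2) {
    warning("too few voxels for standardization; returning zeros")
    return(array(0, dim = dim(volume)))
  }
  mu <- mean(vals)
  sigma <- sd(vals)
  if (sigma == 0) {
    warning("constant volume (zero standard deviation); returning zeros")
    return(array(0, dim = dim(volume)))
  }
  (volume - mu) / sigma
}

#' Z-score every channel of a multimodal volume
#'
#' @param volume a \code{multimodal_volume}.
#' @inheritParams zscore_normalize
#' @return a \code{multimodal_volume} with standardized channels.
#' @export
normalize_volume <- function(volume, nonzero_only = FALSE) {
  stopifnot(inherits(volume, "multimodal_volume"))
  for (c in 1:4)
    volume$data[, , , c] <- zscore_normalize(volume$data[, , , c], nonzero_only)
  volume
}

brats_labels <- c(0L, 1L, 2L, 4L)

validate_labels <- function(labels) {
  bad <- setdiff(unique(as.integer(labels)), brats_labels)
  if (length(bad) > 0)
    stop_mtv("label volume contains unexpected values: %s (allowed: 0, 1, 2, 4)",
             paste(sort(bad), collapse = ", "))
  invisible(labels)
}

#' One-hot encode a BraTS label volume
#'
#' Maps label values \{0, 1, 2, 4\} to binary channels \{0, 1, 2, 3\}:
#' channel 0 background, 1 necrosis, 2 edema, 3 enhancing tumor. Channels sum
#' to exactly 1 at every voxel.
#'
#' @param labels integer 3D array with values in \{0, 1, 2, 4\}.
#' @return D x H x W x 4 binary array (class \code{onehot_mask}).
#' @export
encode_labels_onehot <- function(labels) {
  validate_labels(labels)
  shp <- dim(labels)
  chan_of <- integer(5)                 # label value -> channel (1-based)
  chan_of[c(1L, 2L, 3L, 5L)] <- 1:4     # labels 0,1,2,4
  idx <- chan_of[as.integer(labels) + 1L]
  onehot <- array(0, dim = c(shp, 4L))
  nv <- prod(shp)
  onehot[seq_len(nv) + (idx - 1L) * nv] <- 1
  structure(onehot, class = c("onehot_mask", "array"))
}

#' Decode a one-hot mask back to BraTS labels
#'
#' Argmax over channels, then channel 3 maps back to label 4.
#'
#' @param onehot D x H x W x 4 array (binary or probabilities).
#' @return integer 3D label array with values in \{0, 1, 2, 4\}.
#' @export
decode_onehot <- function(onehot) {
  shp <- dim(onehot)
  stopifnot(length(shp) == 4L, shp[4] == 4L)
  nv <- prod(shp[1:3])
  m <- matrix(onehot, nrow = nv, ncol = 4L)
  ch <- max.col(m, ties.method = "first") - 1L   # lower channel wins ties
  labels <- brats_labels[ch + 1L]
  dim(labels) <- shp[1:3]
  labels
}

find_modality_file <- function(files, suffix) {
  pat <- sprintf("_%s\\.nii(\\.gz)?$", suffix)
  hit <- grep(pat, files, value = TRUE)
  if (length(hit) == 0) return(NULL)
  hit[1]
}

#' Read a BraTS-layout case directory
#'
#' Expects the four modality files \code{*_flair}, \code{*_t1}, \code{*_t1ce},
#' \code{*_t2} (NIfTI, optionally gzipped) and an optional \code{*_seg}
#' segmentation. Channels are returned in the fixed order FLAIR, T1, T1-CE,
#' T2 regardless of directory listing order; label values are validated
#' against \{0, 1, 2, 4\}.
#'
#' @param case_dir path to the case directory.
#' @return list with \code{image} (a \code{multimodal_volume}) and
#'   \code{labels} (integer array, or NULL for validation-style cases without
#'   ground truth).
#' @export
read_case <- function(case_dir) {
  if (!dir.exists(case_dir)) stop_mtv("case directory '%s' not found", case_dir)
  files <- list.files(case_dir, full.names = TRUE)
  mods <- c("flair", "t1", "t1ce", "t2")
  paths <- lapply(mods, function(m) find_modality_file(files, m))
  missing <- mods[vapply(paths, is.null, TRUE)]
  if (length(missing) > 0)
    stop_mtv("case '%s' is missing modality file(s): %s",
             basename(case_dir), paste(missing, collapse = ", "))
  imgs <- lapply(paths, function(p) {
    v <- RNifti::readNifti(p)
    array(as.numeric(v), dim = dim(v))
  })
  hdr <- RNifti::niftiHeader(RNifti::readNifti(paths[[1]]))
  spacing <- hdr$pixdim[2:4]
  img <- stack_modalities(imgs[[1]], imgs[[2]], imgs[[3]], imgs[[4]],
                          spacing = spacing)
  seg_path <- find_modality_file(files, "seg")
  labels <- NULL
  if (!is.null(seg_path)) {
    seg <- RNifti::readNifti(seg_path)
    labels <- array(as.integer(round(as.numeric(seg))), dim = dim(seg))
    validate_labels(labels)
  }
  list(image = img, labels = labels)
}

#' Write a case in BraTS layout
#'
#' @param image a \code{multimodal_volume}.
#' @param labels integer label array or NULL.
#' @param dir output directory (created if needed).
#' @param case_id file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_case <- function(image, labels, dir, case_id) {
  stopifnot(inherits(image, "multimodal_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mods <- image$modalities
  paths <- character(0)
  for (m in seq_along(mods)) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", case_id, mods[m]))
    RNifti::writeNifti(RNifti::asNifti(image$data[, , , m],
                                       pixdim = image$spacing), p)
    paths <- c(paths, p)
  }
  if (!is.null(labels)) {
    p <- file.path(dir, sprintf("%s_seg.nii.gz", case_id))
    RNifti::writeNifti(RNifti::asNifti(labels, pixdim = image$spacing,
                                       datatype = "int16"), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

grid_starts <- function(n, patch, stride) {
  s <- unique(c(seq(0L, n - patch, by = stride), n - patch))
  as.integer(s)
}

#' Extract congruent image/mask patches
#'
#' Two sampling modes. \code{grid}: a deterministic overlapping tiling whose
#' patches cover every voxel at least once (the inference path). \code{random}:
#' seeded uniform patch origins with a configurable fraction of draws forced
#' to contain at least one tumor voxel when the mask has any (the training
#' path, biased against background-only patches).
#'
#' @param image a \code{multimodal_volume}.
#' @param mask a one-hot mask congruent with \code{image} (may be NULL in
#'   grid mode).
#' @param patch_shape voxel triple, each \code{<=} the volume shape.
#' @param mode \code{"grid"} or \code{"random"}.
#' @param stride grid stride (defaults to \code{patch_shape}, i.e. abutting
#'   tiles plus a final flush tile per axis).
#' @param n_patches number of random patches.
#' @param tumor_fraction fraction of random patches forced to intersect tumor
#'   (non-background mask voxels), when any exist.
#' @param seed seed for random mode.
#' @return list of patch pairs: each has \code{image}, \code{mask} (or NULL),
#'   and \code{origin}, the 0-based voxel offset in the parent volume.
#' @export
extract_patches <- function(image, mask = NULL, patch_shape,
                            mode = c("grid", "random"), stride = NULL,
                            n_patches = 1L, tumor_fraction = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(image, "multimodal_volume"))
  shp <- dim(image$data)[1:3]
  patch_shape <- as.integer(patch_shape)
  if (any(patch_shape > shp))
    stop_mtv("patch shape (%s) exceeds volume shape (%s)",
             paste(patch_shape, collapse = "x"), paste(shp, collapse = "x"))
  if (!is.null(mask)) stopifnot(identical(dim(mask)[1:3], shp))

  crop <- function(origin) {
    i1 <- origin + 1L; i2 <- origin + patch_shape
    list(image = image$data[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3], , drop = FALSE],
         mask = if (is.null(mask)) NULL else
           mask[i1[1]:i2[1], i1[2]:i2[2], i1[3]:i2[3], , drop = FALSE],
         origin = origin)
  }

  if (mode == "grid") {
    if (is.null(stride)) stride <- patch_shape
    stride <- as.integer(rep_len(stride, 3L))
    starts <- lapply(1:3, function(a) grid_starts(shp[a], patch_shape[a], stride[a]))
    origins <- expand.grid(starts[[1]], starts[[2]], starts[[3]])
    return(lapply(seq_len(nrow(origins)),
                  function(i) crop(as.integer(origins[i, ]))))
  }

  # random mode
  tumor_idx <- NULL
  if (!is.null(mask)) {
    fg <- which(apply(mask[, , , -1, drop = FALSE] > 0, 1:3, any))
    if (length(fg) > 0) tumor_idx <- arrayInd(fg, shp) - 1L  # 0-based
  }
  with_seed(seed, {
    lapply(seq_len(n_patches), function(i) {
      force_tumor <- !is.null(tumor_idx) && runif(1) <= tumor_fraction
      if (force_tumor) {
        t0 <- tumor_idx[sample.int(nrow(tumor_idx), 1L), ]
        lo <- pmax(0L, t0 - patch_shape + 1L)
        hi <- pmin(t0, shp - patch_shape)
        origin <- as.integer(lo + floor(runif(3) * (hi - lo + 1L)))
      } else {
        origin <- as.integer(floor(runif(3) * (shp - patch_shape + 1L)))
      }
      crop(origin)
    })
  })
}
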