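#' Specification of a synthetic multimodal brain-tumor phantom
#'
#' Defines the geometry, contrast and noise of a synthetic BraTS-like case:
#' a brain ellipsoid on a zero background, optionally carrying a nested tumor
#' (edema shell, enhancing rim, necrotic core) rendered in the four standard
#' MRI modalities (FLAIR, T1, T1-CE, T2) with modality-dependent tissue
#' contrast. Phantoms reproduce the BraTS label convention
#' \{0 background, 1 necrosis, 2 edema, 4 enhancing tumor\} and the nesting
#' WT (1,2,4) \eqn{\supseteq} TC (1,4) \eqn{\supseteq} ET (4).
#'
#' Tumor subregions are concentric ellipsoids sharing one center and one
#' per-axis anisotropy, so the nesting is exact by construction: necrosis is
#' the inner core (radius \code{subregion_radii[3]}), the enhancing rim lies
#' between the inner and core radii (\code{subregion_radii[2]}), and edema
#' fills out to \code{subregion_radii[1]}.
#'
#' @param volume_shape integer triple, voxel grid size (default 64^3).
#' @param brain_radius_fraction brain ellipsoid semi-axes as a fraction of the
#'   half-grid, in (0, 1].
#' @param tumor_present logical; if FALSE the label volume is identically 0.
#' @param subregion_radii strictly decreasing voxel radii
#'   (edema, tumor core, necrotic inner core).
#' @param modality_contrast_table 4 x 4 numeric matrix of mean intensities,
#'   rows \code{c("flair","t1","t1ce","t2")}, columns
#'   \code{c("brain","edema","necrosis","enhancing")}. Background is always 0
#'   (skull-stripped convention). Defaults make edema bright in FLAIR/T2 and
#'   the enhancing rim bright in T1-CE.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param jitter fractional per-axis radius jitter applied jointly to all
#'   three subregions (keeps them nested).
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class \code{phantom_spec}.
#' @seealso [generate_case()], [generate_dataset()]
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 64L),
                         brain_radius_fraction = 0.85,
                         tumor_present = TRUE,
                         subregion_radii = c(12, 8, 5),
                         modality_contrast_table = default_contrast_table(),
                         noise_sd = 10,
                         jitter = 0.25,
                         seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L))
    stop_mtv("volume_shape must be three integers >= 8")
  if (brain_radius_fraction <= 0 || brain_radius_fraction > 1)
    stop_mtv("brain_radius_fraction must lie in (0, 1]")
  if (length(subregion_radii) != 3L || any(diff(subregion_radii) >= 0))
    stop_mtv("subregion_radii must be three strictly decreasing radii, got (%s)",
             paste(subregion_radii, collapse = ", "))
  brain_r <- brain_radius_fraction * min(volume_shape) / 2
  if (subregion_radii[1] * (1 + jitter) >= brain_r)
    stop_mtv("edema radius %.1f (with jitter) does not fit inside brain radius %.1f",
             subregion_radii[1], brain_r)
  tab <- modality_contrast_table
  if (!is.matrix(tab) || !identical(dim(tab), c(4L, 4L)))
    stop_mtv("modality_contrast_table must be a 4 x 4 matrix")
  rownames(tab) <- c("flair", "t1", "t1ce", "t2")
  colnames(tab) <- c("brain", "edema", "necrosis", "enhancing")
  structure(list(volume_shape = volume_shape,
                 brain_radius_fraction = brain_radius_fraction,
                 tumor_present = isTRUE(tumor_present),
                 subregion_radii = as.numeric(subregion_radii),
                 modality_contrast_table = tab,
                 noise_sd = noise_sd, jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom contrast table
#'
#' Mean intensities (arbitrary units) per modality and tissue. The values are
#' conventions chosen to reproduce the qualitative contrast radiologists rely
#' on: edema hyperintense in FLAIR and T2, the enhancing rim hyperintense in
#' contrast-enhanced T1, necrosis dark in T1/T1-CE.
#'
#' @return 4 x 4 numeric matrix (modalities x tissues).
#' @export
default_contrast_table <- function() {
  tab <- rbind(flair = c(100, 180,  70, 120),
               t1    = c(100,  80,  60, 110),
               t1ce  = c(100,  90,  50, 200),
               t2    = c(100, 190, 140, 120))
  colnames(tab) <- c("brain", "edema", "necrosis", "enhancing")
  tab
}

#' Generate one synthetic multimodal case
#'
#' Renders the phantom described by \code{spec}: a label volume with BraTS
#' values \{0, 1, 2, 4\} and a 4-channel intensity volume (FLAIR, T1, T1-CE,
#' T2) equal to per-tissue mean intensity plus i.i.d. Gaussian noise inside
#' the brain; voxels outside the brain ellipsoid are exactly 0.
#'
#' @param spec a [phantom_spec()].
#' @return list with \code{image} (a \code{multimodal_volume}) and
#'   \code{labels} (integer 3D array).
#' @export
generate_case <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    shp <- spec$volume_shape
    ctr <- (shp + 1) / 2
    brain_r <- spec$brain_radius_fraction * shp / 2   # per-axis semi-axes

    ax <- lapply(1:3, function(i) seq_len(shp[i]) - ctr[i])
    # squared normalized brain coordinates, recycled over the grid
    g1 <- array(ax[[1]], dim = shp)
    g2 <- array(rep(ax[[2]], each = shp[1]), dim = shp)
    g3 <- array(rep(ax[[3]], each = shp[1] * shp[2]), dim = shp)
    brain <- (g1 / brain_r[1])^2 + (g2 / brain_r[2])^2 + (g3 / brain_r[3])^2 <= 1

    labels <- array(0L, dim = shp)
    if (spec$tumor_present) {
      aniso <- runif(3, 1 - spec$jitter, 1 + spec$jitter)
      r_ede <- spec$subregion_radii[1] * aniso
      # center such that the jittered edema ellipsoid stays inside the brain
      margin <- pmax(brain_r - r_ede - 1, 0)
      tc <- ctr + runif(3, -1, 1) * margin * 0.8
      d1 <- g1 + ctr[1] - tc[1]; d2 <- g2 + ctr[2] - tc[2]; d3 <- g3 + ctr[3] - tc[3]
      rho <- sqrt((d1 / aniso[1])^2 + (d2 / aniso[2])^2 + (d3 / aniso[3])^2)
      labels[rho <= spec$subregion_radii[1]] <- 2L  # edema
      labels[rho <= spec$subregion_radii[2]] <- 4L  # enhancing rim
      labels[rho <= spec$subregion_radii[3]] <- 1L  # necrotic core
      labels[!brain] <- 0L
    }

    tab <- spec$modality_contrast_table
    tissue <- array(1L, dim = shp)              # 1 brain, 2 edema, 3 necrosis, 4 enhancing
    tissue[labels == 2L] <- 2L
    tissue[labels == 1L] <- 3L
    tissue[labels == 4L] <- 4L
    chans <- vector("list", 4)
    for (m in 1:4) {
      vol <- tab[m, ][tissue]
      dim(vol) <- shp
      vol <- vol + rnorm(length(vol), sd = spec$noise_sd)
      vol[!brain] <- 0
      chans[[m]] <- vol
    }
    img <- stack_modalities(chans[[1]], chans[[2]], chans[[3]], chans[[4]])
    list(image = img, labels = labels)
  })
}

#' Generate a BraTS-layout dataset of phantom cases
#'
#' Writes one directory per case containing the five NIfTI files of the BraTS
#' naming convention (\code{<case>_flair.nii.gz}, \code{_t1}, \code{_t1ce},
#' \code{_t2}, \code{_seg}). Per-case seeds are drawn deterministically from
#' the master seed, so the whole dataset is a pure function of (spec, seed).
#'
#' @param n_cases number of cases to generate.
#' @param root output directory; refused if it exists non-empty unless
#'   \code{overwrite = TRUE}.
#' @param spec a [phantom_spec()] used as template (its \code{seed} field is
#'   replaced per case).
#' @param seed master seed.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param prefix case-name prefix.
#' @return data.frame manifest with columns \code{case}, \code{dir},
#'   \code{seed}.
#' @export
generate_dataset <- function(n_cases, root, spec = phantom_spec(), seed = 1L,
                             overwrite = FALSE, prefix = "phantom") {
  if (dir.exists(root) && length(list.files(root)) > 0 && !overwrite)
    stop_mtv("output directory '%s' exists and is not empty (use overwrite = TRUE)", root)
  if (n_cases == 0L)
    return(data.frame(case = character(), dir = character(), seed = integer()))
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_cases))
  ids <- sprintf("%s_%03d", prefix, seq_len(n_cases))
  dirs <- file.path(root, ids)
  for (i in seq_len(n_cases)) {
    cs <- spec
    cs$seed <- case_seeds[i]
    case <- generate_case(cs)
    dir.create(dirs[i], showWarnings = FALSE)
    write_case(case$image, case$labels, dirs[i], ids[i])
  }
  data.frame(case = ids, dir = dirs, seed = case_seeds,
             stringsAsFactors = FALSE)
}
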