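# Synthetic rodent-head phantoms: paired (biased source, bias-free
# brain-extracted target, brain mask) volumes that emulate surface-coil
# GE-EPI and SE-EPI acquisitions. The head is a smoothly perturbed ellipsoid
# with a white-matter core, gray-matter rim and two CSF pockets, wrapped in a
# scalp/muscle shell (brighter in SE-EPI), optionally with an external
# reference object above the head (SE-EPI only). The coil sensitivity is the
# normalized on-axis field magnitude of a circular loop placed dorsal to the
# brain.

LABEL_WM <- 1L
LABEL_GM <- 2L
LABEL_CSF <- 3L
LABEL_SHELL <- 4L
LABEL_EXT <- 5L

#' Specification of a synthetic head phantom
#'
#' All geometry is in voxel units; intensities are relative (arbitrary) units.
#' Defaults mimic a mouse GE-EPI protocol on a 64x64x16 grid with
#' 0.3x0.3x0.5 mm voxels; `modality = "SE"` brightens the scalp/muscle shell
#' and adds an external reference object above the head, as in spin-echo
#' acquisitions of the rat.
#'
#' @param grid_shape Integer length-3 voxel counts.
#' @param voxel_size Numeric length-3, mm per axis.
#' @param modality `"GE"` or `"SE"`.
#' @param brain_axes Ellipsoid semi-axes of the brain, voxels.
#' @param brain_center Brain center in voxel coordinates (default: mid-plane
#'   in x/y, slightly ventral in z to leave room for the coil side).
#' @param shell_thickness Scalp/muscle shell thickness, voxels (0 disables).
#' @param shell_intensity Relative shell intensity; default 0.45 for GE and
#'   0.9 for SE (scalp and muscle are brighter on spin-echo).
#' @param tissue_intensities Named vector with `WM`, `GM`, `CSF` relative
#'   intensities.
#' @param external_phantom Logical; only allowed for SE.
#' @param phantom_center,phantom_radius,phantom_intensity Geometry/intensity
#'   of the external reference object (voxel units). Reference phantoms are
#'   water/saline, so the default intensity equals the CSF value: on
#'   T2-weighted spin-echo EPI nothing much exceeds free water.
#' @param noise_sigma SD of the additive Gaussian noise on the source, in the
#'   same relative units as the intensities.
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 16L),
                         voxel_size = c(0.3, 0.3, 0.5),
                         modality = c("GE", "SE"),
                         brain_axes = c(20, 24, 4),
                         brain_center = NULL,
                         shell_thickness = 1.5,
                         shell_intensity = NULL,
                         tissue_intensities = c(WM = 0.8, GM = 1.0, CSF = 1.4),
                         external_phantom = NULL,
                         phantom_center = NULL,
                         phantom_radius = c(6, 6, 1.2),
                         phantom_intensity = 1.4,
                         noise_sigma = 0.03,
                         seed = 1L) {
  modality <- match.arg(modality)
  grid_shape <- as.integer(grid_shape)
  if (is.null(brain_center)) brain_center <- grid_shape * c(0.5, 0.5, 0.45)
  if (is.null(shell_intensity)) {
    shell_intensity <- if (modality == "SE") 0.9 else 0.45
  }
  if (is.null(external_phantom)) external_phantom <- modality == "SE"
  if (is.null(phantom_center)) {
    phantom_center <- c(grid_shape[1:2] * 0.5, grid_shape[3] * 0.9)
  }
  spec <- structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                         modality = modality, brain_axes = brain_axes,
                         brain_center = brain_center,
                         shell_thickness = shell_thickness,
                         shell_intensity = shell_intensity,
                         tissue_intensities = tissue_intensities,
                         external_phantom = external_phantom,
                         phantom_center = phantom_center,
                         phantom_radius = phantom_radius,
                         phantom_intensity = phantom_intensity,
                         noise_sigma = noise_sigma,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape < 4)) {
      stop("grid_shape must be 3 voxel counts >= 4")
    }
    if (any(brain_axes <= 0)) stop("brain ellipsoid semi-axes must be > 0")
    if (any(tissue_intensities < 0) || shell_intensity < 0 ||
        phantom_intensity < 0) {
      stop("intensities must be >= 0")
    }
    if (!all(c("WM", "GM", "CSF") %in% names(tissue_intensities))) {
      stop("tissue_intensities must name WM, GM and CSF")
    }
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    if (shell_thickness < 0) stop("shell_thickness must be >= 0")
    if (external_phantom && modality == "GE") {
      stop("external reference phantom is only present in SE acquisitions")
    }
    outer_r <- brain_axes + shell_thickness
    lo <- brain_center - outer_r
    hi <- brain_center + outer_r
    bad <- which(lo < 0.5 | hi > grid_shape + 0.5)
    if (length(bad) > 0) {
      stop(sprintf(
        "head geometry exceeds the grid along axis %d (extent %.1f..%.1f on %d voxels)",
        bad[1], lo[bad[1]], hi[bad[1]], grid_shape[bad[1]]))
    }
    if (external_phantom) {
      plo <- phantom_center - phantom_radius
      phi <- phantom_center + phantom_radius
      bad <- which(plo < 0.5 | phi > grid_shape + 0.5)
      if (length(bad) > 0) {
        stop(sprintf("external phantom exceeds the grid along axis %d", bad[1]))
      }
    }
  })
  invisible(spec)
}

#' Surface-coil sensitivity profile
#'
#' A single receive loop of radius `radius_mm` centred at `center` (voxel
#' coordinates, typically dorsal to -- possibly outside -- the grid). The
#' sensitivity follows the normalized on-axis field magnitude of a circular
#' current loop, `s(d) = (1 + (d/a)^2)^(-3/2)`, where `d` is the distance
#' from the loop center in mm, floored at `floor` so the field stays in
#' `[floor, 1]`.
#'
#' @param center Loop center, voxel coordinates (length 3).
#' @param radius_mm Loop radius in mm.
#' @param floor Minimum relative sensitivity, in (0, 1]; `floor = 1` gives a
#'   degenerate uniform coil.
#' @return A `coil_profile` list.
#' @export
coil_profile <- function(center = c(32.5, 32.5, 14.5), radius_mm = 5,
                         floor = 0.1) {
  stopifnot(length(center) == 3L, radius_mm > 0, floor > 0, floor <= 1)
  structure(list(center = center, radius_mm = radius_mm, floor = floor),
            class = "coil_profile")
}

#' Place a surface loop on the head of a phantom
#'
#' Surface receive coils are sized to the head and sit essentially on the
#' scalp: the loop is centred laterally on the brain, its radius defaults to
#' 0.9x the head depth (dorsal-ventral extent including the shell) and its
#' plane to 0.18x the head depth above the head apex. For the default
#' mouse-like head these rules reproduce a ~5 mm-radius loop with a ~1 mm
#' standoff, close to the real 10-mm mouse coil, and they scale geometrically
#' for smaller test worlds. The close placement produces the
#' characteristic strong dorsal-to-ventral sensitivity gradient of
#' single-loop rodent coils.
#'
#' @param spec A [phantom_spec()].
#' @param standoff_mm Gap between scalp apex and loop plane, mm.
#' @param radius_mm Loop radius, mm.
#' @param floor Minimum relative sensitivity.
#' @return A [coil_profile()].
#' @export
coil_for_spec <- function(spec, standoff_mm = NULL, radius_mm = NULL,
                          floor = 0.1) {
  head_d <- 2 * (spec$brain_axes[3] + spec$shell_thickness) *
    spec$voxel_size[3]
  if (is.null(radius_mm)) radius_mm <- 0.9 * head_d
  if (is.null(standoff_mm)) standoff_mm <- 0.18 * head_d
  apex <- spec$brain_center[3] + spec$brain_axes[3] + spec$shell_thickness
  coil_profile(center = c(spec$brain_center[1:2],
                          apex + standoff_mm / spec$voxel_size[3]),
               radius_mm = radius_mm, floor = floor)
}

# Smooth pseudo-random field (sum of low-frequency cosines), roughly unit
# scale; used to perturb the ellipsoid surface so the brain is not a perfect
# quadric. Draws from the current RNG stream.
smooth_field <- function(grid_shape, n_modes = 6L) {
  ix <- seq_len(grid_shape[1]) / grid_shape[1]
  iy <- seq_len(grid_shape[2]) / grid_shape[2]
  iz <- seq_len(grid_shape[3]) / grid_shape[3]
  field <- array(0, dim = grid_shape)
  for (m in seq_len(n_modes)) {
    k <- runif(3, 0.5, 2)
    phi <- runif(3, 0, 2 * pi)
    fx <- cos(2 * pi * k[1] * ix + phi[1])
    fy <- cos(2 * pi * k[2] * iy + phi[2])
    fz <- cos(2 * pi * k[3] * iz + phi[3])
    field <- field + outer(outer(fx, fy), fz)
  }
  field / sqrt(n_modes)
}

# Squared ellipsoid coordinate: <=1 inside the ellipsoid.
ellipsoid_q2 <- function(grid_shape, center, axes) {
  nx <- (seq_len(grid_shape[1]) - center[1]) / axes[1]
  ny <- (seq_len(grid_shape[2]) - center[2]) / axes[2]
  nz <- (seq_len(grid_shape[3]) - center[3]) / axes[3]
  outer(outer(nx^2, ny^2, `+`), nz^2, `+`)
}

# Separable "same" Gaussian blur used for partial-volume softening.
blur_same <- function(arr, sigma = 0.6, half = 2L) {
  kern <- dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  out <- arr
  for (axis in 1:3) out <- conv_axis(out, kern, axis, mode = "same")
  out
}

#' Generate a labeled head phantom
#'
#' Deterministic given `spec$seed`. Labels: 0 background, 1 WM, 2 GM, 3 CSF,
#' 4 scalp/muscle shell, 5 external phantom. The intensity volume maps labels
#' to their relative intensities and softens compartment boundaries by a
#' partial-volume blur confined to the head support (so background stays
#' exactly zero and the brain mask equals the nonzero support when the shell
#' and external phantom are absent).
#'
#' @param spec A [phantom_spec()].
#' @return A `labeled_volume`: list with `intensity`, `labels`, `brain_mask`
#'   (3D arrays) and the `spec`.
#' @export
make_brain_phantom <- function(spec) {
  validate_phantom_spec(spec)
  gs <- spec$grid_shape
  field <- with_seed_local(spec$seed, smooth_field(gs))
  q2 <- ellipsoid_q2(gs, spec$brain_center, spec$brain_axes)
  q2 <- q2 * (1 + 0.06 * field)
  brain <- q2 <= 1
  labels <- array(0L, dim = gs)
  labels[brain & q2 > 0.55^2] <- LABEL_GM
  labels[brain & q2 <= 0.55^2] <- LABEL_WM
  # two CSF pockets (lateral-ventricle-like) at fixed fractional positions
  for (sgn in c(-1, 1)) {
    csf_center <- spec$brain_center +
      c(sgn * 0.3 * spec$brain_axes[1], 0, 0.2 * spec$brain_axes[3])
    q2c <- ellipsoid_q2(gs, csf_center, 0.2 * spec$brain_axes)
    labels[q2c <= 1 & brain] <- LABEL_CSF
  }
  if (spec$shell_thickness > 0) {
    q2s <- ellipsoid_q2(gs, spec$brain_center,
                        spec$brain_axes + spec$shell_thickness)
    q2s <- q2s * (1 + 0.06 * field)
    labels[q2s <= 1 & !brain] <- LABEL_SHELL
  }
  if (spec$external_phantom) {
    q2p <- ellipsoid_q2(gs, spec$phantom_center, spec$phantom_radius)
    ext <- q2p <= 1
    if (any(ext & labels > 0L)) {
      stop("external phantom overlaps the head; move it or shrink the shell")
    }
    labels[ext] <- LABEL_EXT
  }
  lut <- c(0, spec$tissue_intensities[["WM"]], spec$tissue_intensities[["GM"]],
           spec$tissue_intensities[["CSF"]], spec$shell_intensity,
           spec$phantom_intensity)
  intensity <- array(lut[labels + 1L], dim = gs)
  support <- array(as.numeric(labels > 0L), dim = gs)
  num <- blur_same(intensity * support)
  den <- blur_same(support)
  smoothed <- array(0, dim = gs)
  inside <- support > 0
  smoothed[inside] <- num[inside] / den[inside]
  brain_mask <- array(labels %in% c(LABEL_WM, LABEL_GM, LABEL_CSF), dim = gs)
  structure(list(intensity = smoothed, labels = labels,
                 brain_mask = brain_mask, spec = spec),
            class = "labeled_volume")
}

#' Multiplicative coil-sensitivity (bias) field
#'
#' Evaluates `b(r) = floor + (1 - floor) * s(d(r))` on the grid, where `d` is
#' the mm distance from the loop center and `s` the normalized loop falloff
#' (see [coil_profile()]). Values lie in `[floor, 1]`, equal 1 at the loop
#' center and decrease monotonically with distance.
#'
#' @param profile A [coil_profile()].
#' @param grid_shape Integer length-3 voxel counts.
#' @param voxel_size Numeric length-3 mm per axis (default 1 mm isotropic, so
#'   distances are in voxel units).
#' @return 3D array, the bias field.
#' @export
#' @examples
#' b <- make_coil_bias(coil_profile(c(1, 1, 1), radius_mm = 10, floor = 0.2),
#'                     c(21, 1, 1))
#' b[11, 1, 1] # 0.2 + 0.8 / 2^1.5, at distance a
make_coil_bias <- function(profile, grid_shape, voxel_size = c(1, 1, 1)) {
  stopifnot(inherits(profile, "coil_profile"), length(grid_shape) == 3L)
  dx2 <- ((seq_len(grid_shape[1]) - profile$center[1]) * voxel_size[1])^2
  dy2 <- ((seq_len(grid_shape[2]) - profile$center[2]) * voxel_size[2])^2
  dz2 <- ((seq_len(grid_shape[3]) - profile$center[3]) * voxel_size[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  s <- (1 + d2 / profile$radius_mm^2)^(-1.5)
  profile$floor + (1 - profile$floor) * s
}

#' Generate one source/target training pair
#'
#' The source is the full-head intensity multiplied by the coil bias field
#' plus additive Gaussian noise (clipped at 0); the target is the unbiased,
#' noise-free intensity restricted to the brain mask (exactly zero elsewhere)
#' -- i.e. the ideal inhomogeneity-corrected, brain-extracted image.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param profile A [coil_profile()].
#' @return An `image_pair`: list with `source`, `target`, `brain_mask`,
#'   `modality`, `spec`, `profile`.
#' @export
make_pair <- function(spec, profile = coil_for_spec(spec)) {
  ph <- make_brain_phantom(spec)
  bias <- make_coil_bias(profile, spec$grid_shape, spec$voxel_size)
  source <- ph$intensity * bias
  if (spec$noise_sigma > 0) {
    noise <- with_seed_local(derive_seed(spec$seed, "noise"),
                             rnorm(length(source), sd = spec$noise_sigma))
    source <- source + array(noise, dim = spec$grid_shape)
  }
  source <- pmax(source, 0)
  target <- ph$intensity * ph$brain_mask
  structure(list(source = source, target = target,
                 brain_mask = ph$brain_mask, modality = spec$modality,
                 spec = spec, profile = profile),
            class = "image_pair")
}

jitter_spec <- function(base, modality, seed) {
  # per-pair anatomical/intensity/coil variability; draws from current stream
  axes <- base$brain_axes * runif(3, 0.92, 1.08)
  tis <- base$tissue_intensities * runif(3, 0.9, 1.1)
  shell_int <- (if (modality == "SE") 0.9 else 0.45) * runif(1, 0.9, 1.1)
  center <- base$brain_center + runif(3, -0.06, 0.06) * base$brain_axes
  spec <- phantom_spec(grid_shape = base$grid_shape,
                       voxel_size = base$voxel_size,
                       modality = modality, brain_axes = axes,
                       brain_center = center,
                       shell_thickness = base$shell_thickness,
                       shell_intensity = shell_int,
                       tissue_intensities = tis,
                       phantom_center = base$phantom_center,
                       phantom_radius = base$phantom_radius,
                       phantom_intensity = base$phantom_intensity,
                       noise_sigma = base$noise_sigma, seed = seed)
  head_d <- 2 * (spec$brain_axes[3] + spec$shell_thickness) *
    spec$voxel_size[3]
  profile <- coil_for_spec(spec,
                           standoff_mm = 0.18 * head_d * runif(1, 0.8, 1.3),
                           radius_mm = 0.9 * head_d * runif(1, 0.9, 1.1))
  profile$center[1:2] <- profile$center[1:2] +
    runif(2, -0.1, 0.1) * spec$brain_axes[1:2]
  list(spec = spec, profile = profile)
}

#' Generate a paired phantom dataset with a train/test split
#'
#' Per-pair anatomy, intensities and coil placement are jittered from seeded
#' RNG; the test set (`max(1, round(n * test_fraction))` pairs) is drawn at
#' random. Deterministic given `seed`.
#'
#' @param n_ge,n_se Number of GE-EPI-like and SE-EPI-like pairs.
#' @param test_fraction Proportion held out for testing (0 < f < 1).
#' @param seed Master seed for jitter, per-pair phantoms and the split.
#' @param base_spec Template [phantom_spec()] providing grid, voxel size,
#'   shell thickness and noise level.
#' @return A `phantom_dataset`: list with `pairs` (list of `image_pair`),
#'   `split` (character vector `"train"`/`"test"`), `composition` (tibble of
#'   counts per modality and split) and `seed`.
#' @export
make_dataset <- function(n_ge, n_se, test_fraction = 0.1, seed = 1L,
                         base_spec = phantom_spec()) {
  n <- n_ge + n_se
  if (n < 2) stop("need at least 2 pairs to split into train and test")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be strictly between 0 and 1")
  }
  modalities <- c(rep("GE", n_ge), rep("SE", n_se))
  pairs <- with_seed_local(derive_seed(seed, "jitter"), {
    lapply(seq_len(n), function(i) {
      jp <- jitter_spec(base_spec, modalities[i],
                        seed = derive_seed(seed, paste0("pair", i)))
      make_pair(jp$spec, jp$profile)
    })
  })
  n_test <- max(1L, round(n * test_fraction))
  if (n_test >= n) stop("test split would leave no training pairs")
  test_idx <- with_seed_local(derive_seed(seed, "split"),
                              sample(n, n_test))
  split <- rep("train", n)
  split[test_idx] <- "test"
  composition <- dplyr::count(
    tibble(modality = modalities, split = split),
    .data$modality, .data$split, name = "n")
  structure(list(pairs = pairs, split = split, composition = composition,
                 seed = as.integer(seed)),
            class = "phantom_dataset")
}

#' Extract the train or test pairs of a dataset
#'
#' @param dataset A `phantom_dataset`.
#' @param which `"train"` or `"test"`.
#' @return List of `image_pair`s.
#' @export
dataset_pairs <- function(dataset, which = c("train", "test")) {
  which <- match.arg(which)
  dataset$pairs[dataset$split == which]
}

#' Write an image pair as NIfTI files plus a JSON sidecar
#'
#' Writes `<prefix>_source.nii.gz`, `<prefix>_target.nii.gz`,
#' `<prefix>_mask.nii.gz` (float32, voxel size in the header) and
#' `<prefix>.json` recording the phantom specification.
#'
#' @param pair An `image_pair`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param split Optional split tag recorded in the sidecar.
#' @return Character vector of the files written, invisibly.
#' @export
write_pair <- function(pair, dir, prefix, split = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vs <- pair$spec$voxel_size
  files <- file.path(dir, paste0(prefix, c("_source.nii.gz",
                                           "_target.nii.gz",
                                           "_mask.nii.gz", ".json")))
  write_volume(pair$source, files[1], vs)
  write_volume(pair$target, files[2], vs)
  write_volume(array(as.numeric(pair$brain_mask), dim = dim(pair$brain_mask)),
               files[3], vs)
  side <- unclass(pair$spec)
  side$tissue_intensities <- as.list(side$tissue_intensities)
  side$split <- split
  jsonlite::write_json(side, files[4], auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' @rdname write_pair
#' @param dataset A `phantom_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  files <- unlist(lapply(seq_along(dataset$pairs), function(i) {
    write_pair(dataset$pairs[[i]], dir, sprintf("pair%03d", i),
               split = dataset$split[i])
  }))
  invisible(files)
}
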