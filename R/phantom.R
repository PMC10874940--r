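#' Define a 3-D image grid
#'
#' Light-weight grid descriptor used for all volumes in the package. World
#' coordinates of voxel `(i, j, k)` (1-based) are
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param spacing Voxel size per axis in mm (length 1 or 3).
#' @param origin World coordinate of the first voxel (length 3, mm).
#' @return An object of class `grid3d`.
#' @export
grid3d <- function(spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be positive and finite", call. = FALSE)
  if (any(!is.finite(origin)))
    stop("grid origin must be finite", call. = FALSE)
  structure(list(spacing = spacing, origin = origin), class = "grid3d")
}

#' Specify a synthetic bAVM imaging phantom
#'
#' A phantom emulates the inputs of the automated segmentation: a T2-weighted
#' intensity volume with three tissue classes inside a nidus (flow-void vessel
#' darkest, brain parenchyma intermediate, CSF brightest) and a co-registered
#' dose volume whose margin-dose isosurface coincides with the nidus boundary.
#'
#' Defaults follow the reported cohort medians: tissue proportions
#' 30.9 / 52.2 / 16.8 percent (vessel / brain / CSF; these marginal medians
#' sum to 99.9, so the default rescales them to a 100% composition,
#' preserving their ratios), margin dose 17.5 Gy, maximum dose 30.5 Gy.
#' Intensity means sit on an arbitrary 8-bit-like scale.
#'
#' @param grid_shape Voxels per axis (length 1 or 3), each axis >= 8.
#' @param voxel_size Isotropic voxel edge length in mm.
#' @param nidus_radius Nidus radius in mm (length 1 for a sphere, 3 for an
#'   ellipsoid of semi-axes).
#' @param target_proportions Vessel/brain/CSF percentages, summing to 100.
#' @param intensity_means Class mean T2 intensities, strictly increasing
#'   (vessel < brain < CSF).
#' @param intensity_sd Common within-class standard deviation.
#' @param margin_dose Prescribed margin dose in Gy; the dose field equals this
#'   value exactly on the nidus boundary.
#' @param max_dose Maximum (central) dose in Gy, must exceed `margin_dose`.
#' @param smoothing_fwhm FWHM (voxels) of the Gaussian-smoothed random field
#'   whose quantiles carve the tissue classes. Larger values give coarse,
#'   compact-looking clusters; smaller values give fine diffuse intermixing.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96),
                         voxel_size = 1,
                         nidus_radius = 20,
                         target_proportions = c(vessel = 30.9, brain = 52.2,
                                                csf = 16.8) * 100 / 99.9,
                         intensity_means = c(60, 140, 220),
                         intensity_sd = 20,
                         margin_dose = 17.5,
                         max_dose = 30.5,
                         smoothing_fwhm = 3,
                         seed = 1L) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  if (any(grid_shape < 8L))
    stop("degenerate grid: every axis must have at least 8 voxels", call. = FALSE)
  if (voxel_size <= 0) stop("voxel_size must be positive", call. = FALSE)
  nidus_radius <- as.numeric(nidus_radius)
  if (!length(nidus_radius) %in% c(1L, 3L) || any(nidus_radius <= 0))
    stop("nidus_radius must be a positive scalar or length-3 vector", call. = FALSE)
  target_proportions <- as.numeric(target_proportions)
  if (length(target_proportions) != 3L || any(target_proportions < 0))
    stop("target_proportions must be three non-negative percentages", call. = FALSE)
  if (abs(sum(target_proportions) - 100) > 1e-9)
    stop("target_proportions must sum to 100", call. = FALSE)
  intensity_means <- as.numeric(intensity_means)
  if (length(intensity_means) != 3L || any(diff(intensity_means) <= 0))
    stop("intensity_means must be strictly increasing (vessel < brain < csf)",
         call. = FALSE)
  if (intensity_sd <= 0) stop("intensity_sd must be positive", call. = FALSE)
  if (margin_dose <= 0 || max_dose <= margin_dose)
    stop("require 0 < margin_dose < max_dose", call. = FALSE)
  if (smoothing_fwhm <= 0) stop("smoothing_fwhm must be positive", call. = FALSE)
  structure(list(
    grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
    nidus_radius = nidus_radius,
    target_proportions = stats::setNames(target_proportions,
                                         c("vessel", "brain", "csf")),
    intensity_means = intensity_means, intensity_sd = as.numeric(intensity_sd),
    margin_dose = as.numeric(margin_dose), max_dose = as.numeric(max_dose),
    smoothing_fwhm = as.numeric(smoothing_fwhm), seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Periodic Gaussian smoothing of a 3-D array via FFT; sigma in voxels.
gaussian_smooth3d <- function(x, sigma) {
  dims <- dim(x)
  kern1 <- lapply(dims, function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- exp(-d^2 / (2 * sigma^2))
    k / sum(k)
  })
  k3 <- outer(outer(kern1[[1]], kern1[[2]]), kern1[[3]])
  dim(k3) <- dims
  Re(stats::fft(stats::fft(x) * stats::fft(k3), inverse = TRUE)) / prod(dims)
}

#' Generate a bAVM imaging phantom
#'
#' Builds a labelled T2-like volume, a radially decaying dose field and a
#' ground-truth tissue label map from a [phantom_spec()]. Inside the nidus,
#' tissue classes are carved by thresholding a Gaussian-smoothed random field
#' at the empirical quantiles matching `target_proportions`, so the realised
#' class counts match the targets to within one voxel. The dose field falls
#' off quadratically from `max_dose` at the nidus centre and equals
#' `margin_dose` exactly on the nidus boundary, so the prescription isodose
#' volume coincides with the nidus.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `avm_phantom`: list with `t2`, `dose`
#'   (numeric 3-D arrays, Gy for dose), `truth_labels` (integer 3-D array,
#'   0 = outside, 1 = vessel, 2 = brain, 3 = csf), `grid` ([grid3d()]) and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- spec$grid_shape
  grid <- grid3d(spacing = spec$voxel_size, origin = c(0, 0, 0))
  radii <- rep_len(spec$nidus_radius, 3L)

  # normalised radial coordinate: 1 on the nidus boundary
  centre <- grid$origin + (dims - 1) / 2 * grid$spacing
  ax <- lapply(1:3, function(a) {
    w <- grid$origin[a] + (seq_len(dims[a]) - 1) * grid$spacing[a]
    (w - centre[a]) / radii[a]
  })
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  dim(r2) <- dims
  nidus <- r2 <= 1

  # tissue classes: quantile-threshold a smoothed noise field inside the nidus
  sigma <- spec$smoothing_fwhm / (2 * sqrt(2 * log(2)))
  field <- gaussian_smooth3d(array(stats::rnorm(prod(dims)), dim = dims), sigma)
  fv <- field[nidus]
  n_in <- length(fv)
  rk <- rank(fv, ties.method = "first")
  n_vessel <- round(spec$target_proportions[["vessel"]] / 100 * n_in)
  n_vb <- round(sum(spec$target_proportions[c("vessel", "brain")]) / 100 * n_in)
  lab_in <- ifelse(rk <= n_vessel, 1L, ifelse(rk <= n_vb, 2L, 3L))
  truth <- array(0L, dim = dims)
  truth[nidus] <- lab_in

  # intensities: class-conditional normals; background looks like parenchyma
  t2 <- array(stats::rnorm(prod(dims), mean = spec$intensity_means[2],
                           sd = spec$intensity_sd), dim = dims)
  for (cls in 1:3) {
    idx <- truth == cls
    t2[idx] <- stats::rnorm(sum(idx), mean = spec$intensity_means[cls],
                            sd = spec$intensity_sd)
  }

  # quadratic dose falloff, margin_dose exactly at the boundary, floored at 0
  dose <- pmax(0, spec$max_dose - (spec$max_dose - spec$margin_dose) * r2)
  dim(dose) <- dims

  structure(list(t2 = t2, dose = dose, truth_labels = truth,
                 grid = grid, spec = spec),
            class = "avm_phantom")
}

#' @export
print.avm_phantom <- function(x, ...) {
  d <- dim(x$t2)
  n_in <- sum(x$truth_labels != 0L)
  props <- truth_proportions(x)
  cat(sprintf("bAVM phantom: %d x %d x %d voxels (%.3g mm), %d in nidus\n",
              d[1], d[2], d[3], x$grid$spacing[1], n_in))
  cat(sprintf("  realised proportions: vessel %.1f%%, brain %.1f%%, csf %.1f%%\n",
              props[1], props[2], props[3]))
  cat(sprintf("  dose: %.3g Gy max, %.3g Gy margin\n",
              x$spec$max_dose, x$spec$margin_dose))
  invisible(x)
}

#' Realised ground-truth tissue proportions of a phantom
#'
#' @param phantom An `avm_phantom`.
#' @return Named percentages (vessel, brain, csf) over in-nidus voxels.
#' @export
truth_proportions <- function(phantom) {
  stopifnot(inherits(phantom, "avm_phantom"))
  lab <- phantom$truth_labels[phantom$truth_labels != 0L]
  100 * c(vessel = mean(lab == 1L), brain = mean(lab == 2L),
          csf = mean(lab == 3L))
}

#' Write / read a phantom as NIfTI volumes
#'
#' `write_phantom()` stores `t2.nii.gz`, `dose.nii.gz` and `labels.nii.gz`
#' (integer codes 0 = outside, 1 = vessel, 2 = brain, 3 = csf) plus a
#' `phantom.json` sidecar carrying the grid and spec, under `dir`.
#' `read_phantom()` reverses this; scalar volumes round-trip voxelwise
#' exactly (double precision on disk).
#'
#' @param phantom An `avm_phantom`.
#' @param dir Directory to write to (created if needed).
#' @return `write_phantom()` returns the directory invisibly;
#'   `read_phantom()` returns an `avm_phantom`.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "avm_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  put <- function(arr, file, datatype) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- phantom$grid$spacing
    RNifti::writeNifti(img, file.path(dir, file), datatype = datatype)
  }
  put(phantom$t2, "t2.nii.gz", "double")
  put(phantom$dose, "dose.nii.gz", "double")
  put(phantom$truth_labels, "labels.nii.gz", "int16")
  meta <- list(grid = list(spacing = phantom$grid$spacing,
                           origin = phantom$grid$origin),
               spec = unclass(phantom$spec))
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  files <- file.path(dir, c("t2.nii.gz", "dose.nii.gz", "labels.nii.gz",
                            "phantom.json"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("malformed phantom directory; missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(files[4], simplifyVector = TRUE)
  sp <- meta$spec
  spec <- phantom_spec(grid_shape = sp$grid_shape, voxel_size = sp$voxel_size,
                       nidus_radius = sp$nidus_radius,
                       target_proportions = sp$target_proportions,
                       intensity_means = sp$intensity_means,
                       intensity_sd = sp$intensity_sd,
                       margin_dose = sp$margin_dose, max_dose = sp$max_dose,
                       smoothing_fwhm = sp$smoothing_fwhm, seed = sp$seed)
  as_plain <- function(img) {
    a <- as.array(img)
    attributes(a) <- list(dim = dim(a))
    a
  }
  structure(list(
    t2 = as_plain(RNifti::readNifti(files[1])),
    dose = as_plain(RNifti::readNifti(files[2])),
    truth_labels = {
      l <- as_plain(RNifti::readNifti(files[3])); storage.mode(l) <- "integer"; l
    },
    grid = grid3d(spacing = meta$grid$spacing, origin = meta$grid$origin),
    spec = spec
  ), class = "avm_phantom")
}
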