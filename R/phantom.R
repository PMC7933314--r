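#' Digital liver phantom specification
#'
#' Geometry and imaging model for a synthetic activity distribution: an
#' ellipsoidal liver of unit activity concentration, spherical tumors with a
#' configurable uptake multiplier (the tumor-to-normal ratio), an ellipsoidal
#' lung region receiving a configurable shunt fraction of the total activity,
#' Gaussian point-spread blurring, and Poisson counting noise scaled to a
#' total count level. All coordinates are physical mm; the grid origin is at
#' the corner of voxel (1,1,1) and voxel centers sit at `(i - 0.5) * dx`.
#'
#' The default geometry keeps liver and lung separated by more than the blur
#' kernel support (the kernel is truncated at 4 sigma) and away from the
#' grid edges, so that organ counts stay attributable to their organ and
#' noise-free shunt recovery is exact.
#'
#' @param dim Grid dimensions (voxels), length 3.
#' @param spacing_mm Voxel spacing, length 3, mm.
#' @param liver_center_mm,liver_semiaxes_mm Liver ellipsoid (mm).
#' @param tumors List of tumors, each `list(center_mm=, radius_mm=, tnr=)`;
#'   every tumor must lie inside the liver.
#' @param lung_center_mm,lung_semiaxes_mm Lung ellipsoid (mm).
#' @param shunt_fraction Fraction of total activity shunted to lung,
#'   in \[0, 0.5\].
#' @param psf_sigma_mm Isotropic Gaussian PSF sigma (mm); 0 disables blur.
#' @param total_counts Expected total counts over the volume (Poisson
#'   scaling).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Integer seed; mandatory, recorded in outputs.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 88),
                         spacing_mm = c(2, 2, 2),
                         liver_center_mm = c(64, 64, 50),
                         liver_semiaxes_mm = c(45, 40, 30),
                         tumors = list(list(center_mm = c(75, 64, 55),
                                            radius_mm = 15, tnr = 2.6)),
                         lung_center_mm = c(64, 64, 132),
                         lung_semiaxes_mm = c(45, 40, 18),
                         shunt_fraction = 0.069,
                         psf_sigma_mm = 4,
                         total_counts = 5e6,
                         noise = c("none", "poisson"),
                         seed) {
  noise <- match.arg(noise)
  total_counts <- as.numeric(total_counts)
  psf_sigma_mm <- as.numeric(psf_sigma_mm)
  shunt_fraction <- as.numeric(shunt_fraction)
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for reproducible phantom generation",
         call. = FALSE)
  }
  stopifnot(length(dim) == 3, all(dim >= 4),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            shunt_fraction >= 0, shunt_fraction <= 0.5,
            psf_sigma_mm >= 0, total_counts > 0)
  structure(list(dim = as.integer(dim), spacing_mm = as.numeric(spacing_mm),
                 liver_center_mm = liver_center_mm,
                 liver_semiaxes_mm = liver_semiaxes_mm,
                 tumors = tumors,
                 lung_center_mm = lung_center_mm,
                 lung_semiaxes_mm = lung_semiaxes_mm,
                 shunt_fraction = shunt_fraction,
                 psf_sigma_mm = psf_sigma_mm,
                 total_counts = total_counts,
                 noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Read a phantom specification from YAML
#'
#' @param path YAML file whose keys match the arguments of [phantom_spec()];
#'   `tumors` is a list of mappings with `center_mm`, `radius_mm`, `tnr`.
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  numeric_fields <- c("dim", "spacing_mm", "liver_center_mm",
                      "liver_semiaxes_mm", "lung_center_mm",
                      "lung_semiaxes_mm", "shunt_fraction", "psf_sigma_mm",
                      "total_counts", "seed")
  for (nm in intersect(numeric_fields, names(y))) {
    y[[nm]] <- as.numeric(unlist(y[[nm]]))
  }
  if (!is.null(y$tumors)) {
    y$tumors <- lapply(y$tumors, function(tm) lapply(tm, function(v)
      as.numeric(unlist(v))))
  }
  do.call(phantom_spec, y)
}

# voxel-center coordinate arrays for one axis, broadcast to the full grid
coord_array <- function(dim, spacing, axis) {
  ax <- (seq_len(dim[axis]) - 0.5) * spacing[axis]
  switch(axis,
         array(rep(ax, times = dim[2] * dim[3]), dim),
         array(rep(rep(ax, each = dim[1]), times = dim[3]), dim),
         array(rep(ax, each = dim[1] * dim[2]), dim))
}

ellipsoid_mask <- function(dim, spacing, center, semiaxes) {
  x <- coord_array(dim, spacing, 1)
  y <- coord_array(dim, spacing, 2)
  z <- coord_array(dim, spacing, 3)
  ((x - center[1]) / semiaxes[1])^2 + ((y - center[2]) / semiaxes[2])^2 +
    ((z - center[3]) / semiaxes[3])^2 <= 1
}

sphere_mask <- function(dim, spacing, center, radius) {
  x <- coord_array(dim, spacing, 1)
  y <- coord_array(dim, spacing, 2)
  z <- coord_array(dim, spacing, 3)
  (x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= radius^2
}

# Separable Gaussian convolution; the 1D kernel is truncated at 4 sigma and
# normalized, so mass beyond the truncation radius is exactly zero and total
# counts are conserved away from the grid edges (zero padding).
gaussian_blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- ceiling(4 * s)
    k <- stats::dnorm(-r:r, sd = s)
    k <- k / sum(k)
    n <- d[axis]
    # band matrix applying the 1D convolution along this axis
    K <- matrix(0, n, n)
    for (off in -r:r) {
      idx <- seq_len(n - abs(off))
      if (off >= 0) K[cbind(idx + off, idx)] <- k[off + r + 1]
      else K[cbind(idx, idx - off)] <- k[off + r + 1]
    }
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = n)
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}

#' Generate a digital liver phantom
#'
#' Builds the piecewise-constant activity distribution described by the
#' spec (normal liver concentration 1, each tumor at its TNR multiplier,
#' lung receiving the shunt fraction uniformly), scales it so the expected
#' total equals `total_counts` with the liver compartment holding
#' `1 - shunt_fraction` of it, applies the Gaussian PSF, adds Poisson noise
#' if requested, and forms anterior/posterior planar views by summation
#' along the anteroposterior (second) axis. Planar lung/liver ROIs partition
#' the coronal plane at the midpoint between the liver top and lung bottom.
#'
#' Deterministic given the spec seed: the same spec yields bit-identical
#' outputs.
#'
#' @param spec A [phantom_spec()].
#' @return List with `map` (an [activity_map()]), `planar` (a
#'   [planar_scan()]), `truth` (analytic and voxelized target/tumor volumes
#'   in ml, `tnr`, `hps`, seed) and `masks` (liver, tumors, normal, lung).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim; sp <- spec$spacing_mm
  voxvol_ml <- prod(sp) / 1000

  liver <- ellipsoid_mask(d, sp, spec$liver_center_mm, spec$liver_semiaxes_mm)
  lung <- ellipsoid_mask(d, sp, spec$lung_center_mm, spec$lung_semiaxes_mm)
  if (any(liver & lung)) stop("liver and lung regions overlap", call. = FALSE)

  tumor_masks <- lapply(spec$tumors, function(tm)
    sphere_mask(d, sp, tm$center_mm, tm$radius_mm))
  for (i in seq_along(tumor_masks)) {
    if (any(tumor_masks[[i]] & !liver)) {
      stop("tumor ", i, " extends outside the liver", call. = FALSE)
    }
  }
  tumor_any <- Reduce(`|`, tumor_masks,
                      array(FALSE, d))
  normal <- liver & !tumor_any

  conc <- array(0, d)
  conc[normal] <- 1
  for (i in seq_along(tumor_masks)) {
    conc[tumor_masks[[i]]] <- spec$tumors[[i]]$tnr
  }
  liver_total <- sum(conc)
  if (liver_total <= 0) stop("empty liver region", call. = FALSE)
  vals <- conc * ((1 - spec$shunt_fraction) * spec$total_counts / liver_total)
  if (spec$shunt_fraction > 0) {
    n_lung <- sum(lung)
    if (n_lung == 0) stop("empty lung region with nonzero shunt",
                          call. = FALSE)
    vals[lung] <- spec$shunt_fraction * spec$total_counts / n_lung
  }

  if (spec$psf_sigma_mm > 0) {
    vals <- gaussian_blur3d(vals, spec$psf_sigma_mm / sp)
    # convolution of non-negative input; clamp numerical round-off
    vals[vals < 0] <- 0
  }

  expect <- vals
  set.seed(spec$seed)
  if (spec$noise == "poisson") {
    vals <- array(stats::rpois(length(vals), vals), d)
  }
  map <- activity_map(vals, sp)

  # conjugate planar views: axis sums of the expectation along y
  # (anteroposterior), no attenuation; independent Poisson counts per view
  # when noisy
  proj_expect <- apply(expect, c(1, 3), sum)
  if (spec$noise == "poisson") {
    ant <- matrix(stats::rpois(length(proj_expect), proj_expect), d[1])
    post <- matrix(stats::rpois(length(proj_expect), proj_expect), d[1])
  } else {
    ant <- proj_expect
    post <- proj_expect
  }
  liver_top_mm <- spec$liver_center_mm[3] + spec$liver_semiaxes_mm[3]
  lung_bot_mm <- spec$lung_center_mm[3] - spec$lung_semiaxes_mm[3]
  z_split_mm <- (liver_top_mm + lung_bot_mm) / 2
  zc <- (seq_len(d[3]) - 0.5) * sp[3]
  lung_rows <- matrix(rep(zc > z_split_mm, each = d[1]), d[1])
  planar <- planar_scan(ant, post, lung_roi = lung_rows,
                        liver_roi = !lung_rows)

  truth <- list(
    target_ml_analytic = 4 / 3 * pi * prod(spec$liver_semiaxes_mm) / 1000,
    target_ml_voxel = sum(liver) * voxvol_ml,
    tumor_ml_analytic = vapply(spec$tumors, function(tm)
      4 / 3 * pi * tm$radius_mm^3 / 1000, 0),
    tumor_ml_voxel = vapply(tumor_masks, function(m) sum(m) * voxvol_ml, 0),
    tnr = if (length(spec$tumors) > 0)
      mean(vapply(spec$tumors, function(tm) tm$tnr, 0)) else NA_real_,
    hps = spec$shunt_fraction,
    seed = spec$seed)

  list(map = map, planar = planar, truth = truth,
       masks = list(liver = liver, tumors = tumor_masks, normal = normal,
                    lung = lung))
}
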