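#' 3D activity map
#'
#' A voxelized activity (or count) distribution, such as a reconstructed
#' MAA SPECT/CT or 90Y PET/CT volume, with its voxel spacing in mm.
#'
#' @param values Non-negative 3D numeric array.
#' @param spacing_mm Voxel spacing `(dx, dy, dz)` in mm, all > 0.
#' @return An `activity_map`.
#' @export
activity_map <- function(values, spacing_mm) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            is.numeric(spacing_mm), length(spacing_mm) == 3,
            all(spacing_mm > 0))
  if (any(values < 0)) stop("activity values must be non-negative",
                            call. = FALSE)
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm)),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("Activity map %s voxels at %s mm, total %.4g\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              sum(x$values)))
  invisible(x)
}

#' Voxel volume of an activity map, in ml
#'
#' @param map An [activity_map()].
#' @return dx*dy*dz / 1000 (mm^3 to ml).
#' @export
voxel_volume_ml <- function(map) {
  prod(map$spacing_mm) / 1000
}

check_mask <- function(mask, map) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), dim(map$values))) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match map shape ",
         paste(dim(map$values), collapse = "x"), call. = FALSE)
  }
  mask
}

#' Isocontour volume (MTV) at a percentage of the maximum
#'
#' Emulates the "VOI + isocontour" tool of clinical workstations: inside a
#' search volume of interest, every voxel whose value is at least
#' `threshold_pct`\% of the maximum voxel value in that VOI belongs to the
#' segmented volume; the result in ml is the "molecular tumor volume" (MTV)
#' used as the functional target volume. The threshold is relative to the
#' VOI-local maximum (not the global image maximum), comparison is `>=`
#' (voxels exactly at the threshold are included), and no connectivity
#' filtering is applied.
#'
#' @param map An [activity_map()].
#' @param search_voi Logical array delimiting the search region; `NULL`
#'   searches the whole map.
#' @param threshold_pct Isocontour threshold in percent of the VOI maximum,
#'   in \[1, 100\].
#' @return A `volumetry_result`: list with `mtv_ml`, `threshold_pct`,
#'   `voxel_count` and the segmented `mask`.
#' @examples
#' vals <- array(0, c(10, 10, 10)); vals[3:7, 3:7, 3:7] <- 1
#' m <- activity_map(vals, c(2, 2, 2))
#' isocontour_volume(m, threshold_pct = 3)$mtv_ml  # 125 voxels * 0.008 ml
#' @export
isocontour_volume <- function(map, search_voi = NULL, threshold_pct) {
  stopifnot(inherits(map, "activity_map"),
            is.numeric(threshold_pct), length(threshold_pct) == 1,
            threshold_pct >= 1, threshold_pct <= 100)
  voi <- if (is.null(search_voi)) {
    array(TRUE, dim(map$values))
  } else check_mask(search_voi, map)
  vmax <- max(map$values[voi])
  if (!is.finite(vmax) || vmax <= 0) {
    stop("no signal in VOI", call. = FALSE)
  }
  sel <- voi & (map$values >= threshold_pct / 100 * vmax)
  count <- sum(sel)
  structure(list(mtv_ml = count * voxel_volume_ml(map),
                 threshold_pct = threshold_pct,
                 voxel_count = count,
                 mask = sel),
            class = "volumetry_result")
}

#' @export
print.volumetry_result <- function(x, ...) {
  cat(sprintf("Isocontour at %g%% of max: %d voxels, MTV = %.3f ml\n",
              x$threshold_pct, x$voxel_count, x$mtv_ml))
  invisible(x)
}

#' Choose the isocontour threshold matching a reference volume
#'
#' Automated surrogate for the visual per-patient adjustment of the
#' isocontour level: evaluates each candidate threshold and returns the one
#' whose MTV is closest to a reference volume (e.g. an anatomical volume).
#' Ties are broken toward the lower threshold.
#'
#' @param map An [activity_map()].
#' @param search_voi Logical search region, or `NULL` for the whole map.
#' @param reference_ml Reference volume in ml.
#' @param candidate_pcts Candidate thresholds in percent, each in \[1, 100\].
#' @return The winning `volumetry_result` (see [isocontour_volume()]).
#' @export
fit_isocontour_to_reference <- function(map, search_voi = NULL, reference_ml,
                                        candidate_pcts = 1:10) {
  stopifnot(length(candidate_pcts) >= 1, all(candidate_pcts >= 1),
            all(candidate_pcts <= 100), reference_ml >= 0)
  candidate_pcts <- sort(candidate_pcts)
  results <- lapply(candidate_pcts, function(p)
    isocontour_volume(map, search_voi, p))
  err <- vapply(results, function(r) abs(r$mtv_ml - reference_ml), 0)
  results[[which.min(err)]]  # which.min takes the first = lowest threshold
}

#' Mean tumor-to-normal activity concentration ratio
#'
#' Per-tumor TNR is the mean voxel value inside a tumor VOI divided by the
#' mean value inside the normal-parenchyma VOI; with several tumors the
#' unweighted mean of the per-tumor TNRs is returned (a single scalar per
#' patient is what the dosimetry consumes).
#'
#' @param map An [activity_map()].
#' @param tumor_vois A logical array or list of logical arrays.
#' @param normal_voi Logical array over normal parenchyma with positive mean
#'   uptake.
#' @return Scalar TNR.
#' @export
tumor_to_normal_ratio <- function(map, tumor_vois, normal_voi) {
  stopifnot(inherits(map, "activity_map"))
  if (!is.list(tumor_vois)) tumor_vois <- list(tumor_vois)
  normal_voi <- check_mask(normal_voi, map)
  if (sum(normal_voi) == 0) stop("empty normal VOI", call. = FALSE)
  normal_mean <- mean(map$values[normal_voi])
  if (normal_mean <= 0) stop("zero uptake in normal VOI", call. = FALSE)
  per_tumor <- vapply(tumor_vois, function(voi) {
    voi <- check_mask(voi, map)
    if (sum(voi) == 0) stop("empty tumor VOI", call. = FALSE)
    mean(map$values[voi]) / normal_mean
  }, 0)
  mean(per_tumor)
}

#' Planar conjugate-view scan with lung and liver ROIs
#'
#' Anterior and posterior 2D count maps from planar scintigraphy, with
#' disjoint lung and liver regions of interest, as used to estimate the
#' hepatopulmonary shunt.
#'
#' @param anterior,posterior Non-negative 2D count arrays of equal shape.
#' @param lung_roi,liver_roi Disjoint logical 2D arrays of the same shape.
#' @return A `planar_scan`.
#' @export
planar_scan <- function(anterior, posterior, lung_roi, liver_roi) {
  stopifnot(is.matrix(anterior), is.matrix(posterior),
            identical(dim(anterior), dim(posterior)),
            identical(dim(lung_roi), dim(anterior)),
            identical(dim(liver_roi), dim(anterior)))
  lung_roi <- matrix(as.logical(lung_roi), nrow(anterior))
  liver_roi <- matrix(as.logical(liver_roi), nrow(anterior))
  if (any(anterior < 0) || any(posterior < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(lung_roi & liver_roi)) {
    stop("lung and liver ROIs must be disjoint", call. = FALSE)
  }
  structure(list(anterior = anterior, posterior = posterior,
                 lung_roi = lung_roi, liver_roi = liver_roi),
            class = "planar_scan")
}

#' Hepatopulmonary shunt fraction from planar imaging
#'
#' Conjugate-view quantification: for each ROI the geometric mean of the
#' anterior and posterior total counts, \eqn{GM = \sqrt{C_{ant} C_{post}}},
#' then \eqn{HPS = GM_{lung} / (GM_{lung} + GM_{liver})}. A shunt above 20\%
#' is conventionally a contraindication for treatment (the lung dose would
#' be excessive).
#'
#' @param scan A [planar_scan()].
#' @param contraindication_threshold Shunt fraction above which the
#'   `contraindicated` flag is set (default 0.20).
#' @return List with `hps` (fraction), `gm_lung`, `gm_liver`,
#'   `contraindicated`.
#' @export
lung_shunt_fraction <- function(scan, contraindication_threshold = 0.20) {
  stopifnot(inherits(scan, "planar_scan"))
  gm <- function(roi) {
    # double sums: integer count maps overflow the int product otherwise
    sqrt(sum(as.numeric(scan$anterior[roi])) *
           sum(as.numeric(scan$posterior[roi])))
  }
  gm_lung <- gm(scan$lung_roi)
  gm_liver <- gm(scan$liver_roi)
  if (gm_liver <= 0) {
    if (gm_lung <= 0) stop("zero counts in both ROIs", call. = FALSE)
    stop("zero liver counts; shunt fraction undefined", call. = FALSE)
  }
  hps <- gm_lung / (gm_lung + gm_liver)
  list(hps = hps, gm_lung = gm_lung, gm_liver = gm_liver,
       contraindicated = hps > contraindication_threshold)
}
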