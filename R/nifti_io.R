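#' Read and write activity maps as NIfTI
#'
#' Voxel spacing is carried in the NIfTI pixdim. Values are stored as-is
#' (counts or activity); negative voxels on read are clipped to zero with a
#' warning, since reconstructed maps occasionally contain small negative
#' ringing values.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return [read_activity_map()]: an [activity_map()].
#' @export
read_activity_map <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  vals <- array(as.numeric(vals), dim(vals))  # drop NIfTI attributes
  if (length(dim(vals)) != 3) {
    stop("expected a 3D NIfTI volume, got ",
         length(dim(vals)), " dimensions", call. = FALSE)
  }
  if (any(vals < 0)) {
    warning("clipping ", sum(vals < 0), " negative voxel(s) to zero")
    vals[vals < 0] <- 0
  }
  spacing <- RNifti::pixdim(img)[1:3]
  activity_map(vals, spacing)
}

#' @param map An [activity_map()] to write.
#' @rdname read_activity_map
#' @return [write_activity_map()]: `path`, invisibly.
#' @export
write_activity_map <- function(map, path) {
  stopifnot(inherits(map, "activity_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- map$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write planar scans as 4-plane NIfTI
#'
#' A [planar_scan()] is serialized as a single 3D NIfTI with four planes
#' stacked along the third axis: anterior counts, posterior counts, lung ROI
#' (0/1) and liver ROI (0/1).
#'
#' @param path NIfTI file.
#' @return [read_planar_scan()]: a [planar_scan()].
#' @export
read_planar_scan <- function(path) {
  vals <- as.array(RNifti::readNifti(path))
  vals <- array(as.numeric(vals), dim(vals))
  if (length(dim(vals)) != 3 || dim(vals)[3] != 4) {
    stop("expected a NIfTI with 4 stacked planes", call. = FALSE)
  }
  planar_scan(anterior = vals[, , 1], posterior = vals[, , 2],
              lung_roi = vals[, , 3] > 0.5, liver_roi = vals[, , 4] > 0.5)
}

#' @param scan A [planar_scan()] to write.
#' @rdname read_planar_scan
#' @return [write_planar_scan()]: `path`, invisibly.
#' @export
write_planar_scan <- function(scan, path) {
  stopifnot(inherits(scan, "planar_scan"))
  arr <- array(c(scan$anterior, scan$posterior,
                 as.numeric(scan$lung_roi), as.numeric(scan$liver_roi)),
               dim = c(dim(scan$anterior), 4))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
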