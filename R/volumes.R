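#' @useDynLib radsig, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd var quantile median rnorm runif cor
#' @importFrom utils combn read.csv write.csv
NULL

## ---- VoxelVolume -----------------------------------------------------------

#' Create a voxel volume
#'
#' A `voxel_volume` is a 3D scalar grid (CT or PET intensities) together with
#' its geometry: voxel spacing in mm, world-space origin in mm, and an
#' orthonormal direction matrix. World coordinates of the voxel with 0-based
#' index `i` are `origin + direction %*% (spacing * i)`, matching the NIfTI
#' affine convention.
#'
#' @param data 3D numeric array, all dimensions >= 1.
#' @param spacing numeric length-3, strictly positive, mm per axis.
#' @param origin numeric length-3, world mm.
#' @param direction 3x3 orthonormal matrix (defaults to identity).
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         direction = diag(3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values", call. = FALSE)
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be a 3x3 orthonormal matrix", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " | spacing (mm): ", paste(format(x$spacing), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Create a lesion mask
#'
#' A binary volume of interest (VOI) on the same kind of grid as a
#' [voxel_volume()]. Values must be 0/1.
#'
#' @inheritParams voxel_volume
#' @return An object of class `lesion_mask` (also a `voxel_volume`).
#' @export
lesion_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  vol <- voxel_volume(data, spacing, origin, direction)
  if (!all(vol$data %in% c(0, 1)))
    stop("mask values must all be 0 or 1", call. = FALSE)
  storage.mode(vol$data) <- "integer"
  class(vol) <- c("lesion_mask", "voxel_volume")
  vol
}

same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

check_pair <- function(volume, mask) {
  if (!inherits(volume, "voxel_volume")) stop("`volume` must be a voxel_volume")
  if (!inherits(mask, "lesion_mask")) stop("`mask` must be a lesion_mask")
  if (!same_geometry(volume, mask))
    stop("volume and mask geometries do not match", call. = FALSE)
  if (sum(mask$data) == 0L) stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}

# world coordinates (3 x n matrix) of 0-based voxel indices (n x 3)
voxel_to_world <- function(geom, idx0) {
  idx0 <- matrix(idx0, ncol = 3L)
  t(geom$origin + geom$direction %*% (geom$spacing * t(idx0)))
}

## ---- AcquisitionInfo -------------------------------------------------------

#' PET acquisition metadata
#'
#' Holds the quantities needed to standardize PET voxel activity: injected
#' dose `d` (MBq), acquisition time `t` and radiopharmaceutical start
#' (injection) time `t_i` (seconds since a common epoch), radionuclide
#' half-life `tau` (s), and patient weight `w` (kg).
#'
#' @param dose_MBq injected dose, > 0.
#' @param weight_kg patient weight, > 0.
#' @param injection_time injection time, s since epoch.
#' @param acquisition_time acquisition time, s since epoch; must be
#'   >= `injection_time`.
#' @param half_life_s radionuclide half-life in seconds, > 0 (default the
#'   18F value, 6586.2 s).
#' @return An object of class `acquisition_info`.
#' @export
acquisition_info <- function(dose_MBq, weight_kg, injection_time,
                             acquisition_time, half_life_s = 6586.2) {
  vals <- c(dose_MBq, weight_kg, injection_time, acquisition_time, half_life_s)
  if (any(!is.finite(vals))) stop("acquisition fields must be finite")
  if (dose_MBq <= 0) stop("`dose_MBq` must be > 0", call. = FALSE)
  if (weight_kg <= 0) stop("`weight_kg` must be > 0", call. = FALSE)
  if (half_life_s <= 0) stop("`half_life_s` must be > 0", call. = FALSE)
  if (acquisition_time < injection_time)
    stop("`acquisition_time` must be >= `injection_time`", call. = FALSE)
  structure(list(dose_MBq = dose_MBq, weight_kg = weight_kg,
                 injection_time = injection_time,
                 acquisition_time = acquisition_time,
                 half_life_s = half_life_s),
            class = "acquisition_info")
}

## ---- NIfTI / sidecar I/O ---------------------------------------------------

#' Read or write a volume as NIfTI-1
#'
#' Thin wrappers around RNifti. The NIfTI affine carries the geometry;
#' reading reconstructs spacing/origin/direction from it.
#'
#' @param path file path (.nii or .nii.gz).
#' @param x a [voxel_volume()] or [lesion_mask()].
#' @param mask logical: read as a binary lesion mask?
#' @return `read_nifti_volume` returns a `voxel_volume` (or `lesion_mask`).
#' @export
read_nifti_volume <- function(path, mask = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume")
  aff <- RNifti::xform(img)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  direction <- sweep(aff[1:3, 1:3], 2, spacing, "/")
  origin <- aff[1:3, 4]
  if (mask) lesion_mask(round(arr), spacing, origin, direction)
  else voxel_volume(arr, spacing, origin, direction)
}

#' @rdname read_nifti_volume
#' @export
write_nifti_volume <- function(x, path) {
  stopifnot(inherits(x, "voxel_volume"))
  aff <- rbind(cbind(x$direction %*% diag(x$spacing), x$origin), c(0, 0, 0, 1))
  img <- RNifti::asNifti(x$data)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read or write acquisition metadata as a JSON sidecar
#'
#' Keys: `dose_MBq`, `weight_kg`, `injection_time`, `acquisition_time`,
#' `half_life_s`.
#'
#' @param path JSON file path.
#' @param acq an [acquisition_info()].
#' @export
read_acquisition_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_info(dose_MBq = j$dose_MBq, weight_kg = j$weight_kg,
                   injection_time = j$injection_time,
                   acquisition_time = j$acquisition_time,
                   half_life_s = j$half_life_s)
}

#' @rdname read_acquisition_json
#' @export
write_acquisition_json <- function(acq, path) {
  stopifnot(inherits(acq, "acquisition_info"))
  jsonlite::write_json(unclass(acq), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
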