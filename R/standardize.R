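## PET voxel standardization and mask transfer between grids.

#' Standardize PET voxel activity
#'
#' Rescales each PET voxel by injected dose, decay since injection and patient
#' weight, making uptake comparable across scans:
#' \deqn{v' = v \cdot d \cdot e^{-(t - t_i)/\tau} / w}
#' with `d` the injected dose (MBq), `t` the acquisition time, `t_i` the
#' injection time, `tau` the radionuclide half-life and `w` the patient
#' weight (kg). The default `"plain"` convention evaluates the exponent
#' exactly as written; the `"ln2"` convention multiplies the exponent by
#' `log(2)` so that `tau` acts as a true physical half-life (activity halves
#' every `tau` seconds).
#'
#' @param volume a PET [voxel_volume()].
#' @param acq an [acquisition_info()].
#' @param decay_convention `"plain"` (default) or `"ln2"`.
#' @return A `voxel_volume` with identical geometry and standardized values.
#' @export
standardize_pet <- function(volume, acq, decay_convention = c("plain", "ln2")) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(acq, "acquisition_info"))
  decay_convention <- match.arg(decay_convention)
  dt <- acq$acquisition_time - acq$injection_time
  rate <- dt / acq$half_life_s
  if (decay_convention == "ln2") rate <- rate * log(2)
  factor <- acq$dose_MBq * exp(-rate) / acq$weight_kg
  out <- volume
  out$data <- volume$data * factor
  out
}

#' Transfer a lesion mask onto another grid
#'
#' Resamples a binary mask onto a target geometry by nearest-neighbour lookup
#' in world coordinates: each target voxel takes the value of the source voxel
#' whose center is nearest to the target voxel center. Used to carry a VOI
#' segmented on the PET grid onto the CT grid. Nearest-neighbour interpolation
#' preserves binarity; no intensity interpolation occurs anywhere.
#'
#' @param mask a [lesion_mask()].
#' @param target_geometry a list (or `voxel_volume`) with fields `dim` (or a
#'   `data` array), `spacing`, `origin`, `direction`.
#' @return A `lesion_mask` on the target geometry.
#' @export
resample_mask_to_grid <- function(mask, target_geometry) {
  stopifnot(inherits(mask, "lesion_mask"))
  tg <- target_geometry
  tdim <- if (!is.null(tg$data)) dim(tg$data) else as.integer(tg$dim)
  tspacing <- as.numeric(tg$spacing)
  torigin <- if (is.null(tg$origin)) c(0, 0, 0) else as.numeric(tg$origin)
  tdir <- if (is.null(tg$direction)) diag(3) else as.matrix(tg$direction)
  if (length(tdim) != 3L || any(tdim < 1L)) stop("bad target dimensions")
  if (any(tspacing <= 0) || any(mask$spacing <= 0))
    stop("degenerate geometry: spacing must be strictly positive")

  tgeom <- list(spacing = tspacing, origin = torigin, direction = tdir)
  if (all(tdim == dim(mask$data)) &&
      same_geometry(mask, c(tgeom, list(data = mask$data))))
    return(lesion_mask(mask$data, tspacing, torigin, tdir))

  # target voxel centers -> world -> continuous source index -> round
  idx <- as.matrix(expand.grid(i = seq_len(tdim[1]) - 1L,
                               j = seq_len(tdim[2]) - 1L,
                               k = seq_len(tdim[3]) - 1L))
  world <- voxel_to_world(tgeom, idx)
  src <- t(crossprod(mask$direction, t(world) - mask$origin)) # inverse rotate
  src <- sweep(src, 2, mask$spacing, "/")
  src <- round(src)
  inside <- src[, 1] >= 0 & src[, 1] < dim(mask$data)[1] &
            src[, 2] >= 0 & src[, 2] < dim(mask$data)[2] &
            src[, 3] >= 0 & src[, 3] < dim(mask$data)[3]
  out <- integer(nrow(src))
  lin <- src[inside, 1] + dim(mask$data)[1] *
    (src[inside, 2] + dim(mask$data)[2] * src[inside, 3])
  out[inside] <- as.integer(mask$data)[lin + 1L]
  lesion_mask(array(out, tdim), tspacing, torigin, tdir)
}

## ---- Discretization --------------------------------------------------------

#' Gray-level discretization settings
#'
#' Texture features operate on integer gray levels. Two modes are supported:
#' `"fixed-bin-count"` (equal-width bins spanning the masked intensity range)
#' and `"fixed-bin-width"` (bins of a given intensity width anchored at the
#' masked minimum).
#'
#' @param mode `"fixed-bin-count"` or `"fixed-bin-width"`.
#' @param value bin count (positive integer) or bin width (> 0).
#' @return An object of class `discretization`.
#' @export
discretization <- function(mode = c("fixed-bin-count", "fixed-bin-width"),
                           value = 64) {
  mode <- match.arg(mode)
  if (mode == "fixed-bin-count") {
    if (value < 1 || value != round(value))
      stop("bin count must be a positive integer", call. = FALSE)
  } else if (value <= 0) stop("bin width must be > 0", call. = FALSE)
  structure(list(mode = mode, value = value), class = "discretization")
}

#' Discretize masked intensities to integer gray levels
#'
#' Returns the volume restricted to the mask with intensities mapped to
#' consecutive integer gray levels starting at 1. In fixed-bin-count mode the
#' bins are equal-width over `[min, max]` of the masked intensities (half-open
#' bins, top edge closed); a constant region maps to the single level 1. In
#' fixed-bin-width mode levels are `floor((x - min)/width) + 1`.
#'
#' @param volume a [voxel_volume()].
#' @param mask a matching [lesion_mask()] (nonempty).
#' @param disc a [discretization()].
#' @return An integer 3D array with `NA` outside the mask and gray levels
#'   `1..n_levels` inside; attribute `n_levels` gives the occupied maximum.
#' @export
discretize_intensities <- function(volume, mask, disc = discretization()) {
  check_pair(volume, mask)
  stopifnot(inherits(disc, "discretization"))
  inside <- mask$data == 1L
  x <- volume$data[inside]
  if (any(!is.finite(x))) stop("non-finite intensities inside mask")
  lo <- min(x); hi <- max(x)
  if (disc$mode == "fixed-bin-count") {
    nb <- as.integer(disc$value)
    if (hi == lo) lev <- rep(1L, length(x))
    else {
      lev <- floor((x - lo) / (hi - lo) * nb) + 1L
      lev[lev > nb] <- nb  # close the top edge
    }
  } else {
    lev <- as.integer(floor((x - lo) / disc$value)) + 1L
  }
  out <- array(NA_integer_, dim(volume$data))
  out[inside] <- as.integer(lev)
  attr(out, "n_levels") <- max(lev)
  attr(out, "spacing") <- volume$spacing
  out
}
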