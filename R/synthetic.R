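## Synthetic stand-ins for the restricted patient data: labelled feature
## tables with planted jointly-discriminative pairs, and small two-class
## texture phantoms. Both are seed-deterministic.

#' Specification of a planted-signature feature table
#'
#' The defaults emulate the cohort shape of the study the pipeline targets:
#' 44 samples with 29 positives (prevalence 29/44, about 2:1 imbalance).
#' Each planted pair is bivariate normal with class means at
#' `+/-(delta/2)` along the rotated axis `(1,-1)/sqrt(2)` and correlation
#' `rho` along `(1,1)/sqrt(2)`: each marginal separates the classes weakly
#' (mean shift `delta/2` along each axis with unit variance) while the pair
#' jointly separates strongly — exactly the structure pairwise selection is
#' designed to find. Noise features are class-independent standard normal.
#'
#' @param n_samples number of samples (default 44); must be >= 4.
#' @param prevalence positive-class fraction in (0,1); default 29/44. The
#'   positive count is `round(prevalence * n_samples)`, hit exactly.
#' @param n_noise_features number of pure-noise features (default 100).
#' @param pairs list of planted pairs, each `c(delta = , rho = )` with
#'   `delta >= 0`, `|rho| < 1`. Defaults to one pair with delta 2.5, rho 0.7.
#' @param seed integer seed.
#' @return An object of class `planted_signature_spec`.
#' @export
planted_signature_spec <- function(n_samples = 44L, prevalence = 29 / 44,
                                   n_noise_features = 100L,
                                   pairs = list(c(delta = 2.5, rho = 0.7)),
                                   seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 4L) stop("`n_samples` must be >= 4", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) stop("`prevalence` must be in (0,1)")
  for (p in pairs) {
    if (p[["delta"]] < 0) stop("`delta` must be >= 0")
    if (abs(p[["rho"]]) >= 1) stop("`|rho|` must be < 1")
  }
  structure(list(n_samples = n_samples, prevalence = prevalence,
                 n_noise_features = as.integer(n_noise_features),
                 pairs = pairs, seed = as.integer(seed)),
            class = "planted_signature_spec")
}

#' Generate a feature table with planted discriminative pairs
#'
#' @param spec a [planted_signature_spec()].
#' @return A list with `table` (a [feature_table()]) and `truth` (data frame
#'   of planted pair columns: `feature_a`, `feature_b`, `delta`, `rho`).
#' @export
gen_feature_table <- function(spec = planted_signature_spec()) {
  stopifnot(inherits(spec, "planted_signature_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  n_pos <- as.integer(round(spec$prevalence * n))
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  u1 <- c(1, 1) / sqrt(2)   # correlated direction
  u2 <- c(1, -1) / sqrt(2)  # discriminative direction
  cols <- list(); truth <- list()
  for (q in seq_along(spec$pairs)) {
    dl <- spec$pairs[[q]][["delta"]]; rho <- spec$pairs[[q]][["rho"]]
    sign_ <- ifelse(labels == 1L, 1, -1)
    z1 <- rnorm(n); z2 <- rnorm(n)
    xy <- outer(sign_ * dl / 2, u2) +
      sqrt(1 + rho) * outer(z1, u1) + sqrt(1 - rho) * outer(z2, u2)
    a <- sprintf("planted%d_a", q); b <- sprintf("planted%d_b", q)
    cols[[a]] <- xy[, 1]; cols[[b]] <- xy[, 2]
    truth[[q]] <- data.frame(feature_a = a, feature_b = b, delta = dl,
                             rho = rho, stringsAsFactors = FALSE)
  }
  if (spec$n_noise_features > 0L) {
    noise <- matrix(rnorm(n * spec$n_noise_features), n)
    colnames(noise) <- sprintf("noise_%03d", seq_len(spec$n_noise_features))
    for (nm in colnames(noise)) cols[[nm]] <- noise[, nm]
  }
  x <- do.call(cbind, cols)
  list(table = feature_table(x, labels), truth = do.call(rbind, truth))
}

## ---- phantoms --------------------------------------------------------------

#' Specification of a two-class texture phantom
#'
#' A 3D grid with an ellipsoidal lesion. The lesion signal is a constant base
#' plus multi-scale Gaussian-field texture whose amplitude is the
#' `heterogeneity` level — the knob that separates the two phantom classes
#' (recurrent-like lesions are more heterogeneous) — plus white noise.
#'
#' Intensities are on a CT-like absolute scale (lesion base 100, texture and
#' noise in the same units, think Hounsfield-like), so fixed-bin-width
#' discretization sees heterogeneous lesions as genuinely more entropic.
#'
#' @param grid_dim integer length-3 grid shape (default 32^3).
#' @param spacing mm per axis (default 1 mm isotropic).
#' @param center_mm lesion centre in mm (default grid centre).
#' @param radii_mm ellipsoid radii in mm, > 0; the lesion must fit inside
#'   the grid.
#' @param heterogeneity texture amplitude (intensity SD inside the lesion),
#'   >= 0; default 30, with ~7.5 as a typical homogeneous-class setting.
#' @param noise_sd white-noise SD, >= 0 (default 5).
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(32L, 32L, 32L), spacing = c(1, 1, 1),
                         center_mm = NULL, radii_mm = c(9, 11, 7),
                         heterogeneity = 30, noise_sd = 5, seed = 1L) {
  grid_dim <- as.integer(grid_dim)
  extent <- (grid_dim - 1L) * spacing
  if (is.null(center_mm)) center_mm <- extent / 2
  if (any(radii_mm <= 0)) stop("`radii_mm` must be > 0")
  if (any(center_mm - radii_mm < 0) || any(center_mm + radii_mm > extent))
    stop("lesion does not fit inside the grid", call. = FALSE)
  if (heterogeneity < 0 || noise_sd < 0)
    stop("`heterogeneity` and `noise_sd` must be >= 0")
  structure(list(grid_dim = grid_dim, spacing = as.numeric(spacing),
                 center_mm = as.numeric(center_mm),
                 radii_mm = as.numeric(radii_mm),
                 heterogeneity = heterogeneity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

smooth3 <- function(data, spacing, sigma_mm) {
  sv <- sigma_mm / spacing
  k <- lapply(1:3, function(a) gauss_kernel(max(sv[a], 1e-6)))
  array(cpp_conv3_sep(as.numeric(data), as.integer(dim(data)),
                      k[[1]], k[[2]], k[[3]]), dim(data))
}

#' Generate a CT-like / PET-like phantom pair with its lesion mask
#'
#' The mask is the voxelization of the ellipsoid. The CT-like volume carries
#' the lesion texture at full resolution; the PET-like volume is a smoothed,
#' rescaled sibling of the same lesion signal (emulating the lower PET
#' resolution). Identical seeds give bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `ct` and `pet` ([voxel_volume()]s) and `mask`
#'   (a [lesion_mask()]), all on the same grid.
#' @export
gen_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  dims <- spec$grid_dim; sp <- spec$spacing
  coords <- lapply(1:3, function(a) (seq_len(dims[a]) - 1L) * sp[a])
  dist2 <- array(0, dims)
  for (a in 1:3) {
    d <- (coords[[a]] - spec$center_mm[a]) / spec$radii_mm[a]
    dist2 <- dist2 + array(rep(d^2, each = prod(dims[seq_len(a - 1)])), dims)
  }
  mask_arr <- ifelse(dist2 <= 1, 1L, 0L)
  # multi-scale texture: smoothed white noise at two scales
  tex <- 0
  if (spec$heterogeneity > 0) {
    w1 <- array(rnorm(prod(dims)), dims)
    w2 <- array(rnorm(prod(dims)), dims)
    s1 <- smooth3(w1, sp, sigma_mm = 1.5 * mean(sp))
    s2 <- smooth3(w2, sp, sigma_mm = 3 * mean(sp))
    # rescale each field to unit SD so `heterogeneity` is the lesion SD
    tex <- spec$heterogeneity *
      (s1 / stats::sd(s1) + 0.5 * s2 / stats::sd(s2)) / sqrt(1.25)
  }
  wn <- if (spec$noise_sd > 0) array(rnorm(prod(dims), sd = spec$noise_sd),
                                     dims) else 0
  lesion <- array(100, dims) + tex + wn  # CT-like: soft-tissue HU scale
  ct <- array(0, dims)
  ct[mask_arr == 1L] <- lesion[mask_arr == 1L]
  pet_raw <- smooth3(ct, sp, sigma_mm = 2.5 * mean(sp)) * 0.08
  list(ct = voxel_volume(ct, sp),
       pet = voxel_volume(pet_raw, sp),
       mask = lesion_mask(mask_arr, sp))
}
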