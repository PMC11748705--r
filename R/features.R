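## The radiomic feature extraction engine: a configurable class-and-filter
## registry producing the named feature vector for one image/mask pair.
## Feature families follow the IBSI reference formulations; texture matrices
## are built by the compiled backend (src/texture.cpp).

FEATURE_CLASSES <- c("first_order", "shape_3d", "glcm", "glrlm", "glszm",
                     "ngtdm", "gldm")
CLASS_COUNTS <- c(first_order = 18L, shape_3d = 14L, glcm = 24L, glrlm = 16L,
                  glszm = 16L, ngtdm = 5L, gldm = 14L)
FILTERS <- c("original", "wavelet", "log")

#' Extraction configuration
#'
#' Controls which feature classes and image filters contribute to the feature
#' vector. Shape features are computed on the original geometry only; no
#' image interpolation is ever applied (intensities are used on their native
#' grid to preserve voxel integrity).
#'
#' @param feature_classes subset of
#'   `c("first_order","shape_3d","glcm","glrlm","glszm","ngtdm","gldm")`.
#' @param filters subset of `c("original","wavelet","log")`.
#' @param wavelet_levels positive integer; each level contributes 8 sub-bands
#'   of a 3D undecimated coif1 decomposition.
#' @param log_sigmas_mm positive reals; Laplacian-of-Gaussian scales in mm.
#' @param disc a [discretization()] used for all intensity-based features.
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(feature_classes = FEATURE_CLASSES,
                              filters = FILTERS,
                              wavelet_levels = 1L,
                              log_sigmas_mm = c(1, 2, 3, 4),
                              disc = discretization("fixed-bin-count", 64)) {
  feature_classes <- match.arg(feature_classes, FEATURE_CLASSES,
                               several.ok = TRUE)
  if (length(feature_classes) == 0L) stop("empty feature class set")
  filters <- match.arg(filters, FILTERS, several.ok = TRUE)
  if (length(filters) == 0L) stop("empty filter set")
  wavelet_levels <- as.integer(wavelet_levels)
  if (wavelet_levels < 1L) stop("`wavelet_levels` must be >= 1")
  if ("log" %in% filters &&
      (length(log_sigmas_mm) == 0L || any(log_sigmas_mm <= 0)))
    stop("`log_sigmas_mm` must be positive")
  stopifnot(inherits(disc, "discretization"))
  structure(list(feature_classes = feature_classes, filters = filters,
                 wavelet_levels = wavelet_levels,
                 log_sigmas_mm = as.numeric(log_sigmas_mm), disc = disc,
                 interpolation = "none"),
            class = "extraction_config")
}

#' Default extraction configuration
#'
#' All 7 feature classes over the original image plus one wavelet level
#' (8 sub-bands) and 4 LoG scales (1--4 mm), for a total of 1223 features:
#' 107 original-image features and 93 intensity features on each of the 12
#' filtered images.
#'
#' @return An `extraction_config`.
#' @export
default_config <- function() extraction_config()

#' Number of features implied by a configuration
#'
#' Shape features are counted once (original image only); every other
#' selected class is counted once for the original image and once per
#' filtered image (8 wavelet sub-bands per level, one LoG image per sigma).
#'
#' @param config an [extraction_config()].
#' @return Integer feature count.
#' @export
expected_feature_count <- function(config) {
  stopifnot(inherits(config, "extraction_config"))
  n_all <- sum(CLASS_COUNTS[config$feature_classes])
  nonshape <- setdiff(config$feature_classes, "shape_3d")
  n_nonshape <- sum(CLASS_COUNTS[nonshape])
  n_filtered <- 0L
  if ("wavelet" %in% config$filters)
    n_filtered <- n_filtered + 8L * config$wavelet_levels
  if ("log" %in% config$filters)
    n_filtered <- n_filtered + length(config$log_sigmas_mm)
  as.integer(n_all * ("original" %in% config$filters) +
               n_nonshape * n_filtered)
}

## ---- filter bank -----------------------------------------------------------

COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578, 0.8525720202116004,
              0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
              -0.8525720202116004, 0.3848648468648578,
              0.07273261951252645, -0.015655728135791993)

# dilate a filter with 2^(level-1) - 1 zeros between taps (a trous scheme)
dilate_filter <- function(f, level) {
  if (level == 1L) return(f)
  step <- 2L^(level - 1L)
  out <- numeric((length(f) - 1L) * step + 1L)
  out[seq(1L, length(out), by = step)] <- f
  out
}

# one-level undecimated 3D wavelet decomposition: 8 same-size sub-bands
wavelet_subbands <- function(data, level = 1L) {
  dims <- dim(data)
  lo <- dilate_filter(COIF1_LO, level)
  hi <- dilate_filter(COIF1_HI, level)
  out <- list()
  for (cx in c("L", "H")) for (cy in c("L", "H")) for (cz in c("L", "H")) {
    fx <- if (cx == "L") lo else hi
    fy <- if (cy == "L") lo else hi
    fz <- if (cz == "L") lo else hi
    name <- paste0(cx, cy, cz)
    out[[name]] <- array(cpp_conv3_sep(as.numeric(data), as.integer(dims),
                                       fx, fy, fz), dims)
  }
  out
}

gauss_kernel <- function(sigma_vox, deriv2 = FALSE) {
  r <- max(1L, ceiling(4 * sigma_vox))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  if (!deriv2) return(g)
  g * (t^2 - sigma_vox^2) / sigma_vox^4
}

# scale-normalized Laplacian of Gaussian at sigma (mm), anisotropy-aware
log_filter <- function(data, spacing, sigma_mm) {
  dims <- dim(data)
  sv <- sigma_mm / spacing  # per-axis sigma in voxel units
  acc <- array(0, dims)
  for (ax in 1:3) {
    ker <- lapply(1:3, function(a) gauss_kernel(sv[a], deriv2 = (a == ax)))
    d2 <- array(cpp_conv3_sep(as.numeric(data), as.integer(dims),
                              ker[[1]], ker[[2]], ker[[3]]), dims)
    # second derivative is per voxel^2 along this axis; convert to mm^-2
    acc <- acc + d2 / spacing[ax]^2
  }
  sigma_mm^2 * acc  # scale normalization
}

## ---- per-family statistics -------------------------------------------------

entropy_bits <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

fo_stats <- function(x, lev_p, voxel_vol) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- unname(quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7))
  rob <- x[x >= qs[1] & x <= qs[4]]
  c(Energy = sum(x^2),
    TotalEnergy = voxel_vol * sum(x^2),
    Entropy = entropy_bits(lev_p),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[4],
    Maximum = max(x),
    Mean = mu,
    Median = median(x),
    InterquartileRange = qs[3] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation =
      if (length(rob)) mean(abs(rob - mean(rob))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((x - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(lev_p^2))
}

glcm_stats <- function(M) {
  ng <- nrow(M)
  P <- M / sum(M)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # difference |i-j| and sum i+j marginals
  k_d <- 0:(ng - 1)
  pd <- vapply(k_d, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_s <- 2:(2 * ng)
  ps <- vapply(k_s, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(k_d * pd)
  sa <- sum(k_s * ps)
  hx <- entropy_bits(px); hy <- entropy_bits(py)
  hxy <- entropy_bits(as.vector(P))
  pxy <- outer(px, py)
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  hxy2 <- entropy_bits(as.vector(pxy))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sdx > 0 && sdy > 0)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else 1
  offd <- i != j
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy_bits(pd),
    DifferenceVariance = sum((k_d - da)^2 * pd),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[offd] / (i[offd] - j[offd])^2),
    MaximumProbability = max(P),
    SumAverage = sa,
    SumEntropy = entropy_bits(ps),
    SumSquares = sum((i - mux)^2 * P),
    SumVariance = sum((k_s - sa)^2 * ps))
}

# shared small/large run-or-zone statistics; jname distinguishes families
rl_like_stats <- function(M, n_vox, kind = c("glrlm", "glszm")) {
  kind <- match.arg(kind)
  nz <- sum(M)
  P <- M / nz
  i <- row(P); j <- col(P)
  pi_ <- rowSums(P); pj <- colSums(P)
  mui <- sum(seq_len(nrow(P)) * pi_)
  muj <- sum(seq_len(ncol(P)) * pj)
  v <- c(sum(P / j^2), sum(P * j^2),
         sum(rowSums(M)^2) / nz, sum(rowSums(P)^2),
         sum(colSums(M)^2) / nz, sum(colSums(P)^2),
         nz / n_vox,
         sum(P * (i - mui)^2), sum(P * (j - muj)^2),
         entropy_bits(as.vector(P)),
         sum(P / i^2), sum(P * i^2),
         sum(P / (i^2 * j^2)), sum(P * i^2 / j^2),
         sum(P * j^2 / i^2), sum(P * i^2 * j^2))
  names(v) <- if (kind == "glrlm")
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  else
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  v
}

ngtdm_stats <- function(tab) {
  nvec <- tab[, 1]; svec <- tab[, 2]
  N <- sum(nvec)
  p <- nvec / N
  lv <- seq_along(p)
  keep <- which(p > 0)
  ngp <- length(keep)
  coarse <- { d <- sum(p * svec); if (d > 0) min(1 / d, 1e6) else 1e6 }
  contr <- if (ngp > 1) {
    s1 <- 0
    for (a in keep) for (b in keep) s1 <- s1 + p[a] * p[b] * (a - b)^2
    (s1 / (ngp * (ngp - 1))) * (sum(svec) / N)
  } else 0
  busy_den <- 0; cplx <- 0; str_num <- 0
  for (a in keep) for (b in keep) {
    busy_den <- busy_den + abs(a * p[a] - b * p[b])
    cplx <- cplx + abs(a - b) * (p[a] * svec[a] + p[b] * svec[b]) /
      (p[a] + p[b])
    str_num <- str_num + (p[a] + p[b]) * (a - b)^2
  }
  busy <- if (busy_den > 0) sum(p * svec) / busy_den else 0
  strength <- if (sum(svec) > 0) str_num / sum(svec) else 0
  c(Coarseness = coarse, Contrast = contr, Busyness = busy,
    Complexity = cplx / N, Strength = strength)
}

gldm_stats <- function(M) {
  nz <- sum(M)
  P <- M / nz
  i <- row(P); j <- col(P)
  mui <- sum(seq_len(nrow(P)) * rowSums(P))
  muj <- sum(seq_len(ncol(P)) * colSums(P))
  c(SmallDependenceEmphasis = sum(P / j^2),
    LargeDependenceEmphasis = sum(P * j^2),
    GrayLevelNonUniformity = sum(rowSums(M)^2) / nz,
    DependenceNonUniformity = sum(colSums(M)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2),
    GrayLevelVariance = sum(P * (i - mui)^2),
    DependenceVariance = sum(P * (j - muj)^2),
    DependenceEntropy = entropy_bits(as.vector(P)),
    LowGrayLevelEmphasis = sum(P / i^2),
    HighGrayLevelEmphasis = sum(P * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2))
}

shape_stats <- function(mask) {
  sp <- mask$spacing
  n <- sum(mask$data)
  vol <- n * prod(sp)
  area <- ref_surface_area(mask)
  idx <- which(mask$data == 1L, arr.ind = TRUE) - 1L
  w <- voxel_to_world(mask, idx)
  # diameters from surface voxels only (extremes lie on the boundary)
  surf <- surface_voxels(mask)
  ws <- voxel_to_world(mask, surf)
  d3 <- if (nrow(ws) > 1L) max(stats::dist(ws)) else 0
  # largest in-plane diameter over slices orthogonal to one voxel axis
  d2 <- function(fix_axis) {
    best <- 0
    for (v in unique(surf[, fix_axis])) {
      pts <- ws[surf[, fix_axis] == v, , drop = FALSE]
      if (nrow(pts) > 1L) best <- max(best, max(stats::dist(pts)))
    }
    best
  }
  ev <- if (nrow(w) > 1L) {
    lam <- sort(eigen(stats::cov(w), symmetric = TRUE,
                      only.values = TRUE)$values, decreasing = TRUE)
    pmax(lam, 0)
  } else c(0, 0, 0)
  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  c(VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = sph,
    SphericalDisproportion = 1 / sph,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2(3),
    Maximum2DDiameterColumn = d2(2),
    Maximum2DDiameterRow = d2(1),
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

surface_voxels <- function(mask) {
  dims <- dim(mask$data)
  m <- mask$data
  pad <- array(0L, dims + 2L)
  pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- m
  inner <- pad[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)]
  nb6 <- pad[1:dims[1], 2:(dims[2] + 1), 2:(dims[3] + 1)] +
         pad[3:(dims[1] + 2), 2:(dims[2] + 1), 2:(dims[3] + 1)] +
         pad[2:(dims[1] + 1), 1:dims[2], 2:(dims[3] + 1)] +
         pad[2:(dims[1] + 1), 3:(dims[2] + 2), 2:(dims[3] + 1)] +
         pad[2:(dims[1] + 1), 2:(dims[2] + 1), 1:dims[3]] +
         pad[2:(dims[1] + 1), 2:(dims[2] + 1), 3:(dims[3] + 2)]
  which(inner == 1L & nb6 < 6L, arr.ind = TRUE) - 1L
}

## ---- engine ----------------------------------------------------------------

CLASS_PREFIX <- c(first_order = "firstorder", shape_3d = "shape",
                  glcm = "glcm", glrlm = "glrlm", glszm = "glszm",
                  ngtdm = "ngtdm", gldm = "gldm")

intensity_features <- function(data, mask, disc, classes, spacing) {
  vol <- voxel_volume(data, spacing = mask$spacing, origin = mask$origin,
                      direction = mask$direction)
  lev <- discretize_intensities(vol, mask, disc)
  nlev <- attr(lev, "n_levels")
  dims <- as.integer(dim(lev))
  levvec <- as.integer(lev)
  n_vox <- sum(mask$data)
  out <- c()
  if ("first_order" %in% classes) {
    x <- data[mask$data == 1L]
    p <- tabulate(lev[!is.na(lev)], nbins = nlev) / n_vox
    out <- c(out, prefixed(fo_stats(x, p, prod(spacing)), "firstorder"))
  }
  if ("glcm" %in% classes)
    out <- c(out, prefixed(glcm_stats(cpp_glcm(levvec, dims, nlev)), "glcm"))
  if ("glrlm" %in% classes)
    out <- c(out, prefixed(rl_like_stats(cpp_glrlm(levvec, dims, nlev),
                                         n_vox, "glrlm"), "glrlm"))
  if ("glszm" %in% classes)
    out <- c(out, prefixed(rl_like_stats(cpp_glszm(levvec, dims, nlev),
                                         n_vox, "glszm"), "glszm"))
  if ("ngtdm" %in% classes)
    out <- c(out, prefixed(ngtdm_stats(cpp_ngtdm(levvec, dims, nlev)),
                           "ngtdm"))
  if ("gldm" %in% classes)
    out <- c(out, prefixed(gldm_stats(cpp_gldm(levvec, dims, nlev)), "gldm"))
  out
}

prefixed <- function(v, cls) stats::setNames(v, paste0(cls, "_", names(v)))

#' Extract the radiomic feature vector for one image/mask pair
#'
#' Computes every feature implied by the configuration on the original image
#' and on each filtered image (wavelet sub-bands, LoG scales). Feature names
#' follow the `filter_class_feature` scheme, e.g.
#' `original_firstorder_Entropy` or `wavelet-LLH_glcm_Contrast`.
#'
#' @param image a [voxel_volume()].
#' @param mask a matching nonempty [lesion_mask()].
#' @param config an [extraction_config()].
#' @return A named numeric vector of length `expected_feature_count(config)`.
#'   Non-finite values (possible only for degenerate regions) are reported
#'   with a warning and left in place for the caller to filter.
#' @export
extract_features <- function(image, mask, config = default_config()) {
  check_pair(image, mask)
  stopifnot(inherits(config, "extraction_config"))
  classes <- config$feature_classes
  nonshape <- setdiff(classes, "shape_3d")
  out <- c()
  if ("original" %in% config$filters) {
    v <- intensity_features(image$data, mask, config$disc, nonshape,
                            image$spacing)
    if (length(v)) out <- c(out, stats::setNames(v, paste0("original_", names(v))))
    if ("shape_3d" %in% classes) {
      sh <- prefixed(shape_stats(mask), "shape")
      out <- c(out, stats::setNames(sh, paste0("original_", names(sh))))
    }
  }
  if ("wavelet" %in% config$filters && length(nonshape)) {
    for (l in seq_len(config$wavelet_levels)) {
      sb <- wavelet_subbands(image$data, level = l)
      tag <- if (config$wavelet_levels > 1L) paste0("-L", l) else ""
      for (nm in names(sb)) {
        v <- intensity_features(sb[[nm]], mask, config$disc, nonshape,
                                image$spacing)
        out <- c(out, stats::setNames(
          v, paste0("wavelet", tag, "-", nm, "_", names(v))))
      }
    }
  }
  if ("log" %in% config$filters && length(nonshape)) {
    for (s in config$log_sigmas_mm) {
      fl <- log_filter(image$data, image$spacing, s)
      v <- intensity_features(fl, mask, config$disc, nonshape, image$spacing)
      out <- c(out, stats::setNames(
        v, paste0("log-sigma-", format(s), "-mm_", names(v))))
    }
  }
  if (anyDuplicated(names(out))) stop("internal: duplicate feature names")
  bad <- !is.finite(out)
  if (any(bad))
    warning("non-finite feature value(s): ",
            paste(names(out)[bad], collapse = ", "))
  out
}
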