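## Native reference implementations of the six signature features, written as
## plain first-principles loops over the masked region. They are deliberately
## independent of the compiled texture-matrix backend used by the extraction
## engine, so the two paths cross-check each other.

neighbour_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

#' Reference texture features
#'
#' First-principles implementations of the four texture statistics that make
#' up the CT and PET signatures: first-order entropy, gray-level dependence
#' matrix (GLDM) large dependence emphasis, gray-level run-length matrix
#' (GLRLM) run variance, and neighbouring gray-tone difference matrix (NGTDM)
#' strength. Conventions: GLDM dependence counted with tolerance 0 over the
#' 26-neighbourhood with the centre voxel included (minimum dependence 1);
#' GLRLM uses the 13 unique 3D directions with matrices summed before
#' statistics; NGTDM uses the mean over available 26-neighbours.
#'
#' @param name one of `"first_order_entropy"`,
#'   `"gldm_large_dependence_emphasis"`, `"glrlm_run_variance"`,
#'   `"ngtdm_strength"`.
#' @param volume a [voxel_volume()].
#' @param mask a matching nonempty [lesion_mask()].
#' @param disc a [discretization()].
#' @return A single finite numeric value.
#' @export
reference_texture_feature <- function(name, volume, mask,
                                      disc = discretization()) {
  name <- match.arg(name, c("first_order_entropy",
                            "gldm_large_dependence_emphasis",
                            "glrlm_run_variance", "ngtdm_strength"))
  lev <- discretize_intensities(volume, mask, disc)
  switch(name,
    first_order_entropy = ref_entropy(lev),
    gldm_large_dependence_emphasis = ref_gldm_lde(lev),
    glrlm_run_variance = ref_glrlm_run_variance(lev),
    ngtdm_strength = ref_ngtdm_strength(lev))
}

ref_entropy <- function(lev) {
  x <- lev[!is.na(lev)]
  p <- tabulate(x, nbins = max(x)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

ref_gldm_lde <- function(lev) {
  dims <- dim(lev)
  off <- neighbour_offsets_26()
  idx <- which(!is.na(lev), arr.ind = TRUE)
  dep <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    ijk <- idx[r, ]
    g <- lev[ijk[1], ijk[2], ijk[3]]
    d <- 1L  # the centre voxel counts in its own dependence
    for (o in seq_len(nrow(off))) {
      nb <- ijk + off[o, ]
      if (any(nb < 1L) || any(nb > dims)) next
      gnb <- lev[nb[1], nb[2], nb[3]]
      if (!is.na(gnb) && gnb == g) d <- d + 1L
    }
    dep[r] <- d
  }
  mean(dep^2)  # sum P(i,j) j^2 with P = counts / Nz collapses to a mean
}

ref_glrlm_matrix <- function(lev) {
  dims <- dim(lev)
  dirs <- rbind(c(1,0,0), c(0,1,0), c(0,0,1),
                c(1,1,0), c(1,-1,0), c(1,0,1), c(1,0,-1), c(0,1,1), c(0,1,-1),
                c(1,1,1), c(1,1,-1), c(1,-1,1), c(1,-1,-1))
  nlev <- max(lev, na.rm = TRUE)
  runs <- matrix(0, nlev, sum(dims))
  at <- function(p) {
    if (any(p < 1L) || any(p > dims)) return(NA_integer_)
    lev[p[1], p[2], p[3]]
  }
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (d in seq_len(nrow(dirs))) {
    dd <- dirs[d, ]
    for (r in seq_len(nrow(idx))) {
      p0 <- idx[r, ]
      g <- at(p0)
      prev <- at(p0 - dd)
      if (!is.na(prev) && prev == g) next  # not a run start
      len <- 1L
      nxt <- p0 + dd
      while (!is.na(at(nxt)) && at(nxt) == g) { len <- len + 1L; nxt <- nxt + dd }
      runs[g, len] <- runs[g, len] + 1
    }
  }
  runs
}

ref_glrlm_run_variance <- function(lev) {
  M <- ref_glrlm_matrix(lev)
  P <- M / sum(M)
  j <- seq_len(ncol(P))
  pj <- colSums(P)
  mu <- sum(pj * j)
  sum(pj * (j - mu)^2)
}

ref_ngtdm_strength <- function(lev) {
  dims <- dim(lev)
  off <- neighbour_offsets_26()
  nlev <- max(lev, na.rm = TRUE)
  nvec <- numeric(nlev); svec <- numeric(nlev)
  idx <- which(!is.na(lev), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    ijk <- idx[r, ]
    g <- lev[ijk[1], ijk[2], ijk[3]]
    nb <- numeric(0)
    for (o in seq_len(nrow(off))) {
      q <- ijk + off[o, ]
      if (any(q < 1L) || any(q > dims)) next
      gq <- lev[q[1], q[2], q[3]]
      if (!is.na(gq)) nb <- c(nb, gq)
    }
    if (length(nb) == 0L) next
    nvec[g] <- nvec[g] + 1
    svec[g] <- svec[g] + abs(g - mean(nb))
  }
  p <- nvec / sum(nvec)
  keep <- which(p > 0)
  den <- sum(svec)
  if (den == 0) return(0)
  num <- 0
  for (i in keep) for (j in keep) num <- num + (p[i] + p[j]) * (i - j)^2
  num / den
}

#' Reference shape features
#'
#' Voxel-based conventions: the maximum 3D diameter is the largest Euclidean
#' distance (mm) between centres of in-mask voxels, and the surface area is
#' the total area of voxel faces exposed to the outside (not a meshed
#' surface). Both are exactly brute-force checkable; they differ from
#' mesh-based definitions by up to the voxel scale.
#'
#' @param name `"max_3d_diameter"` or `"surface_volume_ratio"`.
#' @param mask a nonempty [lesion_mask()].
#' @return A non-negative numeric value.
#' @export
reference_shape_feature <- function(name, mask) {
  name <- match.arg(name, c("max_3d_diameter", "surface_volume_ratio"))
  stopifnot(inherits(mask, "lesion_mask"))
  if (sum(mask$data) == 0L) stop("mask is empty", call. = FALSE)
  if (name == "max_3d_diameter") {
    idx <- which(mask$data == 1L, arr.ind = TRUE) - 1L
    w <- voxel_to_world(mask, idx)
    if (nrow(w) == 1L) return(0)
    max(stats::dist(w))
  } else {
    ref_surface_area(mask) / (sum(mask$data) * prod(mask$spacing))
  }
}

ref_surface_area <- function(mask) {
  dims <- dim(mask$data)
  sp <- mask$spacing
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  off <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  area <- 0
  idx <- which(mask$data == 1L, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    for (o in 1:6) {
      nb <- idx[r, ] + off[o, ]
      exposed <- any(nb < 1L) || any(nb > dims) ||
        mask$data[nb[1], nb[2], nb[3]] == 0L
      if (exposed) area <- area + face_area[ceiling(o / 2)]
    }
  }
  area
}
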