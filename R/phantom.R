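# Zero-download substrate: a synthetic labeled head phantom and a bank of
# smooth random velocity fields, standing in for an atlas + registration-
# derived velocity fields. Not anatomically realistic by design; it carries
# the statistical structure the simulation needs (nested tissue intensities,
# three disjoint role regions with the required spatial relations).

# ellipsoid mask in voxel coordinates; center/radii in voxels (0-based)
ellipsoidMask <- function(gridDim, center, radii) {
  x <- seq_len(gridDim[1]) - 1
  y <- seq_len(gridDim[2]) - 1
  z <- seq_len(gridDim[3]) - 1
  dx2 <- ((x - center[1]) / radii[1])^2
  dy2 <- ((y - center[2]) / radii[2])^2
  dz2 <- ((z - center[3]) / radii[3])^2
  m <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  storage.mode(m) <- "integer"
  m
}

# does any face-neighboring voxel pair connect mask a and mask b?
masksAdjacent <- function(a, b) {
  d <- dim(a)
  shift <- function(m, ax, by) {
    out <- array(0L, d)
    idx <- lapply(d, seq_len)
    src <- idx; dst <- idx
    n <- d[ax]
    if (by == 1) { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
    else { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(1, -1))
    if (any(shift(a, ax, by) & b)) return(TRUE)
  FALSE
}

#' Generate a synthetic labeled head phantom
#'
#' Builds a head-like template (nested ellipsoidal tissue intensities on a
#' constant zero background) with labeled subregions. Three regions carry
#' the roles needed for bias trials: a disease region in the left
#' hemisphere, a near-bias region face-adjacent to it, and a far-bias region
#' in the mirrored hemisphere sharing no axial (z) slice with the disease
#' region. Role regions receive distinct intensity levels so deformations of
#' them are visible to an image-based classifier.
#'
#' @param gridShape integer triple, each dimension at least 16. The
#'   full-scale analogue is 173 x 211 x 155 at 1 mm; desk-scale grids
#'   (16-32 voxels) are the default working size.
#' @param seed integer; the phantom is deterministic in it.
#' @param roleRegionFrac target role-region volume as a fraction of head
#'   volume (1-3% is anatomically plausible for insula/putamen-sized
#'   structures).
#' @param textureAmplitude amplitude of the smooth deterministic intensity
#'   texture added to break symmetry.
#' @return a [PhantomTemplate-class].
#' @export
makePhantomTemplate <- function(gridShape = c(32, 32, 32), seed = 0,
                                roleRegionFrac = 0.02,
                                textureAmplitude = 0.02) {
  gridShape <- as.integer(gridShape)
  if (length(gridShape) != 3 || any(gridShape < 16))
    stop("configuration error: each grid dimension must be at least 16")
  nx <- gridShape[1]; ny <- gridShape[2]; nz <- gridShape[3]
  ctr <- (gridShape - 1) / 2

  headR <- 0.42 * gridShape
  head <- ellipsoidMask(gridShape, ctr, headR)
  inner <- ellipsoidMask(gridShape, ctr, 0.30 * gridShape)
  vent <- ellipsoidMask(gridShape, ctr, 0.08 * gridShape)
  headVol <- sum(head)

  # role region radius from the target volume fraction
  r <- (3 * roleRegionFrac * headVol / (4 * pi))^(1 / 3)

  relPos <- function(fx, fy, fz) c(fx * (nx - 1), fy * (ny - 1), fz * (nz - 1))
  cDis <- relPos(0.30, 0.50, 0.42)
  disease <- ellipsoidMask(gridShape, cDis, rep(r, 3))
  # near-bias: ellipsoid overlapping the disease region, minus it -> the cut
  # guarantees at least one face-adjacent voxel pair
  cNear <- cDis + c(0, 1.6 * r, 0)
  near <- ellipsoidMask(gridShape, cNear, rep(r, 3))
  near <- near & !disease
  storage.mode(near) <- "integer"
  # far-bias: mirrored hemisphere, axial range disjoint from the disease's
  cFar <- relPos(0.70, 0.50, 0.42)
  zDis <- range(which(apply(disease, 3, sum) > 0))
  zFar <- min(nz - 1 - 1.2 * r, cDis[3] + 2.6 * r + 2)
  cFar[3] <- zFar
  far <- ellipsoidMask(gridShape, cFar, rep(r, 3))
  # filler regions give the saliency score table realistic competition
  contra <- ellipsoidMask(gridShape, relPos(0.70, 0.50, 0.42), rep(r, 3))
  frontal <- ellipsoidMask(gridShape, relPos(0.50, 0.24, 0.50), rep(r, 3))

  lab <- array(0L, gridShape)
  lab[head == 1] <- 1L
  lab[inner == 1 & head == 1] <- 2L
  lab[vent == 1] <- 3L
  place <- function(lab, m, id) { lab[m == 1 & head == 1] <- id; lab }
  lab <- place(lab, contra, 13L)
  lab <- place(lab, frontal, 14L)
  lab <- place(lab, disease, 10L)
  lab <- place(lab, near, 11L)
  lab <- place(lab, far, 12L)

  disease <- (lab == 10L) * 1; dim(disease) <- gridShape
  near <- (lab == 11L) * 1; dim(near) <- gridShape
  far <- (lab == 12L) * 1; dim(far) <- gridShape
  if (sum(disease) == 0 || sum(near) == 0 || sum(far) == 0)
    stop("configuration error: grid too small to place the three role regions")
  if (!masksAdjacent(array(as.integer(disease), gridShape),
                     array(as.integer(near), gridShape)))
    stop("configuration error: near-bias region not adjacent to disease region")
  zSliceDis <- which(apply(disease, 3, sum) > 0)
  zSliceFar <- which(apply(far, 3, sum) > 0)
  if (length(intersect(zSliceDis, zSliceFar)))
    stop("configuration error: far-bias region shares an axial slice with the disease region")

  # role regions get strong contrast against the surrounding tissue so that
  # deformations of them are visible to an image-based classifier
  levels <- c(`1` = 0.45, `2` = 0.75, `3` = 0.15, `10` = 0.95, `11` = 0.10,
              `12` = 0.10, `13` = 0.60, `14` = 0.65)
  vol <- array(0, gridShape)
  for (id in names(levels)) vol[lab == as.integer(id)] <- levels[[id]]
  vol <- cpp_gaussian_smooth(vol, 0.6)
  tex <- withSeed(seed, array(rnorm(prod(gridShape)), gridShape))
  tex <- cpp_gaussian_smooth(tex, 2)
  tex <- tex / max(abs(tex))
  vol <- vol + textureAmplitude * tex * (head == 1)
  vol[head == 0] <- 0

  rt <- data.frame(
    id = c(1L, 2L, 3L, 10L, 11L, 12L, 13L, 14L),
    role = c("other", "other", "other", "disease_region", "near_bias_region",
             "far_bias_region", "other", "other"),
    name = c("cortex", "deep_tissue", "ventricle", "disease_target",
             "near_bias_target", "far_bias_target", "contralateral_target",
             "frontal_blob"),
    stringsAsFactors = FALSE)
  rt$voxel_count <- vapply(rt$id, function(i) sum(lab == i), integer(1))
  rt <- rt[rt$voxel_count > 0, ]

  new("PhantomTemplate", intensity = vol, labels = lab, regionTable = rt,
      background = 0)
}

#' Generate a bank of smooth random velocity fields
#'
#' Each field is Gaussian-smoothed white noise per component, zeroed outside
#' the head mask (with a smooth interior taper toward the head surface, as
#' registration-derived velocity fields decay smoothly at the brain
#' boundary), and scaled so its maximum displacement magnitude equals
#' `amplitude` voxels. Fields are mutually independent given distinct
#' sub-draws of the seeded generator; the bank is deterministic in `seed`.
#'
#' @param template a [PhantomTemplate-class].
#' @param nFields number of fields (>= 2; 50 mirrors a typical
#'   registration-derived bank).
#' @param smoothnessSigma Gaussian smoothing width in voxels.
#' @param amplitude maximum displacement magnitude in voxels (> 0).
#' @param seed integer seed.
#' @return list of velocity field arrays.
#' @export
makePhantomFieldBank <- function(template, nFields = 50, smoothnessSigma = 4,
                                 amplitude = 2, seed = 0) {
  if (nFields < 2) stop("nFields must be at least 2")
  if (amplitude <= 0) stop("amplitude must be > 0")
  gd <- dim(regionLabels(template))
  headMask <- (regionLabels(template) > 0) * 1
  dim(headMask) <- gd
  # linear distance ramp to zero at the head surface (continuous; a hard cut
  # would make the exponential lose inverse consistency at the boundary)
  w <- max(2L, as.integer(round(1.5 * smoothnessSigma)))
  taper <- array(0, gd)
  cur <- headMask
  for (k in seq_len(w)) {
    cur <- 1 - cpp_dilate(1 - cur, 1L)  # erode
    taper <- taper + cur
  }
  taper <- (headMask + taper) / (w + 1)
  withSeed(seed, {
    lapply(seq_len(nFields), function(i) {
      f <- array(0, c(gd, 3L))
      for (c in 1:3) {
        comp <- array(rnorm(prod(gd)), gd)
        comp <- cpp_gaussian_smooth(comp, smoothnessSigma)
        f[, , , c] <- comp * taper
      }
      mag <- sqrt(f[, , , 1]^2 + f[, , , 2]^2 + f[, , , 3]^2)
      f * (amplitude / max(mag))
    })
  })
}
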