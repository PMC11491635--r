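# Deformation algebra: PCA effect models over stationary velocity fields,
# region masking, Log-Euclidean exponentiation (scaling and squaring) and
# template warping. Fields are arrays dim (nx,ny,nz,3), voxel units.

flattenField <- function(field) as.vector(field)

unflattenField <- function(v, gridDim) array(v, dim = c(gridDim, 3L))

#' Fit a PCA generative model to velocity fields
#'
#' The mean field is the voxelwise mean; components and scales come from an
#' SVD of the mean-centered flattened fields. With `nComponents = n - 1` the
#' model reconstructs every training field to numerical precision.
#'
#' @param fields list of velocity fields, all on the same grid.
#' @param nComponents number of components to retain (at most `n - 1`).
#' @param supportMask optional binary mask recorded with the model (fields
#'   should already be restricted to it, see [restrictToRegion()]).
#' @return an [EffectModel-class].
#' @export
fitEffectModel <- function(fields, nComponents, supportMask = NULL) {
  n <- length(fields)
  if (n < 2) stop("at least 2 fields are required to fit an effect model")
  d <- dim(fields[[1]])
  for (f in fields) {
    if (!identical(dim(f), d))
      stop("all fields must share the same grid shape")
  }
  gridDim <- as.integer(d[1:3])
  if (nComponents > n - 1)
    stop("nComponents must be at most length(fields) - 1")
  X <- t(vapply(fields, flattenField, numeric(prod(d))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = nComponents)
  k <- nComponents
  scales <- sv$d[seq_len(k)] / sqrt(n - 1)
  basis <- sv$v[, seq_len(k), drop = FALSE]
  new("EffectModel", meanField = unflattenField(mu, gridDim),
      basis = basis, scales = scales, gridDim = gridDim,
      supportMask = supportMask)
}

# standardized (Mahalanobis) norm of coefficients; components with zero
# scale carry no variance and are excluded
effectMagnitude <- function(coefficients, scales) {
  nz <- scales > 0
  if (!any(nz)) return(0)
  sqrt(sum((coefficients[nz] / scales[nz])^2))
}

#' Draw one effect sample from a PCA model
#'
#' Coefficients are independent zero-mean normals with the model's
#' per-component standard deviations; the sampled field is
#' `meanField + sum(coef_k * component_k)`. The magnitude is the Mahalanobis
#' norm of the coefficients (a scale-free scalar used for stratification).
#' When `targetMagnitude` is given the coefficients are rescaled to hit it
#' exactly; 0 returns the mean field.
#'
#' @param model an [EffectModel-class] with at least one nonzero scale.
#' @param seed integer; the draw is a pure function of `(model, seed)`.
#' @param targetMagnitude optional non-negative scalar.
#' @param materialize build the field array (set FALSE to keep only
#'   coefficients, e.g. when designing large cohorts).
#' @return an [EffectSample-class].
#' @export
sampleEffect <- function(model, seed, targetMagnitude = NULL,
                         materialize = TRUE) {
  scales <- model@scales
  if (!any(scales > 0))
    stop("model has no component with nonzero scale")
  if (!is.null(targetMagnitude) && targetMagnitude < 0)
    stop("targetMagnitude must be >= 0")
  coefs <- withSeed(seed, rnorm(length(scales), mean = 0, sd = scales))
  if (!is.null(targetMagnitude)) {
    m <- effectMagnitude(coefs, scales)
    coefs <- if (m == 0) coefs * 0 else coefs * (targetMagnitude / m)
    if (targetMagnitude == 0) coefs[] <- 0
  }
  sampleFromCoefficients(model, coefs, materialize = materialize)
}

# deterministic construction of an EffectSample from given coefficients
sampleFromCoefficients <- function(model, coefs, materialize = TRUE) {
  field <- if (materialize) {
    v <- flattenField(model@meanField) + as.vector(model@basis %*% coefs)
    unflattenField(v, model@gridDim)
  } else NULL
  new("EffectSample", coefficients = as.numeric(coefs), field = field,
      magnitude = effectMagnitude(coefs, model@scales))
}

# n draws of coefficients only; rows are samples (cohort design)
sampleCoefficientMatrix <- function(model, n, seed) {
  scales <- model@scales
  withSeed(seed, {
    matrix(rnorm(n * length(scales), mean = 0, sd = rep(scales, each = n)),
           nrow = n)
  })
}

#' Restrict a velocity field to a labeled region
#'
#' Multiplies the field by the region mask smoothed with a Gaussian of width
#' `boundarySigma` (renormalized to max 1), giving a localized effect with a
#' smooth boundary. Weights below 1e-8 are set exactly to zero, so the
#' restricted field has compact support.
#'
#' @param field velocity field array (nx,ny,nz,3).
#' @param mask binary 3D array on the same grid; must be non-empty.
#' @param boundarySigma Gaussian width in voxels; 0 gives a hard mask.
#' @return velocity field with support inside the (smoothed) mask.
#' @export
restrictToRegion <- function(field, mask, boundarySigma = 0) {
  stopifnotShape(field, mask, "field and mask")
  if (boundarySigma < 0) stop("boundarySigma must be >= 0")
  m <- (mask > 0) * 1
  dim(m) <- dim(mask)[1:3]
  if (sum(m) == 0) stop("mask is empty: a localized effect must have support")
  w <- if (boundarySigma == 0) m else cpp_gaussian_smooth(m, boundarySigma)
  w <- w / max(w)
  w[w < 1e-8] <- 0
  out <- field
  for (c in 1:3) out[, , , c] <- field[, , , c] * w
  out
}

#' Exponentiate a stationary velocity field (scaling and squaring)
#'
#' Computes the displacement field of the group exponential in the
#' Log-Euclidean framework: the field is scaled by `2^-nSquarings`, taken as
#' a small displacement, and composed with itself `nSquarings` times using
#' trilinear interpolation.
#'
#' @param field velocity field (nx,ny,nz,3), voxel units.
#' @param nSquarings number of squaring steps (default 6).
#' @return displacement field array of the same shape.
#' @export
exponentiate <- function(field, nSquarings = 6) {
  if (nSquarings < 0) stop("nSquarings must be >= 0")
  u <- field / (2^nSquarings)
  for (i in seq_len(nSquarings)) u <- cpp_compose_disp(u, u)
  u
}

#' Compose effect velocity fields
#'
#' Effects combine by velocity-field addition before a single exponentiation
#' (Log-Euclidean sum), which is order-independent and needs one
#' interpolation pass.
#'
#' @param subject global subject-morphology velocity field.
#' @param disease,bias optional localized effect fields (NULL to omit).
#' @return the summed velocity field.
#' @export
composeEffectFields <- function(subject, disease = NULL, bias = NULL) {
  out <- subject
  if (!is.null(disease)) {
    stopifnotShape(out, disease, "subject and disease fields")
    out <- out + disease
  }
  if (!is.null(bias)) {
    stopifnotShape(out, bias, "subject and bias fields")
    out <- out + bias
  }
  out
}

#' Compose two displacement fields
#'
#' `composeDisplacements(a, b)` applies `a` first, then `b`:
#' `(x) -> a(x) + b(x + a(x))` with border-clamped trilinear sampling.
#'
#' @param a,b displacement fields on the same grid.
#' @return displacement field of the composition.
#' @export
composeDisplacements <- function(a, b) {
  stopifnotShape(a, b, "displacement fields")
  cpp_compose_disp(a, b)
}

#' Warp a volume by a displacement field
#'
#' Backward warping with trilinear interpolation: output(x) = input(x + d(x)).
#' Out-of-bounds samples take `background`, which defaults to the most
#' frequent corner value of the input (brain templates have constant
#' background).
#'
#' @param volume 3D numeric array.
#' @param displacement displacement field (nx,ny,nz,3) in voxel units.
#' @param background scalar fill value for out-of-bounds samples.
#' @return warped 3D array.
#' @export
warpVolume <- function(volume, displacement, background = NULL) {
  stopifnotShape(volume, displacement, "volume and displacement")
  if (is.null(background)) background <- cornerBackground(volume)
  cpp_warp_volume(volume, displacement, background)
}

#' Jacobian determinant of a displacement field
#'
#' Determinant of the Jacobian of the map `x + d(x)` by central differences
#' (one-sided at the boundary). Strictly positive values everywhere indicate
#' a locally invertible (diffeomorphic) deformation.
#'
#' @param displacement displacement field (nx,ny,nz,3).
#' @return 3D array of determinants.
#' @export
jacobianDeterminant <- function(displacement) {
  cpp_jacobian_det(displacement)
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable FIR Gaussian (kernel truncated at 4 sigma, zero boundary).
#'
#' @param volume 3D numeric array.
#' @param sigma standard deviation in voxels.
#' @return smoothed array.
#' @export
gaussianSmooth <- function(volume, sigma) {
  if (sigma < 0) stop("sigma must be >= 0")
  cpp_gaussian_smooth(volume, sigma)
}

#' Binary dilation of a mask
#'
#' Chebyshev (box) dilation by `radius` voxels.
#'
#' @param mask 3D 0/1 array.
#' @param radius integer dilation radius.
#' @return dilated 0/1 array.
#' @export
dilateMask <- function(mask, radius) {
  m <- (mask > 0) * 1
  dim(m) <- dim(mask)[1:3]
  cpp_dilate(m, as.integer(radius))
}

#' Serialize an effect model to a tar archive
#'
#' Writes mean field and components as NIfTI vector fields plus a YAML
#' metadata header (grid shape, number of components, scales, mask) into a
#' single `.tar` archive.
#'
#' @param model an [EffectModel-class].
#' @param path output `.tar` path.
#' @return `path`, invisibly.
#' @export
writeEffectModel <- function(model, path) {
  tmp <- tempfile("effectmodel")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  writeNifti(model@meanField, file.path(tmp, "mean.nii.gz"))
  k <- ncol(model@basis)
  for (i in seq_len(k))
    writeNifti(unflattenField(model@basis[, i], model@gridDim),
               file.path(tmp, sprintf("component_%03d.nii.gz", i)))
  if (!is.null(model@supportMask))
    writeNifti(model@supportMask, file.path(tmp, "support_mask.nii.gz"))
  meta <- list(grid_shape = as.integer(model@gridDim),
               n_components = k,
               component_scales = as.numeric(model@scales),
               has_support_mask = !is.null(model@supportMask))
  yaml::write_yaml(meta, file.path(tmp, "meta.yaml"))
  owd <- setwd(tmp)
  on.exit(setwd(owd), add = TRUE, after = FALSE)
  utils::tar(path.expand(path), files = list.files(tmp), tar = "internal")
  invisible(path)
}

#' Read an effect model archive written by [writeEffectModel()]
#'
#' @param path a `.tar` archive.
#' @return an [EffectModel-class].
#' @export
readEffectModel <- function(path) {
  tmp <- tempfile("effectmodel")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  untar(path.expand(path), exdir = tmp, tar = "internal")
  meta <- yaml::read_yaml(file.path(tmp, "meta.yaml"))
  gridDim <- as.integer(meta$grid_shape)
  mu <- readNifti(file.path(tmp, "mean.nii.gz"))
  k <- meta$n_components
  basis <- matrix(0, nrow = 3 * prod(gridDim), ncol = k)
  for (i in seq_len(k))
    basis[, i] <- as.vector(readNifti(
      file.path(tmp, sprintf("component_%03d.nii.gz", i))))
  mask <- if (isTRUE(meta$has_support_mask))
    readNifti(file.path(tmp, "support_mask.nii.gz")) else NULL
  mf <- array(as.numeric(mu), dim = c(gridDim, 3L))
  if (!is.null(mask)) { mask <- array(as.numeric(mask), dim = gridDim) }
  new("EffectModel", meanField = mf, basis = basis,
      scales = as.numeric(meta$component_scales), gridDim = gridDim,
      supportMask = mask)
}
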