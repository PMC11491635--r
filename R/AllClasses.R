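# S4 classes for the central objects. Velocity / displacement fields stay
# plain numeric arrays dim (nx,ny,nz,3) in voxel units (0-based index space);
# wrapping every field would cost more than it buys in a simulation loop.

#' PCA generative model over stationary velocity fields
#'
#' Fitted by [fitEffectModel()]. `basis` holds the orthonormal principal
#' velocity fields as columns of a (3*prod(gridDim)) x k matrix;
#' `scales` are the per-component standard deviations (sqrt of the PCA
#' eigenvalues) in non-increasing order.
#'
#' @slot meanField numeric array (nx,ny,nz,3), the voxelwise mean field.
#' @slot basis numeric matrix of flattened orthonormal components.
#' @slot scales numeric, per-component standard deviations.
#' @slot gridDim integer triple.
#' @slot supportMask optional binary array the model was restricted to, or NULL.
#' @export
setClass("EffectModel",
  representation(meanField = "array", basis = "matrix", scales = "numeric",
                 gridDim = "integer", supportMask = "ANY"),
  validity = function(object) {
    msg <- character()
    p <- 3L * prod(object@gridDim)
    if (!identical(dim(object@meanField), c(object@gridDim, 3L)))
      msg <- c(msg, "meanField dimensions do not match gridDim x 3")
    if (nrow(object@basis) != p)
      msg <- c(msg, "basis row count does not match grid")
    if (ncol(object@basis) != length(object@scales))
      msg <- c(msg, "one scale per component required")
    if (length(object@scales) &&
        any(diff(object@scales) > 1e-8 * max(object@scales, 1)))
      msg <- c(msg, "component scales must be non-increasing")
    if (ncol(object@basis) > 1) {
      g <- crossprod(object@basis)
      if (max(abs(g - diag(ncol(g)))) > 1e-6)
        msg <- c(msg, "components must be orthonormal (tol 1e-6)")
    }
    if (!all(is.finite(object@meanField)))
      msg <- c(msg, "meanField must be finite")
    if (length(msg)) msg else TRUE
  })

#' A sampled deformation effect
#'
#' One draw from an [EffectModel-class]: PCA coefficients, optionally the
#' materialized velocity field, and the standardized (Mahalanobis) magnitude
#' used for stratification.
#'
#' @slot coefficients numeric, one value per retained component.
#' @slot field numeric array (nx,ny,nz,3) or NULL when not materialized.
#' @slot magnitude non-negative scalar; 0 iff all coefficients are 0.
#' @export
setClass("EffectSample",
  representation(coefficients = "numeric", field = "ANY", magnitude = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@magnitude) != 1 || object@magnitude < 0)
      msg <- c(msg, "magnitude must be a scalar >= 0")
    zero <- all(object@coefficients == 0)
    if (zero != (object@magnitude == 0))
      msg <- c(msg, "magnitude must be 0 iff all coefficients are 0")
    if (length(msg)) msg else TRUE
  })

#' Synthetic labeled head phantom
#'
#' A head-like template volume with an integer label map and a region table
#' assigning the roles `disease_region`, `near_bias_region` and
#' `far_bias_region` (plus unlabeled-role regions) to label ids.
#'
#' @slot intensity numeric 3D array in [0,1].
#' @slot labels integer 3D array, 0 = background.
#' @slot regionTable data.frame with columns id, role, name, voxel_count.
#' @slot background scalar background intensity.
#' @export
setClass("PhantomTemplate",
  representation(intensity = "array", labels = "array",
                 regionTable = "data.frame", background = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@intensity), dim(object@labels)))
      msg <- c(msg, "intensity and labels must share a grid")
    need <- c("disease_region", "near_bias_region", "far_bias_region")
    if (!all(need %in% object@regionTable$role))
      msg <- c(msg, "regionTable must assign all three role regions")
    if (length(msg)) msg else TRUE
  })

#' 3D CNN disease classifier
#'
#' Weights for the convolutional encoder (`blocks`) and the dense disease
#' head, plus the configuration used to build it. Training state (history,
#' best epoch) is attached by [trainClassifier()].
#'
#' @slot blocks list of per-block parameters (W, b, gamma, beta, run_mean,
#'   run_var).
#' @slot headW numeric matrix (features x 1), the disease head.
#' @slot headb numeric, head bias.
#' @slot config the [modelConfig()] list used.
#' @slot inputShape integer triple.
#' @slot trained logical.
#' @slot history data.frame of per-epoch losses, or NULL.
#' @export
setClass("CnnClassifier",
  representation(blocks = "list", headW = "matrix", headb = "numeric",
                 config = "list", inputShape = "integer", trained = "logical",
                 history = "ANY"))

#' Linear scoring stand-in model
#'
#' Scores a volume as `sum(weights * x) + bias`. Used as an analytically
#' tractable model for validating gradient-based saliency.
#'
#' @slot weights numeric array matching the input volume.
#' @slot bias scalar offset.
#' @export
setClass("LinearScorer",
  representation(weights = "array", bias = "numeric"))

#' Subgroup confusion counts and rates
#'
#' Confusion counts per bias group and aggregate, with accuracy/TPR/FPR in
#' percent. Rates are recomputed from the stored counts on access, so no
#' rounding accumulates; a rate whose denominator is zero is NA (flagged
#' missing, never 0).
#'
#' @slot counts data.frame with rows non_bias, bias, aggregate and columns
#'   TP, FN, FP, TN.
#' @export
setClass("GroupMetrics",
  representation(counts = "data.frame"),
  validity = function(object) {
    cc <- object@counts
    msg <- character()
    if (!all(c("TP", "FN", "FP", "TN") %in% names(cc)))
      msg <- c(msg, "counts must have TP, FN, FP, TN")
    if (!all(c("non_bias", "bias", "aggregate") %in% rownames(cc)))
      msg <- c(msg, "counts must have rows non_bias, bias, aggregate")
    else {
      agg <- cc["aggregate", c("TP", "FN", "FP", "TN")]
      sums <- cc["non_bias", c("TP", "FN", "FP", "TN")] +
        cc["bias", c("TP", "FN", "FP", "TN")]
      if (!isTRUE(all.equal(as.numeric(agg), as.numeric(sums))))
        msg <- c(msg, "aggregate counts must equal the sum of group counts")
    }
    if (length(msg)) msg else TRUE
  })

setMethod("show", "EffectModel", function(object) {
  cat("EffectModel on", paste(object@gridDim, collapse = "x"), "grid;",
      ncol(object@basis), "components\n")
  cat("  scales:", paste(signif(object@scales, 4), collapse = ", "), "\n")
  if (!is.null(object@supportMask))
    cat("  restricted support:", sum(object@supportMask > 0), "voxels\n")
})

setMethod("show", "EffectSample", function(object) {
  cat("EffectSample:", length(object@coefficients), "coefficients, magnitude",
      signif(object@magnitude, 4),
      if (is.null(object@field)) "(field not materialized)\n" else "\n")
})

setMethod("show", "PhantomTemplate", function(object) {
  cat("PhantomTemplate", paste(dim(object@intensity), collapse = "x"), "\n")
  print(object@regionTable, row.names = FALSE)
})

setMethod("show", "CnnClassifier", function(object) {
  nf <- vapply(object@blocks, function(b) ncol(b$W), integer(1))
  cat("CnnClassifier input", paste(object@inputShape, collapse = "x"),
      "| blocks:", paste(nf, collapse = ","),
      "|", countParams(object), "trainable parameters",
      if (object@trained) "(trained)\n" else "(untrained)\n")
})

setMethod("show", "GroupMetrics", function(object) {
  print(metricsTable(object))
})

#' @describeIn EffectModel voxelwise mean velocity field
#' @param object an object.
#' @export
setGeneric("meanField", function(object) standardGeneric("meanField"))
setMethod("meanField", "EffectModel", function(object) object@meanField)

#' @describeIn EffectModel per-component standard deviations
#' @export
setGeneric("componentScales", function(object) standardGeneric("componentScales"))
setMethod("componentScales", "EffectModel", function(object) object@scales)

#' @describeIn EffectModel number of retained components
#' @export
setGeneric("nComponents", function(object) standardGeneric("nComponents"))
setMethod("nComponents", "EffectModel", function(object) ncol(object@basis))

#' @describeIn EffectSample standardized effect magnitude
#' @export
setGeneric("magnitude", function(object) standardGeneric("magnitude"))
setMethod("magnitude", "EffectSample", function(object) object@magnitude)

#' @describeIn EffectSample the sampled velocity field (materialized)
#' @export
setGeneric("effectField", function(object, ...) standardGeneric("effectField"))
setMethod("effectField", "EffectSample", function(object, ...) object@field)

#' @rdname EffectSample-class
#' @param object an `EffectSample`.
#' @param ... unused.
#' @export
setMethod("coef", "EffectSample", function(object, ...) object@coefficients)

#' @describeIn PhantomTemplate template intensity volume
#' @export
setGeneric("intensityVolume", function(object) standardGeneric("intensityVolume"))
setMethod("intensityVolume", "PhantomTemplate", function(object) object@intensity)

#' @describeIn PhantomTemplate integer label volume
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
setMethod("regionLabels", "PhantomTemplate", function(object) object@labels)

#' @describeIn PhantomTemplate region id/role/name table
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))
setMethod("regionTable", "PhantomTemplate", function(object) object@regionTable)

#' Binary mask of a template region by role or id
#'
#' @param template a [PhantomTemplate-class].
#' @param role one of the roles in `regionTable(template)` (e.g.
#'   `"disease_region"`), or an integer region id.
#' @return numeric 0/1 array.
#' @export
regionMask <- function(template, role) {
  rt <- regionTable(template)
  id <- if (is.numeric(role)) role else {
    hit <- rt$id[rt$role == role]
    if (!length(hit)) stop("no region with role '", role, "'")
    hit[1]
  }
  m <- (regionLabels(template) == id) * 1
  dim(m) <- dim(regionLabels(template))
  m
}
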