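# SmoothGrad saliency (mean absolute input gradient of the positive-class
# pre-threshold score over noisy copies), subgroup-averaged maps, and
# region-wise weighted saliency scores (size-normalized enrichment).

#' Linear scoring stand-in model
#'
#' @param weights numeric array matching the volumes to be scored.
#' @param bias scalar offset.
#' @return a [LinearScorer-class]; its score is `sum(weights * x) + bias`
#'   and its input gradient is `weights` everywhere, making saliency
#'   analytically checkable.
#' @export
linearScorer <- function(weights, bias = 0) {
  new("LinearScorer", weights = weights, bias = bias)
}

#' SmoothGrad saliency map
#'
#' Mean over `nNoise` draws of the absolute input gradient of the
#' positive-class pre-threshold score, evaluated at the volume plus Gaussian
#' noise with standard deviation `noiseFraction * (max - min)` of the
#' volume's intensity range. `noiseFraction = 0` reduces to the plain
#' absolute gradient map. Deterministic in `seed`.
#'
#' @param model a [CnnClassifier-class] or [LinearScorer-class].
#' @param volume 3D array matching the model input.
#' @param nNoise number of noisy draws (default 25).
#' @param noiseFraction noise SD as a fraction of the intensity range
#'   (default 0.10).
#' @param seed RNG seed.
#' @return nonnegative 3D saliency array with metadata attributes.
#' @export
setGeneric("smoothGrad", function(model, volume, nNoise = 25,
                                  noiseFraction = 0.10, seed = 0)
  standardGeneric("smoothGrad"))

saliencyMeta <- function(map, nNoise, noiseFraction) {
  attr(map, "n_noise") <- nNoise
  attr(map, "noise_fraction") <- noiseFraction
  map
}

#' @rdname smoothGrad
setMethod("smoothGrad", "CnnClassifier",
  function(model, volume, nNoise = 25, noiseFraction = 0.10, seed = 0) {
    if (nNoise < 1) stop("nNoise must be >= 1")
    if (!identical(dim(volume), model@inputShape))
      stop("volume shape does not match the model input shape")
    rng <- diff(range(volume))
    sdev <- noiseFraction * rng
    d <- dim(volume)
    batch <- withSeed(seed, {
      b <- array(rep(as.vector(volume), nNoise), c(d, nNoise))
      if (sdev > 0) b <- b + array(rnorm(length(b), sd = sdev), dim(b))
      b
    })
    r <- cnnRun(model, batch, loss = "score", inputGrad = TRUE)
    g <- abs(r$input_grad)
    map <- array(rowMeans(matrix(g, nrow = prod(d))), d)
    saliencyMeta(map, nNoise, noiseFraction)
  })

#' @rdname smoothGrad
setMethod("smoothGrad", "LinearScorer",
  function(model, volume, nNoise = 25, noiseFraction = 0.10, seed = 0) {
    if (nNoise < 1) stop("nNoise must be >= 1")
    # the gradient of a linear score is the weight array, at any input and
    # noise level
    map <- abs(model@weights)
    saliencyMeta(map, nNoise, noiseFraction)
  })

#' Average saliency map of a subgroup
#'
#' Voxelwise mean of per-subject SmoothGrad maps over the first `nSubjects`
#' correctly classified test-split subjects of the requested (class, group)
#' cell, ordered by subject id. If fewer are available, all are used with a
#' warning.
#'
#' @param model a [CnnClassifier-class].
#' @param dataset list with `x` and `manifest`.
#' @param classLabel disease class of the cell (0/1).
#' @param groupLabel bias group of the cell (0/1).
#' @param nSubjects number of subjects to average (default 10).
#' @param split evaluation split (default `"test"`).
#' @param nNoise,noiseFraction,seed passed to [smoothGrad()].
#' @param predictions optional precomputed data.frame from
#'   [predictLabels()] for the split (avoids re-scoring).
#' @return 3D saliency array.
#' @export
averageGroupSaliency <- function(model, dataset, classLabel, groupLabel,
                                 nSubjects = 10, split = "test", nNoise = 25,
                                 noiseFraction = 0.10, seed = 0,
                                 predictions = NULL) {
  mf <- dataset$manifest
  sel <- mf$split == split & mf$disease_label == classLabel &
    mf$bias_group == groupLabel
  ids <- sort(mf$subject_id[sel])
  if (is.null(predictions))
    predictions <- predictLabels(model, dataset$x[ids])
  pr <- predictions[match(ids, predictions$subject_id), ]
  ok <- ids[!is.na(pr$label) & pr$label == classLabel]
  if (!length(ok))
    stop("no correctly classified subjects in the requested cell")
  if (length(ok) < nSubjects)
    warning("only ", length(ok), " correctly classified subjects available; ",
            "using all of them")
  use <- head(ok, nSubjects)
  maps <- lapply(use, function(id)
    smoothGrad(model, dataset$x[[id]], nNoise = nNoise,
               noiseFraction = noiseFraction, seed = seed))
  out <- Reduce(`+`, maps) / length(maps)
  attr(out, "subjects") <- use
  out
}

#' Region-wise weighted saliency scores
#'
#' For each labeled region r, the score is the mean saliency intensity in r
#' divided by the mean saliency intensity over all labeled voxels — a
#' dimensionless enrichment. Uniform saliency gives every region a score of
#' 1; the voxel-count-weighted mean of the scores is 1.
#'
#' @param saliency nonnegative 3D array.
#' @param labels integer label array (0 = background, excluded).
#' @param regionTable optional data.frame with id/role/name merged into the
#'   output.
#' @return data.frame with region_id, score, voxel_count (plus role/name if
#'   a region table is given).
#' @export
weightedSaliencyScores <- function(saliency, labels, regionTable = NULL) {
  if (!identical(dim(saliency), dim(labels)[1:3]))
    stop("saliency and labels must share a grid")
  lab <- as.vector(labels)
  sal <- as.vector(saliency)
  keep <- lab > 0
  ids <- sort(unique(lab[keep]))
  if (!length(ids)) stop("label volume has no labeled region")
  total <- sum(sal[keep])
  nLabeled <- sum(keep)
  out <- data.frame(region_id = ids,
                    voxel_count = vapply(ids, function(i) sum(lab == i),
                                         numeric(1)))
  if (total == 0) {
    warning("all-zero saliency: region scores are undefined")
    out$score <- NA_real_
  } else {
    sums <- vapply(ids, function(i) sum(sal[lab == i]), numeric(1))
    out$score <- (sums / total) / (out$voxel_count / nLabeled)
  }
  if (!is.null(regionTable)) {
    rt <- regionTable[, c("id", "role", "name")]
    out <- merge(rt, out, by.x = "id", by.y = "region_id", sort = TRUE)
    names(out)[names(out) == "id"] <- "region_id"
  }
  out
}
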