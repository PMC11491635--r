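# Counterfactual dataset composition: class/bias-group assignment with fixed
# proportions, magnitude stratification across the class-by-group cells,
# paired No-Bias / Near-Bias / Far-Bias volume generation, and shared
# stratified train/val/test splits.

#' Dataset composition configuration
#'
#' Defaults mirror the full-scale design: 1000 disease / 1002 non-disease
#' subjects, 70% of the disease class and 30% of the non-disease class in
#' the bias group, 50/25/25 splits, 4 stratification bins.
#'
#' @param nDisease,nNondisease class sizes.
#' @param pBiasDisease,pBiasNondisease bias-group fraction per class.
#' @param splitFractions train/val/test fractions (must sum to 1).
#' @param nStratBins quantile bins used for magnitude stratification.
#' @param seed integer seed governing all composition randomness.
#' @return a `compositionConfig` list.
#' @export
compositionConfig <- function(nDisease = 1000, nNondisease = 1002,
                              pBiasDisease = 0.70, pBiasNondisease = 0.30,
                              splitFractions = c(0.50, 0.25, 0.25),
                              nStratBins = 4, seed = 0) {
  stopifnot(pBiasDisease >= 0, pBiasDisease <= 1,
            pBiasNondisease >= 0, pBiasNondisease <= 1,
            length(splitFractions) == 3, all(splitFractions >= 0),
            nStratBins >= 2)
  if (abs(sum(splitFractions) - 1) > 1e-9)
    stop("splitFractions must sum to 1")
  structure(list(nDisease = nDisease, nNondisease = nNondisease,
                 pBiasDisease = pBiasDisease,
                 pBiasNondisease = pBiasNondisease,
                 splitFractions = splitFractions,
                 nStratBins = nStratBins, seed = seed),
            class = "compositionConfig")
}

#' Assign disease and bias-group labels
#'
#' Exactly `nDisease` disease and `nNondisease` non-disease subjects; per
#' class, `round(p * n)` subjects (round half away from zero) belong to the
#' bias group. Which subjects land in the bias group, and the order of the
#' roster, are randomized by the config seed.
#'
#' @param config a [compositionConfig()].
#' @return data.frame with subject_id, disease_label, bias_group.
#' @export
assignLabels <- function(config) {
  nD <- config$nDisease; nN <- config$nNondisease
  if (nD <= 0 || nN <= 0) stop("class sizes must be positive")
  nbD <- as.integer(roundHalfAway(config$pBiasDisease * nD))
  nbN <- as.integer(roundHalfAway(config$pBiasNondisease * nN))
  if (nbD == 0 && config$pBiasDisease > 0)
    warning("pBiasDisease > 0 rounds to zero bias-group subjects")
  if (nbN == 0 && config$pBiasNondisease > 0)
    warning("pBiasNondisease > 0 rounds to zero bias-group subjects")
  withSeed(config$seed, {
    disease <- c(rep(1L, nD), rep(0L, nN))
    bias <- integer(nD + nN)
    bias[sample(which(disease == 1L), nbD)] <- 1L
    bias[sample(which(disease == 0L), nbN)] <- 1L
    ord <- sample(nD + nN)
    data.frame(subject_id = sprintf("S%05d", seq_len(nD + nN)),
               disease_label = disease[ord], bias_group = bias[ord],
               stringsAsFactors = FALSE)
  })
}

#' Two-sample Kolmogorov-Smirnov statistic and critical value
#'
#' `ksStatistic` is the max absolute ECDF difference; `ksCriticalValue` is
#' the asymptotic two-sample critical value
#' `sqrt(-log(alpha/2)/2) * sqrt((n1+n2)/(n1*n2))`.
#'
#' @param x,y numeric samples.
#' @return scalar statistic.
#' @export
ksStatistic <- function(x, y) {
  g <- sort(unique(c(x, y)))
  ex <- vapply(g, function(t) mean(x <= t), numeric(1))
  ey <- vapply(g, function(t) mean(y <= t), numeric(1))
  max(abs(ex - ey))
}

#' @rdname ksStatistic
#' @param n1,n2 sample sizes.
#' @param alpha significance level (default 0.10).
#' @export
ksCriticalValue <- function(n1, n2, alpha = 0.10) {
  sqrt(-log(alpha / 2) / 2) * sqrt((n1 + n2) / (n1 * n2))
}

# evenly interleaved dealing sequence: cell names repeated size_c times,
# arranged so each cell appears at near-uniform rank spacing (Bresenham)
dealingSequence <- function(cellSizes) {
  total <- sum(cellSizes)
  acc <- numeric(length(cellSizes))
  left <- as.numeric(cellSizes)
  out <- character(total)
  for (i in seq_len(total)) {
    acc <- acc + cellSizes / total
    # pick the cell with the largest accumulated credit that still has demand
    cand <- which(left > 0)
    j <- cand[which.max(acc[cand])]
    out[i] <- names(cellSizes)[j]
    acc[j] <- acc[j] - 1
    left[j] <- left[j] - 1
  }
  out
}

#' Stratify effect magnitudes across cells
#'
#' Samples are ranked by magnitude and dealt to cells in an evenly
#' interleaved order proportional to cell sizes, so every cell receives a
#' near-identical magnitude distribution (quantile-bin counts differ by at
#' most one). The starting rotation and magnitude ties are randomized by
#' `seed`. When the pool exceeds total demand, a seeded random subset of the
#' pool is used.
#'
#' @param magnitudes numeric vector, one per pool sample.
#' @param cellSizes named integer vector of cell demands.
#' @param nBins number of quantile bins the contract is stated over (>= 2;
#'   recorded, the dealing itself is rank-based and finer than any binning).
#' @param seed integer seed.
#' @return data.frame with pool_index and cell, one row per dealt sample.
#' @export
stratifyMagnitudes <- function(magnitudes, cellSizes, nBins = 4, seed = 0) {
  total <- sum(cellSizes)
  if (length(magnitudes) < total)
    stop("pool smaller than total cell demand")
  if (nBins < 2) stop("nBins must be >= 2")
  withSeed(seed, {
    use <- if (length(magnitudes) > total) sort(sample(length(magnitudes), total))
           else seq_along(magnitudes)
    m <- magnitudes[use]
    ord <- order(m, stats::runif(length(m)))  # random tie-break
    seqc <- dealingSequence(cellSizes)
    rot <- sample(length(seqc), 1) - 1
    seqc <- c(seqc[-seq_len(rot)], seqc[seq_len(rot)])
    data.frame(pool_index = use[ord], cell = seqc,
               stringsAsFactors = FALSE)
  })
}

#' Design a counterfactual cohort
#'
#' Draws subject, disease and bias effect coefficients from the three PCA
#' models and assigns them to subjects such that magnitude distributions are
#' stratified across the class-by-group cells: subject magnitudes across all
#' four cells, disease magnitudes across the two cells of the disease class,
#' bias magnitudes across the two cells of the bias group. Disease effects
#' are only given to disease-class subjects; bias coefficients are shared
#' across scenarios (the counterfactual contract).
#'
#' @param models named list with elements `subject`, `disease`, `bias`
#'   ([EffectModel-class] objects on a common grid).
#' @param config a [compositionConfig()].
#' @param poolFactor pool oversampling factor (>= 1).
#' @return a `cohort` list: `subjects` data.frame (labels, magnitudes,
#'   split), coefficient matrices, and the config.
#' @export
designCohort <- function(models, config, poolFactor = 1.2) {
  subj <- assignLabels(config)
  n <- nrow(subj)
  cellOf <- function(d, b) paste0("d", d, "b", b)
  subj$cell <- cellOf(subj$disease_label, subj$bias_group)

  poolN <- ceiling(n * poolFactor)
  subjCoef <- sampleCoefficientMatrix(models$subject, poolN, config$seed + 1)
  subjMag <- apply(subjCoef, 1, effectMagnitude, scales = models$subject@scales)
  cells <- table(subj$cell)
  cellSizes <- setNames(as.integer(cells), names(cells))
  deal <- stratifyMagnitudes(subjMag, cellSizes, config$nStratBins,
                             config$seed + 2)
  # map dealt pool rows to subjects within each cell (seeded order)
  subj$subject_row <- NA_integer_
  withSeed(config$seed + 3, {
    for (cl in names(cellSizes)) {
      rows <- deal$pool_index[deal$cell == cl]
      members <- which(subj$cell == cl)
      subj$subject_row[members] <- rows[sample(length(rows))]
    }
  })
  subj$subject_magnitude <- subjMag[subj$subject_row]

  nDis <- sum(subj$disease_label == 1)
  disPool <- ceiling(nDis * poolFactor)
  disCoef <- sampleCoefficientMatrix(models$disease, disPool, config$seed + 4)
  disMag <- apply(disCoef, 1, effectMagnitude, scales = models$disease@scales)
  disCells <- table(subj$cell[subj$disease_label == 1])
  dealD <- stratifyMagnitudes(disMag, setNames(as.integer(disCells),
                                               names(disCells)),
                              config$nStratBins, config$seed + 5)
  subj$disease_row <- NA_integer_
  withSeed(config$seed + 6, {
    for (cl in names(disCells)) {
      rows <- dealD$pool_index[dealD$cell == cl]
      members <- which(subj$cell == cl & subj$disease_label == 1)
      subj$disease_row[members] <- rows[sample(length(rows))]
    }
  })
  subj$disease_magnitude <- ifelse(is.na(subj$disease_row), NA,
                                   disMag[subj$disease_row])

  nBias <- sum(subj$bias_group == 1)
  biasRowsAssigned <- NULL
  biasCoef <- NULL
  subj$bias_row <- NA_integer_
  subj$bias_magnitude <- NA_real_
  if (nBias > 0) {
    biasPool <- ceiling(nBias * poolFactor)
    biasCoef <- sampleCoefficientMatrix(models$bias, biasPool, config$seed + 7)
    biasMag <- apply(biasCoef, 1, effectMagnitude, scales = models$bias@scales)
    biasCells <- table(subj$cell[subj$bias_group == 1])
    dealB <- stratifyMagnitudes(biasMag, setNames(as.integer(biasCells),
                                                  names(biasCells)),
                                config$nStratBins, config$seed + 8)
    withSeed(config$seed + 9, {
      for (cl in names(biasCells)) {
        rows <- dealB$pool_index[dealB$cell == cl]
        members <- which(subj$cell == cl & subj$bias_group == 1)
        subj$bias_row[members] <- rows[sample(length(rows))]
      }
    })
    subj$bias_magnitude <- ifelse(is.na(subj$bias_row), NA,
                                  biasMag[subj$bias_row])
  }

  cohort <- list(subjects = subj, subjectCoef = subjCoef, diseaseCoef = disCoef,
                 biasCoef = biasCoef, config = config)
  cohort$subjects <- splitCohort(cohort)$subjects
  structure(cohort, class = "cohort")
}

#' Assign stratified train/val/test splits
#'
#' Stratification keys are (disease label, bias group, subject-magnitude
#' quantile bin, disease-magnitude quantile bin); within each stratum the
#' split fractions are honored by largest-remainder rounding. Strata smaller
#' than 3 subjects fall back to the coarser (disease, bias) stratum with a
#' warning. The split is assigned at subject level, so it is identical for a
#' given subject across scenarios (and across model seeds).
#'
#' @param cohort a cohort from [designCohort()] (which already calls this;
#'   exported for re-splitting with a changed config).
#' @return the cohort with an updated `split` column.
#' @export
splitManifest <- function(cohort) splitCohort(cohort)

# stratified train/val/test split at subject level (scenario-invariant)
splitCohort <- function(cohort) {
  subj <- cohort$subjects
  config <- cohort$config
  nb <- config$nStratBins
  magBin <- function(m) {
    out <- integer(length(m))
    ok <- !is.na(m)
    if (any(ok)) {
      br <- unique(quantile(m[ok], probs = seq(0, 1, length.out = nb + 1)))
      out[ok] <- as.integer(cut(m[ok], breaks = br, include.lowest = TRUE))
    }
    out
  }
  subj$sbin <- magBin(subj$subject_magnitude)
  subj$dbin <- magBin(subj$disease_magnitude)
  key <- paste(subj$disease_label, subj$bias_group, subj$sbin, subj$dbin)
  # fall back to coarser strata where a stratum has fewer than 3 subjects
  tab <- table(key)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    warning("falling back to coarser stratification for ", length(small),
            " small strata")
    coarse <- paste(subj$disease_label, subj$bias_group)
    key[key %in% small] <- coarse[key %in% small]
  }
  subj$split <- NA_character_
  withSeed(config$seed + 10, {
    for (k in unique(key)) {
      members <- which(key == k)
      counts <- largestRemainder(length(members), config$splitFractions)
      lab <- rep(c("train", "val", "test"), counts)
      subj$split[members] <- lab[sample(length(members))]
    }
  })
  subj$sbin <- NULL; subj$dbin <- NULL
  cohort$subjects <- subj
  cohort
}

#' Build manifests for each scenario
#'
#' One record per subject per scenario with labels, effect magnitudes, split
#' and (optional) file path.
#'
#' @param cohort a cohort from [designCohort()].
#' @param scenarios subset of `c("no_bias", "near_bias", "far_bias")`.
#' @param outDir optional output root used to fill the file column.
#' @return named list of data.frames, one per scenario.
#' @export
buildManifests <- function(cohort,
                           scenarios = c("no_bias", "near_bias", "far_bias"),
                           outDir = NULL) {
  subj <- cohort$subjects
  out <- lapply(scenarios, function(sc) {
    data.frame(subject_id = subj$subject_id, scenario = sc,
               file = if (is.null(outDir)) NA_character_ else
                 file.path(outDir, sc, paste0(subj$subject_id, ".nii.gz")),
               disease_label = subj$disease_label,
               bias_group = subj$bias_group,
               subject_magnitude = subj$subject_magnitude,
               disease_magnitude = subj$disease_magnitude,
               bias_magnitude = subj$bias_magnitude,
               split = subj$split, stringsAsFactors = FALSE)
  })
  names(out) <- scenarios
  out
}

#' Generate the paired counterfactual datasets
#'
#' For each subject and scenario the velocity field is the Log-Euclidean sum
#' of the subject field, the disease field (disease class only) and — for
#' bias-group subjects outside the No-Bias scenario — the shared bias field
#' masked to the scenario's region. One exponentiation and one warp produce
#' the volume. Non-bias-group subjects are computed once and reused, so
#' their volumes are bit-identical across scenarios.
#'
#' @param template a [PhantomTemplate-class].
#' @param models named list of `subject`, `disease`, `bias` effect models.
#' @param config a [compositionConfig()].
#' @param scenarios scenarios to generate.
#' @param cohort optional pre-designed cohort (defaults to
#'   [designCohort()]).
#' @param boundarySigma smooth-mask width (voxels) for the bias region.
#' @param biasRegionScale optional named numeric (per scenario) multiplier
#'   applied to the masked bias field; used to equalize the effective local
#'   effect strength across bias regions (a region near the head boundary
#'   receives systematically weaker fields from a globally normalized bank).
#' @param nSquarings scaling-and-squaring steps.
#' @param outDir if non-NULL, volumes are written as NIfTI under
#'   `outDir/{scenario}/{subject_id}.nii.gz` and manifests as CSV with a
#'   sidecar YAML of the config.
#' @param keepVolumes keep volumes in memory (default TRUE).
#' @return list with `manifests`, `volumes` (per scenario, named by
#'   subject), and `cohort`.
#' @export
buildCounterfactualDatasets <- function(template, models, config,
                                        scenarios = c("no_bias", "near_bias",
                                                      "far_bias"),
                                        cohort = NULL, boundarySigma = 1,
                                        biasRegionScale = NULL,
                                        nSquarings = 6, outDir = NULL,
                                        keepVolumes = TRUE) {
  if (is.null(cohort)) cohort <- designCohort(models, config)
  subj <- cohort$subjects
  tvol <- intensityVolume(template)
  bg <- template@background
  masks <- list(near_bias = regionMask(template, "near_bias_region"),
                far_bias = regionMask(template, "far_bias_region"))

  manifests <- buildManifests(cohort, scenarios, outDir)
  volumes <- lapply(scenarios, function(sc) vector("list", nrow(subj)))
  names(volumes) <- scenarios
  if (!is.null(outDir))
    for (sc in scenarios)
      dir.create(file.path(outDir, sc), recursive = TRUE, showWarnings = FALSE)

  makeVolume <- function(i, scenario) {
    vs <- unflattenField(flattenField(models$subject@meanField) +
      as.vector(models$subject@basis %*% cohort$subjectCoef[subj$subject_row[i], ]),
      models$subject@gridDim)
    vd <- NULL; vb <- NULL
    if (subj$disease_label[i] == 1) {
      vd <- unflattenField(flattenField(models$disease@meanField) +
        as.vector(models$disease@basis %*% cohort$diseaseCoef[subj$disease_row[i], ]),
        models$disease@gridDim)
    }
    if (subj$bias_group[i] == 1 && scenario != "no_bias") {
      raw <- unflattenField(flattenField(models$bias@meanField) +
        as.vector(models$bias@basis %*% cohort$biasCoef[subj$bias_row[i], ]),
        models$bias@gridDim)
      vb <- restrictToRegion(raw, masks[[scenario]], boundarySigma)
      if (!is.null(biasRegionScale) && scenario %in% names(biasRegionScale))
        vb <- vb * biasRegionScale[[scenario]]
    }
    v <- composeEffectFields(vs, vd, vb)
    warpVolume(tvol, exponentiate(v, nSquarings), background = bg)
  }

  for (i in seq_len(nrow(subj))) {
    base <- NULL # the no-bias volume, shared wherever the field is identical
    for (sc in scenarios) {
      needsBias <- subj$bias_group[i] == 1 && sc != "no_bias"
      if (!needsBias) {
        if (is.null(base)) base <- makeVolume(i, "no_bias")
        v <- base
      } else v <- makeVolume(i, sc)
      if (keepVolumes) volumes[[sc]][[i]] <- v
      if (!is.null(outDir))
        writeNifti(v, file.path(outDir, sc, paste0(subj$subject_id[i], ".nii.gz")))
    }
  }
  for (sc in scenarios) names(volumes[[sc]]) <- subj$subject_id
  if (!is.null(outDir)) {
    for (sc in scenarios)
      write.csv(manifests[[sc]], file.path(outDir, paste0("manifest_", sc, ".csv")),
                row.names = FALSE)
    yaml::write_yaml(unclass(config), file.path(outDir, "composition.yaml"))
  }
  list(manifests = manifests, volumes = if (keepVolumes) volumes else NULL,
       cohort = cohort)
}
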