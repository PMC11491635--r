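# End-to-end orchestration: phantom -> effect models -> counterfactual
# datasets -> (scenario x strategy x seed) training -> subgroup evaluation ->
# saliency scoring -> one summary table. Deterministic given the config.

#' Trial configuration
#'
#' Defaults describe the full-scale design (173x211x155 grid, 2002 subjects,
#' the 32..512-filter CNN, 5 seeds). [deskTrialConfig()] is the scaled
#' preset actually runnable on a single CPU.
#'
#' @param gridShape template grid.
#' @param templateSeed phantom / field-bank seed.
#' @param roleRegionFrac role-region volume fraction of the head.
#' @param nFields velocity-field bank size.
#' @param fieldSmoothness bank smoothing sigma (voxels).
#' @param subjectAmplitude,diseaseAmplitude,biasAmplitude max displacement
#'   (voxels) of the subject/disease/bias banks.
#' @param nComponents PCA components per effect model.
#' @param boundarySigma smooth-mask width for localized effects.
#' @param biasLocalRms optional target prior RMS displacement (voxels) of
#'   the masked bias effect inside each bias region; equalizes effect
#'   strength across the near and far scenarios (NULL disables).
#' @param nSquarings scaling-and-squaring steps.
#' @param composition a [compositionConfig()].
#' @param model a [modelConfig()].
#' @param train a [trainConfig()]; its seed is overridden per replicate.
#' @param scenarios scenarios to simulate (`no_bias` must be present when
#'   relative disparities are wanted).
#' @param seeds model weight-initialization seeds (distinct).
#' @param strategies subset of naive/reweighing/unlearning/group_models.
#' @param unlearn an [unlearnConfig()].
#' @param stats a [statsConfig()].
#' @param explain list: nNoise, noiseFraction, nSubjects.
#' @param pretrainEpochs group-model shared pretraining epochs.
#' @param outputRoot optional artifact directory.
#' @param writeVolumes also write every generated volume as NIfTI.
#' @return a `trialConfig` list.
#' @export
trialConfig <- function(gridShape = c(173, 211, 155), templateSeed = 0,
                        roleRegionFrac = 0.02, nFields = 50,
                        fieldSmoothness = 4, subjectAmplitude = 2,
                        diseaseAmplitude = 3, biasAmplitude = 3,
                        nComponents = 20, boundarySigma = 1,
                        biasLocalRms = NULL, nSquarings = 6,
                        composition = compositionConfig(),
                        model = modelConfig(), train = trainConfig(),
                        scenarios = c("no_bias", "near_bias", "far_bias"),
                        seeds = 1:5,
                        strategies = c("naive", "reweighing", "unlearning",
                                       "group_models"),
                        unlearn = unlearnConfig(), stats = statsConfig(),
                        explain = list(nNoise = 25, noiseFraction = 0.10,
                                       nSubjects = 10),
                        pretrainEpochs = 5,
                        outputRoot = NULL, writeVolumes = FALSE) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  bad <- setdiff(scenarios, c("no_bias", "near_bias", "far_bias"))
  if (length(bad)) stop("unknown scenarios: ", paste(bad, collapse = ", "))
  bad <- setdiff(strategies, c("naive", "reweighing", "unlearning",
                               "group_models"))
  if (length(bad)) stop("unknown strategies: ", paste(bad, collapse = ", "))
  structure(list(gridShape = as.integer(gridShape),
                 templateSeed = templateSeed,
                 roleRegionFrac = roleRegionFrac, nFields = nFields,
                 fieldSmoothness = fieldSmoothness,
                 subjectAmplitude = subjectAmplitude,
                 diseaseAmplitude = diseaseAmplitude,
                 biasAmplitude = biasAmplitude, nComponents = nComponents,
                 boundarySigma = boundarySigma, biasLocalRms = biasLocalRms,
                 nSquarings = nSquarings,
                 composition = composition, model = model, train = train,
                 scenarios = scenarios, seeds = seeds,
                 strategies = strategies, unlearn = unlearn, stats = stats,
                 explain = explain, pretrainEpochs = pretrainEpochs,
                 outputRoot = outputRoot, writeVolumes = writeVolumes),
            class = "trialConfig")
}

#' Desk-scale trial preset
#'
#' The scaled world used for single-CPU experiments and the test suite:
#' 16^3 grid, 220 subjects with the 70%/30% bias-group composition, a
#' 3-block (4,8,16) CNN, 3 seeds. Effect amplitudes are chosen so the
#' disease task is learnable but imperfect (the regime in which a shortcut
#' is worth taking).
#'
#' @param ... overrides forwarded to [trialConfig()].
#' @return a `trialConfig` list.
#' @export
deskTrialConfig <- function(...) {
  defaults <- list(
    gridShape = c(16, 16, 16), templateSeed = 0, roleRegionFrac = 0.03,
    nFields = 40, fieldSmoothness = 2.5, subjectAmplitude = 1.5,
    diseaseAmplitude = 2.4, biasAmplitude = 10, nComponents = 12,
    boundarySigma = 0, biasLocalRms = 4.5,
    composition = compositionConfig(nDisease = 130, nNondisease = 130,
                                    seed = 0),
    model = modelConfig(convFilters = c(4, 8, 16), blockActivation = "relu",
                        headInit = "normal"),
    train = trainConfig(batchSize = 8, learningRate = 2e-3, patience = 8,
                        maxEpochs = 30),
    seeds = 1:3,
    unlearn = unlearnConfig(alpha = 2, confusionLrFactor = 1,
                            diseaseLrFactor = 0.3, innerRounds = 6,
                            patience = 5, maxEpochs = 5, headEpochs = 60,
                            headLr = 0.02, probeEpochs = 30),
    explain = list(nNoise = 8, noiseFraction = 0.10, nSubjects = 8))
  over <- list(...)
  do.call(trialConfig, utils::modifyList(defaults, over))
}

# prior RMS displacement of an effect model inside a region:
# sqrt(mean over region voxels of ||mean(x)||^2 + sum_k lambda_k ||phi_k(x)||^2)
priorRegionRms <- function(model, mask) {
  msk <- mask == 1
  gd <- model@gridDim
  mu <- model@meanField
  e2 <- mu[, , , 1]^2 + mu[, , , 2]^2 + mu[, , , 3]^2
  sc <- model@scales
  for (k in seq_along(sc)) {
    ph <- array(model@basis[, k], c(gd, 3L))
    e2 <- e2 + sc[k]^2 * (ph[, , , 1]^2 + ph[, , , 2]^2 + ph[, , , 3]^2)
  }
  sqrt(mean(e2[msk]))
}

# fit the three effect models from phantom banks; localized disease fields
# are masked (and renormalized to the intended amplitude inside the region)
# before fitting, the bias model stays global and is masked at build time
fitTrialModels <- function(template, config) {
  diseaseMask <- regionMask(template, "disease_region")
  subjBank <- makePhantomFieldBank(template, config$nFields,
                                   config$fieldSmoothness,
                                   config$subjectAmplitude,
                                   seed = config$templateSeed + 1)
  disBank <- makePhantomFieldBank(template, config$nFields,
                                  config$fieldSmoothness,
                                  config$diseaseAmplitude,
                                  seed = config$templateSeed + 2)
  disBank <- lapply(disBank, function(f) {
    g <- restrictToRegion(f, diseaseMask, config$boundarySigma)
    mag <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
    if (max(mag) > 0) g * (config$diseaseAmplitude / max(mag)) else g
  })
  biasBank <- makePhantomFieldBank(template, config$nFields,
                                   config$fieldSmoothness,
                                   config$biasAmplitude,
                                   seed = config$templateSeed + 3)
  k <- min(config$nComponents, config$nFields - 1)
  list(subject = fitEffectModel(subjBank, k),
       disease = fitEffectModel(disBank, k, supportMask = diseaseMask),
       bias = fitEffectModel(biasBank, k))
}

# orchestration-level counterfactual guarantee: non-bias subjects must be
# bit-identical across scenario volumes before any training happens
checkCounterfactual <- function(data) {
  if (length(data$manifests) < 2) return(invisible(TRUE))
  subj <- data$cohort$subjects
  ref <- names(data$volumes)[1]
  for (sc in names(data$volumes)[-1]) {
    for (id in subj$subject_id[subj$bias_group == 0])
      if (!identical(data$volumes[[ref]][[id]], data$volumes[[sc]][[id]]))
        stop("counterfactual violation: non-bias subject ", id,
             " differs between ", ref, " and ", sc)
  }
  invisible(TRUE)
}

evalOnTest <- function(predDf) {
  gm <- groupConfusionMetrics(predDf$disease_label, predDf$label,
                              predDf$bias_group)
  tb <- metricsTable(gm)
  dsp <- disparity(gm)
  data.frame(accuracy = tb$accuracy[tb$group == "aggregate"],
             acc_bias = tb$accuracy[tb$group == "bias"],
             acc_non_bias = tb$accuracy[tb$group == "non_bias"],
             TPR_bias = tb$TPR[tb$group == "bias"],
             TPR_non_bias = tb$TPR[tb$group == "non_bias"],
             FPR_bias = tb$FPR[tb$group == "bias"],
             FPR_non_bias = tb$FPR[tb$group == "non_bias"],
             dTPR = dsp["dTPR"], dFPR = dsp["dFPR"])
}

#' Run a full in silico bias trial
#'
#' Executes generate -> split -> (scenario x strategy x seed) train ->
#' evaluate -> explain -> aggregate and returns (and optionally writes) a
#' summary table of accuracy, ΔTPR/ΔFPR, relative disparities and
#' bias-region weighted saliency scores per scenario and strategy.
#'
#' @param config a [trialConfig()].
#' @param resume when an output root holds a finished summary with a
#'   matching config hash, reload it instead of recomputing; a mismatched
#'   hash refuses to resume.
#' @param verbose log per-stage progress.
#' @return a `biasTrial` list: summary, metrics (per seed), relatives,
#'   stats, saliency, probe results, config and config hash.
#' @export
runTrial <- function(config, resume = FALSE, verbose = TRUE) {
  hash <- digest::digest(config)
  say <- function(...) if (verbose) message("[synthbias] ", ...)
  root <- config$outputRoot
  if (!is.null(root) && resume) {
    hf <- file.path(root, "trial_hash.txt")
    sf <- file.path(root, "report", "summary.csv")
    if (file.exists(hf)) {
      if (!identical(readLines(hf)[1], hash))
        stop("existing run has a different config hash; refusing to resume")
      if (file.exists(sf)) {
        say("resuming from ", root)
        out <- list(summary = read.csv(sf),
                    metrics = read.csv(file.path(root, "report", "metrics.csv")),
                    config = config, hash = hash, resumed = TRUE)
        class(out) <- "biasTrial"
        return(out)
      }
    }
  }

  say("stage 1/5: phantom template and effect models")
  template <- makePhantomTemplate(config$gridShape, config$templateSeed,
                                  config$roleRegionFrac)
  models <- fitTrialModels(template, config)

  say("stage 2/5: counterfactual datasets (",
      sum(config$composition$nDisease, config$composition$nNondisease),
      " subjects x ", length(config$scenarios), " scenarios)")
  biasRegionScale <- NULL
  if (!is.null(config$biasLocalRms)) {
    biasRegionScale <- list()
    for (sc in intersect(config$scenarios, c("near_bias", "far_bias"))) {
      role <- paste0(sub("_bias", "", sc), "_bias_region")
      biasRegionScale[[sc]] <- config$biasLocalRms /
        priorRegionRms(models$bias, regionMask(template, role))
    }
  }
  data <- buildCounterfactualDatasets(
    template, models, config$composition, scenarios = config$scenarios,
    boundarySigma = config$boundarySigma,
    biasRegionScale = biasRegionScale, nSquarings = config$nSquarings,
    outDir = if (isTRUE(config$writeVolumes)) root else NULL)
  checkCounterfactual(data)

  say("stage 3/5: training (", length(config$scenarios), " scenarios x ",
      length(config$strategies), " strategies x ", length(config$seeds),
      " seeds)")
  metrics <- NULL
  probes <- NULL
  kept <- list()
  for (sc in config$scenarios) {
    ds <- list(x = data$volumes[[sc]], manifest = data$manifests[[sc]])
    testIds <- ds$manifest$subject_id[ds$manifest$split == "test"]
    for (seed in config$seeds) {
      tc <- config$train
      tc$seed <- seed
      init <- buildCnn(config$model, config$gridShape, seed = seed)
      naive <- NULL
      for (strat in config$strategies) {
        if (strat %in% c("naive", "unlearning") && is.null(naive))
          naive <- trainClassifier(init, ds, tc)
        fit <- switch(strat,
          naive = naive,
          reweighing = {
            w <- sampleWeights(ds$manifest, reweighingWeights(ds$manifest))
            trainClassifier(init, ds, tc, weights = w)
          },
          unlearning = unlearnBias(naive, ds, config$unlearn, tc),
          group_models = trainGroupModels(init, ds, tc,
                                          pretrainEpochs = config$pretrainEpochs))
        pred <- if (strat == "group_models") predictGrouped(fit, ds)
        else {
          p <- predictLabels(fit, ds$x[testIds])
          cbind(p, ds$manifest[match(p$subject_id, ds$manifest$subject_id),
                               c("disease_label", "bias_group")])
        }
        row <- evalOnTest(pred)
        row <- cbind(data.frame(scenario = sc, strategy = strat, seed = seed),
                     row)
        if (strat == "unlearning") {
          dg <- attr(fit, "diagnostics")
          probes <- rbind(probes, data.frame(
            scenario = sc, seed = seed,
            probe_accuracy = dg$probe$accuracy, chance = dg$probe$chance,
            phase2_val_acc = dg$phase2_val_acc))
        }
        metrics <- rbind(metrics, row)
        kept[[sc]][[strat]][[as.character(seed)]] <-
          if (strat == "group_models") fit$bias else fit
        say("  ", sc, " / ", strat, " / seed ", seed, ": acc ",
            round(row$accuracy, 1), "%, dTPR ", round(row$dTPR, 1), "pp")
      }
    }
  }
  rownames(metrics) <- NULL

  say("stage 4/5: disparities and statistics")
  relatives <- NULL
  if ("no_bias" %in% config$scenarios) {
    for (strat in config$strategies) {
      base <- metrics[metrics$scenario == "no_bias" &
                        metrics$strategy == strat, c("seed", "dTPR", "dFPR")]
      for (sc in setdiff(config$scenarios, "no_bias")) {
        rep <- metrics[metrics$scenario == sc & metrics$strategy == strat,
                       c("seed", "dTPR", "dFPR")]
        rel <- relativeDisparity(rep, base)
        relatives <- rbind(relatives, cbind(
          data.frame(scenario = sc, strategy = strat), rel))
      }
    }
    rownames(relatives) <- NULL
  }
  statsOut <- NULL
  if (length(config$seeds) >= 3 && length(config$scenarios) >= 2 &&
      length(config$strategies) >= 2) {
    long <- rbind(
      data.frame(value = metrics$dTPR, metric = "dTPR",
                 scenario = metrics$scenario, strategy = metrics$strategy,
                 seed = metrics$seed),
      data.frame(value = metrics$dFPR, metric = "dFPR",
                 scenario = metrics$scenario, strategy = metrics$strategy,
                 seed = metrics$seed))
    anova <- tryCatch(
      do.call(rbind, lapply(split(long, long$metric), function(d)
        cbind(metric = d$metric[1], rmAnovaGate(d)))),
      error = function(e) NULL)
    pairwise <- NULL
    if (length(config$seeds) >= 3 && "naive" %in% config$strategies) {
      for (sc in config$scenarios)
        for (strat in setdiff(config$strategies, "naive")) {
          a <- metrics$dTPR[metrics$scenario == sc & metrics$strategy == strat]
          b <- metrics$dTPR[metrics$scenario == sc & metrics$strategy == "naive"]
          if (length(a) == length(b) && length(a) >= 3) {
            ct <- compareConditions(a, b, config$stats)
            pairwise <- rbind(pairwise, data.frame(
              scenario = sc, strategy = strat, metric = "dTPR",
              test = ct$test, p.value = ct$p.value,
              significant = ct$significant))
          }
        }
    }
    statsOut <- list(anova = anova, pairwise = pairwise)
  }

  say("stage 5/5: saliency scoring")
  labels <- regionLabels(template)
  rt <- regionTable(template)
  nearId <- rt$id[rt$role == "near_bias_region"]
  farId <- rt$id[rt$role == "far_bias_region"]
  disId <- rt$id[rt$role == "disease_region"]
  saliency <- NULL
  for (sc in names(kept)) {
    ds <- list(x = data$volumes[[sc]], manifest = data$manifests[[sc]])
    for (strat in names(kept[[sc]])) {
      for (seed in names(kept[[sc]][[strat]])) {
        m <- kept[[sc]][[strat]][[seed]]
        # too-few-correct warnings are expected at desk scale
        wss <- tryCatch(suppressWarnings({
          avg <- averageGroupSaliency(
            m, ds, classLabel = 1, groupLabel = 1,
            nSubjects = config$explain$nSubjects,
            nNoise = config$explain$nNoise,
            noiseFraction = config$explain$noiseFraction,
            seed = config$templateSeed)
          weightedSaliencyScores(avg, labels)
        }), error = function(e) NULL)
        if (is.null(wss)) next
        pick <- function(id) if (length(id) && id %in% wss$region_id)
          wss$score[wss$region_id == id] else NA_real_
        saliency <- rbind(saliency, data.frame(
          scenario = sc, strategy = strat, seed = as.integer(seed),
          wss_disease = pick(disId), wss_near = pick(nearId),
          wss_far = pick(farId)))
      }
    }
  }

  summary <- aggregateTrial(metrics, relatives, saliency)
  out <- list(summary = summary, metrics = metrics, relatives = relatives,
              stats = statsOut, saliency = saliency, probes = probes,
              config = config, hash = hash, resumed = FALSE,
              template = template)
  class(out) <- "biasTrial"
  if (!is.null(root)) writeTrialArtifacts(out, root)
  out
}

# strategy x scenario summary table (means and SDs over seeds)
aggregateTrial <- function(metrics, relatives, saliency) {
  agg <- function(df, cols) {
    sp <- split(df, list(df$scenario, df$strategy), drop = TRUE)
    do.call(rbind, lapply(sp, function(d) {
      out <- data.frame(scenario = d$scenario[1], strategy = d$strategy[1])
      for (cl in cols) {
        out[[paste0(cl, "_mean")]] <- mean(d[[cl]])
        out[[paste0(cl, "_sd")]] <- if (nrow(d) > 1) sd(d[[cl]]) else NA_real_
      }
      out
    }))
  }
  s <- agg(metrics, c("accuracy", "dTPR", "dFPR"))
  if (!is.null(relatives)) {
    r <- agg(relatives, c("rel_dTPR", "rel_dFPR"))
    s <- merge(s, r, by = c("scenario", "strategy"), all.x = TRUE)
  }
  if (!is.null(saliency)) {
    w <- agg(saliency, c("wss_disease", "wss_near", "wss_far"))
    s <- merge(s, w, by = c("scenario", "strategy"), all.x = TRUE)
  }
  rownames(s) <- NULL
  s[order(s$scenario, s$strategy), ]
}

writeTrialArtifacts <- function(trial, root) {
  repDir <- file.path(root, "report")
  dir.create(repDir, recursive = TRUE, showWarnings = FALSE)
  write.csv(trial$summary, file.path(repDir, "summary.csv"), row.names = FALSE)
  write.csv(trial$metrics, file.path(repDir, "metrics.csv"), row.names = FALSE)
  if (!is.null(trial$relatives))
    write.csv(trial$relatives, file.path(repDir, "relatives.csv"),
              row.names = FALSE)
  if (!is.null(trial$saliency))
    write.csv(trial$saliency, file.path(repDir, "saliency.csv"),
              row.names = FALSE)
  if (!is.null(trial$probes))
    write.csv(trial$probes, file.path(repDir, "bias_probes.csv"),
              row.names = FALSE)
  writeLines(trial$hash, file.path(root, "trial_hash.txt"))
  yaml::write_yaml(rapply(unclass(trial$config), unclass, how = "replace"),
                   file.path(root, "trial_config.yaml"))
  md <- file.path(repDir, "summary.md")
  s <- trial$summary
  fmt <- function(m, sdv) sprintf("%.2f ± %.2f", m, sdv)
  lines <- c("| scenario | strategy | accuracy (%) | ΔTPR (pp) | ΔFPR (pp) | rel ΔTPR | rel ΔFPR |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(s))) {
    rel1 <- if ("rel_dTPR_mean" %in% names(s) && !is.na(s$rel_dTPR_mean[i]))
      fmt(s$rel_dTPR_mean[i], s$rel_dTPR_sd[i]) else "-"
    rel2 <- if ("rel_dFPR_mean" %in% names(s) && !is.na(s$rel_dFPR_mean[i]))
      fmt(s$rel_dFPR_mean[i], s$rel_dFPR_sd[i]) else "-"
    lines <- c(lines, paste("|", s$scenario[i], "|", s$strategy[i], "|",
                            fmt(s$accuracy_mean[i], s$accuracy_sd[i]), "|",
                            fmt(s$dTPR_mean[i], s$dTPR_sd[i]), "|",
                            fmt(s$dFPR_mean[i], s$dFPR_sd[i]), "|",
                            rel1, "|", rel2, "|"))
  }
  writeLines(lines, md)
  invisible(root)
}

#' @export
print.biasTrial <- function(x, ...) {
  cat("biasTrial (", length(unique(x$metrics$scenario)), " scenarios, ",
      length(unique(x$metrics$strategy)), " strategies, ",
      length(unique(x$metrics$seed)), " seeds)\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
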