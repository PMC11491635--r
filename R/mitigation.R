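# Bias-mitigation strategies: reweighing (per-cell sample weights that make
# class and group independent in the weighted training distribution),
# adversarial unlearning (confusion loss against uniform group predictions),
# and per-group models fine-tuned from a shared pretrained base.

#' Reweighing sample weights (Calders-style)
#'
#' For each (class, group) cell, `w(c,g) = N(c) * N(g) / (N * N(c,g))`
#' computed from the training split only. Under these weights the weighted
#' joint distribution of (class, group) factorizes exactly.
#'
#' @param manifest a scenario manifest (data.frame with disease_label,
#'   bias_group, split).
#' @param split the split the counts come from (default `"train"`).
#' @return data.frame with disease_label, bias_group, count, weight.
#' @export
reweighingWeights <- function(manifest, split = "train") {
  mf <- manifest[manifest$split == split, ]
  N <- nrow(mf)
  cells <- expand.grid(disease_label = c(0L, 1L), bias_group = c(0L, 1L))
  cells$count <- mapply(function(d, b)
    sum(mf$disease_label == d & mf$bias_group == b),
    cells$disease_label, cells$bias_group)
  empty <- cells$count == 0
  if (any(empty))
    stop("empty (class, group) cell in the ", split, " split: ",
         paste(sprintf("(disease=%d, bias=%d)",
                       cells$disease_label[empty], cells$bias_group[empty]),
               collapse = ", "))
  nClass <- tapply(cells$count, cells$disease_label, sum)
  nGroup <- tapply(cells$count, cells$bias_group, sum)
  cells$weight <- as.numeric(nClass[as.character(cells$disease_label)] *
    nGroup[as.character(cells$bias_group)] / (N * cells$count))
  rownames(cells) <- NULL
  cells
}

#' Per-subject sample weights from a reweighing table
#'
#' @param manifest a scenario manifest.
#' @param table output of [reweighingWeights()].
#' @return named numeric vector (subject_id -> weight).
#' @export
sampleWeights <- function(manifest, table) {
  key <- paste(manifest$disease_label, manifest$bias_group)
  tkey <- paste(table$disease_label, table$bias_group)
  w <- table$weight[match(key, tkey)]
  names(w) <- manifest$subject_id
  w
}

# ---- dense softmax head on frozen features (phase-2 / probe training) ----
trainDenseHead <- function(f, y, K = 2, epochs = 50, lr = 0.01,
                           batchSize = 32, seed = 0, valF = NULL,
                           valY = NULL, patience = 15) {
  C <- ncol(f)
  W <- matrix(0, C, K); b <- numeric(K)
  params <- list(W = W, b = b)
  opt <- adamInit(params)
  softmax <- function(Z) {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z); E / rowSums(E)
  }
  evalLoss <- function(F0, y0) {
    P <- softmax(sweep(F0 %*% params$W, 2, params$b, `+`))
    pc <- pmax(P[cbind(seq_along(y0), y0 + 1)], 1e-12)
    list(loss = -mean(log(pc)), acc = mean(max.col(P, ties.method = "first") - 1 == y0))
  }
  best <- list(loss = Inf, params = params, epoch = 0)
  wait <- 0
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(y))
      for (s in seq(1, length(ord), by = batchSize)) {
        ii <- ord[s:min(length(ord), s + batchSize - 1)]
        Fb <- f[ii, , drop = FALSE]
        P <- softmax(sweep(Fb %*% params$W, 2, params$b, `+`))
        Yh <- matrix(0, length(ii), K)
        Yh[cbind(seq_along(ii), y[ii] + 1)] <- 1
        dZ <- (P - Yh) / length(ii)
        g <- list(W = crossprod(Fb, dZ), b = colSums(dZ))
        st <- adamStep(params, g, opt, lr)
        params <- st$params; opt <- st$state
      }
      if (!is.null(valF)) {
        v <- evalLoss(valF, valY)
        if (v$loss < best$loss) {
          best <- list(loss = v$loss, params = params, epoch = ep)
          wait <- 0
        } else wait <- wait + 1
        if (wait >= patience) break
      }
    }
  })
  if (!is.null(valF)) params <- best$params
  train <- evalLoss(f, y)
  out <- list(W = params$W, b = params$b, trainAcc = train$acc)
  if (!is.null(valF)) {
    v <- evalLoss(valF, valY)
    out$valAcc <- v$acc; out$valLoss <- v$loss
  }
  out
}

headAccuracy <- function(head, f, y) {
  P <- sweep(f %*% head$W, 2, head$b, `+`)
  mean(max.col(P, ties.method = "first") - 1 == y)
}

#' Unlearning configuration
#'
#' @param alpha weight of the confusion loss in the adversarial phase.
#' @param patience epochs without disease-accuracy improvement and without
#'   bias-accuracy decrease before stopping.
#' @param maxEpochs adversarial-phase epoch cap.
#' @param headEpochs epoch cap for frozen-encoder bias-head training.
#' @param headLr learning rate for bias-head training.
#' @param confusionLrFactor encoder learning rate for the confusion step, as
#'   a fraction of the base learning rate; small values remove group
#'   information gradually instead of wrecking the shared representation.
#' @param diseaseLrFactor disease-step learning rate as a fraction of the
#'   base rate; below 1 the adversarial phase fine-tunes rather than
#'   re-learns, which keeps the disease objective from re-introducing the
#'   shortcut as fast as the confusion steps remove it.
#' @param probeEpochs epochs for the post-hoc bias probe; the per-epoch
#'   adversary is refit with the same protocol so the confusion gradient
#'   targets exactly what a probe can read.
#' @return an `unlearnConfig` list.
#' @export
unlearnConfig <- function(alpha = 1, patience = 5, maxEpochs = 30,
                          headEpochs = 50, headLr = 0.02,
                          confusionLrFactor = 0.25, diseaseLrFactor = 1,
                          innerRounds = 1, probeEpochs = 20) {
  stopifnot(alpha >= 0, patience >= 1, maxEpochs >= 1,
            confusionLrFactor >= 0, diseaseLrFactor >= 0, innerRounds >= 1)
  structure(list(alpha = alpha, patience = patience, maxEpochs = maxEpochs,
                 headEpochs = headEpochs, headLr = headLr,
                 confusionLrFactor = confusionLrFactor,
                 diseaseLrFactor = diseaseLrFactor,
                 innerRounds = innerRounds,
                 probeEpochs = probeEpochs),
            class = "unlearnConfig")
}

#' Adversarially unlearn the bias group from a trained classifier
#'
#' Three phases. (1) is the supplied naive model, which is never modified.
#' (2) A 2-class bias head is trained to convergence on the frozen encoder's
#' pooled features. (3) Alternating per-batch updates: a disease step
#' (encoder + disease head, cross-entropy), an adversary step (bias head
#' only, keeping the confusion signal meaningful) and a confusion step
#' (encoder only, `alpha` times the cross-entropy between the bias head's
#' softmax and the uniform distribution). Stops when disease validation
#' accuracy has not improved and bias validation accuracy has not decreased
#' for `patience` consecutive epochs. A post-hoc probe (a fresh head trained
#' on the frozen unlearned encoder) measures the group information left in
#' the representation.
#'
#' @param model a trained naive [CnnClassifier-class].
#' @param dataset list with `x` and `manifest` (needs bias_group).
#' @param config an [unlearnConfig()].
#' @param trainCfg a [trainConfig()] supplying batch size / learning rate /
#'   seed for the adversarial phase.
#' @return the unlearned [CnnClassifier-class]; diagnostics (probe accuracy,
#'   chance level, per-epoch log) in `attr(, "diagnostics")`.
#' @export
unlearnBias <- function(model, dataset, config = unlearnConfig(),
                        trainCfg = trainConfig()) {
  mf <- dataset$manifest
  xs <- dataset$x[mf$subject_id]
  trainIdx <- which(mf$split == "train")
  valIdx <- which(mf$split == "val")
  yDis <- mf$disease_label
  yBias <- mf$bias_group

  # phase 2: frozen-encoder bias head
  fTrain <- cnnFeatures(model, xs[trainIdx])
  fVal <- cnnFeatures(model, xs[valIdx])
  head2 <- trainDenseHead(fTrain, yBias[trainIdx], K = 2,
                          epochs = config$headEpochs, lr = config$headLr,
                          batchSize = trainCfg$batchSize * 4,
                          seed = trainCfg$seed + 101,
                          valF = fVal, valY = yBias[valIdx],
                          patience = 15)
  chanceVal <- max(mean(yBias[valIdx]), 1 - mean(yBias[valIdx]))
  if (head2$valAcc <= chanceVal + 0.02)
    warning("bias head does not beat chance on validation: nothing to unlearn")

  # phase 3: alternating adversarial updates. Each epoch: (i) per-batch
  # disease steps; (ii) the adversary (bias head) is retrained to near
  # optimality on the current pooled features, so the confusion gradient
  # targets the directions that actually carry group information; (iii)
  # per-batch confusion steps against that frozen head.
  unl <- model
  params <- list(enc = encoderParams(unl@blocks), headW = unl@headW,
                 headb = unl@headb)
  biasHead <- list(W = head2$W, b = head2$b)
  optDis <- adamInit(params)
  optConf <- adamInit(params$enc)
  blocks <- unl@blocks
  bestDis <- -Inf; minBias <- Inf; wait <- 0
  log <- NULL
  p <- unl@config$dropout
  C <- ncol(blocks[[length(blocks)]]$W)

  withSeed(trainCfg$seed + 202, {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample(trainIdx)
      # (i) disease epoch
      for (s in seq(1, length(ord), by = trainCfg$batchSize)) {
        ii <- ord[s:min(length(ord), s + trainCfg$batchSize - 1)]
        xb <- asBatch(xs[ii], unl@inputShape)
        blocks <- setEncoderParams(blocks, params$enc)
        tmp <- unl; tmp@blocks <- blocks
        r <- cnnRun(tmp, xb, y = yDis[ii], headW = params$headW,
                    headb = params$headb, training = TRUE, loss = "bce",
                    gradEncoder = TRUE, gradHead = TRUE,
                    dropMask = newDropMask(p, C, length(ii)))
        blocks <- setRunStats(blocks, r$run_stats)
        g <- list(enc = lapply(r$grads$blocks, function(b)
                    b[c("W", "b", "gamma", "beta")]),
                  headW = r$grads$headW, headb = r$grads$headb)
        st <- adamStep(params, g, optDis,
                       trainCfg$learningRate * config$diseaseLrFactor)
        params <- st$params; optDis <- st$state
      }
      blocks <- setEncoderParams(blocks, params$enc)
      tmp <- unl; tmp@blocks <- blocks
      if (config$alpha > 0) {
        # (ii)+(iii) adversarial rounds: refit the bias head on current
        # features with the probe's own protocol (so confusion fights what a
        # probe would read), then run a confusion epoch against it; repeat
        # until the refit adversary itself is near chance
        chanceTrain <- max(mean(yBias[trainIdx]), 1 - mean(yBias[trainIdx]))
        for (round in seq_len(config$innerRounds)) {
          fT <- cnnFeatures(tmp, xs[trainIdx])
          refit <- trainDenseHead(fT, yBias[trainIdx], K = 2,
                                  epochs = config$probeEpochs, lr = 0.05,
                                  batchSize = 32,
                                  seed = trainCfg$seed + 500 + 31 * epoch + round)
          biasHead <- list(W = refit$W, b = refit$b)
          if (refit$trainAcc <= chanceTrain + 0.03) break
          for (s in seq(1, length(ord), by = trainCfg$batchSize)) {
            ii <- ord[s:min(length(ord), s + trainCfg$batchSize - 1)]
            xb <- asBatch(xs[ii], unl@inputShape)
            blocks <- setEncoderParams(blocks, params$enc)
            tmp@blocks <- blocks
            r <- cnnRun(tmp, xb, y = yBias[ii], headW = biasHead$W,
                        headb = biasHead$b, training = FALSE,
                        loss = "confusion", gradEncoder = TRUE)
            gC <- lapply(r$grads$blocks, function(b)
              lapply(b[c("W", "b", "gamma", "beta")],
                     function(a) config$alpha * a))
            st <- adamStep(params$enc, gC, optConf,
                           trainCfg$learningRate * config$confusionLrFactor)
            params$enc <- st$params; optConf <- st$state
          }
          blocks <- setEncoderParams(blocks, params$enc)
          tmp@blocks <- blocks
        }
      }
      # epoch-end monitoring
      tmp <- unl; tmp@blocks <- blocks
      vDis <- cnnPredictProb(tmp, xs[valIdx], headW = params$headW,
                             headb = params$headb)[, 1]
      disAcc <- mean((vDis >= 0.5) == (yDis[valIdx] == 1))
      fV <- cnnFeatures(tmp, xs[valIdx])
      biasAcc <- headAccuracy(biasHead, fV, yBias[valIdx])
      log <- rbind(log, data.frame(epoch = epoch, disease_val_acc = disAcc,
                                   bias_val_acc = biasAcc))
      improved <- disAcc > bestDis + 1e-9 || biasAcc < minBias - 1e-9
      bestDis <- max(bestDis, disAcc)
      minBias <- min(minBias, biasAcc)
      if (improved) wait <- 0 else wait <- wait + 1
      if (wait >= config$patience) break
    }
  })

  unl@blocks <- setEncoderParams(blocks, params$enc)
  unl@headW <- params$headW
  unl@headb <- as.numeric(params$headb)
  unl@trained <- TRUE
  probe <- biasProbe(unl, dataset, epochs = config$probeEpochs,
                     seed = trainCfg$seed + 303)
  attr(unl, "diagnostics") <- list(log = log, probe = probe,
                                   phase2_val_acc = head2$valAcc,
                                   chance_val = chanceVal)
  unl
}

#' Bias probe: how much group information is left in the encoder
#'
#' Trains a freshly initialized 2-class head for a fixed number of epochs on
#' the frozen encoder's pooled features (train split) and reports its
#' accuracy on the test split together with the chance level (the majority
#' group fraction).
#'
#' @param model a [CnnClassifier-class].
#' @param dataset list with `x` and `manifest`.
#' @param epochs probe training epochs (default 20).
#' @param seed probe seed.
#' @return list with accuracy, chance, and the fitted head.
#' @export
biasProbe <- function(model, dataset, epochs = 20, seed = 0) {
  mf <- dataset$manifest
  xs <- dataset$x[mf$subject_id]
  trainIdx <- which(mf$split == "train")
  testIdx <- which(mf$split == "test")
  f <- cnnFeatures(model, xs[trainIdx])
  head <- trainDenseHead(f, mf$bias_group[trainIdx], K = 2, epochs = epochs,
                         lr = 0.05, batchSize = 32, seed = seed)
  fT <- cnnFeatures(model, xs[testIdx])
  acc <- headAccuracy(head, fT, mf$bias_group[testIdx])
  chance <- max(mean(mf$bias_group[testIdx]),
                1 - mean(mf$bias_group[testIdx]))
  list(accuracy = acc, chance = chance, head = head)
}

#' Train per-group models from a shared pretrained base
#'
#' One model is pretrained for `pretrainEpochs` on the full training split
#' (no early stopping), then cloned and fine-tuned to convergence on the
#' bias group and the non-bias group separately. With `pretrainEpochs = 0`
#' the two group models are trained independently from the same
#' initialization.
#'
#' @param model an untrained [CnnClassifier-class] (shared initialization).
#' @param dataset list with `x` and `manifest`.
#' @param config a [trainConfig()].
#' @param pretrainEpochs shared pretraining epochs (default 5).
#' @return list with elements `bias` and `non_bias` (trained models) and
#'   `pretrained`.
#' @export
trainGroupModels <- function(model, dataset, config = trainConfig(),
                             pretrainEpochs = 5) {
  mf <- dataset$manifest
  for (g in c(0, 1))
    if (!any(mf$bias_group == g & mf$split == "train"))
      stop("bias group ", g, " is absent from the train split")
  base <- model
  if (pretrainEpochs > 0) {
    preCfg <- config
    preCfg$maxEpochs <- as.integer(pretrainEpochs)
    base <- trainClassifier(model, dataset, preCfg, earlyStopping = FALSE)
  }
  fitGroup <- function(g) {
    sel <- mf$bias_group == g
    ds <- list(x = dataset$x, manifest = mf[sel, ])
    trainClassifier(base, ds, config)
  }
  list(non_bias = fitGroup(0), bias = fitGroup(1), pretrained = base)
}

#' Route test samples to their group's model
#'
#' Every sample is scored by exactly one model (its own bias group's), so
#' aggregate confusion counts equal the sum of the per-group counts.
#'
#' @param models output of [trainGroupModels()].
#' @param dataset list with `x` and `manifest`.
#' @param split which split to score (default `"test"`).
#' @return data.frame with subject_id, probability, label, bias_group,
#'   disease_label.
#' @export
predictGrouped <- function(models, dataset, split = "test") {
  mf <- dataset$manifest[dataset$manifest$split == split, ]
  out <- mf[, c("subject_id", "disease_label", "bias_group")]
  out$probability <- NA_real_
  for (g in c(0, 1)) {
    sel <- mf$bias_group == g
    if (!any(sel)) next
    m <- if (g == 1) models$bias else models$non_bias
    out$probability[sel] <-
      cnnPredictProb(m, dataset$x[mf$subject_id[sel]])[, 1]
  }
  out$label <- as.integer(out$probability >= 0.5)
  out
}
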