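# 3D CNN disease classifier: conv(3x3x3) -> batch norm -> activation ->
# max pool (2x2x2) blocks, global average pooling, dropout, dense sigmoid
# output. Deterministic given (seed, data, config): all randomness (init,
# shuffling, dropout) flows from R's RNG, and the compiled engine is
# single-threaded double-precision.

#' CNN architecture configuration
#'
#' @param convFilters filters per block; the classic full-scale stack is
#'   `c(32, 64, 128, 256, 512)`.
#' @param blockActivation `"sigmoid"` (the default stack) or
#'   `"relu"` (ablation switch).
#' @param dropout dropout fraction applied after global average pooling.
#' @param headInit dense-head initialization: `"zero"` (an untrained model
#'   scores every input at exactly 0.5) or `"normal"` (small random head,
#'   avoids the dead warmup phase of a zero head on small models).
#' @return a `modelConfig` list. Kernel (3x3x3) and pool (2x2x2) are fixed.
#' @export
modelConfig <- function(convFilters = c(32, 64, 128, 256, 512),
                        blockActivation = c("sigmoid", "relu"),
                        dropout = 0.20, headInit = c("zero", "normal")) {
  blockActivation <- match.arg(blockActivation)
  headInit <- match.arg(headInit)
  stopifnot(length(convFilters) >= 1, all(convFilters >= 1),
            dropout >= 0, dropout < 1)
  structure(list(convFilters = as.integer(convFilters), kernel = 3L,
                 pool = 2L, blockActivation = blockActivation,
                 dropout = dropout, headInit = headInit),
            class = "modelConfig")
}

#' Training configuration
#'
#' @param batchSize minibatch size (reference: 4).
#' @param learningRate Adam learning rate (reference: 1e-4).
#' @param patience early-stopping patience on validation loss (reference:
#'   15); ties keep the earliest best epoch.
#' @param maxEpochs epoch cap.
#' @param seed weight-init / shuffling / dropout seed.
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(batchSize = 4, learningRate = 1e-4, patience = 15,
                        maxEpochs = 200, seed = 0) {
  stopifnot(batchSize >= 1, patience >= 1, maxEpochs >= 1, learningRate > 0)
  structure(list(batchSize = as.integer(batchSize),
                 learningRate = learningRate, patience = as.integer(patience),
                 maxEpochs = as.integer(maxEpochs), seed = seed),
            class = "trainConfig")
}

# number of blocks the input can support (each pool halves even dims)
usableBlocks <- function(inputShape, requested) {
  d <- as.integer(inputShape)
  n <- 0L
  while (n < requested && all(d >= 2L) && all(d %% 2L == 0L)) {
    d <- d %/% 2L
    n <- n + 1L
  }
  n
}

#' Build an (untrained) CNN classifier
#'
#' Convolution weights get Glorot-uniform initialization from `seed`;
#' batch-norm scale/shift start at 1/0 and the dense head at zero (an
#' untrained model scores every input at probability 0.5). If the input grid
#' cannot survive one 2x2x2 pooling per requested block, the block count is
#' reduced with a warning.
#'
#' @param config a [modelConfig()].
#' @param inputShape integer triple.
#' @param seed weight-initialization seed.
#' @return a [CnnClassifier-class].
#' @export
buildCnn <- function(config, inputShape, seed = 0) {
  inputShape <- as.integer(inputShape)
  nb <- usableBlocks(inputShape, length(config$convFilters))
  if (nb < 1)
    stop("configuration error: input shape ",
         paste(inputShape, collapse = "x"), " cannot support any 2x2x2 pooling")
  filters <- config$convFilters
  if (nb < length(filters)) {
    warning("input ", paste(inputShape, collapse = "x"), " supports only ",
            nb, " blocks; reducing from ", length(filters))
    filters <- filters[seq_len(nb)]
  }
  cf <- filters[length(filters)]
  init <- withSeed(seed, {
    cin <- 1L
    blocks <- lapply(filters, function(cout) {
      fanIn <- 27 * cin; fanOut <- 27 * cout
      lim <- sqrt(6 / (fanIn + fanOut))
      W <- matrix(runif(27 * cin * cout, -lim, lim), nrow = 27 * cin)
      b <- list(W = W, b = numeric(cout), gamma = rep(1, cout),
                beta = numeric(cout), run_mean = numeric(cout),
                run_var = rep(1, cout))
      cin <<- cout
      b
    })
    headW <- if (identical(config$headInit, "normal"))
      matrix(rnorm(cf, sd = 0.1), nrow = cf, ncol = 1)
    else matrix(0, nrow = cf, ncol = 1)
    list(blocks = blocks, headW = headW)
  })
  new("CnnClassifier", blocks = init$blocks,
      headW = init$headW, headb = 0,
      config = unclass(config), inputShape = inputShape,
      trained = FALSE, history = NULL)
}

#' Count trainable parameters
#'
#' Conv weights + biases + batch-norm scale/shift + dense head (running
#' batch-norm statistics are state, not parameters).
#'
#' @param model a [CnnClassifier-class].
#' @return integer count.
#' @export
countParams <- function(model) {
  n <- sum(vapply(model@blocks, function(b)
    length(b$W) + length(b$b) + length(b$gamma) + length(b$beta), numeric(1)))
  as.integer(n + length(model@headW) + length(model@headb))
}

# stack a list of 3D arrays (or an n-first 4D array) into the (x,y,z,n)
# batch layout the engine expects
asBatch <- function(volumes, inputShape) {
  if (is.array(volumes) && length(dim(volumes)) == 3) volumes <- list(volumes)
  n <- length(volumes)
  out <- array(0, c(inputShape, n))
  for (i in seq_len(n)) out[, , , i] <- volumes[[i]]
  out
}

# one engine call; params can carry an alternative head (bias head etc.)
cnnRun <- function(model, xbatch, y = NULL, sw = NULL,
                   headW = model@headW, headb = model@headb,
                   training = FALSE, loss = "none", gradEncoder = FALSE,
                   gradHead = FALSE, inputGrad = FALSE, dropMask = NULL,
                   bnMomentum = 0.1) {
  cpp_cnn_run(model@blocks, headW, headb, xbatch,
              if (is.null(y)) NULL else as.numeric(y),
              if (is.null(sw)) NULL else as.numeric(sw),
              model@config$blockActivation, dropMask,
              training, loss, gradEncoder, gradHead, inputGrad,
              bnMomentum, 1e-5)
}

# eval-mode forward in chunks; returns n x K probability matrix
cnnPredictProb <- function(model, volumes, headW = model@headW,
                           headb = model@headb, chunk = 32) {
  n <- length(volumes)
  K <- ncol(headW)
  out <- matrix(NA_real_, n, K)
  for (s in seq(1, n, by = chunk)) {
    ii <- s:min(n, s + chunk - 1)
    r <- cnnRun(model, asBatch(volumes[ii], model@inputShape),
                headW = headW, headb = headb, loss = "none")
    out[ii, ] <- r$prob
  }
  out
}

# eval-mode pooled encoder features (pre-dropout), n x C
cnnFeatures <- function(model, volumes, chunk = 32) {
  C <- ncol(model@blocks[[length(model@blocks)]]$W)
  n <- length(volumes)
  out <- matrix(NA_real_, n, C)
  for (s in seq(1, n, by = chunk)) {
    ii <- s:min(n, s + chunk - 1)
    r <- cnnRun(model, asBatch(volumes[ii], model@inputShape), loss = "none")
    out[ii, ] <- r$features
  }
  out
}

# ---- Adam ----
adamInit <- function(params) {
  list(m = treeMap(params, function(a) a * 0),
       v = treeMap(params, function(a) a * 0), t = 0)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- treeMap2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- treeMap2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- treeMap2(state$m, state$v,
                  function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- treeMap2(params, upd, `-`)
  list(params = params, state = state)
}

# extract/insert trainable encoder params (excludes running stats)
encoderParams <- function(blocks)
  lapply(blocks, function(b) b[c("W", "b", "gamma", "beta")])

setEncoderParams <- function(blocks, params) {
  for (l in seq_along(blocks)) blocks[[l]][c("W", "b", "gamma", "beta")] <-
      params[[l]]
  blocks
}

setRunStats <- function(blocks, rs) {
  for (l in seq_along(blocks)) {
    blocks[[l]]$run_mean <- as.numeric(rs[[l]]$run_mean)
    blocks[[l]]$run_var <- as.numeric(rs[[l]]$run_var)
  }
  blocks
}

newDropMask <- function(p, C, n) {
  if (p <= 0) return(NULL)
  matrix(stats::rbinom(C * n, 1, 1 - p) / (1 - p), nrow = C)
}

#' Train the CNN disease classifier
#'
#' Sample-weighted binary cross-entropy minimized with Adam; validation loss
#' early stopping with the configured patience, restoring the weights of the
#' earliest best epoch. With a fixed seed, repeated runs are bit-identical.
#'
#' @param model an untrained (or pre-trained) [CnnClassifier-class].
#' @param dataset list with `x` (named list of 3D volumes) and `manifest`
#'   (data.frame with subject_id, disease_label, split).
#' @param config a [trainConfig()].
#' @param weights optional per-sample training weights named by subject_id.
#' @param earlyStopping use validation early stopping (disable for fixed
#'   pre-training epochs).
#' @param labelColumn manifest column holding the binary label.
#' @return the trained [CnnClassifier-class]; the per-epoch history is in
#'   `@history`.
#' @export
trainClassifier <- function(model, dataset, config = trainConfig(),
                            weights = NULL, earlyStopping = TRUE,
                            labelColumn = "disease_label") {
  mf <- dataset$manifest
  trainIdx <- which(mf$split == "train")
  valIdx <- which(mf$split == "val")
  if (!length(trainIdx)) stop("manifest has an empty train split")
  if (earlyStopping && !length(valIdx))
    stop("manifest has an empty val split")
  xs <- dataset$x[mf$subject_id]
  y <- mf[[labelColumn]]
  sw <- rep(1, nrow(mf))
  if (!is.null(weights)) {
    sw <- weights[mf$subject_id]
    if (any(is.na(sw))) stop("weights must cover every subject")
  }
  p <- model@config$dropout
  C <- ncol(model@blocks[[length(model@blocks)]]$W)

  params <- list(enc = encoderParams(model@blocks), headW = model@headW,
                 headb = model@headb)
  opt <- adamInit(params)
  blocks <- model@blocks
  best <- list(loss = Inf, epoch = 0L, blocks = NULL, headW = NULL,
               headb = NULL)
  hist <- NULL
  wait <- 0L

  withSeed(config$seed, {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample(trainIdx)
      eLoss <- 0; eAcc <- 0; nSeen <- 0
      for (s in seq(1, length(ord), by = config$batchSize)) {
        ii <- ord[s:min(length(ord), s + config$batchSize - 1)]
        xb <- asBatch(xs[ii], model@inputShape)
        dm <- newDropMask(p, C, length(ii))
        blocks <- setEncoderParams(blocks, params$enc)
        tmp <- model; tmp@blocks <- blocks
        r <- cnnRun(tmp, xb, y = y[ii], sw = sw[ii], headW = params$headW,
                    headb = params$headb, training = TRUE, loss = "bce",
                    gradEncoder = TRUE, gradHead = TRUE, dropMask = dm)
        if (!is.finite(r$loss))
          stop("non-finite training loss at epoch ", epoch,
               "; try a lower learning rate")
        blocks <- setRunStats(blocks, r$run_stats)
        g <- list(enc = lapply(r$grads$blocks, function(b)
                    b[c("W", "b", "gamma", "beta")]),
                  headW = r$grads$headW, headb = r$grads$headb)
        st <- adamStep(params, g, opt, config$learningRate)
        params <- st$params; opt <- st$state
        eLoss <- eLoss + r$loss * length(ii)
        eAcc <- eAcc + sum((r$prob[, 1] >= 0.5) == (y[ii] == 1))
        nSeen <- nSeen + length(ii)
      }
      blocks <- setEncoderParams(blocks, params$enc)
      tmp <- model; tmp@blocks <- blocks
      if (length(valIdx)) {
        vp <- cnnPredictProb(tmp, xs[valIdx], headW = params$headW,
                             headb = params$headb)[, 1]
        vp <- pmin(pmax(vp, 1e-12), 1 - 1e-12)
        vLoss <- -mean(y[valIdx] * log(vp) + (1 - y[valIdx]) * log(1 - vp))
        vAcc <- mean((vp >= 0.5) == (y[valIdx] == 1))
      } else { vLoss <- NA_real_; vAcc <- NA_real_ }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = eLoss / nSeen,
                                     train_acc = eAcc / nSeen,
                                     val_loss = vLoss, val_acc = vAcc))
      if (earlyStopping) {
        if (vLoss < best$loss) {  # strict: ties keep the earliest best epoch
          best <- list(loss = vLoss, epoch = epoch, blocks = blocks,
                       headW = params$headW, headb = params$headb)
          wait <- 0L
        } else wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })

  if (earlyStopping && !is.null(best$blocks)) {
    model@blocks <- best$blocks
    model@headW <- best$headW
    model@headb <- as.numeric(best$headb)
    attr(hist, "best_epoch") <- best$epoch
  } else {
    model@blocks <- blocks
    model@headW <- params$headW
    model@headb <- as.numeric(params$headb)
  }
  model@trained <- TRUE
  model@history <- hist
  model
}

#' Predict disease probabilities and hard labels
#'
#' @param model a [CnnClassifier-class].
#' @param volumes named list of 3D volumes (or a single volume).
#' @return data.frame with subject_id (if named), probability, and label
#'   (probability >= 0.5 maps to 1; the threshold is inclusive).
#' @export
predictLabels <- function(model, volumes) {
  if (is.array(volumes) && length(dim(volumes)) == 3) volumes <- list(volumes)
  for (v in volumes)
    if (!identical(dim(v), model@inputShape))
      stop("volume shape does not match the model input shape")
  prob <- cnnPredictProb(model, volumes)[, 1]
  data.frame(subject_id = if (is.null(names(volumes))) NA_character_
             else names(volumes),
             probability = prob, label = as.integer(prob >= 0.5),
             stringsAsFactors = FALSE)
}

#' Write the training history as CSV
#'
#' @param model a trained [CnnClassifier-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeTrainingHistory <- function(model, path) {
  if (is.null(model@history)) stop("model has no training history")
  write.csv(model@history, path, row.names = FALSE)
  invisible(path)
}
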