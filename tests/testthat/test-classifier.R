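# CNN construction, parameter counting, determinism, prediction contract,
# and learnability on a trivially separable task.

test_that("parameter count matches the hand-counted oracle", {
  # 1 block, 1 filter, 8^3 input: conv 3^3*1*1 + 1, BN scale+shift, dense 1+1
  m <- buildCnn(modelConfig(convFilters = 1), c(8, 8, 8), seed = 0)
  expect_equal(countParams(m), 27 + 1 + 2 + 1 + 1)
  # identical config -> identical counts
  m2 <- buildCnn(modelConfig(convFilters = c(4, 8)), c(16, 16, 16), seed = 1)
  m3 <- buildCnn(modelConfig(convFilters = c(4, 8)), c(16, 16, 16), seed = 2)
  expect_equal(countParams(m2), countParams(m3))
  expect_equal(countParams(m2),
               (27 * 1 * 4 + 4 + 8) + (27 * 4 * 8 + 8 + 16) + (8 + 1))
})

test_that("block count adapts to the input grid", {
  # 32^3 survives 5 halvings: spatial size after blocks is 1^3
  expect_equal(synthbias:::usableBlocks(c(32, 32, 32), 5), 5L)
  # 16^3 supports only 4
  expect_warning(m <- buildCnn(modelConfig(), c(16, 16, 16), seed = 0),
                 "reducing")
  expect_length(m@blocks, 4)
  expect_error(buildCnn(modelConfig(), c(3, 3, 3), seed = 0),
               "configuration error")
})

test_that("an untrained zero-head model scores 0.5 and ties go positive", {
  m <- buildCnn(modelConfig(convFilters = c(2, 4)), c(8, 8, 8), seed = 3)
  vols <- list(a = array(rnorm(512), c(8, 8, 8)),
               b = array(rnorm(512), c(8, 8, 8)))
  pr <- predictLabels(m, vols)
  expect_equal(pr$probability, c(0.5, 0.5))
  # threshold is inclusive: probability 0.5 maps to label 1
  expect_equal(pr$label, c(1L, 1L))
  # identical volume scores identically
  pr2 <- predictLabels(m, vols["a"])
  expect_identical(pr2$probability, pr$probability[1])
  expect_error(predictLabels(m, array(0, c(4, 4, 4))), "shape")
})

# small separable task: class-1 volumes carry a bright blob
blobTask <- function(n, seed) {
  withSeed(seed, {
    y <- rep(0:1, length.out = n)
    x <- lapply(seq_len(n), function(i) {
      v <- array(rnorm(16^3, sd = 0.25), c(16, 16, 16))
      if (y[i] == 1) v[5:9, 5:9, 5:9] <- v[5:9, 5:9, 5:9] + 1.5
      v
    })
    names(x) <- sprintf("S%03d", seq_len(n))
    mf <- data.frame(subject_id = names(x), disease_label = y,
                     bias_group = rep(0:1, each = n / 2),
                     split = NA_character_, stringsAsFactors = FALSE)
    for (cl in 0:1) {  # class-stratified split
      ix <- which(y == cl)
      mf$split[ix] <- rep(c("train", "train", "val", "test"),
                          length.out = length(ix))
    }
    list(x = x, manifest = mf)
  })
}

test_that("training is deterministic and learns a separable task", {
  ds <- blobTask(80, seed = 5)
  mc <- modelConfig(convFilters = c(4, 8), blockActivation = "relu",
                    headInit = "normal")
  tc <- trainConfig(batchSize = 8, learningRate = 2e-3, patience = 5,
                    maxEpochs = 8, seed = 2)
  f1 <- trainClassifier(buildCnn(mc, c(16, 16, 16), seed = 2), ds, tc)
  f2 <- trainClassifier(buildCnn(mc, c(16, 16, 16), seed = 2), ds, tc)
  # determinism: identical loss trajectory and identical weights
  expect_identical(f1@history$val_loss, f2@history$val_loss)
  expect_identical(f1@headW, f2@headW)
  expect_identical(f1@blocks[[1]]$W, f2@blocks[[1]]$W)
  te <- ds$manifest$split == "test"
  pr <- predictLabels(f1, ds$x[ds$manifest$subject_id[te]])
  acc <- mean(pr$label == ds$manifest$disease_label[te])
  expect_gte(acc, 0.75)
  # history bookkeeping
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_acc") %in%
                    names(f1@history)))
  p <- file.path(tempdir(), "hist.csv")
  writeTrainingHistory(f1, p)
  expect_equal(nrow(read.csv(p)), nrow(f1@history))
  unlink(p)
})

test_that("constant-label training converges to the majority rate", {
  ds <- blobTask(40, seed = 6)
  ds$manifest$disease_label <- 1L
  mc <- modelConfig(convFilters = c(2, 4), headInit = "normal",
                    blockActivation = "relu")
  tc <- trainConfig(batchSize = 8, learningRate = 5e-3, patience = 3,
                    maxEpochs = 6, seed = 1)
  f <- trainClassifier(buildCnn(mc, c(16, 16, 16), seed = 1), ds, tc)
  expect_gte(max(f@history$train_acc), 0.99)
})
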