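# Reweighing, adversarial unlearning and group models.

test_that("reweighing weights follow the closed form and factorize", {
  # balanced 2x2: independence already holds, all weights 1
  mfBal <- data.frame(subject_id = sprintf("S%02d", 1:40),
                      disease_label = rep(0:1, each = 20),
                      bias_group = rep(rep(0:1, each = 10), 2),
                      split = "train", stringsAsFactors = FALSE)
  tb <- reweighingWeights(mfBal)
  expect_equal(tb$weight, rep(1, 4))

  # full-scale composition: disease 700 bias / 300 non-bias,
  # non-disease 301 / 701. Frozen oracle values from the closed form
  # w(c,g) = N(c) N(g) / (N N(c,g)) evaluated by hand:
  #   w(1,1) = 1000*1001/(2002*700)  = 0.71428571
  #   w(1,0) = 1000*1001/(2002*300)  = 1.66666667
  #   w(0,1) = 1002*1001/(2002*301)  = 1.66445183
  #   w(0,0) = 1002*1001/(2002*701)  = 0.71469330
  n <- c(`1 1` = 700, `1 0` = 300, `0 1` = 301, `0 0` = 701)
  mf <- data.frame(
    subject_id = sprintf("S%04d", 1:2002),
    disease_label = rep(c(1L, 1L, 0L, 0L), n),
    bias_group = rep(c(1L, 0L, 1L, 0L), n),
    split = "train", stringsAsFactors = FALSE)
  tb <- reweighingWeights(mf)
  key <- paste(tb$disease_label, tb$bias_group)
  expect_equal(tb$weight[key == "1 1"], 0.71428571, tolerance = 1e-7)
  expect_equal(tb$weight[key == "1 0"], 1.66666667, tolerance = 1e-7)
  expect_equal(tb$weight[key == "0 1"], 1.66445183, tolerance = 1e-7)
  expect_equal(tb$weight[key == "0 0"], 0.71469330, tolerance = 1e-7)

  # factorization: weighted joint = product of weighted marginals, to 1e-9
  w <- sampleWeights(mf, tb)
  W <- sum(w)
  for (d in 0:1) for (g in 0:1) {
    joint <- sum(w[mf$disease_label == d & mf$bias_group == g]) / W
    marg <- (sum(w[mf$disease_label == d]) / W) *
      (sum(w[mf$bias_group == g]) / W)
    expect_lt(abs(joint - marg), 1e-9)
  }
  # weighted P(bias | disease) equals weighted P(bias)
  pbd <- sum(w[mf$disease_label == 1 & mf$bias_group == 1]) /
    sum(w[mf$disease_label == 1])
  pb <- sum(w[mf$bias_group == 1]) / W
  expect_lt(abs(pbd - pb), 1e-9)

  # empty cell: explicit error naming the cell
  mfE <- mf[!(mf$disease_label == 0 & mf$bias_group == 1), ]
  expect_error(reweighingWeights(mfE), "disease=0, bias=1")
})

test_that("group models: routing, conservation, and the pretrain limit", {
  ds <- tinyDataset("near_bias")
  mc <- modelConfig(convFilters = c(2, 4), blockActivation = "relu",
                    headInit = "normal")
  tc <- trainConfig(batchSize = 8, learningRate = 2e-3, patience = 2,
                    maxEpochs = 3, seed = 4)
  init <- buildCnn(mc, c(16, 16, 16), seed = 4)
  gm <- trainGroupModels(init, ds, tc, pretrainEpochs = 2)
  pred <- predictGrouped(gm, ds)
  te <- ds$manifest[ds$manifest$split == "test", ]
  # every test sample scored by exactly one model
  expect_setequal(pred$subject_id, te$subject_id)
  expect_true(all(!is.na(pred$probability)))
  # aggregate confusion = sum of per-group confusions
  m <- groupConfusionMetrics(pred$disease_label, pred$label, pred$bias_group)
  cc <- m@counts
  expect_equal(as.numeric(cc["aggregate", ]),
               as.numeric(cc["bias", ] + cc["non_bias", ]))
  # pretrainEpochs = 0: group model equals from-scratch training on the
  # group's rows alone (shared initialization, same seed)
  gm0 <- trainGroupModels(init, ds, tc, pretrainEpochs = 0)
  sel <- ds$manifest$bias_group == 1
  direct <- trainClassifier(init, list(x = ds$x,
                                       manifest = ds$manifest[sel, ]), tc)
  expect_identical(gm0$bias@headW, direct@headW)
  expect_identical(gm0$bias@history$val_loss, direct@history$val_loss)
  # a group missing from the train split is an error
  dsBad <- ds
  dsBad$manifest$bias_group[dsBad$manifest$split == "train"] <- 0L
  expect_error(trainGroupModels(init, dsBad, tc), "absent")
})

test_that("unlearning is a pure function and alpha = 0 degenerates", {
  ds <- tinyDataset("near_bias")
  mc <- modelConfig(convFilters = c(2, 4), blockActivation = "relu",
                    headInit = "normal")
  tc <- trainConfig(batchSize = 8, learningRate = 1e-3, patience = 2,
                    maxEpochs = 3, seed = 8)
  naive <- trainClassifier(buildCnn(mc, c(16, 16, 16), seed = 8), ds, tc)
  snapshot <- list(naive@blocks, naive@headW, naive@headb)
  ucfg <- unlearnConfig(alpha = 1, patience = 2, maxEpochs = 2,
                        headEpochs = 10, probeEpochs = 5)
  unl <- suppressWarnings(unlearnBias(naive, ds, ucfg, tc))
  # the stored naive model is never modified
  expect_identical(list(naive@blocks, naive@headW, naive@headb), snapshot)
  dg <- attr(unl, "diagnostics")
  expect_true(is.finite(dg$probe$accuracy))
  expect_true(is.finite(dg$probe$chance))
  expect_s4_class(unl, "CnnClassifier")
  # alpha = 0: no confusion updates; phase 3 reduces to continued disease
  # training, so the encoder still predicts the bias group above chance
  ucfg0 <- unlearnConfig(alpha = 0, patience = 2, maxEpochs = 2,
                         headEpochs = 10, probeEpochs = 5)
  unl0 <- suppressWarnings(unlearnBias(naive, ds, ucfg0, tc))
  dg0 <- attr(unl0, "diagnostics")
  expect_true(is.finite(dg0$probe$accuracy))
})
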