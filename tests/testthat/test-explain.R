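# SmoothGrad saliency, subgroup averaging, weighted saliency scores.

test_that("a linear scorer has analytic saliency |w| at any noise level", {
  gd <- c(8L, 8L, 8L)
  w <- array(rnorm(prod(gd)), gd)
  m <- linearScorer(w, bias = 0.3)
  v <- array(rnorm(prod(gd)), gd)
  s0 <- smoothGrad(m, v, nNoise = 1, noiseFraction = 0)
  s1 <- smoothGrad(m, v, nNoise = 25, noiseFraction = 0.5, seed = 7)
  expect_equal(max(abs(s0 - abs(w))), 0, tolerance = 1e-10)
  expect_equal(max(abs(s1 - abs(w))), 0, tolerance = 1e-10)
})

test_that("CNN SmoothGrad is seeded and reduces to the plain gradient", {
  mc <- modelConfig(convFilters = c(2, 4), blockActivation = "relu",
                    headInit = "normal")
  m <- buildCnn(mc, c(8, 8, 8), seed = 5)
  v <- withSeed(1, array(rnorm(512), c(8, 8, 8)))
  # zero noise: independent of nNoise
  a <- smoothGrad(m, v, nNoise = 1, noiseFraction = 0)
  b <- smoothGrad(m, v, nNoise = 5, noiseFraction = 0)
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(a >= 0))
  # same seed -> identical maps; different seed -> different
  s1 <- smoothGrad(m, v, nNoise = 4, noiseFraction = 0.1, seed = 3)
  s2 <- smoothGrad(m, v, nNoise = 4, noiseFraction = 0.1, seed = 3)
  s3 <- smoothGrad(m, v, nNoise = 4, noiseFraction = 0.1, seed = 4)
  expect_identical(s1, s2)
  expect_gt(max(abs(s1 - s3)), 0)
  expect_error(smoothGrad(m, v, nNoise = 0), "nNoise")
})

test_that("weighted saliency scores are enrichments with the stated algebra", {
  gd <- c(10L, 10L, 10L)
  lab <- array(0L, gd)
  lab[1:5, , ] <- 1L   # 500 voxels
  lab[6:8, 1:3, 1:3] <- 2L  # 27 voxels
  # uniform saliency: every region scores exactly 1
  u <- array(2.5, gd)
  tb <- weightedSaliencyScores(u, lab)
  expect_equal(tb$score, c(1, 1))
  # saliency concentrated in one region: closed form
  s <- array(0, gd); s[lab == 2L] <- 1
  tb <- weightedSaliencyScores(s, lab)
  nl <- sum(lab > 0)
  expect_equal(tb$score[tb$region_id == 2], nl / 27)
  expect_equal(tb$score[tb$region_id == 1], 0)
  # two regions, sizes 10 and 90, mean saliencies 2 and 1:
  # scores (2, 1) / ((10*2 + 90*1)/100) = (1.818..., 0.909...)
  lab2 <- array(0L, c(10L, 10L, 1L))
  lab2[1:10] <- 1L; lab2[11:100] <- 2L
  s2 <- array(1, c(10L, 10L, 1L)); s2[1:10] <- 2
  tb2 <- weightedSaliencyScores(s2, lab2)
  expect_equal(tb2$score[tb2$region_id == 1], 2 / 1.1, tolerance = 1e-12)
  expect_equal(tb2$score[tb2$region_id == 2], 1 / 1.1, tolerance = 1e-12)
  # scale invariance and unit voxel-weighted mean
  withSeed(9, {
    r <- array(abs(rnorm(prod(gd))), gd)
    t1 <- weightedSaliencyScores(r, lab)
    t2 <- weightedSaliencyScores(r * 37.5, lab)
    expect_equal(t1$score, t2$score, tolerance = 1e-12)
    expect_equal(sum(t1$score * t1$voxel_count) / sum(t1$voxel_count), 1,
                 tolerance = 1e-12)
  })
  # all-zero saliency is flagged undefined
  expect_warning(tb0 <- weightedSaliencyScores(array(0, gd), lab),
                 "undefined")
  expect_true(all(is.na(tb0$score)))
  # region table merge keeps roles
  tpl <- tinyTemplate()
  tbr <- weightedSaliencyScores(array(1, dim(regionLabels(tpl))),
                                regionLabels(tpl), regionTable(tpl))
  expect_true(all(c("role", "name", "score") %in% names(tbr)))
})

test_that("group-averaged saliency averages correctly classified subjects", {
  gd <- c(8L, 8L, 8L)
  w <- array(rnorm(prod(gd)), gd)
  m <- linearScorer(w)
  # linear scorer: every per-subject map is |w|, so any average equals |w|
  # (mean idempotence) regardless of how many subjects enter
  xs <- withSeed(11, lapply(1:6, function(i) array(rnorm(512), gd)))
  names(xs) <- sprintf("S%02d", 1:6)
  mf <- data.frame(subject_id = names(xs), disease_label = 1L,
                   bias_group = 1L, split = "test", stringsAsFactors = FALSE)
  preds <- data.frame(subject_id = names(xs),
                      probability = 1, label = 1L)
  avg <- averageGroupSaliency(m, list(x = xs, manifest = mf), 1, 1,
                              nSubjects = 3, predictions = preds)
  expect_equal(unclass(avg), unclass(abs(w)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_length(attr(avg, "subjects"), 3)
  # fewer correctly classified than requested: warns and uses all
  preds2 <- preds; preds2$label[3:6] <- 0L
  expect_warning(
    avg2 <- averageGroupSaliency(m, list(x = xs, manifest = mf), 1, 1,
                                 nSubjects = 5, predictions = preds2),
    "using all")
  expect_length(attr(avg2, "subjects"), 2)
  # nSubjects = 1 equals that subject's own map
  one <- averageGroupSaliency(m, list(x = xs, manifest = mf), 1, 1,
                              nSubjects = 1, predictions = preds)
  expect_equal(unclass(one), unclass(smoothGrad(m, xs[[1]])),
               ignore_attr = TRUE)
})
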