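# Composition, stratification, counterfactual build and splits.

test_that("assignLabels hits the composition counts exactly", {
  cfg <- compositionConfig()  # 1000/1002, 70%/30%
  lab <- assignLabels(cfg)
  expect_equal(nrow(lab), 2002)
  expect_equal(sum(lab$disease_label), 1000)
  expect_equal(sum(lab$bias_group[lab$disease_label == 1]), 700)
  # round(0.3 * 1002) = round(300.6) = 301, half away from zero
  expect_equal(sum(lab$bias_group[lab$disease_label == 0]), 301)
  expect_identical(assignLabels(cfg), lab)  # deterministic in seed
  # zero bias proportions
  cfg0 <- compositionConfig(nDisease = 10, nNondisease = 10,
                            pBiasDisease = 0, pBiasNondisease = 0)
  expect_equal(sum(assignLabels(cfg0)$bias_group), 0)
  expect_warning(assignLabels(compositionConfig(nDisease = 4, nNondisease = 4,
                                                pBiasDisease = 0.1,
                                                pBiasNondisease = 0)),
                 "rounds to zero")
  expect_error(assignLabels(compositionConfig(nDisease = 0, nNondisease = 4)),
               "positive")
})

test_that("stratifyMagnitudes deals rank-interleaved cells (0..99 oracle)", {
  mags <- 0:99
  cells <- c(a = 25L, b = 25L, c = 25L, d = 25L)
  deal <- stratifyMagnitudes(mags, cells, nBins = 4, seed = 1)
  expect_equal(nrow(deal), 100)
  expect_equal(as.vector(table(deal$cell)), rep(25L, 4))
  # quantile-bin counts per cell are near-identical (6 or 7 per bin)
  got <- mags[deal$pool_index]
  bin <- cut(got, breaks = quantile(mags, 0:4 / 4), include.lowest = TRUE)
  tab <- table(deal$cell, bin)
  expect_true(all(tab %in% c(6L, 7L)))
  # max pairwise KS below the 10%-level critical value
  byCell <- split(got, deal$cell)
  for (i in 1:3) for (j in (i + 1):4) {
    ks <- ksStatistic(byCell[[i]], byCell[[j]])
    expect_lte(ks, ksCriticalValue(25, 25, 0.10))
  }
  # identical magnitudes: any deal is valid, KS exactly 0
  dealSame <- stratifyMagnitudes(rep(1, 40), c(a = 20L, b = 20L), 4, seed = 2)
  expect_equal(ksStatistic(rep(1, 20), rep(1, 20)), 0)
  expect_error(stratifyMagnitudes(1:10, c(a = 20L), 4), "pool smaller")
})

test_that("counterfactual build: identity, locality, conservation", {
  d <- tinyData()
  subj <- d$cohort$subjects
  tpl <- tinyTemplate()
  # every subject appears exactly once per scenario
  for (sc in names(d$manifests)) {
    expect_equal(sort(d$manifests[[sc]]$subject_id), sort(subj$subject_id))
    expect_equal(nrow(d$manifests[[sc]]), 60)
  }
  # non-bias subjects: volumes bit-identical across scenarios
  nb <- subj$subject_id[subj$bias_group == 0]
  for (id in nb)
    expect_identical(d$volumes$no_bias[[id]], d$volumes$near_bias[[id]])
  # bias subjects differ between scenarios
  bi <- subj$subject_id[subj$bias_group == 1]
  for (id in bi)
    expect_gt(max(abs(d$volumes$near_bias[[id]] - d$volumes$no_bias[[id]])), 0)
  # locality: with only a masked bias effect, the warped volume differs from
  # the template only inside the bias region dilated by the maximum
  # displacement (plus one voxel of interpolation support)
  near <- regionMask(tpl, "near_bias_region")
  for (s in 1:3) {
    smp <- sampleEffect(tinyModels()$bias, seed = s)
    vb <- restrictToRegion(effectField(smp), near, 0)
    disp <- exponentiate(vb)
    maxDisp <- max(sqrt(disp[, , , 1]^2 + disp[, , , 2]^2 + disp[, , , 3]^2))
    dil <- dilateMask(near, ceiling(maxDisp) + 1)
    diff <- abs(warpVolume(intensityVolume(tpl), disp) - intensityVolume(tpl))
    expect_lte(max(diff[dil == 0]), 1e-6)
    expect_gt(max(diff), 0)
  }
  # realized composition equals round(p * n) / n exactly
  expect_equal(sum(subj$bias_group[subj$disease_label == 1]),
               as.integer(round(0.7 * 30)))
  expect_equal(sum(subj$bias_group[subj$disease_label == 0]),
               as.integer(round(0.3 * 30)))
})

test_that("splits are stratified, conserved and scenario-invariant", {
  cfg <- compositionConfig(nDisease = 200, nNondisease = 200, seed = 11)
  cohort <- suppressWarnings(designCohort(tinyModels(), cfg))
  subj <- cohort$subjects
  expect_equal(sum(table(subj$split)), 400)
  # 50/25/25 within largest-remainder rounding across strata
  expect_lt(abs(sum(subj$split == "train") - 200), 10)
  expect_lt(abs(sum(subj$split == "val") - 100), 10)
  # deterministic
  cohort2 <- suppressWarnings(designCohort(tinyModels(), cfg))
  expect_identical(cohort2$subjects$split, subj$split)
  # per-split class/bias proportions within 2 percentage points of global
  for (sp in c("train", "val", "test")) {
    sel <- subj$split == sp
    expect_lt(abs(mean(subj$disease_label[sel]) - 0.5), 0.02)
    expect_lt(abs(mean(subj$bias_group[sel]) - mean(subj$bias_group)), 0.02)
  }
  # manifests carry the split through unchanged
  mfs <- buildManifests(cohort)
  expect_identical(mfs$no_bias$split, mfs$far_bias$split)
})

test_that("cohort magnitude stratification matches across cells", {
  cfg <- compositionConfig(nDisease = 200, nNondisease = 200, seed = 11)
  cohort <- suppressWarnings(designCohort(tinyModels(), cfg))
  subj <- cohort$subjects
  cells <- split(subj$subject_magnitude, subj$cell)
  nm <- names(cells)
  for (i in seq_along(nm)) for (j in seq_len(i - 1)) {
    ks <- ksStatistic(cells[[i]], cells[[j]])
    expect_lte(ks, ksCriticalValue(length(cells[[i]]), length(cells[[j]])))
  }
  # disease magnitudes exist only for the disease class
  expect_true(all(is.na(subj$disease_magnitude[subj$disease_label == 0])))
  expect_true(all(!is.na(subj$disease_magnitude[subj$disease_label == 1])))
})
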