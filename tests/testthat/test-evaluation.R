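# Subgroup metrics, disparities, and the statistical comparison protocol.

toyLabels <- function() {
  # bias group: TP 9, FN 1, FP 3, TN 7; non-bias: TP 6, FN 4, FP 1, TN 9
  truth <- c(rep(1, 10), rep(0, 10), rep(1, 10), rep(0, 10))
  pred <- c(rep(1, 9), 0, rep(1, 3), rep(0, 7),
            rep(1, 6), rep(0, 4), 1, rep(0, 9))
  grp <- c(rep(1, 20), rep(0, 20))
  list(truth = truth, pred = pred, grp = grp)
}

test_that("group confusion metrics match hand arithmetic", {
  tl <- toyLabels()
  m <- groupConfusionMetrics(tl$truth, tl$pred, tl$grp)
  tb <- metricsTable(m)
  expect_equal(tb$TPR[tb$group == "bias"], 90)
  expect_equal(tb$TPR[tb$group == "non_bias"], 60)
  expect_equal(tb$FPR[tb$group == "bias"], 30)
  expect_equal(tb$FPR[tb$group == "non_bias"], 10)
  d <- disparity(m)
  expect_equal(unname(d["dTPR"]), 30)
  expect_equal(unname(d["dFPR"]), 20)
  # confusion conservation is enforced by the class validity
  expect_true(validObject(m))
  # perfect predictions
  mp <- groupConfusionMetrics(tl$truth, tl$truth, tl$grp)
  tbp <- metricsTable(mp)
  expect_equal(tbp$TPR, c(100, 100, 100))
  expect_equal(tbp$FPR, c(0, 0, 0))
  # all-positive predictions: TPR and FPR both 100 in every group
  ma <- groupConfusionMetrics(tl$truth, rep(1, 40), tl$grp)
  tba <- metricsTable(ma)
  expect_equal(tba$TPR, c(100, 100, 100))
  expect_equal(tba$FPR, c(100, 100, 100))
  # a group without positives has undefined (NA) TPR, never 0
  mna <- groupConfusionMetrics(c(0, 0, 1, 1), c(0, 0, 1, 1), c(0, 0, 1, 1))
  tbna <- metricsTable(mna)
  expect_true(is.na(tbna$TPR[tbna$group == "non_bias"]))
  expect_true(is.na(disparity(mna)["dTPR"]))
})

test_that("disparity is antisymmetric under group relabeling", {
  withSeed(13, {
    for (rep in 1:20) {
      truth <- rbinom(40, 1, 0.5)
      pred <- rbinom(40, 1, 0.5)
      grp <- rbinom(40, 1, 0.5)
      m1 <- groupConfusionMetrics(truth, pred, grp)
      m2 <- groupConfusionMetrics(truth, pred, 1 - grp)
      d1 <- disparity(m1); d2 <- disparity(m2)
      if (all(is.finite(c(d1, d2)))) {
        expect_equal(d1["dTPR"], -d2["dTPR"])
        expect_equal(d1["dFPR"], -d2["dFPR"])
      }
    }
  })
})

test_that("relative disparity subtracts the matched-seed baseline", {
  rep1 <- data.frame(seed = 1:3, dTPR = c(5, 6, 7), dFPR = c(1, 2, 3))
  base <- data.frame(seed = 1:3, dTPR = c(1, 1, 1), dFPR = c(0, 1, 2))
  rel <- relativeDisparity(rep1, base)
  expect_equal(rel$rel_dTPR, c(4, 5, 6))
  expect_equal(attr(rel, "summary")$mean[1], 5)
  # baseline against itself is all zero
  rel0 <- relativeDisparity(base, base)
  expect_true(all(rel0$rel_dTPR == 0) && all(rel0$rel_dFPR == 0))
  expect_error(relativeDisparity(rep1, base[1:2, ]), "seed mismatch")
  # linearity: mean of seedwise differences equals difference of means
  withSeed(3, {
    a <- data.frame(seed = 1:8, dTPR = rnorm(8), dFPR = rnorm(8))
    b <- data.frame(seed = 1:8, dTPR = rnorm(8), dFPR = rnorm(8))
    rel <- relativeDisparity(a, b)
    expect_equal(mean(rel$rel_dTPR), mean(a$dTPR) - mean(b$dTPR))
  })
})

test_that("compareConditions picks the branch the differences dictate", {
  cfg <- statsConfig()
  # identical vectors: degenerate, p = 1, never significant
  r <- compareConditions(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5), cfg)
  expect_equal(r$p.value, 1)
  expect_false(r$significant)
  # heavy outlier in the differences: Shapiro-Wilk rejects, Wilcoxon branch
  a <- c(1, 2, 3, 4, 100); b <- rep(0, 5)
  expect_lt(shapiro.test(a - b)$p.value, 0.05)  # oracle for the gate
  r <- compareConditions(a, b, cfg)
  expect_equal(r$test, "wilcoxon")
  # well-behaved normal differences: paired t branch
  withSeed(5, {
    r <- compareConditions(rnorm(10, mean = 3), rnorm(10), cfg)
    expect_equal(r$test, "paired t")
  })
  # constant nonzero differences go to the rank test
  r <- compareConditions(c(2, 3, 4), c(1, 2, 3), cfg)
  expect_equal(r$test, "wilcoxon")
  expect_error(compareConditions(1:2, 2:3, cfg), "at least 3")
})

test_that("a 5-SD mean shift at n = 5 is usually detected at alpha = 0.005", {
  # Monte-Carlo power of the full gate-then-test pipeline on independent
  # normal samples shifted by 5 SD. The Wilcoxon fallback can never reach
  # p < 0.005 at n = 5 (min two-sided p = 0.0625) and the paired t power at
  # this design is 0.885, so the pipeline's power is ~0.95 * 0.885 ~ 0.84
  # (Monte-Carlo oracle at 1000 reps: 0.834). Frozen threshold below the
  # oracle minus binomial noise.
  cfg <- statsConfig()
  hits <- withSeed(99, {
    mean(vapply(1:200, function(i) {
      compareConditions(rnorm(5, mean = 5), rnorm(5), cfg)$significant
    }, logical(1)))
  })
  expect_gte(hits, 0.75)
})

test_that("the repeated-measures ANOVA gate reports the design effects", {
  withSeed(21, {
    d <- expand.grid(scenario = c("no_bias", "near_bias", "far_bias"),
                     strategy = c("naive", "reweighing"), seed = 1:5)
    d$value <- rnorm(nrow(d)) +
      ifelse(d$scenario == "near_bias" & d$strategy == "naive", 8, 0)
    out <- rmAnovaGate(d)
    expect_true(all(c("scenario", "strategy", "scenario:strategy") %in%
                      out$effect))
    expect_true(all(out$p.value >= 0 & out$p.value <= 1))
  })
})

test_that("KS machinery behaves at the extremes", {
  expect_equal(ksStatistic(1:10, 1:10), 0)
  expect_equal(ksStatistic(1:10, 101:110), 1)
  # asymptotic critical value grows as samples shrink
  expect_gt(ksCriticalValue(10, 10), ksCriticalValue(100, 100))
})
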