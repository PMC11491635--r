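# Subgroup metrics, ΔTPR/ΔFPR disparities (absolute and relative to the
# No-Bias baseline) and the statistical comparison protocol: Shapiro-Wilk
# gated paired t / Wilcoxon tests at the Bonferroni-corrected level, with a
# two-way repeated-measures ANOVA as omnibus gate.

#' Statistics configuration
#'
#' @param alpha Bonferroni-corrected significance level (default 0.005).
#' @param normalityAlpha Shapiro-Wilk level deciding t-test vs Wilcoxon.
#' @return a `statsConfig` list.
#' @export
statsConfig <- function(alpha = 0.005, normalityAlpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, normalityAlpha = normalityAlpha),
            class = "statsConfig")
}

#' Subgroup confusion metrics
#'
#' Confusion counts per bias group and aggregate; accuracy, TPR and FPR are
#' derived from the counts on access and reported in percent. The disease
#' class is the positive prediction. A rate whose denominator is zero is NA.
#'
#' @param trueLabels,predictedLabels binary vectors.
#' @param biasGroups binary vector (1 = bias group).
#' @return a [GroupMetrics-class].
#' @export
groupConfusionMetrics <- function(trueLabels, predictedLabels, biasGroups) {
  n <- length(trueLabels)
  if (length(predictedLabels) != n || length(biasGroups) != n)
    stop("trueLabels, predictedLabels and biasGroups must have equal length")
  if (!all(trueLabels %in% 0:1) || !all(predictedLabels %in% 0:1))
    stop("labels must be binary")
  cnt <- function(sel) {
    y <- trueLabels[sel]; p <- predictedLabels[sel]
    c(TP = sum(y == 1 & p == 1), FN = sum(y == 1 & p == 0),
      FP = sum(y == 0 & p == 1), TN = sum(y == 0 & p == 0))
  }
  counts <- rbind(non_bias = cnt(biasGroups == 0),
                  bias = cnt(biasGroups == 1))
  counts <- rbind(counts, aggregate = colSums(counts))
  new("GroupMetrics", counts = as.data.frame(counts))
}

#' @describeIn groupConfusionMetrics rates table (percent) derived from the
#'   stored counts.
#' @param metrics a [GroupMetrics-class].
#' @export
metricsTable <- function(metrics) {
  cc <- metrics@counts
  rate <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  data.frame(group = rownames(cc), cc,
             accuracy = rate(cc$TP + cc$TN, cc$TP + cc$FN + cc$FP + cc$TN),
             TPR = rate(cc$TP, cc$TP + cc$FN),
             FPR = rate(cc$FP, cc$FP + cc$TN),
             row.names = NULL)
}

#' Subgroup performance disparity
#'
#' Signed bias-minus-non-bias differences in TPR and FPR, in percentage
#' points. NA when either group's rate is undefined.
#'
#' @param metrics a [GroupMetrics-class].
#' @return named numeric `c(dTPR, dFPR)`.
#' @export
disparity <- function(metrics) {
  tb <- metricsTable(metrics)
  bi <- tb[tb$group == "bias", ]
  nb <- tb[tb$group == "non_bias", ]
  c(dTPR = bi$TPR - nb$TPR, dFPR = bi$FPR - nb$FPR)
}

#' Relative disparity (seedwise, against the No-Bias baseline)
#'
#' Subtracts the matched-seed baseline disparities; mean and SD over seeds
#' are attached as the `summary` attribute.
#'
#' @param report data.frame with seed, dTPR, dFPR for one scenario/strategy.
#' @param baseline same layout for the No-Bias scenario of the same
#'   strategy; seeds must match.
#' @return data.frame with seed, relative dTPR and dFPR.
#' @export
relativeDisparity <- function(report, baseline) {
  if (!setequal(report$seed, baseline$seed))
    stop("seed mismatch between report and baseline")
  b <- baseline[match(report$seed, baseline$seed), ]
  out <- data.frame(seed = report$seed,
                    rel_dTPR = report$dTPR - b$dTPR,
                    rel_dFPR = report$dFPR - b$dFPR)
  attr(out, "summary") <- data.frame(
    metric = c("rel_dTPR", "rel_dFPR"),
    mean = c(mean(out$rel_dTPR), mean(out$rel_dFPR)),
    sd = c(sd(out$rel_dTPR), sd(out$rel_dFPR)))
  out
}

#' Paired comparison between two conditions
#'
#' Shapiro-Wilk on the paired differences decides the branch: paired t-test
#' when normality is not rejected, Wilcoxon matched-pairs signed-rank
#' otherwise. All-zero differences give exact p = 1; constant nonzero
#' differences go to the rank test (whose tie handling applies).
#'
#' @param a,b paired per-seed values (length >= 3).
#' @param config a [statsConfig()].
#' @return list with test, statistic, p.value, significant.
#' @export
compareConditions <- function(a, b, config = statsConfig()) {
  if (length(a) != length(b)) stop("a and b must be paired")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  if (all(d == 0))
    return(list(test = "degenerate (all differences zero)", statistic = NA,
                p.value = 1, significant = FALSE))
  useWilcox <- if (sd(d) == 0) TRUE else {
    shapiro.test(d)$p.value <= config$normalityAlpha
  }
  if (useWilcox) {
    ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                       alternative = "two.sided"))
  } else {
    ht <- t.test(a, b, paired = TRUE, alternative = "two.sided")
  }
  list(test = if (useWilcox) "wilcoxon" else "paired t",
       statistic = unname(ht$statistic), p.value = ht$p.value,
       significant = ht$p.value < config$alpha)
}

#' Two-way repeated-measures ANOVA gate
#'
#' Omnibus test on a long table of per-seed disparities with scenario and
#' strategy as within-seed factors, delegated to `stats::aov` with an
#' `Error(seed/(scenario*strategy))` term. Reported as a gate before the
#' pairwise tests.
#'
#' @param data data.frame with columns value, scenario, strategy, seed.
#' @return data.frame of effects and p-values.
#' @export
rmAnovaGate <- function(data) {
  data$scenario <- factor(data$scenario)
  data$strategy <- factor(data$strategy)
  data$seed <- factor(data$seed)
  fit <- aov(value ~ scenario * strategy +
               Error(seed / (scenario * strategy)), data = data)
  sm <- summary(fit)
  out <- NULL
  for (stratum in sm) {
    tb <- stratum[[1]]
    keep <- !grepl("Residuals", rownames(tb))
    if (any(keep))
      out <- rbind(out, data.frame(effect = trimws(rownames(tb)[keep]),
                                   F = tb[keep, "F value"],
                                   p.value = tb[keep, "Pr(>F)"]))
  }
  rownames(out) <- NULL
  out
}
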