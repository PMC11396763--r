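test_that("AUC handles perfect separation, anti-separation and ties", {
  expect_equal(roc_curve(1:4, c("reference", "reference", "target",
                                "target"))$auc, 1)
  expect_equal(roc_curve(1:4, c("target", "target", "reference",
                                "reference"))$auc, 0)
  # pair enumeration with a half for the tie: (2>1) + (2==2)/2 + (3>1) +
  # (3>2) over 4 pairs = 3.5/4
  expect_equal(roc_curve(c(1, 2, 2, 3),
                         c("reference", "target", "reference",
                           "target"))$auc, 0.875)
  expect_error(roc_curve(1:4, rep("target", 4)), "both classes")
})

test_that("pair-counting AUC equals the trapezoidal area and pROC on random sets", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    scores <- round(stats::rnorm(n), 1)  # rounding induces ties
    labels <- sample(c("reference", "target"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    roc <- roc_curve(scores, labels)
    # trapezoid under the swept curve, points ordered by threshold
    fpr <- 1 - roc$points$specificity
    tpr <- roc$points$sensitivity
    o <- order(fpr, tpr)
    trap <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) +
                                utils::tail(tpr[o], -1)) / 2)
    expect_equal(roc$auc, trap, tolerance = 1e-9)
    ref_auc <- as.numeric(suppressMessages(
      pROC::auc(labels, scores, levels = c("reference", "target"),
                direction = "<")))
    expect_equal(roc$auc, ref_auc, tolerance = 1e-12)
  }
})

test_that("AUC satisfies its symmetry and invariance properties", {
  set.seed(22)
  scores <- stats::rnorm(15)
  labels <- sample(c("reference", "target"), 15, replace = TRUE,
                   prob = c(0.6, 0.4))
  auc <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(-scores, labels)$auc, 1 - auc, tolerance = 1e-12)
  expect_equal(roc_curve(exp(scores), labels)$auc, auc, tolerance = 1e-12)
})

test_that("Youden threshold maximises J with the documented tie-break", {
  # perfect separation: both rates 100%
  roc <- roc_curve(c(1, 2, 3, 10, 11, 12),
                   rep(c("reference", "target"), each = 3))
  yd <- youden_threshold(roc)
  expect_equal(yd$j, 1)
  expect_equal(yd$sensitivity, 1)
  expect_equal(yd$specificity, 1)
  expect_false(yd$degenerate)
  # all scores identical: no information
  yd0 <- youden_threshold(roc_curve(rep(1, 6),
                                    rep(c("reference", "target"), 3)))
  expect_equal(yd0$j, 0)
  expect_true(yd0$degenerate)
})

test_that("co-optimal Youden cuts are all returned; tie-break prefers specificity", {
  # two J-maximising cuts by construction
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- c("reference", "target", "reference", "target", "reference",
              "target")
  roc <- roc_curve(scores, labels)
  # exhaustive oracle over all swept thresholds
  j_all <- roc$points$sensitivity + roc$points$specificity - 1
  jmax <- max(j_all)
  oracle <- roc$points[abs(j_all - jmax) < 1e-12, ]
  yd <- youden_threshold(roc)
  expect_equal(nrow(yd$cooptimal), nrow(oracle))
  expect_setequal(yd$cooptimal$threshold, oracle$threshold)
  expect_equal(yd$specificity, max(oracle$specificity))
  expect_gte(nrow(yd$cooptimal), 2L)
})

test_that("predictive values reproduce confusion-matrix arithmetic with half-up rounding", {
  pv <- predictive_values(10, 2, 13, 5)
  expect_equal(pv$ppv, 83)
  expect_equal(pv$npv, 72)
  pv2 <- predictive_values(14, 7, 8, 1)
  expect_equal(pv2$ppv, 67)
  expect_equal(pv2$npv, 89)
  pv3 <- predictive_values(13, 6, 9, 2)
  expect_equal(pv3$ppv, 68)
  expect_equal(pv3$npv, 82)
  und <- predictive_values(0, 0, 5, 3)
  expect_true(is.na(und$ppv))
  expect_false(und$ppv_defined)
  expect_equal(und$npv, 63)
  expect_error(predictive_values(-1, 0, 0, 0), "non-negative")
})

test_that("classification uses a strict greater-than threshold", {
  expect_equal(classify(c(1, 2, 3), 5), rep("reference", 3))
  expect_equal(classify(c(1, 2, 3), 2), c("reference", "reference",
                                          "target"))
  # boundary: exactly at threshold is reference
  expect_equal(classify(2, 2), "reference")
})

test_that("reported Youden metrics agree with reclassification counts", {
  set.seed(23)
  scores <- stats::rnorm(20)
  labels <- rep(c("reference", "target"), each = 10)
  m <- roc_metrics(scores, labels)
  pred <- classify(scores, m$threshold)
  conf <- c(tp = sum(pred == "target" & labels == "target"),
            fp = sum(pred == "target" & labels == "reference"),
            tn = sum(pred == "reference" & labels == "reference"),
            fn = sum(pred == "reference" & labels == "target"))
  expect_equal(m$confusion, conf)
  expect_equal(sum(conf), 20)
  expect_equal(m$sensitivity,
               floor(100 * conf["tp"] / (conf["tp"] + conf["fn"]) + 0.5),
               ignore_attr = TRUE)
  expect_equal(m$specificity,
               floor(100 * conf["tn"] / (conf["tn"] + conf["fp"]) + 0.5),
               ignore_attr = TRUE)
})

test_that("concordance restricts metrics to agreeing subjects", {
  pred <- rep(c("reference", "target"), 5)
  truth <- rep(c("reference", "target"), each = 5)
  # full agreement
  full <- concordance_combine(pred, pred, truth)
  expect_equal(full$concordance_percent, 100)
  expect_equal(sum(full$confusion), 10)
  # complete disagreement
  flip <- ifelse(pred == "target", "reference", "target")
  none <- concordance_combine(pred, flip, truth)
  expect_equal(none$concordance_percent, 0)
  expect_true(none$empty_subset)
  # hand-tallied partial agreement: 6 of 10 agree
  a <- c("target", "target", "reference", "reference", "target",
         "reference", "target", "reference", "target", "reference")
  b <- c("target", "reference", "reference", "target", "target",
         "reference", "reference", "target", "target", "reference")
  tr <- c("target", "target", "reference", "reference", "target",
          "target", "reference", "reference", "reference", "reference")
  out <- concordance_combine(a, b, tr)
  expect_equal(out$concordance_percent, 60)
  # within the agreeing 6 (indices 1,3,5,6,9,10): tp 2, fp 1, tn 2, fn 1
  expect_equal(unname(out$confusion), c(2, 1, 2, 1))
  expect_equal(out$metrics_within_concordant$sensitivity, 67)
  expect_equal(out$metrics_within_concordant$specificity, 67)
  expect_error(concordance_combine(a, b[1:5], tr), "equal length")
})
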