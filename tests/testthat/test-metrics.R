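test_that("confusion tally matches a brute-force count", {
  lab <- c("AFIB", "AFIB", "AFIB", "N", "N", "N", "AFIB", "N", "AFIB", "N")
  prd <- c("AFIB", "N", "AFIB", "N", "AFIB", "N", "AFIB", "N", "N", "AFIB")
  cm <- confusion(lab, prd)
  oracle <- c(TP = 0, FN = 0, FP = 0, TN = 0)
  for (i in seq_along(lab)) {
    key <- if (lab[i] == "AFIB" && prd[i] == "AFIB") "TP"
    else if (lab[i] == "AFIB") "FN"
    else if (prd[i] == "AFIB") "FP" else "TN"
    oracle[key] <- oracle[key] + 1
  }
  expect_equal(unlist(cm[c("TP", "FN", "FP", "TN")]), oracle)
  expect_equal(cm$TP + cm$FN + cm$FP + cm$TN, 10)

  perfect <- confusion(lab, lab)
  expect_equal(perfect$FP + perfect$FN, 0)
  all_afib <- confusion(lab, rep("AFIB", 10))
  expect_equal(all_afib$TN + all_afib$FN, 0)
  expect_error(confusion(lab, prd[-1]), class = "ecgbispec_length_mismatch")
})

test_that("likelihood ratios and F-scores reproduce the published worked examples", {
  r <- round_report(metrics_report(sensitivity = 0.953, specificity = 0.937))
  expect_equal(r$lr_plus, 15.127)
  expect_equal(r$lr_minus, 0.050)

  r <- round_report(metrics_report(sensitivity = 0.967, ppv = 0.846))
  expect_equal(r$f1_afib, 0.902)
  r <- round_report(metrics_report(sensitivity = 0.967, npv = 0.961))
  expect_equal(r$f1_n, 0.964)
})

test_that("the full published measure column is internally consistent", {
  r <- round_report(metrics_report(sensitivity = 0.953, specificity = 0.937,
                                   ppv = 0.938, npv = 0.952, pv = 0.5))
  expect_equal(r$acc, 0.945)
  expect_equal(r$lr_plus, 15.127)
  expect_equal(r$lr_minus, 0.050)
  expect_equal(r$f1_afib, 0.945)
  expect_equal(r$f1_n, 0.952)
})

test_that("count form and rate form of every measure agree", {
  set.seed(3)
  for (i in 1:10) {
    cm <- confusion(sample(c("AFIB", "N"), 60, TRUE),
                    sample(c("AFIB", "N"), 60, TRUE))
    rc <- metrics_report(cm)
    rr <- metrics_report(sensitivity = rc$sensitivity,
                         specificity = rc$specificity, ppv = rc$ppv,
                         npv = rc$npv, pv = rc$pv)
    for (f in c("sensitivity", "specificity", "ppv", "npv", "pv", "acc",
                "lr_plus", "lr_minus", "f1_afib", "f1_n")) {
      expect_equal(rc[[f]], rr[[f]], tolerance = 1e-12)
    }
  }
})

test_that("balanced-everything counts give the symmetric half report", {
  cm <- structure(list(TP = 5L, FN = 5L, FP = 5L, TN = 5L),
                  class = "confusion_counts")
  r <- metrics_report(cm)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 0.5)
  expect_equal(r$acc, 0.5)
  expect_equal(r$lr_plus, 1)
  expect_equal(r$lr_minus, 1)
})

test_that("undefined measures surface as NA with a warning, never silently", {
  cm <- confusion(rep("AFIB", 5), rep("AFIB", 5))
  expect_warning(r <- metrics_report(cm), "undefined")
  expect_true(is.na(r$specificity))
  expect_equal(r$sensitivity, 1)
})

test_that("per-class F1 alternative uses the N-class precision/recall pair", {
  cm <- confusion(c(rep("AFIB", 6), rep("N", 4)),
                  c(rep("AFIB", 5), "N", "AFIB", rep("N", 3)))
  r <- metrics_report(cm, f1_n = "per_class")
  expect_equal(r$f1_n, 2 * r$npv * r$specificity / (r$npv + r$specificity))
})

test_that("ROC: endpoints, monotonicity, trapezoid AUC equals Mann-Whitney", {
  set.seed(12)
  for (i in 1:8) {
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)          # ties likely
    labels <- sample(c("AFIB", "N"), n, TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("AFIB", "N")
    rc <- roc_curve(scores, labels)
    expect_equal(rc$tpr[1], 0); expect_equal(rc$fpr[1], 0)
    expect_equal(rc$tpr[nrow(rc)], 1); expect_equal(rc$fpr[nrow(rc)], 1)
    expect_true(all(diff(rc$tpr) >= 0))
    expect_true(all(diff(rc$fpr) >= 0))
    expect_equal(attr(rc, "auc"), mw_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC special cases: separation, reversal, degenerate labels", {
  rc <- roc_curve(c(.9, .8, .3, .2), c("AFIB", "AFIB", "N", "N"))
  expect_equal(attr(rc, "auc"), 1)
  # alternating labels on a score grid: AUC equals the exhaustive pair count
  s <- seq(0, 1, length.out = 8)
  l <- rep(c("AFIB", "N"), 4)
  expect_equal(attr(roc_curve(s, l), "auc"), mw_auc(s, l))
  # reversing scores maps AUC -> 1 - AUC
  set.seed(5)
  s <- runif(30); l <- sample(c("AFIB", "N"), 30, TRUE)
  expect_equal(attr(roc_curve(1 - s, l), "auc"),
               1 - attr(roc_curve(s, l), "auc"), tolerance = 1e-12)
  expect_true(is.na(attr(roc_curve(s, rep("AFIB", 30)), "auc")))
})

test_that("trapezoid AUC agrees with an established external implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- runif(80)
  l <- ifelse(runif(80) < plogis(4 * (s - 0.5)), "AFIB", "N")
  ours <- attr(roc_curve(s, l), "auc")
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = factor(l, levels = c("N", "AFIB")), predictor = s,
    quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("operating point sits on the curve at threshold 0.5", {
  set.seed(2)
  s <- runif(40); l <- sample(c("AFIB", "N"), 40, TRUE)
  rc <- roc_curve(s, l)
  op <- attr(rc, "operating_point")
  expect_equal(unname(op["tpr"]), sum(s[l == "AFIB"] >= 0.5) / sum(l == "AFIB"))
  expect_equal(unname(op["fpr"]), sum(s[l == "N"] >= 0.5) / sum(l == "N"))
})
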