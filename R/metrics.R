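#' Confusion counts for binary rhythm classification
#'
#' Tallies true/false positives and negatives with AFIB as the positive
#' class.
#'
#' @param labels True labels (`"AFIB"` / `"N"`).
#' @param predictions Predicted labels, same length and coding.
#' @param positive Positive class (default `"AFIB"`).
#' @return An object of class `confusion_counts`: list with integer `TP`,
#'   `FN`, `FP`, `TN`.
#' @export
#' @examples
#' confusion(c("AFIB", "AFIB", "N"), c("AFIB", "N", "N"))
confusion <- function(labels, predictions, positive = "AFIB") {
  if (length(labels) != length(predictions)) {
    abort("labels and predictions must have equal length",
          class = "ecgbispec_length_mismatch")
  }
  lab_pos <- as.character(labels) == positive
  pred_pos <- as.character(predictions) == positive
  structure(list(
    TP = sum(lab_pos & pred_pos),
    FN = sum(lab_pos & !pred_pos),
    FP = sum(!lab_pos & pred_pos),
    TN = sum(!lab_pos & !pred_pos)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("true AFIB", "true N"),
                              c("pred AFIB", "pred N")))
  print(m)
  invisible(x)
}

safe_ratio <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_

#' Diagnostic-test report for AFIB classification
#'
#' Computes the standard binary diagnostic measures with AFIB as the
#' positive class: sensitivity (TPR), specificity (TNR), positive and
#' negative predictive values (PPV, NPV), prevalence (PV), accuracy (ACC,
#' both as a count ratio and in the prevalence-weighted form
#' `sens * PV + spec * (1 - PV)`), the likelihood ratios
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`, and F-scores.
#'
#' `F1_AFIB` is the harmonic mean of PPV and sensitivity.  With
#' `f1_n = "npv_tpr"` (the default), `F1_N` is the harmonic mean of NPV and
#' the AFIB sensitivity; `f1_n = "per_class"` instead uses the conventional
#' N-class precision/recall pair (NPV and specificity).
#'
#' The report can be computed either from [confusion()] counts or directly
#' from rates (`sensitivity`, `specificity`, `ppv`, `npv`, `pv`), e.g. when
#' reproducing a published results table.  Undefined fields (zero
#' denominators) are returned as `NA` with a warning.
#'
#' @param counts A `confusion_counts`, or `NULL` when rates are supplied.
#' @param sensitivity,specificity,ppv,npv,pv Rates in \[0, 1\] (used when
#'   `counts` is `NULL`; any subset may be given, derived fields require the
#'   rates entering their formulas).
#' @param scores,labels Optional classifier scores and true labels; when
#'   both are supplied the AUC of the ROC curve is included.
#' @param f1_n `"npv_tpr"` or `"per_class"` (see Details).
#' @return A one-row tibble of class `metrics_report`.
#' @export
#' @examples
#' metrics_report(sensitivity = 0.953, specificity = 0.937)
metrics_report <- function(counts = NULL, sensitivity = NULL,
                           specificity = NULL, ppv = NULL, npv = NULL,
                           pv = NULL, scores = NULL, labels = NULL,
                           f1_n = c("npv_tpr", "per_class")) {
  f1_n <- match.arg(f1_n)
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "confusion_counts"))
    TP <- counts$TP; FN <- counts$FN; FP <- counts$FP; TN <- counts$TN
    total <- TP + FN + FP + TN
    if (total <= 0) abort("empty confusion counts",
                          class = "ecgbispec_invalid_parameter")
    sensitivity <- safe_ratio(TP, TP + FN)
    specificity <- safe_ratio(TN, TN + FP)
    ppv <- safe_ratio(TP, TP + FP)
    npv <- safe_ratio(TN, TN + FN)
    pv <- (TP + FN) / total
    acc <- (TP + TN) / total
    acc_prev <- sensitivity * pv + specificity * (1 - pv)
    if (is.finite(acc_prev) && abs(acc - acc_prev) > 1e-12) {
      abort("internal accuracy cross-check failed")   # cannot happen
    }
  } else {
    acc <- if (!is.null(sensitivity) && !is.null(specificity) &&
               !is.null(pv)) {
      sensitivity * pv + specificity * (1 - pv)
    } else NA_real_
  }
  sens <- sensitivity %||% NA_real_
  spec <- specificity %||% NA_real_
  # a zero denominator with a positive numerator is an infinite ratio (e.g.
  # perfect specificity); 0/0 alone is undefined
  lratio <- function(num, den) {
    if (den > 0) num / den else if (num > 0) Inf else NA_real_
  }
  lr_plus <- if (!is.na(sens) && !is.na(spec)) {
    lratio(sens, 1 - spec)
  } else NA_real_
  lr_minus <- if (!is.na(sens) && !is.na(spec)) {
    lratio(1 - sens, spec)
  } else NA_real_
  harm <- function(a, b) {
    if (is.null(a) || is.null(b) || is.na(a) || is.na(b)) return(NA_real_)
    if (a + b <= 0) return(NA_real_)
    2 * a * b / (a + b)
  }
  f1_afib <- harm(ppv, sens)
  f1_nval <- if (f1_n == "npv_tpr") harm(npv, sens) else harm(npv, spec)
  auc <- NA_real_
  if (!is.null(scores) && !is.null(labels)) {
    auc <- attr(roc_curve(scores, labels), "auc")
  }
  out <- tibble(
    sensitivity = sens, specificity = spec,
    ppv = ppv %||% NA_real_, npv = npv %||% NA_real_,
    pv = pv %||% NA_real_, acc = acc,
    lr_plus = lr_plus, lr_minus = lr_minus,
    f1_afib = f1_afib, f1_n = f1_nval, auc = auc
  )
  # zero denominators are flagged, never silent; absent rate inputs are not
  from_counts <- !is.null(counts)
  undefined <- c(
    if (from_counts && anyNA(out[, c("sensitivity", "specificity",
                                     "ppv", "npv")])) "rates",
    if (!is.na(sens) && !is.na(spec) &&
        (is.na(lr_plus) || is.na(lr_minus))) "likelihood ratios"
  )
  if (length(undefined)) {
    warn(paste("undefined measure(s) due to zero denominators:",
               paste(undefined, collapse = ", ")))
  }
  class(out) <- c("metrics_report", class(out))
  out
}

#' Round a metrics report for presentation
#'
#' Half-up rounding to a fixed number of decimals, the convention of results
#' tables (so 15.1265 prints as 15.127); raw values are kept in the
#' unrounded report.
#'
#' @param report A `metrics_report` (or any numeric data frame).
#' @param digits Decimals (default 3).
#' @return The rounded tibble.
#' @export
round_report <- function(report, digits = 3) {
  round_half_up <- function(x) {
    ifelse(is.na(x), x,
           sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits)
  }
  dplyr::mutate(as_tibble(report),
                across(dplyr::where(is.numeric), round_half_up))
}

#' ROC curve and AUC for AFIB scores
#'
#' Sweeps the decision threshold over the unique scores (predicting AFIB
#' when `score >= threshold`; tied scores enter together), computes the
#' (FPR, TPR) pairs, and integrates the area under the curve by the
#' trapezoidal rule.  The operating point at threshold 0.5 is recorded.
#'
#' @param scores AFIB scores in \[0, 1\].
#' @param labels True labels (`"AFIB"` / `"N"`).
#' @param positive Positive class (default `"AFIB"`).
#' @return A tibble of class `roc_curve` with columns `threshold`, `tpr`,
#'   `fpr`, and attributes `auc` and `operating_point` (named vector `fpr`,
#'   `tpr` at threshold 0.5).  AUC is `NA` when only one class is present.
#' @export
#' @examples
#' rc <- roc_curve(c(.9, .8, .3, .2), c("AFIB", "AFIB", "N", "N"))
#' attr(rc, "auc")  # 1
roc_curve <- function(scores, labels, positive = "AFIB") {
  if (length(scores) != length(labels)) {
    abort("scores and labels must have equal length",
          class = "ecgbispec_length_mismatch")
  }
  pos <- as.character(labels) == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) if (n_pos) sum(scores[pos] >= t) / n_pos
                else NA_real_, numeric(1))
  fpr <- vapply(thr, function(t) if (n_neg) sum(scores[!pos] >= t) / n_neg
                else NA_real_, numeric(1))
  auc <- if (n_pos > 0 && n_neg > 0) {
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  } else NA_real_
  op <- c(fpr = if (n_neg) sum(scores[!pos] >= 0.5) / n_neg else NA_real_,
          tpr = if (n_pos) sum(scores[pos] >= 0.5) / n_pos else NA_real_)
  out <- tibble(threshold = thr, tpr = tpr, fpr = fpr)
  attr(out, "auc") <- auc
  attr(out, "operating_point") <- op
  class(out) <- c("roc_curve", class(out))
  out
}

#' @describeIn roc_curve ROC plot with the threshold-0.5 operating point.
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @export
autoplot.roc_curve <- function(object, ...) {
  op <- attr(object, "operating_point")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = op["fpr"], y = op["tpr"], colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC, AUC = %.3f", attr(object, "auc"))
    )
}
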