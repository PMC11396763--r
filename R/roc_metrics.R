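# Round half up to integer percent, matching clinical reporting precision.
round_half_up <- function(x) floor(x + 0.5)

#' ROC curve and AUC from subject scores
#'
#' Sweeps the classification threshold over the unique score values (a
#' subject is called target when its score is strictly greater than the
#' threshold; `-Inf` is prepended so the all-target operating point is
#' included). The AUC is computed by pair counting: the fraction of
#' (target, reference) score pairs ranked correctly, ties contributing 1/2 —
#' identical to the trapezoidal area under the swept curve.
#'
#' @param scores numeric subject scores (higher = more target-like).
#' @param labels `"reference"`/`"target"` per subject; both must occur.
#' @return An object of class `roc_report`: list with `points` (data frame:
#'   `threshold`, `sensitivity`, `specificity` as proportions), `auc`,
#'   `scores`, `labels`, `n_target`, `n_reference`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  is_t <- labels == "target"
  n_t <- sum(is_t); n_r <- sum(!is_t)
  if (n_t == 0L || n_r == 0L)
    stop("both classes must be present for ROC analysis")
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) sum(scores[is_t] > t) / n_t, 0)
  spec <- vapply(thr, function(t) sum(scores[!is_t] <= t) / n_r, 0)
  cmp <- outer(scores[is_t], scores[!is_t], `-`)
  auc <- (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (n_t * n_r)
  structure(list(points = data.frame(threshold = thr, sensitivity = sens,
                                     specificity = spec),
                 auc = auc, scores = scores, labels = labels,
                 n_target = n_t, n_reference = n_r),
            class = "roc_report")
}

#' Youden-optimal classification threshold
#'
#' Maximises Youden's J = sensitivity + specificity - 1 over the swept
#' operating points. Ties are broken toward higher specificity, then higher
#' threshold (prioritising a confident call of the target phenotype); the
#' full co-optimal set is returned alongside, since real score sets can
#' admit several optimal settings. A maximum J of 0 (uninformative scores)
#' is flagged degenerate.
#'
#' @param roc a [roc_curve()] result.
#' @return List with `threshold`, `sensitivity`, `specificity` (proportions
#'   at the chosen cut), `j`, `cooptimal` (data frame of all J-maximising
#'   points) and `degenerate`.
#' @export
youden_threshold <- function(roc) {
  pts <- roc$points
  if (nrow(pts) < 1L) stop("ROC has no operating points")
  j <- pts$sensitivity + pts$specificity - 1
  jmax <- max(j)
  co <- pts[abs(j - jmax) < 1e-12, , drop = FALSE]
  co <- co[order(-co$specificity, -co$threshold), , drop = FALSE]
  best <- co[1L, ]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity, j = jmax,
       cooptimal = co, degenerate = jmax <= 1e-12)
}

#' Classify subjects by score threshold
#'
#' A subject is called `"target"` when its score is strictly greater than
#' the threshold; a score exactly at the threshold is called `"reference"`.
#'
#' @param scores numeric scores.
#' @param threshold finite cut-point.
#' @return Character vector of `"reference"`/`"target"` calls.
#' @export
classify <- function(scores, threshold) {
  if (!is.finite(threshold) && !identical(threshold, -Inf))
    stop("threshold must be finite (or -Inf)")
  ifelse(scores > threshold, "target", "reference")
}

# TP/FP/TN/FN of predicted vs true labels ("target" = positive).
confusion_counts <- function(predicted, truth) {
  c(tp = sum(predicted == "target" & truth == "target"),
    fp = sum(predicted == "target" & truth == "reference"),
    tn = sum(predicted == "reference" & truth == "reference"),
    fn = sum(predicted == "reference" & truth == "target"))
}

#' Positive and negative predictive values from a confusion matrix
#'
#' PPV = 100 TP/(TP+FP), NPV = 100 TN/(TN+FN), rounded half-up to integer
#' percentages. An empty denominator yields `NA` with the corresponding
#' `*_defined` flag unset — never 0.
#'
#' @param tp,fp,tn,fn non-negative confusion-matrix counts.
#' @return List with `ppv`, `npv` (integer percentages or `NA`) and
#'   `ppv_defined`, `npv_defined`.
#' @export
predictive_values <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("confusion-matrix counts must be non-negative")
  ppv_def <- (tp + fp) > 0
  npv_def <- (tn + fn) > 0
  list(ppv = if (ppv_def) round_half_up(100 * tp / (tp + fp)) else NA_real_,
       npv = if (npv_def) round_half_up(100 * tn / (tn + fn)) else NA_real_,
       ppv_defined = ppv_def, npv_defined = npv_def)
}

#' Full ROC report at the Youden-optimal operating point
#'
#' Combines [roc_curve()], [youden_threshold()], [classify()] and
#' [predictive_values()] into the standard per-modality classification
#' summary: AUC, threshold, and integer-percent sensitivity, specificity,
#' PPV and NPV with the confusion matrix they derive from.
#'
#' @inheritParams roc_curve
#' @return An object of class `roc_metrics`: list with `auc`, `threshold`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (percentages), `confusion`
#'   (named TP/FP/TN/FN vector), `degenerate`, `cooptimal`, and the
#'   underlying `roc`.
#' @export
roc_metrics <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  yd <- youden_threshold(roc)
  pred <- classify(scores, yd$threshold)
  conf <- confusion_counts(pred, roc$labels)
  pv <- predictive_values(conf[["tp"]], conf[["fp"]], conf[["tn"]],
                          conf[["fn"]])
  structure(list(auc = roc$auc, threshold = yd$threshold,
                 sensitivity = round_half_up(100 * yd$sensitivity),
                 specificity = round_half_up(100 * yd$specificity),
                 ppv = pv$ppv, npv = pv$npv,
                 confusion = conf, degenerate = yd$degenerate,
                 cooptimal = yd$cooptimal, roc = roc),
            class = "roc_metrics")
}

#' @export
print.roc_metrics <- function(x, ...) {
  cat(sprintf(paste0("ROC: AUC %.2f, Youden threshold %.3g -> sens %d%%, ",
                     "spec %d%%, PPV %s%%, NPV %s%%\n"),
              x$auc, x$threshold, x$sensitivity, x$specificity,
              format(x$ppv), format(x$npv)))
  invisible(x)
}

#' Two-modality concordance classification
#'
#' Restricts attention to subjects for whom two modality-specific patterns
#' predict the same phenotype; discordant subjects receive no call.
#' Sensitivity, specificity, PPV and NPV are computed within the concordant
#' subset only.
#'
#' @param pred_a,pred_b `"reference"`/`"target"` calls from two modalities,
#'   same subjects in the same order.
#' @param true_labels true group label per subject.
#' @param subject_ids optional identifiers.
#' @return An object of class `concordance_report`: list with
#'   `concordant_ids`, `concordance_percent`, `n`, `confusion` (within the
#'   concordant subset), `metrics_within_concordant` (sensitivity,
#'   specificity, ppv, npv as integer percentages or `NA`), `calls` (per
#'   subject data frame) and `empty_subset`.
#' @export
concordance_combine <- function(pred_a, pred_b, true_labels,
                                subject_ids = NULL) {
  n <- length(pred_a)
  if (length(pred_b) != n || length(true_labels) != n)
    stop("prediction and label vectors must have equal length")
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(n))
  agree <- pred_a == pred_b
  calls <- data.frame(subject_id = subject_ids, truth = true_labels,
                      call_a = pred_a, call_b = pred_b, concordant = agree,
                      final_call = ifelse(agree, pred_a, "no call"),
                      stringsAsFactors = FALSE)
  pct <- 100 * sum(agree) / n
  if (!any(agree)) {
    return(structure(list(concordant_ids = character(0),
                          concordance_percent = pct, n = n,
                          confusion = c(tp = 0L, fp = 0L, tn = 0L, fn = 0L),
                          metrics_within_concordant = NULL,
                          calls = calls, empty_subset = TRUE),
                     class = "concordance_report"))
  }
  conf <- confusion_counts(pred_a[agree], true_labels[agree])
  pv <- predictive_values(conf[["tp"]], conf[["fp"]], conf[["tn"]],
                          conf[["fn"]])
  sens <- if (conf[["tp"]] + conf[["fn"]] > 0)
    round_half_up(100 * conf[["tp"]] / (conf[["tp"]] + conf[["fn"]]))
  else NA_real_
  spec <- if (conf[["tn"]] + conf[["fp"]] > 0)
    round_half_up(100 * conf[["tn"]] / (conf[["tn"]] + conf[["fp"]]))
  else NA_real_
  structure(list(concordant_ids = subject_ids[agree],
                 concordance_percent = pct, n = n, confusion = conf,
                 metrics_within_concordant = list(sensitivity = sens,
                                                  specificity = spec,
                                                  ppv = pv$ppv, npv = pv$npv),
                 calls = calls, empty_subset = FALSE),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance: %.0f%% of %d subjects (%d concordant)\n",
              x$concordance_percent, x$n, length(x$concordant_ids)))
  if (!x$empty_subset) {
    m <- x$metrics_within_concordant
    cat(sprintf("  within concordant: sens %s%%, spec %s%%, PPV %s%%, NPV %s%%\n",
                format(m$sensitivity), format(m$specificity),
                format(m$ppv), format(m$npv)))
  }
  invisible(x)
}
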