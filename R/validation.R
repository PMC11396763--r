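# One-sided rank-sum p-value (target > reference), robust to heavy ties.
ranksum_p_greater <- function(target, reference) {
  if (length(target) == 0L || length(reference) == 0L)
    stop("rank-sum comparison needs non-empty score lists")
  s <- stats::sd(c(target, reference))
  if (!is.finite(s) || s == 0) return(1)
  suppressWarnings(
    stats::wilcox.test(target, reference, alternative = "greater")$p.value)
}

# Stratified bootstrap draw: resample with replacement within each group,
# preserving the original per-group counts.
resample_within_groups <- function(ref_idx, tgt_idx) {
  c(sample(ref_idx, length(ref_idx), replace = TRUE),
    sample(tgt_idx, length(tgt_idx), replace = TRUE))
}

#' Bootstrap stability of the pattern derivation
#'
#' Resamples subjects with replacement within each group (preserving the
#' training composition), re-runs the full derivation (GMP, PCA, retention,
#' stepwise combination, pattern) on each resample, and counts a repetition
#' as a success when the derivation completes with a non-empty selection and
#' the in-resample subject scores separate the groups (one-sided rank-sum
#' `p < alpha`, target above reference). When the original training set
#' yields a pattern, each successful repetition also records the cosine
#' between its pattern and the original.
#'
#' Note that the in-resample separation check inherits the optimism of
#' stepwise selection, so success rates well above the nominal level are
#' expected even on null data; the held-out LOOCV criterion ([loocv()]) is
#' the calibrated test.
#'
#' @param pm training `profile_matrix` with group labels.
#' @param B number of bootstrap repetitions (>= 1).
#' @param alpha separation level.
#' @param seed RNG seed for the resampling stream.
#' @param ... passed to [derive_pattern()].
#' @return An object of class `bootstrap_report`: list with `n_repetitions`,
#'   `success_percent`, and `per_repetition` (data frame: `success`,
#'   `cosine`).
#' @export
bootstrap_stability <- function(pm, B = 1000L, alpha = 0.05, seed = 1L, ...) {
  if (B < 1L) stop("B must be >= 1")
  grp <- pm$group
  ref <- which(grp == "reference")
  tgt <- which(grp == "target")
  if (length(ref) < 2L || length(tgt) < 2L)
    stop("need at least 2 subjects per group")
  original <- derive_pattern(pm, ...)
  set.seed(seed)
  success <- logical(B)
  cosine <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- resample_within_groups(ref, tgt)
    fit <- tryCatch(derive_pattern(subset_rows(pm, idx), ...),
                    error = function(e) NULL)
    if (is.null(fit) || fit$empty) next
    z <- project_score(pm$x[idx, , drop = FALSE], fit$gmp, fit$pattern,
                       type = "raw")
    p <- ranksum_p_greater(z[grp[idx] == "target"], z[grp[idx] == "reference"])
    success[b] <- p < alpha
    if (success[b] && !original$empty)
      cosine[b] <- pattern_truth_cosine(fit$pattern,
                                        original$pattern$pattern)
  }
  structure(list(n_repetitions = B,
                 success_percent = 100 * mean(success),
                 per_repetition = data.frame(success = success,
                                             cosine = cosine)),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("bootstrap stability: %.1f%% success over %d repetitions\n",
              x$success_percent, x$n_repetitions))
  invisible(x)
}

#' Leave-one-out cross-validation of the pattern derivation
#'
#' For each training subject in turn, the whole derivation (grand mean
#' profile from the remaining reference subjects, PCA, retention, stepwise
#' combination, pattern, reference standardisation) is re-run on the other
#' subjects and the held-out subject is scored by projection onto that
#' fold's pattern, z-scored against the fold's reference training scores.
#' The held-out subject therefore never influences any stage of the fold's
#' derivation. The pattern is "sustained" when the one-sided rank-sum test
#' (target above reference) on the cross-validated scores is significant at
#' `alpha`. A fold with an empty selection contributes a score of 0 and
#' marks the report degraded.
#'
#' @param pm training `profile_matrix` with group labels (>= 3 per group).
#' @param alpha significance level for the group comparison.
#' @param ... passed to [derive_pattern()].
#' @return An object of class `loocv_report`: list with `cv_scores` (named,
#'   one per training subject), `group`, `p_value`, `sustained`,
#'   `degraded_folds` (indices of empty-selection folds).
#' @export
loocv <- function(pm, alpha = 0.05, ...) {
  grp <- pm$group
  n <- nrow(pm$x)
  if (min(table(grp)) < 3L)
    stop("LOOCV needs at least 3 subjects per group (got ",
         paste(table(grp), collapse = "/"), ")")
  cv_scores <- numeric(n)
  degraded <- integer(0)
  for (i in seq_len(n)) {
    fit <- derive_pattern(subset_rows(pm, -i), ...)
    if (fit$empty) {
      cv_scores[i] <- 0
      degraded <- c(degraded, i)
    } else {
      cv_scores[i] <- project_score(pm$x[i, ], fit$gmp, fit$pattern,
                                    type = "z")
    }
  }
  names(cv_scores) <- pm$subject_id
  p <- ranksum_p_greater(cv_scores[grp == "target"],
                         cv_scores[grp == "reference"])
  structure(list(cv_scores = cv_scores, group = grp, p_value = p,
                 sustained = p < alpha, alpha = alpha,
                 degraded_folds = degraded),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("LOOCV: %ssustained (one-sided rank-sum p = %.4g, alpha = %g)%s\n",
              if (x$sustained) "" else "not ", x$p_value, x$alpha,
              if (length(x$degraded_folds))
                sprintf("; %d degraded fold(s)", length(x$degraded_folds))
              else ""))
  invisible(x)
}

#' Group test of validation-set pattern expression
#'
#' Tests whether held-out validation subjects express the pattern more
#' strongly than the reference-group training subjects (one-sided rank-sum).
#' A significant result indicates the validation subjects' profiles resemble
#' the target phenotype.
#'
#' @param validation_scores scores of the held-out cohort.
#' @param reference_training_scores scores of the reference training group.
#' @param alpha significance level.
#' @return List with `p_value` and `decision` (`p < alpha`).
#' @export
validation_group_test <- function(validation_scores,
                                  reference_training_scores, alpha = 0.05) {
  p <- ranksum_p_greater(validation_scores, reference_training_scores)
  list(p_value = p, decision = p < alpha)
}
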