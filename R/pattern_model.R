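#' Stepwise-forward logistic combination of principal component scores
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' component whose inclusion most improves the entry criterion — the largest
#' AIC decrease (`"aic"`, default) or the smallest likelihood-ratio p-value
#' below `alpha_enter` (`"lrt_p"`) — and stops when no remaining candidate
#' improves it. An empty selection is a legal outcome (no component
#' discriminates the groups). If the step just taken achieves complete
#' separation of the groups, the candidate is kept, selection stops and
#' `separation` is flagged: the maximum-likelihood coefficients diverge, so
#' the finite values from the fitter's last iteration are returned and only
#' score thresholds (not probabilities) should be interpreted downstream.
#'
#' @param scores numeric matrix, subjects x candidate components.
#' @param labels group label per subject (`"reference"`/`"target"`, or any
#'   two-level factor with the target level last).
#' @param criterion `"aic"` or `"lrt_p"`.
#' @param alpha_enter entry significance level for `"lrt_p"`.
#' @return List with `selected` (column indices in entry order),
#'   `coefficients` (intercept + one slope per selected component) and
#'   `separation` (logical).
#' @export
stepwise_logistic <- function(scores, labels, criterion = c("aic", "lrt_p"),
                              alpha_enter = 0.05) {
  criterion <- match.arg(criterion)
  scores <- as.matrix(scores)
  y <- as.integer(factor(labels)) - 1L
  if (length(unique(y)) != 2L) stop("labels must contain two groups")
  if (min(table(y)) < 2L) stop("need at least 2 subjects per group")
  if (ncol(scores) < 1L) stop("need at least 1 candidate component")

  fit_glm <- function(cols) {
    sep <- FALSE
    dat <- data.frame(y = y)
    fml <- "y ~ 1"
    if (length(cols)) {
      dat <- cbind(dat, as.data.frame(scores[, cols, drop = FALSE]))
      names(dat)[-1] <- paste0("c", cols)
      fml <- paste("y ~", paste(names(dat)[-1], collapse = " + "))
    }
    fit <- withCallingHandlers(
      stats::glm(stats::as.formula(fml), family = stats::binomial(),
                 data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w)))
          sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    # complete separation also shows as fitted values pinned to the labels
    if (length(cols)) {
      p_hat <- stats::fitted(fit)
      if (max(p_hat[y == 0]) < 1e-6 && min(p_hat[y == 1]) > 1 - 1e-6)
        sep <- TRUE
    }
    list(fit = fit, separation = sep)
  }

  selected <- integer(0)
  current <- fit_glm(selected)
  repeat {
    remaining <- setdiff(seq_len(ncol(scores)), selected)
    if (!length(remaining)) break
    trials <- lapply(remaining, function(j) fit_glm(c(selected, j)))
    if (criterion == "aic") {
      aics <- vapply(trials, function(t) stats::AIC(t$fit), 0)
      best <- which.min(aics)
      if (aics[best] >= stats::AIC(current$fit) - 1e-12) break
    } else {
      pvals <- vapply(trials, function(t) {
        dev_drop <- stats::deviance(current$fit) - stats::deviance(t$fit)
        stats::pchisq(max(dev_drop, 0), df = 1, lower.tail = FALSE)
      }, 0)
      best <- which.min(pvals)
      if (pvals[best] >= alpha_enter) break
    }
    selected <- c(selected, remaining[best])
    current <- trials[[best]]
    if (current$separation) break
  }
  list(selected = selected,
       coefficients = stats::coef(current$fit),
       separation = current$separation)
}

#' Combine selected components into the differentiating pattern
#'
#' The pattern is the logistic-slope-weighted sum of the selected voxel-space
#' components, rescaled to unit Euclidean norm so projected subject scores
#' are comparable across derivations; its total VAF is the sum of the
#' selected components' VAF. Reference-group score statistics (for
#' z-scoring) are attached later by [fit_reference_stats()].
#'
#' @param pca an [run_pca()] result.
#' @param selected indices of the components entering the pattern.
#' @param coefficients logistic coefficients: either the full vector from
#'   [stepwise_logistic()] (intercept first) or one slope per selected
#'   component.
#' @param separation logical flag carried from selection.
#' @return An object of class `diff_pattern`: list with `pattern` (unit-norm
#'   vector over in-mask voxels), `selected`, `coefficients`, `total_vaf`,
#'   `ref_mean`, `ref_sd`, `threshold` (the latter three `NA` until set),
#'   `separation`, `voxel_index`, `grid`.
#' @export
combine_pattern <- function(pca, selected, coefficients, separation = FALSE) {
  if (length(selected) == 0L)
    stop("empty component selection: no differentiating pattern can be ",
         "formed (report the modality as non-discriminating)")
  slopes <- if (length(coefficients) == length(selected) + 1L)
    coefficients[-1L] else coefficients
  if (length(slopes) != length(selected))
    stop("coefficients do not align with selected components")
  raw <- pca$components[, selected, drop = FALSE] %*% as.numeric(slopes)
  nrm <- sqrt(sum(raw^2))
  if (nrm == 0) stop("zero-weight combination: pattern undefined")
  structure(list(pattern = as.numeric(raw / nrm),
                 selected = selected,
                 coefficients = coefficients,
                 total_vaf = sum(pca$vaf[selected]),
                 ref_mean = NA_real_, ref_sd = NA_real_,
                 threshold = NA_real_,
                 separation = separation,
                 voxel_index = pca$voxel_index,
                 grid = pca$grid),
            class = "diff_pattern")
}

#' @export
print.diff_pattern <- function(x, ...) {
  cat(sprintf(paste0("differentiating pattern: %d component(s) [%s], ",
                     "total VAF %.1f%%%s\n"),
              length(x$selected), paste(x$selected, collapse = ", "),
              x$total_vaf,
              if (isTRUE(x$separation)) ", complete separation flagged" else ""))
  invisible(x)
}

#' Attach reference-group score statistics to a pattern
#'
#' Computes the raw projection scores of the reference-group training rows
#' and stores their mean and SD on the pattern, defining the z-score scale
#' (reference training group: mean 0, SD 1).
#'
#' @param pattern a [combine_pattern()] result.
#' @param pm the training `profile_matrix` (with group labels).
#' @param gmp the training [compute_gmp()] result.
#' @return The pattern with `ref_mean`/`ref_sd` set; `ref_sd = 0` is flagged
#'   degenerate via an attribute.
#' @export
fit_reference_stats <- function(pattern, pm, gmp) {
  ref <- which(pm$group == "reference")
  if (!length(ref)) stop("no reference subjects to standardise against")
  raw <- project_score(pm$x[ref, , drop = FALSE], gmp, pattern, type = "raw")
  pattern$ref_mean <- mean(raw)
  pattern$ref_sd <- stats::sd(raw)
  if (!is.finite(pattern$ref_sd) || pattern$ref_sd == 0) {
    attr(pattern, "degenerate_reference") <- TRUE
    pattern$ref_sd <- NA_real_
  }
  pattern
}

#' Project subjects onto a differentiating pattern
#'
#' The raw subject score (topographic profile rating) is the inner product
#' of the subject's residual profile (row minus GMP) with the unit-norm
#' pattern; the z-score standardises it against the reference training
#' group's raw-score distribution.
#'
#' @param rows numeric vector (one subject) or matrix (subjects x voxels) of
#'   profile values on the pattern's voxel set.
#' @param gmp a [compute_gmp()] result (or numeric vector).
#' @param pattern a [combine_pattern()] result.
#' @param type `"z"` (default; requires reference statistics set) or `"raw"`.
#' @return Numeric vector of scores.
#' @export
project_score <- function(rows, gmp, pattern, type = c("z", "raw")) {
  type <- match.arg(type)
  g <- if (inherits(gmp, "gmp_profile")) gmp$profile else as.numeric(gmp)
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (ncol(rows) != length(g) || length(g) != length(pattern$pattern))
    stop("subject row, GMP and pattern lengths do not match")
  raw <- as.numeric(sweep(rows, 2L, g, `-`) %*% pattern$pattern)
  if (type == "raw") return(raw)
  if (!is.finite(pattern$ref_mean) || !is.finite(pattern$ref_sd))
    stop("reference score statistics unset: call fit_reference_stats() ",
         "before requesting z-scores")
  (raw - pattern$ref_mean) / pattern$ref_sd
}

#' Derive a differentiating pattern from a training profile matrix
#'
#' Runs the full derivation chain on one training set: grand mean profile of
#' the reference group, residual profiles, subject-space PCA, VAF-based
#' candidate retention, stepwise-forward logistic combination, pattern
#' assembly and reference-score standardisation. This is the unit re-run by
#' bootstrap resampling and every LOOCV fold.
#'
#' @param pm training `profile_matrix` with `"reference"`/`"target"` labels.
#' @param vaf_threshold cumulative VAF (percent) retained as candidates.
#' @param criterion,alpha_enter passed to [stepwise_logistic()].
#' @param selection_rule passed to [select_components()].
#' @param gmp_group `"reference"` (default) for the reference-only grand
#'   mean, or `"pooled"` for the classic all-subject grand mean.
#' @param residual_subjects passed to [residual_profiles()].
#' @return An object of class `ssm_fit`: list with `gmp`, `pca`,
#'   `candidates`, `model` (stepwise result), `pattern` (a `diff_pattern`,
#'   or `NULL` when selection is empty) and `empty` (logical).
#' @export
derive_pattern <- function(pm, vaf_threshold = 50,
                           criterion = c("aic", "lrt_p"), alpha_enter = 0.05,
                           selection_rule = c("cumulative", "per_component"),
                           gmp_group = c("reference", "pooled"),
                           residual_subjects = "all") {
  criterion <- match.arg(criterion)
  selection_rule <- match.arg(selection_rule)
  gmp_group <- match.arg(gmp_group)
  gmp <- if (gmp_group == "pooled") {
    structure(list(profile = colMeans(pm$x), n_reference = nrow(pm$x)),
              class = "gmp_profile")
  } else compute_gmp(pm, group = "reference")
  res <- residual_profiles(pm, gmp, subjects = residual_subjects)
  pca <- run_pca(res)
  candidates <- select_components(pca, vaf_threshold, rule = selection_rule)
  model <- stepwise_logistic(pca$scores[, candidates, drop = FALSE],
                             res$group, criterion = criterion,
                             alpha_enter = alpha_enter)
  selected <- candidates[model$selected]
  if (length(selected) == 0L) {
    fit <- list(gmp = gmp, pca = pca, candidates = candidates, model = model,
                pattern = NULL, empty = TRUE)
  } else {
    pattern <- combine_pattern(pca, selected, model$coefficients,
                               separation = model$separation)
    pattern <- fit_reference_stats(pattern, pm, gmp)
    fit <- list(gmp = gmp, pca = pca, candidates = candidates, model = model,
                pattern = pattern, empty = FALSE)
  }
  class(fit) <- "ssm_fit"
  fit
}

#' @export
print.ssm_fit <- function(x, ...) {
  if (x$empty) {
    cat("SSM fit: no differentiating pattern (empty stepwise selection)\n")
  } else {
    cat("SSM fit:\n  ")
    print(x$pattern)
  }
  invisible(x)
}

#' Cosine similarity between a derived pattern and a ground-truth map
#'
#' Compares a fitted pattern with the phantom cohort's embedded truth over
#' the pattern's voxel set. Cosine similarity is scale-invariant, so the
#' truth's normalisation convention does not matter; the absolute value is
#' conventionally reported since the pattern's sign is fixed by the group
#' ordering, not by the truth.
#'
#' @param pattern a `diff_pattern`.
#' @param truth a 3-D array (e.g. `cohort$truth$pattern`) on the pattern's
#'   grid, or a vector already restricted to the pattern's voxels.
#' @return Signed cosine similarity in `[-1, 1]`.
#' @export
pattern_truth_cosine <- function(pattern, truth) {
  tv <- if (!is.null(dim(truth))) truth[pattern$voxel_index] else as.numeric(truth)
  if (length(tv) != length(pattern$pattern))
    stop("truth does not cover the pattern's voxel set")
  denom <- sqrt(sum(tv^2)) * sqrt(sum(pattern$pattern^2))
  if (denom == 0) return(NA_real_)
  sum(tv * pattern$pattern) / denom
}
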