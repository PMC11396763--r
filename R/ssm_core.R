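#' Grand mean profile of the reference group
#'
#' The grand mean profile (GMP) is the voxel-wise average of the
#' reference-group rows of a profile matrix. Subtracting it from every
#' subject yields the residual profiles that enter PCA.
#'
#' @param pm a `profile_matrix` (see [prepare_modality()]); if it carries
#'   group labels, only rows labelled `group` are averaged. A plain numeric
#'   matrix is treated as all-reference.
#' @param group label of the averaged group (default `"reference"`).
#' @return An object of class `gmp_profile`: list with `profile` (vector over
#'   in-mask voxels) and `n_reference`.
#' @export
compute_gmp <- function(pm, group = "reference") {
  if (is.matrix(pm)) pm <- list(x = pm, group = NULL)
  rows <- if (is.null(pm$group)) seq_len(nrow(pm$x)) else which(pm$group == group)
  if (length(rows) == 0L)
    stop("no rows labelled '", group, "' to average into a grand mean profile")
  structure(list(profile = colMeans(pm$x[rows, , drop = FALSE]),
                 n_reference = length(rows)),
            class = "gmp_profile")
}

#' Residual profiles: subject rows minus the grand mean profile
#'
#' By default the GMP is subtracted from every subject of both groups (the
#' reference rows then average to zero by construction); `subjects =
#' "target"` restricts the output to target-group rows for the literal
#' single-group reading.
#'
#' @param pm a `profile_matrix`.
#' @param gmp a [compute_gmp()] result (or numeric vector).
#' @param subjects `"all"` (default) or `"target"`.
#' @return An object of class `residual_matrix` with the same layout as a
#'   `profile_matrix`.
#' @export
residual_profiles <- function(pm, gmp, subjects = c("all", "target")) {
  subjects <- match.arg(subjects)
  g <- if (inherits(gmp, "gmp_profile")) gmp$profile else as.numeric(gmp)
  if (length(g) != ncol(pm$x))
    stop("GMP length (", length(g), ") does not match voxel count (",
         ncol(pm$x), ")")
  out <- pm
  if (subjects == "target") {
    if (is.null(pm$group)) stop("subjects = 'target' needs group labels")
    out <- subset_rows(out, pm$group == "target")
  }
  out$x <- sweep(out$x, 2L, g, `-`)
  class(out) <- c("residual_matrix", "profile_matrix")
  out
}

#' Principal component analysis of residual profiles
#'
#' Decomposes the residual matrix through subject space: the thin SVD of the
#' subjects x voxels matrix is computed (cost scales with subject count, not
#' voxel count) and the right singular vectors are the voxel-space principal
#' components. At most `n_subjects - 1` components are returned, ordered by
#' decreasing variance accounted for (VAF); components are unit-normalised
#' and mutually orthogonal, and subject scores are the projections of the
#' residual rows onto them.
#'
#' Sign convention: each component is oriented so the mean score of the
#' target group is at least that of the reference group (so a higher score
#' always means "more target-like"); without labels, or on an exact tie, the
#' first nonzero voxel loading is made positive.
#'
#' @param res a `residual_matrix` (see [residual_profiles()]).
#' @param tol relative singular-value tolerance below which trailing
#'   components are dropped as numerically null.
#' @return An object of class `ssm_pca`: list with `components` (voxels x k
#'   matrix, orthonormal columns), `scores` (subjects x k), `vaf`
#'   (percentages of total residual variance, summing to 100 over the full
#'   decomposition), `subject_id`, `group`, `voxel_index`, `grid`.
#' @export
run_pca <- function(res, tol = 1e-10) {
  x <- res$x
  if (nrow(x) < 2L) stop("PCA needs at least 2 subjects")
  if (ncol(x) < 2L) stop("PCA needs at least 2 voxels")
  total <- sum(x^2)
  if (total == 0) stop("all-zero residual matrix: no variance to decompose")
  n <- nrow(x)
  sv <- svd(x, nu = n, nv = min(n, ncol(x)))
  k <- min(n - 1L, sum(sv$d > tol * sv$d[1]))
  if (k < 1L) stop("residual matrix has no non-null component")
  d <- sv$d[seq_len(k)]
  components <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(d, k, k)
  vaf <- 100 * sv$d^2 / sum(sv$d^2)

  # orient: target mean score >= reference mean score, else first nonzero
  # loading positive
  grp <- res$group
  for (j in seq_len(k)) {
    flip <- FALSE
    if (!is.null(grp) && any(grp == "target") && any(grp == "reference")) {
      dm <- mean(scores[grp == "target", j]) - mean(scores[grp == "reference", j])
      if (dm < 0) flip <- TRUE
      else if (dm == 0) flip <- components[which(components[, j] != 0)[1], j] < 0
    } else {
      flip <- components[which(components[, j] != 0)[1], j] < 0
    }
    if (flip) {
      components[, j] <- -components[, j]
      scores[, j] <- -scores[, j]
    }
  }
  gram <- crossprod(components)
  if (max(abs(gram - diag(k))) > 1e-8)
    stop("internal error: components are not orthonormal")
  rownames(scores) <- res$subject_id
  structure(list(components = components, scores = scores,
                 vaf = vaf[seq_len(k)], subject_id = res$subject_id,
                 group = grp, voxel_index = res$voxel_index,
                 grid = res$grid),
            class = "ssm_pca")
}

#' @export
print.ssm_pca <- function(x, ...) {
  cat(sprintf("SSM/PCA decomposition: %d subjects, %d voxels, %d components\n",
              nrow(x$scores), nrow(x$components), ncol(x$components)))
  cat("VAF (%):", paste(sprintf("%.1f", utils::head(x$vaf, 8)),
                        collapse = " "),
      if (length(x$vaf) > 8) "...\n" else "\n")
  invisible(x)
}

#' Select principal components by variance accounted for
#'
#' Under the default `"cumulative"` rule, returns the smallest prefix of
#' components (in decreasing-VAF order) whose cumulative VAF reaches
#' `vaf_threshold` percent; these are the candidates offered to stepwise
#' logistic combination. The `"per_component"` rule instead keeps every
#' component whose own VAF reaches the threshold.
#'
#' @param pca an [run_pca()] result.
#' @param vaf_threshold percentage in (0, 100].
#' @param rule `"cumulative"` (default) or `"per_component"`.
#' @return Integer vector of component indices.
#' @export
select_components <- function(pca, vaf_threshold = 50,
                              rule = c("cumulative", "per_component")) {
  rule <- match.arg(rule)
  if (vaf_threshold <= 0 || vaf_threshold > 100)
    stop("vaf_threshold must lie in (0, 100]")
  vaf <- pca$vaf
  if (rule == "per_component") return(which(vaf >= vaf_threshold))
  cum <- cumsum(vaf)
  # full decomposition sums to 100; the retained prefix may total slightly
  # less when trailing numerically-null components were dropped
  k <- which(cum >= vaf_threshold - 1e-9)[1]
  if (is.na(k)) k <- length(vaf)
  seq_len(k)
}
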