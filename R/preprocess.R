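#' Build the whole-brain analysis mask from tissue-probability maps
#'
#' A voxel enters the mask when its combined grey + white matter probability
#' exceeds `tissue_threshold`. Under the default `"intersection"` rule the
#' condition must hold for every subject, guaranteeing that every cell of the
#' downstream data matrix is brain-supported for every subject; `"union"`
#' keeps voxels passing the threshold in at least one subject.
#'
#' @param gm_maps,wm_maps lists of 3-D arrays (one per subject) on a common
#'   grid; grey and white matter probability maps respectively.
#' @param tissue_threshold probability in `[0, 1)` that GM + WM must exceed.
#' @param rule `"intersection"` (default) or `"union"` across subjects.
#' @return An object of class `brain_mask`: list with `mask` (logical 3-D
#'   array), `n_voxels`, and `provenance` (rule and threshold used).
#' @export
build_brain_mask <- function(gm_maps, wm_maps, tissue_threshold = 0.1,
                             rule = c("intersection", "union")) {
  rule <- match.arg(rule)
  if (length(gm_maps) != length(wm_maps) || length(gm_maps) == 0L)
    stop("need matching, non-empty lists of GM and WM maps")
  if (tissue_threshold < 0 || tissue_threshold >= 1)
    stop("tissue_threshold must lie in [0, 1)")
  ref_dim <- dim(gm_maps[[1]])
  per_subject <- vector("list", length(gm_maps))
  for (i in seq_along(gm_maps)) {
    if (!identical(dim(gm_maps[[i]]), ref_dim) ||
        !identical(dim(wm_maps[[i]]), ref_dim))
      stop("tissue maps of subject ", i, " do not match the common grid ",
           paste(ref_dim, collapse = "x"))
    per_subject[[i]] <- (gm_maps[[i]] + wm_maps[[i]]) > tissue_threshold
  }
  mask <- Reduce(if (rule == "intersection") `&` else `|`, per_subject)
  n_voxels <- sum(mask)
  if (n_voxels == 0L)
    stop("empty brain mask (rule = ", rule,
         ", tissue_threshold = ", tissue_threshold, ")")
  structure(list(mask = mask, n_voxels = n_voxels,
                 provenance = list(rule = rule,
                                   tissue_threshold = tissue_threshold)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain mask: %d voxels (%s of GM+WM > %g)\n", x$n_voxels,
              x$provenance$rule, x$provenance$tissue_threshold))
  invisible(x)
}

#' Globally normalise an image by its in-mask mean
#'
#' Divides in-mask voxels by their mean, the standard treatment for contrasts
#' measured in arbitrary per-scan intensity units; out-of-mask voxels pass
#' through unchanged. The in-mask mean of the result is 1 by construction,
#' and the operation is idempotent and invariant to global rescaling of the
#' input.
#'
#' @param image 3-D array on the mask's grid.
#' @param mask a [build_brain_mask()] result.
#' @return The normalised image.
#' @export
global_normalise <- function(image, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (!identical(dim(image), dim(mask$mask)))
    stop("image grid does not match mask grid")
  m <- mean(image[mask$mask])
  if (!is.finite(m) || m <= 0)
    stop("non-positive in-mask mean (", format(m),
         "): wrong modality or corrupted data")
  image[mask$mask] <- image[mask$mask] / m
  image
}

#' Assemble the subjects-by-voxels data matrix for one modality
#'
#' Applies the selected per-image normalisation and optional natural-log
#' transform, then flattens the in-mask voxels of every image into one row of
#' a subjects x voxels matrix. Voxels are ordered by ascending linear index
#' in the image's native axis order, so row/column correspondence is stable
#' across any two matrices built with the same mask.
#'
#' @param images list of 3-D arrays, one per subject, on the mask's grid.
#' @param mask a [build_brain_mask()] result.
#' @param normalisation `"global_mean"` (divide each image by its in-mask
#'   mean, for globally scaled contrasts) or `"none"` (for intrinsically
#'   normalised maps).
#' @param log_transform apply `log()` to in-mask values after normalisation;
#'   requires all in-mask values positive.
#' @param subject_ids,groups optional per-subject identifiers and group
#'   labels (`"reference"`/`"target"`) carried on the result.
#' @return An object of class `profile_matrix`: list with `x` (numeric
#'   matrix, subjects x in-mask voxels), `voxel_index` (linear indices of the
#'   mask voxels), `grid` (image dimensions), `subject_id`, `group`.
#' @export
prepare_modality <- function(images, mask,
                             normalisation = c("global_mean", "none"),
                             log_transform = FALSE,
                             subject_ids = NULL, groups = NULL) {
  normalisation <- match.arg(normalisation)
  stopifnot(inherits(mask, "brain_mask"))
  n <- length(images)
  if (n == 0L) stop("no images supplied")
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(n))
  voxel_index <- which(mask$mask)
  x <- matrix(NA_real_, n, length(voxel_index),
              dimnames = list(subject_ids, NULL))
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (!identical(dim(img), dim(mask$mask)))
      stop("image of subject ", subject_ids[i], " does not match mask grid")
    if (normalisation == "global_mean") img <- global_normalise(img, mask)
    v <- img[voxel_index]
    if (log_transform) {
      bad <- sum(v <= 0)
      if (bad > 0)
        stop("log transform impossible for subject ", subject_ids[i], ": ",
             bad, " non-positive in-mask voxel(s)")
      v <- log(v)
    }
    x[i, ] <- v
  }
  structure(list(x = x, voxel_index = voxel_index, grid = dim(mask$mask),
                 subject_id = subject_ids, group = groups),
            class = "profile_matrix")
}

#' Extract one modality of a cohort as a profile matrix
#'
#' Convenience wrapper: builds rows from `cohort` for `modality`, keeping
#' subject ids and group labels.
#'
#' @param cohort a `phantom_cohort` (or any list with the same `subjects`
#'   layout, e.g. from [load_cohort()]).
#' @param modality modality name present in every subject's `images`.
#' @param mask a [build_brain_mask()] result.
#' @inheritParams prepare_modality
#' @param subset optional integer/logical index of subjects to keep.
#' @return A `profile_matrix`.
#' @export
cohort_matrix <- function(cohort, modality, mask,
                          normalisation = c("global_mean", "none"),
                          log_transform = FALSE, subset = NULL) {
  subjects <- cohort$subjects
  if (!is.null(subset)) subjects <- subjects[subset]
  imgs <- lapply(subjects, function(s) {
    if (is.null(s$images[[modality]]))
      stop("subject ", s$subject_id, " has no modality '", modality, "'")
    s$images[[modality]]
  })
  prepare_modality(imgs, mask, normalisation, log_transform,
                   subject_ids = vapply(subjects, `[[`, "", "subject_id"),
                   groups = vapply(subjects, `[[`, "", "group"))
}

# Row subset of a profile_matrix (or residual_matrix), keeping metadata.
subset_rows <- function(pm, idx) {
  pm$x <- pm$x[idx, , drop = FALSE]
  pm$subject_id <- pm$subject_id[idx]
  if (!is.null(pm$group)) pm$group <- pm$group[idx]
  pm
}
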