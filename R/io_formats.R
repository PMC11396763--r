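#' Read a 3-D volume from NIfTI
#'
#' @param path NIfTI-1/2 file.
#' @return 3-D numeric array with attribute `n_nonfinite` (count of
#'   non-finite voxels found).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI at ", path, ": ",
                                           conditionMessage(e)))
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "n_nonfinite") <- sum(!is.finite(arr))
  arr
}

#' Write a 3-D volume as NIfTI
#'
#' @param image 3-D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(image),
                                           dim = dim(image))),
                     path, datatype = "double")
  invisible(path)
}

#' Re-embed an in-mask vector into a full volume
#'
#' Places pattern/GMP values back at their mask voxels (0 elsewhere), e.g.
#' for export of a derived pattern as an image.
#'
#' @param values numeric vector over mask voxels.
#' @param voxel_index linear indices of those voxels.
#' @param grid full image dimensions.
#' @return 3-D array.
#' @export
embed_in_volume <- function(values, voxel_index, grid) {
  arr <- array(0, grid)
  arr[voxel_index] <- values
  arr
}

manifest_columns <- c("subject_id", "group", "modality", "image_path",
                      "gm_path", "wm_path")

#' Write a phantom cohort to disk
#'
#' Writes one NIfTI volume per subject and modality, the shared GM/WM
#' tissue maps, the ground-truth pattern (if present), and a tab-separated
#' cohort manifest (`manifest.tsv`) with columns `subject_id`, `group`,
#' `modality`, `image_path`, `gm_path`, `wm_path` (paths relative to `dir`).
#'
#' @param cohort a `phantom_cohort` (see [generate_cohort()]).
#' @param dir output directory (created if missing).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in cohort$subjects) {
    gm_rel <- file.path("tissue", paste0(s$subject_id, "_gm.nii.gz"))
    wm_rel <- file.path("tissue", paste0(s$subject_id, "_wm.nii.gz"))
    write_volume(s$gm, file.path(dir, gm_rel))
    write_volume(s$wm, file.path(dir, wm_rel))
    for (m in names(s$images)) {
      rel <- file.path(m, paste0(s$subject_id, "_", m, ".nii.gz"))
      write_volume(s$images[[m]], file.path(dir, rel))
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = s$subject_id, group = s$group, modality = m,
                   image_path = rel, gm_path = gm_rel, wm_path = wm_rel,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(cohort$truth$pattern))
    write_volume(cohort$truth$pattern, file.path(dir, "truth_pattern.nii.gz"))
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load and validate a cohort manifest
#'
#' Checks the column set, uniqueness of (subject, modality), admissible
#' group labels, existence of every referenced file, and that all referenced
#' volumes share one grid (mismatched grids are an error, not a warning:
#' resampling is out of scope).
#'
#' @param path tab-separated manifest with a header (see [write_cohort()]).
#' @return A data frame of class `cohort_manifest` with attribute `dir` (the
#'   manifest's directory, against which relative paths resolve).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_columns, names(man))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  dup <- duplicated(man[c("subject_id", "modality")])
  if (any(dup))
    stop("duplicate (subject, modality) rows: ",
         paste(unique(man$subject_id[dup]), collapse = ", "))
  bad_grp <- setdiff(unique(man$group), c("reference", "target"))
  if (length(bad_grp))
    stop("group labels must be reference/target; found: ",
         paste(bad_grp, collapse = ", "))
  dir <- dirname(path)
  files <- unique(file.path(dir, unlist(man[c("image_path", "gm_path",
                                              "wm_path")])))
  absent <- files[!file.exists(files)]
  if (length(absent))
    stop("manifest references missing file(s): ",
         paste(absent, collapse = ", "))
  dims <- unique(vapply(files, function(f) {
    paste(RNifti::niftiHeader(f)$dim[2:4], collapse = "x")
  }, ""))
  if (length(dims) > 1L)
    stop("inconsistent grids across cohort volumes: ",
         paste(dims, collapse = " vs "))
  structure(man, class = c("cohort_manifest", "data.frame"), dir = dir)
}

#' Load a cohort from a manifest
#'
#' Reads every referenced volume into the same in-memory structure
#' [generate_cohort()] emits (without ground truth), ready for
#' [run_study()].
#'
#' @param manifest a [load_manifest()] result, or a manifest path.
#' @return A `phantom_cohort`-shaped list (no `truth` component unless a
#'   `truth_pattern.nii.gz` sits beside the manifest).
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  dir <- attr(manifest, "dir")
  ids <- unique(manifest$subject_id)
  subjects <- lapply(ids, function(id) {
    rows <- manifest[manifest$subject_id == id, , drop = FALSE]
    images <- lapply(seq_len(nrow(rows)), function(r)
      read_volume(file.path(dir, rows$image_path[r])))
    names(images) <- rows$modality
    list(subject_id = id, group = rows$group[1], images = images,
         gm = read_volume(file.path(dir, rows$gm_path[1])),
         wm = read_volume(file.path(dir, rows$wm_path[1])))
  })
  truth_path <- file.path(dir, "truth_pattern.nii.gz")
  truth <- if (file.exists(truth_path))
    list(pattern = read_volume(truth_path)) else NULL
  structure(list(subjects = subjects, truth = truth, config = NULL),
            class = "phantom_cohort")
}
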