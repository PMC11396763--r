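# Shared fixture builders: all fixtures are generated in code at test time.

# Small, fast phantom configuration; override any field via ...
tiny_config <- function(...) {
  defaults <- list(grid_shape = c(16L, 16L, 16L),
                   modalities = c(qmap = "intrinsically_normalised"),
                   lesion_count_range = c(2L, 5L),
                   seed = 1L)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

# Cohort -> mask -> profile matrix for one modality, in one call.
phantom_pm <- function(cfg, modality = names(cfg$modalities)[1],
                       normalisation = "none") {
  cohort <- generate_cohort(cfg)
  mask <- build_brain_mask(lapply(cohort$subjects, `[[`, "gm"),
                           lapply(cohort$subjects, `[[`, "wm"))
  list(cohort = cohort, mask = mask,
       pm = cohort_matrix(cohort, modality, mask,
                          normalisation = normalisation))
}

# Wrap a plain matrix as a profile_matrix with optional group labels.
as_pm <- function(x, groups = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(x)))
  structure(list(x = x, voxel_index = seq_len(ncol(x)), grid = NULL,
                 subject_id = ids, group = groups),
            class = "profile_matrix")
}

# Labelled residual matrix with a planted group difference along `direction`.
planted_residuals <- function(n_ref, n_tgt, n_vox, effect = 0,
                              direction = NULL, sd = 1) {
  x <- matrix(stats::rnorm((n_ref + n_tgt) * n_vox, sd = sd),
              n_ref + n_tgt, n_vox)
  groups <- rep(c("reference", "target"), c(n_ref, n_tgt))
  if (effect != 0) {
    if (is.null(direction)) direction <- stats::rnorm(n_vox)
    direction <- direction / sqrt(sum(direction^2))
    x[groups == "target", ] <- x[groups == "target", ] +
      matrix(effect * direction, n_tgt, n_vox, byrow = TRUE)
  }
  pm <- as_pm(x, groups)
  res <- residual_profiles(pm, compute_gmp(pm))
  res
}
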