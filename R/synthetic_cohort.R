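#' Configuration for a synthetic brain-phantom cohort
#'
#' Defines the study conditions emulated by [generate_cohort()]: two groups of
#' subjects sharing one ellipsoidal "brain" (an inner white-matter core
#' surrounded by a grey-matter shell), a group-specific spatial pattern of
#' hypo-/hyper-intensities composed of Gaussian blobs, subject-level loading
#' variability, i.i.d. voxel noise, group-unrelated focal lesions, and one or
#' more imaging modalities drawn from two contrast families:
#' `"globally_scaled"` contrasts carry an arbitrary per-subject intensity
#' factor (as conventional weighted MRI does) and need global normalisation,
#' while `"intrinsically_normalised"` contrasts (ratio/quantitative maps) do
#' not.
#'
#' `effect_amplitude` and `noise_sd` share intensity units: the pattern used
#' to build images is scaled to root-mean-square 1 over its active region
#' (voxels above 10% of the peak magnitude), so `effect_amplitude` is the
#' typical per-voxel intensity shift inside the affected regions for
#' target-group subjects. The ground-truth pattern returned with the cohort
#' is the same spatial map rescaled to unit Euclidean norm.
#'
#' @param grid_shape integer triple, voxels per axis (each >= 8).
#' @param n_reference,n_target subjects per group.
#' @param effect_amplitude mean pattern loading of the target group (0 gives a
#'   null cohort); reference subjects have mean loading 0.
#' @param loading_sd standard deviation of the per-subject pattern loading
#'   (both groups).
#' @param noise_sd standard deviation of i.i.d. voxel noise added inside the
#'   brain support.
#' @param n_blobs number of 3-D Gaussian blobs composing the true pattern.
#' @param modalities named character vector mapping modality name to contrast
#'   family, each `"globally_scaled"` or `"intrinsically_normalised"`.
#' @param global_scale_sd SD of the per-subject multiplicative intensity
#'   factor (globally scaled modalities only; factor ~ Normal(1, sd)).
#' @param lesion_count_range integer range (min, max) of lesions per subject;
#'   `c(0, 0)` disables lesions.
#' @param lesion_amplitude absolute intensity perturbation of a lesion; each
#'   lesion is randomly hyper- or hypo-intense.
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   cohort bit for bit.
#' @return An object of class `phantom_config`.
#' @seealso [generate_cohort()]
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 32L),
                           n_reference = 15L,
                           n_target = 15L,
                           effect_amplitude = 0.5,
                           loading_sd = 0.15,
                           noise_sd = 0.1,
                           n_blobs = 6L,
                           modalities = c(qmap = "intrinsically_normalised",
                                          t1w = "globally_scaled"),
                           global_scale_sd = 0.08,
                           lesion_count_range = c(5L, 20L),
                           lesion_amplitude = 0.3,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(is.na(grid_shape)))
    stop("grid_shape must be an integer triple")
  if (any(grid_shape < 8L))
    stop("grid_shape axes must each be >= 8 (got ",
         paste(grid_shape, collapse = "x"), ")")
  if (n_reference < 0 || n_target < 0) stop("group sizes must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (loading_sd < 0) stop("loading_sd must be >= 0")
  if (n_blobs < 0) stop("n_blobs must be >= 0")
  if (length(modalities) < 1L || is.null(names(modalities)) ||
      any(!nzchar(names(modalities))))
    stop("modalities must be a named character vector")
  bad <- setdiff(unique(modalities),
                 c("globally_scaled", "intrinsically_normalised"))
  if (length(bad))
    stop("unknown modality kind: ", paste(bad, collapse = ", "))
  lesion_count_range <- as.integer(lesion_count_range)
  if (length(lesion_count_range) != 2L ||
      any(lesion_count_range < 0L) ||
      lesion_count_range[1] > lesion_count_range[2])
    stop("lesion_count_range must be a non-decreasing pair of counts >= 0")
  structure(list(grid_shape = grid_shape,
                 n_reference = as.integer(n_reference),
                 n_target = as.integer(n_target),
                 effect_amplitude = effect_amplitude,
                 loading_sd = loading_sd,
                 noise_sd = noise_sd,
                 n_blobs = as.integer(n_blobs),
                 modalities = modalities,
                 global_scale_sd = global_scale_sd,
                 lesion_count_range = lesion_count_range,
                 lesion_amplitude = lesion_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Ellipsoidal two-tissue geometry shared by every subject of a cohort.
# Outer ellipsoid (semi-axes 0.45 * grid) bounds the brain; the inner
# ellipsoid (0.28 * grid) is white matter, the shell between them grey matter.
phantom_geometry <- function(grid_shape) {
  axis_sq <- function(d, semi) ((seq_len(d) - (d + 1) / 2) / semi)^2
  r2 <- function(f) {
    outer(outer(axis_sq(grid_shape[1], f * grid_shape[1]),
                axis_sq(grid_shape[2], f * grid_shape[2]), "+"),
          axis_sq(grid_shape[3], f * grid_shape[3]), "+")
  }
  brain <- r2(0.45) <= 1
  wm <- r2(0.28) <= 1
  list(brain = brain, wm = wm & brain, gm = brain & !wm)
}

# Sum of signed Gaussian blobs restricted to the brain support.
# Returns the construction pattern (peak |value| = 1) and the unit-L2 truth.
make_truth_pattern <- function(geom, n_blobs, grid_shape) {
  pat <- array(0, grid_shape)
  if (n_blobs > 0L) {
    brain_idx <- which(geom$brain)
    centres <- arrayInd(sample(brain_idx, n_blobs, replace = TRUE), grid_shape)
    sigmas <- stats::runif(n_blobs, 1.5, 3.5)
    signs <- sample(c(-1, 1), n_blobs, replace = TRUE)
    ax <- lapply(grid_shape, seq_len)
    for (b in seq_len(n_blobs)) {
      d2 <- outer(outer((ax[[1]] - centres[b, 1])^2,
                        (ax[[2]] - centres[b, 2])^2, "+"),
                  (ax[[3]] - centres[b, 3])^2, "+")
      pat <- pat + signs[b] * exp(-d2 / (2 * sigmas[b]^2))
    }
  }
  pat[!geom$brain] <- 0
  # zero mean over the brain: the pattern is a relative redistribution of
  # intensity (hypo- and hyper-intense regions), not a global shift, so
  # pattern expression cannot masquerade as a per-subject scaling factor
  pat[geom$brain] <- pat[geom$brain] - mean(pat[geom$brain])
  # construction scale: RMS 1 over the active blob region (|p| > 10% of
  # peak), so the cohort's effect_amplitude is the typical per-voxel
  # intensity shift inside the affected regions
  peak <- max(abs(pat))
  active <- abs(pat) > 0.1 * peak
  rms <- if (any(active)) sqrt(mean(pat[active]^2)) else 0
  l2 <- sqrt(sum(pat^2))
  list(raw = if (rms > 0) pat / rms else pat,
       unit = if (l2 > 0) pat / l2 else pat)
}

# n_lesions small spheres at random WM locations, random sign, fixed amplitude.
draw_lesions <- function(geom, grid_shape, count_range, amplitude) {
  lesions <- array(0, grid_shape)
  n <- if (count_range[1] == count_range[2]) count_range[1] else
    sample(seq.int(count_range[1], count_range[2]), 1L)
  if (n == 0L) return(lesions)
  wm_idx <- which(geom$wm)
  for (k in seq_len(n)) {
    ctr <- arrayInd(wm_idx[sample.int(length(wm_idx), 1L)], grid_shape)
    r <- sample(1:2, 1L)
    s <- sample(c(-1, 1), 1L)
    rng <- lapply(1:3, function(a)
      max(1L, ctr[a] - r):min(grid_shape[a], ctr[a] + r))
    for (i in rng[[1]]) for (j in rng[[2]]) for (k3 in rng[[3]]) {
      if ((i - ctr[1])^2 + (j - ctr[2])^2 + (k3 - ctr[3])^2 <= r^2)
        lesions[i, j, k3] <- lesions[i, j, k3] + s * amplitude
    }
  }
  lesions
}

#' Generate a synthetic multimodal phantom cohort
#'
#' Builds the shared ellipsoidal brain, draws the ground-truth differentiating
#' pattern (signed Gaussian blobs, restricted to the brain, unit-normalised),
#' then simulates every subject as
#' \deqn{image = baseline + loading \times pattern + lesions + noise,}
#' with `loading ~ Normal(effect_amplitude, loading_sd)` for target-group
#' subjects and `Normal(0, loading_sd)` for reference subjects. Baseline
#' tissue intensities are fixed (WM 1.0, GM 0.7, background 0) so analytic
#' checks are possible. Lesions are group-unrelated intensity perturbations at
#' random white-matter locations, acting as structured nuisance. Globally
#' scaled modalities are additionally multiplied by a per-subject factor
#' `~ Normal(1, global_scale_sd)`.
#'
#' One RNG stream is seeded from `config$seed` for cohort-level draws
#' (pattern geometry); per-subject sub-seeds are drawn from that stream, so
#' the cohort is reproducible bit for bit.
#'
#' @param config a [phantom_config()].
#' @return An object of class `phantom_cohort`: a list with `subjects` (each
#'   with `subject_id`, `group` in `{"reference","target"}`, a named list
#'   `images` of 3-D arrays, and `gm`/`wm` tissue-probability maps), `truth`
#'   (`pattern`, the unit-norm ground-truth map; `loadings` per subject;
#'   `support`, the brain voxel mask), and the `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "phantom_config"))
    stop("config must be a phantom_config")
  grid_shape <- config$grid_shape
  geom <- phantom_geometry(grid_shape)
  if (!any(geom$brain))
    stop("degenerate phantom geometry: empty brain support on grid ",
         paste(grid_shape, collapse = "x"))
  set.seed(config$seed)
  truth <- make_truth_pattern(geom, config$n_blobs, grid_shape)
  baseline <- 1.0 * geom$wm + 0.7 * geom$gm
  gm_map <- geom$gm * 1.0
  wm_map <- geom$wm * 1.0

  n_total <- config$n_reference + config$n_target
  groups <- rep(c("reference", "target"),
                c(config$n_reference, config$n_target))
  ids <- sprintf("%s%02d", ifelse(groups == "reference", "ref", "tgt"),
                 c(seq_len(config$n_reference), seq_len(config$n_target)))
  subj_seeds <- if (n_total > 0) sample.int(.Machine$integer.max - 1L, n_total)
                else integer(0)

  n_brain <- sum(geom$brain)
  loadings <- numeric(n_total)
  names(loadings) <- ids
  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    set.seed(subj_seeds[i])
    mu <- if (groups[i] == "target") config$effect_amplitude else 0
    loadings[i] <- stats::rnorm(1, mu, config$loading_sd)
    lesions <- draw_lesions(geom, grid_shape, config$lesion_count_range,
                            config$lesion_amplitude)
    base_i <- baseline + loadings[i] * truth$raw + lesions
    images <- vector("list", length(config$modalities))
    names(images) <- names(config$modalities)
    for (m in names(config$modalities)) {
      img <- base_i
      if (config$noise_sd > 0)
        img[geom$brain] <- img[geom$brain] +
          stats::rnorm(n_brain, 0, config$noise_sd)
      if (config$modalities[[m]] == "globally_scaled")
        img <- img * stats::rnorm(1, 1, config$global_scale_sd)
      images[[m]] <- img
    }
    subjects[[i]] <- list(subject_id = ids[i], group = groups[i],
                          images = images, gm = gm_map, wm = wm_map)
  }
  structure(list(subjects = subjects,
                 truth = list(pattern = truth$unit,
                              loadings = loadings,
                              support = geom$brain),
                 config = config),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  n_ref <- sum(vapply(x$subjects, function(s) s$group == "reference", TRUE))
  cat(sprintf(paste0("phantom cohort: %d reference + %d target subjects, ",
                     "grid %s, modalities: %s\n"),
              n_ref, length(x$subjects) - n_ref,
              paste(x$config$grid_shape, collapse = "x"),
              paste(names(x$config$modalities), collapse = ", ")))
  invisible(x)
}

cohort_groups <- function(cohort) {
  vapply(cohort$subjects, function(s) s$group, character(1))
}

cohort_ids <- function(cohort) {
  vapply(cohort$subjects, function(s) s$subject_id, character(1))
}
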