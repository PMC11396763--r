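#!/usr/bin/env Rscript
# Simulate the study cohort: 30 reference-phenotype and 20 target-phenotype
# subjects on a 32^3 grid, two contrast families sharing one embedded
# differentiating pattern — an intrinsically normalised quantitative map
# ("qmap", needing no global scaling) and a globally scaled weighted
# contrast ("t1w", carrying an arbitrary per-subject intensity factor).
# Volumes (binary) go to scratch/cohort; the subject table goes to results/.

library(ssmpca)

cfg <- phantom_config(grid_shape = c(32L, 32L, 32L),
                      n_reference = 30L, n_target = 20L,
                      effect_amplitude = 0.5, loading_sd = 0.15,
                      noise_sd = 0.1, n_blobs = 6L,
                      modalities = c(qmap = "intrinsically_normalised",
                                     t1w = "globally_scaled"),
                      global_scale_sd = 0.08,
                      lesion_count_range = c(5L, 20L),
                      seed = 20240904L)

cohort <- generate_cohort(cfg)
print(cohort)

manifest <- write_cohort(cohort, "scratch/cohort")
cat("cohort written to", dirname(manifest), "\n")

dir.create("results", showWarnings = FALSE)
subjects <- data.frame(
  subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
  group = vapply(cohort$subjects, `[[`, "", "group"),
  true_loading = round(unname(cohort$truth$loadings), 4))
write.table(subjects, "results/cohort_subjects.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("subject table -> results/cohort_subjects.tsv;",
    "true pattern loadings: reference mean",
    round(mean(subjects$true_loading[subjects$group == "reference"]), 3),
    "| target mean",
    round(mean(subjects$true_loading[subjects$group == "target"]), 3), "\n")
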