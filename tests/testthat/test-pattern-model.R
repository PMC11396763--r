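test_that("a perfectly separating candidate is selected and flagged", {
  set.seed(1)
  lab <- rep(c("reference", "target"), each = 10)
  sc <- cbind(c(stats::rnorm(10, 0, 0.1), stats::rnorm(10, 5, 0.1)))
  out <- stepwise_logistic(sc, lab)
  expect_equal(out$selected, 1L)
  expect_true(out$separation)
})

test_that("the label-correlated candidate enters before a noise candidate", {
  set.seed(3)
  lab <- rep(c("reference", "target"), each = 15)
  y <- as.integer(lab == "target")
  sc <- cbind(stats::rnorm(30), y + stats::rnorm(30, 0, 0.3))
  out <- stepwise_logistic(sc, lab)
  expect_equal(out$selected[1], 2L)
  # oracle: the single-candidate model criteria agree with the choice
  a1 <- stats::AIC(stats::glm(y ~ sc[, 1], family = stats::binomial()))
  a2 <- suppressWarnings(
    stats::AIC(stats::glm(y ~ sc[, 2], family = stats::binomial())))
  expect_lt(a2, a1)
})

test_that("pure-noise candidates often leave the intercept-only model standing", {
  # repeated-simulation oracle; an AIC entry needs a deviance drop > 2,
  # so with 5 independent noise candidates the no-selection rate sits near
  # (1 - P[chisq_1 > 2])^5 ~ 0.43, not above it
  set.seed(11)
  empty <- replicate(200, {
    sc <- matrix(stats::rnorm(30 * 5), 30, 5)
    lab <- rep(c("reference", "target"), each = 15)
    length(stepwise_logistic(sc, lab)$selected) == 0L
  })
  expect_gt(mean(empty), 0.25)
  expect_lt(mean(empty), 0.60)
})

test_that("stepwise preconditions are enforced", {
  expect_error(stepwise_logistic(cbind(1:4), rep("reference", 4)),
               "two groups")
  expect_error(stepwise_logistic(cbind(1:3),
                                 c("reference", "target", "target")),
               "2 subjects per group")
})

test_that("pattern combination is the normalised weighted component sum", {
  res <- planted_residuals(5, 5, 40, effect = 2)
  pca <- run_pca(res)
  one <- combine_pattern(pca, 1L, c(0, 1))  # intercept 0, weight 1
  expect_equal(one$pattern, pca$components[, 1], tolerance = 1e-12)
  expect_equal(sum(one$pattern^2), 1, tolerance = 1e-9)
  # Pythagoras on orthonormal components: |2 c1 - c2| = sqrt(5)
  two <- combine_pattern(pca, 1:2, c(2, -1))
  expect_equal(two$pattern,
               as.numeric(pca$components[, 1:2] %*% c(2, -1)) / sqrt(5),
               tolerance = 1e-9)
  # VAF additivity
  expect_equal(two$total_vaf, sum(pca$vaf[1:2]), tolerance = 1e-6)
  expect_error(combine_pattern(pca, integer(0), numeric(0)), "empty")
})

test_that("projection scores satisfy the defining identities", {
  res <- planted_residuals(6, 6, 30, effect = 2)
  pm <- as_pm(res$x + 1, res$group)  # arbitrary profile matrix
  gmp <- compute_gmp(pm)
  fit_res <- residual_profiles(pm, gmp)
  pca <- run_pca(fit_res)
  pat <- combine_pattern(pca, 1L, c(0, 1))
  # subject equal to the GMP scores zero; GMP + pattern scores one
  expect_equal(project_score(gmp$profile, gmp, pat, type = "raw"), 0,
               tolerance = 1e-9)
  expect_equal(project_score(gmp$profile + pat$pattern, gmp, pat,
                             type = "raw"), 1, tolerance = 1e-9)
  # linearity
  set.seed(4)
  u <- stats::rnorm(30); v <- stats::rnorm(30)
  s <- function(w) project_score(gmp$profile + w, gmp, pat, type = "raw")
  expect_equal(s(2 * u + 3 * v), 2 * s(u) + 3 * s(v), tolerance = 1e-9)
  # z-scores of the reference training group standardise to mean 0, SD 1
  pat <- fit_reference_stats(pat, pm, gmp)
  ref_z <- project_score(pm$x[pm$group == "reference", ], gmp, pat,
                         type = "z")
  expect_equal(mean(ref_z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(ref_z), 1, tolerance = 1e-9)
  # z-scores without reference statistics are refused
  pat2 <- combine_pattern(pca, 1L, c(0, 1))
  expect_error(project_score(u, gmp, pat2, type = "z"), "unset")
})

test_that("derived phantom patterns recover the embedded truth", {
  ph <- phantom_pm(tiny_config(effect_amplitude = 0.5, seed = 6L))
  fit <- derive_pattern(ph$pm)
  expect_false(fit$empty)
  expect_gte(abs(pattern_truth_cosine(fit$pattern, ph$cohort$truth$pattern)),
             0.8)
})

test_that("null phantom pattern-truth cosines are centred at zero", {
  # under the null the truth direction is still a variance component of the
  # data (loading_sd > 0), so |cosine| may be large when selection latches
  # onto it; what the null removes is its group association, so the SIGN of
  # the cosine (fixed by the target-above-reference orientation) is random
  cos <- vapply(1:8, function(s) {
    ph <- phantom_pm(tiny_config(effect_amplitude = 0, seed = 40L + s))
    fit <- derive_pattern(ph$pm)
    if (fit$empty) 0
    else pattern_truth_cosine(fit$pattern, ph$cohort$truth$pattern)
  }, 0)
  expect_lt(abs(mean(cos)), 0.4)
  expect_lt(abs(mean(sign(cos[cos != 0]))), 1)  # both signs occur
})
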