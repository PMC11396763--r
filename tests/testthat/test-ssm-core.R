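test_that("grand mean profile averages reference rows only", {
  x <- rbind(c(0, 0, 0, 0), c(2, 4, 6, 8))
  pm <- as_pm(x, groups = c("reference", "reference"))
  expect_equal(unname(compute_gmp(pm)$profile), c(1, 2, 3, 4))
  pm1 <- as_pm(x[1, , drop = FALSE], groups = "reference")
  expect_equal(unname(compute_gmp(pm1)$profile), c(0, 0, 0, 0))
  # target rows must not contribute
  pm2 <- as_pm(rbind(x, c(100, 100, 100, 100)),
               groups = c("reference", "reference", "target"))
  expect_equal(unname(compute_gmp(pm2)$profile), c(1, 2, 3, 4))
  expect_error(compute_gmp(as_pm(x, groups = c("target", "target"))),
               "no rows")
})

test_that("grand mean over 15 random rows equals explicit loop summation", {
  set.seed(1)
  x <- matrix(stats::rnorm(15 * 40), 15, 40)
  sums <- numeric(40)
  for (i in 1:15) for (j in 1:40) sums[j] <- sums[j] + x[i, j]
  gmp <- compute_gmp(as_pm(x, groups = rep("reference", 15)))
  expect_equal(unname(gmp$profile), sums / 15, tolerance = 1e-12)
  expect_equal(gmp$n_reference, 15L)
})

test_that("residual profiles subtract the GMP with expected identities", {
  set.seed(2)
  x <- matrix(stats::rnorm(6 * 10), 6, 10)
  grp <- rep(c("reference", "target"), each = 3)
  pm <- as_pm(x, grp)
  gmp <- compute_gmp(pm)
  res <- residual_profiles(pm, gmp)
  # self-subtraction
  pm_self <- as_pm(matrix(gmp$profile, 1), "target")
  expect_true(all(residual_profiles(pm_self, gmp)$x == 0))
  # linearity in a constant offset
  pm_off <- pm; pm_off$x <- pm$x + 2
  expect_equal(residual_profiles(pm_off, gmp)$x, res$x + 2)
  # reference rows centre to zero when the GMP came from them
  expect_equal(unname(colMeans(res$x[grp == "reference", ])),
               rep(0, 10), tolerance = 1e-9)
  expect_error(residual_profiles(pm, gmp$profile[1:5]), "does not match")
})

test_that("rank-1 residuals give a single component with full VAF", {
  v <- stats::rnorm(30)
  x <- outer(c(1, -2, 3, 0.5), v)
  res <- as_pm(x, rep(c("reference", "target"), each = 2))
  class(res) <- c("residual_matrix", "profile_matrix")
  pca <- run_pca(res)
  expect_equal(ncol(pca$components), 1L)
  expect_equal(pca$vaf[1], 100, tolerance = 1e-9)
})

test_that("scores times components reconstruct the residual matrix", {
  res <- planted_residuals(4, 4, 25, effect = 1)
  pca <- run_pca(res)
  expect_equal(pca$scores %*% t(pca$components), unname(res$x),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("subject-space route matches brute-force voxel-space eigendecomposition", {
  for (s in 1:5) {
    set.seed(100 + s)
    res <- planted_residuals(3, 2, 20)
    pca <- run_pca(res)
    scatter <- t(res$x) %*% res$x           # voxel-space (20 x 20) scatter
    ev <- eigen(scatter, symmetric = TRUE)$values
    expect_equal(pca$vaf, 100 * ev[seq_along(pca$vaf)] / sum(ev),
                 tolerance = 1e-8)
    gram <- crossprod(pca$components)
    expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
    # residuals of a reference-derived GMP have rank <= n - 1
    expect_lte(ncol(pca$components), nrow(res$x) - 1L)
    expect_equal(sum(pca$vaf), 100, tolerance = 1e-6)
  }
})

test_that("component signs orient target mean scores above reference means", {
  res <- planted_residuals(10, 10, 50, effect = 3)
  pca <- run_pca(res)
  for (j in seq_len(ncol(pca$scores))) {
    expect_gte(mean(pca$scores[res$group == "target", j]),
               mean(pca$scores[res$group == "reference", j]))
  }
})

test_that("permuting subjects permutes scores and leaves components unchanged", {
  set.seed(5)
  res <- planted_residuals(4, 4, 30, effect = 2)
  pca <- run_pca(res)
  perm <- sample(nrow(res$x))
  res_p <- res
  res_p$x <- res$x[perm, ]
  res_p$subject_id <- res$subject_id[perm]
  res_p$group <- res$group[perm]
  pca_p <- run_pca(res_p)
  expect_equal(pca_p$components, pca$components, tolerance = 1e-8)
  expect_equal(unname(pca_p$scores), unname(pca$scores[perm, ]),
               tolerance = 1e-8)
})

test_that("degenerate PCA inputs raise errors", {
  res <- as_pm(matrix(0, 4, 10), rep(c("reference", "target"), 2))
  expect_error(run_pca(res), "no variance")
  expect_error(run_pca(as_pm(matrix(1, 1, 10), "reference")), "2 subjects")
})

test_that("cumulative VAF selection returns the smallest sufficient prefix", {
  fake <- function(vaf) list(vaf = vaf)
  expect_equal(select_components(fake(c(60, 30, 10)), 50), 1L)
  expect_equal(select_components(fake(c(30, 25, 20, 15, 10)), 50), 1:2)
  expect_equal(select_components(fake(c(50, 50)), 100), 1:2)
  expect_equal(select_components(fake(c(30, 25, 20, 15, 10)), 50,
                                 rule = "per_component"), integer(0))
  expect_equal(select_components(fake(c(60, 30, 10)), 25,
                                 rule = "per_component"), 1:2)
  expect_error(select_components(fake(c(100)), 0), "vaf_threshold")
})
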