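test_that("saturated tissue maps produce a whole-grid mask", {
  d <- c(8L, 8L, 8L)
  gm <- replicate(3, array(0.5, d), simplify = FALSE)
  wm <- replicate(3, array(0.5, d), simplify = FALSE)
  mask <- build_brain_mask(gm, wm, tissue_threshold = 0.1)
  expect_equal(mask$n_voxels, prod(d))
})

test_that("intersection excludes a voxel any subject lacks; union keeps it", {
  d <- c(8L, 8L, 8L)
  gm <- replicate(3, array(1, d), simplify = FALSE)
  wm <- replicate(3, array(0, d), simplify = FALSE)
  gm[[2]][3, 4, 5] <- 0  # subject 2 has no tissue at v
  m_int <- build_brain_mask(gm, wm, rule = "intersection")
  m_uni <- build_brain_mask(gm, wm, rule = "union")
  expect_false(m_int$mask[3, 4, 5])
  expect_true(m_uni$mask[3, 4, 5])
  expect_equal(m_int$n_voxels, prod(d) - 1L)
})

test_that("mask errors are informative", {
  d <- c(8L, 8L, 8L)
  zeros <- replicate(2, array(0, d), simplify = FALSE)
  expect_error(build_brain_mask(zeros, zeros), "empty")
  gm <- list(array(1, d), array(1, c(8L, 8L, 9L)))
  expect_error(build_brain_mask(gm, zeros), "subject 2")
  expect_error(build_brain_mask(zeros, zeros, tissue_threshold = 1),
               "tissue_threshold")
})

test_that("phantom mask voxel count matches an independent point-in-ellipsoid count", {
  cfg <- tiny_config(seed = 2L)
  ph <- phantom_pm(cfg)
  d <- cfg$grid_shape
  # independent oracle: count grid points inside the outer ellipsoid used
  # for the GM+WM anatomy (semi-axes 0.45 * grid, centred mid-grid)
  count <- 0L
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    r2 <- ((i - (d[1] + 1) / 2) / (0.45 * d[1]))^2 +
          ((j - (d[2] + 1) / 2) / (0.45 * d[2]))^2 +
          ((k - (d[3] + 1) / 2) / (0.45 * d[3]))^2
    if (r2 <= 1) count <- count + 1L
  }
  expect_equal(ph$mask$n_voxels, count)
})

test_that("global normalisation divides by the in-mask mean", {
  d <- c(8L, 8L, 8L)
  gm <- list(array(1, d)); wm <- list(array(0, d))
  mask <- build_brain_mask(gm, wm)
  img <- array(5, d)
  out <- global_normalise(img, mask)
  expect_true(all(out == 1))
  img2 <- array(stats::runif(prod(d), 0.5, 2), d)
  expect_equal(mean(global_normalise(img2, mask)[mask$mask]), 1,
               tolerance = 1e-9)
  expect_equal(global_normalise(img2, mask), global_normalise(3 * img2, mask))
  # idempotence
  once <- global_normalise(img2, mask)
  expect_equal(global_normalise(once, mask), once)
  expect_error(global_normalise(-img2, mask), "non-positive")
})

test_that("prepare_modality matches hand-computed normalised rows on a toy mask", {
  d <- c(2L, 2L, 1L)
  gm <- list(array(1, d)); wm <- list(array(0, d))
  mask <- build_brain_mask(gm, wm)
  vals <- list(c(1, 2, 3, 4), c(2, 2, 2, 2), c(1, 1, 3, 3))
  imgs <- lapply(vals, array, dim = d)
  pm_raw <- prepare_modality(imgs, mask, normalisation = "none")
  expect_equal(unname(pm_raw$x), do.call(rbind, vals))
  pm_gn <- prepare_modality(imgs, mask, normalisation = "global_mean")
  hand <- do.call(rbind, lapply(vals, function(v) v / mean(v)))
  expect_equal(unname(pm_gn$x), hand)
  # scale invariance of the global-mean path
  pm_2x <- prepare_modality(lapply(imgs, function(i) 2 * i), mask,
                            normalisation = "global_mean")
  expect_equal(pm_gn$x, pm_2x$x)
})

test_that("log transform applies after normalisation and rejects non-positive voxels", {
  d <- c(2L, 2L, 1L)
  mask <- build_brain_mask(list(array(1, d)), list(array(0, d)))
  img <- array(c(1, 2, 4, 8), d)
  pm <- prepare_modality(list(img), mask, normalisation = "none",
                         log_transform = TRUE)
  expect_equal(unname(pm$x[1, ]), log(c(1, 2, 4, 8)))
  bad <- array(c(1, 0, 4, 8), d)
  expect_error(prepare_modality(list(bad), mask, normalisation = "none",
                                log_transform = TRUE,
                                subject_ids = "subA"),
               "subA.*1 non-positive")
})

test_that("voxel ordering is stable: columns map to ascending linear mask indices", {
  cfg <- tiny_config(seed = 4L)
  ph <- phantom_pm(cfg)
  expect_identical(ph$pm$voxel_index, which(ph$mask$mask))
  img1 <- ph$cohort$subjects[[1]]$images$qmap
  expect_equal(unname(ph$pm$x[1, ]), img1[which(ph$mask$mask)])
  # a second matrix over the same mask aligns column-for-column
  pm2 <- cohort_matrix(ph$cohort, "qmap", ph$mask, normalisation = "none",
                       subset = 1:5)
  expect_identical(pm2$voxel_index, ph$pm$voxel_index)
  expect_equal(pm2$x, ph$pm$x[1:5, ])
})
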