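test_that("parcellation covers all labels with connected regions", {
  p <- make_parcellation(c(4, 4, 4), n_rois = 2, seed = 1)
  expect_setequal(setdiff(unique(as.vector(p)), 0L), 1:2)
  expect_true(all(tabulate(p[p > 0], 2) >= 1))

  p8 <- make_parcellation(c(10, 10, 10), n_rois = 8, seed = 7)
  for (lab in 1:8)
    expect_identical(flood_fill_components(p8, lab), 1L)

  expect_error(make_parcellation(c(1, 1, 1), n_rois = 2),
               "too small")
})

test_that("parcellation is reproducible under the seed", {
  a <- make_parcellation(c(6, 6, 6), 5, seed = 42)
  b <- make_parcellation(c(6, 6, 6), 5, seed = 42)
  expect_identical(a, b)
})

test_that("simulated BOLD realises the requested coherence structure", {
  p <- make_parcellation(c(5, 5, 5), 3, seed = 2)
  # degenerate mixture: full coherence, no noise -> identical series per ROI
  b <- simulate_bold(p, 20, 2, local_coherence = 1, noise_sd = 0, seed = 1)
  for (r in 1:3) {
    vox <- which(p == r)
    Y <- matrix(b$data, 125, 20)[vox, , drop = FALSE]
    expect_lt(max(abs(sweep(Y, 2, Y[1, ]))), 1e-12)
  }
  # identity latent covariance -> near-zero cross-ROI correlation at T = 500
  b2 <- simulate_bold(p, 500, 2, roi_cov = diag(3), local_coherence = 1,
                      noise_sd = 0, seed = 3)
  tc <- roi_timecourses(b2, p)
  cc <- cor(t(tc))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.15)
  # seeded determinism
  b3 <- simulate_bold(p, 20, 2, seed = 9)
  b4 <- simulate_bold(p, 20, 2, seed = 9)
  expect_identical(b3$data, b4$data)
  # non-PSD covariance rejected
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3, 3)
  expect_error(simulate_bold(p, 20, 2, roi_cov = bad), "semi-definite")
})

test_that("tensor generator round-trips FA and orients bundles", {
  p <- make_parcellation(c(8, 8, 8), 4, seed = 5)
  tf <- simulate_tensor_field(p, fa_targets = 0, seed = 1)
  # isotropic: all eigenvalues trace/3
  v <- which(tf$mask)[1]
  D <- matrix(c(tf$components[, , , 1][v], tf$components[, , , 2][v],
                tf$components[, , , 3][v], tf$components[, , , 2][v],
                tf$components[, , , 4][v], tf$components[, , , 5][v],
                tf$components[, , , 3][v], tf$components[, , , 5][v],
                tf$components[, , , 6][v]), 3, 3)
  expect_equal(eigen(D, symmetric = TRUE)$values, rep(2.4e-3 / 3, 3),
               tolerance = 1e-12)

  # round-trip through the FA formula at 0.7
  tf7 <- simulate_tensor_field(p, fa_targets = 0.7, seed = 2)
  fm <- fa_map(tf7)
  expect_lt(max(abs(fm$data[fm$mask] - 0.7)), 1e-10)

  # round-trip across the FA range
  for (f in c(0, 0.2, 0.5, 0.9, 0.99)) {
    lam <- painfuse:::prolate_eigenvalues(f, 2.4e-3)
    expect_equal(fa_from_eigenvalues(lam[1], lam[2], lam[3]), f,
                 tolerance = 1e-10)
    expect_equal(sum(lam), 2.4e-3, tolerance = 1e-15)
  }

  # bundle voxels aligned with the ROI1 -> ROI2 axis
  slab <- slab_parcellation()
  tfb <- simulate_tensor_field(slab, fa_targets = 0.05,
                               bundle_specs = list(list(roi_a = 1, roi_b = 2,
                                                        width = 1, fa = 0.8)),
                               seed = 3)
  fmb <- fa_map(tfb)
  corridor <- which(abs(fmb$data - 0.8) < 1e-9)
  expect_gt(length(corridor), 3)
  for (v in corridor[1:3]) {
    d <- painfuse:::principal_direction(painfuse:::tensor_at(tfb, v))
    expect_gt(abs(d[1]), 0.99)  # slab axis is x
  }

  expect_error(simulate_tensor_field(p, fa_targets = 1), "\\[0, 1\\)")
})

test_that("staircase thresholds snap up and average on the 0.125 grid", {
  # fixed latent 2.57, no noise: both measurements snap to 2.75
  X <- matrix(0, 20, 1)
  ph <- simulate_thresholds(X, support = 1L, weights = 0, intercept = 2.57,
                            noise_sd = 0, measurement_sd = 0, seed = 1)
  expect_true(all(ph$threshold_J == 2.75))
  # a latent already on the grid is a fixed point
  ph2 <- simulate_thresholds(X, intercept = 1.25, noise_sd = 0,
                             measurement_sd = 0, seed = 1)
  expect_true(all(ph2$threshold_J == 1.25))
  # staircase closure: single measurements on the 0.25 grid from 1 J,
  # averages of two on the 0.125 grid
  set.seed(99)
  feats <- matrix(rnorm(500), 500, 1)
  ph3 <- simulate_thresholds(feats, support = 1L, weights = 0.5, seed = 2)
  expect_true(all(abs((ph3$threshold_J - 1) / 0.125 -
                        round((ph3$threshold_J - 1) / 0.125)) < 1e-9))
  expect_true(all(ph3$threshold_J >= 1))
  # determinism and error contract
  ph4 <- simulate_thresholds(feats, support = 1L, weights = 0.5, seed = 2)
  expect_identical(ph3$threshold_J, ph4$threshold_J)
  expect_error(simulate_thresholds(X, support = 5L, weights = 1),
               "out of range")
})

test_that("threshold population calibrates to 2.57 +/- 0.53 J", {
  st <- simulate_feature_tables(generator_config(n_subjects = 1000, seed = 17))
  expect_lt(abs(mean(st$phenotype$threshold_J) - 2.57), 0.1)
  expect_lt(abs(sd(st$phenotype$threshold_J) - 0.53), 0.1)
})

test_that("redundancy knob controls cross-block signal sharing", {
  cfg1 <- generator_config(n_subjects = 500, n_regional = 30, n_rois = 10,
                           n_planted = 3, cross_modality_redundancy = 1,
                           feature_noise_sd = 0.1, seed = 4)
  st1 <- simulate_feature_tables(cfg1)
  # redundant: planted columns in different blocks correlate strongly
  c1 <- st1$tables$reho$matrix[, st1$planted$support$reho[1]]
  c2 <- st1$tables$fa$matrix[, st1$planted$support$fa[1]]
  expect_gt(cor(c1, c2), 0.9)

  cfg0 <- generator_config(n_subjects = 500, n_regional = 30, n_rois = 10,
                           n_planted = 3, cross_modality_redundancy = 0,
                           feature_noise_sd = 0.1, seed = 4)
  st0 <- simulate_feature_tables(cfg0)
  # complementary: block signals mutually uncorrelated
  sg <- st0$planted$signals
  cc <- cor(sg)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.1)
  # shape contract
  st210 <- simulate_feature_tables(generator_config(n_subjects = 210,
                                                    n_regional = 20,
                                                    n_rois = 5, n_planted = 2,
                                                    seed = 1))
  expect_identical(nrow(st210$tables$reho$matrix), 210L)
  expect_identical(nrow(st210$phenotype), 210L)
})

test_that("simulated motion hits the requested spike fraction", {
  m <- simulate_motion(300, spike_fraction = 0.1, seed = 3)
  fd <- framewise_displacement(m)
  expect_equal(mean(fd > 0.2), 0.1, tolerance = 0.02)
  expect_identical(m, simulate_motion(300, spike_fraction = 0.1, seed = 3))
})
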