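# helpers to build tiny volumes in code
toy_bold <- function(series_list, tr_s = 2) {
  # series_list: list of per-voxel series laid out along x
  t <- length(series_list[[1]])
  d <- array(0, c(length(series_list), 1, 1, t))
  for (i in seq_along(series_list)) d[i, 1, 1, ] <- series_list[[i]]
  bold_volume(d, tr_s)
}

test_that("initial-volume discard keeps order and errors when too short", {
  b <- toy_bold(list(1:300, 301:600))
  out <- discard_initial_volumes(b, 10)
  expect_identical(dim(out$data)[4], 290L)
  expect_identical(as.vector(out$data[1, 1, 1, ]), 11:300 + 0)
  expect_identical(discard_initial_volumes(b, 0), b)
  expect_error(discard_initial_volumes(toy_bold(list(1:5)), 10), "discard")
})

test_that("Friston-24 expansion matches the hand-computed layout", {
  z <- matrix(0, 5, 6)
  expect_true(all(friston24(z) == 0))
  expect_identical(ncol(friston24(z)), 24L)

  m <- matrix(0, 4, 6)
  m[, 1] <- 0:3
  f <- friston24(m)
  expect_equal(f[, 1], 0:3 + 0)          # p
  expect_equal(f[, 7], c(0, 0, 1, 2))    # lag
  expect_equal(f[, 13], (0:3)^2)         # p^2
  expect_equal(f[, 19], c(0, 0, 1, 4))   # lag^2
  expect_error(friston24(matrix(0, 4, 5)), "6 columns")
})

test_that("framewise displacement sums translations and scaled rotations", {
  m <- matrix(1, 5, 6)
  expect_equal(framewise_displacement(m), rep(0, 5))
  m2 <- matrix(0, 3, 6)
  m2[2, 1:3] <- 0.1
  expect_equal(framewise_displacement(m2), c(0, 0.3, 0.3))
  m3 <- matrix(0, 2, 6)
  m3[2, 4] <- 0.001
  expect_equal(framewise_displacement(m3, head_radius_mm = 50), c(0, 0.05))
})

test_that("scrubbing uses a strict threshold and one spike per frame", {
  s0 <- scrub_mask(rep(0, 5))
  expect_identical(ncol(s0$spikes), 0L)
  expect_true(all(s0$keep))
  s1 <- scrub_mask(c(0, 0.3, 0.1))
  expect_identical(ncol(s1$spikes), 1L)
  expect_equal(s1$spikes[, 1], c(0, 1, 0))
  expect_identical(s1$keep, c(TRUE, FALSE, TRUE))
  # boundary: fd exactly at the threshold is kept
  s2 <- scrub_mask(c(0, 0.2, 0.21), threshold = 0.2)
  expect_identical(s2$keep, c(TRUE, TRUE, FALSE))
  expect_identical(ncol(s2$spikes), 1L)
})

test_that("nuisance regression is an orthogonal projection", {
  set.seed(1)
  t <- 30
  x <- rnorm(t)
  b <- toy_bold(list(x, 5 + 2 * x, rnorm(t)))
  # intercept-only design: demeaning
  res0 <- nuisance_regress(b, matrix(numeric(0), t, 0))
  expect_equal(as.vector(res0$data[1, 1, 1, ]), x - mean(x), tolerance = 1e-12)
  # a voxel equal to a design column has zero residual
  res1 <- nuisance_regress(b, cbind(x))
  expect_lt(max(abs(res1$data[2, 1, 1, ])), 1e-10)
  # residuals orthogonal to the design
  D <- cbind(x, rnorm(t))
  res2 <- nuisance_regress(b, D)
  r3 <- as.vector(res2$data[3, 1, 1, ])
  dots <- abs(crossprod(cbind(1, D), r3))
  expect_lt(max(dots), 1e-8 * sqrt(sum(r3^2)) * max(sqrt(colSums(cbind(1, D)^2))))
  # rank-deficient design rejected with the offending column named
  expect_error(nuisance_regress(b, cbind(a = x, b = 2 * x)), "rank-deficient")
})

test_that("band-pass keeps in-band and rejects out-of-band sinusoids", {
  t <- 290; tr <- 2
  tt <- seq_len(t) - 1
  s_in <- sin(2 * pi * 0.05 * tt * tr)
  s_out <- sin(2 * pi * 0.2 * tt * tr)
  b <- toy_bold(list(s_in, s_out, rep(3, t)), tr_s = tr)
  f <- bandpass(b, 0.01, 0.1)
  amp <- function(v) sqrt(mean(v^2)) / sqrt(0.5)
  expect_gt(amp(as.vector(f$data[1, 1, 1, ])), 0.95)
  expect_lt(amp(as.vector(f$data[2, 1, 1, ])), 0.05)
  expect_lt(max(abs(f$data[3, 1, 1, ])), 1e-10)  # DC removed
  expect_error(bandpass(b, 0.01, 0.3), "Nyquist")
})

test_that("Kendall's W matches the brute-force oracle and its bounds", {
  # perfect concordance: 27 identical non-constant series
  t <- 10
  base <- sin(seq_len(t))
  d <- array(rep(base, each = 27), c(3, 3, 3, t))
  for (i in 1:27) d[((i - 1) %% 3) + 1, (((i - 1) %/% 3) %% 3) + 1,
                    ((i - 1) %/% 9) + 1, ] <- base
  b <- bold_volume(d, 2)
  w <- reho_map(b, k_min = 4)
  expect_equal(w$data[2, 2, 2], 1, tolerance = 1e-12)

  # randomized neighborhoods against the independent rank-sum oracle
  set.seed(42)
  for (rep in 1:100) {
    K <- sample(3:27, 1)
    n <- sample(3:20, 1)
    S <- matrix(sample(0:5, K * n, replace = TRUE) + rnorm(K * n, sd = 0.01),
                n, K)
    expect_equal(painfuse:::kendall_w(apply(S, 2, rank)),
                 kendall_w_bruteforce(S), tolerance = 1e-12)
  }

  # null: long independent series give small W
  set.seed(7)
  d2 <- array(rnorm(27 * 300), c(3, 3, 3, 300))
  w2 <- reho_map(bold_volume(d2, 2), k_min = 4)
  expect_lt(w2$data[2, 2, 2], 0.2)

  # all-constant neighbourhood: W = 0 with a warning
  d3 <- array(1, c(3, 3, 3, 5))
  expect_warning(w3 <- reho_map(bold_volume(d3, 2)), "all-constant")
  expect_true(all(w3$data == 0))

  # bounds on random data
  set.seed(8)
  d4 <- array(rnorm(4 * 4 * 4 * 8), c(4, 4, 4, 8))
  w4 <- reho_map(bold_volume(d4, 2))
  expect_true(all(w4$data >= 0 & w4$data <= 1))
})

test_that("Gaussian smoothing is mask-aware and matches the closed form", {
  m <- array(2.5, c(7, 7, 7))
  rm_ <- regional_map(m, "reho")
  expect_identical(smooth_gaussian(rm_, fwhm_mm = 0), rm_)
  sm <- smooth_gaussian(rm_, fwhm_mm = 6, voxel_size_mm = c(3, 3, 3))
  expect_lt(max(abs(sm$data - 2.5)), 1e-10)  # constant preserved in mask

  # single impulse reproduces the normalized separable kernel (grid large
  # enough that the kernel support is not truncated at the probed voxels)
  imp <- array(0, c(13, 13, 13)); imp[7, 7, 7] <- 1
  sm2 <- smooth_gaussian(regional_map(imp, "reho"), fwhm_mm = 6,
                         voxel_size_mm = c(3, 3, 3))
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1, ceiling(4 * sigma))
  k1 <- dnorm(-r:r, sd = sigma); k1 <- k1 / sum(k1)
  expect_equal(sm2$data[7, 7, 7], k1[r + 1]^3, tolerance = 1e-10)
  expect_equal(sm2$data[8, 7, 7], k1[r + 2] * k1[r + 1]^2, tolerance = 1e-10)
})

test_that("equalization divides by the in-mask mean", {
  m <- array(c(1, 3), c(2, 1, 1))
  eq <- equalize(regional_map(m, "reho"))
  expect_equal(as.vector(eq$data), c(0.5, 1.5))
  cm <- equalize(regional_map(array(4, c(3, 3, 3)), "fa"))
  expect_true(all(cm$data == 1))
  set.seed(2)
  rmap <- regional_map(array(runif(27) + 1, c(3, 3, 3)), "reho")
  expect_equal(mean(equalize(rmap)$data), 1, tolerance = 1e-12)
  expect_error(equalize(regional_map(array(0, c(2, 1, 1)), "reho")), "zero")
})

test_that("ROI time courses average in-mask voxels", {
  p <- array(c(1L, 1L, 2L, 0L), c(4, 1, 1))
  d <- array(0, c(4, 1, 1, 5))
  d[1, 1, 1, ] <- 1:5; d[2, 1, 1, ] <- -(1:5); d[3, 1, 1, ] <- 11:15
  b <- bold_volume(d, 2)
  tc <- roi_timecourses(b, p)
  expect_equal(unname(tc[1, ]), rep(0, 5))           # s and -s average to zero
  expect_equal(unname(tc[2, ]), 11:15 + 0)           # single-voxel ROI
  # brute-force loop oracle on random data
  set.seed(3)
  p2 <- make_parcellation(c(4, 4, 4), 3, seed = 1)
  b2 <- simulate_bold(p2, 12, 2, seed = 4)
  tc2 <- roi_timecourses(b2, p2)
  for (r in 1:3) for (t in c(1, 7)) {
    vox <- which(p2 == r)
    acc <- 0
    for (v in vox) acc <- acc + matrix(b2$data, 64, 12)[v, t]
    expect_equal(unname(tc2[r, t]), acc / length(vox), tolerance = 1e-12)
  }
  p3 <- array(c(1L, 2L, 3L, 3L), c(4, 1, 1))
  b3 <- bold_volume(d, 2, mask = array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1)))
  expect_error(roi_timecourses(b3, p3), "ROI 3")
})

test_that("FC matrix is clipped Fisher z with zero diagonal", {
  t <- 40
  tc <- rbind(sin(1:t), sin(1:t), cos(1:t * 2))
  rownames(tc) <- paste0("ROI_", 1:3)
  fc <- fc_matrix(tc)
  expect_equal(fc$values[1, 2], atanh(1 - 1e-7), tolerance = 1e-10)
  expect_true(all(diag(fc$values) == 0))
  expect_equal(fc$values, t(fc$values))
  # orthogonal sinusoids over full periods: z ~ 0
  tt <- seq(0, 2 * pi, length.out = 41)[-41]
  tc2 <- rbind(sin(tt), cos(tt))
  expect_lt(abs(fc_matrix(tc2)$values[1, 2]), 1e-6)
  # antisymmetry z(-r) = -z(r)
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  z1 <- fc_matrix(rbind(a, b))$values[1, 2]
  z2 <- fc_matrix(rbind(a, -b))$values[1, 2]
  expect_equal(z1, -z2, tolerance = 1e-12)
  expect_error(fc_matrix(rbind(a, rep(1, 50))), "constant")
})

test_that("lower-triangle vectorization round-trips and counts correctly", {
  m90 <- matrix(rnorm(90 * 90), 90, 90)
  m90 <- (m90 + t(m90)) / 2; diag(m90) <- 0
  v <- vectorize_lower(m90)
  expect_identical(length(v$values), 4005L)
  expect_true(all(v$meta$roi_a > v$meta$roi_b))
  expect_equal(devectorize_lower(v$values, 90), m90, tolerance = 1e-12)

  m2 <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_identical(length(vectorize_lower(m2)$values), 1L)
  expect_error(vectorize_lower(matrix(0, 2, 3)), "square")
})

test_that("FC is equivariant under ROI relabeling", {
  p <- make_parcellation(c(5, 5, 5), 4, seed = 6)
  b <- simulate_bold(p, 30, 2, seed = 7)
  fc <- fc_matrix(roi_timecourses(b, p))
  perm <- c(3L, 1L, 4L, 2L)
  p2 <- array(0L, dim(p)); for (r in 1:4) p2[p == r] <- perm[r]
  fc2 <- fc_matrix(roi_timecourses(b, p2))
  expect_equal(fc2$values[perm, perm], fc$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a strong planted ROI-pair attains the largest |z|", {
  hits <- 0
  for (s in 1:10) {
    p <- make_parcellation(c(6, 6, 6), 5, seed = s)
    cov <- diag(5); cov[2, 4] <- cov[4, 2] <- 0.8
    b <- simulate_bold(p, 300, 2, roi_cov = cov, local_coherence = 0.9,
                       noise_sd = 1, seed = 100 + s)
    z <- abs(fc_matrix(roi_timecourses(b, p))$values)
    top <- which(z == max(z), arr.ind = TRUE)[1, ]
    if (all(sort(top) == c(2, 4))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the preprocessing chain runs in the documented order", {
  p <- make_parcellation(c(5, 5, 5), 3, seed = 8)
  b <- simulate_bold(p, 40, 2, seed = 9)
  m <- simulate_motion(40, spike_fraction = 0.1, seed = 10)
  pre <- preprocess_bold(b, m)
  expect_identical(dim(pre$bold$data)[4], 30L)
  expect_identical(length(pre$fd), 30L)
  # output is band-limited: the DC component of every voxel is ~0
  Y <- matrix(pre$bold$data, 125, 30)
  expect_lt(max(abs(rowMeans(Y))), 1e-10)
  # motion of the wrong length is rejected
  expect_error(preprocess_bold(b, m[-1, , drop = FALSE]), "match")
})
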