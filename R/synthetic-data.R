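# Synthetic study generator: parcellations, BOLD volumes, tensor fields,
# motion traces, staircase-quantised pain thresholds and planted-signal
# feature tables. Every generator is a pure function of its arguments
# including the seed.

#' Generate a connected random parcellation
#'
#' ROIs are grown from randomly placed seed voxels by multi-source
#' breadth-first expansion (6-connectivity), so every label 1..n_rois is a
#' single connected component covering at least one voxel.
#'
#' @param grid_dims integer length-3 grid size.
#' @param n_rois number of regions (>= 2).
#' @param seed RNG seed.
#' @return 3D integer array of labels in 1..n_rois with attribute `n_rois`.
#' @examples
#' p <- make_parcellation(c(6, 6, 6), n_rois = 4, seed = 1)
#' table(p)
#' @export
make_parcellation <- function(grid_dims, n_rois, seed = 1) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3)
  if (n_rois < 2) stop("n_rois must be at least 2")
  nv <- prod(grid_dims)
  if (nv < n_rois)
    stop(sprintf("grid %s has only %d voxels, too small for n_rois = %d",
                 paste(grid_dims, collapse = "x"), nv, n_rois))
  set.seed(seed)
  lab <- array(0L, grid_dims)
  seeds <- sample.int(nv, n_rois)
  lab[seeds] <- seq_len(n_rois)
  # FIFO multi-source BFS over the 6-neighbourhood; queue holds linear indices
  queue <- seeds
  head <- 1L
  d1 <- grid_dims[1]; d2 <- grid_dims[2]; d3 <- grid_dims[3]
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    z <- (v - 1L) %/% (d1 * d2)
    rem <- (v - 1L) %% (d1 * d2)
    y <- rem %/% d1
    x <- rem %% d1
    l <- lab[v]
    for (k in 1:6) {
      nx <- x + c(-1L, 1L, 0L, 0L, 0L, 0L)[k]
      ny <- y + c(0L, 0L, -1L, 1L, 0L, 0L)[k]
      nz <- z + c(0L, 0L, 0L, 0L, -1L, 1L)[k]
      if (nx < 0L || nx >= d1 || ny < 0L || ny >= d2 || nz < 0L || nz >= d3)
        next
      w <- 1L + nx + ny * d1 + nz * d1 * d2
      if (lab[w] == 0L) {
        lab[w] <- l
        queue <- c(queue, w)
      }
    }
  }
  attr(lab, "n_rois") <- as.integer(n_rois)
  lab
}

#' Simulate a BOLD volume with ROI-level covariance and local coherence
#'
#' Each ROI draws a latent time series from a multivariate normal with
#' covariance `roi_cov`; every voxel's series is
#' `local_coherence * latent + (1 - local_coherence) * iid noise`, which is
#' what regional homogeneity and functional connectivity measure.
#'
#' @param parcellation label array from [make_parcellation()].
#' @param n_timepoints number of frames (>= 10).
#' @param tr_s repetition time in seconds.
#' @param roi_cov R x R symmetric positive semi-definite latent covariance
#'   (default identity).
#' @param local_coherence scalar or per-ROI mixing weight in \[0, 1\].
#' @param noise_sd standard deviation of the voxel-level noise.
#' @param seed RNG seed.
#' @return A [bold_volume()].
#' @export
simulate_bold <- function(parcellation, n_timepoints, tr_s = 2,
                          roi_cov = NULL, local_coherence = 0.7,
                          noise_sd = 1, seed = 1) {
  R <- max(parcellation)
  if (n_timepoints < 10) stop("n_timepoints must be at least 10")
  if (is.null(roi_cov)) roi_cov <- diag(R)
  if (!isTRUE(all.equal(roi_cov, t(roi_cov), tolerance = 1e-10)))
    stop("roi_cov must be symmetric")
  ev <- eigen(roi_cov, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("roi_cov is not positive semi-definite")
  lc <- rep_len(local_coherence, R)
  if (any(lc < 0 | lc > 1)) stop("local_coherence must lie in [0, 1]")
  set.seed(seed)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), R)
  latent <- matrix(stats::rnorm(n_timepoints * R), n_timepoints, R) %*% t(A)
  sp <- dim(parcellation)
  vox <- which(parcellation > 0)
  labs <- parcellation[vox]
  noise <- matrix(stats::rnorm(length(vox) * n_timepoints, sd = noise_sd),
                  length(vox), n_timepoints)
  series <- lc[labs] * t(latent)[labs, , drop = FALSE] +
    (1 - lc[labs]) * noise
  data <- array(0, c(sp, n_timepoints))
  step <- prod(sp)
  for (t in seq_len(n_timepoints))
    data[vox + (t - 1L) * step] <- series[, t]
  bold_volume(data, tr_s = tr_s, mask = array(parcellation > 0, sp))
}

# eigenvalues of a prolate tensor (l1, l2, l2) hitting a target FA at a
# given trace: d = l1 - l2 = fa * trace / sqrt(3 - 2 fa^2)
prolate_eigenvalues <- function(fa, trace) {
  d <- fa * trace / sqrt(3 - 2 * fa^2)
  l2 <- (trace - d) / 3
  cbind(l1 = l2 + d, l2 = l2, l3 = l2)
}

#' Simulate a diffusion tensor field with target FA values
#'
#' Every voxel receives a prolate tensor (eigenvalues l1 >= l2 = l3) solving
#' the fractional-anisotropy formula in closed form for the requested FA at
#' the requested trace, oriented along a random axis, except inside optional
#' straight "bundle" corridors between two ROIs where the principal axis is
#' the corridor direction and FA is elevated.
#'
#' @param parcellation label array (defines grid and mask).
#' @param fa_targets scalar or 3D array of target FA values in \[0, 1).
#' @param bundle_specs list of `list(roi_a, roi_b, width, fa)` corridors:
#'   voxels within `width` voxels of the straight segment joining the two ROI
#'   centroids get principal axis along that segment and FA `fa` (default 0.8).
#' @param trace tensor trace (sum of eigenvalues), default 2.4e-3 mm^2/s.
#' @param voxel_size_mm physical voxel size.
#' @param seed RNG seed (random per-voxel axes).
#' @return A [tensor_field()].
#' @export
simulate_tensor_field <- function(parcellation, fa_targets = 0.05,
                                  bundle_specs = list(), trace = 2.4e-3,
                                  voxel_size_mm = c(2, 2, 2), seed = 1) {
  sp <- dim(parcellation)
  if (trace <= 0) stop("trace must be positive")
  fa <- if (length(fa_targets) == 1) array(fa_targets, sp) else fa_targets
  if (!identical(dim(fa), sp)) stop("fa_targets shape must match the grid")
  if (any(fa < 0) || any(fa >= 1))
    stop("fa_targets must lie in [0, 1); FA = 1 needs a degenerate tensor")
  set.seed(seed)
  nv <- prod(sp)
  axes <- matrix(stats::rnorm(3 * nv), nv, 3)
  axes <- axes / sqrt(rowSums(axes^2))
  coords <- arrayInd(seq_len(nv), sp)
  for (b in bundle_specs) {
    w <- if (is.null(b$width)) 1 else b$width
    bfa <- if (is.null(b$fa)) 0.8 else b$fa
    if (bfa < 0 || bfa >= 1) stop("bundle fa must lie in [0, 1)")
    ca <- colMeans(coords[parcellation == b$roi_a, , drop = FALSE])
    cb <- colMeans(coords[parcellation == b$roi_b, , drop = FALSE])
    u <- (cb - ca) / sqrt(sum((cb - ca)^2))
    # distance from each voxel centre to the segment ca--cb
    rel <- sweep(coords, 2, ca)
    t_par <- as.vector(rel %*% u)
    t_par_cl <- pmin(pmax(t_par, 0), sqrt(sum((cb - ca)^2)))
    d2 <- rowSums((rel - outer(t_par_cl, u))^2)
    inside <- d2 <= w^2
    fa[inside] <- bfa
    axes[inside, ] <- matrix(u, sum(inside), 3, byrow = TRUE)
  }
  lam <- prolate_eigenvalues(as.vector(fa), trace)
  d <- lam[, 1] - lam[, 2]
  comp <- array(0, c(sp, 6))
  # D = l2 * I + d * v v^T ; components ordered xx, xy, xz, yy, yz, zz
  comp[, , , 1] <- array(lam[, 2] + d * axes[, 1]^2, sp)
  comp[, , , 2] <- array(d * axes[, 1] * axes[, 2], sp)
  comp[, , , 3] <- array(d * axes[, 1] * axes[, 3], sp)
  comp[, , , 4] <- array(lam[, 2] + d * axes[, 2]^2, sp)
  comp[, , , 5] <- array(d * axes[, 2] * axes[, 3], sp)
  comp[, , , 6] <- array(lam[, 2] + d * axes[, 3]^2, sp)
  tensor_field(comp, voxel_size_mm = voxel_size_mm,
               mask = array(parcellation > 0, sp))
}

#' Simulate head-motion parameters
#'
#' Smoothed Gaussian random walks for 3 translations (mm) and 3 rotations
#' (rad), rescaled so that a chosen fraction of frames exceeds the
#' framewise-displacement scrubbing threshold.
#'
#' @param n_timepoints number of frames.
#' @param spike_fraction target fraction of frames with FD above `fd_threshold`.
#' @param fd_threshold scrubbing threshold in mm (default 0.2).
#' @param seed RNG seed.
#' @return t x 6 numeric matrix with columns trans_x..rot_z.
#' @export
simulate_motion <- function(n_timepoints, spike_fraction = 0.05,
                            fd_threshold = 0.2, seed = 1) {
  set.seed(seed)
  inc <- matrix(stats::rnorm(n_timepoints * 6), n_timepoints, 6)
  # 3-point moving average smooths the walk increments
  inc <- apply(inc, 2, function(v) stats::filter(v, rep(1 / 3, 3), sides = 2))
  inc[is.na(inc)] <- 0
  m <- apply(inc, 2, cumsum)
  colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  fd <- framewise_displacement(m)
  pos <- fd[fd > 0]
  scale <- if (spike_fraction <= 0 || length(pos) == 0) {
    if (max(fd) > 0) 0.5 * fd_threshold / max(fd) else 1
  } else {
    q <- stats::quantile(pos, probs = 1 - spike_fraction, names = FALSE)
    fd_threshold / q
  }
  m * scale
}

# ascending staircase starting at 1 J with 0.25 J steps: snap a latent
# threshold UP to the first grid value at or above it
staircase_snap <- function(x) {
  x <- pmax(x, 1)
  1 + 0.25 * ceiling((x - 1) / 0.25 - 1e-9)
}

#' Simulate staircase-measured pain thresholds from planted features
#'
#' The latent threshold is an affine combination of planted feature columns
#' plus Gaussian noise. Each of two simulated measurements adds measurement
#' noise and snaps UP to the ascending 0.25 J staircase grid (1.00, 1.25,
#' 1.50, ...); the reported threshold is the mean of the two, so it lies on
#' the 0.125 J grid.
#'
#' @param features numeric matrix (subjects x features).
#' @param support integer column indices carrying the planted weights.
#' @param weights numeric weights, same length as `support`.
#' @param intercept latent intercept in Joules. The default 2.445, together
#'   with the other defaults, calibrates the reported population to
#'   approximately 2.57 +/- 0.53 J (snap-up adds about +0.125 J on average).
#' @param noise_sd latent noise sd (J).
#' @param measurement_sd per-measurement noise sd (J).
#' @param seed RNG seed.
#' @return tibble with `subject_id` and `threshold_J`.
#' @export
simulate_thresholds <- function(features, support = integer(0),
                                weights = numeric(0), intercept = 2.445,
                                noise_sd = 0.165, measurement_sd = 0.05,
                                seed = 1) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(support) != length(weights))
    stop("support and weights must have the same length")
  if (length(support) &&
      (min(support) < 1 || max(support) > ncol(features)))
    stop(sprintf("planted weight index out of range (features have %d columns)",
                 ncol(features)))
  set.seed(seed)
  signal <- if (length(support))
    as.vector(features[, support, drop = FALSE] %*% weights) else 0
  latent <- intercept + signal + stats::rnorm(n, sd = noise_sd)
  m1 <- staircase_snap(latent + stats::rnorm(n, sd = measurement_sd))
  m2 <- staircase_snap(latent + stats::rnorm(n, sd = measurement_sd))
  tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)),
                 threshold_J = (m1 + m2) / 2)
}

#' Configuration for the synthetic feature-table study
#'
#' Defaults are the study conditions for the desk-scale replication of the
#' cohort design: 210 subjects, 500 columns per regional block (ReHo, FA),
#' a 90-ROI connectivity layout (4005 columns for FC and SC), 10 planted
#' columns per block, and complementary cross-modality signal (`rho = 0`).
#'
#' @param n_subjects number of subjects.
#' @param n_regional number of columns in each regional block.
#' @param n_rois number of ROIs implied by the connectivity blocks
#'   (columns per block = n_rois * (n_rois - 1) / 2).
#' @param n_planted planted (signal-carrying) columns per block.
#' @param block_beta named per-block latent effect weights. The default
#'   0.263 per block makes each block's signal explain one quarter of the
#'   latent threshold variance; with `noise_sd = 0` the four blocks account
#'   for all of it, and the residual variance of the reported thresholds
#'   comes from the staircase observation model, keeping the population at
#'   about 2.57 +/- 0.53 J.
#' @param cross_modality_redundancy rho in \[0, 1\]: 1 = all blocks share one
#'   latent signal (redundant), 0 = independent block signals (complementary).
#' @param feature_noise_sd noise sd added to planted columns on top of the
#'   unit-variance block signal.
#' @param noise_sd residual latent threshold noise (J).
#' @param intercept,measurement_sd passed to [simulate_thresholds()].
#' @param seed RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 210, n_regional = 500, n_rois = 90,
                             n_planted = 10,
                             block_beta = c(reho = 0.263, fc = 0.263,
                                            fa = 0.263, sc = 0.263),
                             cross_modality_redundancy = 0,
                             feature_noise_sd = 0.5, noise_sd = 0,
                             intercept = 2.445, measurement_sd = 0.05,
                             seed = 1) {
  if (n_rois < 2) stop("n_rois must be at least 2")
  if (cross_modality_redundancy < 0 || cross_modality_redundancy > 1)
    stop("cross_modality_redundancy must lie in [0, 1]")
  if (feature_noise_sd < 0 || noise_sd < 0 || measurement_sd < 0)
    stop("all noise standard deviations must be nonnegative")
  blocks <- c("reho", "fc", "fa", "sc")
  if (is.null(names(block_beta)) && length(block_beta) == 4)
    names(block_beta) <- blocks
  if (!all(blocks %in% names(block_beta)))
    stop("block_beta must name all of reho, fc, fa, sc")
  structure(list(n_subjects = n_subjects, n_regional = n_regional,
                 n_rois = n_rois, n_planted = n_planted,
                 block_beta = block_beta[blocks],
                 cross_modality_redundancy = cross_modality_redundancy,
                 feature_noise_sd = feature_noise_sd, noise_sd = noise_sd,
                 intercept = intercept, measurement_sd = measurement_sd,
                 seed = seed),
            class = "generator_config")
}

#' Simulate the four feature blocks and matching pain thresholds
#'
#' Each block b carries a unit-variance latent signal
#' `s_b = sqrt(rho) g0 + sqrt(1 - rho) g_b` (g0 shared, g_b block-specific);
#' planted columns are `s_b` plus feature noise, null columns are iid
#' standard normal. The latent threshold combines the block signals with
#' weights `block_beta`, rescaled so its variance does not depend on rho,
#' and is observed through the two-measurement staircase.
#'
#' @param config a [generator_config()].
#' @return list with `tables` (named list of four [feature_table()]s:
#'   reho, fc, fa, sc), `phenotype` (tibble), and `planted` (per-block
#'   support indices and the latent block signals, for diagnostics).
#' @export
simulate_feature_tables <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  rho <- config$cross_modality_redundancy
  blocks <- c("reho", "fc", "fa", "sc")
  p_conn <- config$n_rois * (config$n_rois - 1) / 2
  p_block <- c(reho = config$n_regional, fc = p_conn,
               fa = config$n_regional, sc = p_conn)
  set.seed(config$seed)
  g0 <- stats::rnorm(n)
  signals <- sapply(blocks, function(b)
    sqrt(rho) * g0 + sqrt(1 - rho) * stats::rnorm(n))
  # lower-triangle ROI-pair metadata, row-major (i, j), i > j
  ij <- which(lower.tri(matrix(0, config$n_rois, config$n_rois)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  subject_ids <- sprintf("S%03d", seq_len(n))
  tables <- list()
  support <- list()
  for (b in blocks) {
    p <- p_block[[b]]
    if (config$n_planted > p) stop("n_planted exceeds block width")
    X <- matrix(stats::rnorm(n * p), n, p)
    sup <- sort(sample.int(p, config$n_planted))
    X[, sup] <- signals[, b] +
      matrix(stats::rnorm(n * config$n_planted, sd = config$feature_noise_sd),
             n, config$n_planted)
    meta <- if (b %in% c("reho", "fa")) {
      tibble::tibble(type = b, voxel = seq_len(p))
    } else {
      tibble::tibble(type = b, roi_a = ij[, 1], roi_b = ij[, 2])
    }
    tables[[b]] <- feature_table(X, meta, subject_ids)
    support[[b]] <- sup
  }
  beta <- config$block_beta
  raw_var <- rho * sum(beta)^2 + (1 - rho) * sum(beta^2)
  rescale <- sqrt(sum(beta^2) / raw_var)
  latent_signal <- as.vector(signals %*% beta) * rescale
  pheno <- simulate_thresholds(matrix(latent_signal, ncol = 1), support = 1L,
                               weights = 1, intercept = config$intercept,
                               noise_sd = config$noise_sd,
                               measurement_sd = config$measurement_sd,
                               seed = config$seed + 104729L)
  list(tables = tables, phenotype = pheno,
       planted = list(support = support, signals = signals,
                      latent_signal = latent_signal))
}
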