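# fMRI feature extraction: temporal preprocessing (discard, Friston-24,
# FD scrubbing with spike regressors, nuisance OLS, band-pass) and the two
# fMRI feature types: voxel-wise regional homogeneity (Kendall's W) and
# ROI-pair functional connectivity (Fisher-z Pearson correlation).

#' Discard initial BOLD volumes
#'
#' Drops the first `n` frames to remove pre-steady-state magnetisation
#' effects (300 acquired frames minus 10 leaves 290 analysed).
#'
#' @param bold a [bold_volume()].
#' @param n number of leading frames to drop (default 10).
#' @return A [bold_volume()] with `t - n` frames.
#' @export
discard_initial_volumes <- function(bold, n = 10) {
  stopifnot(inherits(bold, "bold_volume"))
  t <- dim(bold$data)[4]
  if (n == 0) return(bold)
  if (t <= n)
    stop(sprintf("cannot discard %d volumes from a series of length %d", n, t))
  bold_volume(bold$data[, , , (n + 1):t, drop = FALSE], bold$tr_s, bold$mask)
}

#' Friston 24-parameter motion expansion
#'
#' Expands the 6 rigid-body parameters into 24 regressors: the parameters,
#' the parameters one frame before (first row zero-filled), and the squares
#' of both.
#'
#' @param motion t x 6 numeric matrix (3 translations mm, 3 rotations rad).
#' @return t x 24 numeric matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6)
    stop(sprintf("motion must have 6 columns, got %d", ncol(motion)))
  lag <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag, motion^2, lag^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_lag"),
                     paste0("p", 1:6, "_sq"), paste0("p", 1:6, "_lag_sq"))
  out
}

#' Power-style framewise displacement
#'
#' FD(1) = 0; FD(t) is the sum of absolute frame-to-frame translation
#' changes (mm) plus `head_radius_mm` times the sum of absolute rotation
#' changes (rad), converting rotations to arc length on a sphere.
#'
#' @param motion t x 6 matrix (translations then rotations).
#' @param head_radius_mm assumed head radius, default 50.
#' @return numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("framewise displacement needs at least 2 frames")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' Scrubbing mask and spike regressors
#'
#' Frames with FD strictly above the threshold are scrubbed; each scrubbed
#' frame gets its own indicator ("spike") regressor so it can be modelled as
#' a separate covariate instead of deleted, preserving temporal continuity.
#' A frame with FD exactly at the threshold is kept.
#'
#' @param fd per-frame framewise displacement.
#' @param threshold scrubbing threshold in mm (default 0.2).
#' @return list with `keep` (logical vector) and `spikes`
#'   (t x n_scrubbed indicator matrix; zero columns if nothing scrubbed).
#' @export
scrub_mask <- function(fd, threshold = 0.2) {
  if (any(!is.finite(fd))) stop("fd must be finite")
  bad <- which(fd > threshold)
  spikes <- matrix(0, length(fd), length(bad))
  if (length(bad)) {
    spikes[cbind(bad, seq_along(bad))] <- 1
    colnames(spikes) <- paste0("spike_", bad)
  }
  list(keep = fd <= threshold, spikes = spikes)
}

#' Voxel-wise nuisance regression
#'
#' Ordinary least-squares residuals of every voxel's series on the design
#' matrix (an intercept is always added).
#'
#' @param bold a [bold_volume()].
#' @param design t x k numeric matrix (e.g. Friston-24 plus spikes).
#' @return A [bold_volume()] of residuals.
#' @export
nuisance_regress <- function(bold, design) {
  stopifnot(inherits(bold, "bold_volume"))
  t <- dim(bold$data)[4]
  design <- as.matrix(design)
  if (nrow(design) != t)
    stop(sprintf("design has %d rows but the series has %d frames",
                 nrow(design), t))
  if (ncol(design) > 0 && is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  X <- cbind(intercept = 1, design)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("design is rank-deficient; offending columns: %s",
                 paste(dropped, collapse = ", ")))
  }
  Y <- matrix(bold$data, prod(dim(bold$data)[1:3]), t)
  res <- t(qr.resid(qx, t(Y)))
  out <- bold
  out$data <- array(res, dim(bold$data))
  out
}

#' Ideal frequency-domain band-pass filter
#'
#' Per-voxel FFT after demeaning; frequency bins with
#' `low_hz <= f <= high_hz` are retained, everything else (including DC)
#' is zeroed.
#'
#' @param bold a [bold_volume()].
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.01 and 0.1).
#' @return A filtered [bold_volume()].
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(bold, "bold_volume"))
  t <- dim(bold$data)[4]
  nyquist <- 1 / (2 * bold$tr_s)
  if (low_hz < 0 || low_hz >= high_hz)
    stop("need 0 <= low_hz < high_hz")
  if (high_hz > nyquist + 1e-12)
    stop(sprintf("high_hz = %g exceeds the Nyquist frequency %g", high_hz, nyquist))
  Y <- t(matrix(bold$data, prod(dim(bold$data)[1:3]), t))  # t x V
  Y <- sweep(Y, 2, colMeans(Y))
  f <- pmin(0:(t - 1), t - (0:(t - 1))) / (t * bold$tr_s)
  keep <- f >= low_hz & f <= high_hz & (0:(t - 1)) != 0
  Fy <- stats::mvfft(Y)
  Fy[!keep, ] <- 0
  out <- bold
  out$data <- array(t(Re(stats::mvfft(Fy, inverse = TRUE)) / t),
                    dim(bold$data))
  out
}

# neighbourhood offsets within the 3x3x3 cube: 7 = faces, 19 = faces+edges,
# 27 = full cube (centre included in all)
cube_offsets <- function(neighborhood) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nn <- rowSums(abs(g))
  switch(as.character(neighborhood),
         "7" = g[nn <= 1, , drop = FALSE],
         "19" = g[nn <= 2, , drop = FALSE],
         "27" = g,
         stop("neighborhood must be one of 7, 19, 27"))
}

# Kendall's coefficient of concordance over K rank profiles of length n:
# W = 12 S / (K^2 (n^3 - n) - K * tie_term), S = sum_t (R_t - mean R)^2
kendall_w <- function(ranks, tie_correct = FALSE) {
  n <- nrow(ranks)
  K <- ncol(ranks)
  Rt <- rowSums(ranks)
  S <- sum((Rt - mean(Rt))^2)
  denom <- K^2 * (n^3 - n)
  if (tie_correct) {
    tt <- sum(apply(ranks, 2, function(r) {
      tb <- table(r)
      sum(tb^3 - tb)
    }))
    denom <- denom - K * tt
  }
  if (denom <= 0) return(NA_real_)
  12 * S / denom
}

#' Regional homogeneity map (Kendall's W)
#'
#' For each in-mask voxel, Kendall's coefficient of concordance of the time
#' series in the surrounding 3x3x3 block (truncated to in-mask members).
#' Ties receive average ranks; by default no tie-correction term is applied
#' to the denominator (the common toolbox convention), switchable with
#' `tie_correct`. Voxels with fewer than `k_min` in-mask neighbours, or
#' whose neighbourhood series are all constant, get W = 0 (the latter with
#' a warning).
#'
#' @param bold a preprocessed [bold_volume()].
#' @param mask optional 3D logical mask (defaults to the volume's mask).
#' @param neighborhood 7, 19 or 27 (default 27).
#' @param k_min minimum in-mask neighbourhood size (default 4).
#' @param tie_correct apply the tie-correction term in the denominator.
#' @return A [regional_map()] of kind `"reho"` with values in \[0, 1\].
#' @export
reho_map <- function(bold, mask = NULL, neighborhood = 27, k_min = 4,
                     tie_correct = FALSE) {
  stopifnot(inherits(bold, "bold_volume"))
  if (is.null(mask)) mask <- bold$mask
  sp <- dim(bold$data)[1:3]
  t <- dim(bold$data)[4]
  if (t < 3) stop("ReHo needs at least 3 timepoints")
  offs <- cube_offsets(neighborhood)
  vox <- which(mask)
  col_of <- array(0L, sp)
  col_of[vox] <- seq_along(vox)
  Y <- matrix(bold$data, prod(sp), t)[vox, , drop = FALSE]
  ranks <- t(apply(Y, 1, rank))           # V x t, average ranks on ties
  coords <- arrayInd(vox, sp)
  w <- numeric(length(vox))
  n_allconst <- 0L
  for (i in seq_along(vox)) {
    nb <- sweep(offs, 2, coords[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= sp[1] & nb[, 2] >= 1 & nb[, 2] <= sp[2] &
      nb[, 3] >= 1 & nb[, 3] <= sp[3]
    cols <- col_of[nb[ok, , drop = FALSE]]
    cols <- cols[cols > 0L]
    if (length(cols) < k_min) next
    rk <- t(ranks[cols, , drop = FALSE])  # t x K
    if (all(abs(rk - rk[1, ][col(rk)]) < .Machine$double.eps * t)) {
      # every series constant: ranks all tied, W undefined
      n_allconst <- n_allconst + 1L
      next
    }
    wi <- kendall_w(rk, tie_correct = tie_correct)
    w[i] <- if (is.na(wi)) 0 else wi
  }
  if (n_allconst > 0)
    warning(sprintf("%d voxel(s) had all-constant neighbourhood series; W set to 0",
                    n_allconst))
  out <- array(0, sp)
  out[vox] <- w
  regional_map(out, kind = "reho", mask = mask)
}

# 1D convolution of a 3D array along one axis with zero padding
conv_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1) / 2
  out <- array(0, dim(arr))
  n <- dim(arr)[axis]
  for (k in seq_along(kernel)) {
    s <- k - 1 - r                        # shift
    src <- seq_len(n) + s
    ok <- src >= 1 & src <= n
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (axis == 1) out[idx_dst, , ] <- out[idx_dst, , ] +
        kernel[k] * arr[idx_src, , , drop = FALSE]
    if (axis == 2) out[, idx_dst, ] <- out[, idx_dst, ] +
        kernel[k] * arr[, idx_src, , drop = FALSE]
    if (axis == 3) out[, , idx_dst] <- out[, , idx_dst] +
        kernel[k] * arr[, , idx_src, drop = FALSE]
  }
  out
}

#' Mask-aware Gaussian smoothing of a regional map
#'
#' Separable Gaussian kernel with sigma = FWHM / (2 sqrt(2 ln 2)) per axis in
#' voxel units; smoothing weights are renormalised over in-mask voxels
#' (smooth(map * mask) / smooth(mask)), so a constant map stays constant
#' inside the mask.
#'
#' @param map a [regional_map()].
#' @param fwhm_mm full width at half maximum in mm (default 6; 0 = identity).
#' @param voxel_size_mm length-3 physical voxel size.
#' @return A smoothed [regional_map()].
#' @export
smooth_gaussian <- function(map, fwhm_mm = 6, voxel_size_mm = c(3, 3, 3)) {
  stopifnot(inherits(map, "regional_map"))
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  if (fwhm_mm == 0) return(map)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  num <- map$data * map$mask
  den <- map$mask * 1
  for (axis in 1:3) {
    r <- max(1L, ceiling(4 * sigma[axis]))
    k <- stats::dnorm(-r:r, sd = sigma[axis])
    k <- k / sum(k)
    num <- conv_axis(num, k, axis)
    den <- conv_axis(den, k, axis)
  }
  out <- array(0, dim(map$data))
  out[map$mask] <- num[map$mask] / den[map$mask]
  regional_map(out, kind = map$kind, mask = map$mask)
}

#' Whole-brain equalisation of a regional map
#'
#' Divides every in-mask voxel by the in-mask mean (the "mReHo" convention),
#' so the equalised in-mask mean is exactly 1. With `method = "zscore"` the
#' map is standardised to in-mask mean 0, sd 1 instead.
#'
#' @param map a [regional_map()].
#' @param mask optional mask override.
#' @param method `"mean"` (default) or `"zscore"`.
#' @return An equalised [regional_map()].
#' @export
equalize <- function(map, mask = NULL, method = c("mean", "zscore")) {
  stopifnot(inherits(map, "regional_map"))
  method <- match.arg(method)
  if (is.null(mask)) mask <- map$mask
  v <- map$data[mask]
  mu <- mean(v)
  out <- array(0, dim(map$data))
  if (method == "mean") {
    if (abs(mu) < 1e-300) stop("in-mask mean is zero; cannot equalize")
    out[mask] <- v / mu
  } else {
    s <- stats::sd(v)
    if (s == 0) stop("in-mask sd is zero; cannot z-standardize")
    out[mask] <- (v - mu) / s
  }
  regional_map(out, kind = map$kind, mask = mask)
}

#' ROI mean time courses
#'
#' Row r is the unweighted mean over in-mask voxels with label r.
#'
#' @param bold a [bold_volume()].
#' @param parcellation integer label array aligned with the BOLD grid.
#' @return R x t numeric matrix with rownames `ROI_1..ROI_R`.
#' @export
roi_timecourses <- function(bold, parcellation) {
  stopifnot(inherits(bold, "bold_volume"))
  sp <- dim(bold$data)[1:3]
  if (!identical(dim(parcellation), sp))
    stop("parcellation grid does not match the BOLD spatial grid")
  R <- max(parcellation)
  t <- dim(bold$data)[4]
  Y <- matrix(bold$data, prod(sp), t)
  out <- matrix(0, R, t, dimnames = list(paste0("ROI_", seq_len(R)), NULL))
  for (r in seq_len(R)) {
    vox <- which(parcellation == r & bold$mask)
    if (!length(vox))
      stop(sprintf("ROI %d has no in-mask voxels", r))
    out[r, ] <- colMeans(Y[vox, , drop = FALSE])
  }
  out
}

#' Functional connectivity matrix (Fisher-z Pearson correlation)
#'
#' Pairwise Pearson correlations between ROI time courses, Fisher
#' z-transformed (z = arctanh(r), with r clipped to +/-(1 - 1e-7) to keep z
#' finite); the diagonal is stored as 0.
#'
#' @param timecourses R x t matrix from [roi_timecourses()].
#' @return A [connectivity_matrix()] of kind `"fc_fisher_z"`.
#' @export
fc_matrix <- function(timecourses) {
  tc <- as.matrix(timecourses)
  sds <- apply(tc, 1, stats::sd)
  if (any(sds == 0))
    stop(sprintf("constant time course for ROI(s): %s",
                 paste(which(sds == 0), collapse = ", ")))
  r <- stats::cor(t(tc))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  connectivity_matrix(z, kind = "fc_fisher_z", roi_labels = rownames(tc))
}

#' Vectorise the strictly-lower triangle of a connectivity matrix
#'
#' Row-major order over entries (i, j) with i > j; a 90-ROI matrix yields
#' 4005 features.
#'
#' @param m a [connectivity_matrix()] or square numeric matrix.
#' @return list with `values` (length R(R-1)/2) and `meta` (tibble with
#'   `roi_a` = row index i, `roi_b` = column index j, i > j).
#' @export
vectorize_lower <- function(m) {
  vals <- if (inherits(m, "connectivity_matrix")) m$values else m
  if (!is.matrix(vals) || nrow(vals) != ncol(vals))
    stop("input must be a square matrix")
  R <- nrow(vals)
  ij <- which(lower.tri(vals), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  list(values = vals[ij],
       meta = tibble::tibble(roi_a = ij[, 1], roi_b = ij[, 2]))
}

#' Rebuild a symmetric matrix from its strictly-lower triangle
#'
#' Inverse of [vectorize_lower()] (diagonal restored as 0).
#'
#' @param values vector of length R(R-1)/2.
#' @param n_rois matrix dimension R.
#' @return R x R symmetric numeric matrix.
#' @export
devectorize_lower <- function(values, n_rois) {
  if (length(values) != n_rois * (n_rois - 1) / 2)
    stop("length of values does not match n_rois (n_rois - 1) / 2")
  m <- matrix(0, n_rois, n_rois)
  ij <- which(lower.tri(m), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  m[ij] <- values
  m + t(m)
}

#' Standard fMRI temporal preprocessing chain
#'
#' Fixed order: discard initial volumes, then nuisance regression on the
#' Friston-24 motion expansion plus spike regressors for frames with
#' framewise displacement above the scrubbing threshold, then band-pass
#' filtering.
#'
#' @param bold raw [bold_volume()].
#' @param motion t x 6 motion matrix aligned with the raw series.
#' @param n_discard leading frames to drop (default 10).
#' @param fd_threshold scrubbing threshold in mm (default 0.2).
#' @param head_radius_mm FD head radius (default 50).
#' @param low_hz,high_hz band-pass edges (defaults 0.01, 0.1).
#' @return list with `bold` (preprocessed), `fd`, `keep`, `n_spikes`.
#' @export
preprocess_bold <- function(bold, motion, n_discard = 10, fd_threshold = 0.2,
                            head_radius_mm = 50, low_hz = 0.01, high_hz = 0.1) {
  motion <- as.matrix(motion)
  if (nrow(motion) != dim(bold$data)[4])
    stop("motion rows must match the raw BOLD series length")
  bold <- discard_initial_volumes(bold, n_discard)
  if (n_discard > 0) motion <- motion[-seq_len(n_discard), , drop = FALSE]
  fd <- framewise_displacement(motion, head_radius_mm)
  sc <- scrub_mask(fd, fd_threshold)
  design <- cbind(friston24(motion), sc$spikes)
  bold <- nuisance_regress(bold, design)
  bold <- bandpass(bold, low_hz, high_hz)
  list(bold = bold, fd = fd, keep = sc$keep, n_spikes = ncol(sc$spikes))
}
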