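# DTI feature extraction: voxel-wise fractional anisotropy from tensor
# eigenvalues, and ROI-pair structural connectivity probabilities from a
# stochastic streamline sampler that perturbs the principal tensor axis.

#' Fractional anisotropy from diffusion-tensor eigenvalues
#'
#' FA = sqrt(1/2) * sqrt(((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#' (l1^2 + l2^2 + l3^2)). Scale-invariant, 0 for a spherical diffusion
#' ellipsoid (equal eigenvalues) and 1 in the degenerate single-axis limit
#' (l, 0, 0).
#'
#' @param l1,l2,l3 nonnegative eigenvalues (vectorised).
#' @return FA value(s) in \[0, 1\].
#' @examples
#' fa_from_eigenvalues(1, 1, 1)   # 0
#' fa_from_eigenvalues(1, 0, 0)   # 1
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  if (any(l1 < 0 | l2 < 0 | l3 < 0))
    stop("eigenvalues must be nonnegative")
  ss <- l1^2 + l2^2 + l3^2
  if (any(ss == 0)) stop("all-zero eigenvalues have no defined FA")
  fa <- sqrt(0.5 * ((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2) / ss)
  pmin(pmax(fa, 0), 1)
}

# reassemble the 3x3 tensor at voxel linear index v
tensor_at <- function(field, v) {
  cp <- field$components
  step <- prod(dim(cp)[1:3])
  m <- cp[v + step * 0:5]
  matrix(c(m[1], m[2], m[3],
           m[2], m[4], m[5],
           m[3], m[5], m[6]), 3, 3)
}

#' Fractional anisotropy map from a tensor field
#'
#' Per in-mask voxel, FA from the eigenvalues of the reassembled 3x3 tensor;
#' out-of-mask voxels are 0. Tensors whose smallest eigenvalue is below
#' -1e-10 (relative to the largest) are rejected with the voxel index.
#'
#' @param field a [tensor_field()].
#' @return A [regional_map()] of kind `"fa"`.
#' @export
fa_map <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  sp <- dim(field$components)[1:3]
  out <- array(0, sp)
  vox <- which(field$mask)
  for (v in vox) {
    ev <- eigen(tensor_at(field, v), symmetric = TRUE, only.values = TRUE)$values
    tol <- 1e-10 * max(abs(ev), 1e-300)
    if (ev[3] < -tol) {
      ijk <- arrayInd(v, sp)
      stop(sprintf("tensor at voxel (%d, %d, %d) is not positive semi-definite",
                   ijk[1], ijk[2], ijk[3]))
    }
    ev <- pmax(ev, 0)
    out[v] <- if (sum(ev) == 0) 0 else
      fa_from_eigenvalues(ev[1], ev[2], ev[3])
  }
  regional_map(out, kind = "fa", mask = field$mask)
}

#' Principal diffusion direction of a tensor
#'
#' Unit eigenvector of the largest eigenvalue. The direction is
#' sign-ambiguous; a deterministic convention (largest-magnitude component
#' positive) is applied, and both signs are used during tracking. Degenerate
#' tensors (l1 close to l2) return an arbitrary but deterministic axis.
#'
#' @param tensor 3x3 symmetric PSD matrix.
#' @return unit length-3 numeric vector.
#' @export
principal_direction <- function(tensor) {
  e <- eigen(tensor, symmetric = TRUE)
  v <- e$vectors[, 1]
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Tractography parameters
#'
#' @param samples_per_voxel streamlines seeded per voxel (5000 in the full
#'   protocol; tests and desk-scale runs use far fewer — reaching
#'   probabilities are binomial proportions, so properties are stated in
#'   binomial standard errors and hold at any sample count).
#' @param step_mm step length in mm (default: half the smallest voxel size,
#'   resolved at tracking time when `NULL`).
#' @param max_steps hard cap on steps per streamline.
#' @param angle_limit_deg maximum turning angle between successive steps.
#' @param fa_stop stop when local FA falls below this (default 0.15).
#' @param direction_jitter_kappa concentration of the von Mises-Fisher-like
#'   perturbation around the principal axis; `Inf` = deterministic tracking.
#' @param count_mode `"membership"` counts a streamline once per target ROI
#'   it visits; `"first_hit"` counts only the first non-seed ROI entered.
#' @param seed RNG seed.
#' @return list of class `tractography_params`.
#' @export
tractography_params <- function(samples_per_voxel = 5000, step_mm = NULL,
                                max_steps = 500, angle_limit_deg = 45,
                                fa_stop = 0.15, direction_jitter_kappa = 50,
                                count_mode = c("membership", "first_hit"),
                                seed = 1) {
  if (samples_per_voxel < 1) stop("samples_per_voxel must be at least 1")
  if (!is.null(step_mm) && step_mm <= 0) stop("step_mm must be positive")
  if (fa_stop < 0 || fa_stop > 1) stop("fa_stop must lie in [0, 1]")
  if (direction_jitter_kappa <= 0)
    stop("direction_jitter_kappa must be positive")
  structure(list(samples_per_voxel = samples_per_voxel, step_mm = step_mm,
                 max_steps = max_steps, angle_limit_deg = angle_limit_deg,
                 fa_stop = fa_stop,
                 direction_jitter_kappa = direction_jitter_kappa,
                 count_mode = match.arg(count_mode), seed = seed),
            class = "tractography_params")
}

# precompute per-voxel FA and sign-fixed principal axes for tracking
field_geometry <- function(field) {
  sp <- dim(field$components)[1:3]
  fa <- fa_map(field)$data
  vox <- which(field$mask)
  axes <- matrix(0, prod(sp), 3)
  for (v in vox) axes[v, ] <- principal_direction(tensor_at(field, v))
  list(fa = fa, axes = axes, sp = sp, mask = field$mask,
       voxel_size = field$voxel_size_mm)
}

# one streamline from the centre of start voxel (1-based subscripts);
# geometry precomputed by field_geometry(); uses the current RNG stream
trace_streamline <- function(geom, start_voxel, params) {
  sp <- geom$sp
  step_mm <- if (is.null(params$step_mm)) min(geom$voxel_size) / 2 else
    params$step_mm
  step_vox <- step_mm / geom$voxel_size
  cos_lim <- cos(params$angle_limit_deg * pi / 180)
  kappa <- params$direction_jitter_kappa
  pos <- as.numeric(start_voxel)
  prev <- NULL
  path <- matrix(0L, params$max_steps + 1L, 3L)
  npath <- 0L
  for (s in seq_len(params$max_steps + 1L)) {
    v <- round(pos)
    if (any(v < 1) || any(v > sp)) break
    vlin <- v[1] + (v[2] - 1) * sp[1] + (v[3] - 1) * sp[1] * sp[2]
    if (npath == 0L || any(path[npath, ] != v)) {
      npath <- npath + 1L
      path[npath, ] <- v
    }
    if (!geom$mask[vlin] || geom$fa[vlin] < params$fa_stop) break
    if (s > params$max_steps) break
    axis <- geom$axes[vlin, ]
    if (!is.null(prev) && sum(axis * prev) < 0) axis <- -axis
    dir <- if (is.infinite(kappa)) axis else {
      d <- kappa * axis + stats::rnorm(3)
      d / sqrt(sum(d^2))
    }
    if (!is.null(prev) && sum(dir * prev) < cos_lim) break
    pos <- pos + dir * step_vox
    prev <- dir
  }
  if (npath == 0L)
    return(matrix(as.integer(start_voxel), 1L, 3L))
  path[seq_len(npath), , drop = FALSE]
}

#' Track a single streamline
#'
#' Iterative stepping from a seed voxel: at each step the direction is
#' sampled around the local principal axis with the configured
#' concentration, its sign chosen to keep the turning angle minimal;
#' tracking stops on mask exit, FA below `fa_stop`, an angle violation, or
#' `max_steps`.
#'
#' @param field a [tensor_field()].
#' @param start_voxel length-3 integer voxel subscript (1-based).
#' @param params a [tractography_params()].
#' @return integer matrix of visited voxel subscripts (one row per voxel,
#'   in visit order; length-1 path for degenerate starts).
#' @export
track_streamline <- function(field, start_voxel, params = tractography_params()) {
  geom <- field_geometry(field)
  set.seed(params$seed)
  trace_streamline(geom, start_voxel, params)
}

#' Structural connectivity probability matrix
#'
#' Seeds `samples_per_voxel` streamlines from every in-mask voxel of each
#' ROI; entry (i, j) is the number of streamlines seeded in ROI i whose path
#' passes through ROI j, divided by the total number seeded in ROI i
#' (samples_per_voxel times the voxel count of i). The diagonal is 0. Rows
#' are reproducible given the seed.
#'
#' @param field a [tensor_field()].
#' @param parcellation label array aligned with the field.
#' @param params a [tractography_params()].
#' @return A [connectivity_matrix()] of kind `"sc_probability"`.
#' @export
structural_connectivity <- function(field, parcellation,
                                    params = tractography_params()) {
  stopifnot(inherits(field, "tensor_field"))
  sp <- dim(field$components)[1:3]
  if (!identical(dim(parcellation), sp))
    stop("parcellation grid does not match the tensor field")
  R <- max(parcellation)
  geom <- field_geometry(field)
  P <- matrix(0, R, R)
  for (i in seq_len(R)) {
    vox <- which(parcellation == i & field$mask)
    if (!length(vox)) stop(sprintf("ROI %d has no in-mask voxels", i))
    set.seed(params$seed + 7919L * i)
    counts <- numeric(R)
    coords <- arrayInd(vox, sp)
    for (k in seq_along(vox)) {
      for (s in seq_len(params$samples_per_voxel)) {
        path <- trace_streamline(geom, coords[k, ], params)
        labs <- parcellation[path]
        if (params$count_mode == "first_hit") {
          hit <- labs[labs != 0 & labs != i]
          if (length(hit)) counts[hit[1]] <- counts[hit[1]] + 1
        } else {
          for (j in unique(labs))
            if (j != 0 && j != i) counts[j] <- counts[j] + 1
        }
      }
    }
    P[i, ] <- counts / (params$samples_per_voxel * length(vox))
  }
  diag(P) <- 0
  connectivity_matrix(P, kind = "sc_probability")
}

#' Symmetrise a structural connectivity matrix
#'
#' Tractography reaching probabilities are directional; (A + t(A)) / 2 is
#' the symmetrised matrix whose strict lower triangle enters the feature
#' vector, giving SC the same 4005-length layout as FC at 90 ROIs. The
#' asymmetry (max |A - t(A)|) is attached as attribute `"asymmetry"`.
#'
#' @param sc a [connectivity_matrix()] of kind `"sc_probability"`.
#' @return A symmetrised [connectivity_matrix()] of the same kind.
#' @export
symmetrize_sc <- function(sc) {
  stopifnot(inherits(sc, "connectivity_matrix"), sc$kind == "sc_probability")
  sym <- (sc$values + t(sc$values)) / 2
  out <- connectivity_matrix(sym, kind = "sc_probability",
                             roi_labels = sc$roi_labels)
  attr(out, "asymmetry") <- max(abs(sc$values - t(sc$values)))
  out
}
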