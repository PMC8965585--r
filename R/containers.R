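#' painfuse: multimodal MRI feature fusion for pain-sensitivity prediction
#'
#' Core containers are lightweight S3 lists. All voxel indices are 1-based
#' linear indices into the volume array (R convention); ROI labels are
#' integers 1..R with 0 reserved for background.
#'
#' @keywords internal
"_PACKAGE"

#' BOLD volume container
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr_s repetition time in seconds.
#' @param mask 3D logical array matching the spatial grid; defaults to all
#'   voxels in-mask.
#' @return An object of class `bold_volume`.
#' @export
bold_volume <- function(data, tr_s, mask = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 4)
  if (dim(data)[4] < 2) stop("a BOLD volume needs at least 2 timepoints")
  if (!is.numeric(tr_s) || length(tr_s) != 1 || tr_s <= 0)
    stop("tr_s must be a single positive number")
  sp <- dim(data)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  if (!identical(dim(mask), sp))
    stop("mask shape must equal the spatial shape of the data")
  structure(list(data = data, tr_s = tr_s, mask = mask > 0),
            class = "bold_volume")
}

#' @export
print.bold_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_volume> %dx%dx%d voxels, %d timepoints, TR = %g s, %d in mask\n",
              d[1], d[2], d[3], d[4], x$tr_s, sum(x$mask)))
  invisible(x)
}

#' Diffusion tensor field container
#'
#' Tensors are stored as their 6 unique components per voxel, in the order
#' xx, xy, xz, yy, yz, zz (a 4D array with 6 volumes).
#'
#' @param components 4D numeric array (x, y, z, 6).
#' @param voxel_size_mm length-3 positive numeric, physical voxel size.
#' @param mask 3D logical array; defaults to all in-mask.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(components, voxel_size_mm = c(2, 2, 2), mask = NULL) {
  stopifnot(is.array(components), length(dim(components)) == 4)
  if (dim(components)[4] != 6)
    stop("components must carry 6 volumes (xx, xy, xz, yy, yz, zz)")
  if (length(voxel_size_mm) != 3 || any(voxel_size_mm <= 0))
    stop("voxel_size_mm must be 3 positive numbers")
  sp <- dim(components)[1:3]
  if (is.null(mask)) mask <- array(TRUE, sp)
  if (!identical(dim(mask), sp)) stop("mask shape must equal the spatial shape")
  structure(list(components = components,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 mask = mask > 0),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$components)
  cat(sprintf("<tensor_field> %dx%dx%d voxels (%s mm), %d in mask\n",
              d[1], d[2], d[3], paste(x$voxel_size_mm, collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' Regional scalar map container (ReHo or FA)
#'
#' @param data 3D numeric array.
#' @param kind `"reho"` or `"fa"`.
#' @param mask 3D logical array.
#' @return An object of class `regional_map`.
#' @export
regional_map <- function(data, kind = c("reho", "fa"), mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  if (!identical(dim(mask), dim(data))) stop("mask shape must equal map shape")
  if (any(!is.finite(data[mask > 0])))
    stop("regional map must be finite inside the mask")
  structure(list(data = data, kind = kind, mask = mask > 0),
            class = "regional_map")
}

#' @export
print.regional_map <- function(x, ...) {
  cat(sprintf("<regional_map:%s> %s, range [%.3g, %.3g] in mask\n", x$kind,
              paste(dim(x$data), collapse = "x"),
              min(x$data[x$mask]), max(x$data[x$mask])))
  invisible(x)
}

#' ROI-pair connectivity matrix container
#'
#' Functional connectivity (`fc_fisher_z`) is symmetric with the diagonal
#' stored as 0 after the Fisher transform; structural connectivity
#' (`sc_probability`) holds reaching probabilities in \[0, 1\] and may be
#' asymmetric.
#'
#' @param values R x R numeric matrix.
#' @param kind `"fc_fisher_z"` or `"sc_probability"`.
#' @param roi_labels optional character labels, length R.
#' @return An object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind = c("fc_fisher_z", "sc_probability"),
                                roi_labels = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(roi_labels)) roi_labels <- paste0("ROI_", seq_len(nrow(values)))
  if (length(roi_labels) != nrow(values)) stop("roi_labels length mismatch")
  if (kind == "fc_fisher_z" && max(abs(values - t(values))) > 1e-8)
    stop("functional connectivity matrix must be symmetric")
  if (kind == "sc_probability" &&
      (min(values) < -1e-12 || max(values) > 1 + 1e-12))
    stop("structural connectivity probabilities must lie in [0, 1]")
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(list(values = values, kind = kind, roi_labels = roi_labels),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix:%s> %d ROIs\n", x$kind, nrow(x$values)))
  invisible(x)
}

#' Subjects-by-features table with per-feature metadata
#'
#' @param matrix numeric matrix, subjects in rows.
#' @param feature_meta tibble with one row per column: `type` (one of reho,
#'   fa, fc, sc) plus either `voxel` (1-based linear voxel index, regional
#'   types) or `roi_a`/`roi_b` (connectivity types).
#' @param subject_ids character or integer vector, one per row.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(matrix, feature_meta, subject_ids = NULL) {
  stopifnot(is.matrix(matrix))
  if (anyNA(matrix)) stop("feature table must not contain missing values")
  if (nrow(feature_meta) != ncol(matrix))
    stop("feature_meta must have one row per feature column")
  if (!all(feature_meta$type %in% c("reho", "fa", "fc", "sc")))
    stop("feature type tags must be in {reho, fa, fc, sc}")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(matrix)))
  if (length(subject_ids) != nrow(matrix)) stop("subject_ids length mismatch")
  structure(list(matrix = matrix,
                 feature_meta = tibble::as_tibble(feature_meta),
                 subject_ids = as.character(subject_ids)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(unique(x$feature_meta$type), collapse = ", ")))
  invisible(x)
}

# internal constructor for out-of-fold prediction results
new_prediction_result <- function(predicted, true, subject_ids,
                                  per_fold_selected, model_spec,
                                  feature_meta = NULL) {
  stopifnot(length(predicted) == length(true),
            length(per_fold_selected) == length(true))
  structure(list(predicted = as.numeric(predicted), true = as.numeric(true),
                 subject_ids = as.character(subject_ids),
                 per_fold_selected = per_fold_selected,
                 model_spec = model_spec, feature_meta = feature_meta),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  r <- tryCatch(stats::cor(x$predicted, x$true), error = function(e) NA_real_)
  cat(sprintf("<prediction_result> %d subjects, model [%s], out-of-fold r = %.3f\n",
              length(x$true),
              paste(x$model_spec$feature_types, collapse = "+"), r))
  invisible(x)
}
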