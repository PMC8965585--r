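# Selection-frequency stability: which features are selected in more than
# half of the leave-one-out folds, and where they sit anatomically.

#' Per-feature selection frequency across LOOCV folds
#'
#' frequency = (number of folds selecting the feature) / (total folds).
#' Only single-feature-type results carry a flat per-fold selection log; for
#' fused models, compute stability on each constituent single-type result.
#'
#' @param result a single-type `prediction_result`.
#' @return tibble (stability table) with the feature metadata columns,
#'   `feature` (column index) and `frequency`.
#' @export
selection_frequency <- function(result) {
  stopifnot(inherits(result, "prediction_result"))
  sel <- result$per_fold_selected
  if (any(vapply(sel, is.null, logical(1))))
    stop("missing per-fold selection log")
  if (any(vapply(sel, is.list, logical(1))))
    stop("fused result: compute selection frequency on each constituent single-type model")
  if (is.null(result$feature_meta))
    stop("result carries no feature metadata")
  n_folds <- length(sel)
  p <- nrow(result$feature_meta)
  counts <- tabulate(unlist(sel), nbins = p)
  out <- result$feature_meta
  out$feature <- seq_len(p)
  out$frequency <- counts / n_folds
  out
}

#' Common predictive features
#'
#' Features selected in strictly more than `threshold` of the folds
#' ("more than half of the time"): a frequency of exactly 0.5 is not
#' retained at the default threshold.
#'
#' @param stability_table tibble from [selection_frequency()].
#' @param threshold retention threshold (default 0.5, strict inequality).
#' @return the retained subset of the stability table.
#' @export
common_features <- function(stability_table, threshold = 0.5) {
  stability_table[stability_table$frequency > threshold, , drop = FALSE]
}

#' Annotate retained features with region labels
#'
#' Regional features (reho, fa) are mapped voxel -> ROI through the
#' parcellation; connectivity features (fc, sc) are mapped to
#' order-normalised ROI-pair names. Also returns per-region voxel counts
#' and per-region-pair edge counts.
#'
#' @param features stability-table subset (e.g. from [common_features()]).
#' @param parcellation label array (needed for regional features).
#' @param label_names optional character vector of region names, length R.
#' @return list with `features` (annotated tibble), `regional_counts`
#'   (tibble region / n_voxels) and `edge_counts`
#'   (tibble region_a / region_b / n_edges).
#' @export
annotate_regions <- function(features, parcellation = NULL,
                             label_names = NULL) {
  R <- if (!is.null(parcellation)) max(parcellation) else
    max(c(features$roi_a, features$roi_b, 0), na.rm = TRUE)
  if (is.null(label_names)) label_names <- paste0("ROI_", seq_len(R))
  if (length(label_names) < R) stop("label_names shorter than the label range")
  regional <- features$type %in% c("reho", "fa")
  region <- character(nrow(features))
  if (any(regional)) {
    if (is.null(parcellation))
      stop("regional features need a parcellation for annotation")
    vox <- features$voxel[regional]
    if (any(vox < 1 | vox > length(parcellation)))
      stop(sprintf("voxel index out of range: %s",
                   paste(vox[vox < 1 | vox > length(parcellation)],
                         collapse = ", ")))
    lab <- parcellation[vox]
    region[regional] <- ifelse(lab == 0, "background", label_names[pmax(lab, 1)])
  }
  if (any(!regional)) {
    a <- features$roi_a[!regional]
    b <- features$roi_b[!regional]
    if (any(c(a, b) < 1 | c(a, b) > R))
      stop("ROI pair index out of label range")
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    region[!regional] <- paste0(label_names[lo], "-", label_names[hi])
  }
  out <- features
  out$region <- region
  regional_counts <- if (any(regional)) {
    tb <- table(region[regional])
    tibble::tibble(region = names(tb), n_voxels = as.integer(tb))
  } else tibble::tibble(region = character(), n_voxels = integer())
  edge_counts <- if (any(!regional)) {
    a <- features$roi_a[!regional]
    b <- features$roi_b[!regional]
    key <- paste(pmin(a, b), pmax(a, b))
    tb <- table(key)
    ab <- do.call(rbind, lapply(strsplit(names(tb), " "), as.integer))
    tibble::tibble(region_a = label_names[ab[, 1]],
                   region_b = label_names[ab[, 2]],
                   n_edges = as.integer(tb))
  } else tibble::tibble(region_a = character(), region_b = character(),
                        n_edges = integer())
  list(features = out, regional_counts = regional_counts,
       edge_counts = edge_counts)
}
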