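# File I/O: NIfTI volumes via RNifti, TSV tables via readr, JSON configs via
# jsonlite. Every file written through write_with_sidecar() gets a companion
# .json recording the producing config hash and seed.

#' Read / write a NIfTI volume
#'
#' Thin wrappers over RNifti preserving the array and (for writing with a
#' template) the affine. Voxel indices elsewhere in the package are 1-based
#' linear indices into these arrays; no reorientation is performed — inputs
#' are assumed co-registered.
#'
#' @param path file path (.nii or .nii.gz).
#' @return `read_nifti_volume`: numeric array with RNifti attributes.
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  RNifti::readNifti(path)
}

#' @rdname read_nifti_volume
#' @param data numeric array (3D or 4D).
#' @param pixdim physical voxel sizes for the spatial axes.
#' @export
write_nifti_volume <- function(data, path, pixdim = c(3, 3, 3)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(pixdim, rep(1, length(dim(data)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a parcellation volume
#'
#' Labels must be integers 0 (background) and 1..R with every label in that
#' range present; anything else is rejected with the offending values.
#'
#' @param path NIfTI path.
#' @return integer 3D label array with attribute `n_rois`.
#' @export
read_parcellation <- function(path) {
  arr <- round(as.array(read_nifti_volume(path)))
  labs <- sort(unique(as.vector(arr)))
  R <- max(labs)
  expected <- c(if (0 %in% labs) 0, seq_len(R))
  bad <- setdiff(labs, expected)
  missing_l <- setdiff(seq_len(R), labs)
  if (length(bad) || length(missing_l))
    stop(sprintf("parcellation labels must be 0..R contiguous; offenders: %s",
                 paste(c(bad, missing_l), collapse = ", ")))
  storage.mode(arr) <- "integer"
  attr(arr, "n_rois") <- as.integer(R)
  arr
}

#' @rdname read_parcellation
#' @param parcellation integer label array.
#' @param pixdim voxel sizes.
#' @export
write_parcellation <- function(parcellation, path, pixdim = c(3, 3, 3)) {
  write_nifti_volume(parcellation + 0L, path, pixdim)
}

#' Read / write a tensor field as a 6-volume NIfTI
#'
#' Component order xx, xy, xz, yy, yz, zz along the 4th dimension.
#'
#' @param path NIfTI path.
#' @param mask optional mask for the returned [tensor_field()].
#' @return A [tensor_field()].
#' @export
read_tensor_field <- function(path, mask = NULL) {
  img <- read_nifti_volume(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 4 || dim(arr)[4] != 6)
    stop("a tensor file must hold 6 volumes (xx, xy, xz, yy, yz, zz)")
  vs <- RNifti::pixdim(img)[1:3]
  if (any(vs <= 0)) vs <- c(2, 2, 2)
  tensor_field(arr, voxel_size_mm = vs, mask = mask)
}

#' @rdname read_tensor_field
#' @param field a [tensor_field()].
#' @export
write_tensor_field <- function(field, path) {
  write_nifti_volume(field$components, path, pixdim = field$voxel_size_mm)
}

#' Read / write a feature table as TSV
#'
#' The data file has `subject_id` plus one column per feature; a companion
#' `<path>.meta.tsv` stores the per-feature metadata (type and 1-based voxel
#' index or ROI pair).
#'
#' @param path TSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  meta_path <- paste0(path, ".meta.tsv")
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  if (!file.exists(meta_path)) stop(sprintf("no such file: %s", meta_path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  feature_table(m, meta, subject_ids = df$subject_id)
}

#' @rdname read_feature_table
#' @param table a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- tibble::as_tibble(table$matrix, .name_repair = "minimal")
  names(df) <- sprintf("feat_%05d", seq_len(ncol(df)))
  df <- tibble::add_column(df, subject_id = table$subject_ids, .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  readr::write_tsv(table$feature_meta, paste0(path, ".meta.tsv"),
                   progress = FALSE)
  invisible(path)
}

#' Read / write a phenotype table (subject_id, threshold_J)
#'
#' @param path TSV path.
#' @return tibble.
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("subject_id", "threshold_J") %in% names(ph)))
    stop("phenotype table needs subject_id and threshold_J columns")
  if (any(ph$threshold_J <= 0)) stop("thresholds must be positive")
  ph
}

#' @rdname read_phenotype
#' @param phenotype tibble with subject_id and threshold_J.
#' @export
write_phenotype <- function(phenotype, path) {
  readr::write_tsv(phenotype, path, progress = FALSE)
  invisible(path)
}

#' Read a motion-parameter table (t x 6, header optional)
#'
#' @param path TSV path.
#' @return t x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1)
  has_header <- any(grepl("[A-Za-z]", strsplit(first, "\t")[[1]]))
  m <- as.matrix(utils::read.table(path, header = has_header, sep = "\t"))
  if (ncol(m) != 6) stop(sprintf("motion table must have 6 columns, got %d",
                                 ncol(m)))
  storage.mode(m) <- "double"
  m
}

#' Serialise / deserialise a run configuration as JSON
#'
#' `read_config` validates against the known key set of the given
#' constructor and rejects unknown keys.
#'
#' @param config a `generator_config` or `study_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @param constructor the config constructor the file must match
#'   (default [generator_config()]).
#' @export
read_config <- function(path, constructor = generator_config) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(constructor))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  do.call(constructor, raw)
}

#' Write a file with a provenance sidecar
#'
#' Calls `writer(object, path)` and then writes `<path>.json` recording the
#' seed and a hash of the producing configuration.
#'
#' @param object object to write.
#' @param path destination path.
#' @param writer writing function taking (object, path).
#' @param config configuration to hash into the sidecar.
#' @param seed resolved RNG seed.
#' @export
write_with_sidecar <- function(object, path, writer, config, seed) {
  writer(object, path)
  jsonlite::write_json(list(config_hash = rlang::hash(unclass(config)),
                            seed = seed,
                            written = format(Sys.time(), tz = "UTC")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
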