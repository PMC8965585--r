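# End-to-end synthetic imaging study: simulate a cohort's volumes, extract
# all four feature types, run the nine-model suite, and write the report
# and stability tables. This is the "run everything" entry point the
# analysis scripts drive.

#' Configuration for the end-to-end imaging study
#'
#' Defaults define a desk-scale cohort: an 8x8x8 grid with 6 connected
#' ROIs, 40 subjects, 60 BOLD frames at TR 2 s, and a cheap tractography
#' setting (2 streamlines per seed voxel — SC probabilities are binomial
#' proportions, so the pipeline is unchanged at any sample count).
#' A per-subject latent trait u drives the planted signal in all four
#' feature types: the ROI 1-2 BOLD covariance, local BOLD coherence, the
#' ROI 1-2 white-matter bundle FA, and (through u) the pain threshold.
#'
#' @param grid_dims,n_rois,n_subjects,n_timepoints,tr_s cohort geometry.
#' @param samples_per_voxel tractography seeds per voxel.
#' @param latent_beta effect of the latent trait on the threshold (J per sd).
#' @param seed RNG seed.
#' @return list of class `study_config`.
#' @export
study_config <- function(grid_dims = c(8, 8, 8), n_rois = 6, n_subjects = 40,
                         n_timepoints = 60, tr_s = 2, samples_per_voxel = 2,
                         latent_beta = 0.35, seed = 1) {
  if (n_timepoints < 20) stop("n_timepoints must be at least 20")
  structure(list(grid_dims = grid_dims, n_rois = n_rois,
                 n_subjects = n_subjects, n_timepoints = n_timepoints,
                 tr_s = tr_s, samples_per_voxel = samples_per_voxel,
                 latent_beta = latent_beta, seed = seed),
            class = "study_config")
}

# extract all four feature blocks for one simulated subject
simulate_subject_features <- function(parcellation, u, cfg, subject_seed) {
  R <- cfg$n_rois
  # fMRI: ROI covariance with a u-modulated 1-2 edge, u-modulated coherence
  rho12 <- tanh(0.6 + 0.5 * u)
  cov <- diag(R)
  cov[1, 2] <- cov[2, 1] <- rho12
  bold <- simulate_bold(parcellation, cfg$n_timepoints, cfg$tr_s,
                        roi_cov = cov,
                        local_coherence = min(max(0.55 + 0.2 * u, 0.05), 0.95),
                        noise_sd = 1, seed = subject_seed)
  motion <- simulate_motion(cfg$n_timepoints, spike_fraction = 0.05,
                            seed = subject_seed + 1L)
  prep <- preprocess_bold(bold, motion)
  reho <- equalize(smooth_gaussian(reho_map(prep$bold), fwhm_mm = 6,
                                   voxel_size_mm = c(3, 3, 3)))
  fc <- fc_matrix(roi_timecourses(prep$bold, parcellation))
  # DTI: low-FA background, one ROI 1-2 bundle whose FA and calibre track u
  # (a wider corridor recruits more seed voxels, so the reaching
  # probability carries the trait too)
  bundle_fa <- min(max(0.55 + 0.12 * u, 0.2), 0.9)
  field <- simulate_tensor_field(
    parcellation, fa_targets = 0.05,
    bundle_specs = list(list(roi_a = 1, roi_b = 2,
                             width = min(max(1.2 + 0.45 * u, 0.7), 2.5),
                             fa = bundle_fa)),
    seed = subject_seed + 2L)
  fa <- fa_map(field)
  sc <- symmetrize_sc(structural_connectivity(
    field, parcellation,
    tractography_params(samples_per_voxel = cfg$samples_per_voxel,
                        seed = subject_seed + 3L)))
  list(reho = reho, fc = fc, fa = fa, sc = sc)
}

#' Run the full synthetic study end to end
#'
#' Simulates the cohort (volumes, motion, tensors, staircase thresholds),
#' extracts ReHo, FC, FA and SC features for every subject, runs the
#' nine-model leave-one-out suite, evaluates it, computes per-type
#' selection-frequency stability, and (optionally) writes the
#' Table-1-shaped report, Table-2/3-shaped stability tables and per-subject
#' predictions as TSVs with provenance sidecars under `out_dir`.
#'
#' @param config a [study_config()].
#' @param out_dir output directory (NULL = return results only).
#' @param verbose print progress.
#' @return list with `tables`, `phenotype`, `suite`, `report`, `stability`,
#'   `parcellation`, `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  parcellation <- make_parcellation(config$grid_dims, config$n_rois,
                                    seed = config$seed)
  set.seed(config$seed + 555L)
  u <- stats::rnorm(config$n_subjects)
  feats <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    feats[[s]] <- simulate_subject_features(parcellation, u[s], config,
                                            subject_seed = config$seed + 101L * s)
    if (verbose && s %% 10 == 0)
      message(sprintf("  extracted features for %d / %d subjects",
                      s, config$n_subjects))
  }
  vox <- which(parcellation > 0)
  subject_ids <- sprintf("S%03d", seq_len(config$n_subjects))
  regional_meta <- function(type) tibble::tibble(type = type, voxel = vox)
  stack_regional <- function(kind)
    do.call(rbind, lapply(feats, function(f) f[[kind]]$data[vox]))
  lower_meta <- vectorize_lower(feats[[1]]$fc)$meta
  stack_conn <- function(kind)
    do.call(rbind, lapply(feats, function(f) vectorize_lower(f[[kind]])$values))
  tables <- list(
    reho = feature_table(stack_regional("reho"), regional_meta("reho"),
                         subject_ids),
    fc = feature_table(stack_conn("fc"),
                       tibble::add_column(lower_meta, type = "fc", .before = 1),
                       subject_ids),
    fa = feature_table(stack_regional("fa"), regional_meta("fa"), subject_ids),
    sc = feature_table(stack_conn("sc"),
                       tibble::add_column(lower_meta, type = "sc", .before = 1),
                       subject_ids))
  phenotype <- simulate_thresholds(matrix(u, ncol = 1), support = 1L,
                                   weights = config$latent_beta,
                                   noise_sd = 0.35,
                                   seed = config$seed + 999L)
  if (verbose) message("  running the nine-model suite")
  suite <- run_model_suite(tables, phenotype, seed = config$seed)
  report <- build_report(suite)
  stability <- lapply(suite[c("reho", "fc", "fa", "sc")], function(res)
    annotate_regions(common_features(selection_frequency(res)), parcellation))
  out <- list(tables = tables, phenotype = phenotype, suite = suite,
              report = report, stability = stability,
              parcellation = parcellation, config = config)
  if (!is.null(out_dir)) write_study_outputs(out, out_dir)
  out
}

# write the Table-1/2/3-shaped TSVs plus predictions, with sidecars
write_study_outputs <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  w <- function(obj, name, writer = function(o, p)
    readr::write_tsv(o, p, progress = FALSE))
    write_with_sidecar(obj, file.path(out_dir, name), writer, cfg, cfg$seed)
  w(study$report$per_model, "model_performance.tsv")
  w(study$report$pairwise, "model_comparisons.tsv")
  preds <- do.call(rbind, lapply(names(study$suite), function(m) {
    r <- study$suite[[m]]
    tibble::tibble(model = m, subject_id = r$subject_ids,
                   true_J = r$true, predicted_J = r$predicted)
  }))
  w(preds, "predictions.tsv")
  for (b in names(study$stability)) {
    w(study$stability[[b]]$features, sprintf("stable_features_%s.tsv", b))
    reg <- study$stability[[b]]$regional_counts
    if (nrow(reg)) w(reg, sprintf("stable_regions_%s.tsv", b))
    edg <- study$stability[[b]]$edge_counts
    if (nrow(edg)) w(edg, sprintf("stable_edges_%s.tsv", b))
  }
  w(study$phenotype, "phenotype.tsv")
  write_with_sidecar(study$parcellation, file.path(out_dir, "parcellation.nii"),
                     function(o, p) write_parcellation(o, p), cfg, cfg$seed)
  invisible(out_dir)
}
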