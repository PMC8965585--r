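#!/usr/bin/env Rscript
# Stage 5: selection-frequency stability. From the stage-3 selection logs,
# compute each feature's fold-selection frequency, keep the "common
# predictive features" (selected in more than half of the folds), annotate
# them with region labels, and check recovery of the planted support.
# Writes results/stability/.
suppressMessages(library(painfuse))

ind_s <- file.path("results", "study")
ind_p <- file.path("results", "predictions")
out <- file.path("results", "stability")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- read_config(file.path(ind_s, "generator_config.json"))
planted <- jsonlite::read_json(file.path(ind_s, "planted_support.json"),
                               simplifyVector = TRUE)
# a synthetic parcellation to exercise the voxel -> region annotation of
# the regional (voxel-indexed) feature blocks
parc <- make_parcellation(c(10, 10, 5), n_rois = 25, seed = cfg$seed)

for (b in c("reho", "fc", "fa", "sc")) {
  meta <- read_feature_table(file.path(ind_s, paste0("features_", b,
                                                     ".tsv")))$feature_meta
  log <- readr::read_tsv(file.path(ind_p, paste0("selection_log_", b, ".tsv")),
                         show_col_types = FALSE, progress = FALSE)
  n_folds <- cfg$n_subjects
  freq <- tabulate(log$feature, nbins = nrow(meta)) / n_folds
  tab <- meta
  tab$feature <- seq_len(nrow(meta))
  tab$frequency <- freq
  kept <- common_features(tab)
  ann <- if (b %in% c("reho", "fa")) annotate_regions(kept, parc) else
    annotate_regions(kept, label_names = paste0("ROI_", seq_len(cfg$n_rois)))
  write_with_sidecar(ann$features, file.path(out, paste0("stable_features_",
                                                         b, ".tsv")),
                     function(o, p) readr::write_tsv(o, p, progress = FALSE),
                     cfg, cfg$seed)
  counts <- if (b %in% c("reho", "fa")) ann$regional_counts else ann$edge_counts
  write_with_sidecar(counts, file.path(out, paste0("stable_counts_", b, ".tsv")),
                     function(o, p) readr::write_tsv(o, p, progress = FALSE),
                     cfg, cfg$seed)
  hit <- mean(planted[[b]] %in% kept$feature)
  message(sprintf("  %s: %d stable features; planted support recovered %.0f%%",
                  b, nrow(kept), 100 * hit))
}
message("Wrote stability tables to ", out)
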