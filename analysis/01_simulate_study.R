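#!/usr/bin/env Rscript
# Stage 1: simulate the desk-scale cohort of feature tables and staircase
# pain thresholds (210 subjects; 500-column regional blocks; 90-ROI / 4005-
# column connectivity blocks; complementary planted signal) and write them
# under results/study/.
suppressMessages(library(painfuse))

seed <- 1
cfg <- generator_config(seed = seed)
out <- file.path("results", "study")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("Simulating feature tables (n = ", cfg$n_subjects, ", rho = ",
        cfg$cross_modality_redundancy, ") ...")
st <- simulate_feature_tables(cfg)

write_config(cfg, file.path(out, "generator_config.json"))
for (b in names(st$tables))
  write_with_sidecar(st$tables[[b]], file.path(out, paste0("features_", b, ".tsv")),
                     write_feature_table, cfg, seed)
write_with_sidecar(st$phenotype, file.path(out, "phenotype.tsv"),
                   write_phenotype, cfg, seed)
# planted supports, for the recovery analysis in stage 5
jsonlite::write_json(st$planted$support, file.path(out, "planted_support.json"))

message(sprintf("Thresholds: %.2f +/- %.2f J over %d subjects",
                mean(st$phenotype$threshold_J), sd(st$phenotype$threshold_J),
                nrow(st$phenotype)))
message("Wrote feature tables and phenotype to ", out)
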