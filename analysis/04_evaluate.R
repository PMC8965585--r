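#!/usr/bin/env Rscript
# Stage 4: evaluate the stage-3 predictions: per-model PCC and MAE, paired
# t-tests on absolute errors, and the dependent-correlation z-test between
# every pair of models. Writes the performance table (one row per model)
# and the 36-row comparison table to results/evaluation/.
suppressMessages(library(painfuse))

ind <- file.path("results", "predictions")
out <- file.path("results", "evaluation")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

preds <- readr::read_tsv(file.path(ind, "predictions.tsv"),
                         show_col_types = FALSE, progress = FALSE)
suite <- lapply(split(preds, preds$model), function(df)
  painfuse:::new_prediction_result(df$predicted_J, df$true_J, df$subject_id,
                                   rep(list(integer(0)), nrow(df)),
                                   model_spec("reho")))
order_ <- c("reho", "fc", "fa", "sc", "regional", "connectivity",
            "fmri", "dti", "fused")
suite <- suite[order_[order_ %in% names(suite)]]

report <- build_report(suite)
print(report)

cfg <- read_config(file.path("results", "study", "generator_config.json"))
write_with_sidecar(report$per_model, file.path(out, "model_performance.tsv"),
                   function(o, p) readr::write_tsv(o, p, progress = FALSE),
                   cfg, cfg$seed)
write_with_sidecar(report$pairwise, file.path(out, "model_comparisons.tsv"),
                   function(o, p) readr::write_tsv(o, p, progress = FALSE),
                   cfg, cfg$seed)

gain <- subset(report$pairwise, model_a == "fused" | model_b == "fused")
message(sprintf("Fused-vs-single dependent-correlation tests: %d of %d at p < 0.05",
                sum(gain$pcc_p < 0.05), nrow(gain)))
message("Wrote evaluation tables to ", out)
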