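#!/usr/bin/env Rscript
# Feature selection: IQR filter, sum normalization, Pareto scaling, Welch
# t-tests and fold changes, O-PLS-DA VIP scores, and the three-way rule
# p < 0.1 AND (FC > 2 OR FC < 0.5) AND VIP > 1. Recovery is scored against
# the generator's ground truth.

suppressPackageStartupMessages(library(ntscreen))

d <- read_dataset("results/dataset")
cfg <- default_run_config()
fs <- qc_rsd_filter(d$fs, cfg$qc_rsd_max_pct)$features

bio <- names(fs$design)[fs$design %in% cfg$groups]
iqr <- iqr_filter(fs$intensities[, bio])
ns <- normalize_and_scale(iqr$matrix)
uni <- univariate_stats(ns$normalized, ns$scaled, fs$design, cfg$groups)
vip <- plsda_vip(ns$scaled, fs$design, cfg$groups,
                 n_components = cfg$n_components, orthogonal = cfg$orthogonal)
sel <- select_significant(uni, vip, p_max = cfg$p_max, fc_up = cfg$fc_up,
                          fc_down = cfg$fc_down, vip_min = cfg$vip_min)
write.csv(sel, "results/selection.csv", row.names = FALSE)
write.csv(sel[c("feature_id", "log2_fc", "neglog10_p", "significant")],
          "results/volcano.csv", row.names = FALSE)

sig <- sel$feature_id[sel$significant]
spiked <- unlist(d$truth$spiked)
nulls <- names(d$truth$true_fc)[unlist(d$truth$true_fc) == 1]
cat(sprintf("%d of %d features significant\n", length(sig), nrow(sel)))
cat(sprintf("spiked-feature sensitivity: %.0f%% (%d/%d)\n",
            100 * mean(spiked %in% sig), sum(spiked %in% sig), length(spiked)))
cat(sprintf("false selections among significant: %d\n", sum(sig %in% nulls)))
cat("tables: results/selection.csv, results/volcano.csv\n")
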