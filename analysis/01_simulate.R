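#!/usr/bin/env Rscript
# Build the synthetic study cohort: 10 PD vs 10 Ctrl plasma/feces-style
# samples with 6 pooled QC injections, 500 aligned LC-HRMS features
# (30 annotated compounds, 20 spiked at fold change 4, the rest null),
# an MSP reference library, four suspect lists and a pathway table.
# Everything downstream reads the dataset directory written here.

suppressPackageStartupMessages(library(ntscreen))

seed <- 1L
dir <- "results/dataset"
d <- generate_cohort(default_cohort_config(), seed = seed, dir = dir)

cat("dataset written to", dir, "\n")
cat(sprintf("  %d features x %d samples; %d with MS/MS; %d suspects in %d lists\n",
            nrow(d$fs$features), ncol(d$fs$intensities),
            length(d$fs$ms2), nrow(d$suspects),
            length(unique(d$suspects$list_code))))
cat(sprintf("  ground truth: %d annotated compounds, %d spiked (FC %.1f), %d QC-fail targets\n",
            nrow(d$truth$compounds), length(d$truth$spiked),
            d$truth$config$spike_fc, length(d$truth$qc_fail)))
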