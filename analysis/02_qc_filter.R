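#!/usr/bin/env Rscript
# QC reproducibility filter: per-feature RSD over the pooled QC injections,
# retaining features with RSD < 50%.

suppressPackageStartupMessages(library(ntscreen))

d <- read_dataset("results/dataset")
qc <- qc_rsd_filter(d$fs, threshold_pct = 50)
write.csv(qc$stats, "results/qc_stats.csv", row.names = FALSE)

cat(sprintf("%d of %d features retained (QC RSD < 50%%)\n",
            sum(qc$stats$retained), nrow(qc$stats)))
cat(sprintf("median QC RSD of retained features: %.1f%%\n",
            median(qc$stats$rsd[qc$stats$retained])))
cat("table: results/qc_stats.csv\n")
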