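#!/usr/bin/env Rscript
# Annotation: suspect screening by exact mass/adduct, MS/MS library search,
# formula annotation with isotope and MS/MS consistency scores, and
# identification confidence levels under all three schemes.

suppressPackageStartupMessages(library(ntscreen))

d <- read_dataset("results/dataset")
cfg <- default_run_config()
fs <- qc_rsd_filter(d$fs, cfg$qc_rsd_max_pct)$features

hits <- screen_suspects(fs, d$suspects, adducts = cfg$adducts,
                        tol_ppm = cfg$ms1_tol_ppm)
summary <- merge_hits_across_lists(hits)
evidence <- assemble_evidence(fs, hits, d$library, cfg)
levels_tbl <- do.call(rbind, lapply(
  c("suspect_patroon", "nt_patroon", "nt_msdial"),
  function(s) assign_levels(evidence, s)))

write.csv(hits, "results/suspect_hits.csv", row.names = FALSE)
write.csv(summary, "results/hit_summary.csv", row.names = FALSE)
write.csv(evidence, "results/evidence.csv", row.names = FALSE)
write.csv(levels_tbl, "results/levels.csv", row.names = FALSE)

cat(sprintf("%d suspect hits on %d features (%d after cross-list merging)\n",
            nrow(hits), length(unique(hits$feature_id)), nrow(summary)))
for (s in unique(levels_tbl$scheme)) {
  tb <- table(levels_tbl$level[levels_tbl$scheme == s])
  cat(sprintf("  %-16s %s\n", s,
              paste(names(tb), tb, sep = "=", collapse = " ")))
}
cat("tables: results/{suspect_hits,hit_summary,evidence,levels}.csv\n")
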