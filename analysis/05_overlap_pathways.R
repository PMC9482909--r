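#!/usr/bin/env Rscript
# Overlap and pathway analysis: InChIKey-based comparison of annotations
# across ESI modes and across suspect lists (annotations without a
# structure identity are excluded and counted), then hypergeometric
# over-representation of the selected compounds in the pathway table.

suppressPackageStartupMessages(library(ntscreen))

d <- read_dataset("results/dataset")
res <- run_pipeline(d, default_run_config())

if (!is.null(res$overlap_esi)) {
  write.csv(res$overlap_esi$cells, "results/overlap_esi.csv", row.names = FALSE)
  cat("ESI mode overlap (structure-identified annotations):\n")
  print(res$overlap_esi$cells, row.names = FALSE)
  cat(sprintf("excluded (level 2b/3c/5, no InChIKey): %d\n",
              res$overlap_esi$excluded_count))
}
if (!is.null(res$overlap_lists))
  write.csv(res$overlap_lists$cells, "results/overlap_lists.csv", row.names = FALSE)
if (!is.null(res$ora)) {
  write.csv(res$ora, "results/ora.csv", row.names = FALSE)
  cat("\npathway over-representation (selected vs annotated universe):\n")
  print(res$ora[c("pathway_id", "hits", "pathway_size", "p_value")],
        row.names = FALSE)
}
cat("tables: results/{overlap_esi,overlap_lists,ora}.csv\n")
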