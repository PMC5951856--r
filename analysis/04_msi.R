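#!/usr/bin/env Rscript
# Step 4 — per-tumor microsatellite-instability scoring against the matched
# normal, with the 15%-relative rule for MSI-high.
#
# Reads scratch/cohort/ (run 01 first); writes results/msi_calls.tsv.

source("analysis/00_cohort_design.R")
if (!dir.exists(COHORT_DIR)) stop("run analysis/01_simulate_cohort.R first")

design <- cohort_design()
rows <- lapply(design, function(tm) {
  loci <- read_tsv_table(file.path(COHORT_DIR, paste0(tm$id, "_msi_loci.tsv")))
  tum <- read_tsv_table(file.path(COHORT_DIR, paste0(tm$id, "_msi_tumor.tsv")))
  nrm <- read_tsv_table(file.path(COHORT_DIR, paste0(tm$id, "_msi_normal.tsv")))
  call <- msi_score(tum, nrm, loci)
  data.frame(
    sample = tm$id,
    n_evaluated = call$n_evaluated,
    pct_unstable_tumor = round(call$percent_unstable, 2),
    pct_unstable_normal = round(call$percent_unstable_normal, 2),
    relative_pct = round(call$relative_percent, 2),
    msi_high = call$msi_high,
    true_rate_pct = 100 * tm$msi_rate
  )
})
res <- do.call(rbind, rows)
write_tsv_table(res, file.path(RESULTS_DIR, "msi_calls.tsv"))

cat("MSI-high in", sum(res$msi_high), "of", nrow(res), "tumors\n")
print(res, row.names = FALSE)
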