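#!/usr/bin/env Rscript
# Step 6 — combine prevalence, signature exposures, indel fraction and MSI
# status into the three-class call, and screen the mismatch-repair genes on
# a small annotated variant set.
#
# Reads results/ tables from steps 03-05; writes results/class_calls.tsv.

source("analysis/00_cohort_design.R")
sig <- read_tsv_table(file.path(RESULTS_DIR, "signature_exposures.tsv"))
msi <- read_tsv_table(file.path(RESULTS_DIR, "msi_calls.tsv"))
cnv <- read_tsv_table(file.path(RESULTS_DIR, "purity_ploidy.tsv"))
truth <- read_tsv_table(file.path(RESULTS_DIR, "cohort_truth.tsv"))

rows <- lapply(seq_len(nrow(sig)), function(i) {
  s <- sig[i, ]
  m <- msi[msi$sample == s$sample, ]
  profile <- list(
    n_snv = s$n_snv, n_indel = s$n_indel,
    prevalence = s$prevalence_per_mb,
    exposures = c(S6 = s$exp_s6_s15, S7 = s$exp_s7_s11, S1 = s$exp_s1),
    msi_high = m$msi_high
  )
  call <- classify_tumor(profile)
  data.frame(
    sample = s$sample,
    class = call$class,
    true_class = truth$true_class[truth$sample == s$sample],
    prevalence_per_mb = s$prevalence_per_mb,
    indel_fraction = round(call$evidence$indel_fraction, 3),
    msi_exposure = s$exp_s6_s15,
    uv_exposure = s$exp_s7_s11,
    msi_high = m$msi_high,
    cnv_purity = cnv$alpha_hat[cnv$sample == s$sample],
    flags = paste(call$flags, collapse = ";")
  )
})
res <- do.call(rbind, rows)
write_tsv_table(res, file.path(RESULTS_DIR, "class_calls.tsv"))

acc <- mean(res$class == res$true_class)
cat(sprintf("Classified %d tumors, accuracy vs truth %.0f%% (%s)\n",
            nrow(res), 100 * acc,
            paste(table(res$class), names(table(res$class)), collapse = ", ")))
print(res[, c("sample", "class", "true_class", "prevalence_per_mb",
              "indel_fraction", "msi_high", "flags")], row.names = FALSE)

# mismatch-repair screen on a small annotated set, including the
# germline-nonsense case the cohort design plants in an MSI tumor
variants <- data.frame(
  gene = c("MSH6", "MLH1", "MSH2", "TP53", "MLH1"),
  consequence = c("nonsense", "frameshift", "missense", "nonsense", "nonsense"),
  origin = c("germline", "somatic", "somatic", "somatic", "somatic"),
  hgvsp = c("p.R911*", "p.K383fs", "p.V384D", "p.R175H", "p.Q62*")
)
mmr <- screen_mmr_genes(variants, cn_losses = data.frame(gene = "MSH2"))
cat("\nDisruptive mismatch-repair events:\n")
print(mmr, row.names = FALSE)
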