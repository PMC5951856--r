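#!/usr/bin/env Rscript
# Step 1 — simulate every input the pipeline consumes for a 13-tumor cohort
# with known ground truth: mutation catalogs (MAF-like TSV + VCF),
# microsatellite repeat-length tables, exon coverage/allele-fraction
# profiles, and per-tumor truth sidecars.
#
# Bulky per-tumor inputs go to scratch/cohort/; the cohort truth manifest is
# written to results/cohort_truth.tsv.

source("analysis/00_cohort_design.R")

dir.create(COHORT_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

catalog <- cohort_catalog()
design <- cohort_design(catalog)
write_tsv_table(data.frame(signature = rownames(catalog), catalog,
                           check.names = FALSE),
                file.path(COHORT_DIR, "signature_catalog.tsv"))

manifest <- list()
for (tm in design) {
  id <- tm$id
  mut <- sim_mutation_catalog(catalog, tm$exposures, tm$n_snv, tm$n_indel,
                              capture_mb = CAPTURE_MB,
                              seed = tumor_seed(id, 1))
  write_tsv_table(mut, file.path(COHORT_DIR, paste0(id, "_mutations.tsv")))
  write_mutations_vcf(mut, file.path(COHORT_DIR, paste0(id, "_mutations.vcf")),
                      sample = id)

  msi <- sim_msi_data(800, tm$msi_rate, mean_depth = 100,
                      seed = tumor_seed(id, 2))
  write_tsv_table(msi$loci, file.path(COHORT_DIR, paste0(id, "_msi_loci.tsv")))
  write_tsv_table(msi$tumor, file.path(COHORT_DIR, paste0(id, "_msi_tumor.tsv")))
  write_tsv_table(msi$normal, file.path(COHORT_DIR, paste0(id, "_msi_normal.tsv")))

  st <- sim_segment_truth(tm$tau, n_aberrant = 6, seed = tumor_seed(id, 3))
  prof <- sim_cnv_profile(st, purity = tm$purity, n_exons = 300,
                          het_snp_rate = 1.5, seed = tumor_seed(id, 4))
  write_tsv_table(prof$exons, file.path(COHORT_DIR, paste0(id, "_exons.tsv")))

  manifest[[id]] <- data.frame(
    sample = id, true_class = tm$class,
    n_snv = tm$n_snv, n_indel = tm$n_indel,
    true_msi_rate = tm$msi_rate,
    true_purity = tm$purity, true_ploidy = attr(st, "tau"),
    exposure_s6_s15 = sum(tm$exposures[c("S6", "S15")]),
    exposure_s7_s11 = sum(tm$exposures[c("S7", "S11")])
  )
}
truth <- do.call(rbind, manifest)
write_tsv_table(truth, file.path(RESULTS_DIR, "cohort_truth.tsv"))

cat("Simulated", nrow(truth), "tumors:",
    paste(table(truth$true_class), names(table(truth$true_class)),
          collapse = ", "), "\n")
cat("Inputs under", COHORT_DIR, "- truth manifest at",
    file.path(RESULTS_DIR, "cohort_truth.tsv"), "\n")
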