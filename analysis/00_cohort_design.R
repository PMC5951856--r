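# Shared design of the synthetic 13-tumor cohort used by the numbered
# analysis scripts: four MSI-like, four UV-like, four pauci-mutational
# tumors plus one mixed-signature tumor, with class-typical mutation
# burdens, signature mixtures, microsatellite instability rates and
# copy-number/purity truths.
#
# Sourced by the 01..08 drivers; not part of the package.

library(sebclass)

COHORT_SEED <- 20260930L
CAPTURE_MB <- 62.52

# one 30-signature catalog shared by the whole cohort (ids S1..S30; S1 plays
# the aging role, S6/S15 mismatch-repair, S7/S11 UV)
cohort_catalog <- function() {
  sim_signature_catalog(30, concentration = 0.05, seed = split_seed(COHORT_SEED, 1))
}

expo <- function(catalog, ...) {
  v <- c(...)
  out <- stats::setNames(numeric(nrow(catalog)), rownames(catalog))
  out[names(v)] <- v
  out
}

cohort_design <- function(catalog = cohort_catalog()) {
  tumors <- list()
  add <- function(id, class, exposures, n_snv, n_indel, msi_rate,
                  purity, tau) {
    tumors[[id]] <<- list(id = id, class = class, exposures = exposures,
                          n_snv = n_snv, n_indel = n_indel,
                          msi_rate = msi_rate, purity = purity, tau = tau)
  }
  # MSI-like: ~30-80/Mb, >=30% indels, unstable microsatellites
  add("T01", "MSI", expo(catalog, S6 = 0.45, S15 = 0.10, S1 = 0.45), 2600, 1400, 0.30, 0.65, 2.0)
  add("T02", "MSI", expo(catalog, S6 = 0.35, S1 = 0.65),             1900, 1030, 0.25, 0.75, 2.0)
  add("T03", "MSI", expo(catalog, S6 = 0.30, S15 = 0.12, S1 = 0.58), 3400, 1800, 0.40, 0.55, 1.8)
  add("T04", "MSI", expo(catalog, S6 = 0.40, S15 = 0.05, S1 = 0.55), 2100, 1200, 0.22, 0.70, 2.0)
  # UV-like: high burden, SSNV-dominated
  add("T05", "UV", expo(catalog, S7 = 0.60, S11 = 0.10, S1 = 0.30), 6252, 310, 0.01, 0.60, 2.0)
  add("T06", "UV", expo(catalog, S7 = 0.50, S11 = 0.15, S1 = 0.35), 12000, 500, 0.01, 0.80, 3.0)
  add("T07", "UV", expo(catalog, S7 = 0.70, S1 = 0.30),             20000, 800, 0.02, 0.70, 2.0)
  add("T08", "UV", expo(catalog, S7 = 0.45, S11 = 0.20, S1 = 0.35), 3700, 150, 0.01, 0.50, 1.8)
  # pauci-mutational: ~1-5/Mb, aging signature, quiet genomes
  add("T09", "PAUCI", expo(catalog, S1 = 1.0),            120, 6, 0.01, 0.75, 2.0)
  add("T10", "PAUCI", expo(catalog, S1 = 0.85, S5 = 0.15), 200, 10, 0.01, 0.85, 2.0)
  add("T11", "PAUCI", expo(catalog, S1 = 0.90, S5 = 0.10),  90, 4, 0.00, 0.70, 2.0)
  add("T12", "PAUCI", expo(catalog, S1 = 1.0),            310, 15, 0.02, 0.80, 2.0)
  # mixed-signature tumor modeled on the one forehead tumor carrying both
  # mismatch-repair and UV exposures (46% sig 6/15, 3% sig 7)
  add("T13", "MSI", expo(catalog, S6 = 0.30, S15 = 0.16, S7 = 0.03, S1 = 0.51),
      5000, 1000, 0.28, 0.65, 2.0)
  tumors
}

tumor_seed <- function(id, k = 0L) {
  split_seed(COHORT_SEED, 100L * as.integer(sub("T", "", id)) + k)
}

COHORT_DIR <- "scratch/cohort"
RESULTS_DIR <- "results"
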