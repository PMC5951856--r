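# Exon statistics, agglomerative segmentation, AF correction, purity/ploidy
# fitting and allelic-state assignment.

test_that("exon statistics: RC, depth removal, heterozygosity bounds", {
  ex <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                   end = c(500, 1500, 2500),
                   depth_t = c(50, 4, 100), depth_n = c(50, 4, 50))
  snps <- data.frame(chrom = "chr1",
                     pos = c(100, 200, 2100),
                     ref_t = c(30, 10, 20), alt_t = c(30, 40, 20),
                     ref_n = c(25, 10, 6),  alt_n = c(25, 40, 24))
  st <- compute_exon_stats(ex, snps)
  # exon 2 removed: depth < 5 in both samples
  expect_equal(nrow(st), 2)
  expect_equal(st$rc_mean[1], 1.0)
  expect_equal(st$rc_mean[2], 2.0)
  # SNP at 200 has normal AF 0.8: not heterozygous; SNP at 100 is (AF 0.5)
  expect_equal(st$n_het_snps[1], 1L)
  expect_equal(st$af_t[1], 0.5)
  # SNP at 2100: normal AF 0.8 > 0.75 -> excluded entirely
  expect_equal(st$n_het_snps[2], 0L)
})

test_that("majority allele is the better-supported germline allele", {
  ex <- data.frame(chrom = "chr1", start = 0, end = 1000,
                   depth_t = 60, depth_n = 60)
  snps <- data.frame(chrom = "chr1", pos = 10,
                     ref_t = 10, alt_t = 40,   # tumor skewed to alt
                     ref_n = 18, alt_n = 22)   # normal majority = alt
  st <- compute_exon_stats(ex, snps)
  expect_equal(st$af_t, 0.8)            # alt / total in tumor
  expect_equal(st$af_n, 22 / 40)
})

test_that("agglomeration merges identical neighbours and centers the median", {
  mk <- function(n, rc, chrom = "chr1") {
    data.frame(chrom = chrom, start = (0:(n - 1)) * 1000,
               end = (0:(n - 1)) * 1000 + 200, length = 200,
               rc_mean = rc, rc_sd = 0.05,
               af_t = NA_real_, af_n = NA_real_,
               af_t_sd = NA_real_, af_n_sd = NA_real_, n_het_snps = 0L)
  }
  two <- agglomerate_segments(mk(2, 1.0), center = FALSE)
  expect_equal(nrow(two), 1)
  expect_equal(two$n_exons, 2L)
  expect_equal(two$length, 400)

  # 8 identical exons collapse to one segment in exactly three rounds
  eight <- agglomerate_segments(mk(8, 1.3), center = FALSE)
  expect_equal(nrow(eight), 1)

  # clearly different neighbours never merge
  diff2 <- mk(2, 1.0); diff2$rc_mean <- c(1.0, 2.0); diff2$rc_sd <- 0.01
  expect_equal(nrow(agglomerate_segments(diff2, center = FALSE)), 2)

  # centering: genome-wide weighted median is exactly 1
  mixed <- rbind(mk(4, 1.4), mk(4, 2.8, chrom = "chr2"))
  cent <- agglomerate_segments(mixed)
  o <- order(cent$rc_mean)
  x <- cent$rc_mean[o]; w <- cent$length[o]
  med <- x[which(cumsum(w) / sum(w) >= 0.5)[1]]
  expect_equal(med, 1.0)
})

test_that("AF correction matches the closed form and its limits", {
  # identity when the normal shows no skew
  expect_equal(correct_majority_af(0.77, 0.5), 0.77)
  # equal tumor/normal AF: full correction, clamped at 0.5
  expect_equal(correct_majority_af(0.55, 0.55), 0.50, tolerance = 1e-12)
  # far-apart AFs: correction vanishes
  expect_equal(correct_majority_af(0.9, 0.6),
               0.9 - 0.1 * exp(-0.5 * 36), tolerance = 1e-9)
  expect_lt(abs(correct_majority_af(0.9, 0.6) - 0.9), 1e-6)
  expect_error(correct_majority_af(1.2, 0.5), "\\[0, 1\\]")
  # continuity spot check around the Gaussian window
  eps <- 1e-6
  expect_lt(abs(correct_majority_af(0.6, 0.55) -
                correct_majority_af(0.6 + eps, 0.55)), 1e-4)
})

test_that("purity and ploidy are recovered from a simulated genome", {
  # alpha = 1, 90% (1,1) + 10% (2,1): ploidy 2.1
  st <- data.frame(chrom = paste0("chr", 1:10),
                   start = 0, end = c(rep(9e6, 9), 10e6),
                   A = c(rep(1, 9), 2), B = 1)
  st$end[10] <- 10e6
  prof <- sim_cnv_profile(st, purity = 1.0, n_exons = 300,
                          het_snp_rate = 1.5, seed = 41)
  segs <- agglomerate_segments(prof$exons)
  fit <- fit_purity_ploidy(segs, n_restarts = 10, seed = 42)
  expect_lt(abs(fit$alpha - 1.0), 0.05)
  expect_lt(abs(fit$ploidy - prof$truth$tau), 0.05)
  expect_false(fit$degenerate)
})

test_that("a (2,0) segment at alpha 0.5 shows AF 0.75 and is assigned CN-LOH", {
  st <- data.frame(chrom = paste0("chr", 1:6), start = 0,
                   end = c(rep(10e6, 5), 6e6),
                   A = c(1, 1, 1, 2, 1, 2), B = c(1, 1, 1, 1, 1, 0))
  prof <- sim_cnv_profile(st, purity = 0.5, n_exons = 300,
                          het_snp_rate = 2, seed = 43)
  # forward-model expectation for (2,0) at alpha 0.5: (0.5*2+0.5)/(0.5*2+1)
  cnloh <- prof$exons$segment_truth == 6 & !is.na(prof$exons$af_t)
  expect_equal(mean(prof$exons$af_t[cnloh]), 0.75, tolerance = 0.02)

  segs <- agglomerate_segments(prof$exons)
  fit <- fit_purity_ploidy(segs, n_restarts = 10, seed = 44)
  expect_lt(abs(fit$alpha - 0.5), 0.05)
  called <- assign_allelic_states(segs, fit)
  hit <- called[called$chrom == "chr6" & called$called, ]
  expect_true(nrow(hit) > 0)
  expect_true(any(hit$state_A == 2 & hit$state_B == 0))
})

test_that("an all-normal genome flags degeneracy", {
  st <- data.frame(chrom = paste0("chr", 1:4), start = 0, end = 10e6,
                   A = 1, B = 1)
  prof <- sim_cnv_profile(st, purity = 0.7, n_exons = 120,
                          het_snp_rate = 2, seed = 45)
  segs <- agglomerate_segments(prof$exons)
  fit <- fit_purity_ploidy(segs, n_restarts = 10, seed = 46)
  expect_true(fit$degenerate)
})

test_that("the fit errors without AF-bearing segments and is seed-deterministic", {
  st <- sim_segment_truth(2.0, 5, seed = 47)
  prof <- sim_cnv_profile(st, purity = 0.6, n_exons = 200,
                          het_snp_rate = 1.5, seed = 48)
  segs <- agglomerate_segments(prof$exons)
  noaf <- segs; noaf$af_t <- NA_real_
  expect_error(fit_purity_ploidy(noaf, seed = 1), "unidentifiable")

  f1 <- fit_purity_ploidy(segs, n_restarts = 10, seed = 49)
  f2 <- fit_purity_ploidy(segs, n_restarts = 10, seed = 49)
  expect_identical(f1$alpha, f2$alpha)
  expect_identical(f1$restarts, f2$restarts)
})

test_that("state assignment excludes (1,1) and sizes the report at 2.5 Mb", {
  st <- data.frame(chrom = c("chr1", "chr2", "chr3"), start = 0,
                   end = c(10e6, 3e6, 1e6),
                   A = c(1, 2, 2), B = c(1, 1, 1))
  prof <- sim_cnv_profile(st, purity = 1, n_exons = 220,
                          het_snp_rate = 2, noise_sd = 0.03, seed = 50)
  # fit on truth-scale segments directly (each truth segment as one unit)
  segs <- do.call(rbind, lapply(split(prof$exons, prof$exons$segment_truth),
    function(df) data.frame(
      chrom = df$chrom[1], start = min(df$start), end = max(df$end),
      length = sum(st$end[df$segment_truth[1]] - st$start[df$segment_truth[1]]),
      rc_mean = mean(df$rc_mean), rc_sd = sd(df$rc_mean),
      af_t = mean(df$af_t, na.rm = TRUE), af_n = mean(df$af_n, na.rm = TRUE),
      af_t_sd = sd(df$af_t, na.rm = TRUE), af_n_sd = sd(df$af_n, na.rm = TRUE),
      n_het_snps = sum(df$n_het_snps), n_exons = nrow(df))))
  fit <- fit_purity_ploidy(segs, n_restarts = 10, seed = 51)
  res <- assign_allelic_states(segs, fit, p_dev = 1e-4)
  normal <- res[res$state_A == 1 & res$state_B == 1 & res$state_clonal == 1, ]
  expect_true(all(!normal$called))
  gain3mb <- res[res$chrom == "chr2", ]
  expect_true(gain3mb$called && gain3mb$in_report)
  gain1mb <- res[res$chrom == "chr3", ]
  expect_true(gain1mb$called && !gain1mb$in_report)
})
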