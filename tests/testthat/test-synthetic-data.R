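# The synthetic-data generators: validity, determinism, and the statistical
# properties downstream recovery tests rely on.

test_that("signature catalog rows are simplex points and sparse at low concentration", {
  cat1 <- sim_signature_catalog(1, 0.5, seed = 3)
  expect_equal(unname(rowSums(cat1)), 1, tolerance = 1e-12)
  expect_true(all(cat1 >= 0))

  # sparse Dirichlet rows rarely share support: median cosine similarity
  # between two rows stays small (direct sampling)
  cosims <- vapply(1:20, function(s) {
    m <- sim_signature_catalog(2, 0.01, seed = 100 + s)
    sum(m[1, ] * m[2, ]) / sqrt(sum(m[1, ]^2) * sum(m[2, ]^2))
  }, 0)
  expect_lt(median(cosims), 0.2)

  expect_error(sim_signature_catalog(0, 0.1, 1), "n_signatures")
})

test_that("generators are deterministic given the seed", {
  expect_identical(sim_signature_catalog(3, 0.05, 7),
                   sim_signature_catalog(3, 0.05, 7))
  cat2 <- sim_signature_catalog(2, 0.05, 7)
  expect_identical(sim_mutation_catalog(cat2, c(0.5, 0.5), 50, 5, seed = 9),
                   sim_mutation_catalog(cat2, c(0.5, 0.5), 50, 5, seed = 9))
  expect_identical(sim_msi_data(40, 0.3, 80, seed = 2),
                   sim_msi_data(40, 0.3, 80, seed = 2))
  st <- sim_segment_truth(2.0, 5, seed = 4)
  expect_identical(sim_cnv_profile(st, 0.6, 100, seed = 5),
                   sim_cnv_profile(st, 0.6, 100, seed = 5))
  expect_identical(sim_variant_records(30, list(sb = 0.3), seed = 6),
                   sim_variant_records(30, list(sb = 0.3), seed = 6))
  expect_identical(sim_expression_matrix(600, c(A = 3, B = 3), 1, seed = 8),
                   sim_expression_matrix(600, c(A = 3, B = 3), 1, seed = 8))
})

test_that("mutation catalog honors counts, classes, and the exposure mix", {
  cat2 <- sim_signature_catalog(2, 0.05, seed = 11)
  ind <- sim_mutation_catalog(cat2, c(1, 0), n_snv = 0, n_indel = 5, seed = 1)
  expect_equal(nrow(ind), 5)
  expect_true(all(ind$var_class %in% c("insertion", "deletion")))

  mut <- sim_mutation_catalog(cat2, c(1, 0), n_snv = 1000, seed = 2)
  sp <- build_spectrum(mut)
  gof <- suppressWarnings(
    chisq.test(as.integer(sp), p = cat2[1, ], rescale.p = TRUE,
               simulate.p.value = TRUE, B = 2000))
  expect_gt(gof$p.value, 0.001)

  expect_error(sim_mutation_catalog(cat2, c(0.7, 0.2), 10), "sum to 1")
})

test_that("msi generator: stable loci stay stable, shallow loci are excluded", {
  d0 <- sim_msi_data(200, instability_rate = 0, mean_depth = 100, seed = 3)
  call0 <- msi_score(d0$tumor, d0$normal, d0$loci, min_loci = 50)
  expect_equal(call0$percent_unstable, 0)
  expect_false(call0$msi_high)

  shallow <- sim_msi_data(120, 0.2, mean_depth = 10, seed = 4)
  expect_error(msi_score(shallow$tumor, NULL, shallow$loci, min_loci = 50),
               "evaluable")
})

test_that("msi generator recovers the programmed instability rate", {
  d <- sim_msi_data(500, 0.2, mean_depth = 100, seed = 5)
  call <- msi_score(d$tumor, d$normal, d$loci)
  # within 3 binomial SD of the programmed rate
  expect_lt(abs(call$relative_percent / 100 - 0.2),
            3 * sqrt(0.2 * 0.8 / 500))
  # per-locus recovery matches the generator's own truth exactly
  expect_setequal(call$unstable_loci, d$truth$locus_id[d$truth$unstable])
})

test_that("cnv forward model reproduces the mixture expectations", {
  flat <- data.frame(chrom = "chr1", start = 0, end = 10e6, A = 1, B = 1)
  p <- sim_cnv_profile(flat, purity = 1, n_exons = 200, noise_sd = 0.01,
                       het_snp_rate = 2, seed = 6)
  expect_equal(mean(p$exons$rc_mean), 1.0, tolerance = 0.01)
  expect_equal(mean(p$exons$af_t, na.rm = TRUE), 0.5, tolerance = 0.02)

  # copy-neutral LOH at full purity: AF -> 1, coverage stays 1 at ploidy 2
  cnloh <- rbind(flat, data.frame(chrom = "chr2", start = 0, end = 10e6,
                                  A = 2, B = 0))
  p2 <- sim_cnv_profile(cnloh, purity = 1, n_exons = 200, noise_sd = 0.01,
                        het_snp_rate = 2, seed = 7)
  seg2 <- p2$exons[p2$exons$chrom == "chr2", ]
  expect_equal(mean(seg2$af_t, na.rm = TRUE), 1.0, tolerance = 0.02)
  expect_equal(mean(seg2$rc_mean), 1.0, tolerance = 0.02)

  # (2,1) at alpha = 0.5: expected AF = (0.5*2 + 0.5)/(0.5*3 + 1) = 0.6
  gain <- rbind(flat, data.frame(chrom = "chr2", start = 0, end = 10e6,
                                 A = 2, B = 1))
  p3 <- sim_cnv_profile(gain, purity = 0.5, n_exons = 400, noise_sd = 0.01,
                        het_snp_rate = 3, seed = 8)
  seg3 <- p3$exons[p3$exons$chrom == "chr2", ]
  expect_equal(mean(seg3$af_t, na.rm = TRUE), 0.6, tolerance = 0.02)

  bad <- data.frame(chrom = "chr1", start = 0, end = 1e6, A = 0, B = 0)
  expect_error(sim_cnv_profile(bad, 0.5), "allelic state")
  expect_error(sim_cnv_profile(flat, 0), "purity")
})

test_that("segment-truth builder realizes the requested ploidy", {
  for (tau in c(1.8, 2.0, 3.0)) {
    st <- sim_segment_truth(tau, n_aberrant = 5, seed = 9)
    expect_equal(attr(st, "tau"), tau, tolerance = 0.1)
    expect_gte(sum(!(st$A == 1 & st$B == 1)), 5)
    expect_true(all(st$A >= st$B))
  }
})

test_that("variant-record corruption fails exactly the constructed filters", {
  clean <- sim_variant_records(100, list(), seed = 10)
  res <- apply_site_filters_df(clean)
  expect_true(all(res$filter_verdict == "pass"))
  expect_true(all(clean$failed_truth == ""))

  mq0 <- sim_variant_records(50, list(mq0 = 1.0), seed = 11)
  res <- apply_site_filters_df(mq0)
  expect_true(all(res$filter_failed == "mq0"))
  expect_true(all(mq0$mq0_reads >= 5))

  sb <- sim_variant_records(1000, list(sb = 0.5), seed = 12)
  n_fail <- sum(sb$failed_truth == "sb")
  expect_lt(abs(n_fail - 500), 3 * sqrt(1000 * 0.25))
  res <- apply_site_filters_df(sb)
  expect_identical(res$filter_failed, sb$failed_truth)

  expect_error(sim_variant_records(10, list(bogus = 1)), "unknown filter")
})

test_that("expression generator produces group structure scaling with effect size", {
  null <- sim_expression_matrix(600, c(A = 4, B = 4), effect_size = 0, seed = 13)
  # gene-centered: shared per-gene baselines carry no sample structure;
  # row-centering over n samples puts the null correlation at -1/(n-1)
  lg <- log2(1 + null)
  lg <- lg - rowMeans(lg)
  cc <- cor(lg)
  off <- cc[upper.tri(cc)]
  expect_lt(abs(mean(off) - (-1 / 7)), 0.05)
  grp0 <- attr(null, "group")
  same <- outer(grp0, grp0, "==")[upper.tri(cc)]
  expect_lt(abs(mean(off[same]) - mean(off[!same])), 0.05)

  grp <- sim_expression_matrix(1000, c(A = 4, B = 4), effect_size = 3, seed = 14)
  cm <- correlation_map(grp, top_n = 500)
  halves <- cutree(cm$hclust, k = 2)
  expect_equal(length(unique(halves[attr(grp, "group") == "A"])), 1)
  expect_equal(length(unique(halves[attr(grp, "group") == "B"])), 1)
  expect_false(halves[["A.1"]] == halves[["B.1"]])
})
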