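# Paired genotype model and the ten-rule site filter engine.

test_that("genotype likelihoods pick the supported genotype and enforce the read floor", {
  hom <- genotype_likelihoods(make_reads(rep("A", 20)))
  expect_equal(names(which.max(hom)), "AA")

  het <- genotype_likelihoods(make_reads(c(rep("A", 10), rep("T", 10))))
  expect_equal(names(which.max(het)), "AT")

  expect_null(genotype_likelihoods(make_reads(rep("A", 7))))
  # duplicates and low mapping quality do not count toward the floor
  r <- make_reads(rep("A", 12))
  r$is_dup[1:3] <- TRUE
  r$mapq[4:5] <- 10
  expect_null(genotype_likelihoods(r))
})

test_that("genotype pairs classify as germline, LOH, and somatic", {
  het_t <- genotype_likelihoods(make_reads(c(rep("A", 10), rep("T", 10))))
  het_n <- genotype_likelihoods(make_reads(c(rep("A", 11), rep("T", 9))))
  hom_t <- genotype_likelihoods(make_reads(rep("T", 20)))
  ref_n <- genotype_likelihoods(make_reads(rep("A", 20)))

  germ <- classify_genotype_pair(het_t, het_n, "A")
  expect_equal(germ$category, "germline")
  expect_equal(germ$tumor_genotype, "AT")
  expect_gt(germ$germline_quality, 0)

  loh <- classify_genotype_pair(hom_t, het_n, "A")
  expect_equal(loh$category, "LOH")

  som <- classify_genotype_pair(het_t, ref_n, "A")
  expect_equal(som$category, "somatic")
  expect_gte(som$somatic_score, 15)
})

test_that("somatic score matches brute-force enumeration of the 100 pairs", {
  tll <- genotype_likelihoods(make_reads(c(rep("A", 12), rep("T", 8))))
  nll <- genotype_likelihoods(make_reads(rep("A", 15)))
  call <- classify_genotype_pair(tll, nll, "A",
                                 priors = list(het_rate = 1e-3,
                                               somatic_rate = 1e-4))

  # independent enumeration: explicit loops over all genotype pairs
  gts <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
  prior_n <- numeric(10)
  for (i in 1:10) {
    g <- gts[i]
    has_ref <- grepl("A", g)
    prior_n[i] <- if (g == "AA") 1 - 1e-3 - 1e-6
      else if (has_ref) 1e-3 / 3 else 1e-6 / 6
  }
  prior_n <- prior_n / sum(prior_n)
  joint <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    trans <- if (i == j) 1 - 1e-4 else 1e-4 / 9
    joint[i, j] <- exp(nll[i] + tll[j] - max(nll) - max(tll)) *
      prior_n[i] * trans
  }
  joint <- joint / sum(joint)
  p_equal <- sum(diag(joint))
  ss_brute <- min(255, -10 * log10(p_equal))
  expect_equal(call$somatic_score, ss_brute, tolerance = 1e-6)
  expect_equal(sum(call$posterior), 1, tolerance = 1e-12)
})

test_that("SS is invariant to shifting all log-likelihoods by a constant", {
  tll <- genotype_likelihoods(make_reads(c(rep("C", 9), rep("G", 9))))
  nll <- genotype_likelihoods(make_reads(rep("C", 18)))
  a <- classify_genotype_pair(tll, nll, "C")
  b <- classify_genotype_pair(tll + 123.4, nll - 55.5, "C")
  expect_equal(a$somatic_score, b$somatic_score, tolerance = 1e-9)
  expect_equal(a$category, b$category)
})

test_that("somatic_rate -> 0 never yields a somatic call (prior dominance)", {
  set.seed(20)
  for (i in 1:10) {
    n_alt <- sample(0:12, 1)
    tll <- genotype_likelihoods(
      make_reads(c(rep("A", 20 - n_alt), rep("G", n_alt))))
    nll <- genotype_likelihoods(make_reads(rep("A", 20)))
    call <- classify_genotype_pair(tll, nll, "A",
                                   priors = list(het_rate = 1e-3,
                                                 somatic_rate = 1e-300))
    expect_false(call$category == "somatic")
  }
})

test_that("two-supporting-read rule deems sites homozygous reference", {
  site <- list(ref_base = "A",
               tumor = make_reads(c(rep("A", 19), "T")),
               normal = make_reads(rep("A", 20)))
  expect_equal(call_site(site)$category, "hom_ref")
  site$normal <- make_reads(rep("A", 7))
  expect_null(call_site(site))
})

test_that("single filters fire on their documented boundaries", {
  clean <- sim_variant_records(1, list(), seed = 1)

  r <- clean; r$somatic_score <- 14; r$genotype_quality <- 14
  expect_equal(apply_site_filters(r)$failed, "conf")
  # either-suffices: a good genotype quality rescues a low SS
  r$genotype_quality <- 40
  expect_equal(apply_site_filters(r)$verdict, "pass")

  r <- clean; r$mq0_reads <- 5
  expect_equal(apply_site_filters(r)$failed, "mq0")
  r$mq0_reads <- 4
  expect_equal(apply_site_filters(r)$verdict, "pass")

  # 12:0 strand split: exact two-sided binomial p = 2 * 0.5^12 ~ 4.9e-4
  r <- clean; r$alt_t <- 12; r$alt_fwd <- 12; r$alt_rev <- 0
  expect_equal(exact_binom_p(12, 12), 2 * 0.5^12, tolerance = 1e-12)
  expect_equal(apply_site_filters(r)$failed, "sb")

  r <- clean; r$detp_frac <- 0.1
  expect_equal(apply_site_filters(r)$failed, "detp")

  expect_equal(apply_site_filters(clean)$verdict, "pass")
  expect_length(apply_site_filters(clean)$failed, 0)
})

test_that("missing metrics fail closed", {
  r <- sim_variant_records(1, list(), seed = 2)
  r$mmqs <- NA
  res <- apply_site_filters(r)
  expect_equal(res$verdict, "fail")
  expect_true("mmqs" %in% res$failed)
})

test_that("filter engine agrees with brute-force re-evaluation on fuzzed records", {
  recs <- fuzz_records(2000, seed = 99)
  res <- apply_site_filters_df(recs)
  brute <- vapply(seq_len(nrow(recs)), function(i) {
    paste(brute_filters(recs[i, ]), collapse = ",")
  }, "")
  expect_identical(res$filter_failed, brute)
})
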