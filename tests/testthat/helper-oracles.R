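# Independent oracles used across the suite. These re-derive expectations by
# brute force and must stay independent of the implementation paths they
# check.

# Two-sided exact binomial p-value for x of n at p = 0.5, from first
# principles (sum of outcome probabilities no larger than the observed one).
exact_binom_p <- function(x, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# Brute-force re-evaluation of the ten site-filter inequalities.
brute_filters <- function(rec) {
  failed <- character(0)
  if (!(rec$genotype_quality >= 15 || rec$somatic_score >= 15)) {
    failed <- c(failed, "conf")
  }
  if (!(rec$depth_t + rec$depth_n >= 4)) failed <- c(failed, "dp")
  if (!(rec$mq0_reads < 5)) failed <- c(failed, "mq0")
  n_alt <- rec$alt_fwd + rec$alt_rev
  p_sb <- if (n_alt == 0) 1 else exact_binom_p(rec$alt_fwd, n_alt)
  if (!(p_sb > 0.005)) failed <- c(failed, "sb")
  if (!(rec$mmqs <= 20)) failed <- c(failed, "mmqs")
  if (!(rec$amm <= 1.5)) failed <- c(failed, "amm")
  if (rec$detp_frac < 0.2 || rec$detp_frac > 0.8) failed <- c(failed, "detp")
  if (!(rec$alt_t >= 4)) failed <- c(failed, "ad")
  if (!(rec$alt_n <= 3)) failed <- c(failed, "gad")
  if (rec$n_multi_alt >= 2) failed <- c(failed, "ma")
  failed
}

# Random records straddling every filter boundary.
fuzz_records <- function(n, seed) {
  set.seed(seed)
  alt_t <- sample(0:20, n, replace = TRUE)
  alt_fwd <- vapply(alt_t, function(a) sample(0:a, 1L), 1L)
  data.frame(
    somatic_score = runif(n, 0, 40),
    genotype_quality = runif(n, 0, 40),
    depth_t = sample(0:30, n, replace = TRUE),
    depth_n = sample(0:30, n, replace = TRUE),
    alt_t = alt_t,
    alt_fwd = alt_fwd,
    alt_rev = alt_t - alt_fwd,
    alt_n = sample(0:6, n, replace = TRUE),
    mq0_reads = sample(0:8, n, replace = TRUE),
    mmqs = runif(n, 0, 40),
    amm = runif(n, 0, 3),
    detp_frac = runif(n, 0, 1),
    n_multi_alt = sample(1:3, n, replace = TRUE)
  )
}

# Every 9-substring of the mutant protein covering any novel residue.
brute_9mers <- function(mutant, novel_pos) {
  L <- nchar(mutant)
  if (L < 9L) return(character(0))
  peps <- character(0)
  for (s in 1:(L - 8L)) {
    if (any(novel_pos >= s & novel_pos <= s + 8L)) {
      peps <- c(peps, substr(mutant, s, s + 8L))
    }
  }
  unique(peps)
}

# Exhaustive 0.01-step search over the 2-signature simplex (scale optimized
# in closed form per step): the NNLS oracle.
grid_fractions_2sig <- function(spectrum, c1, c2) {
  s <- as.numeric(spectrum)
  best <- c(f = NA, res = Inf)
  for (f in seq(0, 1, by = 0.01)) {
    d <- f * c1 + (1 - f) * c2
    m <- sum(s * d) / sum(d * d)
    res <- sum((s - m * d)^2)
    if (res < best["res"]) best <- c(f = f, res = res)
  }
  best[["f"]]
}

# Simple pileup builder for the genotype model tests.
make_reads <- function(bases, qual = 40, mapq = 50) {
  data.frame(base = bases, qual = qual, mapq = mapq, is_dup = FALSE)
}

# A random 30-signature catalog named S1..S30 shared by classification tests.
cosmic_like_catalog <- function(seed = 42) {
  sim_signature_catalog(30, concentration = 0.05, seed = seed)
}

# Build a tumor profile end-to-end from simulated mutations.
profile_from_simulation <- function(catalog, exposures, n_snv, n_indel,
                                    seed, msi_high = NULL) {
  mut <- sim_mutation_catalog(catalog, exposures, n_snv, n_indel, seed = seed)
  sp <- build_spectrum(mut)
  pr <- fit_exposures(sp, catalog)
  list(
    n_snv = n_snv, n_indel = n_indel,
    prevalence = mutation_prevalence(n_snv + n_indel),
    exposures = pr$fractions,
    msi_high = msi_high
  )
}
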