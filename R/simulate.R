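## Synthetic-data generators.
##
## Every input the pipeline consumes can be generated here with known ground
## truth, so each analysis stage is testable without controlled-access
## sequencing data. All generators are deterministic given their seed.

#' Derive a per-generator sub-seed from a master seed
#'
#' A simple multiplicative split so that independent generators driven by one
#' master seed do not share streams. Result always fits a 32-bit integer.
#'
#' @param seed master integer seed.
#' @param k stream index (small non-negative integer).
#' @return integer sub-seed in [0, 2^31 - 2].
#' @export
split_seed <- function(seed, k = 0L) {
  as.integer((as.numeric(seed) * 48271 + 7919 * (k + 1)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a signature catalog
#'
#' Draws each signature as a Dirichlet sample over the 96 trinucleotide
#' channels. Small concentration values give sparse, nearly disjoint
#' signatures (easy to separate); large values give flat ones.
#'
#' @param n_signatures number of signatures (rows), >= 1.
#' @param concentration Dirichlet concentration per channel (default 0.05,
#'   sparse enough that two signatures rarely share support).
#' @param seed integer seed.
#' @return matrix of n_signatures x 96, rows summing to 1, rownames "S1"...
#' @export
sim_signature_catalog <- function(n_signatures, concentration = 0.05, seed = 1L) {
  if (!is.numeric(n_signatures) || n_signatures < 1) {
    stop("n_signatures must be >= 1")
  }
  set.seed(seed)
  n_signatures <- as.integer(n_signatures)
  m <- matrix(stats::rgamma(n_signatures * 96L, shape = concentration),
              nrow = n_signatures)
  m <- m / rowSums(m)
  rownames(m) <- paste0("S", seq_len(n_signatures))
  colnames(m) <- trinuc_channels()
  m
}

## Default per-site read metrics engineered to pass all ten site filters.
pass_metrics <- function(n) {
  depth_t <- 60L + stats::rpois(n, 20)
  depth_n <- 30L + stats::rpois(n, 10)
  alt_t <- pmax(8L, as.integer(round(0.4 * depth_t)))
  alt_fwd <- alt_t %/% 2L
  data.frame(
    depth_t = depth_t,
    depth_n = depth_n,
    alt_t = alt_t,
    alt_n = 0L,
    mq0_reads = 0L,
    alt_fwd = alt_fwd,
    alt_rev = alt_t - alt_fwd,
    mmqs = 5,
    amm = 0.5,
    detp_frac = 0.5,
    n_multi_alt = 1L,
    somatic_score = 60,
    genotype_quality = 60
  )
}

#' Simulate a somatic mutation catalog from known signature exposures
#'
#' SNV channels are multinomial draws from `t(catalog) %*% exposures`; each
#' SNV is emitted with a consistent reference trinucleotide context, on a
#' random strand (so purine-reference records exercise the strand collapse).
#' Indels are 1-bp insertions/deletions in homopolymer context. All records
#' carry read metrics that pass the site filters.
#'
#' @param catalog signature catalog matrix (rows x 96).
#' @param exposures per-signature fractions summing to 1.
#' @param n_snv,n_indel counts of SNVs and indels to emit.
#' @param capture_mb capture size in megabases (default 62.52).
#' @param seed integer seed.
#' @return data.frame of mutation records with `channel_truth` column.
#' @export
sim_mutation_catalog <- function(catalog, exposures, n_snv, n_indel = 0L,
                                 capture_mb = 62.52, seed = 1L) {
  if (length(exposures) != nrow(catalog)) {
    stop("exposures length must equal catalog rows")
  }
  if (abs(sum(exposures) - 1) > 1e-6) {
    stop("exposures must sum to 1 (within 1e-6)")
  }
  if (n_snv < 0 || n_indel < 0) stop("counts must be non-negative")
  set.seed(seed)
  n_snv <- as.integer(n_snv); n_indel <- as.integer(n_indel)
  n <- n_snv + n_indel
  if (n == 0L) {
    return(cbind(data.frame(chrom = character(0), pos = integer(0),
                            ref = character(0), alt = character(0),
                            var_class = character(0), context = character(0),
                            channel_truth = character(0)),
                 pass_metrics(0L)))
  }
  mix <- as.numeric(crossprod(catalog, exposures))
  chans <- trinuc_channels()
  bases <- c("A", "C", "G", "T")

  ## genomic coordinates: spread over 22 chromosomes, no adjacent collisions
  chrom <- sample(paste0("chr", 1:22), n, replace = TRUE)
  span <- max(2L, as.integer(ceiling(capture_mb * 1e6 / 22)))
  pos <- sample.int(span %/% 2L, n, replace = TRUE) * 2L  # even positions: never adjacent

  rec <- data.frame(chrom = chrom, pos = pos, ref = NA_character_,
                    alt = NA_character_, var_class = NA_character_,
                    context = NA_character_, channel_truth = NA_character_,
                    stringsAsFactors = FALSE)

  if (n_snv > 0L) {
    idx <- seq_len(n_snv)
    ch <- sample.int(96L, n_snv, replace = TRUE, prob = mix)
    lab <- chans[ch]
    ref <- substr(lab, 3, 3); alt <- substr(lab, 5, 5)
    ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
    flip <- stats::runif(n_snv) < 0.5
    ref[flip] <- complement_base(ref[flip])
    alt[flip] <- complement_base(alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
    rec$ref[idx] <- ref; rec$alt[idx] <- alt; rec$context[idx] <- ctx
    rec$var_class[idx] <- "SNV"
    rec$channel_truth[idx] <- lab
  }
  if (n_indel > 0L) {
    idx <- n_snv + seq_len(n_indel)
    unit <- sample(bases, n_indel, replace = TRUE)
    is_del <- stats::runif(n_indel) < 0.5
    rec$ref[idx] <- ifelse(is_del, paste0(unit, unit), unit)
    rec$alt[idx] <- ifelse(is_del, unit, paste0(unit, unit))
    rec$var_class[idx] <- ifelse(is_del, "deletion", "insertion")
    rec$context[idx] <- paste0(unit, unit, unit)  # homopolymer context
  }
  out <- cbind(rec, pass_metrics(n))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

site_filter_names <- function() {
  c("conf", "dp", "mq0", "sb", "mmqs", "amm", "detp", "ad", "gad", "ma")
}

#' Simulate per-site records with controlled filter failures
#'
#' Records default to metrics that pass all ten site filters; `corruption_spec`
#' names filters and the fraction of records corrupted to fail each. Each
#' record's `failed_truth` column lists the filters it was constructed to
#' fail (comma-separated; empty string = clean). Corruptions touching the
#' alt-depth metrics (dp, sb, ad) are mutually exclusive per record; note a
#' `dp` corruption necessarily also fails `ad` (alt depth cannot exceed a
#' total depth below 4), so its label is "dp,ad".
#'
#' @param n_sites number of records.
#' @param corruption_spec named list/vector of rates in [0,1], names drawn
#'   from the ten filter names.
#' @param seed integer seed.
#' @return data.frame of records with metric columns and `failed_truth`.
#' @export
sim_variant_records <- function(n_sites, corruption_spec = list(), seed = 1L) {
  rates <- unlist(corruption_spec)
  if (length(rates)) {
    bad <- setdiff(names(rates), site_filter_names())
    if (length(bad)) stop("unknown filter name(s): ", paste(bad, collapse = ", "))
    if (any(rates < 0 | rates > 1)) stop("corruption rates must be in [0,1]")
  }
  set.seed(seed)
  n_sites <- as.integer(n_sites)
  rec <- pass_metrics(n_sites)
  failed <- vector("list", n_sites)
  for (i in seq_len(n_sites)) failed[[i]] <- character(0)

  fire <- function(nm) {
    if (is.null(rates) || !nm %in% names(rates)) return(logical(n_sites))
    stats::runif(n_sites) < rates[[nm]]
  }
  hit <- lapply(stats::setNames(site_filter_names(), site_filter_names()), fire)
  ## dp/sb/ad all rewrite alt depths: keep only the first that fired
  excl <- c("dp", "sb", "ad")
  for (i in seq_len(n_sites)) {
    on <- excl[vapply(excl, function(f) hit[[f]][i], TRUE)]
    if (length(on) > 1L) for (f in on[-1L]) hit[[f]][i] <- FALSE
  }

  w <- hit$conf
  rec$somatic_score[w] <- 10; rec$genotype_quality[w] <- 10
  w <- hit$dp
  rec$depth_t[w] <- 2L; rec$depth_n[w] <- 1L
  rec$alt_t[w] <- 2L; rec$alt_fwd[w] <- 1L; rec$alt_rev[w] <- 1L
  w <- hit$mq0
  rec$mq0_reads[w] <- 5L
  w <- hit$sb
  rec$alt_t[w] <- pmax(rec$alt_t[w], 12L)
  rec$alt_fwd[w] <- rec$alt_t[w]; rec$alt_rev[w] <- 0L
  w <- hit$mmqs; rec$mmqs[w] <- 30
  w <- hit$amm; rec$amm[w] <- 2.5
  w <- hit$detp; rec$detp_frac[w] <- 0.1
  w <- hit$ad
  rec$alt_t[w] <- 2L; rec$alt_fwd[w] <- 1L; rec$alt_rev[w] <- 1L
  w <- hit$gad; rec$alt_n[w] <- 5L
  w <- hit$ma; rec$n_multi_alt[w] <- 2L

  for (i in seq_len(n_sites)) {
    lab <- site_filter_names()[vapply(site_filter_names(),
                                      function(f) hit[[f]][i], TRUE)]
    if ("dp" %in% lab) lab <- union(lab, "ad")
    failed[[i]] <- lab[order(match(lab, site_filter_names()))]
  }
  rec$failed_truth <- vapply(failed, paste, "", collapse = ",")
  rec
}

#' Simulate microsatellite loci and tumor/normal repeat-length distributions
#'
#' Stable loci concentrate read support on the germline repeat length, with a
#' number of well-supported lengths at most `floor(mu + 3*sigma)` plus
#' sub-threshold stutter. Unstable loci emit at least `ceil(mu + 3*sigma) + 1`
#' distinct lengths each clearing the 5%-of-max support rule. The normal
#' sample is always stable.
#'
#' @param n_loci number of homopolymer loci.
#' @param instability_rate fraction of loci made unstable in the tumor.
#' @param mean_depth mean read depth per locus (Poisson).
#' @param seed integer seed.
#' @return list with `loci` (locus table incl. background mu/sigma),
#'   `tumor` and `normal` long-format count tables, and `truth` flags.
#' @export
sim_msi_data <- function(n_loci, instability_rate, mean_depth = 100, seed = 1L) {
  if (instability_rate < 0 || instability_rate > 1) {
    stop("instability_rate must be in [0,1]")
  }
  if (mean_depth <= 0) stop("mean_depth must be positive")
  set.seed(seed)
  n_loci <- as.integer(n_loci)
  germ_len <- sample(8:15, n_loci, replace = TRUE)
  loci <- data.frame(
    locus_id = sprintf("MS%05d", seq_len(n_loci)),
    chrom = sample(paste0("chr", 1:22), n_loci, replace = TRUE),
    start = sample.int(1e8, n_loci),
    unit = sample(c("A", "T"), n_loci, replace = TRUE),
    mu = round(stats::runif(n_loci, 1.5, 3.0), 2),
    sigma = round(stats::runif(n_loci, 0.3, 0.8), 2),
    stringsAsFactors = FALSE
  )
  loci$end <- loci$start + germ_len
  unstable <- stats::runif(n_loci) < instability_rate

  emit <- function(i, make_unstable) {
    depth <- stats::rpois(1, mean_depth)
    if (depth < 1) depth <- 1L
    L <- germ_len[i]
    if (!make_unstable) {
      k_cap <- max(1L, floor(loci$mu[i] + 3 * loci$sigma[i]))
      k <- sample.int(min(2L, k_cap), 1L)
      lens <- L + seq_len(k) - 1L
      main <- as.integer(ceiling(depth * 0.78))
      counts <- c(main, rep(as.integer(ceiling(depth * 0.15)), k - 1L))
      ## sub-threshold stutter (support <= 5% of max: not tallied)
      stut <- floor(0.04 * main)
      if (stut >= 1) { lens <- c(lens, L - 1L); counts <- c(counts, stut) }
    } else {
      k <- as.integer(ceiling(loci$mu[i] + 3 * loci$sigma[i])) + 1L +
        sample(0:2, 1L)
      offs <- c(0L, as.integer(ceiling(seq_len(k - 1L) / 2)) *
                  rep_len(c(1L, -1L), k - 1L))
      lens <- L + offs
      main <- as.integer(ceiling(depth * 0.4))
      rest <- as.integer(ceiling(depth * 0.6 / (k - 1L)))
      counts <- c(main, rep(rest, k - 1L))
    }
    data.frame(locus_id = loci$locus_id[i], repeat_length = lens,
               read_count = counts, stringsAsFactors = FALSE)
  }

  tumor <- do.call(rbind, lapply(seq_len(n_loci), function(i) emit(i, unstable[i])))
  normal <- do.call(rbind, lapply(seq_len(n_loci), function(i) emit(i, FALSE)))
  list(loci = loci, tumor = tumor, normal = normal,
       truth = data.frame(locus_id = loci$locus_id, unstable = unstable))
}

#' Build an allelic-state segment list realizing a target tumor ploidy
#'
#' Composes a genome of (A, B) segments, mostly diploid (1,1), whose
#' length-weighted mean copy number equals approximately the requested
#' ploidy. Always includes a copy-neutral LOH (2,0) block for allele-fraction
#' identifiability, and at least `n_aberrant` non-(1,1) segments.
#'
#' @param tau_target target tumor ploidy (length-weighted mean copy number).
#' @param n_aberrant minimum number of aberrant segments (>= 5 recommended).
#' @param genome_mb total genome span in Mb (spread over 22 chromosomes).
#' @param seed integer seed.
#' @return data.frame(chrom, start, end, A, B); attribute `tau` holds the
#'   realized length-weighted ploidy.
#' @export
sim_segment_truth <- function(tau_target = 2.0, n_aberrant = 6L,
                              genome_mb = 880, seed = 1L) {
  set.seed(seed)
  ## aberrant composition: fractions of the genome by state, solved so that
  ## the length-weighted mean copy number equals tau_target exactly.
  ## Always: (2,0) CN-LOH (tau-neutral, anchors purity via AF) and a small
  ## (1,0) loss; the (2,1)/(2,2) gain fractions absorb the remainder.
  if (tau_target < 1.3 || tau_target > 3.4) {
    stop("tau_target must lie in [1.3, 3.4] for this composition")
  }
  frac <- list(`2_0` = 0.075)
  if (tau_target < 2) {
    frac[["1_0"]] <- (2 - tau_target) + 0.05
    frac[["2_1"]] <- 0.05
  } else {
    frac[["1_0"]] <- 0.05
    need <- tau_target - 2 + 0.05
    g1 <- min(need, 0.4)
    frac[["2_1"]] <- g1
    if (need > g1 + 1e-12) frac[["2_2"]] <- (need - g1) / 2
  }
  used <- sum(unlist(frac))

  ## split each state's fraction into 1+ segments until >= n_aberrant
  pieces <- list()
  for (nm in names(frac)) {
    ab <- as.integer(strsplit(nm, "_")[[1]])
    k <- max(1L, as.integer(round(frac[[nm]] / 0.1)))
    for (j in seq_len(k)) {
      pieces[[length(pieces) + 1L]] <- list(A = ab[1], B = ab[2],
                                            w = frac[[nm]] / k)
    }
  }
  while (length(pieces) < n_aberrant) {
    i <- which.max(vapply(pieces, function(p) p$w, 0))
    p <- pieces[[i]]
    pieces[[i]]$w <- p$w / 2
    pieces[[length(pieces) + 1L]] <- list(A = p$A, B = p$B, w = p$w / 2)
  }
  ## remaining genome is diploid, split into a few blocks
  n_dip <- 8L
  for (j in seq_len(n_dip)) {
    pieces[[length(pieces) + 1L]] <- list(A = 1L, B = 1L, w = (1 - used) / n_dip)
  }
  pieces <- sample(pieces)

  w <- vapply(pieces, function(p) p$w, 0)
  len <- round(w * genome_mb * 1e6)
  chrom <- paste0("chr", rep_len(1:22, length(pieces)))
  start <- integer(length(pieces))
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    start[i] <- c(0L, cumsum(len[i]))[seq_along(i)]
  }
  seg <- data.frame(chrom = chrom, start = start, end = start + len,
                    A = vapply(pieces, function(p) p$A, 0L),
                    B = vapply(pieces, function(p) p$B, 0L))
  cn <- seg$A + seg$B
  attr(seg, "tau") <- sum(cn * len) / sum(len)
  seg
}

#' Simulate exon-level coverage and allele-fraction statistics
#'
#' Forward model of the copy-number inference: given segment truth (A, B),
#' purity alpha and the implied ploidy tau, relative coverage per exon is
#' drawn around `(alpha*(A+B) + 2*(1-alpha)) / (alpha*tau + 2*(1-alpha))`
#' and heterozygous-SNP majority allele fractions around
#' `(alpha*A + (1-alpha)) / (alpha*(A+B) + 2*(1-alpha))`, both with Gaussian
#' noise.
#'
#' @param segment_truth data.frame(chrom, start, end, A, B).
#' @param purity tumor purity alpha in (0, 1].
#' @param n_exons total number of exons to distribute over segments.
#' @param het_snp_rate mean heterozygous SNPs per exon (Poisson).
#' @param noise_sd per-exon relative-coverage noise sd.
#' @param af_sd per-SNP allele-fraction noise sd.
#' @param seed integer seed.
#' @param tumor_ploidy override the ploidy implied by segment_truth.
#' @return list(exons = exon-stat data.frame, truth = list(alpha, tau, segments)).
#' @export
sim_cnv_profile <- function(segment_truth, purity, n_exons = 400L,
                            het_snp_rate = 1.0, noise_sd = 0.05,
                            af_sd = 0.02, seed = 1L, tumor_ploidy = NULL) {
  st <- segment_truth
  if (any(st$B > st$A) || any(st$A < 0) || any(st$B < 0) ||
      any(st$A + st$B == 0)) {
    stop("invalid allelic state: need A >= B >= 0 and (A,B) != (0,0)")
  }
  if (purity <= 0 || purity > 1) stop("purity must be in (0,1]")
  set.seed(seed)
  len <- st$end - st$start
  tau <- if (is.null(tumor_ploidy)) sum((st$A + st$B) * len) / sum(len)
         else tumor_ploidy
  a <- purity
  denom_g <- a * tau + 2 * (1 - a)
  n_seg <- nrow(st)
  ## distribute exons proportional to segment length, >= 2 each
  n_ex <- pmax(2L, as.integer(round(n_exons * len / sum(len))))
  rows <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    k <- n_ex[s]
    A <- st$A[s]; B <- st$B[s]
    rc_exp <- (a * (A + B) + 2 * (1 - a)) / denom_g
    af_exp <- (a * A + (1 - a)) / (a * (A + B) + 2 * (1 - a))
    estart <- st$start[s] + sort(sample.int(max(len[s] - 200L, k), k))
    elen <- 150L
    nh <- stats::rpois(k, het_snp_rate)
    af_t <- rep(NA_real_, k); af_n <- rep(NA_real_, k)
    af_t_sd <- rep(NA_real_, k); af_n_sd <- rep(NA_real_, k)
    has <- nh > 0L
    af_t[has] <- clamp(stats::rnorm(sum(has), af_exp, af_sd / sqrt(nh[has])),
                       0.5, 1)
    af_n[has] <- clamp(0.5 + abs(stats::rnorm(sum(has), 0, 0.01)), 0.5, 0.75)
    many <- nh >= 3L
    af_t_sd[many] <- af_sd
    af_n_sd[many] <- 0.01
    rows[[s]] <- data.frame(
      chrom = st$chrom[s], start = estart, end = estart + elen,
      length = elen,
      rc_mean = stats::rnorm(k, rc_exp, noise_sd),
      rc_sd = noise_sd,
      af_t = af_t, af_n = af_n, af_t_sd = af_t_sd, af_n_sd = af_n_sd,
      n_het_snps = nh,
      segment_truth = s,
      stringsAsFactors = FALSE
    )
  }
  exons <- do.call(rbind, rows)
  exons$rc_mean <- pmax(exons$rc_mean, 0.01)
  list(exons = exons,
       truth = list(alpha = a, tau = tau, segments = st))
}

#' Simulate a TPM expression matrix with group structure
#'
#' Genes have log-normal baseline expression; each group gets a disjoint set
#' of marker genes shifted by `effect_size` on the log2 scale. Columns are
#' rescaled to sum to 1e6 (TPM convention).
#'
#' @param n_genes number of genes (>= 500 recommended for downstream top-500
#'   selection).
#' @param groups named integer vector: samples per group, e.g. c(A = 5, B = 5).
#' @param effect_size log2 shift applied to group-marker genes.
#' @param seed integer seed.
#' @return numeric matrix genes x samples; attribute `group` holds labels.
#' @export
sim_expression_matrix <- function(n_genes = 2000L, groups = c(A = 5L, B = 5L),
                                  effect_size = 2, seed = 1L) {
  if (effect_size < 0) stop("effect_size must be non-negative")
  set.seed(seed)
  n_genes <- as.integer(n_genes)
  n_samples <- sum(groups)
  glab <- rep(names(groups), groups)
  base <- stats::rnorm(n_genes, mean = 3, sd = 2)
  n_mark <- max(1L, n_genes %/% 10L)
  markers <- split(sample.int(n_genes, n_mark * length(groups)),
                   rep(names(groups), each = n_mark))
  lg <- matrix(stats::rnorm(n_genes * n_samples, 0, 1), n_genes, n_samples) + base
  for (g in names(groups)) {
    lg[markers[[g]], glab == g] <- lg[markers[[g]], glab == g] + effect_size
  }
  tpm <- pmax(2^lg - 1, 0)
  tpm <- sweep(tpm, 2, colSums(tpm), "/") * 1e6
  rownames(tpm) <- sprintf("gene%05d", seq_len(n_genes))
  colnames(tpm) <- paste0(glab, ".", stats::ave(seq_len(n_samples), glab,
                                                FUN = seq_along))
  attr(tpm, "group") <- glab
  tpm
}
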