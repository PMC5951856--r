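## Paired tumor/normal genotype model.
##
## Sites with at least 8 unique (non-duplicate) reads of mapping quality >= 20
## in both samples are scored over the 10 diploid genotypes; the joint
## tumor/normal pair posterior classifies each site as homozygous-reference,
## germline, LOH, or somatic, with a Phred-scaled somatic score (SS).

DIPLOID_GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")

#' Per-sample genotype log-likelihoods from a read pileup
#'
#' Reads with mapping quality below 20 or flagged duplicate are ignored. Each
#' remaining read contributes `log(0.5 * p(base|a1) + 0.5 * p(base|a2))` per
#' genotype \{a1, a2\}, with `p(base|a) = 1 - eps` when the read base equals a
#' and `eps / 3` otherwise, `eps = 10^(-min(base quality, mapping quality)/10)`.
#' Qualities are capped at Q60 and floored at Q2 (so eps never reaches 0 or 1).
#'
#' @param reads data.frame with columns `base`, `qual`, `mapq`, `is_dup`.
#' @param min_reads qualifying-read floor below which the site is skipped.
#' @return named numeric vector of 10 log-likelihoods, or NULL when fewer
#'   than `min_reads` qualifying reads remain (site-skipped signal).
#' @export
genotype_likelihoods <- function(reads, min_reads = 8L) {
  keep <- !reads$is_dup & reads$mapq >= 20
  reads <- reads[keep, , drop = FALSE]
  if (nrow(reads) < min_reads) return(NULL)
  q <- clamp(pmin(reads$qual, reads$mapq), 2, 60)
  eps <- 10^(-q / 10)
  bases <- c("A", "C", "G", "T")
  ## p[read, allele]
  p <- matrix(rep(eps / 3, 4L), ncol = 4L)
  for (j in seq_along(bases)) {
    hit <- reads$base == bases[j]
    p[hit, j] <- 1 - eps[hit]
  }
  ll <- vapply(DIPLOID_GENOTYPES, function(g) {
    a1 <- match(substr(g, 1, 1), bases)
    a2 <- match(substr(g, 2, 2), bases)
    sum(log(0.5 * p[, a1] + 0.5 * p[, a2]))
  }, 0)
  ll
}

genotype_prior <- function(ref_base, het_rate = 1e-3, other_rate = 1e-6,
                           reference_prior = NULL) {
  gts <- DIPLOID_GENOTYPES
  hom_ref <- paste0(ref_base, ref_base)
  has_ref <- grepl(ref_base, gts, fixed = TRUE)
  het_ref <- has_ref & gts != hom_ref          # 3 heterozygotes with ref
  prior <- numeric(10L)
  prior[het_ref] <- het_rate / sum(het_ref)
  prior[!has_ref] <- other_rate / sum(!has_ref)
  if (is.null(reference_prior)) reference_prior <- 1 - het_rate - other_rate
  prior[gts == hom_ref] <- reference_prior
  stats::setNames(prior / sum(prior), gts)
}

#' Classify a tumor/normal genotype pair
#'
#' Forms the joint posterior over the 100 genotype pairs with prior
#' `P(G_n)` built from a reference prior and the heterozygosity rate, and
#' `P(G_t | G_n) = 1 - somatic_rate` when equal, `somatic_rate / 9` otherwise.
#' The maximum-a-posteriori pair determines the category: equal genotypes are
#' germline (hom_ref when both match the reference), normal-het with tumor-hom
#' is LOH, anything else is somatic. The somatic score is
#' `SS = -10 log10 P(G_t = G_n | data)` capped at 255; germline/LOH calls get
#' a Phred-scaled pair quality instead. Argmax ties break toward genotypes
#' containing the reference allele.
#'
#' @param tumor_ll,normal_ll named log-likelihood vectors from
#'   [genotype_likelihoods()].
#' @param ref_base reference base at the site.
#' @param priors list with `het_rate`, `somatic_rate`, and optionally
#'   `reference_prior`, `other_rate`.
#' @return list with `tumor_genotype`, `normal_genotype`, `category`
#'   (hom_ref/germline/LOH/somatic), `somatic_score` (somatic only),
#'   `germline_quality` (otherwise), and `posterior` (10x10 matrix).
#' @export
classify_genotype_pair <- function(tumor_ll, normal_ll, ref_base,
                                   priors = list(het_rate = 1e-3,
                                                 somatic_rate = 1e-4)) {
  stopifnot(all(is.finite(tumor_ll)), all(is.finite(normal_ll)))
  het_rate <- priors$het_rate %||% 1e-3
  somatic_rate <- priors$somatic_rate %||% 1e-4
  other_rate <- priors$other_rate %||% 1e-6
  pn <- genotype_prior(ref_base, het_rate, other_rate, priors$reference_prior)
  gts <- DIPLOID_GENOTYPES

  ## joint log posterior over 100 pairs (rows: normal, cols: tumor)
  trans <- matrix(log(somatic_rate / 9), 10L, 10L)
  diag(trans) <- log(1 - somatic_rate)
  lj <- outer(normal_ll + log(pn), tumor_ll, "+") + trans
  lj <- lj - max(lj)
  post <- exp(lj) / sum(exp(lj))
  dimnames(post) <- list(normal = gts, tumor = gts)

  ## MAP pair; ties break toward genotypes containing the reference allele
  mx <- max(post)
  cand <- which(post >= mx - 1e-12, arr.ind = TRUE)
  if (nrow(cand) > 1L) {
    score <- grepl(ref_base, gts[cand[, 1]], fixed = TRUE) +
      grepl(ref_base, gts[cand[, 2]], fixed = TRUE)
    cand <- cand[order(-score, cand[, 1], cand[, 2]), , drop = FALSE]
  }
  gn <- gts[cand[1, 1]]; gt <- gts[cand[1, 2]]

  hom_ref <- paste0(ref_base, ref_base)
  is_hom <- function(g) substr(g, 1, 1) == substr(g, 2, 2)
  category <-
    if (gn == gt && gn == hom_ref) "hom_ref"
    else if (gn == gt) "germline"
    else if (!is_hom(gn) && is_hom(gt)) "LOH"
    else "somatic"

  p_equal <- sum(diag(post))
  p_pair <- post[cand[1, 1], cand[1, 2]]
  phred <- function(p) min(255, -10 * log10(max(p, 1e-26)))
  out <- list(tumor_genotype = gt, normal_genotype = gn, category = category,
              posterior = post)
  if (category == "somatic") {
    out$somatic_score <- phred(p_equal)
    out$germline_quality <- NULL
  } else {
    out$somatic_score <- NULL
    out$germline_quality <- phred(1 - p_pair)
  }
  out
}

#' Call one pileup site through the paired genotype model
#'
#' Applies the qualifying-read floor in both samples, the two-supporting-read
#' rule (fewer than two reads supporting any non-reference allele deems the
#' site homozygous reference), then classifies the genotype pair.
#'
#' @param site list with `ref_base`, `tumor` and `normal` read data.frames
#'   (columns base, qual, mapq, is_dup).
#' @param priors see [classify_genotype_pair()].
#' @return a genotype-pair call list, a list with `category = "hom_ref"`,
#'   or NULL when the site is skipped for read support.
#' @export
call_site <- function(site, priors = list(het_rate = 1e-3, somatic_rate = 1e-4)) {
  tll <- genotype_likelihoods(site$tumor)
  nll <- genotype_likelihoods(site$normal)
  if (is.null(tll) || is.null(nll)) return(NULL)
  nonref <- function(r) sum(!r$is_dup & r$mapq >= 20 & r$base != site$ref_base)
  if (nonref(site$tumor) < 2L && nonref(site$normal) < 2L) {
    return(list(category = "hom_ref",
                tumor_genotype = paste0(site$ref_base, site$ref_base),
                normal_genotype = paste0(site$ref_base, site$ref_base)))
  }
  classify_genotype_pair(tll, nll, site$ref_base, priors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
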