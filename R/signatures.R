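## 96-channel mutational-signature decomposition.
##
## The spectrum counts classifiable SNVs by pyrimidine-centered trinucleotide
## channel; exposures against a fixed signature catalog are fitted by
## non-negative least squares (with the basis fixed, single-sample NMF
## reduces to NNLS).

#' Build the 96-channel trinucleotide spectrum
#'
#' SNVs only; indels are excluded. Purine-reference mutations are
#' reverse-complemented into the pyrimidine-centered convention. Records
#' whose recorded context disagrees with the reference allele are dropped
#' and reported via the `n_errors` attribute.
#'
#' @param mutations data.frame with `ref`, `alt`, `context`, `var_class`.
#' @return named integer vector of 96 channel counts (class
#'   `trinuc_spectrum`), attribute `n_errors` = inconsistent records dropped.
#' @export
build_spectrum <- function(mutations) {
  snv <- mutations[mutations$var_class == "SNV", , drop = FALSE]
  chans <- trinuc_channels()
  counts <- stats::setNames(integer(96L), chans)
  n_err <- 0L
  if (nrow(snv)) {
    lab <- snv_channel(snv$ref, snv$alt, snv$context)
    n_err <- sum(is.na(lab))
    tab <- table(factor(lab[!is.na(lab)], levels = chans))
    counts <- stats::setNames(as.integer(tab), chans)
  }
  structure(counts, n_errors = n_err, class = c("trinuc_spectrum", "integer"))
}

#' Fit signature exposures by non-negative least squares
#'
#' Minimizes `|| spectrum - t(catalog) %*% exposures ||_2` subject to
#' non-negativity, then normalizes exposures to fractions. With a fixed,
#' known basis this is the exact single-sample analogue of the NMF fit used
#' for signature attribution.
#'
#' @param spectrum 96-channel count vector.
#' @param catalog signature matrix, rows = signatures, 96 columns.
#' @return list (class `exposure_profile`) with `fractions` (sum 1),
#'   `attributed_counts`, `active` placeholder, `residual_norm`.
#' @export
fit_exposures <- function(spectrum, catalog) {
  total <- sum(spectrum)
  if (total <= 0) stop("zero spectrum: no decomposition defined")
  stopifnot(length(spectrum) == 96L, ncol(catalog) == 96L)
  fit <- pracma::lsqnonneg(t(catalog), as.numeric(spectrum))
  w <- fit$x
  if (sum(w) == 0) stop("degenerate fit: all exposures zero")
  fractions <- stats::setNames(w / sum(w), rownames(catalog))
  structure(list(
    fractions = fractions,
    attributed_counts = fractions * total,
    residual_norm = sqrt(max(fit$resid.norm, 0)),
    total = total
  ), class = "exposure_profile")
}

#' Signatures active in a sample
#'
#' A signature is active when it is attributed at least 100 mutations or
#' more than 25% of the total.
#'
#' @param profile an `exposure_profile` from [fit_exposures()].
#' @param total_mutations total mutation count of the sample.
#' @return character vector of active signature ids.
#' @export
active_signatures <- function(profile, total_mutations = profile$total) {
  stopifnot(total_mutations >= 0)
  counts <- profile$fractions * total_mutations
  names(profile$fractions)[counts >= 100 | profile$fractions > 0.25]
}

#' Count CC>TT dinucleotide mutation events
#'
#' Counts adjacent same-chromosome SNV pairs at consecutive positions where
#' the reference dinucleotide CC mutates to TT (or GG to AA on the opposite
#' strand). Each pair is counted once. The UV hallmark.
#'
#' @param mutations data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `var_class`, sorted by (chrom, pos).
#' @return integer count.
#' @export
count_cc_tt <- function(mutations) {
  snv <- mutations[mutations$var_class == "SNV", , drop = FALSE]
  if (nrow(snv) < 2L) return(0L)
  snv <- snv[order(snv$chrom, snv$pos), , drop = FALSE]
  i <- seq_len(nrow(snv) - 1L)
  adj <- snv$chrom[i] == snv$chrom[i + 1L] & snv$pos[i + 1L] - snv$pos[i] == 1L
  cc_tt <- snv$ref[i] == "C" & snv$alt[i] == "T" &
    snv$ref[i + 1L] == "C" & snv$alt[i + 1L] == "T"
  gg_aa <- snv$ref[i] == "G" & snv$alt[i] == "A" &
    snv$ref[i + 1L] == "G" & snv$alt[i + 1L] == "A"
  sum(adj & (cc_tt | gg_aa))
}

#' Mutation prevalence per megabase
#'
#' @param n_mutations mutation count.
#' @param capture_size_mb capture size in Mb (default 62.52, the exome
#'   capture of the study design this pipeline models).
#' @return mutations per Mb, rounded to 3 significant figures.
#' @export
mutation_prevalence <- function(n_mutations, capture_size_mb = 62.52) {
  if (capture_size_mb <= 0) stop("capture_size_mb must be positive")
  signif(n_mutations / capture_size_mb, 3)
}
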