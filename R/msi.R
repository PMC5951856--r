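## Microsatellite-instability scoring from homopolymer repeat-length
## distributions.

#' Count repeat-length polymorphisms at one locus
#'
#' Loci covered by fewer than 30 reads are excluded. Otherwise the count is
#' the number of distinct repeat lengths whose read support strictly exceeds
#' 5% of the maximally supported length's support.
#'
#' @param counts named numeric vector (repeat length -> read count) or
#'   data.frame with `repeat_length`, `read_count`.
#' @param min_depth exclusion floor (default 30 reads).
#' @return integer count, or NA_integer_ when the locus is excluded.
#' @export
polymorphism_count <- function(counts, min_depth = 30L) {
  if (is.data.frame(counts)) counts <- stats::setNames(counts$read_count,
                                                       counts$repeat_length)
  counts <- counts[counts > 0]
  if (length(counts) == 0L || sum(counts) < min_depth) return(NA_integer_)
  sum(counts > 0.05 * max(counts))
}

#' Is a locus unstable?
#'
#' A microsatellite is unstable when its polymorphism count strictly exceeds
#' the background mean plus three standard deviations.
#'
#' @param n polymorphism count at the locus.
#' @param mu,sigma background mean and sd of the polymorphism count.
#' @return logical.
#' @export
is_unstable <- function(n, mu, sigma) {
  stopifnot(sigma >= 0)
  n > mu + 3 * sigma
}

per_locus_counts <- function(dists, loci, min_depth) {
  sp <- split(dists$read_count, dists$locus_id)
  n <- vapply(loci$locus_id, function(id) {
    x <- sp[[id]]
    if (is.null(x)) return(NA_integer_)
    x <- x[x > 0]
    if (length(x) == 0L || sum(x) < min_depth) return(NA_integer_)
    sum(x > 0.05 * max(x))
  }, 1L)
  n
}

#' Sample-level MSI score and MSI-high call
#'
#' Computes the percentage of evaluable loci that are unstable in the tumor,
#' subtracts the matched normal's percentage when available (each sample uses
#' its own evaluable-locus denominator), and flags MSI-high when the
#' (relative) percentage is 15% or higher.
#'
#' @param tumor_dists long-format data.frame (locus_id, repeat_length,
#'   read_count) for the tumor.
#' @param normal_dists same for the matched normal, or NULL.
#' @param loci locus table with `locus_id`, `mu`, `sigma`.
#' @param threshold MSI-high threshold in percent (default 15).
#' @param min_depth per-locus read floor (default 30).
#' @param min_loci minimum evaluable loci required (default 100).
#' @return list (class `msi_call`): `n_evaluated`, `n_unstable`,
#'   `percent_unstable`, normal counterparts when present,
#'   `relative_percent`, `msi_high`.
#' @export
msi_score <- function(tumor_dists, normal_dists = NULL, loci,
                      threshold = 15, min_depth = 30L, min_loci = 100L) {
  n_t <- per_locus_counts(tumor_dists, loci, min_depth)
  eval_t <- !is.na(n_t)
  if (sum(eval_t) < max(1L, min_loci)) {
    stop("too few evaluable loci in tumor (", sum(eval_t), " < ", min_loci, ")")
  }
  unst_t <- eval_t & is_unstable(ifelse(eval_t, n_t, 0L), loci$mu, loci$sigma)
  pct_t <- 100 * sum(unst_t) / sum(eval_t)

  pct_n <- NULL; n_unst_n <- NULL; n_eval_n <- NULL
  if (!is.null(normal_dists)) {
    n_n <- per_locus_counts(normal_dists, loci, min_depth)
    eval_n <- !is.na(n_n)
    if (sum(eval_n) < 1L) stop("no evaluable loci in normal")
    unst_n <- eval_n & is_unstable(ifelse(eval_n, n_n, 0L), loci$mu, loci$sigma)
    pct_n <- 100 * sum(unst_n) / sum(eval_n)
    n_unst_n <- sum(unst_n); n_eval_n <- sum(eval_n)
  }
  rel <- if (is.null(pct_n)) pct_t else pct_t - pct_n
  structure(list(
    n_evaluated = sum(eval_t),
    n_unstable = sum(unst_t),
    percent_unstable = pct_t,
    n_evaluated_normal = n_eval_n,
    n_unstable_normal = n_unst_n,
    percent_unstable_normal = pct_n,
    relative_percent = rel,
    msi_high = rel >= threshold,
    unstable_loci = loci$locus_id[unst_t]
  ), class = "msi_call")
}
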