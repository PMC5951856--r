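## The ten-rule somatic site filter engine.
##
## A record passes only if every filter passes; a missing metric makes that
## filter not-evaluable and the record fails closed.

#' Apply the ten somatic site filters to one record
#'
#' Filters (a record passes iff all pass):
#' \describe{
#'   \item{conf}{genotype quality or somatic score >= 15 (either suffices)}
#'   \item{dp}{tumor + normal total depth >= 4}
#'   \item{mq0}{number of mapping-quality-0 reads < 5}
#'   \item{sb}{two-sided exact binomial strand-bias p > 0.005 on the
#'     forward/reverse alternate-read split against 0.5}
#'   \item{mmqs}{mismatch quality sum per read <= 20}
#'   \item{amm}{average mismatches per read <= 1.5}
#'   \item{detp}{mean fractional distance to the 3' read end inside
#'     [0.2, 0.8]; values < 0.2 or > 0.8 mark end-of-read artifact clustering
#'     and reject}
#'   \item{ad}{tumor alternate-allele depth >= 4}
#'   \item{gad}{normal alternate-allele depth <= 3}
#'   \item{ma}{fewer than two alternate alleles each supported by >= 2 reads}
#' }
#'
#' @param record one-row data.frame (or list) with metric columns
#'   `somatic_score`, `genotype_quality`, `depth_t`, `depth_n`, `mq0_reads`,
#'   `alt_fwd`, `alt_rev`, `mmqs`, `amm`, `detp_frac`, `alt_t`, `alt_n`,
#'   `n_multi_alt`.
#' @return list(verdict = "pass"|"fail", failed = character vector of failed
#'   filter names, in canonical order).
#' @export
apply_site_filters <- function(record) {
  m <- as.list(record)
  num <- function(x) if (is.null(x) || length(x) == 0L) NA_real_ else as.numeric(x)

  checks <- c(
    conf = {
      v <- c(num(m$genotype_quality), num(m$somatic_score))
      if (all(is.na(v))) NA else any(v >= 15, na.rm = TRUE)
    },
    dp = num(m$depth_t) + num(m$depth_n) >= 4,
    mq0 = num(m$mq0_reads) < 5,
    sb = {
      f <- num(m$alt_fwd); r <- num(m$alt_rev)
      if (is.na(f) || is.na(r)) NA
      else if (f + r == 0) TRUE
      else stats::binom.test(f, f + r, p = 0.5)$p.value > 0.005
    },
    mmqs = num(m$mmqs) <= 20,
    amm = num(m$amm) <= 1.5,
    detp = {
      d <- num(m$detp_frac)
      if (is.na(d)) NA else (d >= 0.2 && d <= 0.8)
    },
    ad = num(m$alt_t) >= 4,
    gad = num(m$alt_n) <= 3,
    ma = num(m$n_multi_alt) < 2
  )
  failed <- names(checks)[is.na(checks) | !checks]  # fail closed on NA
  list(verdict = if (length(failed)) "fail" else "pass", failed = failed)
}

#' Apply the site filters to a table of records
#'
#' @param records data.frame of mutation records with the metric columns of
#'   [apply_site_filters()].
#' @return the input with `filter_verdict` and `filter_failed`
#'   (comma-separated names; "" when clean) columns appended.
#' @export
apply_site_filters_df <- function(records) {
  res <- lapply(seq_len(nrow(records)),
                function(i) apply_site_filters(records[i, , drop = FALSE]))
  records$filter_verdict <- vapply(res, `[[`, "", "verdict")
  records$filter_failed <- vapply(res, function(r) paste(r$failed, collapse = ","), "")
  records
}
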