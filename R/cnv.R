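## Allele-specific copy number: exon statistics, agglomerative segmentation,
## majority-allele-fraction correction, and joint purity/ploidy fitting.

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Compute exon-level coverage and allele-fraction statistics
#'
#' Relative coverage is tumor depth over matched-normal depth per exon; exons
#' with average depth below 5 reads in both samples are removed. SNPs are
#' deemed heterozygous when tumor depth >= 10, normal depth >= 20 and the
#' normal allele fraction lies in [0.25, 0.75]; the majority allele fraction
#' is the better-supported germline allele's depth fraction. The AF standard
#' deviation is reported only for exons with at least three heterozygous
#' SNPs.
#'
#' @param exons data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   `depth_t`, `depth_n` (mean depths), optional `rc_sd`.
#' @param snps data.frame with `chrom`, `pos`, `ref_t`, `alt_t`, `ref_n`,
#'   `alt_n` (allele read depths), or NULL.
#' @return exon-stat data.frame with `rc_mean`, `rc_sd`, `af_t`, `af_n`,
#'   `af_t_sd`, `af_n_sd`, `n_het_snps`, `length`.
#' @export
compute_exon_stats <- function(exons, snps = NULL) {
  keep <- !(exons$depth_t < 5 & exons$depth_n < 5)
  exons <- exons[keep, , drop = FALSE]
  out <- data.frame(
    chrom = exons$chrom, start = exons$start, end = exons$end,
    length = exons$end - exons$start,
    rc_mean = exons$depth_t / exons$depth_n,
    rc_sd = if ("rc_sd" %in% names(exons)) exons$rc_sd
            else (exons$depth_t / exons$depth_n) *
              sqrt(1 / pmax(exons$depth_t, 1) + 1 / pmax(exons$depth_n, 1)),
    af_t = NA_real_, af_n = NA_real_,
    af_t_sd = NA_real_, af_n_sd = NA_real_,
    n_het_snps = 0L,
    stringsAsFactors = FALSE
  )
  if (!is.null(snps) && nrow(snps)) {
    dp_t <- snps$ref_t + snps$alt_t
    dp_n <- snps$ref_n + snps$alt_n
    af_n_alt <- ifelse(dp_n > 0, snps$alt_n / dp_n, NA_real_)
    het <- dp_t >= 10 & dp_n >= 20 & !is.na(af_n_alt) &
      af_n_alt >= 0.25 & af_n_alt <= 0.75
    snps <- snps[het, , drop = FALSE]
    if (nrow(snps)) {
      ## majority allele = germline allele with the greater normal support
      major_is_alt <- snps$alt_n >= snps$ref_n
      af_m_t <- ifelse(major_is_alt, snps$alt_t, snps$ref_t) /
        (snps$ref_t + snps$alt_t)
      af_m_n <- pmax(snps$ref_n, snps$alt_n) / (snps$ref_n + snps$alt_n)
      for (i in seq_len(nrow(out))) {
        in_ex <- snps$chrom == out$chrom[i] &
          snps$pos >= out$start[i] & snps$pos < out$end[i]
        k <- sum(in_ex)
        if (k > 0L) {
          out$n_het_snps[i] <- k
          out$af_t[i] <- mean(af_m_t[in_ex])
          out$af_n[i] <- mean(af_m_n[in_ex])
          if (k >= 3L) {
            out$af_t_sd[i] <- stats::sd(af_m_t[in_ex])
            out$af_n_sd[i] <- stats::sd(af_m_n[in_ex])
          }
        }
      }
    }
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

## Welch t-test p-value from summary statistics.
welch_p <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 1 || n2 < 1) return(NA_real_)
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  se2 <- v1 + v2
  if (!is.finite(se2) || se2 <= 0) return(if (m1 == m2) 1 else 0)
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / max(n1 - 1, 1) + v2^2 / max(n2 - 1, 1))
  2 * stats::pt(-abs(t), df)
}

merge_pair <- function(a, b) {
  ## base-pair-weighted combine of RC; pooled combine of AF summaries
  wa <- a$length; wb <- b$length
  m <- (a$rc_mean * wa + b$rc_mean * wb) / (wa + wb)
  v <- (wa * (a$rc_sd^2 + (a$rc_mean - m)^2) +
        wb * (b$rc_sd^2 + (b$rc_mean - m)^2)) / (wa + wb)
  out <- a
  out$end <- b$end
  out$length <- wa + wb
  out$rc_mean <- m
  out$rc_sd <- sqrt(v)
  out$n_exons <- a$n_exons + b$n_exons
  na <- a$n_het_snps; nb <- b$n_het_snps
  out$n_het_snps <- na + nb
  pool <- function(ma, sa, mb, sb) {
    if (na + nb == 0L) return(c(NA_real_, NA_real_))
    if (na == 0L) return(c(mb, sb))
    if (nb == 0L) return(c(ma, sa))
    mm <- (ma * na + mb * nb) / (na + nb)
    sa2 <- if (is.na(sa)) 0 else sa^2
    sb2 <- if (is.na(sb)) 0 else sb^2
    vv <- ((na - 1) * sa2 + (nb - 1) * sb2 +
             na * (ma - mm)^2 + nb * (mb - mm)^2) / max(na + nb - 1, 1)
    c(mm, sqrt(vv))
  }
  t_ <- pool(a$af_t, a$af_t_sd, b$af_t, b$af_t_sd)
  n_ <- pool(a$af_n, a$af_n_sd, b$af_n, b$af_n_sd)
  out$af_t <- t_[1]
  out$af_n <- n_[1]
  out$af_t_sd <- if (out$n_het_snps >= 3L) t_[2] else NA_real_
  out$af_n_sd <- if (out$n_het_snps >= 3L) n_[2] else NA_real_
  out
}

#' Agglomerate exon statistics into copy-number segments
#'
#' Runs the fixed number of merge rounds. In each round, a left-to-right
#' single pass over current neighbours (within a chromosome) merges a pair
#' when its relative coverage — and its tumor majority allele fraction, when
#' both units carry heterozygous SNPs — does not differ (Welch two-sample
#' t-test p-value > `p_merge`); a unit merges at most once per round. Merged
#' relative coverage is the base-pair-weighted mean/sd; AF summaries are
#' pooled. After the final round, relative coverage is centered so the
#' segment-length-weighted genome-wide median equals 1.0.
#'
#' @param exon_stats exon-stat data.frame (see [compute_exon_stats()] or
#'   [sim_cnv_profile()]).
#' @param rounds number of merge rounds (default 3).
#' @param p_merge merge threshold: merge when p > p_merge (default 0.95).
#' @param center center relative coverage to weighted median 1.0 (default
#'   TRUE).
#' @return segment data.frame with the exon-stat columns plus `n_exons`.
#' @export
agglomerate_segments <- function(exon_stats, rounds = 3L, p_merge = 0.95,
                                 center = TRUE) {
  segs <- exon_stats[order(exon_stats$chrom, exon_stats$start), , drop = FALSE]
  segs$n_exons <- 1L
  segs <- split(segs, segs$chrom)
  segs <- lapply(segs, function(df) {
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  })

  can_merge <- function(a, b, p_merge) {
    p_rc <- welch_p(a$rc_mean, a$rc_sd, a$length, b$rc_mean, b$rc_sd, b$length)
    if (is.na(p_rc) || p_rc <= p_merge) return(FALSE)
    if (a$n_het_snps > 0L && b$n_het_snps > 0L &&
        !is.na(a$af_t_sd) && !is.na(b$af_t_sd)) {
      p_af <- welch_p(a$af_t, a$af_t_sd, a$n_het_snps,
                      b$af_t, b$af_t_sd, b$n_het_snps)
      if (is.na(p_af) || p_af <= p_merge) return(FALSE)
    }
    TRUE
  }

  for (r in seq_len(rounds)) {
    segs <- lapply(segs, function(units) {
      out <- list()
      i <- 1L
      while (i <= length(units)) {
        if (i < length(units) && can_merge(units[[i]], units[[i + 1L]], p_merge)) {
          out[[length(out) + 1L]] <- merge_pair(units[[i]], units[[i + 1L]])
          i <- i + 2L  # a unit merges at most once per round
        } else {
          out[[length(out) + 1L]] <- units[[i]]
          i <- i + 1L
        }
      }
      out
    })
  }
  res <- do.call(rbind, lapply(unlist(segs, recursive = FALSE), as.data.frame))
  rownames(res) <- NULL
  if (center && nrow(res)) {
    med <- weighted_median(res$rc_mean, res$length)
    res$rc_mean <- res$rc_mean / med
    res$rc_sd <- res$rc_sd / med
  }
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Correct the tumor majority allele fraction for sampling skew
#'
#' Removes the skew seen in copy-number-balanced regions, where majority-read
#' support reflects sampling bias rather than allelic imbalance:
#' `AF_corr = AF_t - (AF_n - 0.5) * exp(-0.5 * ((AF_t - AF_n) / 0.05)^2)`,
#' clamped to [0.5, 1]. Identity when AF_n = 0.5; vanishing correction when
#' tumor and normal AFs are far apart (a real imbalance).
#'
#' @param af_t,af_n tumor and normal majority allele fractions in [0.5, 1].
#' @return corrected fraction(s) in [0.5, 1].
#' @export
correct_majority_af <- function(af_t, af_n) {
  if (any(af_t < 0 | af_t > 1 | af_n < 0 | af_n > 1, na.rm = TRUE)) {
    stop("allele fractions must lie in [0, 1]")
  }
  corr <- af_t - (af_n - 0.5) * exp(-0.5 * ((af_t - af_n) / 0.05)^2)
  clamp(corr, 0.5, 1)
}

#' The default allelic-state set
#'
#' Clonal states: normal (1,1), single-copy gain (2,1), LOH (1,0),
#' copy-neutral LOH (2,0), balanced amplification (2,2). Subclonal states are
#' 50/50 mixtures of (1,1) with each non-normal basic state (clonal fraction
#' 0.5). Higher amplification states can be supplied explicitly; the default
#' set is kept minimal because redundant high-copy states open purity/state
#' mimicry (half the purity with doubled aberration fits the same data).
#'
#' @return data.frame with `A`, `B`, `clonal`.
#' @export
default_allelic_states <- function() {
  base <- rbind(
    c(1, 1), c(2, 1), c(1, 0), c(2, 0), c(2, 2)
  )
  sub <- rbind(c(2, 1), c(1, 0), c(2, 0), c(2, 2))
  data.frame(
    A = c(base[, 1], sub[, 1]),
    B = c(base[, 2], sub[, 2]),
    clonal = c(rep(1, nrow(base)), rep(0.5, nrow(sub)))
  )
}

state_expectations <- function(alpha, tau, states) {
  a_eff <- alpha * states$clonal
  cn <- states$A + states$B
  denom <- a_eff * cn + 2 * (1 - a_eff)
  rc <- denom / (a_eff * tau + 2 * (1 - a_eff))
  af <- (a_eff * states$A + (1 - a_eff)) / denom
  list(rc = rc, af = af)
}

prepare_fit_data <- function(segments, af_sd_floor, rc_sd_floor) {
  has_af <- !is.na(segments$af_t) & segments$n_het_snps >= 1L
  if (!any(has_af)) {
    stop("no AF-bearing segments: purity is unidentifiable from coverage ",
         "alone; supply segments with heterozygous SNPs")
  }
  af_corr <- rep(NA_real_, nrow(segments))
  af_corr[has_af] <- correct_majority_af(clamp(segments$af_t[has_af], 0.5, 1),
                                         clamp(segments$af_n[has_af], 0.5, 1))
  af_sd <- ifelse(is.na(segments$af_t_sd), af_sd_floor,
                  pmax(segments$af_t_sd, af_sd_floor))
  list(
    rc = segments$rc_mean,
    rc_sd = pmax(segments$rc_sd, rc_sd_floor),
    af = af_corr,
    af_sd = af_sd,
    has_af = has_af,
    w = segments$length / sum(segments$length)
  )
}

fit_loglik <- function(alpha, tau, d, states) {
  ex <- state_expectations(alpha, tau, states)
  n <- length(d$rc); k <- nrow(states)
  ll_rc <- stats::dnorm(matrix(d$rc, n, k), matrix(ex$rc, n, k, byrow = TRUE),
                        matrix(d$rc_sd, n, k), log = TRUE)
  ll_af <- matrix(0, n, k)
  ia <- which(d$has_af)
  if (length(ia)) {
    ll_af[ia, ] <- stats::dnorm(matrix(d$af[ia], length(ia), k),
                                matrix(ex$af, length(ia), k, byrow = TRUE),
                                matrix(d$af_sd[ia], length(ia), k), log = TRUE)
  }
  tot <- ll_rc + ll_af
  best <- max.col(tot, ties.method = "first")
  sum(d$w * tot[cbind(seq_len(n), best)])
}

## Projected numerical-gradient ascent with adaptive step halving.
gradient_ascent <- function(f, init, lower, upper, tol = 1e-6,
                            max_iter = 200L, h = 1e-4) {
  th <- clamp(init, lower, upper)
  ll <- f(th)
  step <- 0.1
  for (it in seq_len(max_iter)) {
    g <- vapply(seq_along(th), function(j) {
      tp <- th; tm <- th
      tp[j] <- min(th[j] + h, upper[j])
      tm[j] <- max(th[j] - h, lower[j])
      if (tp[j] == tm[j]) return(0)
      (f(tp) - f(tm)) / (tp[j] - tm[j])
    }, 0)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) break
    improved <- FALSE
    while (step > 1e-9) {
      cand <- clamp(th + step * g / gn, lower, upper)
      llc <- f(cand)
      if (llc > ll) {
        converged <- abs(llc - ll) < tol && step < 1e-4
        th <- cand; ll <- llc; step <- step * 1.5
        if (converged) { step <- 0; break }
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  list(par = th, value = ll)
}

#' Fit tumor purity and ploidy from segment statistics
#'
#' For a candidate (alpha, tau), each segment's likelihood is the best over
#' the allelic-state set of Gaussian likelihoods of its observed relative
#' coverage and corrected majority allele fraction around the state's
#' expectations; the joint log-likelihood is the segment-length-weighted sum.
#' The objective is maximized by projected numerical-gradient ascent with
#' random restarts; the best restart is kept. The reported ploidy is then
#' recomputed as the length-weighted mean tumor copy number implied by the
#' relative coverage at the fitted purity.
#'
#' @param segments segment data.frame (from [agglomerate_segments()] or
#'   [sim_cnv_profile()] exons).
#' @param state_set allelic states (default [default_allelic_states()]).
#' @param n_restarts random restarts, minimum 10.
#' @param seed integer seed for the restart initializations.
#' @param alpha_bounds,tau_bounds box constraints (defaults [0.05, 1] and
#'   [1, 8]).
#' @param af_sd_floor,rc_sd_floor lower bounds on the noise sds used in the
#'   likelihood (an AF sd floor covers segments with < 3 het SNPs).
#' @return list (class `purity_ploidy_fit`): `alpha`, `tau_opt`, `ploidy`
#'   (recomputed), `loglik`, `restarts` (per-restart solutions), `degenerate`
#'   flag (all segments best explained as normal), `states`.
#' @export
fit_purity_ploidy <- function(segments, state_set = default_allelic_states(),
                              n_restarts = 10L, seed = 1L,
                              alpha_bounds = c(0.05, 1), tau_bounds = c(1, 8),
                              af_sd_floor = 0.03, rc_sd_floor = 0.02) {
  n_restarts <- max(10L, as.integer(n_restarts))
  d <- prepare_fit_data(segments, af_sd_floor, rc_sd_floor)
  f <- function(th) fit_loglik(th[1], th[2], d, state_set)
  set.seed(seed)
  inits <- cbind(stats::runif(n_restarts, alpha_bounds[1], alpha_bounds[2]),
                 stats::runif(n_restarts, tau_bounds[1], min(tau_bounds[2], 4)))
  sols <- lapply(seq_len(n_restarts), function(i) {
    gradient_ascent(f, inits[i, ], c(alpha_bounds[1], tau_bounds[1]),
                    c(alpha_bounds[2], tau_bounds[2]))
  })
  lls <- vapply(sols, `[[`, 0, "value")
  best <- sols[[which.max(lls)]]
  alpha <- best$par[1]; tau <- best$par[2]

  ## recompute ploidy: transform RC into tumor copy number at the fit
  cn <- (d$rc * (alpha * tau + 2 * (1 - alpha)) - 2 * (1 - alpha)) / alpha
  ploidy <- sum(d$w * cn)

  ## degeneracy check: purity is unidentifiable when the aberrant-state model
  ## adds almost nothing over a single-cluster, all-normal explanation of the
  ## data (free coverage center, AF at 0.5); below one nat of average
  ## log-likelihood gain the alpha estimate carries no information
  ll_null <- stats::optimize(function(cc) {
    sum(d$w * (stats::dnorm(d$rc, cc, d$rc_sd, log = TRUE) +
                 ifelse(d$has_af,
                        stats::dnorm(ifelse(d$has_af, d$af, 0.5), 0.5,
                                     d$af_sd, log = TRUE), 0)))
  }, range(d$rc), maximum = TRUE)$objective
  degenerate <- (best$value - ll_null) < 1

  structure(list(
    alpha = alpha, tau_opt = tau, ploidy = ploidy,
    loglik = best$value,
    n_restarts = n_restarts,
    restarts = data.frame(alpha = vapply(sols, function(s) s$par[1], 0),
                          tau = vapply(sols, function(s) s$par[2], 0),
                          loglik = lls),
    degenerate = degenerate,
    states = state_set
  ), class = "purity_ploidy_fit")
}

#' Assign allelic states to segments and build the call set
#'
#' Each segment gets its maximum-likelihood allelic state under the fitted
#' (alpha, tau). Segments that are normal (1,1), or whose observed statistics
#' deviate significantly from every integral state (one-sample t of the
#' segment mean against the state expectation, p < `p_dev`), are excluded
#' from the downstream call set. Segments larger than `report_mb` megabases
#' are flagged for the detailed report.
#'
#' @param segments segment data.frame.
#' @param fit a `purity_ploidy_fit`.
#' @param p_dev deviation-test significance threshold (default 0.05).
#' @param report_mb report-size threshold in Mb (default 2.5).
#' @param af_sd_floor,rc_sd_floor as in [fit_purity_ploidy()].
#' @return the segments with `state_A`, `state_B`, `state_clonal`,
#'   `deviation_p`, `called` (in call set) and `in_report` columns.
#' @export
assign_allelic_states <- function(segments, fit, p_dev = 0.05,
                                  report_mb = 2.5,
                                  af_sd_floor = 0.03, rc_sd_floor = 0.02) {
  d <- prepare_fit_data(segments, af_sd_floor, rc_sd_floor)
  states <- fit$states
  ex <- state_expectations(fit$alpha, fit$tau_opt, states)
  n <- length(d$rc); k <- nrow(states)
  tot <- stats::dnorm(matrix(d$rc, n, k), matrix(ex$rc, n, k, byrow = TRUE),
                      matrix(d$rc_sd, n, k), log = TRUE)
  ia <- which(d$has_af)
  if (length(ia)) {
    tot[ia, ] <- tot[ia, ] +
      stats::dnorm(matrix(d$af[ia], length(ia), k),
                   matrix(ex$af, length(ia), k, byrow = TRUE),
                   matrix(d$af_sd[ia], length(ia), k), log = TRUE)
  }
  ml <- max.col(tot, ties.method = "first")
  segments$state_A <- states$A[ml]
  segments$state_B <- states$B[ml]
  segments$state_clonal <- states$clonal[ml]

  n_eff <- if ("n_exons" %in% names(segments)) pmax(segments$n_exons, 1L)
           else rep(1L, n)
  p_rc <- vapply(seq_len(n), function(i) {
    se <- d$rc_sd[i] / sqrt(n_eff[i])
    t <- (d$rc[i] - ex$rc[ml[i]]) / se
    2 * stats::pt(-abs(t), df = max(n_eff[i] - 1, 1))
  }, 0)
  p_af <- rep(NA_real_, n)
  for (i in ia) {
    ns <- max(segments$n_het_snps[i], 1L)
    se <- d$af_sd[i] / sqrt(ns)
    t <- (d$af[i] - ex$af[ml[i]]) / se
    p_af[i] <- 2 * stats::pt(-abs(t), df = max(ns - 1, 1))
  }
  segments$deviation_p <- pmin(p_rc, p_af, na.rm = TRUE)
  is_normal <- states$A[ml] == 1 & states$B[ml] == 1 & states$clonal[ml] == 1
  segments$called <- !is_normal & segments$deviation_p >= p_dev
  segments$in_report <- segments$called &
    (segments$length >= report_mb * 1e6)
  segments
}
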