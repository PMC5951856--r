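## Three-class tumor assignment (MSI / UV / pauci-mutational) and
## mismatch-repair gene screening.

#' Default classification thresholds
#'
#' @return list of the rule thresholds: `msi_exposure` (combined signature
#'   6+15 fraction), `indel_fraction`, `uv_exposure` (combined signature
#'   7+11 fraction), `uv_min_prevalence` and `pauci_ceiling` in mutations/Mb.
#' @export
default_class_thresholds <- function() {
  list(
    msi_exposure = 0.30,
    indel_fraction = 0.30,
    uv_exposure = 0.30,
    uv_min_prevalence = 10,
    pauci_ceiling = 10,
    msi_signatures = c("S6", "S15"),
    uv_signatures = c("S7", "S11")
  )
}

#' Classify one tumor into the MSI / UV / pauci-mutational scheme
#'
#' Rules, evaluated in precedence order MSI > UV > PAUCI:
#' \itemize{
#'   \item MSI when the combined exposure of the mismatch-repair signatures
#'     (6 and 15) exceeds 30%, or the indel fraction is at least 30%, or the
#'     sample is MSI-high;
#'   \item otherwise UV when the combined UV signatures (7 and 11) exceed 30%
#'     on a high-burden tumor (prevalence >= 10/Mb);
#'   \item otherwise PAUCI when the prevalence is below the pauci ceiling
#'     (default 10/Mb).
#' }
#' When both the MSI and UV criteria fire, MSI wins and the mixed-signature
#' flag is set. When no rule fires, the nearest rule is assigned with a
#' low-confidence flag (UNCLASSIFIED is not permitted).
#'
#' @param profile list/row with `n_snv`, `n_indel`, `prevalence`,
#'   `exposures` (named fractions), optional `msi_high` (logical),
#'   optional `vafs` for the purity sanity check.
#' @param thresholds see [default_class_thresholds()].
#' @return list (class `class_call`): `class` ("MSI"/"UV"/"PAUCI"),
#'   `evidence` (every rule evaluated), `flags`.
#' @export
classify_tumor <- function(profile, thresholds = default_class_thresholds()) {
  th <- utils::modifyList(default_class_thresholds(), thresholds)
  exp_of <- function(ids) {
    sum(profile$exposures[intersect(ids, names(profile$exposures))])
  }
  indel_fraction <- if (profile$n_snv + profile$n_indel > 0) {
    profile$n_indel / (profile$n_snv + profile$n_indel)
  } else 0
  msi_exp <- exp_of(th$msi_signatures)
  uv_exp <- exp_of(th$uv_signatures)
  msi_high <- isTRUE(profile$msi_high)

  msi_fires <- msi_exp > th$msi_exposure ||
    indel_fraction >= th$indel_fraction || msi_high
  uv_fires <- uv_exp > th$uv_exposure &&
    profile$prevalence >= th$uv_min_prevalence
  pauci_fires <- profile$prevalence < th$pauci_ceiling

  flags <- character(0)
  if (msi_fires && uv_fires) flags <- c(flags, "mixed-signature")

  cls <- if (msi_fires) "MSI"
    else if (uv_fires) "UV"
    else if (pauci_fires) "PAUCI"
    else {
      ## nearest rule: distance of each rule's key statistic to its threshold
      flags <- c(flags, "low-confidence")
      dists <- c(
        MSI = min(th$msi_exposure - msi_exp, th$indel_fraction - indel_fraction),
        UV = if (profile$prevalence >= th$uv_min_prevalence)
               th$uv_exposure - uv_exp else Inf,
        PAUCI = (profile$prevalence - th$pauci_ceiling) / th$pauci_ceiling
      )
      names(which.min(dists))
    }

  structure(list(
    class = cls,
    evidence = list(
      msi_exposure = msi_exp,
      indel_fraction = indel_fraction,
      msi_high = msi_high,
      uv_exposure = uv_exp,
      prevalence = profile$prevalence,
      pauci_ceiling = th$pauci_ceiling
    ),
    flags = flags
  ), class = "class_call")
}

#' Purity sanity estimate from somatic variant allele fractions
#'
#' Twice the median somatic VAF; reported alongside the copy-number-derived
#' purity, with no reconciliation attempted.
#'
#' @param vafs numeric vector of somatic variant allele fractions.
#' @return estimate in [0, 1].
#' @export
vaf_purity <- function(vafs) {
  if (!length(vafs)) return(NA_real_)
  min(1, 2 * stats::median(vafs))
}

#' Screen mismatch-repair genes for disruptive alterations
#'
#' Restricted to somatic and germline nonsense SNVs, somatic and germline
#' frameshifting insertions/deletions, and somatic gene losses, over a
#' configurable gene list (default MLH1, MSH2, MSH6, PMS2).
#'
#' @param variants data.frame with `gene`, `consequence`
#'   (nonsense/frameshift/missense/...), `origin` ("somatic"/"germline"),
#'   and optionally `hgvsp`.
#' @param gene_list genes to screen.
#' @param cn_losses optional data.frame of somatic copy-number losses with a
#'   `gene` column.
#' @return data.frame of disruptive events with `gene`, `event`, `origin`.
#' @export
screen_mmr_genes <- function(variants,
                             gene_list = c("MLH1", "MSH2", "MSH6", "PMS2"),
                             cn_losses = NULL) {
  out <- data.frame(gene = character(0), event = character(0),
                    origin = character(0), stringsAsFactors = FALSE)
  if (!is.null(variants) && nrow(variants)) {
    unk <- is.na(variants$consequence) | variants$consequence == ""
    if (any(unk)) {
      warning(sum(unk), " record(s) without annotated consequence skipped")
      variants <- variants[!unk, , drop = FALSE]
    }
    disruptive <- variants$gene %in% gene_list &
      variants$consequence %in% c("nonsense", "frameshift") &
      variants$origin %in% c("somatic", "germline")
    hit <- variants[disruptive, , drop = FALSE]
    if (nrow(hit)) {
      out <- rbind(out, data.frame(
        gene = hit$gene,
        event = paste0(hit$consequence,
                       if ("hgvsp" %in% names(hit))
                         ifelse(is.na(hit$hgvsp) | hit$hgvsp == "", "",
                                paste0(" ", hit$hgvsp)) else ""),
        origin = hit$origin, stringsAsFactors = FALSE))
    }
  }
  if (!is.null(cn_losses) && nrow(cn_losses)) {
    loss <- cn_losses[cn_losses$gene %in% gene_list, , drop = FALSE]
    if (nrow(loss)) {
      out <- rbind(out, data.frame(gene = loss$gene, event = "gene loss",
                                   origin = "somatic",
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
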