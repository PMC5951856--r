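## Flat-file I/O: MAF-like TSV tables, a minimal VCF 4.2 writer for filtered
## mutation records, and long-format microsatellite tables.

#' Write / read a tab-separated table
#'
#' Thin wrappers fixing the conventions used throughout the pipeline
#' (tab-separated, header, no quoting, no row names).
#'
#' @param x data.frame. @param path file path.
#' @return `read_tsv_table` returns a data.frame; writers return the path
#'   invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an expression matrix as genes x samples TSV
#'
#' @param mat numeric matrix with dimnames. @param path file path.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Write mutation records as minimal VCF 4.2
#'
#' Site metrics travel as INFO keys; the FILTER column carries PASS or the
#' semicolon-separated failed filter names from the ten-rule engine (records
#' not yet filtered get '.').
#'
#' @param records mutation-record data.frame (see [sim_mutation_catalog()]),
#'   optionally carrying `filter_failed` from [apply_site_filters_df()].
#' @param path output path.
#' @param sample sample name for the header.
#' @export
write_mutations_vcf <- function(records, path, sample = "TUMOR") {
  info_keys <- c("DPT", "DPN", "ADT", "ADN", "MQ0", "ALTF", "ALTR",
                 "MMQS", "AMM", "DETP", "NMA", "SS", "GQ")
  cols <- c("depth_t", "depth_n", "alt_t", "alt_n", "mq0_reads", "alt_fwd",
            "alt_rev", "mmqs", "amm", "detp_frac", "n_multi_alt",
            "somatic_score", "genotype_quality")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=sebclass %s", as.character(utils::packageVersion("sebclass"))),
    vapply(info_keys, function(k) sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"Site metric %s\">",
      k, k), ""),
    vapply(site_filter_names(), function(f) sprintf(
      "##FILTER=<ID=%s,Description=\"Failed site filter %s\">", f, f), ""),
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  )
  filt <- if ("filter_failed" %in% names(records)) {
    ifelse(records$filter_failed == "", "PASS",
           gsub(",", ";", records$filter_failed))
  } else rep(".", nrow(records))
  info <- vapply(seq_len(nrow(records)), function(i) {
    paste(sprintf("%s=%s", info_keys,
                  vapply(cols, function(cc) {
                    format(records[[cc]][i], digits = 6, trim = TRUE)
                  }, "")),
          collapse = ";")
  }, "")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  records$chrom, as.integer(records$pos), records$ref,
                  records$alt, filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal mutation VCF written by [write_mutations_vcf()]
#'
#' @param path VCF path.
#' @return mutation-record data.frame with metric columns restored.
#' @export
read_mutations_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  info_keys <- c(DPT = "depth_t", DPN = "depth_n", ADT = "alt_t",
                 ADN = "alt_n", MQ0 = "mq0_reads", ALTF = "alt_fwd",
                 ALTR = "alt_rev", MMQS = "mmqs", AMM = "amm",
                 DETP = "detp_frac", NMA = "n_multi_alt",
                 SS = "somatic_score", GQ = "genotype_quality")
  rec <- data.frame(
    chrom = vapply(parts, `[[`, "", 1),
    pos = as.integer(vapply(parts, `[[`, "", 2)),
    ref = vapply(parts, `[[`, "", 4),
    alt = vapply(parts, `[[`, "", 5),
    filter_failed = {
      f <- vapply(parts, `[[`, "", 7)
      ifelse(f %in% c("PASS", "."), "", gsub(";", ",", f))
    },
    stringsAsFactors = FALSE
  )
  rec$var_class <- ifelse(nchar(rec$ref) > nchar(rec$alt), "deletion",
                          ifelse(nchar(rec$ref) < nchar(rec$alt),
                                 "insertion", "SNV"))
  info <- vapply(parts, `[[`, "", 8)
  kv <- strsplit(info, ";", fixed = TRUE)
  for (k in names(info_keys)) {
    rec[[info_keys[[k]]]] <- vapply(kv, function(x) {
      hit <- x[startsWith(x, paste0(k, "="))]
      if (!length(hit)) return(NA_real_)
      as.numeric(sub(".*=", "", hit[1]))
    }, 0)
  }
  rec
}
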