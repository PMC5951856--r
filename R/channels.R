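#' The 96 trinucleotide substitution channels
#'
#' Channel labels follow the COSMIC convention: the six pyrimidine-centered
#' substitutions (C>A, C>G, C>T, T>A, T>C, T>G) each expanded over the 16
#' flanking-base combinations, ordered 5' base then 3' base, A < C < G < T.
#' Every purine-reference SNV is reverse-complemented onto this strand before
#' being assigned a channel.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`, in canonical order.
#' @export
trinuc_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    for (p5 in bases) {
      for (p3 in bases) {
        out <- c(out, paste0(p5, "[", s, "]", p3))
      }
    }
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA strings (A/C/G/T only).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Map an SNV to its pyrimidine-centered channel label
#'
#' @param ref reference base, @param alt alternate base,
#' @param context trinucleotide reference context centered on the site.
#' @return channel label, or NA with attribute when context and ref disagree.
#' @export
snv_channel <- function(ref, alt, context) {
  stopifnot(length(ref) == length(alt), length(ref) == length(context))
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  mid <- substr(context, 2, 2)
  bad <- mid != ref | nchar(context) != 3L
  # collapse purine references onto the pyrimidine strand
  flip <- ref %in% c("A", "G")
  ref[flip] <- complement_base(ref[flip])
  alt[flip] <- complement_base(alt[flip])
  context[flip] <- revcomp(context[flip])
  lab <- paste0(substr(context, 1, 1), "[", ref, ">", alt, "]", substr(context, 3, 3))
  lab[bad] <- NA_character_
  lab
}
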