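## Candidate neoepitope enumeration (9-mer sliding window) and the
## expression / clonality annotations. MHC binding prediction is an external
## hand-off and out of scope.

all_9mers_covering <- function(seq_aa, positions) {
  L <- nchar(seq_aa)
  if (L < 9L || !length(positions)) return(data.frame(start = integer(0)))
  starts <- sort(unique(unlist(lapply(positions, function(p) {
    seq.int(max(1L, p - 8L), min(p, L - 8L))
  }))))
  starts <- starts[starts >= 1L & starts <= L - 8L]
  data.frame(start = starts)
}

#' Enumerate candidate 9-mer neoepitopes for a protein-changing mutation
#'
#' Missense: all distinct 9-mers of the mutant protein overlapping the
#' mutated residue (up to 9 for an internal site, fewer near the termini).
#' Frameshift (and stop-loss, treated alike): all 9-mers overlapping any
#' novel residue, through the new stop. Synonymous changes yield none.
#'
#' @param protein wild-type protein sequence (single-letter amino acids,
#'   no stop character).
#' @param pos 1-based mutated residue position.
#' @param alt_aa replacement residue (missense) — ignored for frameshift.
#' @param type "missense", "synonymous", or "frameshift".
#' @param novel_seq for frameshift: the novel C-terminal sequence replacing
#'   everything from `pos` to the new stop.
#' @param protein_id,mutation_id provenance labels.
#' @return data.frame of peptides: `peptide`, `mut_pos_in_peptide` (position
#'   of the first mutated residue, 1-9), `protein_id`, `mutation_id`.
#' @export
enumerate_neoepitopes <- function(protein, pos, alt_aa = NULL,
                                  type = c("missense", "synonymous",
                                           "frameshift"),
                                  novel_seq = NULL,
                                  protein_id = NA_character_,
                                  mutation_id = NA_character_) {
  type <- match.arg(type)
  empty <- data.frame(peptide = character(0), mut_pos_in_peptide = integer(0),
                      protein_id = character(0), mutation_id = character(0),
                      stringsAsFactors = FALSE)
  if (type == "synonymous") return(empty)
  L <- nchar(protein)
  if (pos < 1L || pos > L) stop("mutation position out of protein bounds")

  if (type == "missense") {
    if (is.null(alt_aa) || nchar(alt_aa) != 1L) {
      stop("missense requires a single replacement residue")
    }
    mutant <- paste0(substr(protein, 1, pos - 1), alt_aa,
                     substr(protein, pos + 1, L))
    novel_pos <- pos
  } else {
    if (is.null(novel_seq)) stop("frameshift requires novel_seq")
    mutant <- paste0(substr(protein, 1, pos - 1), novel_seq)
    novel_pos <- seq.int(pos, pos + nchar(novel_seq) - 1L)
    if (!length(novel_pos)) return(empty)
  }
  win <- all_9mers_covering(mutant, novel_pos)
  if (!nrow(win)) return(empty)
  pep <- substring(mutant, win$start, win$start + 8L)
  first_mut <- vapply(win$start, function(s) {
    hits <- novel_pos[novel_pos >= s & novel_pos <= s + 8L]
    as.integer(min(hits) - s + 1L)
  }, 1L)
  keep <- !duplicated(pep)
  data.frame(peptide = pep[keep], mut_pos_in_peptide = first_mut[keep],
             protein_id = protein_id, mutation_id = mutation_id,
             stringsAsFactors = FALSE)
}

#' Keep only peptides from expressed genes
#'
#' Pass-through when no expression table is available.
#'
#' @param peptides peptide data.frame with a `gene` column.
#' @param expression named numeric vector gene -> TPM, or NULL.
#' @param min_tpm expression floor (default 1 TPM).
#' @return the expressed subset (or the input unchanged).
#' @export
filter_expressed <- function(peptides, expression = NULL, min_tpm = 1) {
  if (is.null(expression) || min_tpm <= 0) return(peptides)
  tpm <- expression[peptides$gene]
  keep <- !is.na(tpm) & tpm >= min_tpm
  peptides[keep, , drop = FALSE]
}

#' Per-mutation clonality of neoantigen-bearing mutations
#'
#' Cancer-cell fraction
#' `CCF = VAF * (purity * CN + 2 * (1 - purity)) / (purity * multiplicity)`;
#' a mutation is clonal when CCF >= `ccf_threshold`. This is a standard CCF
#' rule with an explicit threshold — an interpretation, since the source
#' analysis does not define its clonality computation.
#'
#' @param mutations data.frame with `vaf`, optional `cn` (local total copy
#'   number, default 2) and `multiplicity` (default 1).
#' @param purity tumor purity in (0, 1].
#' @param ccf_threshold clonal cutoff on CCF (default 0.75).
#' @return list: `per_mutation` (data.frame with `ccf`, `clonal`),
#'   `clonal_fraction` in [0, 1].
#' @export
neoantigen_clonality <- function(mutations, purity, ccf_threshold = 0.75) {
  if (purity <= 0) stop("purity must be positive")
  cn <- if ("cn" %in% names(mutations)) mutations$cn else rep(2, nrow(mutations))
  mult <- if ("multiplicity" %in% names(mutations)) mutations$multiplicity
          else rep(1, nrow(mutations))
  ccf <- mutations$vaf * (purity * cn + 2 * (1 - purity)) / (purity * mult)
  per <- cbind(mutations, ccf = ccf, clonal = ccf >= ccf_threshold)
  list(per_mutation = per,
       clonal_fraction = if (nrow(per)) mean(per$clonal) else NA_real_)
}
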