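utils::globalVariables(".")

# Single source of truth for codon/amino-acid bookkeeping used across the
# pipeline. Translation and BLOSUM62 come from Biostrings; the descriptor
# table holds standard physicochemical constants.

#' Translate a codon to a one-letter amino acid
#'
#' Standard genetic code; stop codons translate to `"*"`.
#'
#' @param codon Character vector of trinucleotides (ACGT, case-insensitive).
#' @return Character vector of one-letter amino-acid codes.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    stop("not a valid codon: ", paste(unique(codon[bad]), collapse = ", "))
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

#' The 32 NNK codons
#'
#' NNK = any base at positions 1-2, G or T at position 3. Covers all 20 amino
#' acids plus the TAG stop.
#'
#' @return Character vector of 32 codons.
#' @export
nnk_codons <- function() {
  as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("G", "T"), paste0
  ))
}

# Three-letter amino acid codes for HGVS p. notation
AA3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

#' HGVS-style protein variant name
#'
#' @param wt_aa,mut_aa One-letter amino acids (`"*"` for stop).
#' @param position 1-based protein position.
#' @return Character vector like `"p.Ala101Val"`.
#' @export
hgvs_pro <- function(wt_aa, position, mut_aa) {
  paste0("p.", AA3[wt_aa], position, AA3[mut_aa])
}

#' Variant class from amino-acid change
#'
#' @param wt_aa,mut_aa One-letter amino acids.
#' @return `"synonymous"`, `"nonsense"`, or `"missense"`.
#' @export
variant_class <- function(wt_aa, mut_aa) {
  ifelse(mut_aa == wt_aa, "synonymous",
    ifelse(mut_aa == "*", "nonsense", "missense")
  )
}

#' Physicochemical descriptors for the 20 amino acids
#'
#' Kyte-Doolittle hydropathy, van-der-Waals side-chain volume (A^3), net
#' charge at pH 7, and a binary polarity indicator. Used as intrinsic
#' imputation features.
#'
#' @return data.frame with rownames = one-letter codes and columns
#'   `hydropathy`, `volume`, `charge`, `polarity`.
#' @export
aa_descriptors <- function() {
  data.frame(
    row.names = c(
      "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
    ),
    hydropathy = c(
      1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
      3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2
    ),
    volume = c(
      88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2, 166.7,
      166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8, 193.6, 140.0
    ),
    charge = c(
      0, 1, 0, -1, 0, 0, -1, 0, 0.1, 0,
      0, 1, 0, 0, 0, 0, 0, 0, 0, 0
    ),
    polarity = c(
      0, 1, 1, 1, 0, 1, 1, 0, 1, 0,
      0, 1, 0, 0, 0, 1, 1, 0, 1, 0
    )
  )
}

# BLOSUM62 restricted to the 20 standard residues
blosum62 <- function() {
  bl <- get_blosum62()
  aas <- rownames(aa_descriptors())
  bl[aas, aas]
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
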