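#' Canonical amino-acid alphabet
#'
#' The 20 standard residues in alphabetical one-letter order. All matrices
#' and feature vectors in the package use this column ordering internally;
#' file parsers re-map whatever order the file declares, so file dialects
#' never leak into feature order.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# PSI-BLAST writes its ASCII matrices with columns in NCBI order.
.AA_NCBI <- c("R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
              "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.AA_NCBI <- c("A", .AA_NCBI)

# Side-chain classification schemes used for the category-transition
# features. Class order within a scheme is fixed (label arithmetic
# depends on it).
.AA_CATEGORIES <- list(
  chemical = list(
    basic = c("H", "K", "R"),
    amide = c("N", "Q"),
    acidic = c("D", "E"),
    sulfur = c("C", "M"),
    hydroxyl = c("S", "T"),
    aromatic = c("F", "W", "Y"),
    aliphatic = c("A", "G", "I", "L", "P", "V")
  ),
  size = list(
    small = c("C", "D", "N", "P", "T"),
    medium = c("E", "H", "Q", "V"),
    large = c("I", "K", "L", "M", "R"),
    very_large = c("F", "W", "Y"),
    very_small = c("A", "G", "S")
  ),
  polarity = list(
    polar_basic = c("H", "K", "R"),
    polar_neutral = c("N", "Q", "S", "T", "Y"),
    polar_acidic = c("D", "E"),
    nonpolar = c("A", "C", "F", "G", "I", "L", "M", "P", "V", "W")
  ),
  hbond = list(
    donor = c("K", "R", "W"),
    acceptor = c("D", "E"),
    donor_acceptor = c("H", "N", "Q", "S", "T", "Y"),
    none = c("A", "C", "F", "G", "I", "L", "M", "P", "V")
  ),
  hydrophobicity = list(
    hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W"),
    neutral = c("G", "H", "P", "S", "T", "Y"),
    hydrophilic = c("D", "E", "K", "R", "N", "Q")
  )
)
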