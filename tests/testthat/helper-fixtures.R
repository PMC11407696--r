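# Fixture builders shared across test files. Everything is generated in
# code; no binary data on disk.

AA20 <- aminoAcids()

# official AAIndex1 residue order: row 1 then row 2 of the I block
AAI1_ROW1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
AAI1_ROW2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Render one AAIndex1 record from a named value vector (NA allowed).
aaindex1Record <- function(id, values) {
  fmt <- function(aa) {
    v <- values[[aa]]
    if (is.na(v)) "NA" else format(v)
  }
  paste(c(paste("H", id),
          "D fixture attribute scale",
          paste0("I    ", paste(sprintf("%s/%s", AAI1_ROW1, AAI1_ROW2),
                                collapse = "     ")),
          paste0("    ", paste(vapply(AAI1_ROW1, fmt, character(1)),
                               collapse = "    ")),
          paste0("    ", paste(vapply(AAI1_ROW2, fmt, character(1)),
                               collapse = "    ")),
          "//"), collapse = "\n")
}

AAI2_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Render one AAIndex2 record from a 20x20 matrix (canonical dimnames),
# optionally in lower-triangular form.
aaindex2Record <- function(id, m, triangular = FALSE) {
  m <- m[AAI2_ORDER, AAI2_ORDER]
  rows <- vapply(seq_len(20), function(i) {
    j <- if (triangular) seq_len(i) else seq_len(20)
    paste0(" ", paste(format(m[i, j]), collapse = "  "))
  }, character(1))
  paste(c(paste("H", id),
          "D fixture substitution matrix",
          sprintf("M rows = %s, cols = %s",
                  paste(AAI2_ORDER, collapse = ""),
                  paste(AAI2_ORDER, collapse = "")),
          rows, "//"), collapse = "\n")
}

# A symmetric integer substitution matrix derived from residue codes.
symmetricScoreMatrix <- function() {
  idx <- seq_len(20)
  m <- -abs(outer(idx, idx, "-"))
  dimnames(m) <- list(AA20, AA20)
  m
}

# Small raw PSSM built directly from a score matrix.
pssmFromScores <- function(sequence, scores) {
  colnames(scores) <- AA20
  new("PSSM", sequence = sequence, scores = scores)
}

# Literal double-loop implementation of the lag descriptor, kept naive on
# purpose: the independent oracle for psePSSM.
psePssmOracle <- function(normScores, phi) {
  L <- nrow(normScores)
  out <- numeric(20)
  for (j in seq_len(20)) {
    acc <- 0
    for (i in seq_len(L - phi))
      acc <- acc + (normScores[i, j] - normScores[i + phi, j])^2
    out[j] <- acc / (L - phi)
  }
  out
}
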