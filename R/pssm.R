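#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the plain-text matrix that PSI-BLAST writes with
#' \code{-out_ascii_pssm}: a header row naming 20 + 20 amino-acid columns,
#' then one row per position carrying the position number, the query
#' residue, 20 log-odds scores and 20 weighted-percentage fields (plus
#' optional trailing information-content statistics). Only the first
#' 20-column block (the log-odds scores) is kept, and columns are re-mapped
#' from the file's declared order to the canonical alphabet
#' \code{\link{aminoAcids}}, so the file dialect never leaks into feature
#' order.
#'
#' @param path Path to the ASCII PSSM file.
#' @param text Optional character scalar/vector with the file contents.
#' @return A \code{\linkS4class{PSSM}}.
#' @export
parsePSSM <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n", fixed = TRUE))
           else readLines(path, warn = FALSE)
  hdrAt <- NA_integer_
  hdr <- NULL
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) >= 40L && all(toks[1:40] %in% .AA)) {
      hdrAt <- i
      hdr <- toks[1:20]
      break
    }
  }
  if (is.na(hdrAt))
    stop("no PSSM header row of amino-acid columns found", call. = FALSE)
  if (anyDuplicated(hdr) || !setequal(hdr, .AA))
    stop("PSSM header must name each of the 20 residues once", call. = FALSE)
  seqChars <- character(0)
  rows <- list()
  for (i in (hdrAt + 1L):length(lines)) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) < 2L || is.na(suppressWarnings(as.integer(toks[1]))))
      break
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    nScores <- sum(!is.na(vals))
    if (length(vals) < 40L || any(is.na(vals[1:40])))
      stop(sprintf("PSSM line %d: expected 40 score fields, found %d",
                   i, nScores), call. = FALSE)
    seqChars <- c(seqChars, toupper(toks[2]))
    rows[[length(rows) + 1L]] <- vals[1:20]
  }
  if (!length(rows))
    stop("PSSM file contains no score rows", call. = FALSE)
  sc <- do.call(rbind, rows)
  colnames(sc) <- hdr
  sc <- sc[, .AA, drop = FALSE]
  methods::new("PSSM", sequence = paste(seqChars, collapse = ""),
               scores = sc)
}

#' Write a PSSM in the PSI-BLAST ASCII dialect
#'
#' Emits the layout \code{\link{parsePSSM}} accepts, using NCBI column
#' order as PSI-BLAST does, with a dummy percentage block and trailing
#' statistics so the file exercises the same parsing path as a real one.
#'
#' @param pssm A \code{\linkS4class{PSSM}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writePSSM <- function(pssm, path) {
  stopifnot(methods::is(pssm, "PSSM"))
  sc <- pssm@scores[, .AA_NCBI, drop = FALSE]
  chars <- strsplit(pssm@sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"),
             con)
  writeLines(paste0("           ",
                    paste(sprintf("%4s", c(.AA_NCBI, .AA_NCBI)),
                          collapse = "")), con)
  for (i in seq_len(nrow(sc))) {
    pct <- rep(0L, 20L)
    writeLines(sprintf("%5d %s %s %s  %4.2f %8.2f", i, chars[i],
                       paste(sprintf("%4d", as.integer(round(sc[i, ]))),
                             collapse = ""),
                       paste(sprintf("%4d", pct), collapse = ""),
                       0, 0), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Sigmoid-normalize a PSSM
#'
#' Maps every log-odds entry through the logistic function
#' f(x) = 1/(1 + exp(-x)), giving entries strictly in (0, 1). The map is
#' strictly increasing, so score ordering within and across positions is
#' preserved.
#'
#' @param pssm A \code{\linkS4class{PSSM}}.
#' @return A \code{\linkS4class{NormalizedPSSM}}.
#' @export
sigmoidNormalize <- function(pssm) {
  stopifnot(methods::is(pssm, "PSSM"))
  if (methods::is(pssm, "NormalizedPSSM")) return(pssm)
  methods::new("NormalizedPSSM", sequence = pssm@sequence,
               scores = 1 / (1 + exp(-pssm@scores)))
}

.asNormalized <- function(pssm) {
  if (methods::is(pssm, "NormalizedPSSM")) pssm else sigmoidNormalize(pssm)
}

#' Length-independent averaged PSSM profile
#'
#' Column means of the normalized matrix: one value per amino acid,
#' independent of sequence length, summarizing the whole sequence's
#' substitution preferences.
#'
#' @param pssm A \code{\linkS4class{PSSM}} (normalized on the fly if raw).
#' @return Named numeric vector of length 20, entries in (0, 1).
#' @export
averagePSSM <- function(pssm) {
  norm <- .asNormalized(pssm)
  if (nrow(norm@scores) < 1L) stop("empty PSSM", call. = FALSE)
  colMeans(norm@scores)
}

#' Normalized PSSM row at the mutation site
#'
#' The 20 normalized scores of the single row at the mutated position:
#' the site's substitution profile.
#'
#' @param pssm A \code{\linkS4class{PSSM}}.
#' @param position 1-based sequence position.
#' @return Named numeric vector of length 20.
#' @export
rowPSSM <- function(pssm, position) {
  norm <- .asNormalized(pssm)
  L <- nrow(norm@scores)
  if (length(position) != 1L || is.na(position) || position < 1L ||
      position > L)
    stop(sprintf("position must be in [1, %d]", L), call. = FALSE)
  norm@scores[position, ]
}

#' Pseudo-PSSM sequence-order descriptors
#'
#' For lag phi and amino acid j, the descriptor is the mean squared
#' difference between normalized scores phi positions apart:
#' (1/(L - phi)) * sum_i (P[i, j] - P[i + phi, j])^2. With
#' \code{cumulative = FALSE} the 20 values for the single lag \code{phi}
#' are returned; with \code{cumulative = TRUE} the full descriptor vector
#' is returned: the 20 column averages followed by one 20-value block per
#' lag 1..phi.
#'
#' @param pssm A \code{\linkS4class{PSSM}}.
#' @param phi Lag (or maximum lag when cumulative), 1 <= phi < L.
#' @param cumulative Return the full averaged-profile-plus-all-lags vector.
#' @return Named numeric vector (20 values, or 20 * (phi + 1) cumulative).
#' @export
psePSSM <- function(pssm, phi = 10L, cumulative = FALSE) {
  norm <- .asNormalized(pssm)
  L <- nrow(norm@scores)
  phi <- as.integer(phi)
  if (phi < 1L || phi >= L)
    stop(sprintf("phi must satisfy 1 <= phi < L (L = %d)", L), call. = FALSE)
  lagBlock <- function(p) {
    d <- norm@scores[seq_len(L - p), , drop = FALSE] -
      norm@scores[(1L + p):L, , drop = FALSE]
    stats::setNames(colMeans(d^2), paste0("pse", p, "_", .AA))
  }
  if (!cumulative) return(lagBlock(phi))
  c(stats::setNames(colMeans(norm@scores), paste0("avg_", .AA)),
    unlist(lapply(seq_len(phi), lagBlock)))
}
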