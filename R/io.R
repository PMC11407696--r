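#' Read and write FASTA sequence files
#'
#' Thin wrappers around Biostrings, returning and accepting the plain
#' named character vectors the curation and feature code works with.
#' Sequence names must match the partner identifiers of the affinity
#' table.
#'
#' @param path FASTA file path.
#' @return \code{readFasta}: named character vector of sequences.
#' @export
readFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  stats::setNames(as.character(set),
                  vapply(strsplit(names(set), "[[:space:]]+"),
                         `[`, character(1), 1L))
}

#' @rdname readFasta
#' @param sequences Named character vector of protein sequences.
#' @return \code{writeFasta}: the path, invisibly.
#' @export
writeFasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write and read an assembled feature matrix as TSV
#'
#' The header row carries the spec's feature names in spec order (plus the
#' response column \code{ddg} when present), so a written matrix
#' round-trips with byte-identical column order.
#'
#' @param X Numeric feature matrix with column names.
#' @param path TSV path.
#' @param y Optional response vector written as a final \code{ddg} column.
#' @return \code{writeFeatureMatrix}: the path, invisibly;
#'   \code{readFeatureMatrix}: list with \code{X} and \code{y} (NULL when
#'   absent).
#' @export
writeFeatureMatrix <- function(X, path, y = NULL) {
  df <- as.data.frame(X)
  if (!is.null(y)) df$ddg <- y
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  y <- NULL
  if ("ddg" %in% names(df)) {
    y <- df$ddg
    df$ddg <- NULL
  }
  list(X = as.matrix(df), y = y)
}
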