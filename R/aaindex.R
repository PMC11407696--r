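#' Parse an AAIndex1 flat file
#'
#' Reads the official AAIndex1 layout: records delimited by \code{//},
#' each with an \code{H} accession line and an \code{I} block whose header
#' names the residue order (e.g. \code{A/L R/K ...}) followed by two rows
#' of ten values. \code{NA} marks missing values; an index with any
#' missing value is loaded but flagged unusable.
#'
#' @param path Path to the flat file, or a character vector of lines via
#'   \code{text}.
#' @param text Optional character scalar/vector with the file contents.
#' @return An \code{\linkS4class{AAIndex1Table}} with ids sorted
#'   lexicographically.
#' @export
parseAAIndex1 <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n", fixed = TRUE))
           else readLines(path, warn = FALSE)
  recs <- .splitAAIndexRecords(lines)
  ids <- character(0)
  vals <- list()
  for (rec in recs) {
    id <- .aaindexField(rec, "H")
    if (is.null(id)) stop("AAIndex1 record without an H accession line",
                          call. = FALSE)
    iPos <- grep("^I ", rec)
    if (length(iPos) != 1L)
      stop(sprintf("malformed AAIndex1 record '%s': expected one I line", id),
           call. = FALSE)
    hdr <- strsplit(trimws(sub("^I ", "", rec[iPos])), "[[:space:]]+")[[1]]
    pairs <- strsplit(hdr, "/", fixed = TRUE)
    if (length(pairs) != 10L || any(lengths(pairs) != 2L))
      stop(sprintf("malformed AAIndex1 record '%s': bad I header", id),
           call. = FALSE)
    row1 <- vapply(pairs, `[`, character(1), 1L)
    row2 <- vapply(pairs, `[`, character(1), 2L)
    body <- rec[(iPos + 1L):(iPos + 2L)]
    toks <- unlist(strsplit(trimws(body), "[[:space:]]+"))
    if (length(toks) != 20L)
      stop(sprintf("malformed AAIndex1 record '%s': expected 20 values", id),
           call. = FALSE)
    v <- suppressWarnings(as.numeric(toks))
    v[toks %in% c("NA", "-")] <- NA_real_
    aa <- c(row1, row2)
    out <- stats::setNames(rep(NA_real_, 20L), .AA)
    out[aa] <- v
    ids <- c(ids, id)
    vals[[length(vals) + 1L]] <- out
  }
  ord <- order(ids)
  values <- if (length(vals)) do.call(rbind, vals)[ord, , drop = FALSE]
            else matrix(numeric(0), 0L, 20L)
  colnames(values) <- .AA
  methods::new("AAIndex1Table", ids = ids[ord], values = values,
               usable = apply(values, 1L, function(v) all(is.finite(v))))
}

#' Parse an AAIndex2 flat file
#'
#' Reads the official AAIndex2 layout: records delimited by \code{//},
#' each with an \code{H} accession and an \code{M rows = ..., cols = ...}
#' block followed by the score rows. Square matrices are taken as-is;
#' lower-triangular matrices are mirrored to full symmetric form. Rows or
#' columns for gap/ambiguity symbols are ignored. A matrix that cannot
#' resolve every ordered pair of the 20 standard residues is flagged
#' unusable at load time.
#'
#' @param path Path to the flat file.
#' @param text Optional character scalar/vector with the file contents.
#' @return An \code{\linkS4class{AAIndex2Table}} with ids sorted
#'   lexicographically.
#' @export
parseAAIndex2 <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) unlist(strsplit(text, "\n", fixed = TRUE))
           else readLines(path, warn = FALSE)
  recs <- .splitAAIndexRecords(lines)
  ids <- character(0)
  mats <- list()
  for (rec in recs) {
    id <- .aaindexField(rec, "H")
    if (is.null(id)) stop("AAIndex2 record without an H accession line",
                          call. = FALSE)
    mPos <- grep("^M ", rec)
    if (length(mPos) != 1L)
      stop(sprintf("malformed AAIndex2 record '%s': expected one M line", id),
           call. = FALSE)
    spec <- sub("^M ", "", rec[mPos])
    rows <- sub(".*rows *= *([^,]+).*", "\\1", spec)
    cols <- sub(".*cols *= *([^,]+).*", "\\1", spec)
    rows <- strsplit(gsub("[[:space:]]", "", rows), "")[[1]]
    cols <- strsplit(gsub("[[:space:]]", "", cols), "")[[1]]
    body <- rec[(mPos + 1L):length(rec)]
    body <- body[nzchar(trimws(body))]
    if (length(body) < length(rows))
      stop(sprintf("malformed AAIndex2 record '%s': too few score rows", id),
           call. = FALSE)
    body <- body[seq_along(rows)]
    m <- matrix(NA_real_, 20L, 20L, dimnames = list(.AA, .AA))
    for (i in seq_along(rows)) {
      toks <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
      v <- suppressWarnings(as.numeric(toks))
      v[toks %in% c("NA", "-")] <- NA_real_
      if (!(length(v) %in% c(length(cols), i)))
        stop(sprintf(
          "malformed AAIndex2 record '%s': row %d has %d values", id, i,
          length(v)), call. = FALSE)
      jj <- seq_along(v)
      for (j in jj) {
        ri <- rows[i]; cj <- cols[j]
        if (ri %in% .AA && cj %in% .AA) m[ri, cj] <- v[j]
      }
    }
    # mirror missing half for triangular inputs
    low <- is.na(m) & !is.na(t(m))
    m[low] <- t(m)[low]
    ids <- c(ids, id)
    mats[[length(mats) + 1L]] <- m
  }
  ord <- order(ids)
  methods::new("AAIndex2Table", ids = ids[ord], matrices = mats[ord],
               usable = vapply(mats[ord], function(m) all(is.finite(m)),
                               logical(1)))
}

.splitAAIndexRecords <- function(lines) {
  lines <- lines[!grepl("^\\s*$", lines) | TRUE]
  ends <- grep("^//", lines)
  recs <- list()
  start <- 1L
  for (e in ends) {
    block <- lines[start:(e - 1L)]
    block <- block[nzchar(trimws(block))]
    if (length(block)) recs[[length(recs) + 1L]] <- block
    start <- e + 1L
  }
  recs
}

.aaindexField <- function(rec, tag) {
  hit <- grep(paste0("^", tag, " "), rec)
  if (!length(hit)) return(NULL)
  strsplit(trimws(sub(paste0("^", tag, " "), "", rec[hit[1L]])),
           "[[:space:]]+")[[1]][1L]
}

.checkResiduePair <- function(wt, mut) {
  if (!(wt %in% .AA) || !(mut %in% .AA))
    stop("residues must be standard one-letter codes", call. = FALSE)
}

#' Attribute-difference features from AAIndex1
#'
#' One value per usable index: attribute(mutant) - attribute(wild type),
#' in lexicographic index order. The vector negates elementwise when the
#' residues are swapped.
#'
#' @param table An \code{\linkS4class{AAIndex1Table}}.
#' @param wt,mut Wild-type and mutant one-letter residue codes.
#' @return Named numeric vector (\code{aa1_<accession>}).
#' @export
aaindex1Features <- function(table, wt, mut) {
  stopifnot(methods::is(table, "AAIndex1Table"))
  .checkResiduePair(wt, mut)
  if (!any(table@usable))
    stop("AAIndex1 table has no usable indices", call. = FALSE)
  v <- table@values[table@usable, , drop = FALSE]
  stats::setNames(v[, mut] - v[, wt],
                  paste0("aa1_", table@ids[table@usable]))
}

#' Substitution-score features from AAIndex2
#'
#' One value per usable matrix: the score for substituting the wild-type
#' residue by the mutant, in lexicographic matrix order.
#'
#' @param table An \code{\linkS4class{AAIndex2Table}}.
#' @param wt,mut Wild-type and mutant one-letter residue codes.
#' @return Named numeric vector (\code{aa2_<accession>}).
#' @export
aaindex2Features <- function(table, wt, mut) {
  stopifnot(methods::is(table, "AAIndex2Table"))
  .checkResiduePair(wt, mut)
  use <- which(table@usable)
  if (!length(use))
    stop("AAIndex2 table has no usable matrices", call. = FALSE)
  stats::setNames(
    vapply(use, function(i) table@matrices[[i]][wt, mut], numeric(1)),
    paste0("aa2_", table@ids[use]))
}
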