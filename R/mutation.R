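#' Parse a single-mutation specification
#'
#' Accepts the two common dialects \code{"A123G"} and \code{"A 123 G"}
#' (wild-type residue, 1-based sequence position, mutant residue). Both
#' residues must be standard one-letter codes and must differ; anything
#' else is rejected.
#'
#' @param text Character scalar mutation specification.
#' @param strict Logical; if TRUE (default) malformed input is an error,
#'   otherwise NULL is returned so callers can treat it as a filterable
#'   record defect.
#' @return A list with elements \code{wt}, \code{pos}, \code{mut}, or NULL
#'   when \code{strict = FALSE} and the text does not parse.
#' @export
#' @examples
#' parseMutation("A123G")
#' parseMutation("A 123 G")
parseMutation <- function(text, strict = TRUE) {
  fail <- function(why) {
    if (strict)
      stop(sprintf(
        "invalid mutation '%s' (%s); accepted dialects: 'A123G', 'A 123 G'",
        text, why), call. = FALSE)
    NULL
  }
  if (.isMissingValue(text) || length(text) != 1L)
    return(fail("empty"))
  s <- trimws(text)
  m <- regmatches(s, regexec("^([A-Za-z]) ?([0-9]+) ?([A-Za-z])$", s))[[1]]
  if (length(m) != 4L) return(fail("does not match wt/position/mut"))
  wt <- toupper(m[2]); mut <- toupper(m[4])
  pos <- suppressWarnings(as.integer(m[3]))
  if (!(wt %in% .AA) || !(mut %in% .AA))
    return(fail("non-standard residue"))
  if (is.na(pos) || pos < 1L) return(fail("position must be >= 1"))
  if (wt == mut) return(fail("wild-type and mutant residues are identical"))
  list(wt = wt, pos = pos, mut = mut)
}

.formatMutation <- function(mut) sprintf("%s%d%s", mut$wt, mut$pos, mut$mut)
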