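#' Curation configuration
#'
#' Thermodynamic constants and filtering thresholds for the affinity-table
#' cleaning pipeline. The defaults use R = 1.987e-3 kcal/(mol K) and
#' T = 298.15 K for converting dissociation constants into binding free
#' energies, remove replicate groups whose ddG sample standard deviation
#' exceeds 1.0 kcal/mol, and resolve sign conflicts at an absolute
#' threshold of 0.5 kcal/mol.
#'
#' @param gasConstantR Ideal gas constant, kcal/(mol K).
#' @param temperatureT Absolute temperature, K.
#' @param replicateSdCutoff Replicate ddG standard-deviation cutoff, kcal/mol.
#' @param signConflictCutoff Absolute ddG threshold for sign-conflict
#'   resolution, kcal/mol.
#' @param requireDimer Keep only two-chain complexes in the final stage.
#' @return A list of class \code{"CurationConfig"}.
#' @export
curationConfig <- function(gasConstantR = 1.987e-3, temperatureT = 298.15,
                           replicateSdCutoff = 1.0, signConflictCutoff = 0.5,
                           requireDimer = TRUE) {
  for (v in c(gasConstantR, temperatureT, replicateSdCutoff,
              signConflictCutoff))
    if (!is.numeric(v) || v <= 0)
      stop("all constants and cutoffs must be positive", call. = FALSE)
  structure(list(gasConstantR = gasConstantR, temperatureT = temperatureT,
                 replicateSdCutoff = replicateSdCutoff,
                 signConflictCutoff = signConflictCutoff,
                 requireDimer = isTRUE(requireDimer)),
            class = "CurationConfig")
}

#' Binding free energy from a dissociation constant
#'
#' Computes dG = R T ln(K_D) in kcal/mol. Tighter binding (smaller K_D)
#' gives a more negative dG; the function is strictly increasing in K_D.
#'
#' @param kd Dissociation constant(s), molar. Must be positive.
#' @param config A \code{\link{curationConfig}}.
#' @return Binding free energy, kcal/mol.
#' @export
#' @examples
#' deltaGfromKd(1e-9)  # about -12.3 kcal/mol
deltaGfromKd <- function(kd, config = curationConfig()) {
  if (any(!is.finite(kd) | kd <= 0))
    stop("kd must be positive and finite", call. = FALSE)
  config$gasConstantR * config$temperatureT * log(kd)
}

.AFFINITY_COLS <- c("complex_id", "partner_a_id", "partner_b_id",
                    "mutated_partner", "mutation", "kd_wt", "kd_mut",
                    "dg_wt", "dg_mut", "ddg", "ph", "functional_class",
                    "structural_class", "n_chains")

.asAffinityTable <- function(records) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  n <- nrow(records)
  for (col in .AFFINITY_COLS)
    if (!col %in% names(records))
      records[[col]] <- if (col %in% c("kd_wt", "kd_mut", "dg_wt", "dg_mut",
                                       "ddg", "ph")) rep(NA_real_, n)
                        else if (col == "n_chains") rep(NA_integer_, n)
                        else rep(NA_character_, n)
  num <- c("kd_wt", "kd_mut", "dg_wt", "dg_mut", "ddg", "ph")
  for (col in num) records[[col]] <- as.numeric(records[[col]])
  records$n_chains <- as.integer(records$n_chains)
  chr <- c("complex_id", "partner_a_id", "partner_b_id", "mutated_partner",
           "mutation", "functional_class", "structural_class")
  for (col in chr) {
    records[[col]] <- as.character(records[[col]])
    records[[col]][!is.na(records[[col]]) &
                     !nzchar(trimws(records[[col]]))] <- NA_character_
  }
  rownames(records) <- NULL
  records
}

#' Read an affinity table from CSV or TSV
#'
#' Expects the documented column dictionary (\code{complex_id},
#' \code{partner_a_id}, \code{partner_b_id}, \code{mutated_partner},
#' \code{mutation}, \code{kd_wt}, \code{kd_mut}, \code{dg_wt},
#' \code{dg_mut}, \code{ddg}, \code{ph}, \code{functional_class},
#' \code{structural_class}, \code{n_chains}); missing columns are added as
#' NA and unknown columns are preserved as passthrough metadata.
#'
#' @param path File path; the delimiter is taken from the extension
#'   (\code{.tsv}/\code{.txt} tab, otherwise comma) unless \code{sep} is given.
#' @param sep Optional field separator override.
#' @return A data frame in the package's affinity-record layout.
#' @export
readAffinityTable <- function(path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  .asAffinityTable(df)
}

#' Recompute ddG from its thermodynamic sources
#'
#' When both wild-type and mutant binding free energies are available or
#' derivable (from K_D values via \code{\link{deltaGfromKd}}), the stated
#' ddG is replaced by dG_mutant - dG_wild-type; the published tables are
#' known to contain discrepancies, so the difference always wins. A record
#' carrying only a stated ddG is kept as-is. Records with no value source
#' at all get an NA ddG and are removed at the next stage, not here.
#' Positive ddG means the mutation destabilizes the complex.
#'
#' @param records Affinity-record data frame.
#' @param config A \code{\link{curationConfig}}.
#' @return The data frame with corrected \code{ddg}.
#' @export
recomputeDdg <- function(records, config = curationConfig()) {
  records <- .asAffinityTable(records)
  dgw <- records$dg_wt
  dgm <- records$dg_mut
  fromKd <- function(dg, kd) {
    use <- is.na(dg) & !is.na(kd) & kd > 0
    dg[use] <- deltaGfromKd(kd[use], config)
    dg
  }
  dgw <- fromKd(dgw, records$kd_wt)
  dgm <- fromKd(dgm, records$kd_mut)
  both <- !is.na(dgw) & !is.na(dgm)
  records$dg_wt <- dgw
  records$dg_mut <- dgm
  records$ddg[both] <- dgm[both] - dgw[both]
  records
}

#' Assign deterministic pseudonyms to complexes lacking an ID
#'
#' Records without a complex identifier receive a pseudonym derived from a
#' stable hash of the sorted partner-identifier pair, so records of the
#' same complex share a pseudonym and reruns reproduce the same names.
#' Existing identifiers are never touched.
#'
#' @param records Affinity-record data frame.
#' @return The data frame with every \code{complex_id} non-empty.
#' @export
assignPseudonyms <- function(records) {
  records <- .asAffinityTable(records)
  missing <- is.na(records$complex_id)
  if (any(missing)) {
    key <- vapply(which(missing), function(i) {
      ids <- sort(c(records$partner_a_id[i], records$partner_b_id[i]),
                  na.last = TRUE)
      ids[is.na(ids)] <- ""
      paste(ids, collapse = "|")
    }, character(1))
    records$complex_id[missing] <-
      paste0("PSEUDO-", vapply(key, .hashHex, character(1)))
  }
  records
}

.groupKey <- function(records) {
  mutNorm <- vapply(records$mutation, function(m) {
    p <- parseMutation(m, strict = FALSE)
    if (is.null(p)) ifelse(is.na(m), "<NA>", m) else .formatMutation(p)
  }, character(1))
  paste(records$complex_id, records$mutated_partner, mutNorm, sep = "\r")
}

#' Drop records lacking a ddG value
#'
#' @param records Affinity-record data frame (after
#'   \code{\link{recomputeDdg}}).
#' @return List with elements \code{records} (survivors) and \code{removed}.
#' @export
dropMissingDdg <- function(records) {
  records <- .asAffinityTable(records)
  keep <- !is.na(records$ddg)
  list(records = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Remove replicate groups with inconsistent ddG
#'
#' Records are grouped by (complex, mutated partner, mutation); a group
#' whose ddG sample standard deviation (n-1 denominator; singletons count
#' as 0) exceeds the cutoff is removed entirely. Surviving groups pass
#' through unmerged.
#'
#' @param records Affinity-record data frame.
#' @param config A \code{\link{curationConfig}}.
#' @return List with \code{records} and \code{removed}.
#' @export
filterReplicateSd <- function(records, config = curationConfig()) {
  records <- .asAffinityTable(records)
  key <- .groupKey(records)
  sds <- tapply(records$ddg, key, .sampleSD)
  bad <- names(sds)[sds > config$replicateSdCutoff]
  keep <- !(key %in% bad)
  list(records = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

# Sign-conflict resolution for one replicate group's ddg values.
# Returns logical vector: TRUE = remove.
.signConflictRemove <- function(ddg, cutoff) {
  n <- length(ddg)
  mixed <- any(ddg > 0) && any(ddg < 0)
  if (n == 2L && mixed && all(abs(ddg) > cutoff))
    return(rep(TRUE, n))
  if (n %in% c(3L, 4L) && mixed && any(abs(ddg) > cutoff))
    return(rep(TRUE, n))
  if (n >= 5L) {
    out <- abs(ddg - stats::median(ddg)) > cutoff
    if (any(out) && sum(out) <= 2L) return(out)
  }
  rep(FALSE, n)
}

#' Resolve opposite-sign replicate conflicts
#'
#' Applies the codified conflict rules per replicate group: (i) a pair with
#' opposite signs, both exceeding the absolute cutoff, is removed whole;
#' (ii) groups of three or four with mixed signs and any value beyond the
#' cutoff are removed whole; (iii) in groups of five or more, one or two
#' values deviating from the group median by more than the cutoff are
#' removed individually so the remainder can be averaged later. All other
#' groups pass unchanged.
#'
#' @param records Affinity-record data frame.
#' @param config A \code{\link{curationConfig}}.
#' @return List with \code{records} and \code{removed}.
#' @export
resolveSignConflicts <- function(records, config = curationConfig()) {
  records <- .asAffinityTable(records)
  key <- .groupKey(records)
  remove <- logical(nrow(records))
  for (k in unique(key)) {
    idx <- which(key == k)
    remove[idx] <- .signConflictRemove(records$ddg[idx],
                                       config$signConflictCutoff)
  }
  list(records = records[!remove, , drop = FALSE],
       removed = records[remove, , drop = FALSE])
}

#' Merge duplicate measurements into one consensus record
#'
#' Collapses each (complex, mutated partner, mutation) group to a single
#' record whose ddG is the arithmetic mean of the group. The per-replicate
#' K_D and dG fields are cleared on merged records: the consensus ddG is
#' the curated value and must not be overwritten by a later recomputation.
#'
#' @param records Affinity-record data frame.
#' @return List with \code{records} (one per key) and \code{removed}
#'   (the collapsed extra rows).
#' @export
mergeDuplicates <- function(records) {
  records <- .asAffinityTable(records)
  key <- .groupKey(records)
  first <- !duplicated(key)
  means <- tapply(records$ddg, key, mean)
  out <- records[first, , drop = FALSE]
  dup <- key %in% key[duplicated(key)]
  outKey <- key[first]
  out$ddg <- as.numeric(means[outKey])
  merged <- outKey %in% key[duplicated(key)]
  out$kd_wt[merged] <- NA_real_
  out$kd_mut[merged] <- NA_real_
  out$dg_wt[merged] <- NA_real_
  out$dg_mut[merged] <- NA_real_
  list(records = out,
       removed = records[duplicated(key), , drop = FALSE])
}

.mutatedPartnerId <- function(records) {
  ifelse(records$mutated_partner %in% "B",
         records$partner_b_id, records$partner_a_id)
}

.asSequenceVector <- function(sequences) {
  if (is.null(sequences)) return(character())
  if (methods::is(sequences, "XStringSet"))
    return(stats::setNames(as.character(sequences), names(sequences)))
  stopifnot(is.character(sequences))
  sequences
}

#' Translate structure numbering to sequence numbering and validate
#'
#' Rewrites each mutation position from the reporting (structure) numbering
#' to the 1-based coordinate of the partner's sequence, using the
#' caller-supplied per-partner map (identity when no map is given), then
#' checks that the sequence actually carries the stated wild-type residue
#' at that position. Failures are flagged for removal, never thrown.
#'
#' @param records Affinity-record data frame with parseable mutations.
#' @param sequences Named character vector or \code{AAStringSet}, one entry
#'   per partner identifier.
#' @param maps Optional named list (by partner identifier) of integer
#'   vectors mapping structure positions (names) to sequence positions
#'   (values).
#' @return List with \code{records} (positions rewritten), \code{removed}
#'   and \code{reasons} (\code{"unmapped_position"} or \code{"wt_mismatch"}
#'   per removed record).
#' @export
renumberAndValidate <- function(records, sequences, maps = NULL) {
  records <- .asAffinityTable(records)
  seqs <- .asSequenceVector(sequences)
  reason <- rep(NA_character_, nrow(records))
  pid <- .mutatedPartnerId(records)
  # Records already renumbered by a previous run carry sequence coordinates;
  # re-applying a structure map to them would double-translate, so the
  # marker column suppresses the mapping (validation still runs).
  done <- if ("renumbered" %in% names(records))
    records$renumbered %in% TRUE else rep(FALSE, nrow(records))
  for (i in seq_len(nrow(records))) {
    p <- parseMutation(records$mutation[i], strict = FALSE)
    if (is.null(p)) { reason[i] <- "bad_mutation_format"; next }
    sq <- seqs[[pid[i]]]
    if (is.null(sq) || is.na(sq)) { reason[i] <- "missing_identity"; next }
    pos <- p$pos
    map <- if (!is.null(maps) && !done[i]) maps[[pid[i]]] else NULL
    if (!is.null(map)) {
      hit <- match(as.character(pos), names(map))
      if (is.na(hit)) { reason[i] <- "unmapped_position"; next }
      pos <- as.integer(map[[hit]])
    }
    if (pos < 1L || pos > nchar(sq)) { reason[i] <- "unmapped_position"; next }
    if (substr(sq, pos, pos) != p$wt) { reason[i] <- "wt_mismatch"; next }
    records$mutation[i] <- sprintf("%s%d%s", p$wt, pos, p$mut)
  }
  records$renumbered <- TRUE
  bad <- !is.na(reason)
  list(records = records[!bad, , drop = FALSE],
       removed = records[bad, , drop = FALSE],
       reasons = reason[bad])
}

#' Run the full affinity-curation pipeline
#'
#' Executes, in order: ddG recomputation from thermodynamic sources,
#' pseudonym assignment, removal of records without ddG, replicate
#' standard-deviation filtering, sign-conflict resolution, duplicate
#' merging, removal of records whose mutated partner has no identifier or
#' no importable sequence, mutation-format filtering,
#' structure-to-sequence renumbering with wild-type validation, and
#' finally retention of dimeric (two-chain) single-mutation records.
#' Every removal is recorded with a machine-readable reason and the
#' stage-by-stage accounting is returned as a
#' \code{\linkS4class{CurationReport}}.
#'
#' @param records Affinity-record data frame (see
#'   \code{\link{readAffinityTable}}).
#' @param sequences Named character vector or \code{AAStringSet} keyed by
#'   partner identifier.
#' @param maps Optional named list of structure-to-sequence position maps.
#' @param config A \code{\link{curationConfig}}.
#' @return List with \code{records} (the curated table) and \code{report}
#'   (a \code{CurationReport}).
#' @export
curateAffinities <- function(records, sequences = character(), maps = NULL,
                             config = curationConfig()) {
  records <- .asAffinityTable(records)
  seqs <- .asSequenceVector(sequences)

  stages <- list()
  reasons <- list()
  note <- function(name, n_in, removed, out, why) {
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = name, records_in = n_in, records_removed = nrow(removed),
      records_out = nrow(out),
      distinct_proteins = length(unique(out$complex_id)),
      stringsAsFactors = FALSE)
    reasons[[name]] <<- if (nrow(removed))
      table(rep_len(why, nrow(removed))) else table(character())
  }

  cur <- recomputeDdg(records, config)
  note("recompute_ddg", nrow(cur), cur[0, ], cur, character())

  cur <- assignPseudonyms(cur)
  note("assign_pseudonyms", nrow(cur), cur[0, ], cur, character())

  st <- dropMissingDdg(cur)
  note("drop_missing_ddg", nrow(cur), st$removed, st$records, "missing_ddg")
  cur <- st$records

  st <- filterReplicateSd(cur, config)
  note("filter_replicate_sd", nrow(cur), st$removed, st$records,
       "replicate_sd")
  cur <- st$records

  st <- resolveSignConflicts(cur, config)
  note("resolve_sign_conflicts", nrow(cur), st$removed, st$records,
       "sign_conflict")
  cur <- st$records

  st <- mergeDuplicates(cur)
  note("merge_duplicates", nrow(cur), st$removed, st$records, "duplicate")
  cur <- st$records

  pid <- .mutatedPartnerId(cur)
  keep <- !is.na(pid) & pid %in% names(seqs)
  st <- list(records = cur[keep, , drop = FALSE],
             removed = cur[!keep, , drop = FALSE])
  note("require_sequence", nrow(cur), st$removed, st$records,
       "missing_identity")
  cur <- st$records

  parsed <- lapply(cur$mutation, parseMutation, strict = FALSE)
  keep <- !vapply(parsed, is.null, logical(1))
  st <- list(records = cur[keep, , drop = FALSE],
             removed = cur[!keep, , drop = FALSE])
  note("mutation_format", nrow(cur), st$removed, st$records,
       "bad_mutation_format")
  cur <- st$records

  st <- renumberAndValidate(cur, seqs, maps)
  note("renumber_validate", nrow(cur), st$removed, st$records, st$reasons)
  cur <- st$records

  if (config$requireDimer) {
    keep <- !is.na(cur$n_chains) & cur$n_chains == 2L
    st <- list(records = cur[keep, , drop = FALSE],
               removed = cur[!keep, , drop = FALSE])
    note("retain_dimer", nrow(cur), st$removed, st$records, "not_dimer")
    cur <- st$records
  }

  report <- methods::new("CurationReport",
                         stages = do.call(rbind, stages), reasons = reasons)
  list(records = cur, report = report)
}

#' Write a curation report as JSON
#'
#' @param report A \code{\linkS4class{CurationReport}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeCurationReport <- function(report, path) {
  stopifnot(methods::is(report, "CurationReport"))
  out <- list(stages = report@stages,
              reasons = lapply(report@reasons, function(t)
                as.list(stats::setNames(as.integer(t), names(t)))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
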