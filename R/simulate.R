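#' Random protein sequence
#'
#' Uniform draws over the 20 standard residues; the same seed always
#' yields the same sequence.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer seed.
#' @return Character scalar.
#' @export
randomSequence <- function(length, seed) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  set.seed(seed)
  paste(sample(.AA, length, replace = TRUE), collapse = "")
}

#' Synthetic PSI-BLAST-style PSSM
#'
#' Integer log-odds drawn from a rounded Gaussian centered below zero and
#' clamped to [-16, 13] (the range real PSI-BLAST matrices occupy), with
#' the column of the sequence's own residue up-weighted by
#' \code{conservationWeight} to mimic positional conservation. Rendered to
#' disk with \code{\link{writePSSM}}, the file round-trips exactly through
#' \code{\link{parsePSSM}}.
#'
#' @param sequence Protein sequence.
#' @param conservationWeight Non-negative up-weight (log-odds units) for
#'   the true-residue column.
#' @param seed Integer seed.
#' @return A \code{\linkS4class{PSSM}} with integer scores.
#' @export
syntheticPSSM <- function(sequence, conservationWeight = 3, seed = 1L) {
  if (conservationWeight < 0)
    stop("conservationWeight must be >= 0", call. = FALSE)
  L <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% .AA))
    stop("sequence contains non-standard residues", call. = FALSE)
  set.seed(seed)
  sc <- matrix(round(stats::rnorm(L * 20L, mean = -2, sd = 4)), L, 20L,
               dimnames = list(NULL, .AA))
  for (i in seq_len(L))
    sc[i, chars[i]] <- sc[i, chars[i]] + round(conservationWeight)
  sc[sc < -16] <- -16
  sc[sc > 13] <- 13
  methods::new("PSSM", sequence = sequence, scores = sc)
}

#' Specification for a planted-signal dataset
#'
#' Defaults chosen so that the planted linear signal dominates the noise:
#' three Row-PSSM features (the widest-spread descriptors, SD about 0.38
#' under the synthetic PSSM model) at |weight| 2 kcal/mol and two lag-10
#' pseudo-PSSM features (SD about 0.06) at |weight| 6 kcal/mol give a
#' planted ddG spread of about 1.4 kcal/mol against noise SD 0.3 — a
#' realistic spread for single-mutation binding data.
#'
#' @param nRecords Number of mutation records.
#' @param seqLengthRange Integer range for chain lengths.
#' @param informative Names of ONLY_10_PLUS features carrying signal.
#' @param weights Effect sizes, kcal/mol per unit feature value.
#' @param noiseSd Gaussian noise SD, kcal/mol.
#' @param seed Integer seed.
#' @return List of class \code{"PlantedDatasetSpec"}.
#' @export
plantedDatasetSpec <- function(nRecords = 800L,
                               seqLengthRange = c(30L, 60L),
                               informative = c("row_C", "row_W", "row_K",
                                               "pse10_mut_A",
                                               "pse10_int_L"),
                               weights = c(2, -2, 2, 6, -6),
                               noiseSd = 0.3, seed = 1L) {
  spec <- featureSetSpec("ONLY_10_PLUS")
  if (!all(informative %in% spec@featureNames))
    stop("informative features must be ONLY_10_PLUS feature names",
         call. = FALSE)
  if (length(weights) != length(informative) || noiseSd < 0)
    stop("weights must align with informative features; noiseSd >= 0",
         call. = FALSE)
  structure(list(nRecords = as.integer(nRecords),
                 seqLengthRange = as.integer(seqLengthRange),
                 informative = informative, weights = weights,
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "PlantedDatasetSpec")
}

#' Generate a planted-signal ddG dataset
#'
#' For each record, draws a mutating and an interacting chain with
#' synthetic PSSMs and a random mutation, assembles the ONLY_10_PLUS
#' descriptor vector with the package's own feature code, and sets
#' ddG = sum(weights * informative features) + Gaussian noise — so the
#' planted map is exactly learnable from the emitted features and the
#' ground-truth components are returned for recovery tests.
#'
#' @param spec A \code{\link{plantedDatasetSpec}}.
#' @return List with \code{records} (affinity table), \code{sequences}
#'   (named character vector), \code{pssms} (named list), \code{X}
#'   (feature matrix), \code{y} (noisy ddG), \code{signal} (noise-free
#'   planted values) and \code{spec} (the feature-set spec used).
#' @export
plantedDataset <- function(spec = plantedDatasetSpec()) {
  stopifnot(inherits(spec, "PlantedDatasetSpec"))
  fsSpec <- featureSetSpec("ONLY_10_PLUS")
  n <- spec$nRecords
  X <- matrix(NA_real_, n, length(fsSpec@featureNames),
              dimnames = list(NULL, fsSpec@featureNames))
  sequences <- character(0)
  pssms <- list()
  recs <- vector("list", n)
  for (r in seq_len(n)) {
    sr <- function(tag) .deriveSeed(spec$seed, paste0("rec", r, tag))
    set.seed(sr("len"))
    Ls <- sample(seq(spec$seqLengthRange[1], spec$seqLengthRange[2]), 2L,
                 replace = TRUE)
    mid <- sprintf("MUT%05d", r)
    iid <- sprintf("INT%05d", r)
    mutSeq <- randomSequence(Ls[1], sr("mseq"))
    intSeq <- randomSequence(Ls[2], sr("iseq"))
    mutPSSM <- syntheticPSSM(mutSeq, seed = sr("mpssm"))
    intPSSM <- syntheticPSSM(intSeq, seed = sr("ipssm"))
    set.seed(sr("mut"))
    pos <- sample.int(Ls[1], 1L)
    wt <- substr(mutSeq, pos, pos)
    mut <- sample(setdiff(.AA, wt), 1L)
    sequences[mid] <- mutSeq
    sequences[iid] <- intSeq
    pssms[[mid]] <- mutPSSM
    pssms[[iid]] <- intPSSM
    mutStr <- sprintf("%s%d%s", wt, pos, mut)
    X[r, ] <- assembleFeatures(fsSpec, mutStr, mutPSSM, intPSSM)
    recs[[r]] <- data.frame(complex_id = sprintf("CPX%05d", r),
                            partner_a_id = mid, partner_b_id = iid,
                            mutated_partner = "A", mutation = mutStr,
                            n_chains = 2L, stringsAsFactors = FALSE)
  }
  signal <- as.numeric(X[, spec$informative, drop = FALSE] %*% spec$weights)
  set.seed(.deriveSeed(spec$seed, "noise"))
  y <- signal + stats::rnorm(n, 0, spec$noiseSd)
  records <- .asAffinityTable(do.call(rbind, recs))
  records$ddg <- y
  list(records = records, sequences = sequences, pssms = pssms,
       X = X, y = y, signal = signal, spec = fsSpec)
}

#' Plan of deliberate defects for a messy affinity table
#'
#' Counts of each planted defect class, plus the number of clean records
#' and benign duplicate pairs. Each defect class is constructed to be
#' caught by exactly one curation stage.
#'
#' @param missingDdg Records with no ddG and no thermodynamic source.
#' @param replicateSd Replicate pairs with ddG SD above 1.0 kcal/mol
#'   (two records each).
#' @param signConflict Opposite-sign replicate pairs, both beyond
#'   0.5 kcal/mol (two records each).
#' @param badFormat Records with malformed mutation strings.
#' @param wtMismatch Records whose stated wild-type residue contradicts
#'   the sequence.
#' @param nonDimer Records with three chains.
#' @param missingId Records with no partner identifiers (hence no
#'   importable sequence).
#' @param duplicates Benign duplicate pairs merged by mean (two records
#'   in, one out, each).
#' @param clean Untouched records.
#' @return List of class \code{"DefectPlan"}.
#' @export
defectPlan <- function(missingDdg = 2L, replicateSd = 2L, signConflict = 2L,
                       badFormat = 2L, wtMismatch = 2L, nonDimer = 2L,
                       missingId = 2L, duplicates = 2L, clean = 20L) {
  plan <- list(missingDdg = missingDdg, replicateSd = replicateSd,
               signConflict = signConflict, badFormat = badFormat,
               wtMismatch = wtMismatch, nonDimer = nonDimer,
               missingId = missingId, duplicates = duplicates,
               clean = clean)
  if (any(unlist(plan) < 0L)) stop("all counts must be >= 0", call. = FALSE)
  structure(lapply(plan, as.integer), class = "DefectPlan")
}

#' Generate a deliberately defective affinity table
#'
#' Emits a raw table containing clean records plus exactly the planted
#' defects of the plan, together with the per-stage removal counts the
#' curation pipeline must report and the sequences needed to curate it.
#' Rows are shuffled deterministically so stage behavior never depends on
#' input order.
#'
#' @param plan A \code{\link{defectPlan}}.
#' @param seed Integer seed.
#' @return List with \code{records}, \code{sequences}, \code{expected}
#'   (data frame of stage and records_removed) and \code{nFinal} (curated
#'   record count implied by the plan).
#' @export
messyAffinityTable <- function(plan = defectPlan(), seed = 1L) {
  stopifnot(inherits(plan, "DefectPlan"))
  rows <- list()
  sequences <- character(0)
  counter <- 0L
  baseRecord <- function(tag, ddg, nChains = 2L, mutation = NULL,
                         withIds = TRUE) {
    counter <<- counter + 1L
    cid <- sprintf("%s%04d", tag, counter)
    aid <- paste0(cid, "a"); bid <- paste0(cid, "b")
    sq <- randomSequence(25L, .deriveSeed(seed, paste0("seq", counter)))
    set.seed(.deriveSeed(seed, paste0("pos", counter)))
    pos <- sample(3:23, 1L)
    wt <- substr(sq, pos, pos)
    mutAA <- sample(setdiff(.AA, wt), 1L)
    if (is.null(mutation)) mutation <- sprintf("%s%d%s", wt, pos, mutAA)
    if (withIds) {
      sequences[aid] <<- sq
      sequences[bid] <<- randomSequence(25L,
                                        .deriveSeed(seed,
                                                    paste0("seqb", counter)))
    }
    data.frame(complex_id = cid,
               partner_a_id = if (withIds) aid else NA_character_,
               partner_b_id = if (withIds) bid else NA_character_,
               mutated_partner = "A", mutation = mutation,
               ddg = ddg, ph = 7.4, n_chains = nChains,
               stringsAsFactors = FALSE)
  }
  add <- function(df) rows[[length(rows) + 1L]] <<- df
  rddg <- function(lbl) {
    set.seed(.deriveSeed(seed, paste0("ddg", lbl, counter)))
    round(stats::rnorm(1L, 0, 0.8), 3L)
  }

  for (i in seq_len(plan$clean)) add(baseRecord("CLN", rddg("c")))
  for (i in seq_len(plan$duplicates)) {
    r <- baseRecord("DUP", 1.0)
    r2 <- r; r2$ddg <- 1.2
    add(r); add(r2)
  }
  for (i in seq_len(plan$missingDdg)) add(baseRecord("MIS", NA_real_))
  for (i in seq_len(plan$replicateSd)) {
    r <- baseRecord("RSD", 0.0)
    r2 <- r; r2$ddg <- 3.0    # sample SD 2.12 > 1.0
    add(r); add(r2)
  }
  for (i in seq_len(plan$signConflict)) {
    r <- baseRecord("SGN", 0.7)
    r2 <- r; r2$ddg <- -0.7   # sample SD 0.99 <= 1.0, opposite signs > 0.5
    add(r); add(r2)
  }
  for (i in seq_len(plan$missingId))
    add(baseRecord("NID", rddg("n"), withIds = FALSE))
  for (i in seq_len(plan$badFormat))
    add(baseRecord("FMT", rddg("f"), mutation = "12AG"))
  for (i in seq_len(plan$wtMismatch)) {
    r <- baseRecord("WTM", rddg("w"))
    p <- parseMutation(r$mutation)
    sq <- sequences[[r$partner_a_id]]
    wrong <- sample(setdiff(.AA, c(p$wt, p$mut, substr(sq, p$pos, p$pos))),
                    1L)
    r$mutation <- sprintf("%s%d%s", wrong, p$pos, p$mut)
    add(r)
  }
  for (i in seq_len(plan$nonDimer)) add(baseRecord("TRI", rddg("t"), 3L))

  records <- .asAffinityTable(do.call(rbind, rows))
  set.seed(.deriveSeed(seed, "shuffle"))
  records <- records[sample.int(nrow(records)), , drop = FALSE]
  rownames(records) <- NULL

  expected <- data.frame(
    stage = c("recompute_ddg", "assign_pseudonyms", "drop_missing_ddg",
              "filter_replicate_sd", "resolve_sign_conflicts",
              "merge_duplicates", "require_sequence", "mutation_format",
              "renumber_validate", "retain_dimer"),
    records_removed = c(0L, 0L, plan$missingDdg, 2L * plan$replicateSd,
                        2L * plan$signConflict, plan$duplicates,
                        plan$missingId, plan$badFormat, plan$wtMismatch,
                        plan$nonDimer),
    stringsAsFactors = FALSE)
  list(records = records, sequences = sequences, expected = expected,
       nFinal = plan$clean + plan$duplicates)
}
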