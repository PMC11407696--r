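#' Neighboring-residue index features
#'
#' Integer codes (1-20, canonical alphabet order) of the five residues
#' preceding and the five following the mutation site. Positions falling
#' off either end of the sequence are coded 0.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param position 1-based mutation position.
#' @return Named integer vector of length 10
#'   (\code{nbr_m5..nbr_m1, nbr_p1..nbr_p5}).
#' @export
neighborFeatures <- function(sequence, position) {
  L <- nchar(sequence)
  if (length(position) != 1L || is.na(position) || position < 1L ||
      position > L)
    stop(sprintf("position must be in [1, %d]", L), call. = FALSE)
  chars <- strsplit(sequence, "")[[1]]
  offs <- c(-5:-1, 1:5)
  codes <- vapply(position + offs, function(p) {
    if (p < 1L || p > L) 0L else match(chars[p], .AA, nomatch = 0L)
  }, integer(1))
  stats::setNames(codes, c(paste0("nbr_m", 5:1), paste0("nbr_p", 1:5)))
}

#' Mutation-type label
#'
#' Deterministic bijection from the 380 ordered pairs of distinct standard
#' residues onto the labels 0..379, row-major over the canonical alphabet
#' with the diagonal skipped.
#'
#' @param wt,mut Wild-type and mutant one-letter residue codes (distinct).
#' @return Integer label in 0..379.
#' @export
mutationTypeLabel <- function(wt, mut) {
  .checkResiduePair(wt, mut)
  if (wt == mut)
    stop("wild-type and mutant residues must differ", call. = FALSE)
  i <- match(wt, .AA)
  j <- match(mut, .AA)
  (i - 1L) * 19L + (j - as.integer(j > i)) - 1L
}

#' Residue-category transition labels
#'
#' One label per classification scheme encoding the ordered (wild-type
#' class, mutant class) transition: chemical property (7 classes), size
#' (5), polarity (4), hydrogen bonding (4) and hydrophobicity (3). The
#' label is \code{(wtClass - 1) * nClasses + (mutClass - 1)}, so diagonal
#' (within-class) mutations get diagonal labels.
#'
#' @param wt,mut Wild-type and mutant one-letter residue codes.
#' @return Named integer vector of length 5 (\code{cat_<scheme>}).
#' @export
categoryFeatures <- function(wt, mut) {
  .checkResiduePair(wt, mut)
  out <- vapply(.AA_CATEGORIES, function(scheme) {
    cls <- function(aa) which(vapply(scheme, function(m) aa %in% m,
                                     logical(1)))
    (cls(wt) - 1L) * length(scheme) + (cls(mut) - 1L)
  }, integer(1))
  stats::setNames(out, paste0("cat_", names(.AA_CATEGORIES)))
}

#' Experimental-condition and membrane-class features
#'
#' pH passes through as a numeric value (7.0 when absent); the functional
#' and structural membrane-protein classes are integer-encoded against
#' vocabularies fixed at fit time, with 0 reserved for classes unseen at
#' fit time (or absent).
#'
#' @param record One affinity-record row (list or single-row data frame)
#'   with optional \code{ph}, \code{functional_class},
#'   \code{structural_class}.
#' @param functionalClasses,structuralClasses Character vocabularies frozen
#'   at fit time.
#' @return Named numeric vector \code{db_ph}, \code{db_functional_class},
#'   \code{db_structural_class}.
#' @export
databaseFeatures <- function(record, functionalClasses = character(),
                             structuralClasses = character()) {
  get <- function(field) {
    v <- record[[field]]
    if (.isMissingValue(v)) NA else v
  }
  ph <- get("ph")
  code <- function(value, vocab) {
    if (.isMissingValue(value)) 0L else match(value, vocab, nomatch = 0L)
  }
  c(db_ph = if (is.na(ph)) 7.0 else as.numeric(ph),
    db_functional_class = code(get("functional_class"), functionalClasses),
    db_structural_class = code(get("structural_class"), structuralClasses))
}

.pssmFeatureNames <- function(block, chain = NULL) {
  suffix <- if (is.null(chain)) "" else paste0(chain, "_")
  switch(block,
         avg = paste0("avg_", suffix, .AA),
         row = paste0("row_", .AA))
}

#' Build a feature-set specification
#'
#' Fixes the feature identity and order for one of the four descriptor
#' sets:
#' \describe{
#'   \item{ONLY_10_PLUS}{Averaged PSSM of the mutating and interacting
#'     chains (20 + 20), lag-10 pseudo-PSSM of both chains (20 + 20) and
#'     the Row-PSSM at the mutation site (20): 100 features.}
#'   \item{PHYSICOCHEMICAL}{AAIndex1 attribute differences, the ten
#'     neighboring-residue codes, the five category-transition labels and
#'     the mutation-type label.}
#'   \item{EVOLUTIONARY}{AAIndex2 substitution scores, averaged PSSM of
#'     both chains, Row-PSSM, and pseudo-PSSM lag blocks phi = 1..10 for
#'     both chains.}
#'   \item{ALL_MPAD}{The union of the above plus the database features
#'     (pH, functional class, structural class).}
#' }
#'
#' @param setId One of the four set identifiers.
#' @param aaindex1 \code{\linkS4class{AAIndex1Table}} (required for
#'   PHYSICOCHEMICAL and ALL_MPAD).
#' @param aaindex2 \code{\linkS4class{AAIndex2Table}} (required for
#'   EVOLUTIONARY and ALL_MPAD).
#' @param functionalClasses,structuralClasses Class vocabularies to freeze
#'   (ALL_MPAD only).
#' @return A \code{\linkS4class{FeatureSetSpec}}.
#' @export
featureSetSpec <- function(setId = c("ONLY_10_PLUS", "PHYSICOCHEMICAL",
                                     "EVOLUTIONARY", "ALL_MPAD"),
                           aaindex1 = NULL, aaindex2 = NULL,
                           functionalClasses = character(),
                           structuralClasses = character()) {
  setId <- match.arg(setId)
  pseNames <- function(chain, lags = 1:10)
    unlist(lapply(lags, function(p) paste0("pse", p, "_", chain, "_", .AA)))
  groups <- list()
  if (setId %in% c("PHYSICOCHEMICAL", "ALL_MPAD")) {
    if (is.null(aaindex1))
      stop(sprintf("'%s' needs an AAIndex1 table", setId), call. = FALSE)
    groups$aaindex1 <- paste0("aa1_", aaindex1@ids[aaindex1@usable])
    groups$neighbor <- c(paste0("nbr_m", 5:1), paste0("nbr_p", 1:5))
    groups$category <- paste0("cat_", names(.AA_CATEGORIES))
    groups$muttype <- "muttype"
  }
  if (setId %in% c("EVOLUTIONARY", "ALL_MPAD")) {
    if (is.null(aaindex2))
      stop(sprintf("'%s' needs an AAIndex2 table", setId), call. = FALSE)
    groups$aaindex2 <- paste0("aa2_", aaindex2@ids[aaindex2@usable])
    groups$avg_mut <- paste0("avg_mut_", .AA)
    groups$avg_int <- paste0("avg_int_", .AA)
    groups$row <- paste0("row_", .AA)
    groups$pse_mut <- pseNames("mut")
    groups$pse_int <- pseNames("int")
  }
  if (setId == "ONLY_10_PLUS") {
    groups$avg_mut <- paste0("avg_mut_", .AA)
    groups$avg_int <- paste0("avg_int_", .AA)
    groups$pse10_mut <- paste0("pse10_mut_", .AA)
    groups$pse10_int <- paste0("pse10_int_", .AA)
    groups$row <- paste0("row_", .AA)
  }
  if (setId == "ALL_MPAD")
    groups$database <- c("db_ph", "db_functional_class",
                         "db_structural_class")
  methods::new("FeatureSetSpec", setId = setId,
               featureNames = unname(unlist(groups)), groups = groups,
               classVocab = list(functional = functionalClasses,
                                 structural = structuralClasses))
}

#' Assemble one descriptor vector
#'
#' Computes every feature block the spec demands for a single mutation and
#' concatenates them in the spec's fixed order. The wild-type residue is
#' validated against the mutating sequence; evolutionary blocks require
#' the PSSMs of both chains.
#'
#' @param spec A \code{\linkS4class{FeatureSetSpec}}.
#' @param mutation A mutation spec string or the result of
#'   \code{\link{parseMutation}} (position in mutating-sequence
#'   coordinates).
#' @param mutatingPSSM,interactingPSSM \code{\linkS4class{PSSM}} objects
#'   for the chain carrying the mutation and its binding partner.
#' @param aaindex1,aaindex2 AAIndex tables (when the spec uses them).
#' @param record Affinity-record row supplying pH and membrane classes
#'   (ALL_MPAD only; defaults are used when absent).
#' @param sequence Mutating-chain sequence; defaults to the mutating PSSM's
#'   sequence.
#' @return Named numeric vector with \code{featureNames(spec)} in order.
#' @export
assembleFeatures <- function(spec, mutation, mutatingPSSM = NULL,
                             interactingPSSM = NULL, aaindex1 = NULL,
                             aaindex2 = NULL, record = NULL,
                             sequence = NULL) {
  stopifnot(methods::is(spec, "FeatureSetSpec"))
  mut <- if (is.character(mutation)) parseMutation(mutation) else mutation
  if (is.null(sequence) && !is.null(mutatingPSSM))
    sequence <- mutatingPSSM@sequence
  if (is.null(sequence))
    stop("the mutating sequence is required (directly or via its PSSM)",
         call. = FALSE)
  if (mut$pos > nchar(sequence))
    stop(sprintf("mutation position %d beyond sequence length %d",
                 mut$pos, nchar(sequence)), call. = FALSE)
  if (substr(sequence, mut$pos, mut$pos) != mut$wt)
    stop(sprintf(
      "wild-type residue mismatch: sequence has '%s' at position %d, mutation says '%s'",
      substr(sequence, mut$pos, mut$pos), mut$pos, mut$wt), call. = FALSE)

  needPSSM <- any(c("avg_mut", "row", "pse_mut", "pse10_mut") %in%
                    names(spec@groups))
  normMut <- normInt <- NULL
  if (needPSSM) {
    if (is.null(mutatingPSSM) || is.null(interactingPSSM))
      stop(sprintf("'%s' needs PSSMs for both chains", spec@setId),
           call. = FALSE)
    normMut <- .asNormalized(mutatingPSSM)
    normInt <- .asNormalized(interactingPSSM)
  }

  blocks <- lapply(names(spec@groups), function(g) {
    v <- switch(g,
      aaindex1 = aaindex1Features(aaindex1, mut$wt, mut$mut),
      neighbor = neighborFeatures(sequence, mut$pos),
      category = categoryFeatures(mut$wt, mut$mut),
      muttype = c(muttype = mutationTypeLabel(mut$wt, mut$mut)),
      aaindex2 = aaindex2Features(aaindex2, mut$wt, mut$mut),
      avg_mut = stats::setNames(averagePSSM(normMut), spec@groups$avg_mut),
      avg_int = stats::setNames(averagePSSM(normInt), spec@groups$avg_int),
      row = stats::setNames(rowPSSM(normMut, mut$pos), spec@groups$row),
      pse10_mut = stats::setNames(psePSSM(normMut, 10L),
                                  spec@groups$pse10_mut),
      pse10_int = stats::setNames(psePSSM(normInt, 10L),
                                  spec@groups$pse10_int),
      pse_mut = stats::setNames(
        unlist(lapply(1:10, function(p) psePSSM(normMut, p))),
        spec@groups$pse_mut),
      pse_int = stats::setNames(
        unlist(lapply(1:10, function(p) psePSSM(normInt, p))),
        spec@groups$pse_int),
      database = databaseFeatures(
        if (is.null(record)) list() else record,
        spec@classVocab$functional, spec@classVocab$structural),
      stop(sprintf("unknown feature group '%s'", g), call. = FALSE))
    as.numeric(v)
  })
  out <- stats::setNames(unlist(blocks), spec@featureNames)
  if (anyNA(out))
    stop("assembled vector contains missing values", call. = FALSE)
  out
}

#' Assemble a feature matrix for a curated table
#'
#' Applies \code{\link{assembleFeatures}} to every record of a curated
#' affinity table, looking up each partner's PSSM by identifier.
#'
#' @param records Curated affinity-record data frame.
#' @param pssms Named list of \code{\linkS4class{PSSM}} objects keyed by
#'   partner identifier.
#' @param spec A \code{\linkS4class{FeatureSetSpec}}.
#' @param aaindex1,aaindex2 AAIndex tables when the spec uses them.
#' @return List with \code{X} (numeric matrix, one row per record) and
#'   \code{y} (the ddG values, kcal/mol).
#' @export
featureMatrix <- function(records, pssms, spec, aaindex1 = NULL,
                          aaindex2 = NULL) {
  records <- .asAffinityTable(records)
  pid <- .mutatedPartnerId(records)
  oid <- ifelse(records$mutated_partner %in% "B",
                records$partner_a_id, records$partner_b_id)
  X <- matrix(NA_real_, nrow(records), length(spec@featureNames),
              dimnames = list(NULL, spec@featureNames))
  for (i in seq_len(nrow(records))) {
    pm <- pssms[[pid[i]]]
    po <- pssms[[oid[i]]]
    if (is.null(pm) || is.null(po))
      stop(sprintf("missing PSSM for record %d (partners '%s'/'%s')",
                   i, pid[i], oid[i]), call. = FALSE)
    X[i, ] <- assembleFeatures(spec, records$mutation[i], pm, po,
                               aaindex1 = aaindex1, aaindex2 = aaindex2,
                               record = records[i, ])
  }
  list(X = X, y = records$ddg)
}
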