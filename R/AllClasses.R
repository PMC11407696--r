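#' @import methods
NULL

#' Position-specific scoring matrix
#'
#' An L x 20 profile of per-position substitution scores for one protein
#' sequence, as produced by iterative profile search (PSI-BLAST). Columns
#' follow the canonical alphabet \code{\link{aminoAcids}} regardless of
#' the column order of the source file. Entry (i, j) is the log-odds score
#' for the residue at sequence position i being substituted by amino acid j.
#'
#' @slot sequence Character scalar, the protein sequence (one-letter codes).
#' @slot scores Numeric matrix, \code{nchar(sequence)} rows by 20 columns,
#'   column names \code{aminoAcids()}.
#'
#' @seealso \code{\link{parsePSSM}}, \code{\link{sigmoidNormalize}}
#' @export
setClass("PSSM", representation(sequence = "character", scores = "matrix"))

setValidity("PSSM", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "'sequence' must be a single non-empty string")
  if (!is.numeric(object@scores))
    msg <- c(msg, "'scores' must be numeric")
  if (ncol(object@scores) != 20L)
    msg <- c(msg, "'scores' must have 20 columns")
  if (!identical(colnames(object@scores), .AA))
    msg <- c(msg, "'scores' columns must be named by the canonical alphabet")
  if (length(object@sequence) == 1L &&
      nrow(object@scores) != nchar(object@sequence))
    msg <- c(msg, "row count must equal sequence length")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "all scores must be finite")
  if (length(msg)) msg else TRUE
})

#' Sigmoid-normalized PSSM
#'
#' A \code{\linkS4class{PSSM}} whose entries have been mapped through the
#' logistic function f(x) = 1/(1 + exp(-x)) and therefore lie strictly in
#' (0, 1). All downstream descriptors (averaged PSSM, Row-PSSM, pseudo-PSSM)
#' are computed on this normalized form.
#'
#' @seealso \code{\link{sigmoidNormalize}}
#' @export
setClass("NormalizedPSSM", contains = "PSSM")

setValidity("NormalizedPSSM", function(object) {
  if (any(object@scores <= 0 | object@scores >= 1))
    "all normalized entries must lie strictly in (0, 1)"
  else TRUE
})

#' Table of amino-acid attribute scales (AAIndex1)
#'
#' Holds one row per published index of 20 per-residue attribute values.
#' Indices with any missing value are loaded but flagged unusable and are
#' skipped when building features.
#'
#' @slot ids Character vector of index accessions, lexicographically sorted.
#' @slot values Numeric matrix, one row per index, 20 columns in canonical
#'   alphabet order; NA where the source file said NA.
#' @slot usable Logical vector: TRUE iff the row has 20 finite values.
#'
#' @seealso \code{\link{parseAAIndex1}}
#' @export
setClass("AAIndex1Table",
         representation(ids = "character", values = "matrix",
                        usable = "logical"))

setValidity("AAIndex1Table", function(object) {
  msg <- character()
  if (nrow(object@values) != length(object@ids) ||
      length(object@usable) != length(object@ids))
    msg <- c(msg, "ids, values rows and usable flags must align")
  if (length(object@ids) && ncol(object@values) != 20L)
    msg <- c(msg, "'values' must have 20 columns")
  bad <- object@usable & apply(object@values, 1L, function(v) any(!is.finite(v)))
  if (any(bad))
    msg <- c(msg, "usable indices must have 20 finite values")
  if (length(msg)) msg else TRUE
})

#' Table of amino-acid substitution matrices (AAIndex2)
#'
#' One 20 x 20 score matrix per published substitution scale. Matrices
#' published in lower-triangular form are mirrored to full symmetric form
#' on load; matrices that cannot resolve every ordered residue pair are
#' flagged unusable.
#'
#' @slot ids Character vector of matrix accessions, sorted.
#' @slot matrices List of 20 x 20 numeric matrices (canonical row/column
#'   order), parallel to \code{ids}.
#' @slot usable Logical vector, TRUE iff every ordered pair resolves.
#'
#' @seealso \code{\link{parseAAIndex2}}
#' @export
setClass("AAIndex2Table",
         representation(ids = "character", matrices = "list",
                        usable = "logical"))

setValidity("AAIndex2Table", function(object) {
  if (length(object@matrices) != length(object@ids) ||
      length(object@usable) != length(object@ids))
    "ids, matrices and usable flags must align"
  else TRUE
})

#' Feature-set specification
#'
#' Fixes the identity, order and length of a descriptor vector. Assembled
#' vectors carry the spec's feature names in the spec's order; models refuse
#' feature matrices whose name/order fingerprint does not match the spec
#' they were trained with.
#'
#' @slot setId One of \code{"ONLY_10_PLUS"}, \code{"PHYSICOCHEMICAL"},
#'   \code{"EVOLUTIONARY"}, \code{"ALL_MPAD"}.
#' @slot featureNames Ordered character vector of unique feature names.
#' @slot groups Named list mapping block names to their feature names, in
#'   assembly order.
#' @slot classVocab Named list with character vectors \code{functional} and
#'   \code{structural}: the class vocabularies frozen at fit time for the
#'   database features (empty for sequence-only sets).
#'
#' @seealso \code{\link{featureSetSpec}}, \code{\link{assembleFeatures}}
#' @export
setClass("FeatureSetSpec",
         representation(setId = "character", featureNames = "character",
                        groups = "list", classVocab = "list"))

setValidity("FeatureSetSpec", function(object) {
  msg <- character()
  if (!object@setId %in% c("ONLY_10_PLUS", "PHYSICOCHEMICAL",
                           "EVOLUTIONARY", "ALL_MPAD"))
    msg <- c(msg, "unknown setId")
  if (anyDuplicated(object@featureNames))
    msg <- c(msg, "feature names must be unique")
  if (!identical(unname(unlist(object@groups)), object@featureNames))
    msg <- c(msg, "groups must concatenate to featureNames in order")
  if (length(msg)) msg else TRUE
})

#' Result of one cross-validation run
#'
#' Pooled out-of-fold predictions for every sample, with the Pearson
#' correlation (PCC) and root-mean-square error (RMSE, kcal/mol) computed
#' on the pooled vector, plus the fold assignment used.
#'
#' @slot observed Numeric vector of experimental ddG values.
#' @slot predicted Numeric vector of out-of-fold predictions, aligned to
#'   \code{observed}; every sample is predicted exactly once.
#' @slot folds List of k disjoint integer index vectors partitioning the
#'   samples.
#' @slot pcc Pearson correlation of observed vs predicted.
#' @slot rmse Root-mean-square error in kcal/mol.
#'
#' @seealso \code{\link{crossValidate}}
#' @export
setClass("CVResult",
         representation(observed = "numeric", predicted = "numeric",
                        folds = "list", pcc = "numeric", rmse = "numeric"))

setValidity("CVResult", function(object) {
  msg <- character()
  n <- length(object@observed)
  if (length(object@predicted) != n)
    msg <- c(msg, "observed and predicted must align")
  idx <- sort(unlist(object@folds))
  if (!identical(idx, seq_len(n)))
    msg <- c(msg, "folds must partition the samples (each predicted once)")
  if (length(object@pcc) != 1L || object@pcc < -1 || object@pcc > 1)
    msg <- c(msg, "pcc must be a single value in [-1, 1]")
  if (length(object@rmse) != 1L || object@rmse < 0)
    msg <- c(msg, "rmse must be a single non-negative value")
  if (length(msg)) msg else TRUE
})

#' Fitted ddG regression model
#'
#' A gradient-boosted tree ensemble trained on an assembled feature matrix,
#' together with the feature-set specification it expects, the chosen
#' hyperparameters and reproducibility metadata. Prediction refuses inputs
#' whose feature name/order fingerprint differs from the one recorded at
#' fit time.
#'
#' @slot booster Raw bytes of the serialized ensemble.
#' @slot spec The \code{\linkS4class{FeatureSetSpec}} used at fit time.
#' @slot hp Named list of hyperparameters.
#' @slot featureHash Fingerprint of the ordered feature names.
#' @slot meta Named list: seed, fit date, number of training rows.
#'
#' @seealso \code{\link{fitFinal}}, \code{\link{predictDdg}}
#' @export
setClass("DdgModel",
         representation(booster = "raw", spec = "FeatureSetSpec",
                        hp = "list", featureHash = "character",
                        meta = "list"))

#' Stage-by-stage accounting of a curation run
#'
#' One row per pipeline stage with the records entering, removed and
#' leaving, the distinct protein (complex) count after the stage, and a
#' per-stage table of machine-readable removal reasons. Conservation holds
#' at every stage: records_in - records_removed = records_out, and stage
#' k's output count is stage k+1's input count.
#'
#' @slot stages Data frame with columns \code{stage}, \code{records_in},
#'   \code{records_removed}, \code{records_out}, \code{distinct_proteins}.
#' @slot reasons Named list (by stage) of tables counting removal reasons.
#'
#' @seealso \code{\link{curateAffinities}}
#' @export
setClass("CurationReport",
         representation(stages = "data.frame", reasons = "list"))

setValidity("CurationReport", function(object) {
  s <- object@stages
  msg <- character()
  if (!all(c("stage", "records_in", "records_removed", "records_out",
             "distinct_proteins") %in% names(s)))
    msg <- c(msg, "stages is missing required columns")
  else {
    if (any(s$records_in - s$records_removed != s$records_out))
      msg <- c(msg, "conservation violated: in - removed != out")
    if (nrow(s) > 1L &&
        any(s$records_out[-nrow(s)] != s$records_in[-1L]))
      msg <- c(msg, "stages do not chain: out[k] != in[k+1]")
  }
  if (length(msg)) msg else TRUE
})
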