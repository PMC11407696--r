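#' @include AllClasses.R
NULL

#' Accessors for profile matrices and feature specs
#'
#' @param x A \code{\linkS4class{PSSM}}, \code{\linkS4class{FeatureSetSpec}},
#'   \code{\linkS4class{CVResult}} or \code{\linkS4class{CurationReport}}.
#' @return \code{pssmScores}: the numeric score matrix; \code{pssmSequence}:
#'   the protein sequence; \code{featureNames}: the ordered feature names;
#'   \code{setId}: the feature-set identifier; \code{oofPredictions}: a
#'   data frame of pooled out-of-fold predictions; \code{cvPCC} /
#'   \code{cvRMSE}: scalar fit statistics; \code{curationStages}: the
#'   per-stage accounting data frame; \code{removalReasons}: per-stage
#'   reason tables.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pssmScores", function(x) standardGeneric("pssmScores"))
#' @rdname accessors
#' @export
setMethod("pssmScores", "PSSM", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("pssmSequence", function(x) standardGeneric("pssmSequence"))
#' @rdname accessors
#' @export
setMethod("pssmSequence", "PSSM", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
#' @rdname accessors
#' @export
setMethod("featureNames", "FeatureSetSpec", function(x) x@featureNames)

#' @rdname accessors
#' @export
setGeneric("setId", function(x) standardGeneric("setId"))
#' @rdname accessors
#' @export
setMethod("setId", "FeatureSetSpec", function(x) x@setId)

#' @rdname accessors
#' @export
setGeneric("oofPredictions", function(x) standardGeneric("oofPredictions"))
#' @rdname accessors
#' @export
setMethod("oofPredictions", "CVResult", function(x) {
  fold <- integer(length(x@observed))
  for (k in seq_along(x@folds)) fold[x@folds[[k]]] <- k
  data.frame(observed = x@observed, predicted = x@predicted, fold = fold)
})

#' @rdname accessors
#' @export
setGeneric("cvPCC", function(x) standardGeneric("cvPCC"))
#' @rdname accessors
#' @export
setMethod("cvPCC", "CVResult", function(x) x@pcc)

#' @rdname accessors
#' @export
setGeneric("cvRMSE", function(x) standardGeneric("cvRMSE"))
#' @rdname accessors
#' @export
setMethod("cvRMSE", "CVResult", function(x) x@rmse)

#' @rdname accessors
#' @export
setGeneric("curationStages", function(x) standardGeneric("curationStages"))
#' @rdname accessors
#' @export
setMethod("curationStages", "CurationReport", function(x) x@stages)

#' @rdname accessors
#' @export
setGeneric("removalReasons", function(x) standardGeneric("removalReasons"))
#' @rdname accessors
#' @export
setMethod("removalReasons", "CurationReport", function(x) x@reasons)

setMethod("show", "PSSM", function(object) {
  cat(sprintf("%s profile: %d positions x 20 amino acids\n",
              class(object), nrow(object@scores)))
  cat("sequence: ",
      if (nchar(object@sequence) > 50)
        paste0(substr(object@sequence, 1, 50), "...")
      else object@sequence, "\n", sep = "")
})

setMethod("show", "FeatureSetSpec", function(object) {
  cat(sprintf("FeatureSetSpec '%s': %d features in %d blocks\n",
              object@setId, length(object@featureNames),
              length(object@groups)))
  for (g in names(object@groups))
    cat(sprintf("  %-14s %4d\n", g, length(object@groups[[g]])))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: n=%d, k=%d folds | PCC=%.4f RMSE=%.4f kcal/mol\n",
              length(object@observed), length(object@folds),
              object@pcc, object@rmse))
})

setMethod("show", "DdgModel", function(object) {
  cat(sprintf("DdgModel (%s, %d features), trained on %s rows, seed %s\n",
              object@spec@setId, length(object@spec@featureNames),
              object@meta$n_train, object@meta$seed))
})

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport\n")
  print(object@stages, row.names = FALSE)
})
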