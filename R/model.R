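#' Default hyperparameter search space
#'
#' A discrete dictionary of gradient-boosted-tree hyperparameters from
#' which \code{\link{hyperparameterSearch}} draws uniformly: number of
#' boosting rounds, tree depth, learning rate, row and column subsampling
#' fractions, minimum child weight and L1/L2 regularization weights.
#'
#' @return Named list of candidate-value vectors.
#' @export
defaultHyperSpace <- function() {
  list(nrounds = c(100L, 200L, 300L, 500L),
       max_depth = c(3L, 4L, 5L, 6L, 8L),
       eta = c(0.01, 0.03, 0.05, 0.1, 0.2),
       subsample = c(0.6, 0.8, 1.0),
       colsample_bytree = c(0.6, 0.8, 1.0),
       min_child_weight = c(1, 3, 5),
       alpha = c(0, 0.1, 1),
       lambda = c(0.5, 1, 2))
}

.defaultHP <- list(nrounds = 300L, max_depth = 5L, eta = 0.05,
                   subsample = 0.8, colsample_bytree = 0.8,
                   min_child_weight = 3, alpha = 0, lambda = 1)

.xgbFit <- function(X, y, hp, seed) {
  params <- list(objective = "reg:squarederror",
                 max_depth = hp$max_depth, eta = hp$eta,
                 subsample = hp$subsample,
                 colsample_bytree = hp$colsample_bytree,
                 min_child_weight = hp$min_child_weight,
                 alpha = hp$alpha, lambda = hp$lambda, nthread = 1L)
  set.seed(seed)
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(X, label = y),
                     nrounds = hp$nrounds, verbose = 0)
}

#' Deterministic k-fold split
#'
#' Randomly partitions 1..n into k disjoint folds of sizes differing by at
#' most one; the same seed always yields the same split.
#'
#' @param n Number of samples.
#' @param k Number of folds (2 <= k <= n).
#' @param seed Integer seed.
#' @return List of k integer index vectors.
#' @export
kfoldSplit <- function(n, k, seed) {
  if (k > n || k < 2L) stop("need 2 <= k <= n", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  unname(split(perm, rep(seq_len(k), sizes)))
}

.pcc <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Pearson correlation undefined: constant input", call. = FALSE)
  stats::cor(x, y)
}

.rmse <- function(x, y) sqrt(mean((x - y)^2))

#' Cross-validated evaluation of one hyperparameter set
#'
#' Splits the data into k folds, refits the gradient-boosted ensemble k
#' times, pools the out-of-fold predictions (every sample predicted exactly
#' once, never by a model that saw it) and scores the pooled vector by
#' Pearson correlation and RMSE.
#'
#' @param X Numeric feature matrix with column names.
#' @param y Numeric response (ddG, kcal/mol).
#' @param hp Named list of hyperparameters (see
#'   \code{\link{defaultHyperSpace}} for the fields).
#' @param k Number of folds.
#' @param seed Integer seed controlling the split and the fits.
#' @return A \code{\linkS4class{CVResult}}.
#' @export
crossValidate <- function(X, y, hp = .defaultHP, k = 10L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (stats::sd(y) == 0)
    stop("Pearson correlation undefined: constant response", call. = FALSE)
  folds <- kfoldSplit(nrow(X), k, seed)
  pred <- rep(NA_real_, nrow(X))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(nrow(X)), test)
    stopifnot(length(intersect(train, test)) == 0L)
    fit <- .xgbFit(X[train, , drop = FALSE], y[train], hp,
                   .deriveSeed(seed, paste0("fold", f)))
    pred[test] <- predict(fit, X[test, , drop = FALSE])
  }
  methods::new("CVResult", observed = as.numeric(y), predicted = pred,
               folds = unname(folds), pcc = .pcc(y, pred),
               rmse = .rmse(y, pred))
}

.drawHP <- function(space) {
  lapply(space, function(v) v[[sample.int(length(v), 1L)]])
}

#' Random hyperparameter search scored by cross-validated PCC
#'
#' Draws hyperparameter sets uniformly (with replacement) from a discrete
#' dictionary, scores each by \code{\link{crossValidate}}, and returns the
#' draw with the highest pooled Pearson correlation; ties are broken by
#' lower RMSE, then by earlier draw.
#'
#' @param X,y Feature matrix and response.
#' @param space Candidate dictionary (\code{\link{defaultHyperSpace}}).
#' @param nIters Number of random draws.
#' @param k Folds per evaluation.
#' @param seed Master seed; each draw and each evaluation derives its own
#'   stream from it.
#' @return List with \code{hp} (winning set), \code{result} (its
#'   \code{CVResult}) and \code{trace} (per-iteration PCC/RMSE data frame).
#' @export
hyperparameterSearch <- function(X, y, space = defaultHyperSpace(),
                                 nIters = 1000L, k = 10L, seed = 1L) {
  stopifnot(all(lengths(space) > 0L))
  best <- NULL
  trace <- data.frame(iter = seq_len(nIters), pcc = NA_real_,
                      rmse = NA_real_)
  for (it in seq_len(nIters)) {
    set.seed(.deriveSeed(seed, paste0("draw", it)))
    hp <- .drawHP(space)
    res <- crossValidate(X, y, hp, k, .deriveSeed(seed, paste0("cv", it)))
    trace$pcc[it] <- res@pcc
    trace$rmse[it] <- res@rmse
    if (is.null(best) || res@pcc > best$result@pcc ||
        (res@pcc == best$result@pcc && res@rmse < best$result@rmse))
      best <- list(hp = hp, result = res, iter = it)
  }
  c(best, list(trace = trace))
}

#' Repeated cross-validation
#'
#' Runs \code{\link{crossValidate}} several times with independently
#' derived fold seeds and reports the mean and standard deviation of the
#' pooled Pearson correlation, together with the best-scoring run (the run
#' a deployed model would be taken from).
#'
#' @param X,y Feature matrix and response.
#' @param hp Hyperparameter set.
#' @param nIters Number of repetitions.
#' @param k Folds.
#' @param seed Master seed.
#' @return List with \code{meanPCC}, \code{sdPCC}, \code{meanRMSE},
#'   \code{pcc} (per-iteration vector) and \code{best} (a
#'   \code{CVResult}).
#' @export
repeatedCV <- function(X, y, hp = .defaultHP, nIters = 50L, k = 10L,
                       seed = 1L) {
  pccs <- numeric(nIters)
  rmses <- numeric(nIters)
  best <- NULL
  for (it in seq_len(nIters)) {
    res <- crossValidate(X, y, hp, k, .deriveSeed(seed, paste0("rep", it)))
    pccs[it] <- res@pcc
    rmses[it] <- res@rmse
    if (is.null(best) || res@pcc > best@pcc) best <- res
  }
  list(meanPCC = mean(pccs), sdPCC = stats::sd(pccs),
       meanRMSE = mean(rmses), pcc = pccs, best = best)
}

#' Averaged feature importance
#'
#' Fits the ensemble on every training fold of repeated k-fold
#' cross-validation, accumulates each fold-model's gain-based importance
#' scores, averages them over all fits and normalizes the result to sum
#' to one. Features the ensemble never splits on (e.g. constants) get 0.
#'
#' @param X,y Feature matrix and response.
#' @param hp Hyperparameter set.
#' @param nRepeats Number of cross-validation repetitions.
#' @param k Folds.
#' @param seed Master seed.
#' @param groups Optional named list mapping class names to feature names;
#'   when given, a per-class roll-up is returned too.
#' @return List with \code{importance} (data frame, ranked) and optionally
#'   \code{byGroup}.
#' @export
featureImportance <- function(X, y, hp = .defaultHP, nRepeats = 100L,
                              k = 10L, seed = 1L, groups = NULL) {
  total <- stats::setNames(numeric(ncol(X)), colnames(X))
  nFits <- 0L
  for (r in seq_len(nRepeats)) {
    folds <- kfoldSplit(nrow(X), k, .deriveSeed(seed, paste0("impsplit", r)))
    for (f in seq_along(folds)) {
      train <- setdiff(seq_len(nrow(X)), folds[[f]])
      fit <- .xgbFit(X[train, , drop = FALSE], y[train], hp,
                     .deriveSeed(seed, paste0("imp", r, ".", f)))
      imp <- xgboost::xgb.importance(model = fit)
      total[imp$Feature] <- total[imp$Feature] + imp$Gain
      nFits <- nFits + 1L
    }
  }
  avg <- total / nFits
  if (sum(avg) > 0) avg <- avg / sum(avg)
  ranked <- data.frame(feature = names(avg), importance = unname(avg))
  ranked <- ranked[order(-ranked$importance), ]
  rownames(ranked) <- NULL
  out <- list(importance = ranked)
  if (!is.null(groups))
    out$byGroup <- vapply(groups, function(fn) sum(avg[fn]), numeric(1))
  out
}

#' Fit the final prediction model
#'
#' Trains the gradient-boosted ensemble on all rows of the assembled
#' feature matrix and packages it with the feature-set specification, the
#' hyperparameters and a fingerprint of the ordered feature names, so that
#' prediction can refuse inputs assembled under a different spec.
#'
#' @param X,y Feature matrix (columns named as \code{featureNames(spec)})
#'   and response.
#' @param spec The \code{\linkS4class{FeatureSetSpec}} the matrix was
#'   assembled under.
#' @param hp Hyperparameter set.
#' @param seed Integer seed.
#' @return A \code{\linkS4class{DdgModel}}.
#' @export
fitFinal <- function(X, y, spec, hp = .defaultHP, seed = 1L) {
  stopifnot(methods::is(spec, "FeatureSetSpec"))
  if (!identical(colnames(X), spec@featureNames))
    stop("feature matrix columns do not match the spec", call. = FALSE)
  fit <- .xgbFit(X, y, hp, seed)
  methods::new("DdgModel", booster = xgboost::xgb.save.raw(fit),
               spec = spec, hp = hp,
               featureHash = .hashHex(spec@featureNames),
               meta = list(seed = seed, n_train = nrow(X),
                           date = format(Sys.Date())))
}

#' @describeIn fitFinal Predict ddG for assembled feature rows; refuses
#'   matrices whose feature name/order fingerprint differs from the one
#'   recorded at fit time.
#' @param object A \code{DdgModel}.
#' @param newdata Numeric matrix (or single named vector) of assembled
#'   features.
#' @export
setMethod("predict", "DdgModel", function(object, newdata) {
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, 1L, dimnames = list(NULL, names(newdata)))
  if (!identical(.hashHex(colnames(newdata)), object@featureHash))
    stop("feature name/order mismatch: input was not assembled under the model's feature-set spec",
         call. = FALSE)
  booster <- xgboost::xgb.load.raw(object@booster)
  as.numeric(predict(booster, newdata))
})

#' Predict the effect of one mutation from sequences and PSSMs
#'
#' End-to-end single prediction: validates the mutation against the
#' mutating sequence, assembles the model's feature set from the two
#' chains' PSSMs and returns the predicted binding free energy change in
#' kcal/mol (positive = destabilizing).
#'
#' @param model A \code{\linkS4class{DdgModel}}.
#' @param mutation Mutation spec (\code{"A123G"} or parsed form), position
#'   in mutating-sequence coordinates.
#' @param mutatingPSSM,interactingPSSM PSSMs of the mutated chain and its
#'   partner.
#' @param ... Passed to \code{\link{assembleFeatures}} (AAIndex tables,
#'   record metadata) when the model's spec needs them.
#' @return Predicted ddG, kcal/mol.
#' @export
predictDdg <- function(model, mutation, mutatingPSSM, interactingPSSM,
                       ...) {
  stopifnot(methods::is(model, "DdgModel"))
  v <- assembleFeatures(model@spec, mutation, mutatingPSSM,
                        interactingPSSM, ...)
  predict(model, v)
}

#' Save / load a fitted model artifact
#'
#' The artifact is a single self-describing file embedding the serialized
#' ensemble, the feature-set specification, the hyperparameters and the
#' feature-order fingerprint; loading verifies the fingerprint.
#'
#' @param model A \code{\linkS4class{DdgModel}}.
#' @param path Artifact file path.
#' @return \code{saveModel}: the path, invisibly. \code{loadModel}: the
#'   restored \code{DdgModel}.
#' @export
saveModel <- function(model, path) {
  stopifnot(methods::is(model, "DdgModel"))
  saveRDS(list(booster = model@booster,
               spec = list(setId = model@spec@setId,
                           featureNames = model@spec@featureNames,
                           groups = model@spec@groups,
                           classVocab = model@spec@classVocab),
               hp = model@hp, featureHash = model@featureHash,
               meta = model@meta), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  spec <- methods::new("FeatureSetSpec", setId = obj$spec$setId,
                       featureNames = obj$spec$featureNames,
                       groups = obj$spec$groups,
                       classVocab = obj$spec$classVocab)
  if (!identical(.hashHex(spec@featureNames), obj$featureHash))
    stop("model artifact corrupt: feature-order fingerprint mismatch",
         call. = FALSE)
  methods::new("DdgModel", booster = obj$booster, spec = spec,
               hp = obj$hp, featureHash = obj$featureHash, meta = obj$meta)
}
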