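test_that("k-fold splits partition the samples evenly and reproducibly", {
  f <- kfoldSplit(10, 5, seed = 1)
  expect_equal(lengths(f), rep(2L, 5))
  expect_equal(sort(unlist(f)), 1:10)
  f2 <- kfoldSplit(23, 4, seed = 9)
  expect_equal(sort(unlist(f2)), 1:23)
  expect_true(max(lengths(f2)) - min(lengths(f2)) <= 1L)
  expect_identical(kfoldSplit(23, 4, seed = 9), f2)
  expect_false(identical(kfoldSplit(23, 4, seed = 10), f2))
  expect_error(kfoldSplit(3, 5, seed = 1), "k <= n")
})

test_that("cross-validation learns a noiseless linear signal and pools every sample once", {
  set.seed(5)
  X <- matrix(runif(400 * 8), 400, 8)
  colnames(X) <- paste0("f", 1:8)
  y <- 3 * X[, 2]
  cv <- crossValidate(X, y, k = 5, seed = 5)
  expect_gte(cvPCC(cv), 0.99)
  oof <- oofPredictions(cv)
  expect_equal(nrow(oof), 400L)
  expect_equal(sort(unlist(cv@folds)), 1:400)
  # RMSE equals the brute-force formula on the pooled vector
  expect_equal(cvRMSE(cv), sqrt(mean((oof$observed - oof$predicted)^2)))
})

test_that("cross-validation shows null behavior on permuted responses", {
  set.seed(6)
  X <- matrix(runif(500 * 8), 500, 8)
  colnames(X) <- paste0("f", 1:8)
  y <- 3 * X[, 2]
  yPerm <- sample(y)   # destroys the feature-response link
  cv <- crossValidate(X, yPerm, k = 5, seed = 6)
  expect_lt(abs(cvPCC(cv)), 0.2)
})

test_that("constant responses are rejected with an explicit message", {
  X <- matrix(runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(crossValidate(X, rep(1.5, 20), k = 4, seed = 1),
               "constant")
})

test_that("random search returns the argmax by PCC with deterministic draws", {
  set.seed(7)
  X <- matrix(runif(120 * 5), 120, 5)
  colnames(X) <- paste0("f", 1:5)
  y <- 2 * X[, 1] + rnorm(120, 0, 0.1)
  # single-point space: that point is returned whatever the iteration count
  point <- list(nrounds = 50L, max_depth = 3L, eta = 0.1, subsample = 1.0,
                colsample_bytree = 1.0, min_child_weight = 1, alpha = 0,
                lambda = 1)
  space1 <- lapply(point, function(v) v)
  s1 <- hyperparameterSearch(X, y, space1, nIters = 3, k = 3, seed = 2)
  expect_equal(s1$hp, point)
  # winner's PCC >= every evaluated draw; same seed -> same winner
  space <- list(nrounds = c(20L, 100L), max_depth = c(2L, 4L),
                eta = c(0.05, 0.3), subsample = c(0.7, 1.0),
                colsample_bytree = c(1.0), min_child_weight = c(1),
                alpha = c(0), lambda = c(1))
  s <- hyperparameterSearch(X, y, space, nIters = 6, k = 3, seed = 3)
  expect_true(all(cvPCC(s$result) >= s$trace$pcc))
  s2 <- hyperparameterSearch(X, y, space, nIters = 6, k = 3, seed = 3)
  expect_identical(s$hp, s2$hp)
  expect_equal(cvPCC(s$result), cvPCC(s2$result))
})

test_that("repeated cross-validation summarizes iteration PCCs coherently", {
  set.seed(8)
  X <- matrix(runif(150 * 4), 150, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- X[, 1] - 2 * X[, 3] + rnorm(150, 0, 0.2)
  hp <- list(nrounds = 60L, max_depth = 3L, eta = 0.1, subsample = 0.9,
             colsample_bytree = 1.0, min_child_weight = 1, alpha = 0,
             lambda = 1)
  rep5 <- repeatedCV(X, y, hp, nIters = 5, k = 5, seed = 4)
  expect_length(rep5$pcc, 5L)
  expect_gte(rep5$meanPCC, min(rep5$pcc))
  expect_lte(rep5$meanPCC, max(rep5$pcc))
  expect_equal(cvPCC(rep5$best), max(rep5$pcc))
})

test_that("importance scores normalize to one and constants get nothing", {
  set.seed(9)
  X <- matrix(runif(200 * 6), 200, 6)
  X[, 6] <- 1   # constant feature
  colnames(X) <- paste0("f", 1:6)
  y <- 4 * X[, 1] + rnorm(200, 0, 0.1)
  imp <- featureImportance(X, y, nRepeats = 2, k = 4, seed = 5,
                           groups = list(signal = "f1",
                                         rest = paste0("f", 2:6)))
  expect_equal(sum(imp$importance$importance), 1, tolerance = 1e-9)
  tab <- setNames(imp$importance$importance, imp$importance$feature)
  expect_equal(unname(tab["f6"]), 0)
  # the single informative feature carries most of the gain mass
  expect_gt(imp$byGroup[["signal"]], 0.7)
  expect_equal(imp$byGroup[["signal"]] + imp$byGroup[["rest"]], 1,
               tolerance = 1e-9)
})

test_that("final models round-trip through disk and guard their feature order", {
  pd <- plantedDataset(plantedDatasetSpec(nRecords = 40L, seed = 17))
  hp <- list(nrounds = 40L, max_depth = 3L, eta = 0.1, subsample = 1.0,
             colsample_bytree = 1.0, min_child_weight = 1, alpha = 0,
             lambda = 1)
  model <- fitFinal(pd$X, pd$y, pd$spec, hp, seed = 11)
  predMem <- predict(model, pd$X)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, f)
  back <- loadModel(f)
  expect_identical(predict(back, pd$X), predMem)
  # refit under the same seed gives identical predictions
  model2 <- fitFinal(pd$X, pd$y, pd$spec, hp, seed = 11)
  expect_identical(predict(model2, pd$X), predMem)
  # shuffled columns are refused
  Xbad <- pd$X[, rev(colnames(pd$X))]
  expect_error(predict(model, Xbad), "mismatch")
  expect_error(fitFinal(Xbad, pd$y, pd$spec, hp), "match the spec")
})

test_that("end-to-end prediction validates inputs and is deterministic", {
  pd <- plantedDataset(plantedDatasetSpec(nRecords = 40L, seed = 19))
  hp <- list(nrounds = 40L, max_depth = 3L, eta = 0.1, subsample = 1.0,
             colsample_bytree = 1.0, min_child_weight = 1, alpha = 0,
             lambda = 1)
  model <- fitFinal(pd$X, pd$y, pd$spec, hp, seed = 13)
  rec <- pd$records[1, ]
  pm <- pd$pssms[[rec$partner_a_id]]
  pi <- pd$pssms[[rec$partner_b_id]]
  d1 <- predictDdg(model, rec$mutation, pm, pi)
  d2 <- predictDdg(model, rec$mutation, pm, pi)
  expect_identical(d1, d2)
  expect_length(d1, 1L)
  # a wrong wild-type residue never yields a prediction
  p <- parseMutation(rec$mutation)
  wrong <- setdiff(aminoAcids(), c(p$wt, p$mut))[1]
  expect_error(predictDdg(model, sprintf("%s%d%s", wrong, p$pos, p$mut),
                          pm, pi), "mismatch")
})
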