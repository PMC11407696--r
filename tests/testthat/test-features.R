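test_that("neighbor codes window the sequence and pad termini with zero", {
  s <- "ACDEFGHIKLMNP"
  # interior site: five before, five after
  v <- neighborFeatures(s, 7)
  expect_equal(length(v), 10L)
  aa <- aminoAcids()
  expect_equal(unname(v),
               c(match(c("C", "D", "E", "F", "G"), aa),
                 match(c("I", "K", "L", "M", "N"), aa)))
  # first position: no leading residues
  v1 <- neighborFeatures(s, 1)
  expect_equal(unname(v1[1:5]), rep(0L, 5))
  expect_true(all(v1[6:10] > 0))
  # last position: no lagging residues
  vL <- neighborFeatures(s, nchar(s))
  expect_equal(unname(vL[6:10]), rep(0L, 5))
  expect_error(neighborFeatures(s, 0), "position")
  expect_error(neighborFeatures(s, 14), "position")
})

test_that("mutation-type labels are a bijection onto 0..379", {
  aa <- aminoAcids()
  labels <- integer(0)
  for (wt in aa) for (mut in aa) if (wt != mut)
    labels <- c(labels, mutationTypeLabel(wt, mut))
  expect_equal(length(labels), 380L)
  expect_equal(sort(labels), 0:379)
  expect_equal(mutationTypeLabel("A", "C"), 0L)
  expect_false(mutationTypeLabel("A", "C") == mutationTypeLabel("C", "A"))
  expect_error(mutationTypeLabel("A", "A"), "differ")
})

test_that("category transitions encode ordered class pairs per scheme", {
  # D -> E stays within acidic / polar-acidic / hydrophilic: diagonal labels
  de <- categoryFeatures("D", "E")
  expect_equal(length(de), 5L)
  nClasses <- c(chemical = 7L, size = 5L, polarity = 4L, hbond = 4L,
                hydrophobicity = 3L)
  isDiagonal <- function(label, n) (label %/% n) == (label %% n)
  expect_true(isDiagonal(de[["cat_chemical"]], 7L))
  expect_true(isDiagonal(de[["cat_polarity"]], 4L))
  expect_true(isDiagonal(de[["cat_hydrophobicity"]], 3L))
  # A -> R crosses aliphatic->basic, nonpolar->polar-basic,
  # hydrophobic->hydrophilic: all off-diagonal
  ar <- categoryFeatures("A", "R")
  expect_false(isDiagonal(ar[["cat_chemical"]], 7L))
  expect_false(isDiagonal(ar[["cat_polarity"]], 4L))
  expect_false(isDiagonal(ar[["cat_hydrophobicity"]], 3L))
  # label ranges stay within nClasses^2
  aa <- aminoAcids()
  set.seed(3)
  for (i in seq_len(50)) {
    pair <- sample(aa, 2)
    v <- categoryFeatures(pair[1], pair[2])
    expect_true(all(v >= 0 & v < nClasses[sub("cat_", "", names(v))]^2))
  }
})

test_that("database features pass pH through and encode classes against a frozen vocabulary", {
  rec <- list(ph = 7.4, functional_class = "receptor",
              structural_class = "beta-barrel")
  v <- databaseFeatures(rec, functionalClasses = c("enzyme", "receptor"),
                        structuralClasses = c("beta-barrel"))
  expect_equal(unname(v), c(7.4, 2, 1))
  # absent pH defaults to 7.0; unseen class maps to the reserved 0 code
  v2 <- databaseFeatures(list(functional_class = "transporter"),
                         functionalClasses = c("enzyme", "receptor"))
  expect_equal(unname(v2), c(7.0, 0, 0))
  # same class text -> same code
  expect_equal(databaseFeatures(rec, "receptor", "beta-barrel"),
               databaseFeatures(rec, "receptor", "beta-barrel"))
})

test_that("the 100-feature evolutionary set assembles blockwise in fixed order", {
  spec <- featureSetSpec("ONLY_10_PLUS")
  expect_equal(length(featureNames(spec)), 100L)
  mutSeq <- randomSequence(40, 61)
  intSeq <- randomSequence(35, 62)
  pm <- syntheticPSSM(mutSeq, seed = 63)
  pi <- syntheticPSSM(intSeq, seed = 64)
  pos <- 12L
  wt <- substr(mutSeq, pos, pos)
  mutAA <- setdiff(aminoAcids(), wt)[1]
  mstr <- sprintf("%s%d%s", wt, pos, mutAA)
  v <- assembleFeatures(spec, mstr, pm, pi)
  expect_equal(length(v), 100L)
  expect_identical(names(v), featureNames(spec))
  # concatenation equals the independently computed blocks in spec order
  expect_equal(unname(v),
               unname(c(averagePSSM(pm), averagePSSM(pi),
                        psePSSM(pm, 10), psePSSM(pi, 10),
                        rowPSSM(pm, pos))))
  # identical partner PSSMs make the two averaged blocks identical
  vSame <- assembleFeatures(spec, mstr, pm, pm)
  expect_equal(unname(vSame[1:20]), unname(vSame[21:40]))
  # wild-type mismatch is an error, not a silent feature
  wrong <- setdiff(aminoAcids(), c(wt, mutAA))[1]
  expect_error(assembleFeatures(spec, sprintf("%s%d%s", wrong, pos, mutAA),
                                pm, pi), "mismatch")
  expect_error(assembleFeatures(spec, mstr, pm, NULL), "PSSM")
})

test_that("feature names and order are byte-identical across calls", {
  s1 <- featureSetSpec("ONLY_10_PLUS")
  s2 <- featureSetSpec("ONLY_10_PLUS")
  expect_identical(paste(featureNames(s1), collapse = "\t"),
                   paste(featureNames(s2), collapse = "\t"))
})

test_that("the physicochemical and combined sets honor their composition", {
  v1 <- setNames(rnorm(20), c(AAI1_ROW1, AAI1_ROW2))
  aa1 <- parseAAIndex1(text = paste(aaindex1Record("IDX1", v1),
                                    aaindex1Record("IDX2", v1 * 2),
                                    sep = "\n"))
  aa2 <- parseAAIndex2(text = aaindex2Record("MAT1", symmetricScoreMatrix()))
  phys <- featureSetSpec("PHYSICOCHEMICAL", aaindex1 = aa1)
  # 2 usable indices + 10 neighbor + 5 category + 1 mutation type
  expect_equal(length(featureNames(phys)), 2L + 10L + 5L + 1L)
  evo <- featureSetSpec("EVOLUTIONARY", aaindex2 = aa2)
  # 1 matrix + avg both (40) + row (20) + lag blocks both (400)
  expect_equal(length(featureNames(evo)), 1L + 40L + 20L + 400L)
  all <- featureSetSpec("ALL_MPAD", aaindex1 = aa1, aaindex2 = aa2,
                        functionalClasses = "enzyme")
  expect_equal(length(featureNames(all)),
               length(featureNames(phys)) + length(featureNames(evo)) + 3L)

  mutSeq <- randomSequence(40, 71)
  pm <- syntheticPSSM(mutSeq, seed = 72)
  pi <- syntheticPSSM(randomSequence(33, 73), seed = 74)
  pos <- 20L
  wt <- substr(mutSeq, pos, pos)
  mutAA <- setdiff(aminoAcids(), wt)[1]
  mstr <- sprintf("%s%d%s", wt, pos, mutAA)
  vAll <- assembleFeatures(all, mstr, pm, pi, aaindex1 = aa1, aaindex2 = aa2,
                           record = list(ph = 6.5,
                                         functional_class = "enzyme"))
  expect_identical(names(vAll), featureNames(all))
  expect_equal(unname(vAll[c("db_ph", "db_functional_class")]), c(6.5, 1))
})

test_that("featureMatrix assembles curated records against their PSSMs", {
  pd <- plantedDataset(plantedDatasetSpec(nRecords = 6L, seed = 91))
  fm <- featureMatrix(pd$records, pd$pssms, pd$spec)
  expect_equal(dim(fm$X), c(6L, 100L))
  expect_equal(fm$X, pd$X, ignore_attr = TRUE)
  expect_equal(fm$y, pd$y)
  expect_error(featureMatrix(pd$records, pd$pssms[-1], pd$spec),
               "missing PSSM")
})
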