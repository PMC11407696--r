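test_that("binding free energy follows RT ln(KD) with the stated constants", {
  cfg <- curationConfig()
  expect_equal(deltaGfromKd(1.0, cfg), 0)
  # direct evaluation: 1.987e-3 * 298.15 * ln(1e-9)
  expect_equal(deltaGfromKd(1e-9, cfg), 1.987e-3 * 298.15 * log(1e-9),
               tolerance = 1e-12)
  expect_equal(deltaGfromKd(1e-9, cfg), -12.2769, tolerance = 1e-4)
  expect_lt(deltaGfromKd(1e-10, cfg), deltaGfromKd(1e-9, cfg))
  expect_error(deltaGfromKd(0, cfg), "positive")
  expect_error(deltaGfromKd(-1, cfg), "positive")
})

test_that("ddG recomputation prefers the dG difference and respects the sign convention", {
  cfg <- curationConfig()
  rec <- data.frame(complex_id = "1ABC", partner_a_id = "P1",
                    partner_b_id = "P2", mutated_partner = "A",
                    mutation = "A5G", dg_wt = -10.0, dg_mut = -8.5,
                    ddg = -1.5, n_chains = 2L)
  out <- recomputeDdg(rec, cfg)
  expect_equal(out$ddg, 1.5)   # difference overrides the stated value

  rec$dg_mut <- rec$dg_wt      # identical energies -> ddg 0
  expect_equal(recomputeDdg(rec, cfg)$ddg, 0)

  only <- data.frame(complex_id = "1ABC", mutation = "A5G", ddg = 0.7)
  expect_equal(recomputeDdg(only, cfg)$ddg, 0.7)

  none <- data.frame(complex_id = "1ABC", mutation = "A5G")
  expect_true(is.na(recomputeDdg(none, cfg)$ddg))
})

test_that("kd-derived ddG matches the closed form and kd ordering fixes the sign", {
  cfg <- curationConfig()
  set.seed(42)
  kdw <- 10^runif(1000, -12, -3)
  kdm <- 10^runif(1000, -12, -3)
  rec <- data.frame(complex_id = sprintf("C%04d", seq_len(1000)),
                    mutation = "A5G", kd_wt = kdw, kd_mut = kdm)
  out <- recomputeDdg(rec, cfg)
  closed <- cfg$gasConstantR * cfg$temperatureT * (log(kdm) - log(kdw))
  expect_equal(out$ddg, closed, tolerance = 1e-9)
  # weaker mutant binding (larger kd) is destabilizing: positive ddg
  expect_identical(out$ddg > 0, kdm > kdw)
})

test_that("pseudonyms are deterministic, shared within a complex and never overwrite IDs", {
  rec <- data.frame(
    complex_id = c(NA, NA, "1ABC", NA),
    partner_a_id = c("P1", "P1", "P3", "P9"),
    partner_b_id = c("P2", "P2", "P4", NA),
    mutation = c("A5G", "A6G", "A5G", "A5G"))
  out <- assignPseudonyms(rec)
  expect_true(all(!is.na(out$complex_id)))
  expect_identical(out$complex_id[1], out$complex_id[2])
  expect_identical(out$complex_id[3], "1ABC")
  expect_false(out$complex_id[4] %in% out$complex_id[1:3])
  expect_identical(out$complex_id, assignPseudonyms(rec)$complex_id)
})

test_that("records without ddG are dropped and no others", {
  rec <- data.frame(complex_id = sprintf("C%d", 1:5), mutation = "A5G",
                    ddg = c(1, NA, 2, NA, 3))
  out <- dropMissingDdg(rec)
  expect_equal(nrow(out$records), 3L)
  expect_equal(nrow(out$removed), 2L)
  all_ok <- dropMissingDdg(out$records)
  expect_equal(nrow(all_ok$removed), 0L)
  empty <- dropMissingDdg(rec[0, ])
  expect_equal(nrow(empty$records), 0L)
})

test_that("replicate groups are removed on sample SD above the cutoff", {
  mk <- function(id, ddgs) data.frame(complex_id = id, mutated_partner = "A",
                                      mutation = "A5G", ddg = ddgs)
  rec <- rbind(mk("K1", c(1.0, 1.2)),    # SD 0.141 -> kept
               mk("K2", c(0.0, 2.0)),    # SD 1.414 -> removed
               mk("K3", 5.0))            # singleton -> kept
  out <- filterReplicateSd(rec, curationConfig())
  expect_setequal(out$records$complex_id, c("K1", "K1", "K3"))
  expect_setequal(out$removed$complex_id, c("K2", "K2"))
  # surviving groups pass through unmerged
  expect_equal(nrow(out$records), 3L)
})

test_that("sign conflicts follow the pair, small-group and outlier rules", {
  mk <- function(id, ddgs) data.frame(complex_id = id, mutated_partner = "A",
                                      mutation = "A5G", ddg = ddgs)
  cfg <- curationConfig()
  # rule (i): opposite signs, both beyond 0.5 -> both removed
  out <- resolveSignConflicts(mk("P", c(0.6, -0.6)), cfg)
  expect_equal(nrow(out$records), 0L)
  # neither exceeds the cutoff -> kept
  out <- resolveSignConflicts(mk("P", c(0.3, -0.3)), cfg)
  expect_equal(nrow(out$records), 2L)
  # same sign -> rule does not apply
  out <- resolveSignConflicts(mk("P", c(0.6, 0.7)), cfg)
  expect_equal(nrow(out$records), 2L)
  # rule (ii): 3-4 mixed-sign with any value beyond 0.5 -> all removed
  out <- resolveSignConflicts(mk("P", c(0.6, -0.1, 0.2)), cfg)
  expect_equal(nrow(out$records), 0L)
  out <- resolveSignConflicts(mk("P", c(0.4, -0.1, 0.2)), cfg)
  expect_equal(nrow(out$records), 3L)
  # rule (iii): >=5 with one or two median outliers -> outliers removed only
  out <- resolveSignConflicts(mk("P", c(1.0, 1.1, 0.9, 1.0, 3.0)), cfg)
  expect_equal(nrow(out$records), 4L)
  expect_equal(out$removed$ddg, 3.0)
})

test_that("duplicate merging takes the mean and is order-invariant", {
  rec <- data.frame(complex_id = c("C1", "C1", "C2"),
                    mutated_partner = "A",
                    mutation = c("A5G", "A5G", "A5G"),
                    ddg = c(1.0, 1.2, 4.0))
  out <- mergeDuplicates(rec)
  expect_equal(nrow(out$records), 2L)
  expect_equal(sort(out$records$ddg), c(1.1, 4.0))
  perm <- mergeDuplicates(rec[c(3, 2, 1), ])
  expect_equal(sort(perm$records$ddg), sort(out$records$ddg))
  # no duplicate keys remain
  expect_equal(anyDuplicated(paste(out$records$complex_id,
                                   out$records$mutation)), 0L)
})

test_that("renumbering maps structure to sequence coordinates and validates the wild type", {
  rec <- function(mut) data.frame(complex_id = "C1", partner_a_id = "P1",
                                  mutated_partner = "A", mutation = mut,
                                  ddg = 1)
  seqs <- c(P1 = "MKT")
  ok <- renumberAndValidate(rec("K2A"), seqs)
  expect_equal(nrow(ok$records), 1L)
  bad <- renumberAndValidate(rec("R2A"), seqs)
  expect_equal(nrow(bad$records), 0L)
  expect_equal(bad$reasons, "wt_mismatch")
  # offset map 5->1, 6->2, 7->3: K6A lands on position 2
  maps <- list(P1 = c("5" = 1L, "6" = 2L, "7" = 3L))
  off <- renumberAndValidate(rec("K6A"), seqs, maps)
  expect_equal(off$records$mutation, "K2A")
  miss <- renumberAndValidate(rec("K9A"), seqs, maps)
  expect_equal(miss$reasons, "unmapped_position")
})

test_that("the full pipeline conserves counts, chains stages and is idempotent", {
  m <- messyAffinityTable(defectPlan(), seed = 101)
  res <- curateAffinities(m$records, m$sequences)
  s <- curationStages(res$report)
  expect_true(all(s$records_in - s$records_removed == s$records_out))
  expect_equal(s$records_out[-nrow(s)], s$records_in[-1])
  expect_equal(s$records_removed, m$expected$records_removed)
  expect_equal(nrow(res$records), m$nFinal)
  # idempotence on the record set
  res2 <- curateAffinities(res$records, m$sequences)
  expect_equal(sum(curationStages(res2$report)$records_removed), 0L)
  expect_equal(sort(res2$records$ddg), sort(res$records$ddg))
})
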