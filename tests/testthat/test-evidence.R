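makeEvidence <- function(id, uniq, psm, single = uniq == 1, cv = 5) {
  data.frame(feature_id = id, n_unique_peptides = as.integer(uniq),
             total_psm = as.integer(psm), single_peptide = single,
             cv_percent = cv, stringsAsFactors = FALSE)
}

test_that("peptide aggregation counts evidence and pools CV", {
  pep <- data.frame(
    protein_id = c("P1", "P1", "P2", "P3", "P3", "P3"),
    peptide_sequence = c("a", "b", "c", "d", "e", "f"),
    is_unique = TRUE,
    psm_count = c(1L, 1L, 2L, 1L, 1L, 1L),
    intensities = c("100", "100", "100;300", "50", "60", "70"),
    stringsAsFactors = FALSE)
  ev <- aggregateEvidence(pep)
  expect_equal(ev$feature_id, c("P1", "P2", "P3"))
  expect_equal(ev$n_unique_peptides, c(2L, 1L, 3L))
  expect_equal(ev$total_psm, c(2L, 2L, 3L))
  expect_equal(ev$single_peptide, c(FALSE, TRUE, FALSE))
  expect_equal(ev$cv_percent[1], 0)                      # [100, 100]
  expect_equal(ev$cv_percent[2], 100 * sd(c(100, 300)) / 200)
  expect_equal(ev$cv_percent[2], 70.71068, tolerance = 1e-5)
  expect_error(aggregateEvidence(pep[0, ]), "empty")
  bad <- pep; bad$psm_count[3] <- 5L
  expect_error(aggregateEvidence(bad), "number of intensity")
})

test_that("protein filter applies the two evidence rules and the rescue", {
  ev <- rbind(
    makeEvidence("P1", 2, 2),    # >= 2 unique peptides -> kept
    makeEvidence("P2", 1, 2),    # >= 2 PSM -> kept
    makeEvidence("P3", 1, 1),    # 1/1, transcript unchanged -> dropped
    makeEvidence("P4", 1, 1),    # 1/1, transcript up, delta > 0 -> kept
    makeEvidence("P5", 1, 1),    # 1/1, transcript up, delta < 0 -> dropped
    makeEvidence("P6", 1, 1))    # 1/1, transcript absent -> dropped
  calls <- c(P3 = "unchanged", P4 = "up", P5 = "up")
  delta <- c(P4 = 0.8, P5 = -0.8)
  out <- filterProteins(ev, calls, proteinDelta = delta)
  expect_setequal(out$kept, c("P1", "P2", "P4"))
  expect_equal(out$audit$reason[out$audit$feature_id == "P1"],
               "unique_peptides_ge2")
  expect_equal(out$audit$reason[out$audit$feature_id == "P2"], "psm_ge2")
  expect_equal(out$audit$reason[out$audit$feature_id == "P4"],
               "transcript_rescue")
  expect_match(out$audit$reason[out$audit$feature_id == "P6"],
               "no_transcript")
})

test_that("phospho filter enforces >= 2 PSM and CV strictly below 40%", {
  ev <- rbind(
    makeEvidence("q1", 1, 2, cv = 10),     # kept
    makeEvidence("q2", 1, 1, cv = 0),      # psm -> dropped
    makeEvidence("q3", 1, 3, cv = 70.71068), # cv -> dropped
    makeEvidence("q4", 1, 2, cv = 39.99),  # kept
    makeEvidence("q5", 1, 2, cv = 40),     # boundary -> dropped
    makeEvidence("q6", 1, 4, cv = 0))      # kept
  out <- filterPhosphopeptides(ev)
  expect_setequal(out$kept, c("q1", "q4", "q6"))
  expect_equal(out$audit$reason[out$audit$feature_id == "q2"],
               "psm_lt_min")
  expect_equal(out$audit$reason[out$audit$feature_id == "q5"],
               "cv_ge_max")
})

test_that("filters are idempotent and monotone in added PSMs", {
  set.seed(17)
  ev <- makeEvidence(sprintf("p%02d", 1:40),
                     uniq = sample(1:3, 40, TRUE),
                     psm = sample(1:4, 40, TRUE),
                     cv = runif(40, 0, 80))
  out1 <- filterPhosphopeptides(ev)
  out2 <- filterPhosphopeptides(ev[ev$feature_id %in% out1$kept, ])
  expect_identical(out1$kept, out2$kept)
  p1 <- filterProteins(ev)
  p2 <- filterProteins(ev[ev$feature_id %in% p1$kept, ])
  expect_identical(p1$kept, p2$kept)
  # adding PSMs at fixed CV never drops a kept feature
  more <- ev; more$total_psm <- more$total_psm + 2L
  expect_true(all(p1$kept %in% filterProteins(more)$kept))
  expect_true(all(out1$kept %in% filterPhosphopeptides(more)$kept))
})

test_that("audit drop reasons reconcile with the generator's planted counts", {
  cfg <- simulationConfig(nFeatures = 600, fracSinglePeptide = 0.25,
                          seed = 19)
  sim <- simulateProteome(cfg)
  ev <- aggregateEvidence(sim$peptides)
  out <- filterProteins(ev)   # no transcript calls: no rescue possible
  planted <- truthTable(sim$abundance)$planted_single_peptide
  # generator gives single-peptide proteins exactly one PSM, so they are
  # precisely the drop set when no transcript evidence is offered
  expect_equal(sum(!out$audit$kept), sum(planted))
  expect_setequal(out$audit$feature_id[!out$audit$kept],
                  truthTable(sim$abundance)$feature_id[planted])
})
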