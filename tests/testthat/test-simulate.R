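test_that("simulation config validates its invariants", {
  expect_s4_class(simulationConfig(nFeatures = 10), "SimulationConfig")
  expect_error(simulationConfig(nFeatures = 0), "positive")
  expect_error(simulationConfig(fracUp = 0.6, fracDown = 0.5), "fracUp")
  expect_error(simulationConfig(effectLog2FC = -1), "effectLog2FC")
  expect_error(simulationConfig(librarySize = 0), "librarySize")
})

test_that("paired counts carry planted truth in the stated proportions", {
  cfg <- simulationConfig(nFeatures = 5000, fracUp = 0.02,
                          fracDown = 0.02, effectLog2FC = 2, seed = 7)
  sim <- simulatePairedCounts(cfg)
  tr <- truthTable(sim)
  expect_equal(sum(tr$true_class == "up"), 100)
  expect_equal(sum(tr$true_class == "down"), 100)
  expect_equal(nrow(tr), 5000)         # truth conservation
  expect_false(anyDuplicated(tr$feature_id) > 0)
  cs <- colSums(SummarizedExperiment::assay(sim))
  expect_true(all(abs(cs / 3e7 - 1) < 0.01))  # column sums near library
})

test_that("identical config and seed give identical tables, new seed a new table", {
  cfg <- simulationConfig(nFeatures = 400, seed = 7, librarySize = 1e6)
  a <- simulatePairedCounts(cfg)
  b <- simulatePairedCounts(cfg)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_identical(truthTable(a), truthTable(b))
  cfg8 <- simulationConfig(nFeatures = 400, seed = 8, librarySize = 1e6)
  c <- simulatePairedCounts(cfg8)
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c)))
  expect_equal(table(truthTable(a)$true_class),
               table(truthTable(c)$true_class))
})

test_that("a no-effect, no-noise config yields no differential calls", {
  cfg <- simulationConfig(nFeatures = 2000, fracUp = 0, fracDown = 0,
                          noiseSD = 0, seed = 3, librarySize = 5e6)
  d <- log2cpmPair(cfg)
  res <- piDifferential(d$x, d$y, modality = "transcript")
  expect_equal(sum(piCalls(res) != "unchanged"), 0)
  expect_true(all(truthTable(d$sim)$true_class == "null"))
})

test_that("proteome simulation produces labeled channels and evidence", {
  cfg <- simulationConfig(nFeatures = 1000, nReplicatePairs = 2,
                          fracSinglePeptide = 0.2, seed = 7)
  sim <- simulateProteome(cfg)
  ab <- SummarizedExperiment::assay(sim$abundance)
  expect_identical(colnames(ab), c("ctrl1", "test1", "ctrl2", "test2"))
  expect_true(all(ab > 0))
  ev <- aggregateEvidence(sim$peptides)
  expect_equal(nrow(ev), 1000)
  # the planted single-peptide flags are a reproducible binomial draw
  planted <- sum(truthTable(sim$abundance)$planted_single_peptide)
  expect_equal(sum(ev$single_peptide), planted)
  expect_gt(planted, 150)
  expect_lt(planted, 250)
  again <- simulateProteome(cfg)
  expect_equal(sum(truthTable(again$abundance)$planted_single_peptide),
               planted)
  # no planted effects -> truth all null
  cfg0 <- simulationConfig(nFeatures = 100, fracUp = 0, fracDown = 0,
                           seed = 7)
  expect_true(all(truthTable(simulateProteome(cfg0)$abundance)$true_class
                  == "null"))
})

test_that("phospho simulation splits drivers and marks filter-fated rows", {
  prot <- simulateProteome(simulationConfig(nFeatures = 500, seed = 5))
  cfg <- simulationConfig(nFeatures = 400, fracUp = 0.05, fracDown = 0.05,
                          fracSiteDriver = 1.0, seed = 5)
  phos <- simulatePhospho(cfg, truthTable(prot$abundance))
  tr <- truthTable(phos$abundance)
  planted <- tr[tr$true_class != "null", ]
  expect_true(all(planted$driver == "site"))
  protTr <- truthTable(prot$abundance)
  parents <- protTr$true_class[match(planted$parent_protein,
                                     protTr$feature_id)]
  expect_true(all(parents == "null"))   # site-driven => null parent
  # filter-fated truth: psm-based fate is exact by construction (the
  # cv-based part is recorded from the generating CV, not the empirical one)
  ev <- aggregateEvidence(phos$peptides, groupBy = "phosphopeptide_id")
  expect_true(all(tr$filter_fated[ev$total_psm < 2]))
  expect_gt(sum(tr$filter_fated), 0)
})

test_that("an empty phospho config returns empty tables without error", {
  prot <- simulateProteome(simulationConfig(nFeatures = 50, seed = 1))
  phos <- simulatePhospho(simulationConfig(nFeatures = 1, seed = 1),
                          truthTable(prot$abundance)[0, ])
  expect_equal(nrow(truthTable(phos$abundance)), 0)
  expect_equal(nrow(phos$peptides), 0)
})

test_that("region matrix plants anti-correlated pairs reproducibly", {
  regions <- c("CT", "IT", "LE", "MVP", "PAN")
  m <- simulateRegionMatrix(regions, 50,
                            list(c("gene001", "gene002")), seed = 9)
  expect_equal(dim(m), c(50, 5))
  z1 <- zscore(m["gene001", ])$z
  z2 <- zscore(m["gene002", ])$z
  expect_lt(cor(z1, z2), 0)
  expect_identical(m, simulateRegionMatrix(regions, 50,
                                           list(c("gene001", "gene002")),
                                           seed = 9))
  expect_error(simulateRegionMatrix(c("CT", "CT"), 5), "duplicate")
  expect_error(simulateRegionMatrix("CT", 5), "at least 2")
})
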