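test_that("paired regression reproduces hand-computed OLS", {
  # Sxy = 9.5, Sxx = 5 -> slope 1.9, intercept -0.6, s = sqrt(2.7/2)
  m <- fitPairedRegression(c(0, 1, 2, 3), c(0, 1, 2, 6))
  expect_equal(m@beta1, 1.9)
  expect_equal(m@beta0, -0.6)
  expect_equal(m@sigma, sqrt(1.35), tolerance = 1e-12)
  # identity and exact shift have zero residual SD
  x <- c(1, 2, 4, 8)
  expect_warning(mi <- fitPairedRegression(x, x), "zero residual")
  expect_equal(c(mi@beta1, mi@beta0, mi@sigma), c(1, 0, 0))
  expect_warning(ms <- fitPairedRegression(c(0, 1, 2), c(1, 2, 3)),
                 "zero residual")
  expect_equal(c(ms@beta1, ms@beta0), c(1, 1))
  expect_error(fitPairedRegression(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(fitPairedRegression(1:4, 1:3), "same length")
  expect_error(fitPairedRegression(1:2, 1:2), "at least 3")
})

test_that("prediction interval matches the closed form and predict.lm", {
  m <- fitPairedRegression(c(0, 1, 2, 3), c(0, 1, 2, 6))
  pi <- predictionInterval(m, 1.5)
  expect_equal(pi$y_predicted, 2.25)
  # half-width = t(0.975, 2) * s * sqrt(1 + 1/4 + 0) = 5.589...
  hw <- qt(0.975, 2) * sqrt(1.35) * sqrt(1.25)
  expect_equal(pi$pi_upper - pi$y_predicted, hw, tolerance = 1e-12)
  expect_equal(pi$pi_upper - pi$y_predicted, 5.589, tolerance = 1e-3)
  # oracle equivalence across random models and query points
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(50, 5, 2)
    y <- 0.3 + 0.9 * x + rnorm(50, 0, 0.5)
    x0 <- rnorm(10, 5, 3)
    m2 <- fitPairedRegression(x, y)
    expect_equal(predictionInterval(m2, x0), predictLmOracle(x, y, x0),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # half-width is minimal at x0 = xbar
  hw0 <- with(predictionInterval(m, m@xbar), pi_upper - y_predicted)
  hwAway <- with(predictionInterval(m, m@xbar + c(-3, -1, 1, 3)),
                 pi_upper - y_predicted)
  expect_true(all(hwAway >= hw0))
})

test_that("a zero-residual model collapses the PI onto the prediction", {
  x <- c(1, 2, 4, 8)
  expect_warning(m <- fitPairedRegression(x, 2 * x + 1))
  pi <- predictionInterval(m, 3)
  expect_equal(pi$pi_lower, pi$y_predicted)
  expect_equal(pi$pi_upper, pi$y_predicted)
})

test_that("PI z-score hits -2/+2 at the band edges and 0 at the center", {
  z <- piZscore(y_predicted = 5, pi_upper = 7, y_test = 7)
  expect_equal(z$zscore, -2)           # on the upper bound
  expect_equal(piZscore(5, 7, 3)$zscore, 2)   # on the lower bound
  expect_equal(piZscore(5, 7, 5)$zscore, 0)
  expect_equal(piZscore(5, 7, 7)$sd, 1)
  # degenerate sd
  expect_equal(piZscore(5, 5, 5)$zscore, 0)
  expect_equal(piZscore(5, 5, 9)$zscore, -Inf)
  expect_equal(piZscore(5, 5, 1)$zscore, Inf)
})

test_that("the call rule requires both the PI excursion and the fold gate", {
  rec <- data.frame(
    y_test = c(9.0, 6.4, 1.0, 5.0),
    pi_lower = c(4, 4, 2, 4),
    pi_upper = c(8, 6, 6, 8),
    delta = c(2.0, 0.5, -2.0, 0.0))
  out <- callDifferential(rec, threshold = 1)
  expect_equal(out$call, c("up", "unchanged", "down", "unchanged"))
  expect_error(callDifferential(rec, -1), "nonnegative")
  # raising the threshold never increases the number of calls
  d <- log2cpmPair(simulationConfig(nFeatures = 2000, seed = 13,
                                    librarySize = 2e6))
  nCalls <- vapply(c(0, 0.5, 1, 2, 4), function(th)
    sum(piCalls(piDifferential(d$x, d$y, threshold = th)) != "unchanged"),
    numeric(1))
  expect_true(all(diff(nCalls) <= 0))
})

test_that("swapping arms maps up-calls to down-calls on noise-free data", {
  cfg <- simulationConfig(nFeatures = 1500, noiseSD = 0, effectLog2FC = 3,
                          seed = 21, librarySize = 5e6)
  d <- log2cpmPair(cfg)
  fwd <- piCalls(piDifferential(d$x, d$y))
  rev <- piCalls(piDifferential(setNames(d$y, names(d$x)), d$x))
  expect_true(all(rev[names(fwd)[fwd == "up"]] == "down"))
  expect_true(all(rev[names(fwd)[fwd == "down"]] == "up"))
  expect_equal(sum(fwd == "up"), sum(rev == "down"))
  expect_equal(sum(fwd == "down"), sum(rev == "up"))
})

test_that("planted RNA effects are recovered with high sensitivity", {
  cfg <- simulationConfig(nFeatures = 5000, fracUp = 0.02,
                          fracDown = 0.02, effectLog2FC = 2,
                          noiseSD = 0.2, seed = 7)
  d <- log2cpmPair(cfg)
  res <- piDifferential(d$x, d$y, modality = "transcript")
  met <- recoveryMetrics(piCalls(res), truthTable(d$sim))
  expect_gte(met$sensitivity, 0.9)
  expect_lte(met$fdp, 0.1)
})

test_that("duplicate consensus keeps only direction-concordant calls", {
  c1 <- c(a = "up", b = "up", c = "down", d = "up", e = "unchanged")
  c2 <- c(a = "up", b = "down", c = "down", e = "unchanged", f = "up")
  cons <- concordantDuplicateCalls(c1, c2)
  expect_equal(cons[["a"]], "up")
  expect_equal(cons[["b"]], "unchanged")   # discordant
  expect_equal(cons[["c"]], "down")
  expect_equal(cons[["d"]], "unchanged")   # absent from replicate 2
  expect_equal(cons[["f"]], "unchanged")   # absent from replicate 1
  expect_setequal(names(cons), union(names(c1), names(c2)))
})

test_that("replicate analysis of a proteome pairs channels in order", {
  prot <- simulateProteome(simulationConfig(nFeatures = 800, seed = 5))
  lmat <- log2(columnMeanNormalize(
    SummarizedExperiment::assay(prot$abundance)))
  out <- piDifferentialReplicates(lmat)
  expect_length(out$replicates, 2)
  expect_equal(colnames(out$delta), c("rep1", "rep2"))
  met <- recoveryMetrics(out$consensus, truthTable(prot$abundance))
  expect_gte(met$sensitivity, 0.85)
  expect_error(piDifferentialReplicates(lmat[, 1:3]), "even number")
})
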