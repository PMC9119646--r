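# Independent oracles used across tests. Each is coded as an explicit
# walk/closed form, separate from the package's vectorized paths.

# brute-force running-sum ssGSEA: accumulate weighted hit ECDF minus
# uniform miss ECDF one position at a time
ssgseaOracle <- function(values, geneSet, alpha = 0) {
  ord <- order(-values, names(values))
  ranked <- names(values)[ord]
  N <- length(ranked)
  inSet <- ranked %in% geneSet
  sumW <- 0
  for (i in seq_len(N)) if (inSet[i]) sumW <- sumW + (N - i + 1)^alpha
  nOut <- N - sum(inSet)
  es <- 0; hit <- 0; miss <- 0
  for (i in seq_len(N)) {
    if (inSet[i]) hit <- hit + (N - i + 1)^alpha / sumW
    else if (nOut > 0) miss <- miss + 1 / nOut
    es <- es + (hit - miss)
  }
  es
}

# reference prediction interval through stats::lm / predict
predictLmOracle <- function(x, y, x0, level = 0.95) {
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  p <- predict(fit, newdata = data.frame(x = x0),
               interval = "prediction", level = level)
  data.frame(pi_lower = p[, "lwr"], y_predicted = p[, "fit"],
             pi_upper = p[, "upr"])
}

# small log2 matrix of a simulated RNA pair under the given config
log2cpmPair <- function(cfg) {
  sim <- simulatePairedCounts(cfg)
  lc <- log2Pseudocount(cpmNormalize(SummarizedExperiment::assay(sim)))
  list(sim = sim, x = setNames(lc[, "control"], rownames(lc)),
       y = lc[, "test"])
}

# recovery metrics of a call vector against a truth table
recoveryMetrics <- function(calls, truth) {
  planted <- truth$true_class != "null"
  correct <- calls[truth$feature_id] == truth$true_class
  tp <- sum(planted & correct)
  called <- sum(calls != "unchanged")
  list(sensitivity = tp / sum(planted),
       fdp = if (called > 0) (called - tp) / called else 0,
       n_called = called)
}
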