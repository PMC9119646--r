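#' Configuration for the synthetic paired-omics generator
#'
#' Holds every tunable of the simulator: the number of features, the
#' fractions of planted up/down features, the planted log2 effect size,
#' the baseline abundance distribution on the log2 scale, multiplicative
#' technical noise, sequencing depth (RNA only), the number of labeled
#' replicate channel pairs (proteome/phosphoproteome), peptide-evidence
#' distributions and reporter-intensity CV structure, and the seed.
#'
#' Defaults describe a knockdown-versus-control design: a minority of
#' features planted at a 4-fold (log2 effect 2) change, 30 million reads
#' per RNA library, two iTRAQ replicate channel pairs, and log-normal
#' reporter noise with SD 0.2 on the log2 scale.
#'
#' @slot nFeatures number of features to simulate.
#' @slot fracUp,fracDown proportions of features planted up/down;
#'   their sum must be < 1.
#' @slot effectLog2FC planted absolute log2 fold change (> 0).
#' @slot baselineLog2Mean,baselineLog2SD mean and SD of the per-feature
#'   baseline on the log2 scale (log-normal baseline).
#' @slot noiseSD technical noise SD on the log2 scale (>= 0).
#' @slot librarySize total counts per RNA library.
#' @slot nReplicatePairs number of (control, test) channel pairs for
#'   proteome/phosphoproteome simulation (>= 1).
#' @slot nbSize optional negative-binomial size for over-dispersed RNA
#'   counts; length-0 numeric (the default) means Poisson.
#' @slot fracSinglePeptide fraction of proteins simulated with a single
#'   unique peptide carrying one PSM (exercises the transcript rescue rule).
#' @slot peptideGeomProb success probability of the shifted-geometric
#'   unique-peptide count distribution.
#' @slot psmLambda rate of the shifted-Poisson per-peptide PSM count.
#' @slot fracSiteDriver fraction of planted phosphopeptide effects that are
#'   site-driven (parent protein unchanged) rather than abundance-driven.
#' @slot cvMean,cvSD location/spread (percent) of the per-feature
#'   reporter-intensity CV distribution; values are drawn as
#'   |Normal(cvMean, cvSD)| so a configurable tail exceeds the 40% filter.
#' @slot seed integer seed; identical config + seed gives identical tables.
#'
#' @seealso [simulationConfig()] for the user-facing constructor.
#' @export
setClass("SimulationConfig",
  representation(
    nFeatures = "integer",
    fracUp = "numeric",
    fracDown = "numeric",
    effectLog2FC = "numeric",
    baselineLog2Mean = "numeric",
    baselineLog2SD = "numeric",
    noiseSD = "numeric",
    librarySize = "numeric",
    nReplicatePairs = "integer",
    nbSize = "numeric",
    fracSinglePeptide = "numeric",
    peptideGeomProb = "numeric",
    psmLambda = "numeric",
    fracSiteDriver = "numeric",
    cvMean = "numeric",
    cvSD = "numeric",
    seed = "integer"
  ),
  prototype(
    nFeatures = 5000L,
    fracUp = 0.02,
    fracDown = 0.02,
    effectLog2FC = 2,
    baselineLog2Mean = 5,
    baselineLog2SD = 2,
    noiseSD = 0.2,
    librarySize = 3e7,
    nReplicatePairs = 2L,
    nbSize = numeric(0),
    fracSinglePeptide = 0.2,
    peptideGeomProb = 0.5,
    psmLambda = 2,
    fracSiteDriver = 0.5,
    cvMean = 15,
    cvSD = 10,
    seed = 42L
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (length(object@nFeatures) != 1L || is.na(object@nFeatures) ||
      object@nFeatures < 1L)
    msg <- c(msg, "nFeatures must be a positive integer")
  if (object@fracUp < 0 || object@fracDown < 0 ||
      object@fracUp + object@fracDown >= 1)
    msg <- c(msg, "fracUp + fracDown must be in [0, 1)")
  if (object@effectLog2FC <= 0)
    msg <- c(msg, "effectLog2FC must be > 0")
  if (object@noiseSD < 0)
    msg <- c(msg, "noiseSD must be >= 0")
  if (object@librarySize <= 0)
    msg <- c(msg, "librarySize must be positive")
  if (object@nReplicatePairs < 1L)
    msg <- c(msg, "nReplicatePairs must be >= 1")
  if (length(object@nbSize) > 0 && any(object@nbSize <= 0))
    msg <- c(msg, "nbSize, when set, must be positive")
  for (p in c("fracSinglePeptide", "fracSiteDriver")) {
    v <- slot(object, p)
    if (v < 0 || v > 1) msg <- c(msg, paste(p, "must be in [0, 1]"))
  }
  if (object@peptideGeomProb <= 0 || object@peptideGeomProb > 1)
    msg <- c(msg, "peptideGeomProb must be in (0, 1]")
  if (object@psmLambda < 0)
    msg <- c(msg, "psmLambda must be >= 0")
  if (object@cvMean < 0 || object@cvSD < 0)
    msg <- c(msg, "cvMean and cvSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param nFeatures number of features.
#' @param fracUp,fracDown fractions of features planted up/down.
#' @param effectLog2FC planted absolute log2 fold change.
#' @param baselineLog2Mean,baselineLog2SD baseline log2 abundance
#'   distribution.
#' @param noiseSD technical noise SD on the log2 scale.
#' @param librarySize total RNA counts per library.
#' @param nReplicatePairs number of (control, test) channel pairs.
#' @param nbSize optional negative-binomial size (omit for Poisson counts).
#' @param fracSinglePeptide fraction of single-peptide/1-PSM proteins.
#' @param peptideGeomProb geometric parameter for unique-peptide counts.
#' @param psmLambda Poisson rate for extra PSMs per peptide.
#' @param fracSiteDriver fraction of planted phospho effects that are
#'   site-driven.
#' @param cvMean,cvSD reporter-intensity CV distribution (percent).
#' @param seed integer seed.
#'
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nFeatures = 100, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nFeatures = 5000, fracUp = 0.02,
                             fracDown = 0.02, effectLog2FC = 2,
                             baselineLog2Mean = 5, baselineLog2SD = 2,
                             noiseSD = 0.2, librarySize = 3e7,
                             nReplicatePairs = 2, nbSize = numeric(0),
                             fracSinglePeptide = 0.2,
                             peptideGeomProb = 0.5, psmLambda = 2,
                             fracSiteDriver = 0.5, cvMean = 15, cvSD = 10,
                             seed = 42) {
  new("SimulationConfig",
      nFeatures = as.integer(nFeatures), fracUp = fracUp,
      fracDown = fracDown, effectLog2FC = effectLog2FC,
      baselineLog2Mean = baselineLog2Mean,
      baselineLog2SD = baselineLog2SD, noiseSD = noiseSD,
      librarySize = librarySize,
      nReplicatePairs = as.integer(nReplicatePairs), nbSize = nbSize,
      fracSinglePeptide = fracSinglePeptide,
      peptideGeomProb = peptideGeomProb, psmLambda = psmLambda,
      fracSiteDriver = fracSiteDriver, cvMean = cvMean, cvSD = cvSD,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  features:", object@nFeatures,
      sprintf("(%.1f%% up, %.1f%% down at |log2FC| = %g)",
              100 * object@fracUp, 100 * object@fracDown,
              object@effectLog2FC), "\n")
  cat("  baseline log2 ~ N(", object@baselineLog2Mean, ", ",
      object@baselineLog2SD, "); noise SD ", object@noiseSD, "\n", sep = "")
  cat("  library size:", format(object@librarySize, big.mark = ","),
      "| replicate pairs:", object@nReplicatePairs, "\n")
  cat("  seed:", object@seed, "\n")
  invisible(NULL)
})

#' Per-pair simple linear regression model
#'
#' Summary of the ordinary least-squares fit of the test-arm log2 values
#' on the control-arm log2 values across features; carries the sufficient
#' statistics needed for closed-form prediction intervals.
#'
#' @slot beta0,beta1 intercept and slope.
#' @slot n number of features fitted (>= 3).
#' @slot xbar mean of the control values.
#' @slot sxx centered sum of squares of the control values (> 0).
#' @slot sigma residual standard deviation, divisor n - 2 (>= 0).
#' @slot level prediction level, default 0.95.
#' @export
setClass("RegressionModel",
  representation(beta0 = "numeric", beta1 = "numeric", n = "integer",
                 xbar = "numeric", sxx = "numeric", sigma = "numeric",
                 level = "numeric"),
  prototype(level = 0.95))

setValidity("RegressionModel", function(object) {
  msg <- character(0)
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (object@sxx <= 0) msg <- c(msg, "Sxx must be > 0")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegressionModel", function(object) {
  cat("RegressionModel (test ~ control, per-feature OLS)\n")
  cat(sprintf("  y = %.4f + %.4f x  on n = %d features\n",
              object@beta0, object@beta1, object@n))
  cat(sprintf("  residual SD s = %.4f (df = %d); level = %g\n",
              object@sigma, object@n - 2L, object@level))
  invisible(NULL)
})

#' Prediction-interval differential result
#'
#' One row per feature with the fitted prediction, 95% PI bounds, the
#' observed log2 difference (delta), the PI-derived SD and z-score, and
#' the up/down/unchanged call under the joint PI + fold-change rule.
#'
#' @slot records a [S4Vectors::DataFrame] with columns `feature_id`,
#'   `x_control`, `y_test`, `y_predicted`, `pi_lower`, `pi_upper`,
#'   `delta`, `sd`, `zscore`, `abs_zscore`, `call`.
#' @slot model the fitted [RegressionModel-class].
#' @slot threshold log2 fold-change threshold of the call rule.
#' @slot modality one of `"transcript"`, `"protein"`, `"phosphopeptide"`.
#' @export
setClass("PIDifferentialResult",
  representation(records = "DataFrame", model = "RegressionModel",
                 threshold = "numeric", modality = "character"))

setValidity("PIDifferentialResult", function(object) {
  need <- c("feature_id", "x_control", "y_test", "y_predicted",
            "pi_lower", "pi_upper", "delta", "sd", "zscore",
            "abs_zscore", "call")
  missing <- setdiff(need, colnames(object@records))
  msg <- character(0)
  if (length(missing))
    msg <- c(msg, paste("records lacks columns:",
                        paste(missing, collapse = ", ")))
  if (length(object@threshold) != 1L || object@threshold < 0)
    msg <- c(msg, "threshold must be a single nonnegative number")
  if (!object@modality %in% c("transcript", "protein", "phosphopeptide"))
    msg <- c(msg, "modality must be transcript/protein/phosphopeptide")
  if (!length(msg)) {
    r <- object@records
    bad <- r$pi_lower > r$y_predicted + 1e-9 |
      r$y_predicted > r$pi_upper + 1e-9
    if (any(bad))
      msg <- c(msg, "pi_lower <= y_predicted <= pi_upper violated")
    if (!all(r$call %in% c("up", "down", "unchanged")))
      msg <- c(msg, "call must be up/down/unchanged")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PIDifferentialResult", function(object) {
  tab <- table(factor(object@records$call,
                      levels = c("up", "down", "unchanged")))
  cat("PIDifferentialResult |", object@modality, "\n")
  cat(sprintf("  %d features; threshold |delta| > %g at %g%% PI\n",
              nrow(object@records), object@threshold,
              100 * object@model@level))
  cat(sprintf("  calls: %d up, %d down, %d unchanged\n",
              tab[["up"]], tab[["down"]], tab[["unchanged"]]))
  invisible(NULL)
})
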