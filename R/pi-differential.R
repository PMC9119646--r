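#' Fit the per-pair regression of test on control log2 values
#'
#' Across all features of one (control, test) pair, fits ordinary least
#' squares `y = beta0 + beta1 * x` where `x` is the control-arm log2
#' value and `y` the test-arm log2 value of each feature. The scatter of
#' features about this line provides the residual scale used by the
#' prediction intervals; the residual SD uses divisor n - 2.
#'
#' @param x control-arm log2 values, one per feature.
#' @param y test-arm log2 values, same length and order.
#' @param level prediction level for downstream intervals (default 0.95).
#' @return a [RegressionModel-class].
#' @examples
#' m <- fitPairedRegression(c(0, 1, 2, 3), c(0, 1, 2, 6))
#' m   # slope 1.9, intercept -0.6
#' @export
fitPairedRegression <- function(x, y, level = 0.95) {
  if (length(x) != length(y))
    stop("x and y must have the same length")
  if (length(x) < 3L)
    stop("at least 3 features are required to fit the regression")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  n <- length(x)
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0) stop("control values are constant; regression undefined")
  beta1 <- sum((x - xbar) * (y - mean(y))) / sxx
  beta0 <- mean(y) - beta1 * xbar
  rss <- sum((y - beta0 - beta1 * x)^2)
  s <- sqrt(max(rss, 0) / (n - 2L))
  if (s == 0)
    warning("zero residual SD: prediction intervals are degenerate")
  new("RegressionModel", beta0 = beta0, beta1 = beta1, n = as.integer(n),
      xbar = xbar, sxx = sxx, sigma = s, level = level)
}

#' Prediction interval for a new observation
#'
#' Closed-form prediction interval of the simple linear regression: at a
#' control value `x0`, the predicted test value is
#' `yhat = beta0 + beta1 * x0` and the half-width is
#' `t(1 - (1 - level)/2, n - 2) * s * sqrt(1 + 1/n + (x0 - xbar)^2 / Sxx)`.
#' Unlike a confidence interval for the mean, this interval covers a
#' single new observation, which is what a one-pair design tests.
#'
#' @param model a [RegressionModel-class].
#' @param x0 numeric vector of control values.
#' @return data.frame with columns `pi_lower`, `y_predicted`, `pi_upper`,
#'   one row per element of `x0`.
#' @examples
#' m <- fitPairedRegression(c(0, 1, 2, 3), c(0, 1, 2, 6))
#' predictionInterval(m, 1.5)
#' @export
predictionInterval <- function(model, x0) {
  stopifnot(is(model, "RegressionModel"))
  yhat <- model@beta0 + model@beta1 * x0
  tq <- qt(1 - (1 - model@level) / 2, df = model@n - 2L)
  hw <- tq * model@sigma *
    sqrt(1 + 1 / model@n + (x0 - model@xbar)^2 / model@sxx)
  data.frame(pi_lower = yhat - hw, y_predicted = yhat,
             pi_upper = yhat + hw)
}

#' PI-derived per-feature z-score
#'
#' The 95% prediction band spans roughly +/- 2 SD, so the implied SD is
#' `|pi_upper - y_predicted| / 2` and the z-score is
#' `(y_predicted - y_test) / sd`. Note the orientation: an up-regulated
#' feature (test above prediction) gets a negative z; `abs_zscore` is
#' also returned for ranking. A feature sitting exactly on the upper PI
#' bound has z = -2, on the lower bound z = +2.
#'
#' @param y_predicted,pi_upper,y_test numeric vectors of equal length.
#' @return data.frame with columns `sd`, `zscore`, `abs_zscore`. Where
#'   `sd` is 0, the z-score is 0 if the observation equals the prediction
#'   and +/- Inf otherwise.
#' @export
piZscore <- function(y_predicted, pi_upper, y_test) {
  sdv <- abs(pi_upper - y_predicted) / 2
  z <- ifelse(sdv > 0,
              (y_predicted - y_test) / sdv,
              ifelse(y_test == y_predicted, 0,
                     sign(y_predicted - y_test) * Inf))
  data.frame(sd = sdv, zscore = z, abs_zscore = abs(z))
}

#' Joint PI + fold-change differential call
#'
#' A feature is called `up` iff its test value exceeds the upper PI bound
#' AND its log2 difference exceeds `threshold`; `down` iff the test value
#' is below the lower PI bound AND the difference is below `-threshold`;
#' otherwise `unchanged`. The two gates are both required: a feature far
#' outside the PI but with |delta| below the threshold stays unchanged.
#'
#' @param records data.frame with columns `y_test`, `pi_lower`,
#'   `pi_upper`, `delta`.
#' @param threshold nonnegative log2 fold-change threshold (1 for RNA,
#'   0.58 = log2(1.5) rounded for proteins/phosphopeptides).
#' @return `records` with a `call` column added.
#' @export
callDifferential <- function(records, threshold) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0)
    stop("threshold must be a single nonnegative number")
  up <- records$y_test > records$pi_upper & records$delta > threshold
  down <- records$y_test < records$pi_lower & records$delta < -threshold
  records$call <- ifelse(up, "up", ifelse(down, "down", "unchanged"))
  records
}

#' Default log2 thresholds of the call rule
#'
#' RNA uses a two-fold rule (log2 threshold 1); proteins and
#' phosphopeptides use a 1.5-fold rule, whose log2 is conventionally
#' printed as 0.58.
#'
#' @param modality `"transcript"`, `"protein"` or `"phosphopeptide"`.
#' @return the log2 threshold.
#' @export
defaultThreshold <- function(modality = c("transcript", "protein",
                                          "phosphopeptide")) {
  modality <- match.arg(modality)
  if (modality == "transcript") 1 else round(log2(1.5), 2)
}

#' Differential analysis of one control/test pair
#'
#' End-to-end PI differential analysis of a single pair of log2 vectors:
#' fits the across-feature regression, computes per-feature prediction
#' intervals at the control values, derives delta, PI-based SD and
#' z-score, and applies the joint call rule.
#'
#' @param x named control-arm log2 values (names are feature ids).
#' @param y test-arm log2 values in the same order.
#' @param threshold log2 fold-change threshold; defaults to the modality
#'   convention via [defaultThreshold()].
#' @param level prediction level (default 0.95).
#' @param modality one of `"transcript"`, `"protein"`,
#'   `"phosphopeptide"`.
#' @return a [PIDifferentialResult-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(500, 6, 2)
#' y <- x + rnorm(500, 0, 0.2)
#' y[1:5] <- x[1:5] + 2.5          # planted up
#' names(x) <- sprintf("g%03d", seq_along(x))
#' res <- piDifferential(x, y, modality = "transcript")
#' res
#' @export
piDifferential <- function(x, y, threshold = defaultThreshold(modality),
                           level = 0.95,
                           modality = c("transcript", "protein",
                                        "phosphopeptide")) {
  modality <- match.arg(modality)
  ids <- names(x)
  if (is.null(ids)) ids <- sprintf("feature%05d", seq_along(x))
  model <- fitPairedRegression(x, y, level = level)
  pi <- predictionInterval(model, x)
  zs <- piZscore(pi$y_predicted, pi$pi_upper, y)
  rec <- DataFrame(feature_id = ids, x_control = as.numeric(x),
                   y_test = as.numeric(y),
                   y_predicted = pi$y_predicted, pi_lower = pi$pi_lower,
                   pi_upper = pi$pi_upper, delta = as.numeric(y - x),
                   sd = zs$sd, zscore = zs$zscore,
                   abs_zscore = zs$abs_zscore)
  rec <- DataFrame(callDifferential(as.data.frame(rec), threshold))
  new("PIDifferentialResult", records = rec, model = model,
      threshold = threshold, modality = modality)
}

#' Consensus calls across duplicate replicate pairs
#'
#' The labeled proteome/phosphoproteome design carries two replicate
#' (control, test) channel pairs analyzed separately; a feature is kept
#' as differential only when both replicates agree on the direction.
#' Discordant features, and features detected in only one replicate, are
#' returned as `unchanged`.
#'
#' @param calls1,calls2 named call vectors (`"up"`/`"down"`/`"unchanged"`)
#'   or [PIDifferentialResult-class] objects.
#' @return named character vector over the union of feature ids.
#' @examples
#' concordantDuplicateCalls(c(a = "up", b = "up"),
#'                          c(a = "up", b = "down"))
#' @export
concordantDuplicateCalls <- function(calls1, calls2) {
  if (is(calls1, "PIDifferentialResult")) calls1 <- piCalls(calls1)
  if (is(calls2, "PIDifferentialResult")) calls2 <- piCalls(calls2)
  ids <- union(names(calls1), names(calls2))
  c1 <- calls1[ids]
  c2 <- calls2[ids]
  agree <- !is.na(c1) & !is.na(c2) & c1 == c2 & c1 != "unchanged"
  out <- ifelse(agree, c1, "unchanged")
  setNames(as.character(out), ids)
}

#' PI differential analysis of a multi-channel abundance table
#'
#' Runs the per-pair analysis on each replicate (control, test) channel
#' pair of a normalized log2 abundance matrix and combines the replicate
#' calls into a consensus. Channel columns are taken pairwise in order
#' (ctrl1, test1, ctrl2, test2, ...).
#'
#' @param log2mat numeric matrix of log2 abundances with feature
#'   rownames and 2k columns ordered (control, test) per replicate pair.
#' @param threshold log2 fold-change threshold (default 0.58 rule).
#' @param level prediction level.
#' @param modality `"protein"` or `"phosphopeptide"`.
#' @return list with `replicates` (list of
#'   [PIDifferentialResult-class]), `consensus` (named call vector) and
#'   `delta` (matrix of per-replicate log2 deltas).
#' @export
piDifferentialReplicates <- function(log2mat,
                                     threshold = defaultThreshold("protein"),
                                     level = 0.95,
                                     modality = c("protein",
                                                  "phosphopeptide")) {
  modality <- match.arg(modality)
  log2mat <- as.matrix(log2mat)
  if (ncol(log2mat) %% 2L != 0L)
    stop("expected an even number of channel columns (control, test pairs)")
  k <- ncol(log2mat) / 2L
  reps <- vector("list", k)
  delta <- matrix(NA_real_, nrow(log2mat), k,
                  dimnames = list(rownames(log2mat),
                                  paste0("rep", seq_len(k))))
  for (r in seq_len(k)) {
    x <- setNames(log2mat[, 2L * r - 1L], rownames(log2mat))
    y <- log2mat[, 2L * r]
    reps[[r]] <- piDifferential(x, y, threshold = threshold,
                                level = level, modality = modality)
    delta[, r] <- y - x
  }
  consensus <- piCalls(reps[[1L]])
  if (k > 1L)
    for (r in 2:k)
      consensus <- concordantDuplicateCalls(consensus, piCalls(reps[[r]]))
  list(replicates = reps, consensus = consensus, delta = delta)
}
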