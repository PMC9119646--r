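#' Percentage of wound closure
#'
#' `100 * (A0 - An) / A0` where `A0` is the average wound area at time
#' zero and `An` the average area at hour n (both in pixels; the result
#' is scale-free). Negative values (wound expansion) are allowed with a
#' warning.
#'
#' @param a0 average wound area at 0 hours (> 0).
#' @param an average wound area at hour n (>= 0), vectorized.
#' @return percent closure.
#' @examples
#' woundClosurePercent(100, 30)   # 70
#' @export
woundClosurePercent <- function(a0, an) {
  if (any(a0 <= 0)) stop("A0 must be positive")
  if (any(an < 0)) stop("An must be nonnegative")
  out <- 100 * (a0 - an) / a0
  if (any(out < 0)) warning("negative closure: wound expanded")
  out
}

#' Fold change in invasion
#'
#' Ratio of invading cell counts, test over control.
#'
#' @param nTest invading cells in the test (knockdown) group.
#' @param nControl invading cells in the control group (> 0).
#' @return fold change.
#' @examples
#' invasionFold(200, 100)   # 2
#' @export
invasionFold <- function(nTest, nControl) {
  if (any(nControl <= 0)) stop("control cell count must be positive")
  nTest / nControl
}

#' Relative cytokine spot density
#'
#' Mean pixel density of each cytokine/chemokine spot in the test
#' conditioned medium expressed relative to the control value. Analytes
#' with zero control density yield NA with a warning.
#'
#' @param densityTest,densityControl named numeric vectors over the
#'   same analytes.
#' @return named vector of fold changes.
#' @export
cytokineRelative <- function(densityTest, densityControl) {
  if (!is.null(names(densityTest)) && !is.null(names(densityControl))) {
    if (!setequal(names(densityTest), names(densityControl)))
      stop("analyte lists differ between test and control")
    densityControl <- densityControl[names(densityTest)]
  } else if (length(densityTest) != length(densityControl)) {
    stop("analyte lists differ in length")
  }
  out <- densityTest / densityControl
  zero <- densityControl == 0
  if (any(zero)) {
    warning(sum(zero), " analyte(s) with zero control density set to NA")
    out[zero] <- NA_real_
  }
  out
}

#' Relative expression by the 2^-ddCq method
#'
#' Normalizes the target Cq by the arithmetic mean of the reference-gene
#' Cqs per sample (equivalently, the geometric mean of reference
#' quantities), takes the test-minus-control difference of differences,
#' and returns `2^-ddCq`. Amplification efficiency is fixed at 2.
#'
#' @param cq data.frame or matrix of Cq values, genes in rows (rownames)
#'   and samples in columns.
#' @param target target gene id.
#' @param referenceGenes character vector of reference gene ids.
#' @param testSample,controlSample column names.
#' @return list with `ddcq` and `fold` (= 2^-ddcq).
#' @examples
#' cq <- matrix(c(24, 20, 22, 23, 20, 22), nrow = 3,
#'              dimnames = list(c("T", "r1", "r2"), c("ctrl", "kd")))
#' relativeExpressionDDCq(cq, "T", c("r1", "r2"), "kd", "ctrl")$fold # 2
#' @export
relativeExpressionDDCq <- function(cq, target, referenceGenes,
                                   testSample, controlSample) {
  cq <- as.matrix(cq)
  need <- c(target, referenceGenes)
  if (!all(need %in% rownames(cq)))
    stop("missing Cq rows: ",
         paste(setdiff(need, rownames(cq)), collapse = ", "))
  if (!all(c(testSample, controlSample) %in% colnames(cq)))
    stop("missing sample column(s)")
  vals <- cq[need, c(testSample, controlSample)]
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Cq values must be finite and positive")
  dcq <- function(s) cq[target, s] - mean(cq[referenceGenes, s])
  ddcq <- dcq(testSample) - dcq(controlSample)
  list(ddcq = unname(ddcq), fold = unname(2^(-ddcq)))
}
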