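#' Counts-per-million normalization
#'
#' Scales each column of a raw count matrix to counts per million:
#' `CPM = count / sum(count) * 1e6`, per sample. Columns of the result
#' sum to one million.
#'
#' @param counts numeric matrix of nonnegative counts, features in rows,
#'   samples in columns, or a `SummarizedExperiment` whose first assay is
#'   counts.
#' @return a matrix of the same shape on the CPM scale, with attribute
#'   `scale = "cpm"`.
#' @examples
#' m <- matrix(c(1, 3, 10, 30), ncol = 2,
#'             dimnames = list(c("g1", "g2"), c("a", "b")))
#' cpmNormalize(m)
#' @export
cpmNormalize <- function(counts) {
  if (is(counts, "SummarizedExperiment")) counts <- assay(counts)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  cs <- colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("all-zero count column(s): ", paste(bad, collapse = ", "))
  }
  out <- sweep(counts, 2L, cs, "/") * 1e6
  structure(out, scale = "cpm")
}

#' log2 transform with a pseudocount of one
#'
#' `log2(x + 1)`, elementwise; maps 0 to 0 and is monotone. Applied to
#' CPM values ahead of the regression/PI differential analysis.
#'
#' @param x nonnegative numeric matrix or vector (typically CPM).
#' @return the transformed object with attribute `scale = "log2cpm"`.
#' @examples
#' log2Pseudocount(c(0, 1, 3))   # 0 1 2
#' @export
log2Pseudocount <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- assay(x)
  if (any(x < 0)) stop("log2Pseudocount requires nonnegative input")
  structure(log2(x + 1), scale = "log2cpm")
}

#' Column-mean normalization of reporter-ion abundances
#'
#' Divides every abundance column (iTRAQ channel) by its mean so that
#' each normalized column has mean exactly one; a subsequent plain log2
#' (no pseudocount: abundances are strictly positive) puts channels on a
#' comparable log2 scale.
#'
#' @param a numeric matrix of strictly positive abundances, features in
#'   rows, channels in columns.
#' @return the normalized matrix, attribute `scale = "abundance_norm"`.
#' @examples
#' columnMeanNormalize(matrix(c(2, 4, 6), ncol = 1))
#' @export
columnMeanNormalize <- function(a) {
  if (is(a, "SummarizedExperiment")) a <- assay(a)
  a <- as.matrix(a)
  if (any(a <= 0)) {
    idx <- which(a <= 0, arr.ind = TRUE)[1L, ]
    f <- rownames(a)[idx[1L]] %||% idx[1L]
    ch <- colnames(a)[idx[2L]] %||% idx[2L]
    stop("non-positive abundance for feature ", f, " in channel ", ch)
  }
  structure(sweep(a, 2L, colMeans(a), "/"), scale = "abundance_norm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Standardize a vector (z-score)
#'
#' `z = (X - mean(X)) / sd(X)` with the sample standard deviation
#' (divisor n - 1). Used to put log expression of a gene across samples
#' or anatomic regions on a common scale.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return list with elements `values`, `mean`, `sd`, `z`.
#' @examples
#' zscore(c(1, 2, 3))$z   # -1 0 1
#' @export
zscore <- function(values) {
  if (length(values) < 2L) stop("zscore needs at least two values")
  mu <- mean(values)
  sigma <- sd(values)
  if (!is.finite(sigma) || sigma == 0)
    stop("zscore undefined for a constant vector (sd = 0)")
  list(values = values, mean = mu, sd = sigma, z = (values - mu) / sigma)
}

#' Row-wise z-scoring of an expression matrix
#'
#' Standardizes each feature (row) across samples/regions; rows with zero
#' variance are returned as NA with a warning rather than an error so a
#' whole matrix can be processed.
#'
#' @param x numeric matrix, features in rows.
#' @return matrix of z-scores, attribute `scale = "zscore"`.
#' @export
zscoreRows <- function(x) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  sigma <- apply(x, 1L, sd)
  flat <- sigma == 0 | !is.finite(sigma)
  if (any(flat)) {
    warning(sum(flat), " constant row(s) z-scored to NA")
    sigma[flat] <- NA_real_
  }
  structure((x - mu) / sigma, scale = "zscore")
}
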