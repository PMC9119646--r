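#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Duplicate members are dropped with a warning.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of member gene ids.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    members <- f[-c(1L, 2L)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1L], "' deduplicated")
      members <- unique(members)
    }
    sets[[f[1L]]] <- members
  }
  sets
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Ranks the genes of one sample by decreasing value (ties broken by
#' lexicographic gene id, stably) and walks the ranking accumulating the
#' difference between the weighted in-set ECDF and the uniform
#' out-of-set ECDF; the enrichment score is the sum of that difference
#' over all positions. In-set genes at ranking position i (1 = highest)
#' carry weight `(N - i + 1)^alpha`, normalized to sum to one over the
#' set; weights come from ranks, not raw expression, for numerical
#' stability. With `alpha = 0` the score depends on ranks only and is
#' invariant under strictly monotone transforms of the values.
#'
#' @param values named numeric vector: one sample's expression (or a
#'   differential profile such as log2 deltas).
#' @param geneSet character vector of member gene ids.
#' @param alpha weighting exponent (default 0.25).
#' @return list with `es`, `alpha`, `n_genes`, `n_set_found`,
#'   `n_set_missing`.
#' @examples
#' v <- c(g1 = 4, g2 = 3, g3 = 2, g4 = 1)
#' ssgseaScore(v, "g1", alpha = 0)$es   # 2
#' @export
ssgseaScore <- function(values, geneSet, alpha = 0.25) {
  if (is.null(names(values))) stop("values must be a named vector")
  geneSet <- unique(geneSet)
  nMissing <- sum(!geneSet %in% names(values))
  ord <- order(-values, names(values))
  ranked <- names(values)[ord]
  inSet <- ranked %in% geneSet
  if (!any(inSet))
    stop("no gene of the set is present in the ranking")
  N <- length(ranked)
  w <- (N - seq_len(N) + 1)^alpha
  pHit <- cumsum(ifelse(inSet, w, 0)) / sum(w[inSet])
  nOut <- N - sum(inSet)
  pMiss <- if (nOut > 0) cumsum(!inSet) / nOut else rep(0, N)
  list(es = sum(pHit - pMiss), alpha = alpha, n_genes = N,
       n_set_found = sum(inSet), n_set_missing = nMissing)
}

#' Score a matrix of samples against a list of gene sets
#'
#' @param expr numeric matrix, genes in rows, samples in columns (or a
#'   `SummarizedExperiment`).
#' @param geneSets named list of character vectors (e.g. from
#'   [readGmt()]).
#' @param alpha weighting exponent.
#' @return data.frame with columns `sample_id`, `set_name`, `es`,
#'   `n_set_found`.
#' @export
ssgseaMatrix <- function(expr, geneSets, alpha = 0.25) {
  if (is(expr, "SummarizedExperiment")) expr <- assay(expr)
  expr <- as.matrix(expr)
  out <- expand.grid(sample_id = colnames(expr) %||%
                       as.character(seq_len(ncol(expr))),
                     set_name = names(geneSets),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(s, g) {
    v <- setNames(expr[, s], rownames(expr))
    sc <- ssgseaScore(v, geneSets[[g]], alpha = alpha)
    c(sc$es, sc$n_set_found)
  }, out$sample_id, out$set_name)
  out$es <- res[1L, ]
  out$n_set_found <- as.integer(res[2L, ])
  out
}

#' Mesenchymal-versus-proneural signature contrast of one profile
#'
#' Scores one expression or differential profile against a mesenchymal
#' and a proneural signature and reports both enrichment scores plus
#' their difference; a knockdown shifting cells toward the mesenchymal
#' state shows `es_mes > es_pn`.
#'
#' @param values named numeric profile (expression or log2 deltas).
#' @param mesSet,pnSet character vectors of signature genes.
#' @param alpha weighting exponent.
#' @return list with `es_mes`, `es_pn`, `contrast` (= es_mes - es_pn).
#' @export
signatureContrast <- function(values, mesSet, pnSet, alpha = 0.25) {
  mes <- ssgseaScore(values, mesSet, alpha = alpha)
  pn <- ssgseaScore(values, pnSet, alpha = alpha)
  list(es_mes = mes$es, es_pn = pn$es, contrast = mes$es - pn$es)
}
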