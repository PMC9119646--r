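#' Classify phosphopeptide changes as site- or abundance-driven
#'
#' A differential phosphopeptide can reflect either a genuine change in
#' site phosphorylation or a change in the abundance of its parent
#' protein. Cross-referencing the global proteome calls disambiguates:
#' `phosphorylation_driven` when the phosphopeptide is called up/down
#' while the parent protein is detected and unchanged;
#' `abundance_linked` when both are called (the direction match is
#' recorded); `indeterminate` when the parent protein was not detected
#' in the global proteome; `none` when the phosphopeptide itself is
#' unchanged.
#'
#' @param phosphoCalls named call vector (or
#'   [PIDifferentialResult-class]) for phosphopeptides.
#' @param proteinCalls named call vector (or result) for the global
#'   proteome; proteins absent from it count as not detected.
#' @param map named character vector mapping phosphopeptide id ->
#'   parent protein id.
#' @return data.frame with columns `phosphopeptide_id`,
#'   `parent_protein_id`, `phospho_call`, `protein_call`,
#'   `driver_class`, `direction_match`.
#' @examples
#' classifyPhospho(c(p1 = "up"), c(A = "unchanged"), c(p1 = "A"))
#' @export
classifyPhospho <- function(phosphoCalls, proteinCalls, map) {
  if (is(phosphoCalls, "PIDifferentialResult"))
    phosphoCalls <- piCalls(phosphoCalls)
  if (is(proteinCalls, "PIDifferentialResult"))
    proteinCalls <- piCalls(proteinCalls)
  ids <- names(phosphoCalls)
  missing <- setdiff(ids, names(map))
  if (length(missing))
    stop("phosphopeptide(s) without a parent-protein mapping: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  parent <- unname(map[ids])
  pcall <- ifelse(parent %in% names(proteinCalls),
                  unname(proteinCalls[parent]), "not_detected")
  phos <- unname(phosphoCalls)
  driver <- ifelse(phos == "unchanged", "none",
            ifelse(pcall == "unchanged", "phosphorylation_driven",
            ifelse(pcall == "not_detected", "indeterminate",
                   "abundance_linked")))
  data.frame(phosphopeptide_id = ids, parent_protein_id = parent,
             phospho_call = phos, protein_call = pcall,
             driver_class = driver,
             direction_match = driver == "abundance_linked" &
               phos == pcall,
             stringsAsFactors = FALSE)
}

#' Cross-omics correlation of matched log2 deltas
#'
#' Pearson correlation between matched per-feature log2 differences of
#' two modalities (e.g. protein delta vs transcript delta), computed per
#' replicate pair with the arithmetic mean reported as the average r.
#' Vectors are matched by name when both are named.
#'
#' @param deltaA,deltaB numeric vectors or single-modality matrices with
#'   one column per replicate pair; matched by names/rownames when
#'   present.
#' @return list with `r_by_replicate` (numeric vector) and `r_average`.
#' @examples
#' crossOmicsCorrelation(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3.5))
#' @export
crossOmicsCorrelation <- function(deltaA, deltaB) {
  a <- if (is.matrix(deltaA)) deltaA else matrix(deltaA,
         dimnames = list(names(deltaA), NULL))
  b <- if (is.matrix(deltaB)) deltaB else matrix(deltaB,
         dimnames = list(names(deltaB), NULL))
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    common <- intersect(rownames(a), rownames(b))
    a <- a[common, , drop = FALSE]
    b <- b[common, , drop = FALSE]
  } else if (nrow(a) != nrow(b)) {
    stop("unnamed delta vectors must have equal length")
  }
  if (nrow(a) < 3L)
    stop("need at least 3 matched features, got ", nrow(a))
  k <- max(ncol(a), ncol(b))
  r <- vapply(seq_len(k), function(j) {
    x <- a[, min(j, ncol(a))]
    y <- b[, min(j, ncol(b))]
    if (sd(x) == 0 || sd(y) == 0)
      stop("zero variance in replicate ", j)
    cor(x, y)
  }, numeric(1))
  list(r_by_replicate = r, r_average = mean(r))
}
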