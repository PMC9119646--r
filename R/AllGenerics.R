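#' Extract the ground-truth table of a simulated object
#'
#' The synthetic generators record the planted effect class of every
#' feature. For [SummarizedExperiment::SummarizedExperiment] containers
#' the truth lives in `rowData`; this accessor returns it as a base
#' data.frame with a `feature_id` column.
#'
#' @param x a simulated object.
#' @return a data.frame with columns `feature_id`, `true_class`,
#'   `true_log2fc`, and for phosphopeptides additionally `parent_protein`
#'   and `driver`.
#' @examples
#' sim <- simulatePairedCounts(simulationConfig(nFeatures = 50, seed = 1))
#' head(truthTable(sim))
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname truthTable
setMethod("truthTable", "SummarizedExperiment", function(x) {
  rd <- as.data.frame(rowData(x))
  data.frame(feature_id = rownames(x), rd, row.names = NULL,
             stringsAsFactors = FALSE)
})

#' Per-feature call vector of a differential result
#'
#' @param x a [PIDifferentialResult-class].
#' @return named character vector of `"up"`/`"down"`/`"unchanged"`.
#' @export
setGeneric("piCalls", function(x) standardGeneric("piCalls"))

#' @rdname piCalls
setMethod("piCalls", "PIDifferentialResult", function(x) {
  setNames(x@records$call, x@records$feature_id)
})

#' Full record table of a differential result
#'
#' @param x a [PIDifferentialResult-class].
#' @return a data.frame, one row per feature.
#' @export
setGeneric("piRecords", function(x) standardGeneric("piRecords"))

#' @rdname piRecords
setMethod("piRecords", "PIDifferentialResult", function(x) {
  as.data.frame(x@records)
})

#' @rdname piRecords
#' @param row.names,optional,... passed on as in [base::as.data.frame].
#' @export
setMethod("as.data.frame", "PIDifferentialResult",
          function(x, row.names = NULL, optional = FALSE, ...) {
  as.data.frame(x@records, row.names = row.names, optional = optional, ...)
})

#' Fitted regression model of a differential result
#'
#' @param x a [PIDifferentialResult-class].
#' @return the [RegressionModel-class] used for the prediction intervals.
#' @export
setGeneric("piModel", function(x) standardGeneric("piModel"))

#' @rdname piModel
setMethod("piModel", "PIDifferentialResult", function(x) x@model)
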