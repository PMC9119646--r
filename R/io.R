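#' Write a feature-by-sample matrix as TSV
#'
#' Header row `feature_id<TAB>sample...`; one feature per line.
#'
#' @param x numeric matrix with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMatrixTSV <- function(x, path) {
  x <- as.matrix(x)
  df <- data.frame(feature_id = rownames(x) %||%
                     as.character(seq_len(nrow(x))), x,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample TSV matrix
#'
#' @param path TSV with a `feature_id` first column.
#' @return numeric matrix with feature rownames.
#' @export
readMatrixTSV <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "numeric"
  m
}

#' Write a JSON sidecar recording config and seed
#'
#' Records every simulation/analysis parameter next to an output table
#' so a run can be reproduced from its artifacts alone.
#'
#' @param config a [SimulationConfig-class] or a named list.
#' @param path output path (conventionally `<table>.config.json`).
#' @return `path`, invisibly.
#' @export
writeConfigSidecar <- function(config, path) {
  if (is(config, "SimulationConfig")) {
    nm <- slotNames(config)
    config <- setNames(lapply(nm, function(s) slot(config, s)), nm)
    config <- config[lengths(config) > 0]
  }
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
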