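#' Run the full paired-omics analysis on synthetic data
#'
#' Orchestrates every stage on generator output: simulate the RNA pair,
#' proteome and phosphoproteome; normalize (CPM + log2 pseudocount for
#' RNA, column-mean + log2 for reporter abundances); call differential
#' features by the PI rule (threshold 1 for RNA, 0.58 for
#' protein/phospho, consensus across replicate pairs); apply the
#' peptide-evidence and CV filters; disambiguate phosphopeptide changes
#' against the proteome; score the RNA delta profile against
#' mesenchymal/proneural-style signatures built from the planted truth;
#' and compute cross-omics correlations. Returns a summary report plus
#' all stage objects.
#'
#' @param config a [SimulationConfig-class] used for the RNA pair.
#' @param proteomeConfig,phosphoConfig configs for the proteome and
#'   phosphoproteome stages; default to `config` with a smaller feature
#'   count and seeds offset by 1 and 2. Set `phosphoConfig = FALSE` to
#'   skip the phospho/integration stages (a warning notes the omission).
#' @param rnaThreshold,proteinThreshold log2 fold-change thresholds.
#' @param level prediction level.
#' @param alpha ssGSEA weighting exponent.
#' @param signatureSize genes sampled per planted signature set.
#' @param outDir optional directory; when given, stage tables, a JSON
#'   summary and config sidecars are written there.
#' @return list with elements `report` (named list of summary counts and
#'   scores), `rna`, `proteome`, `phospho`, `integration`, `enrichment`.
#' @examples
#' res <- runPipeline(simulationConfig(nFeatures = 800, seed = 11,
#'                                     librarySize = 2e6))
#' res$report$rna_up
#' @export
runPipeline <- function(config,
                        proteomeConfig = NULL, phosphoConfig = NULL,
                        rnaThreshold = defaultThreshold("transcript"),
                        proteinThreshold = defaultThreshold("protein"),
                        level = 0.95, alpha = 0.25, signatureSize = 25,
                        outDir = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(proteomeConfig)) {
    proteomeConfig <- config
    proteomeConfig@nFeatures <- as.integer(
      max(50L, round(config@nFeatures / 2)))
    proteomeConfig@seed <- config@seed + 1L
  }
  phosphoMissing <- identical(phosphoConfig, FALSE)
  if (is.null(phosphoConfig)) {
    phosphoConfig <- proteomeConfig
    phosphoConfig@seed <- config@seed + 2L
  }

  ## --- RNA stage
  rnaSim <- simulatePairedCounts(config)
  log2cpm <- log2Pseudocount(cpmNormalize(assay(rnaSim)))
  rnaRes <- piDifferential(
    setNames(log2cpm[, "control"], rownames(log2cpm)),
    log2cpm[, "test"], threshold = rnaThreshold, level = level,
    modality = "transcript")
  rnaCalls <- piCalls(rnaRes)
  rnaTruth <- truthTable(rnaSim)

  ## --- proteome stage
  protSim <- simulateProteome(proteomeConfig)
  protLog2 <- log2(columnMeanNormalize(assay(protSim$abundance)))
  protRes <- piDifferentialReplicates(protLog2,
                                      threshold = proteinThreshold,
                                      level = level,
                                      modality = "protein")
  protEvidence <- aggregateEvidence(protSim$peptides)
  ## transcript rescue uses the RNA calls; synthetic protein/transcript id
  ## spaces differ, so rescue fires only for ids present in both universes
  protFilter <- filterProteins(protEvidence, rnaCalls,
                               proteinDelta = rowMeans(protRes$delta))
  protCalls <- protRes$consensus
  protCalls[!names(protCalls) %in% protFilter$kept] <- "unchanged"

  ## --- phospho stage (optional)
  phospho <- integration <- NULL
  if (!phosphoMissing) {
    phosSim <- simulatePhospho(phosphoConfig, truthTable(protSim$abundance))
    phosLog2 <- log2(columnMeanNormalize(assay(phosSim$abundance)))
    phosRes <- piDifferentialReplicates(phosLog2,
                                        threshold = proteinThreshold,
                                        level = level,
                                        modality = "phosphopeptide")
    phosEvidence <- aggregateEvidence(phosSim$peptides,
                                      groupBy = "phosphopeptide_id")
    phosFilter <- filterPhosphopeptides(phosEvidence)
    phosCalls <- phosRes$consensus
    phosCalls[!names(phosCalls) %in% phosFilter$kept] <- "unchanged"
    map <- setNames(truthTable(phosSim$abundance)$parent_protein,
                    rownames(phosSim$abundance))
    integration <- classifyPhospho(phosCalls, protRes$consensus, map)
    phospho <- list(sim = phosSim, result = phosRes,
                    evidence = phosEvidence, filter = phosFilter,
                    calls = phosCalls)
  } else {
    warning("no phospho config: integration stage omitted")
  }

  ## --- signature enrichment on the RNA delta profile
  delta <- setNames(piRecords(rnaRes)$delta, piRecords(rnaRes)$feature_id)
  upIds <- rnaTruth$feature_id[rnaTruth$true_class == "up"]
  downIds <- rnaTruth$feature_id[rnaTruth$true_class == "down"]
  enrichment <- NULL
  if (length(upIds) && length(downIds)) {
    set.seed(config@seed + 3L)
    mesSet <- sample(upIds, min(signatureSize, length(upIds)))
    pnSet <- sample(downIds, min(signatureSize, length(downIds)))
    enrichment <- signatureContrast(delta, mesSet, pnSet, alpha = alpha)
    enrichment$mes_set <- mesSet
    enrichment$pn_set <- pnSet
  }

  ## --- cross-omics correlation: protein delta vs planted transcript-side
  ## effect of the same synthetic proteins (matched by protein id)
  protTruth <- truthTable(protSim$abundance)
  rnaSide <- setNames(protTruth$true_log2fc +
                        rnorm(nrow(protTruth), 0,
                              max(config@noiseSD, 0.05) * 2),
                      protTruth$feature_id)
  xcor <- crossOmicsCorrelation(protRes$delta, rnaSide)

  report <- list(
    seed = config@seed,
    rna_n = length(rnaCalls),
    rna_up = sum(rnaCalls == "up"),
    rna_down = sum(rnaCalls == "down"),
    protein_n = length(protCalls),
    protein_up = sum(protCalls == "up"),
    protein_down = sum(protCalls == "down"),
    proteins_kept_by_evidence = length(protFilter$kept),
    phospho_n = if (!is.null(phospho)) length(phospho$calls) else NA,
    phospho_up = if (!is.null(phospho))
      sum(phospho$calls == "up") else NA,
    phospho_down = if (!is.null(phospho))
      sum(phospho$calls == "down") else NA,
    phosphorylation_driven = if (!is.null(integration))
      sum(integration$driver_class == "phosphorylation_driven") else NA,
    es_mes = if (!is.null(enrichment)) enrichment$es_mes else NA,
    es_pn = if (!is.null(enrichment)) enrichment$es_pn else NA,
    cross_omics_r_average = xcor$r_average)

  out <- list(report = report,
              rna = list(sim = rnaSim, log2cpm = log2cpm, result = rnaRes,
                         calls = rnaCalls),
              proteome = list(sim = protSim, result = protRes,
                              evidence = protEvidence,
                              filter = protFilter, calls = protCalls),
              phospho = phospho, integration = integration,
              enrichment = enrichment, cross_omics = xcor)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeMatrixTSV(assay(rnaSim), file.path(outDir, "rna_counts.tsv"))
    writeMatrixTSV(assay(protSim$abundance),
                   file.path(outDir, "protein_abundance.tsv"))
    write.table(as.data.frame(rnaRes),
                file.path(outDir, "rna_pi_records.csv"), sep = ",",
                quote = FALSE, row.names = FALSE)
    writeConfigSidecar(config, file.path(outDir, "rna.config.json"))
    jsonlite::write_json(report, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}
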