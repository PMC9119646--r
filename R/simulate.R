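## Synthetic paired-omics generator. Every generator plants a minority of
## up/down features at a fixed |log2FC|, records the truth in rowData, and
## is bit-reproducible under (config, seed).

.plantClasses <- function(cfg) {
  n <- cfg@nFeatures
  nUp <- round(cfg@fracUp * n)
  nDown <- round(cfg@fracDown * n)
  cls <- rep("null", n)
  if (nUp > 0) cls[seq_len(nUp)] <- "up"
  if (nDown > 0) cls[nUp + seq_len(nDown)] <- "down"
  # shuffle so planted features are not clustered at the top of the table
  cls[sample.int(n)]
}

.truthLog2fc <- function(cls, effect) {
  ifelse(cls == "up", effect, ifelse(cls == "down", -effect, 0))
}

#' Simulate an unreplicated RNA count pair with ground truth
#'
#' Draws a per-feature log-normal baseline, plants up/down effects of
#' `effectLog2FC` on the test arm, adds log-normal technical noise to
#' both arms, scales expected expression to the library size, and draws
#' counts (Poisson by default, negative binomial when `nbSize` is set).
#' Column sums land near `librarySize` per arm.
#'
#' @param config a [SimulationConfig-class] (see [simulationConfig()]).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (columns `control`, `test`), truth columns in `rowData`,
#'   and the config in `metadata`. Retrieve the truth with
#'   [truthTable()].
#' @examples
#' sim <- simulatePairedCounts(simulationConfig(nFeatures = 200, seed = 3))
#' table(truthTable(sim)$true_class)
#' @export
simulatePairedCounts <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nFeatures
  cls <- .plantClasses(config)
  lfc <- .truthLog2fc(cls, config@effectLog2FC)
  base <- rnorm(n, config@baselineLog2Mean, config@baselineLog2SD)
  noiseC <- rnorm(n, 0, config@noiseSD)
  noiseT <- rnorm(n, 0, config@noiseSD)
  exprC <- 2^(base + noiseC)
  exprT <- 2^(base + lfc + noiseT)
  lamC <- exprC / sum(exprC) * config@librarySize
  lamT <- exprT / sum(exprT) * config@librarySize
  if (length(config@nbSize)) {
    cc <- rnbinom(n, mu = lamC, size = config@nbSize)
    ct <- rnbinom(n, mu = lamT, size = config@nbSize)
  } else {
    cc <- rpois(n, lamC)
    ct <- rpois(n, lamT)
  }
  ids <- sprintf("gene%05d", seq_len(n))
  counts <- cbind(control = cc, test = ct)
  rownames(counts) <- ids
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(true_class = cls, true_log2fc = lfc))
  metadata(se)$config <- config
  se
}

.simChannels <- function(cfg, lfc) {
  # log2 abundance per channel: baseline + planted effect (test arms only)
  # + independent log-normal technical noise per channel
  n <- length(lfc)
  base <- rnorm(n, cfg@baselineLog2Mean, cfg@baselineLog2SD)
  k <- cfg@nReplicatePairs
  ab <- matrix(NA_real_, n, 2L * k)
  cn <- character(2L * k)
  for (r in seq_len(k)) {
    ab[, 2L * r - 1L] <- 2^(base + rnorm(n, 0, cfg@noiseSD))
    ab[, 2L * r] <- 2^(base + lfc + rnorm(n, 0, cfg@noiseSD))
    cn[2L * r - 1L] <- paste0("ctrl", r)
    cn[2L * r] <- paste0("test", r)
  }
  colnames(ab) <- cn
  ab
}

.simPeptides <- function(cfg, ids, abund, phospho = FALSE) {
  # peptide-level evidence: unique-peptide counts (shifted geometric),
  # per-peptide PSM counts (shifted Poisson), per-PSM intensities drawn
  # log-normal around the feature abundance at a per-feature CV (percent)
  n <- length(ids)
  single <- rbinom(n, 1L, cfg@fracSinglePeptide) == 1L
  nPep <- ifelse(single, 1L, 1L + rgeom(n, cfg@peptideGeomProb) +
                   (!phospho))          # proteins get >= 2 when not single
  if (phospho) nPep <- rep(1L, n)       # one peptide per phospho feature
  cv <- abs(rnorm(n, cfg@cvMean, cfg@cvSD))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    np <- nPep[i]
    psm <- if (single[i] && !phospho) rep(1L, np)
           else 1L + rpois(np, cfg@psmLambda)
    sdlog <- sqrt(log(1 + (cv[i] / 100)^2))
    pep <- data.frame(
      protein_id = ids[i],
      peptide_sequence = paste0(ids[i], "_pep", seq_len(np)),
      is_unique = TRUE,
      psm_count = psm,
      stringsAsFactors = FALSE)
    pep$intensities <- vapply(psm, function(m)
      paste(signif(rlnorm(m, log(abund[i]) - sdlog^2 / 2, sdlog), 6),
            collapse = ";"), character(1))
    rows[[i]] <- pep
  }
  out <- do.call(rbind, rows)
  attr(out, "planted_single") <- single
  attr(out, "planted_cv") <- cv
  out
}

#' Simulate a labeled proteome with peptide evidence
#'
#' Generates strictly positive reporter-ion abundances for
#' `nReplicatePairs` (control, test) channel pairs with planted up/down
#' proteins, plus a peptide-level evidence table: unique-peptide counts
#' (shifted geometric), PSM counts per peptide (shifted Poisson),
#' semicolon-joined per-PSM intensities, and a configured fraction of
#' single-peptide/1-PSM proteins to exercise the transcript rescue rule.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `abundance` (SummarizedExperiment, assay
#'   `abundance`, truth in `rowData`) and `peptides` (data.frame of
#'   peptide records).
#' @examples
#' sim <- simulateProteome(simulationConfig(nFeatures = 50, seed = 5))
#' colnames(sim$abundance)
#' @export
simulateProteome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  n <- config@nFeatures
  cls <- .plantClasses(config)
  lfc <- .truthLog2fc(cls, config@effectLog2FC)
  ids <- sprintf("prot%05d", seq_len(n))
  ab <- .simChannels(config, lfc)
  rownames(ab) <- ids
  peptides <- .simPeptides(config, ids, rowMeans(ab), phospho = FALSE)
  single <- attr(peptides, "planted_single")
  se <- SummarizedExperiment(
    assays = list(abundance = ab),
    rowData = DataFrame(true_class = cls, true_log2fc = lfc,
                        planted_single_peptide = single))
  metadata(se)$config <- config
  list(abundance = se, peptides = peptides)
}

#' Simulate a phosphoproteome tied to a simulated proteome
#'
#' Each phosphopeptide maps to a parent protein of `proteomeTruth`.
#' Planted differential phosphopeptides are split by `fracSiteDriver`
#' into site-driven (parent protein null: a genuine phosphorylation
#' change) and abundance-driven (parent planted up/down: the
#' phosphopeptide merely follows protein abundance, concordantly).
#' PSM counts and per-PSM intensity CVs are generated so a configurable
#' tail of features fails the >= 2 PSM / < 40% CV evidence filter; the
#' truth table marks those rows `filter_fated`.
#'
#' @param config a [SimulationConfig-class]; `nFeatures` here is the
#'   number of phosphopeptides.
#' @param proteomeTruth truth data.frame from [simulateProteome()] (via
#'   [truthTable()]), supplying parent protein ids and classes.
#' @return list with `abundance` (SummarizedExperiment) and `peptides`
#'   (data.frame with `phosphopeptide_id`, PSM counts, intensities and a
#'   site annotation).
#' @export
simulatePhospho <- function(config, proteomeTruth) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  if (config@nFeatures == 0L ||
      (is.data.frame(proteomeTruth) && nrow(proteomeTruth) == 0L)) {
    empty <- SummarizedExperiment(
      assays = list(abundance = matrix(numeric(0), 0, 0)),
      rowData = DataFrame(true_class = character(0),
                          true_log2fc = numeric(0),
                          parent_protein = character(0),
                          driver = character(0),
                          filter_fated = logical(0)))
    return(list(abundance = empty,
                peptides = data.frame(protein_id = character(0),
                                      phosphopeptide_id = character(0),
                                      psm_count = integer(0),
                                      intensities = character(0),
                                      site = character(0))))
  }
  if (!all(c("feature_id", "true_class") %in% colnames(proteomeTruth)))
    stop("proteomeTruth must carry feature_id and true_class columns")
  set.seed(config@seed + 1L)    # distinct stream from the parent proteome
  n <- config@nFeatures
  cls <- .plantClasses(config)
  nullParents <- proteomeTruth$feature_id[proteomeTruth$true_class == "null"]
  upParents <- proteomeTruth$feature_id[proteomeTruth$true_class == "up"]
  downParents <- proteomeTruth$feature_id[proteomeTruth$true_class == "down"]
  if (!length(nullParents))
    stop("proteomeTruth has no null proteins to host site-driven effects")
  parent <- sample(nullParents, n, replace = TRUE)
  driver <- rep("none", n)
  planted <- which(cls != "null")
  if (length(planted)) {
    site <- rbinom(length(planted), 1L, config@fracSiteDriver) == 1L
    driver[planted] <- ifelse(site, "site", "abundance")
    for (j in seq_along(planted)) {
      i <- planted[j]
      if (!site[j]) {
        # abundance-driven: attach to a concordantly shifted parent
        pool <- if (cls[i] == "up") upParents else downParents
        if (length(pool)) parent[i] <- sample(pool, 1L)
        else driver[i] <- "site"   # no shifted parent available
      }
    }
  }
  lfc <- .truthLog2fc(cls, config@effectLog2FC)
  ids <- sprintf("phos%05d", seq_len(n))
  ab <- .simChannels(config, lfc)
  rownames(ab) <- ids
  pep <- .simPeptides(config, ids, rowMeans(ab), phospho = TRUE)
  cv <- attr(pep, "planted_cv")
  pep$phosphopeptide_id <- ids
  pep$protein_id <- parent
  pep$site <- paste0("S", sample(10:900, n, replace = TRUE))
  fated <- pep$psm_count < 2L | cv >= 40
  se <- SummarizedExperiment(
    assays = list(abundance = ab),
    rowData = DataFrame(true_class = cls, true_log2fc = lfc,
                        parent_protein = parent, driver = driver,
                        filter_fated = fated))
  metadata(se)$config <- config
  list(abundance = se,
       peptides = pep[, c("protein_id", "phosphopeptide_id",
                          "peptide_sequence", "is_unique", "psm_count",
                          "intensities", "site")])
}

#' Simulate a region-by-gene expression matrix with planted inverse pairs
#'
#' Emulates spatial expression across histologically defined tumor
#' regions (e.g. Ivy GAP's LE/IT/CT/MVP/PAN): genes get independent
#' region profiles except for listed pairs, where one gene's profile is
#' the reflection of the other's (planted anti-correlation).
#'
#' @param regions character vector of >= 2 distinct region labels.
#' @param nGenes number of genes.
#' @param inversePairs list of length-2 character vectors of gene ids
#'   (ids are `gene001`, ... by default) to plant as inverse.
#' @param seed integer seed.
#' @return numeric matrix, genes in rows, regions in columns.
#' @examples
#' m <- simulateRegionMatrix(c("CT", "IT", "LE", "MVP", "PAN"), 10,
#'                           list(c("gene001", "gene002")), seed = 1)
#' cor(m["gene001", ], m["gene002", ]) < 0
#' @export
simulateRegionMatrix <- function(regions, nGenes, inversePairs = list(),
                                 seed = 42) {
  if (length(regions) < 2L) stop("need at least 2 regions")
  if (anyDuplicated(regions)) stop("duplicate region labels")
  set.seed(as.integer(seed))
  ids <- sprintf("gene%03d", seq_len(nGenes))
  m <- matrix(rnorm(nGenes * length(regions), 8, 1.5), nGenes,
              length(regions), dimnames = list(ids, regions))
  for (p in inversePairs) {
    if (length(p) != 2L || !all(p %in% ids))
      stop("inverse pair must name two simulated genes: ",
           paste(p, collapse = ", "))
    prof <- rnorm(length(regions), 0, 2)
    m[p[1L], ] <- 8 + prof + rnorm(length(regions), 0, 0.3)
    m[p[2L], ] <- 8 - prof + rnorm(length(regions), 0, 0.3)
  }
  m
}
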