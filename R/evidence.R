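#' Aggregate peptide-level evidence to feature level
#'
#' Collapses a peptide record table (one row per peptide, with a PSM
#' count and its per-PSM reporter intensities as a semicolon-joined
#' string or numeric list) to one evidence row per feature: number of
#' unique peptides, total PSM count, single-peptide flag, and the
#' coefficient of variation (percent, sample SD / mean * 100) of all
#' PSM-level intensities pooled across peptides and channels.
#'
#' @param peptides data.frame with columns `protein_id` (or the column
#'   named by `groupBy`), `is_unique`, `psm_count`, `intensities`.
#' @param groupBy grouping column, `"protein_id"` for the global
#'   proteome, `"phosphopeptide_id"` for phosphopeptides.
#' @return data.frame with columns `feature_id`, `n_unique_peptides`,
#'   `total_psm`, `single_peptide`, `cv_percent`.
#' @examples
#' pep <- data.frame(protein_id = "P1",
#'                   peptide_sequence = c("a", "b"), is_unique = TRUE,
#'                   psm_count = 1L, intensities = c("100", "300"))
#' aggregateEvidence(pep)$cv_percent   # ~70.7
#' @export
aggregateEvidence <- function(peptides, groupBy = "protein_id") {
  if (!nrow(peptides)) stop("empty peptide table")
  if (!groupBy %in% colnames(peptides))
    stop("no column '", groupBy, "' in the peptide table")
  ints <- peptides$intensities
  if (is.character(ints))
    ints <- lapply(strsplit(ints, ";", fixed = TRUE), as.numeric)
  if (!is.list(ints)) ints <- as.list(ints)
  nObs <- lengths(ints)
  if (any(nObs != peptides$psm_count))
    stop("psm_count must equal the number of intensity observations")
  grp <- factor(peptides[[groupBy]], levels = unique(peptides[[groupBy]]))
  uniq <- tapply(peptides$is_unique, grp, sum)
  psm <- tapply(peptides$psm_count, grp, sum)
  cv <- vapply(split(ints, grp), function(l) {
    v <- unlist(l)
    if (length(v) < 2L) return(0)
    100 * sd(v) / mean(v)
  }, numeric(1))
  data.frame(feature_id = levels(grp),
             n_unique_peptides = as.integer(uniq),
             total_psm = as.integer(psm),
             single_peptide = as.integer(uniq) == 1L,
             cv_percent = as.numeric(cv),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Peptide-evidence filter for proteins, with transcript rescue
#'
#' A protein enters differential interpretation when it has at least two
#' unique peptides, or at least two peptide-spectrum matches in total.
#' Single-peptide identifications with a single PSM are rescued only by
#' concordant transcript-level evidence: the protein's transcript must be
#' called differential in the same direction as the protein's observed
#' log2 delta. Every drop is logged with the rule it failed.
#'
#' @param evidence data.frame from [aggregateEvidence()].
#' @param transcriptCalls named call vector (or
#'   [PIDifferentialResult-class]) for the matching transcripts; may be
#'   empty.
#' @param proteinDelta optional named numeric vector of protein log2
#'   deltas used to judge direction concordance. Without it a rescue
#'   requires only that the transcript be called up or down.
#' @return list with `kept` (character ids) and `audit` (data.frame with
#'   `feature_id`, `kept`, `reason`).
#' @examples
#' ev <- data.frame(feature_id = c("P1", "P2"),
#'                  n_unique_peptides = c(2L, 1L), total_psm = c(2L, 1L),
#'                  single_peptide = c(FALSE, TRUE),
#'                  cv_percent = c(5, 5))
#' filterProteins(ev, c(P2 = "up"), proteinDelta = c(P2 = 0.7))$kept
#' @export
filterProteins <- function(evidence, transcriptCalls = character(0),
                           proteinDelta = NULL) {
  if (is(transcriptCalls, "PIDifferentialResult"))
    transcriptCalls <- piCalls(transcriptCalls)
  n <- nrow(evidence)
  kept <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    id <- evidence$feature_id[i]
    if (evidence$n_unique_peptides[i] >= 2L) {
      kept[i] <- TRUE; reason[i] <- "unique_peptides_ge2"
    } else if (evidence$total_psm[i] >= 2L) {
      kept[i] <- TRUE; reason[i] <- "psm_ge2"
    } else {
      tc <- if (id %in% names(transcriptCalls)) transcriptCalls[[id]]
            else "not_detected"
      concordant <- tc %in% c("up", "down")
      if (concordant && !is.null(proteinDelta) &&
          id %in% names(proteinDelta)) {
        d <- proteinDelta[[id]]
        concordant <- (tc == "up" && d > 0) || (tc == "down" && d < 0)
      }
      if (concordant) {
        kept[i] <- TRUE; reason[i] <- "transcript_rescue"
      } else {
        kept[i] <- FALSE
        reason[i] <- if (tc == "not_detected")
          "single_peptide_1psm_no_transcript"
        else "single_peptide_1psm_discordant_transcript"
      }
    }
  }
  audit <- data.frame(feature_id = evidence$feature_id, kept = kept,
                      reason = reason, stringsAsFactors = FALSE)
  list(kept = evidence$feature_id[kept], audit = audit)
}

#' Evidence filter for phosphopeptides
#'
#' A phosphopeptide is retained for differential interpretation iff it
#' has at least two PSMs and a reporter-intensity coefficient of
#' variation strictly below 40 percent.
#'
#' @param evidence data.frame with columns `feature_id`, `total_psm`
#'   (or `psm_count`), `cv_percent`.
#' @param cvMax CV cutoff in percent (default 40, exclusive).
#' @param minPSM minimum PSM count (default 2).
#' @return list with `kept` (character ids) and `audit` (data.frame).
#' @examples
#' ev <- data.frame(feature_id = c("q1", "q2"), total_psm = c(2L, 1L),
#'                  cv_percent = c(10, 0))
#' filterPhosphopeptides(ev)$kept   # "q1"
#' @export
filterPhosphopeptides <- function(evidence, cvMax = 40, minPSM = 2) {
  psm <- if ("total_psm" %in% colnames(evidence)) evidence$total_psm
         else evidence$psm_count
  if (is.null(psm)) stop("evidence needs a total_psm or psm_count column")
  okPSM <- psm >= minPSM
  okCV <- evidence$cv_percent < cvMax
  kept <- okPSM & okCV
  reason <- ifelse(kept, "kept",
                   ifelse(!okPSM, "psm_lt_min", "cv_ge_max"))
  list(kept = evidence$feature_id[kept],
       audit = data.frame(feature_id = evidence$feature_id, kept = kept,
                          reason = reason, stringsAsFactors = FALSE))
}
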