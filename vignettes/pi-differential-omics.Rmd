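---
title: "Prediction-interval differential analysis of a single multi-omics sample pair"
author: "piOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prediction-interval differential analysis of a single multi-omics sample pair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piOmics)
library(SummarizedExperiment)
```

## The problem

A common perturbation design in cell-line work — one knockdown clone
against one control clone, profiled once by RNA-seq and in two labeled
replicate channel pairs by quantitative LC-MS/MS — provides no biological
replication. Variance cannot be estimated per feature, so replicated-design
machinery (t-tests, moderated statistics, negative-binomial GLMs) is
unavailable. The prediction-interval (PI) approach used here substitutes a
*between-feature* error model: across all features, the test-arm log2 value
is regressed on the control-arm log2 value, and the spread of features
around that line plays the role of residual error. The 95% prediction
interval for a *single new observation* at a feature's control value then
gives a calibrated band within which an unchanged feature should fall.

The key assumption is that the large majority of features are unchanged, so
the regression line and its residual SD describe the null. Planted-truth
simulations in this package quantify how far that assumption carries: a
minority of strong effects inflates the residual SD slightly (making the
caller conservative), and a hypothetical global shift would be absorbed
into the intercept and missed entirely. Both behaviors are inherent to the
design, not implementation artifacts.

## Model and call rule

For feature $g$ with control value $x_g$ and test value $y_g$ (both log2):

$$\hat y_g = \beta_0 + \beta_1 x_g, \qquad
\mathrm{PI}_g = \hat y_g \pm t_{0.975,\,n-2}\; s\,
\sqrt{1 + \tfrac1n + \tfrac{(x_g-\bar x)^2}{S_{xx}}}$$

with $s$ the residual SD (divisor $n-2$). The call is **joint**:

* up iff $y_g$ exceeds the upper PI bound **and** $y_g - x_g > \theta$;
* down iff $y_g$ is below the lower bound **and** $y_g - x_g < -\theta$.

$\theta = 1$ for transcripts (two-fold rule) and $\theta = 0.58$ for
proteins and phosphopeptides (1.5-fold rule; $\log_2 1.5 = 0.585$, printed
as 0.58 and used at that value). No multiple-testing adjustment is applied;
the PI itself is the error control, and the fold-change gate removes most
of the ~5% expected two-sided exceedance (the null-calibration test
measures both fractions).

The per-feature z-score is derived from the band: a 95% band spans roughly
$\pm 2$ SD, so $SD_g = |\mathrm{upper\,PI} - \hat y_g|/2$ and
$z_g = (\hat y_g - y_g)/SD_g$. This orientation makes up-regulated features
*negative*; the magnitude `abs_zscore` is exposed alongside for
volcano-style ranking, and both are reported rather than silently flipping
the sign. A feature exactly on the upper bound has $z = -2$, on the lower
bound $z = +2$; a degenerate zero-width band yields $z = 0$ when the
observation equals the prediction and $\pm\infty$ otherwise (flagged, not
an error — it occurs only for pathological identical inputs, and the fit
emits a warning when $s = 0$).

### Replicates

The labeled proteome design carries two (control, test) channel pairs.
Each pair is analyzed separately with its own regression, and the
consensus keeps a call only when **both** replicates agree on the
direction; discordant features, and features observed in only one
replicate, are reported unchanged. This is deliberately conservative: with
only two technical replicates, a one-replicate call is indistinguishable
from a labeling artifact.

## Normalization

* RNA: counts-per-million per column (`count / colsum * 1e6`), then
  `log2(CPM + 1)`. The pseudocount keeps zero-count features in the fit at
  log2 value 0; no expression floor is applied by default.
* Reporter abundances: each channel divided by its column mean (unit-mean
  columns), then plain `log2` — abundances are strictly positive, so no
  pseudocount is added on the protein side.
* z-scoring of log expression across samples or anatomic regions uses the
  **sample** SD (divisor $n-1$); the property tests pin this choice (the
  alternative population-SD convention differs by a constant factor and
  would propagate into every z value).

## Evidence filters

Protein-level interpretation requires ≥2 unique peptides, or ≥2
peptide-spectrum matches (PSMs) in total. Single-peptide/single-PSM
identifications are rescued only by *concordant* transcript evidence:
the transcript must be called differential in the same direction as the
protein's observed log2 delta — "concordant" is read as directional, not
merely "detected". Phosphopeptides require ≥2 PSMs and a reporter-intensity
coefficient of variation strictly below 40% (the boundary value 40 is
excluded). The CV is computed with the sample SD over raw PSM-level
intensities pooled across peptides and channels; computing it on ratios
instead would be a different, unchosen convention, and the audit log
records every drop with the rule it failed so the choice is inspectable
per run.

## Phospho disambiguation and cross-omics correlation

A differential phosphopeptide may reflect site phosphorylation or a change
in parent-protein abundance. Cross-referencing the global proteome calls:
`phosphorylation_driven` (phospho called, parent detected and unchanged),
`abundance_linked` (both called, direction match recorded),
`indeterminate` (parent not detected — deliberately *not* counted as
site-driven, since nothing is known about its abundance), `none` (phospho
unchanged). Cross-omics agreement is summarized as the Pearson correlation
of matched per-feature log2 deltas, computed per replicate pair with the
arithmetic mean reported as the average r.

## Single-sample enrichment

The ssGSEA statistic ranks one profile by decreasing value (ties broken by
lexicographic gene id, stably, so scores are reproducible across platforms)
and sums, over all ranking positions, the difference between the weighted
in-set ECDF and the uniform out-of-set ECDF. In-set genes at position $i$
of $N$ carry weight $(N-i+1)^\alpha$ normalized over the set — weights come
from ranks rather than raw expression for numerical stability. The default
$\alpha = 0.25$ follows the original single-sample formulation;
$\alpha = 0$ gives a purely rank-based score, invariant under monotone
transforms, which the oracle tests exploit. Scores are not normalized
across samples by default (the single-sample use case compares signatures
within one profile, e.g. mesenchymal vs proneural on a knockdown delta
profile); note the raw ES scales with the length of the ranking, so scores
are comparable between signatures on the same profile, not across rankings
of different size. Genes of a set absent from the ranking are ignored and
counted in the output.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, so
every stage is testable without external downloads:

* **RNA pair**: per-feature baseline $\log_2$ abundance
  $\sim N(5, 2^2)$, log-normal technical noise (SD 0.2 on the log2 scale)
  on each arm, planted effects of $\pm 2$ log2 units on a 2% + 2% minority,
  expected expression scaled to a 30-million-read library, counts Poisson
  (negative binomial via `nbSize` when over-dispersion is wanted). The
  defaults — depth, baseline spread, noise, effect size and planted
  fractions — describe a deeply sequenced knockdown experiment with a
  four-fold perturbation on a small fraction of genes.
* **Proteome**: strictly positive reporter abundances (column-mean
  normalization assumes no zeros, matching search-engine output), two
  replicate channel pairs (`ctrl1, test1, ctrl2, test2`), unique-peptide
  counts shifted-geometric, per-peptide PSM counts shifted-Poisson,
  per-PSM intensities log-normal around the protein abundance at a
  per-feature CV drawn as $|N(15, 10^2)|$ percent — so a small tail
  exceeds the 40% filter. A configured fraction (default 0.2) of proteins
  is forced to single-peptide/1-PSM status to exercise the rescue rule.
* **Phosphoproteome**: each phosphopeptide maps to a parent protein;
  planted effects are split between site-driven (parent drawn from the
  null proteins) and abundance-driven (parent drawn from the concordantly
  shifted proteins) by `fracSiteDriver`. Rows fated to fail the evidence
  filter are labeled in the truth table.
* **Region matrix**: independent per-gene profiles across named anatomic
  regions, with listed gene pairs planted as mirror-image (anti-correlated)
  profiles.

What the generator does **not** emulate: GC/length biases, mapping
ambiguity, shared (non-unique) peptides, ratio compression in isobaric
labeling, batch effects, and any correlation structure between features.
Passing recovery tests therefore demonstrate that the implementation is
faithful to the method under the method's own assumptions — not that the
method is robust to everything real data does.

## Numerical choices and degenerate inputs

* All-zero count columns, non-positive abundances, constant vectors, and
  constant control values are errors naming the offender; empty phospho
  configurations return empty tables without error.
* Identical (config, seed) reproduces tables exactly; the phospho stage
  offsets the seed by one so it does not replay the proteome stream, and
  the pipeline derives stage seeds as small fixed offsets of the run seed.
* Thresholds: the fold gate is strict (`>`), the CV filter strict (`<40`),
  the PSM filter inclusive (`>=2`) — each pinned by a boundary test.

## Problem sizes

The test suite and the results script run at desk scale, chosen to keep
Monte-Carlo variability well inside the asserted margins: 5000 features
(200 planted) for RNA recovery, 2000 for null calibration, 1000 proteins /
800 phosphopeptides for the integration path, 200 features for the
PI-vs-reference-routine comparison, and one hundred 20-gene profiles for
the enrichment oracle. The full suite runs in well under a minute.

## Interface

piOmics is a library: the exported functions (`simulate*`, `cpmNormalize`,
`piDifferential`, `filterProteins`, `classifyPhospho`, `ssgseaScore`,
`runPipeline`, ...) compose in scripts, and `runPipeline()` plus the
TSV/JSON writers cover the batch use case; a shell wrapper would add no
capability beyond argument parsing, so none is shipped.

## Limitations

* The PI model assumes most features are null and is blind to global
  shifts (absorbed by the regression line).
* Two technical replicates support only a direction-concordance consensus,
  not variance estimation.
* Phosphopeptide abundances are *not* normalized by parent-protein
  abundance before calling; disambiguation happens at the call level.
* ssGSEA scores are method-faithful but parameterizations differ across
  published implementations; comparisons should fix $\alpha$ and the
  weighting convention.
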