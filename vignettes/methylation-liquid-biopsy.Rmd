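---
title: "Methods: aqueous-humor cfDNA methylation analysis with methylAH"
author: "methylAH authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aqueous-humor cfDNA methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylAH)
```

## The problem

Retinoblastoma (RB) is a childhood retinal cancer in which direct tumor
biopsy is contraindicated, so the methylation state of the tumor must be
read from a surrogate. The aqueous humor (AH) of the affected eye carries
tumor-derived cell-free DNA (cfDNA) whose methylation profile mirrors the
tumor's. `methylAH` implements the full analysis chain for such data:
methylation-array beta values in, probe filtering and purity gating,
probe-level differential methylation, integration with gene expression,
and derivation of prognostic methylation signatures that separate eyes
likely to be salvaged from eyes that end up enucleated.

The package's universal currency is the **beta value**, the per-probe
methylation fraction `beta = M / (M + U)` computed from methylated (M)
and unmethylated (U) signal intensities, bounded in [0, 1]. A `BetaSet`
(a `SummarizedExperiment` subclass) holds the probes-by-samples beta
matrix with `NA` marking masked cells, the probe annotation in `rowData`
and the sample sheet in `colData`.

## Preprocessing model

* **Detection masking.** Cells whose detection p value exceeds 0.05 are
  masked (`maskByDetection`). Masking is idempotent and all downstream
  statistics are pairwise-complete.
* **Probe exclusion.** Probes linked to known polymorphisms, probes on
  chrX/chrY, and aging-related probes are dropped (`filterProbes`). No
  aging-probe list ships with the package: published epigenetic-clock
  lists differ, so the list is a user-supplied flag column.
* **Platform intersection.** Cohorts profiled on different array
  generations are merged on the probes present on *all* requested
  platforms (`intersectPlatforms`).
* **Purity gating.** Tumor purity is estimated from probes unmethylated
  in leukocytes (LUMP): `score = min(1, mean(beta) / 0.85)` over the
  LUMP set (`lumpScore`). Samples with scores strictly below 0.5 are
  removed; a score exactly at the threshold is retained, matching the
  printed "< 0.5 removed" rule. The 0.85 scale follows the assay's
  published convention and is exposed as an argument. The canonical
  44-CpG list is not redistributed here; synthetic cohorts designate
  their own set.

## Differential methylation

For each probe, a two-sided Welch's t-test compares the contrast arm
(tumor, or salvage) against the reference arm (retina, or enucleated),
with degrees of freedom from the Welch–Satterthwaite approximation.
Effect size is **delta beta**, the difference of group means, oriented
contrast-arm minus reference so that "hyper" always means elevated in
the contrast arm. Probe selection applies *strict* inequalities at the
stated thresholds (delta beta > 0.3 with p < 0.05 for the tumor-vs-retina
contrast; > 0.4 with p < 0.01 for the prognostic panel), because that is
how the selection rules are printed. No multiple-testing correction is
applied by default — the thresholds are raw-p rules — though
`p.adjust`-style correction can be applied by the caller to the returned
p values.

Degenerate inputs are handled explicitly: a probe constant in both arms
with equal means gives t = 0, p = 1; constant with unequal means gives
p = 0 with a `degenerate` flag (the difference is exact, not estimated);
a probe with fewer than three unmasked values in either arm is skipped
and listed with a reason (three being the minimum to estimate a variance
with any redundancy). Variances computed from centred residuals are
snapped to exact zero below 1e-24, which is rounding noise at beta scale.

Genic regions follow the manifest token vocabulary: **promoter** =
TSS200, TSS1500, 5'UTR or first exon; **gene body** = Body or 3'UTR;
everything else **other**. Probes whose transcripts disagree take
promoter over body over other — the conservative promoter superset used
when coupling methylation to expression. Enhancer membership is an
overlapping annotation flag, not an exclusive class.

## Methylation-expression integration

Differentially expressed genes are those past a two-fold change *in both*
of two independent expression datasets (`deOverlap`; the raw-scale
"fold change > 2" rule and the log2 > 1 rule are the same rule,
implemented once on the log2 scale). A gene is called
methylation-regulated when at least one qualifying probe and the
expression call agree in the canonical sign pattern: promoter
hypomethylation with up-regulation, gene-body hypermethylation with
up-regulation, promoter hypermethylation with down-regulation, gene-body
hypomethylation with down-regulation. Aggregation from probes to genes
uses an "any qualifying probe" rule; a gene matching several categories
is reported in all, with the primary category held by its
largest-|delta beta| probe. Integration is conjunctive: with no
expression evidence there are no calls. Gene symbols match exactly and
case-sensitively; harmonise aliases upstream.

## Signatures, clustering, MDS

Unsupervised structure uses the top-10,000 probes by beta SD
(`topVariableProbes`; unbiased SD, ties broken lexicographically so the
selection is reproducible), complete-linkage agglomerative clustering on
Euclidean distance (`clusterSamples`; average and Ward linkage, and a
correlation metric, are exposed), and **classical Torgerson MDS**
(`mdsEmbed`). Classical MDS is a deliberate substitute for the
leading-fold-change MDS heuristic of expression tooling: that dialect is
expression-specific, whereas Torgerson MDS is the textbook metric
embedding and reproduces exactly embeddable geometries to numerical
precision. Embedding signs are fixed by forcing the largest-|coordinate|
sample positive on each axis.

The prognostic workflow derives a `SignaturePanel` between salvaged and
enucleated samples (`derivePanel`, delta beta > 0.4, p < 0.01), then
clusters any cohort over the panel and cuts the tree at k = 2
(`assignClusters`). The published analyses read clusters off heatmaps;
a k = 2 cut is the reproducible stand-in. Label "A" goes to the cluster
enriched for salvaged (SV) outcomes so the label semantics are fixed by
the sample sheet rather than by tree orientation; primary and secondary
enucleation (PE, SE) are merged as "enucleated". A forced cut on an
unstructured cohort is flagged as weak separation via the mean
silhouette (< 0.1). Cluster-outcome association uses the exact
(hypergeometric) test with the doubled-one-tail two-sided convention,
`p = min(1, 2 * min(lower, upper))` — on a perfectly separated 4-vs-8
table this gives 2/C(12,4) ≈ 0.0040 — with the cross-product odds ratio
(`Inf` reported symbolically for zero cells) and cluster-within-subtype
containment booleans.

## Concordance

Paired-sample agreement (tumor vs AH; low input vs bulk) is the square
of Pearson r over pairwise-complete probes, with a minimum of 100 shared
probes per pair; constant profiles are flagged undefined rather than
scored 0. `bestMatchReport` asks whether each AH sample's best-matching
tumor is its declared pair (ties count as failures), and
`titrationCurve` traces mean r-squared against the noise precision
kappa, emulating the rise of concordance with input DNA mass.

## The synthetic-cohort generator

Real AH/RB methylation cohorts require controlled-access downloads and
array preprocessing, so every stage here is exercised on synthetic
cohorts with planted, recorded ground truth (`simulateCohort` +
`CohortTruth`).

**Noise model.** Observed beta values are drawn from a mean-preserving
beta distribution parameterised by mean mu and concentration kappa
(`shape1 = mu * kappa`, `shape2 = (1 - mu) * kappa`), chosen because it
reproduces the heteroscedastic, boundary-respecting scatter of array
beta values: variance `mu(1-mu)/(kappa+1)` vanishes at the 0/1
boundaries and kappa maps monotonically to input DNA mass. Exact 0 and 1
are preserved. The defaults kappa = 200 per role are calibration
choices — the source study reports no distributional description of
AH-vs-tumor noise — picked so that a 10,000-probe profile at kappa = 200
correlates with its clean profile at roughly the level bulk-input arrays
reach, while kappa = 5 reproduces visible low-input skewing.

**Baseline.** Per-probe baseline means come from a 50/50 mixture of two
beta components with modes near 0.1 and 0.9, matching genome-wide
beta bimodality; weights and modes are configurable.

**Planted structure.** Tumor samples shift a designated probe panel by a
signed delta beta (half hyper, half hypo; probes are chosen so the
shifted mean stays inside [0, 1]); a second, disjoint panel separates
two latent tumor subtypes — disjoint by default so recovery tests are
unconfounded. Regulated-gene planting shifts one suitable promoter or
body probe per gene and couples two independent expression tables to the
planted categories. Each AH sample re-reads its paired tumor's latent
profile with the AH kappa; leukocyte profiles are unmethylated at a
designated LUMP set (tissue 0.85, leukocyte ~0), so purity mixtures
behave like the LUMP arithmetic assumes.

**Individual variation.** Each sample first receives a latent profile
drawn around its group mean with precision `kappa_individual`
(default 200), then is observed with its role's kappa. Without this
biological heterogeneity all same-subtype tumors would share one mean
profile and paired-AH matching would be undecidable by construction;
with it, pair recovery is a real test. The default puts tumor-to-tumor
heterogeneity on the same scale as technical noise, a deliberately
conservative choice.

**Seeding.** All randomness flows from one integer seed through a
documented splitting scheme (`childSeed(seed, stream)`), with distinct
streams for the annotation, the cohort, expression, re-noising and
titration, so composed calls with a shared master seed never re-use an
RNG stream. The same seed reproduces a cohort byte for byte.

**What the generator does not emulate.** Infinium I/II chemistry
differences, raw two-channel intensities and IDAT structure,
normalisation artefacts, batch effects, cell-composition heterogeneity
beyond the single leukocyte component, and spatially correlated
(region-level) methylation. Passing recovery tests therefore demonstrate
the correctness of the statistical machinery under the stated model, not
performance on raw array data.

## Problem sizes and numerical choices

The test-suite and acceptance-script cohorts use 10,000–50,000 probes
and 12–62 samples — large enough that binomial bounds on type-I rates
and recovery fractions are tight, while a full run stays in the
minutes range on a laptop. Tie-breaks are deterministic everywhere
(lexicographic probe ids in variance ranking, recorded merge order in
clustering, sign-fixed MDS axes). Threshold comparisons are strict, as
printed in the selection rules. The beta-from-intensity offset defaults
to 0 (the plain ratio), with a nonzero offset exposed for numerical
stability.

## A worked example

```{r example}
ann <- simulateAnnotation(5000, 500, seed = 3)
sim <- simulateCohort(ann,
                      design = c(retina = 12, tumor_subtype1 = 8),
                      effects = list(tumor = list(n_probes = 200,
                                                  delta = 0.4)),
                      seed = 11)
sheet <- sim$sheet
dm <- dmTable(sim$betas,
              arm_a = sheet$sample_id[sheet$role == "tumor"],
              arm_b = sheet$sample_id[sheet$role == "retina"],
              annotation = ann, contrast = "tumor_vs_retina")
dm
sel <- selectDM(dm)
directionFractions(sel$hyper, sel$hypo)
tp <- plantedProbes(sim$truth, "tumor")
mean(tp$probe_id %in% c(sel$hyper, sel$hypo))  # planted-panel sensitivity
```

## Known limitations

* The pipeline starts from beta matrices; IDAT decoding, background and
  dye-bias correction, and probe-type normalisation are upstream and out
  of scope.
* Raw-p thresholding mirrors the published selection rules; users who
  need FDR control should adjust the returned p values.
* The LUMP scale constant and probe list are inputs, not built-ins.
* Cluster labels "A"/"B" are descriptive groupings, not a clinical
  decision rule; no survival modelling is provided.
* Synthetic-recovery results bound what the statistics can do under the
  generator's assumptions; they are not a validation on patient data.
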