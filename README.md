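# methylAH

Methylation-array analysis for retinoblastoma (RB) liquid biopsies.

Retinoblastoma is a childhood retinal cancer in which tumor biopsy is
contraindicated, so tumor methylation state must be read from the aqueous
humor (AH), whose cell-free DNA mirrors the tumor. `methylAH` implements
the complete analysis chain for array beta values from such cohorts, for
epigenomics analysts working with EPIC/HM450-style data:

* **Preprocessing** — beta values from methylated/unmethylated
  intensities (β = M/(M+U)), detection-p masking (p > 0.05 removed),
  exclusion of polymorphism-linked / sex-chromosome / aging probes, and
  cross-platform probe intersection.
* **Purity gating** — leukocyte-unmethylation (LUMP) purity,
  `score = min(1, mean β over LUMP probes / 0.85)`, samples with
  score < 0.5 removed.
* **Differential methylation** — per-probe two-sided Welch's *t*
  (Welch–Satterthwaite df) with the delta-beta effect filter
  (Δβ = mean difference of group β), strict thresholds (Δβ > 0.3,
  p < 0.05), hyper/hypo direction fractions, and genic-region
  classification (promoter = TSS200/TSS1500/5'UTR/1st exon;
  body = gene body/3'UTR) with enrichment summaries.
* **Methylation × expression** — genes past two-fold change in **both**
  of two expression datasets, intersected with promoter/body Δβ calls
  into the four canonical regulation categories (promoter-hypo→up,
  body-hyper→up, promoter-hyper→down, body-hypo→down).
* **Signatures** — top-SD probe ranking, hierarchical clustering,
  classical MDS, prognostic panel derivation (Δβ > 0.4, p < 0.01,
  salvage vs enucleation), Cluster A/B assignment and an exact
  cluster-outcome test.
* **Concordance** — pairwise r² (squared Pearson) between paired
  samples, declared-pair best-match reports and input-mass titration
  curves.
* **Synthetic cohorts** — a generator with bimodal β baselines, planted
  DM panels, latent tumor subtypes, paired AH re-reads, leukocyte
  profiles, purity mixtures and a mean-preserving beta noise model
  (μ, κ), with every planted feature recorded in a truth object so all
  of the above is testable without downloads.

The central data object is `BetaSet`, a `SummarizedExperiment` holding
the probes × samples β matrix (masked cells are `NA`), probe annotation
and sample sheet.

## Worked example

Simulate a retina-vs-tumor cohort with a planted 200-probe panel at
|Δβ| = 0.4, then run the differential methylation contrast:

```r
library(methylAH)

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
#> DMTable 'tumor_vs_retina': 5000 probes tested, 0 skipped
#>   thresholds: |delta beta| > 0.3, p < 0.05
#>   hyper 100 / hypo 100 / none 4800

sel <- selectDM(dm)
directionFractions(sel$hyper, sel$hypo)
#> hyper  hypo
#>   0.5   0.5

tp <- plantedProbes(sim$truth, "tumor")
mean(tp$probe_id %in% c(sel$hyper, sel$hypo))
#> [1] 1
```

All 200 planted probes (100 hyper-, 100 hypomethylated in tumor) are
selected at the (0.3, 0.05) thresholds with no false positives among the
4,800 null probes — the generated noise level (κ = 200) corresponds to
ample input DNA. Region enrichment of the selection against the tested
universe:

```r
regionEnrichment(sel$hyper, sel$hypo, dmRecords(dm)$probe_id, ann)
#>       promoter  body other enhancer    n
#> hyper    0.310 0.460 0.230    0.140  100
#> hypo     0.450 0.360 0.190    0.100  100
#> total    0.397 0.361 0.242    0.097 5000
```

Downstream, `derivePanel()` + `assignClusters()` produce Cluster A/B
labels from a salvage-vs-enucleation panel and `clusterOutcomeTest()`
tests the association exactly; see the methods vignette
(`vignettes/methylation-liquid-biopsy.Rmd`) for the full model
description.

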