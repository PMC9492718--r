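#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

setOldClass("hclust")

#' BetaSet: methylation beta values with missingness mask
#'
#' `BetaSet` is the package's universal currency: a
#' [SummarizedExperiment::SummarizedExperiment] whose `"beta"` assay holds
#' per-probe, per-sample methylation fractions in \[0, 1\]. Masked cells
#' (failed detection, absent probes) are `NA`. Probe annotation lives in
#' `rowData`, the sample sheet in `colData`.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

setValidity("BetaSet", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!("beta" %in% a))
    return("assay 'beta' is required")
  b <- SummarizedExperiment::assay(object, "beta")
  if (!is.numeric(b))
    return("'beta' assay must be numeric")
  rng <- suppressWarnings(range(b, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    return("unmasked beta values must lie in [0, 1]")
  if (is.null(rownames(b)) || anyDuplicated(rownames(b)))
    return("probe ids must be present and unique")
  if (is.null(colnames(b)) || anyDuplicated(colnames(b)))
    return("sample ids must be present and unique")
  TRUE
})

#' Construct a BetaSet
#'
#' @param beta Numeric probes x samples matrix in \[0, 1\]; `NA` marks masked
#'   cells. Row and column names are required (probe / sample ids).
#' @param annotation Optional probe annotation `data.frame` (see
#'   [simulateAnnotation()] for the column contract); matched to rows by
#'   `probe_id`.
#' @param sampleSheet Optional per-sample `data.frame` with a `sample_id`
#'   column (role, pair id, outcome, subtype, cohort).
#' @return A [BetaSet-class] object.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' bs <- BetaSet(b)
#' dim(bs)
#' @export
BetaSet <- function(beta, annotation = NULL, sampleSheet = NULL) {
  beta <- .beta_matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    .stopf("probe and sample ids (dimnames) are required")
  rd <- S4Vectors::DataFrame(row.names = rownames(beta))
  if (!is.null(annotation)) {
    idx <- match(rownames(beta), annotation$probe_id)
    if (anyNA(idx))
      .stopf("%d probes missing from the annotation", sum(is.na(idx)))
    rd <- S4Vectors::DataFrame(annotation[idx, , drop = FALSE],
                               row.names = rownames(beta))
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(beta))
  if (!is.null(sampleSheet)) {
    idx <- match(colnames(beta), sampleSheet$sample_id)
    if (anyNA(idx))
      .stopf("%d samples missing from the sample sheet", sum(is.na(idx)))
    cd <- S4Vectors::DataFrame(sampleSheet[idx, , drop = FALSE],
                               row.names = colnames(beta))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta), rowData = rd, colData = cd)
  methods::new("BetaSet", se)
}

#' @describeIn BetaSet beta value matrix (`NA` = masked).
#' @param x A `BetaSet`.
#' @export
betaValues <- function(x) .beta_matrix(x)

#' @describeIn BetaSet logical mask matrix (`TRUE` = masked / missing).
#' @export
maskValues <- function(x) is.na(.beta_matrix(x))

#' @describeIn BetaSet probe identifiers.
#' @export
probeIds <- function(x) rownames(.beta_matrix(x))

#' @describeIn BetaSet sample identifiers.
#' @export
sampleIds <- function(x) colnames(.beta_matrix(x))

setMethod("show", "BetaSet", function(object) {
  b <- SummarizedExperiment::assay(object, "beta")
  cat(sprintf("BetaSet: %d probes x %d samples (%.2f%% masked)\n",
              nrow(b), ncol(b), 100 * mean(is.na(b))))
  methods::callNextMethod()
})

#' DMTable: one two-group differential-methylation contrast
#'
#' Per-probe group means, delta beta (arm A minus arm B), Welch t statistic,
#' Welch--Satterthwaite degrees of freedom, two-sided p value, direction call
#' and genic-region class, plus the probes skipped for missingness.
#'
#' @slot contrast Character label, e.g. `"tumor_vs_retina"`.
#' @slot records `data.frame` with columns `probe_id`, `mean_a`, `mean_b`,
#'   `delta_beta`, `t_stat`, `df`, `p_value`, `degenerate`, `direction`,
#'   `region_class`.
#' @slot skipped `data.frame` with `probe_id` and `reason`.
#' @slot deltaThreshold,pThreshold Thresholds used for the direction calls.
#' @export
setClass("DMTable", representation(
  contrast = "character",
  records = "data.frame",
  skipped = "data.frame",
  deltaThreshold = "numeric",
  pThreshold = "numeric"))

setValidity("DMTable", function(object) {
  need <- c("probe_id", "mean_a", "mean_b", "delta_beta", "t_stat", "df",
            "p_value", "direction")
  if (!all(need %in% names(object@records)))
    return("records lack required columns")
  d <- object@records$delta_beta
  if (length(d) && any(abs(d) > 1 + 1e-12, na.rm = TRUE))
    return("|delta_beta| must be <= 1")
  if (anyDuplicated(object@records$probe_id))
    return("one record per tested probe")
  TRUE
})

#' @describeIn DMTable per-probe records as a data.frame.
#' @param x A `DMTable`.
#' @export
dmRecords <- function(x) x@records

#' @describeIn DMTable skipped probes with reasons.
#' @export
dmSkipped <- function(x) x@skipped

#' @describeIn DMTable thresholds used for direction calls.
#' @export
dmThresholds <- function(x) c(delta = x@deltaThreshold, p = x@pThreshold)

setMethod("show", "DMTable", function(object) {
  r <- object@records
  cat(sprintf("DMTable '%s': %d probes tested, %d skipped\n",
              object@contrast, nrow(r), nrow(object@skipped)))
  cat(sprintf("  thresholds: |delta beta| > %g, p < %g\n",
              object@deltaThreshold, object@pThreshold))
  cat(sprintf("  hyper %d / hypo %d / none %d\n",
              sum(r$direction == "hyper"), sum(r$direction == "hypo"),
              sum(r$direction == "none")))
})

#' SignaturePanel: an ordered differentially methylated probe panel
#'
#' The product of [derivePanel()]: probes passing the stated delta-beta and
#' p thresholds for a named contrast, with per-probe statistics, applicable
#' to any beta matrix sharing probe ids.
#'
#' @slot contrast Contrast label recorded as provenance.
#' @slot probes `data.frame` with `probe_id`, `delta_beta`, `p_value`,
#'   `direction`, ordered by ascending p value.
#' @slot deltaThreshold,pThreshold The selection thresholds.
#' @slot universeSize Number of probes tested when the panel was derived.
#' @export
setClass("SignaturePanel", representation(
  contrast = "character",
  probes = "data.frame",
  deltaThreshold = "numeric",
  pThreshold = "numeric",
  universeSize = "numeric"))

setValidity("SignaturePanel", function(object) {
  p <- object@probes
  if (nrow(p) == 0) return(TRUE)
  ok_hyper <- p$direction != "hyper" |
    (p$delta_beta > object@deltaThreshold & p$p_value < object@pThreshold)
  ok_hypo <- p$direction != "hypo" |
    (p$delta_beta < -object@deltaThreshold & p$p_value < object@pThreshold)
  if (!all(ok_hyper & ok_hypo))
    return("every panel probe must satisfy the stated thresholds")
  TRUE
})

#' @describeIn SignaturePanel panel probe ids, in panel order.
#' @param x A `SignaturePanel`.
#' @export
panelProbes <- function(x) x@probes$probe_id

#' @describeIn SignaturePanel per-probe statistics as a data.frame.
#' @export
panelStats <- function(x) x@probes

setMethod("show", "SignaturePanel", function(object) {
  cat(sprintf(
    "SignaturePanel '%s': %d probes (|delta beta| > %g, p < %g; universe %d)\n",
    object@contrast, nrow(object@probes), object@deltaThreshold,
    object@pThreshold, object@universeSize))
})

#' ClusterAssignment: two-group sample labels from a signature panel
#'
#' @slot labels Named character vector; `"A"`/`"B"` when outcome annotations
#'   fixed the semantics (A = salvage-enriched), else `"1"`/`"2"`.
#' @slot tree The agglomerative tree (`hclust`).
#' @slot k Number of clusters cut.
#' @slot panelContrast Contrast label of the panel used.
#' @slot silhouette Mean silhouette width of the cut.
#' @slot weakSeparation `TRUE` when the forced cut shows near-zero silhouette.
#' @export
setClass("ClusterAssignment", representation(
  labels = "character",
  tree = "hclust",
  k = "numeric",
  panelContrast = "character",
  silhouette = "numeric",
  weakSeparation = "logical"))

setValidity("ClusterAssignment", function(object) {
  if (is.null(names(object@labels)))
    return("labels must be named by sample id")
  n <- length(object@labels)
  if (nrow(object@tree$merge) != n - 1)
    return("tree must have n - 1 merges for n samples")
  TRUE
})

#' @describeIn ClusterAssignment named cluster labels.
#' @param x A `ClusterAssignment`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusterAssignment the hclust tree.
#' @export
clusterTree <- function(x) x@tree

setMethod("show", "ClusterAssignment", function(object) {
  tab <- table(object@labels)
  cat(sprintf("ClusterAssignment (panel '%s', k = %d): %s\n",
              object@panelContrast, object@k,
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  mean silhouette %.3f%s\n", object@silhouette,
              if (object@weakSeparation) " [weak separation]" else ""))
})

#' CohortTruth: ground truth for a simulated cohort
#'
#' Records every planted feature of a [simulateCohort()] run so recovery can
#' be scored exactly: planted differentially methylated probes per contrast
#' (signed delta beta), latent subtype labels, AH-to-tumor pairing, per-sample
#' purity, planted methylation-regulated genes, per-sample noise precision,
#' and the designated leukocyte-unmethylated (LUMP) probe set.
#'
#' @slot plantedProbes Named list of `data.frame(probe_id, delta)` per
#'   contrast (`"tumor"`, `"subtype"`).
#' @slot subtypeLabels Named integer vector (1 or 2) for tumor and AH samples.
#' @slot pairing Named character vector, AH sample id -> tumor sample id.
#' @slot purity Named numeric vector in \[0, 1\].
#' @slot regulatedGenes `data.frame(gene, category, probe_id, delta)`.
#' @slot noisePrecision Named numeric vector of per-sample kappa.
#' @slot lumpProbes Character vector of designated LUMP probe ids.
#' @export
setClass("CohortTruth", representation(
  plantedProbes = "list",
  subtypeLabels = "integer",
  pairing = "character",
  purity = "numeric",
  regulatedGenes = "data.frame",
  noisePrecision = "numeric",
  lumpProbes = "character"))

setValidity("CohortTruth", function(object) {
  for (df in object@plantedProbes) {
    if (!all(c("probe_id", "delta") %in% names(df)))
      return("plantedProbes entries need probe_id and delta")
    if (length(df$delta) && any(abs(df$delta) > 1))
      return("planted |delta beta| must be <= 1")
  }
  if (length(object@pairing) &&
      !all(object@pairing %in% names(object@subtypeLabels)))
    return("every AH pairing target must be a cohort tumor")
  if (length(object@purity) &&
      any(object@purity < 0 | object@purity > 1))
    return("purity must lie in [0, 1]")
  if (length(object@noisePrecision) && any(object@noisePrecision <= 0))
    return("noise precision kappa must be positive")
  TRUE
})

#' @describeIn CohortTruth planted probe table for one contrast.
#' @param x A `CohortTruth`.
#' @param contrast `"tumor"` or `"subtype"`.
#' @export
plantedProbes <- function(x, contrast = "tumor") {
  if (!contrast %in% names(x@plantedProbes))
    .stopf("no planted contrast '%s'", contrast)
  x@plantedProbes[[contrast]]
}

#' @describeIn CohortTruth named latent subtype labels.
#' @export
subtypeLabels <- function(x) x@subtypeLabels

#' @describeIn CohortTruth AH -> tumor pairing map.
#' @export
pairingMap <- function(x) x@pairing

#' @describeIn CohortTruth planted regulated-gene table.
#' @export
regulatedGenes <- function(x) x@regulatedGenes

#' @describeIn CohortTruth designated LUMP probe ids.
#' @export
lumpProbes <- function(x) x@lumpProbes

setMethod("show", "CohortTruth", function(object) {
  cat("CohortTruth:\n")
  for (nm in names(object@plantedProbes))
    cat(sprintf("  planted '%s': %d probes\n", nm,
                nrow(object@plantedProbes[[nm]])))
  cat(sprintf("  %d subtype-labelled samples, %d AH pairs, %d regulated genes, %d LUMP probes\n",
              length(object@subtypeLabels), length(object@pairing),
              nrow(object@regulatedGenes), length(object@lumpProbes)))
})
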