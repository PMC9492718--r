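#' Top variance-ranked probes
#'
#' Ranks probes by their beta-value standard deviation across the selected
#' samples (unbiased, pairwise-complete) and returns the top `k`, the
#' variance filter used before unsupervised clustering and MDS (default
#' 10,000). Ties are broken by lexicographic probe id so the selection is
#' deterministic; probes with fewer than two unmasked values are
#' ineligible.
#'
#' @param betas [BetaSet-class] or beta matrix.
#' @param samples Optional sample ids (default: all).
#' @param k Number of probes (default 10000). If `k` exceeds the eligible
#'   probe count, all eligible probes are returned with a warning.
#' @return Character vector of probe ids, highest SD first.
#' @export
topVariableProbes <- function(betas, samples = NULL, k = 10000) {
  b <- .beta_matrix(betas)
  if (!is.null(samples)) b <- b[, samples, drop = FALSE]
  if (ncol(b) < 2) .stopf("need >= 2 samples to rank by SD")
  st <- .row_stats(b)
  sd <- sqrt(st$var)
  eligible <- which(st$n >= 2)
  if (k > length(eligible)) {
    .warnf("k = %d exceeds the %d eligible probes; returning all",
           k, length(eligible))
    k <- length(eligible)
  }
  ids <- rownames(b)[eligible]
  ord <- order(-sd[eligible], ids)
  ids[ord][seq_len(k)]
}

## distance over a probe panel; samples as points
.panel_dist <- function(b, metric) {
  if (metric == "euclidean") {
    stats::dist(t(b))
  } else {
    cc <- stats::cor(b, use = "pairwise.complete.obs")
    stats::as.dist(1 - cc)
  }
}

#' Agglomerative clustering of samples over a probe panel
#'
#' Deterministic hierarchical clustering of samples using Euclidean or
#' correlation (1 - Pearson) distance over the given probes, with
#' complete, average or Ward linkage (complete linkage by default,
#' mirroring the common default of heatmap tooling).
#'
#' @param betas [BetaSet-class] or beta matrix.
#' @param probes Optional probe panel (default: all rows).
#' @param samples Optional sample ids (default: all).
#' @param metric `"euclidean"` or `"correlation"`.
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @return An `hclust` tree; serialise with [treeToMergeList()].
#' @export
clusterSamples <- function(betas, probes = NULL, samples = NULL,
                           metric = c("euclidean", "correlation"),
                           linkage = c("complete", "average", "ward")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  b <- .beta_matrix(betas)
  if (!is.null(probes)) {
    missing_p <- setdiff(probes, rownames(b))
    if (length(missing_p))
      .stopf("panel probes absent from the matrix: %s",
             paste(utils::head(missing_p, 5), collapse = ", "))
    b <- b[probes, , drop = FALSE]
  }
  if (!is.null(samples)) b <- b[, samples, drop = FALSE]
  if (ncol(b) < 2) .stopf("need >= 2 samples to cluster")
  miss <- colMeans(is.na(b))
  if (any(miss > 0.5))
    .stopf("sample(s) with >50%% missing over the panel: %s",
           paste(colnames(b)[miss > 0.5], collapse = ", "))
  d <- .panel_dist(b, metric)
  stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
}

#' Cut an agglomerative tree into k clusters
#'
#' @param tree An `hclust` tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Named integer labels, stable across runs.
#' @export
cutClusters <- function(tree, k) {
  n <- length(tree$labels %||% tree$order)
  if (length(k) != 1 || k < 1 || k > n || k != round(k))
    .stopf("k must be an integer in [1, %d]", n)
  stats::cutree(tree, k = k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an hclust tree as a merge list
#'
#' @param tree An `hclust` tree.
#' @return `list(merge, height, labels, order)` suitable for JSON export.
#' @export
treeToMergeList <- function(tree) {
  list(merge = unclass(tree$merge), height = tree$height,
       labels = tree$labels, order = tree$order)
}

#' Classical (Torgerson) MDS embedding of samples
#'
#' Embeds samples by classical metric MDS on Euclidean distances over the
#' probe panel. Coordinates are centred at the origin; the sign of each
#' axis is fixed by forcing the sample with the largest absolute
#' coordinate positive, so embeddings are reproducible. Exactly embeddable
#' distance matrices are reproduced to numerical precision.
#'
#' @param betas [BetaSet-class] or beta matrix.
#' @param probes,samples Optional panel / sample subsets.
#' @param dims Embedding dimension (default 2); needs `dims + 1` samples.
#' @return Numeric samples x dims coordinate matrix.
#' @export
mdsEmbed <- function(betas, probes = NULL, samples = NULL, dims = 2) {
  b <- .beta_matrix(betas)
  if (!is.null(probes)) b <- b[probes, , drop = FALSE]
  if (!is.null(samples)) b <- b[, samples, drop = FALSE]
  if (ncol(b) < dims + 1)
    .stopf("need >= %d samples for a %d-d embedding", dims + 1, dims)
  d <- stats::dist(t(b))
  if (max(d) < 1e-12) {
    .warnf("all inter-sample distances are (near) zero")
    out <- matrix(0, ncol(b), dims,
                  dimnames = list(colnames(b), paste0("MDS", seq_len(dims))))
    return(out)
  }
  xy <- stats::cmdscale(d, k = dims)
  if (ncol(xy) < dims)  # degenerate geometry: pad with zero axes
    xy <- cbind(xy, matrix(0, nrow(xy), dims - ncol(xy)))
  xy <- sweep(xy, 2, colMeans(xy))
  for (j in seq_len(ncol(xy))) {
    i <- which.max(abs(xy[, j]))
    if (xy[i, j] < 0) xy[, j] <- -xy[, j]
  }
  dimnames(xy) <- list(colnames(b), paste0("MDS", seq_len(dims)))
  xy
}

#' Derive a prognostic signature panel
#'
#' Runs the two-group differential methylation contrast and records the
#' probes passing the stated thresholds (default delta beta > 0.4,
#' p < 0.01 — the salvage-vs-enucleation setting) as a
#' [SignaturePanel-class] with provenance. Panels compose: a second-round
#' derivation between recovered clusters refines the signature.
#'
#' @inheritParams dmTable
#' @param delta_thresh,p_thresh Selection thresholds (strict).
#' @return A [SignaturePanel-class]; empty (with a warning) when no probe
#'   passes.
#' @export
derivePanel <- function(betas, arm_a, arm_b, probes = NULL,
                        annotation = NULL, delta_thresh = 0.4,
                        p_thresh = 0.01, min_per_arm = 3,
                        contrast = "salvage_vs_enucleated") {
  dm <- dmTable(betas, arm_a, arm_b, probes = probes,
                annotation = annotation, delta_thresh = delta_thresh,
                p_thresh = p_thresh, min_per_arm = min_per_arm,
                contrast = contrast)
  rec <- dmRecords(dm)
  keep <- rec$direction != "none"
  probes_df <- rec[keep, c("probe_id", "delta_beta", "p_value", "direction")]
  probes_df <- probes_df[order(probes_df$p_value, probes_df$probe_id), ]
  rownames(probes_df) <- NULL
  if (nrow(probes_df) == 0)
    .warnf("no probe passed (|delta beta| > %g, p < %g); empty panel",
           delta_thresh, p_thresh)
  methods::new("SignaturePanel", contrast = contrast, probes = probes_df,
               deltaThreshold = delta_thresh, pThreshold = p_thresh,
               universeSize = nrow(rec))
}

#' Assign samples to Cluster A / Cluster B with a signature panel
#'
#' Clusters the samples over the panel probes (complete-linkage Euclidean
#' by default) and cuts the tree at `k = 2`. When outcome annotations are
#' available (argument or the `outcome` column of the sample sheet),
#' label "A" goes to the cluster with the larger fraction of salvaged
#' (`"SV"`) samples and "B" to the other, so the label semantics are fixed
#' by the sample sheet rather than tree orientation; without outcomes the
#' labels are "1"/"2". A near-zero mean silhouette marks the forced
#' two-cut as weak separation.
#'
#' @param betas [BetaSet-class] or beta matrix.
#' @param panel A [SignaturePanel-class] (or character vector of probe
#'   ids). Panel probes absent from the matrix are an error.
#' @param samples Optional sample ids (default: all).
#' @param outcomes Optional named outcome vector (`"SV"`, `"PE"`, `"SE"`);
#'   defaults to `colData(betas)$outcome` when present.
#' @param metric,linkage Passed to [clusterSamples()].
#' @return A [ClusterAssignment-class].
#' @export
assignClusters <- function(betas, panel, samples = NULL, outcomes = NULL,
                           metric = "euclidean", linkage = "complete") {
  probes <- if (methods::is(panel, "SignaturePanel")) panelProbes(panel)
            else as.character(panel)
  contrast <- if (methods::is(panel, "SignaturePanel")) panel@contrast
              else "custom"
  b <- .beta_matrix(betas)
  if (!is.null(samples)) b <- b[, samples, drop = FALSE]
  missing_p <- setdiff(probes, rownames(b))
  if (length(missing_p))
    .stopf("panel probes absent from the matrix: %s%s",
           paste(utils::head(missing_p, 10), collapse = ", "),
           if (length(missing_p) > 10) ", ..." else "")
  tree <- clusterSamples(b, probes = probes, metric = metric,
                         linkage = linkage)
  cut2 <- stats::cutree(tree, k = 2)

  if (is.null(outcomes) && methods::is(betas, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(betas)
    if ("outcome" %in% names(cd))
      outcomes <- stats::setNames(cd$outcome, rownames(cd))
  }
  labels <- as.character(cut2)
  if (!is.null(outcomes) && any(!is.na(outcomes[names(cut2)]))) {
    sv_frac <- vapply(1:2, function(g) {
      o <- outcomes[names(cut2)[cut2 == g]]
      mean(o == "SV", na.rm = TRUE)
    }, numeric(1))
    sv_frac[is.nan(sv_frac)] <- -Inf
    a_grp <- which.max(sv_frac)
    labels <- ifelse(cut2 == a_grp, "A", "B")
  }
  names(labels) <- names(cut2)

  d <- .panel_dist(b[probes, names(cut2), drop = FALSE], "euclidean")
  sil <- cluster::silhouette(cut2, d)
  msil <- mean(sil[, "sil_width"])
  weak <- msil < 0.1
  if (weak)
    .warnf("weak separation: mean silhouette %.3f for the forced 2-cut",
           msil)
  methods::new("ClusterAssignment", labels = labels, tree = tree, k = 2,
               panelContrast = contrast, silhouette = msil,
               weakSeparation = weak)
}

#' Exact test of cluster vs outcome (or external subtype)
#'
#' Builds the 2x2 contingency table of cluster label against binarised
#' outcome — salvaged (`"SV"`) versus enucleated (`"PE"` and `"SE"`
#' merged) — or against an external subtype labelling (1/2), and reports
#' the exact (Fisher) two-sided p by hypergeometric enumeration with the
#' doubled-one-tail convention (`p = min(1, 2 * min(lower tail, upper
#' tail))`), the cross-product odds ratio (`Inf` symbolically for zero
#' cells), and the containment statements (cluster A entirely inside the
#' first outcome level, cluster B inside the second) as booleans.
#'
#' @param labels A [ClusterAssignment-class] or named cluster label vector.
#' @param outcomes Named vector over the labelled samples: `"SV"/"PE"/"SE"`
#'   or subtype codes (1/2 or "1"/"2"). Every labelled sample needs one.
#' @return `list(table, odds_ratio, p_value, containment)` where
#'   `containment = c(A_in_first, B_in_second)`.
#' @export
clusterOutcomeTest <- function(labels, outcomes) {
  if (methods::is(labels, "ClusterAssignment")) labels <- clusterLabels(labels)
  if (is.null(names(labels))) .stopf("labels must be named by sample id")
  o <- outcomes[names(labels)]
  if (anyNA(o))
    .stopf("every labelled sample needs an outcome/subtype")
  o <- as.character(o)
  o[o %in% c("PE", "SE")] <- "enucleated"
  lv_o <- if (all(o %in% c("SV", "enucleated"))) c("SV", "enucleated")
          else sort(unique(o))
  if (length(lv_o) != 2) .stopf("outcomes must binarise to two levels")
  lv_c <- sort(unique(labels))
  if (length(lv_c) != 2) .stopf("need exactly two cluster labels")
  tab <- table(factor(labels, levels = lv_c), factor(o, levels = lv_o))
  if (any(rowSums(tab) == 0)) .stopf("a cluster has zero members")
  a <- tab[1, 1]; bb <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  ## exact p: hypergeometric tails for the [1,1] cell given fixed margins
  m <- a + bb; nn <- cc + d; kk <- a + cc
  lower <- stats::phyper(a, kk, (m + nn) - kk, m)
  upper <- 1 - stats::phyper(a - 1, kk, (m + nn) - kk, m)
  p <- min(1, 2 * min(lower, upper))
  or <- if (bb * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (bb * cc)
  list(table = tab, odds_ratio = or, p_value = p,
       containment = c(A_in_first = tab[1, 2] == 0,
                       B_in_second = tab[2, 1] == 0))
}
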