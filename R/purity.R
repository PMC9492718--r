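#' Leukocyte-unmethylation (LUMP) purity scores
#'
#' Estimates per-sample tumor purity from a designated set of probes that
#' are unmethylated in leukocytes: blood contamination pulls their mean
#' beta toward zero, so `score = min(1, mean(beta over LUMP probes) /
#' scale)`. The scale constant 0.85 follows the assay's published
#' convention and is exposed as an argument. The 44-CpG reference list is
#' not built in; callers supply their own set (synthetic cohorts carry a
#' designated one in their truth record).
#'
#' @param betas [BetaSet-class] or beta matrix.
#' @param lump_probes Character vector of LUMP probe ids; probes absent
#'   from the matrix are dropped with a warning, and at least one must
#'   remain.
#' @param scale Scaling constant in (0, 1\]; default 0.85.
#' @return `data.frame` with `sample_id`, `lump_score` (`NA` when a sample
#'   has no unmasked LUMP probe; the pipeline continues with that sample
#'   flagged), and `n_probes` used.
#' @examples
#' b <- matrix(c(0.85, 0.8, 0.4, 0.45), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("pure", "half")))
#' lumpScore(b, c("cg1", "cg2"))
#' @export
lumpScore <- function(betas, lump_probes, scale = 0.85) {
  b <- .beta_matrix(betas)
  if (length(scale) != 1 || scale <= 0 || scale > 1)
    .stopf("scale must lie in (0, 1]")
  present <- intersect(lump_probes, rownames(b))
  if (length(present) < length(lump_probes))
    .warnf("%d LUMP probes absent from the matrix",
           length(lump_probes) - length(present))
  if (length(present) == 0)
    .stopf("no LUMP probe present in the matrix")
  sub <- b[present, , drop = FALSE]
  n <- colSums(!is.na(sub))
  m <- colMeans(sub, na.rm = TRUE)
  score <- ifelse(n > 0, pmin(1, m / scale), NA_real_)
  data.frame(sample_id = colnames(b), lump_score = unname(score),
             n_probes = unname(n), stringsAsFactors = FALSE)
}

#' Gate samples on LUMP purity
#'
#' Removes samples whose purity score is strictly below the threshold
#' (scores exactly at the threshold are retained, matching the printed
#' "<0.5 removed" rule). Samples with an undefined score are removed and
#' flagged.
#'
#' @param results Output of [lumpScore()] (or any data.frame with
#'   `sample_id` and `lump_score`).
#' @param threshold Purity cut, default 0.5.
#' @return Character vector of retained sample ids; the full gating table
#'   (with a `retained` column) is attached as attribute `"gating"`.
#' @export
filterByPurity <- function(results, threshold = 0.5) {
  retained <- !is.na(results$lump_score) &
    results$lump_score >= threshold
  tab <- results
  tab$retained <- retained
  structure(results$sample_id[retained], gating = tab)
}
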