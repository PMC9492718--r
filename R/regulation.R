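#' Overlap differentially expressed genes across two datasets
#'
#' Up-regulated genes are those exceeding the fold-change threshold in BOTH
#' expression tables (down-regulated analogously below the negative
#' threshold); genes present in only one table are excluded and counted in
#' a message. The raw-scale threshold (default fold change 2) is applied
#' once on the log2 scale as `|log2FC| > log2(fold_thresh)`.
#'
#' @param tableA,tableB `data.frame`s with columns `gene` and `log2FC`,
#'   one row per gene.
#' @param fold_thresh Raw-scale fold-change threshold, > 1 (default 2).
#' @return `list(up = gene set, down = gene set)`; disjoint.
#' @examples
#' a <- data.frame(gene = c("g1", "g2"), log2FC = c(1.5, -2))
#' b <- data.frame(gene = c("g1", "g2"), log2FC = c(1.2, -1.4))
#' deOverlap(a, b)
#' @export
deOverlap <- function(tableA, tableB, fold_thresh = 2) {
  if (length(fold_thresh) != 1 || fold_thresh <= 1)
    .stopf("fold_thresh must be > 1")
  lthr <- log2(fold_thresh)
  common <- intersect(tableA$gene, tableB$gene)
  n_only <- length(setdiff(union(tableA$gene, tableB$gene), common))
  if (n_only > 0)
    message(sprintf("%d genes present in one table only were excluded",
                    n_only))
  la <- tableA$log2FC[match(common, tableA$gene)]
  lb <- tableB$log2FC[match(common, tableB$gene)]
  list(up = common[la > lthr & lb > lthr],
       down = common[la < -lthr & lb < -lthr])
}

#' Call genes putatively regulated by DNA methylation
#'
#' Conjunctive integration of differential methylation with differential
#' expression: a gene is called `promoter_hypo_up` when at least one of its
#' promoter probes is hypomethylated past the threshold (p passing) AND the
#' gene is in the up-regulated set; the other three categories follow the
#' analogous sign rules (`body_hyper_up`, `promoter_hyper_down`,
#' `body_hypo_down`). A gene matching several categories is reported in
#' all of them, with the primary category being the one holding its
#' largest-|delta beta| supporting probe. With empty expression sets the
#' call list is empty (integration is conjunctive by construction).
#'
#' @param dm [DMTable-class] for the tumor-vs-reference contrast.
#' @param annotation Probe annotation (`probe_id`, `gene`, `region_class`).
#' @param up,down Gene sets from [deOverlap()].
#' @param delta_thresh Delta-beta threshold (default 0.3, strict).
#' @param p_thresh P threshold; defaults to the table's. Set `use_p =
#'   FALSE` to reproduce a delta-beta-only probe selection.
#' @param use_p Apply the p filter in addition to delta beta (default
#'   TRUE).
#' @param log2fc Optional named vector of gene-level log2 fold changes to
#'   report alongside the calls.
#' @return `data.frame` with columns `gene`, `category`, `n_probes`,
#'   `probe_ids` (semicolon-delimited), `max_abs_delta`, `log2FC`,
#'   `primary`.
#' @export
callRegulatedGenes <- function(dm, annotation, up, down, delta_thresh = 0.3,
                               p_thresh = NULL, use_p = TRUE,
                               log2fc = NULL) {
  rec <- dmRecords(dm)
  if (is.null(p_thresh)) p_thresh <- dm@pThreshold
  pass_p <- if (use_p) !is.na(rec$p_value) & rec$p_value < p_thresh
            else rep(TRUE, nrow(rec))
  idx <- match(rec$probe_id, annotation$probe_id)
  gene <- annotation$gene[idx]
  cls <- annotation$region_class[idx]

  empty <- data.frame(gene = character(), category = character(),
                      n_probes = integer(), probe_ids = character(),
                      max_abs_delta = numeric(), log2FC = numeric(),
                      primary = logical(), stringsAsFactors = FALSE)
  rules <- list(
    promoter_hypo_up = list(cls = "promoter", sgn = -1, genes = up),
    body_hyper_up = list(cls = "body", sgn = +1, genes = up),
    promoter_hyper_down = list(cls = "promoter", sgn = +1, genes = down),
    body_hypo_down = list(cls = "body", sgn = -1, genes = down))

  out <- empty
  for (cat in names(rules)) {
    r <- rules[[cat]]
    hit <- pass_p & !is.na(gene) & gene != "" & cls == r$cls &
      (if (r$sgn > 0) rec$delta_beta > delta_thresh
       else rec$delta_beta < -delta_thresh) &
      gene %in% r$genes
    if (!any(hit)) next
    sp <- split(which(hit), gene[hit])
    rows <- do.call(rbind, lapply(names(sp), function(g) {
      i <- sp[[g]]
      data.frame(gene = g, category = cat, n_probes = length(i),
                 probe_ids = paste(rec$probe_id[i], collapse = ";"),
                 max_abs_delta = max(abs(rec$delta_beta[i])),
                 log2FC = if (!is.null(log2fc) && g %in% names(log2fc))
                   unname(log2fc[g]) else NA_real_,
                 primary = FALSE, stringsAsFactors = FALSE)
    }))
    out <- rbind(out, rows)
  }
  if (nrow(out)) {
    ## primary category = the one holding the probe of largest |delta beta|
    out <- out[order(out$gene, -out$max_abs_delta, out$category), ]
    out$primary <- !duplicated(out$gene)
    rownames(out) <- NULL
  }
  out
}
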