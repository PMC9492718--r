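## Vectorised Welch machinery shared by welchT() and dmTable(). XA and XB
## are probes x samples matrices for the two arms; NA cells are ignored
## per probe (pairwise-complete arms).
.welch_rows <- function(XA, XB) {
  a <- .row_stats(XA)
  b <- .row_stats(XB)
  se2a <- a$var / a$n
  se2b <- b$var / b$n
  se2 <- se2a + se2b
  t_stat <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / (se2a^2 / (a$n - 1) + se2b^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  degenerate <- rep(FALSE, length(t_stat))

  ## both arms zero variance: equal means -> t = 0, p = 1; unequal means ->
  ## p = 0 with a degenerate flag (the difference is exact, not estimated)
  zz <- !is.na(a$var) & !is.na(b$var) & a$var == 0 & b$var == 0
  eq <- zz & a$mean == b$mean
  ne <- zz & a$mean != b$mean
  t_stat[eq] <- 0; df[eq] <- NA_real_; p[eq] <- 1
  t_stat[ne] <- sign(a$mean[ne] - b$mean[ne]) * Inf
  df[ne] <- NA_real_; p[ne] <- 0; degenerate[ne] <- TRUE

  data.frame(n_a = a$n, n_b = b$n, mean_a = a$mean, mean_b = b$mean,
             delta_beta = a$mean - b$mean, t_stat = t_stat, df = df,
             p_value = p, degenerate = degenerate)
}

#' Two-sided Welch's t-test
#'
#' Unequal-variance two-sample t: `t = (mean(x) - mean(y)) /
#' sqrt(s2x/nx + s2y/ny)`, degrees of freedom by the Welch--Satterthwaite
#' approximation, two-sided p from the t distribution. When both groups
#' have zero variance the test degenerates: equal means give `t = 0,
#' p = 1`; unequal means give `p = 0` with `degenerate = TRUE`.
#'
#' @param x,y Numeric vectors with at least 2 non-missing values each.
#' @return `list(t_stat, df, p_value, degenerate)`.
#' @examples
#' welchT(c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.8))  # t = -6.124, df = 4
#' @export
welchT <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    .stopf("each group needs >= 2 non-missing values")
  r <- .welch_rows(matrix(x, nrow = 1), matrix(y, nrow = 1))
  list(t_stat = r$t_stat, df = r$df, p_value = r$p_value,
       degenerate = r$degenerate)
}

#' Probe-level differential methylation table
#'
#' Runs the two-sided Welch's t-test on every eligible probe for one
#' two-group contrast, with delta beta oriented arm A minus arm B (so
#' "hyper" means elevated in arm A). Probes are tested on pairwise-complete
#' samples; a probe is skipped (and listed with its reason) when either arm
#' has fewer than `min_per_arm` unmasked values.
#'
#' @param betas [BetaSet-class] or beta matrix.
#' @param arm_a,arm_b Disjoint sample id vectors (contrast arm and
#'   reference arm).
#' @param probes Optional probe universe (default: all rows).
#' @param annotation Optional probe annotation; attaches `region_class` to
#'   each record.
#' @param delta_thresh,p_thresh Thresholds recorded in the table and used
#'   for the per-record direction call (strict inequalities).
#' @param min_per_arm Minimum unmasked values per arm (default 3, the
#'   minimum for a variance plus one).
#' @param contrast Label stored with the table.
#' @return A [DMTable-class].
#' @export
dmTable <- function(betas, arm_a, arm_b, probes = NULL, annotation = NULL,
                    delta_thresh = 0.3, p_thresh = 0.05, min_per_arm = 3,
                    contrast = "A_vs_B") {
  b <- .beta_matrix(betas)
  if (length(intersect(arm_a, arm_b)))
    .stopf("contrast arms overlap: %s",
           paste(intersect(arm_a, arm_b), collapse = ", "))
  missing_s <- setdiff(c(arm_a, arm_b), colnames(b))
  if (length(missing_s))
    .stopf("samples absent from the matrix: %s",
           paste(missing_s, collapse = ", "))
  if (length(arm_a) < 2 || length(arm_b) < 2)
    .stopf("each arm needs >= 2 samples")
  if (is.null(probes)) probes <- rownames(b)
  probes <- intersect(probes, rownames(b))

  XA <- b[probes, arm_a, drop = FALSE]
  XB <- b[probes, arm_b, drop = FALSE]
  st <- .welch_rows(XA, XB)
  ok <- st$n_a >= min_per_arm & st$n_b >= min_per_arm

  skipped <- data.frame(probe_id = probes[!ok],
                        reason = sprintf(
                          "unmasked values below %d per arm (A=%d, B=%d)",
                          min_per_arm, st$n_a[!ok], st$n_b[!ok]),
                        stringsAsFactors = FALSE)
  rec <- st[ok, c("mean_a", "mean_b", "delta_beta", "t_stat", "df",
                  "p_value", "degenerate")]
  rec <- cbind(data.frame(probe_id = probes[ok], stringsAsFactors = FALSE),
               rec)
  rec$direction <- "none"
  rec$direction[rec$delta_beta > delta_thresh &
                  rec$p_value < p_thresh] <- "hyper"
  rec$direction[rec$delta_beta < -delta_thresh &
                  rec$p_value < p_thresh] <- "hypo"
  rec$region_class <- if (!is.null(annotation))
    annotation$region_class[match(rec$probe_id, annotation$probe_id)]
  else NA_character_
  rownames(rec) <- NULL

  methods::new("DMTable", contrast = contrast, records = rec,
               skipped = skipped, deltaThreshold = delta_thresh,
               pThreshold = p_thresh)
}

#' Select differentially methylated probes
#'
#' Applies the delta-beta and p thresholds with strict inequalities, as the
#' selection rules are printed (">0.3", "p < 0.05"): hypermethylated probes
#' have `delta_beta > delta_thresh`, hypomethylated probes
#' `delta_beta < -delta_thresh`, both with `p_value < p_thresh`. The two
#' sets are disjoint for any positive threshold.
#'
#' @param table A [DMTable-class] (or its records data.frame).
#' @param delta_thresh,p_thresh Thresholds in (0, 1); default to the
#'   table's own.
#' @return `list(hyper = probe ids, hypo = probe ids)`.
#' @export
selectDM <- function(table, delta_thresh = NULL, p_thresh = NULL) {
  rec <- if (methods::is(table, "DMTable")) dmRecords(table) else table
  if (is.null(delta_thresh))
    delta_thresh <- if (methods::is(table, "DMTable")) table@deltaThreshold
                    else .stopf("delta_thresh required")
  if (is.null(p_thresh))
    p_thresh <- if (methods::is(table, "DMTable")) table@pThreshold
                else .stopf("p_thresh required")
  if (delta_thresh <= 0 || delta_thresh >= 1 || p_thresh <= 0 ||
      p_thresh >= 1)
    .stopf("thresholds must lie in (0, 1)")
  sig <- !is.na(rec$p_value) & rec$p_value < p_thresh
  list(hyper = rec$probe_id[sig & rec$delta_beta > delta_thresh],
       hypo = rec$probe_id[sig & rec$delta_beta < -delta_thresh])
}

#' Hyper/hypo direction fractions
#'
#' Fractions of the selected probes that are hyper- vs hypomethylated in
#' the contrast arm; the two fractions sum to 1.
#'
#' @param hyper,hypo Probe id sets (at least one non-empty).
#' @return Named numeric vector `c(hyper = , hypo = )`.
#' @examples
#' directionFractions(paste0("cg", 1:19), paste0("cg", 20:100))
#' @export
directionFractions <- function(hyper, hypo) {
  n <- length(hyper) + length(hypo)
  if (n == 0) .stopf("no selected probes: both direction sets are empty")
  c(hyper = length(hyper) / n, hypo = length(hypo) / n)
}

#' Classify genic region from transcript-region tokens
#'
#' Promoter probes sit at the transcription start site (TSS200 or TSS1500),
#' the 5'UTR or the first exon; gene-body probes within gene bodies or
#' 3'UTRs; everything else is "other". When a probe's transcripts disagree,
#' promoter takes precedence over body over other (the biologically
#' conservative promoter superset). Unknown tokens are ignored with a
#' warning.
#'
#' @param tokens One semicolon-delimited token string per probe (character
#'   vector, vectorised over probes), or a list of per-probe token vectors.
#' @return Character vector of classes in
#'   `c("promoter", "body", "other")`, one per probe.
#' @examples
#' classifyRegion("TSS1500")             # promoter
#' classifyRegion("TSS200;Body")         # promoter (precedence)
#' classifyRegion(list(c("Body", "3'UTR"), character(0)))  # body, other
#' @export
classifyRegion <- function(tokens) {
  promoter <- c("TSS200", "TSS1500", "5'UTR", "1stExon")
  body <- c("Body", "3'UTR")
  known <- c(promoter, body, "ExonBnd", "")
  if (is.list(tokens)) {
    toks <- tokens
  } else {
    toks <- strsplit(as.character(tokens), ";", fixed = TRUE)
    toks[lengths(toks) == 0] <- list("")
  }
  unknown <- setdiff(unique(unlist(toks)), known)
  if (length(unknown))
    .warnf("ignoring unknown region token(s): %s",
           paste(unknown, collapse = ", "))
  vapply(toks, function(tk) {
    if (any(tk %in% promoter)) "promoter"
    else if (any(tk %in% body)) "body"
    else "other"
  }, character(1))
}

#' Genomic-location distribution of DM probes
#'
#' For the hypermethylated set, the hypomethylated set and the whole probe
#' universe ("total"), the fraction of probes in each region class
#' (promoter / gene body / other), plus the enhancer fraction reported as
#' an additional overlapping flag rather than an exclusive class.
#'
#' @param hyper,hypo Probe id sets, subsets of `universe`.
#' @param universe Non-empty probe id set (e.g. the filtered array).
#' @param annotation Probe annotation with `region_class` and `enhancer`.
#' @return `data.frame` with rows `hyper`, `hypo`, `total` and columns
#'   `promoter`, `body`, `other`, `enhancer`, `n`.
#' @export
regionEnrichment <- function(hyper, hypo, universe, annotation) {
  if (length(universe) == 0) .stopf("universe is empty")
  if (!all(hyper %in% universe) || !all(hypo %in% universe))
    .stopf("hyper/hypo sets must be subsets of the universe")
  one <- function(ids) {
    idx <- match(ids, annotation$probe_id)
    if (anyNA(idx)) .stopf("probes missing from the annotation")
    cls <- annotation$region_class[idx]
    n <- length(ids)
    c(promoter = sum(cls == "promoter") / n,
      body = sum(cls == "body") / n,
      other = sum(cls == "other") / n,
      enhancer = sum(annotation$enhancer[idx]) / n,
      n = n)
  }
  out <- rbind(hyper = if (length(hyper)) one(hyper) else
                 c(promoter = NA, body = NA, other = NA, enhancer = NA,
                   n = 0),
               hypo = if (length(hypo)) one(hypo) else
                 c(promoter = NA, body = NA, other = NA, enhancer = NA,
                   n = 0),
               total = one(universe))
  as.data.frame(out)
}
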