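#' Compute beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + offset) per cell, the standard array methylation
#' fraction. Cells whose denominator is zero are masked (`NA`).
#'
#' @param M,U Nonnegative numeric matrices (probes x samples) with identical
#'   dimnames.
#' @param offset Nonnegative stabilising constant added to the denominator;
#'   0 by default (the plain ratio).
#' @return A [BetaSet-class].
#' @examples
#' M <- matrix(c(1000, 0, 500, 300), 2, 2,
#'             dimnames = list(c("cg1", "cg2"), c("s1", "s2")))
#' U <- matrix(c(1000, 500, 0, 100), 2, 2, dimnames = dimnames(M))
#' betaValues(betaFromIntensities(M, U))
#' @export
betaFromIntensities <- function(M, U, offset = 0) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (!identical(dim(M), dim(U)) ||
      !identical(dimnames(M), dimnames(U)))
    .stopf("M and U must share identical probe and sample indexing")
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    .stopf("intensities must be nonnegative")
  if (length(offset) != 1 || offset < 0)
    .stopf("offset must be a nonnegative scalar")
  den <- M + U + offset
  beta <- ifelse(den > 0, M / den, NA_real_)
  dimnames(beta) <- dimnames(M)
  BetaSet(beta)
}

#' Mask beta values failing detection
#'
#' Cells whose detection p value exceeds `alpha` are masked; all other
#' cells are unchanged. Re-masking with the same `alpha` is idempotent.
#'
#' @param betas [BetaSet-class] or beta matrix.
#' @param detp Numeric matrix of per-cell detection p values, aligned with
#'   `betas` (same dimensions and dimnames).
#' @param alpha Detection threshold; cells with `detp > alpha` are removed
#'   (default 0.05).
#' @return Object of the same type with the extra cells masked.
#' @export
maskByDetection <- function(betas, detp, alpha = 0.05) {
  b <- .beta_matrix(betas)
  detp <- as.matrix(detp)
  if (!identical(dim(b), dim(detp)) ||
      !identical(dimnames(b), dimnames(detp)))
    .stopf("detection-p matrix is not aligned with the beta matrix")
  b[!is.na(detp) & detp > alpha] <- NA_real_
  if (methods::is(betas, "SummarizedExperiment")) {
    SummarizedExperiment::assay(betas, "beta") <- b
    return(betas)
  }
  b
}

#' Filter probes by exclusion flags
#'
#' Standard pre-analysis probe removal: probes linked to known
#' polymorphisms, probes on the X and Y chromosomes, and aging-related
#' probes (the aging list is user-supplied as the `flag_age` column; no
#' built-in clock list).
#'
#' @param annotation Probe annotation `data.frame` with logical columns
#'   `flag_snp`, `flag_sexchrom`, `flag_age`.
#' @param drop_flags Subset of `c("snp", "sexchrom", "age")`; all three by
#'   default. Unknown names are an error.
#' @return Character vector of surviving probe ids, annotation order
#'   preserved.
#' @export
filterProbes <- function(annotation,
                         drop_flags = c("snp", "sexchrom", "age")) {
  if (nrow(annotation) == 0) .stopf("annotation is empty")
  known <- c("snp", "sexchrom", "age")
  if (length(drop_flags) && !all(drop_flags %in% known))
    .stopf("unknown flag name(s): %s",
           paste(setdiff(drop_flags, known), collapse = ", "))
  drop <- rep(FALSE, nrow(annotation))
  for (f in drop_flags)
    drop <- drop | annotation[[paste0("flag_", f)]]
  annotation$probe_id[!drop]
}

#' Intersect probe sets across array platforms
#'
#' Returns probes whose platform membership contains every requested
#' platform — the cross-platform intersection used when merging EPIC data
#' with HM450 reference cohorts.
#'
#' @param annotation Probe annotation with a semicolon-delimited `platforms`
#'   column.
#' @param platforms Non-empty character vector, e.g. `c("EPIC", "HM450")`.
#' @return Character vector of probe ids, order preserved.
#' @export
intersectPlatforms <- function(annotation, platforms) {
  if (length(platforms) == 0) .stopf("platform list must be non-empty")
  memb <- strsplit(annotation$platforms, ";", fixed = TRUE)
  keep <- vapply(memb, function(m) all(platforms %in% m), logical(1))
  annotation$probe_id[keep]
}

#' Read / write beta matrices, annotations, sample sheets and truth records
#'
#' Plain-text serialisation: beta matrices as TSV with a `probe_id` key
#' column (masked cells written as `NA`), annotations and sample sheets as
#' CSV (region tokens and platform memberships semicolon-delimited within a
#' cell, mirroring manifest conventions), cohort truth records as JSON.
#' A write/read round trip reproduces beta values to full printed precision
#' and the exact mask.
#'
#' @param x Object to write.
#' @param path File path.
#' @param annotation,sampleSheet Optional tables attached on read.
#' @return Readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @name methylIO
NULL

#' @rdname methylIO
#' @export
writeBetaMatrix <- function(x, path) {
  b <- .beta_matrix(x)
  dt <- data.table::data.table(probe_id = rownames(b))
  dt <- cbind(dt, data.table::as.data.table(b))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname methylIO
#' @export
readBetaMatrix <- function(path, annotation = NULL, sampleSheet = NULL) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "NA",
                          data.table = FALSE)
  b <- as.matrix(dt[, -1, drop = FALSE])
  rownames(b) <- dt[[1]]
  storage.mode(b) <- "double"
  BetaSet(b, annotation = annotation, sampleSheet = sampleSheet)
}

#' @rdname methylIO
#' @export
writeProbeAnnotation <- function(x, path) {
  data.table::fwrite(x, path, na = "NA", quote = TRUE)
  invisible(path)
}

#' @rdname methylIO
#' @export
readProbeAnnotation <- function(path) {
  ann <- data.table::fread(path, na.strings = "NA", data.table = FALSE)
  for (col in c("region_tokens", "gene", "platforms"))
    if (col %in% names(ann)) ann[[col]][is.na(ann[[col]])] <- ""
  ann
}

#' @rdname methylIO
#' @export
writeSampleSheet <- function(x, path) {
  data.table::fwrite(x, path, na = "NA", quote = TRUE)
  invisible(path)
}

#' @rdname methylIO
#' @export
readSampleSheet <- function(path) {
  data.table::fread(path, na.strings = "NA", data.table = FALSE)
}

#' @rdname methylIO
#' @export
writeCohortTruth <- function(x, path) {
  obj <- list(
    plantedProbes = x@plantedProbes,
    subtypeLabels = as.list(x@subtypeLabels),
    pairing = as.list(x@pairing),
    purity = as.list(x@purity),
    regulatedGenes = x@regulatedGenes,
    noisePrecision = as.list(x@noisePrecision),
    lumpProbes = x@lumpProbes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname methylIO
#' @export
readCohortTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(d, cols) {
    if (is.null(d) || length(d) == 0)
      return(stats::setNames(
        data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  methods::new(
    "CohortTruth",
    plantedProbes = lapply(obj$plantedProbes, as_df,
                           cols = c("probe_id", "delta")),
    subtypeLabels = stats::setNames(as.integer(unlist(obj$subtypeLabels)),
                                    names(obj$subtypeLabels)),
    pairing = stats::setNames(as.character(unlist(obj$pairing)),
                              names(obj$pairing)),
    purity = stats::setNames(as.numeric(unlist(obj$purity)),
                             names(obj$purity)),
    regulatedGenes = as_df(obj$regulatedGenes,
                           c("gene", "category", "probe_id", "delta")),
    noisePrecision = stats::setNames(as.numeric(unlist(obj$noisePrecision)),
                                     names(obj$noisePrecision)),
    lumpProbes = as.character(unlist(obj$lumpProbes)))
}
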