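#' Pairwise squared Pearson correlation between sample groups
#'
#' For every pair (a, b) of samples from the two groups, the squared
#' Pearson correlation of their beta profiles over pairwise-complete
#' probes — the concordance convention of paired tumor/AH and
#' input-titration comparisons. r-squared is the square of Pearson r, not
#' a regression R-squared through the origin; the signed r is reported
#' alongside it. Pairs with a constant vector or fewer than `min_shared`
#' shared probes are flagged undefined (`NA`), not 0.
#'
#' @param betas [BetaSet-class] or beta matrix.
#' @param samples_a,samples_b Sample id vectors.
#' @param min_shared Minimum pairwise-complete probes per pair (default
#'   100).
#' @return `list(r2, r, n, flag)` of a x b matrices; `flag` is `""`,
#'   `"constant"` or `"too_few_shared"`.
#' @export
pairwiseR2 <- function(betas, samples_a, samples_b, min_shared = 100) {
  b <- .beta_matrix(betas)
  missing_s <- setdiff(c(samples_a, samples_b), colnames(b))
  if (length(missing_s))
    .stopf("samples absent from the matrix: %s",
           paste(missing_s, collapse = ", "))
  na <- length(samples_a); nb <- length(samples_b)
  dn <- list(samples_a, samples_b)
  r <- matrix(NA_real_, na, nb, dimnames = dn)
  n <- matrix(0L, na, nb, dimnames = dn)
  flag <- matrix("", na, nb, dimnames = dn)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    x <- b[, samples_a[i]]; y <- b[, samples_b[j]]
    ok <- !is.na(x) & !is.na(y)
    n[i, j] <- sum(ok)
    if (n[i, j] < min_shared) { flag[i, j] <- "too_few_shared"; next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      flag[i, j] <- "constant"; next
    }
    r[i, j] <- stats::cor(x[ok], y[ok])
  }
  list(r2 = r^2, r = r, n = n, flag = flag)
}

#' Do declared tumor-AH pairs win the concordance contest?
#'
#' For each AH sample, checks whether the tumor with the highest
#' r-squared is its declared pair. Ties at the maximum are reported as
#' ties and count as failures.
#'
#' @param r2 An a x b r-squared matrix (AH rows, tumor columns), e.g.
#'   `pairwiseR2(...)$r2`.
#' @param pairing Named character vector AH id -> tumor id covering every
#'   AH row.
#' @return `list(report = data.frame(ah, declared, best, match, tie),
#'   fraction = proportion of AH samples whose best match is the declared
#'   pair)`.
#' @export
bestMatchReport <- function(r2, pairing) {
  if (is.list(r2) && !is.null(r2$r2)) r2 <- r2$r2
  ah <- rownames(r2)
  if (!all(ah %in% names(pairing)))
    .stopf("pairing must cover all AH samples: missing %s",
           paste(setdiff(ah, names(pairing)), collapse = ", "))
  rows <- lapply(ah, function(s) {
    v <- r2[s, ]
    if (all(is.na(v)))
      return(data.frame(ah = s, declared = pairing[[s]],
                        best = NA_character_, match = FALSE, tie = FALSE,
                        stringsAsFactors = FALSE))
    mx <- max(v, na.rm = TRUE)
    best <- colnames(r2)[!is.na(v) & v == mx]
    tie <- length(best) > 1
    data.frame(ah = s, declared = pairing[[s]],
               best = best[1], match = !tie && best[1] == pairing[[s]],
               tie = tie, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(report = report, fraction = mean(report$match))
}

#' Input-mass titration curve of concordance
#'
#' Emulates the low-input titration: for each noise precision kappa
#' (kappa maps monotonically to input DNA mass), draws `replicates` noisy
#' re-reads of the clean profile under the mean-preserving beta model and
#' reports the mean squared Pearson correlation to the truth. Mean
#' r-squared is nondecreasing in kappa in expectation.
#'
#' @param truth Clean beta vector.
#' @param kappa_levels Vector of positive precisions.
#' @param replicates Replicates per level (>= 1).
#' @param seed Integer seed.
#' @return `data.frame(kappa, mean_r2, n_replicates)`, sorted by kappa.
#' @export
titrationCurve <- function(truth, kappa_levels, replicates = 3, seed = 1) {
  if (any(kappa_levels <= 0)) .stopf("kappa levels must be > 0")
  if (replicates < 1) .stopf("replicates must be >= 1")
  kappa_levels <- sort(kappa_levels)
  set.seed(childSeed(seed, 4))
  mean_r2 <- vapply(kappa_levels, function(k) {
    r2 <- vapply(seq_len(replicates), function(i) {
      noisy <- .rbeta_mu(truth, k)
      stats::cor(noisy, truth)^2
    }, numeric(1))
    mean(r2)
  }, numeric(1))
  data.frame(kappa = kappa_levels, mean_r2 = mean_r2,
             n_replicates = replicates)
}
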