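## Internal helpers shared across modules.

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from one integer seed. Functions that
#' need several independent streams derive them with this splitter so that a
#' single `--seed` reproduces every draw. Results stay below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param stream Integer stream index (>= 0).
#' @return An integer seed usable with [set.seed()].
#' @export
childSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(stream), length(stream) == 1L)
  as.integer((abs(as.double(seed)) %% 2147000000 + 104729 * (stream + 1)) %%
               2147483647)
}

## Mean-preserving beta draw with mean mu and concentration kappa:
## X ~ Beta(mu * kappa, (1 - mu) * kappa), E[X] = mu, Var = mu(1-mu)/(kappa+1).
## mu exactly 0 or 1 is degenerate and returned unchanged; kappa = Inf means
## no noise. Vectorised over mu.
.rbeta_mu <- function(mu, kappa) {
  if (any(mu < 0 | mu > 1, na.rm = TRUE))
    .stopf("beta means must lie in [0, 1]")
  if (!is.finite(kappa)) return(mu)
  out <- mu
  idx <- which(!is.na(mu) & mu > 0 & mu < 1)
  if (length(idx))
    out[idx] <- stats::rbeta(length(idx), mu[idx] * kappa,
                             (1 - mu[idx]) * kappa)
  out
}

## Accept either a BetaSet / SummarizedExperiment or a plain numeric matrix.
.beta_matrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(SummarizedExperiment::assay(x, "beta"))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    .stopf("expected a BetaSet or a numeric probes x samples matrix")
  x
}

## Row means / variances / counts over unmasked cells, all vectorised.
## Variance uses centred residuals so constant rows give exactly zero.
.row_stats <- function(x) {
  n <- rowSums(!is.na(x))
  s <- rowSums(x, na.rm = TRUE)
  m <- ifelse(n > 0, s / n, NA_real_)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  v <- ifelse(n > 1, ss / (n - 1), NA_real_)
  ## variances at rounding-noise level are constant rows in disguise
  v[!is.na(v) & v < 1e-24] <- 0
  list(n = n, mean = m, var = v)
}
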