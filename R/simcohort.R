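#' Simulate a manifest-style probe annotation
#'
#' Generates a probe annotation table with the structure of a methylation
#' array manifest: chromosome and position, gene symbol, transcript-region
#' tokens, an enhancer flag, exclusion flags (polymorphism-linked, sex
#' chromosome, aging-related) and platform membership. The sex-chromosome
#' flag is kept consistent with the chromosome (true iff chrX/chrY).
#'
#' @param n_probes,n_genes Positive integers.
#' @param region_mix Proportions over `c(promoter, body, other)`, summing
#'   to 1.
#' @param flag_rates Rates for `c(snp, sexchrom, age)` flags, assigned
#'   independently.
#' @param enhancer_rate Rate of the (overlapping) enhancer flag.
#' @param hm450_rate Fraction of probes also present on the HM450 platform
#'   (all probes carry EPIC membership).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return `data.frame` with columns `probe_id`, `chrom`, `pos`, `gene`,
#'   `region_tokens` (semicolon-delimited), `enhancer`, `flag_snp`,
#'   `flag_sexchrom`, `flag_age`, `platforms` (semicolon-delimited),
#'   `region_class`.
#' @examples
#' ann <- simulateAnnotation(100, 20, seed = 1)
#' table(ann$region_class)
#' @export
simulateAnnotation <- function(n_probes, n_genes,
                               region_mix = c(promoter = 0.40, body = 0.35,
                                              other = 0.25),
                               flag_rates = c(snp = 0.02, sexchrom = 0.03,
                                              age = 0.01),
                               enhancer_rate = 0.10,
                               hm450_rate = 0.80,
                               seed = 1) {
  if (length(n_probes) != 1 || n_probes < 1 || n_probes != round(n_probes))
    .stopf("n_probes must be a positive integer")
  if (length(n_genes) != 1 || n_genes < 1 || n_genes != round(n_genes))
    .stopf("n_genes must be a positive integer")
  region_mix <- region_mix[c("promoter", "body", "other")]
  if (anyNA(region_mix) || any(region_mix < 0 | region_mix > 1))
    .stopf("region_mix needs proportions in [0,1] named promoter/body/other")
  if (abs(sum(region_mix) - 1) > 1e-9)
    .stopf("region_mix must sum to 1")
  flag_rates <- flag_rates[c("snp", "sexchrom", "age")]
  if (anyNA(flag_rates) || any(flag_rates < 0 | flag_rates > 1))
    .stopf("flag_rates needs rates in [0,1] named snp/sexchrom/age")

  set.seed(childSeed(seed, 0))
  probe_id <- sprintf("cg%08d", seq_len(n_probes))
  region_class <- sample(c("promoter", "body", "other"), n_probes,
                         replace = TRUE, prob = region_mix)
  tokens <- character(n_probes)
  ip <- region_class == "promoter"
  ib <- region_class == "body"
  io <- region_class == "other"
  tokens[ip] <- sample(c("TSS200", "TSS1500", "5'UTR", "1stExon"),
                       sum(ip), replace = TRUE)
  tokens[ib] <- sample(c("Body", "3'UTR"), sum(ib), replace = TRUE)
  tokens[io] <- sample(c("", "ExonBnd"), sum(io), replace = TRUE,
                       prob = c(0.8, 0.2))

  flag_sexchrom <- stats::runif(n_probes) < flag_rates[["sexchrom"]]
  chrom <- character(n_probes)
  chrom[flag_sexchrom] <- sample(c("chrX", "chrY"), sum(flag_sexchrom),
                                 replace = TRUE, prob = c(0.8, 0.2))
  chrom[!flag_sexchrom] <- sample(paste0("chr", 1:22), sum(!flag_sexchrom),
                                  replace = TRUE)
  pos <- sample.int(2e8L, n_probes, replace = TRUE)

  genes <- sprintf("GENE%05d", seq_len(n_genes))
  gene <- character(n_probes)
  has_gene <- tokens != ""
  gene[has_gene] <- sample(genes, sum(has_gene), replace = TRUE)

  data.frame(
    probe_id = probe_id,
    chrom = chrom,
    pos = pos,
    gene = gene,
    region_tokens = tokens,
    enhancer = stats::runif(n_probes) < enhancer_rate,
    flag_snp = stats::runif(n_probes) < flag_rates[["snp"]],
    flag_sexchrom = flag_sexchrom,
    flag_age = stats::runif(n_probes) < flag_rates[["age"]],
    platforms = ifelse(stats::runif(n_probes) < hm450_rate,
                       "EPIC;HM450", "EPIC"),
    region_class = region_class,
    stringsAsFactors = FALSE)
}

## Pick n probes whose baseline mean allows a planted shift of `delta`
## (mean + delta must stay in [0, 1] with a small safety margin).
.pick_plantable <- function(pool, mu0, delta, n, margin = 0.02) {
  ok <- if (delta >= 0) pool[mu0[pool] <= 1 - delta - margin]
        else pool[mu0[pool] >= -delta + margin]
  if (length(ok) < n)
    .stopf("only %d probes can carry a planted delta of %+.2f (need %d)",
           length(ok), delta, n)
  sample(ok, n)
}

#' Simulate a methylation cohort with planted effects
#'
#' Builds a cohort with the statistical structure the downstream analysis
#' assumes: a bimodal genome-wide baseline (modes near 0.1 and 0.9), tumor
#' samples shifted at planted probe panels, two latent tumor subtypes
#' carrying an additional disjoint panel, paired aqueous-humor (AH) samples
#' as noisy re-reads of their tumor's latent profile, leukocyte profiles
#' unmethylated at a designated LUMP probe set, and observation noise from a
#' mean-preserving beta model with concentration `kappa` (larger kappa =
#' more input DNA = less noise). Each tumor/retina/leukocyte sample first
#' receives an individual latent profile (biological heterogeneity,
#' `kappa_individual`) and is then observed with its role's `kappa`.
#'
#' @param annotation Probe annotation from [simulateAnnotation()] (or the
#'   same column contract).
#' @param design Named integer vector of group sizes over
#'   `retina`, `tumor_subtype1`, `tumor_subtype2`, `AH_paired`, `leukocyte`.
#'   Unknown role names are an error. `AH_paired` must not exceed the tumor
#'   count; AH sample `i` is paired with the `i`-th tumor.
#' @param effects List with elements `tumor = list(n_probes, delta)` (the
#'   tumor-vs-retina panel, half hyper / half hypo) and
#'   `subtype = list(n_probes, delta)` (subtype-2-vs-subtype-1 panel,
#'   disjoint from the tumor panel by default).
#' @param regulation Optional `list(n_per_category, delta)`: plants
#'   `n_per_category` genes in each of the four methylation-regulation
#'   categories (`promoter_hypo_up`, `body_hyper_up`, `promoter_hyper_down`,
#'   `body_hypo_down`) by shifting one suitable probe per gene in the tumor
#'   contrast; recorded in the truth for [simulateExpression()].
#' @param kappa Named numeric vector of observation precisions per role
#'   (`retina`, `tumor`, `AH`, `leukocyte`), all > 0.
#' @param kappa_individual Precision of per-sample latent (biological)
#'   variation around the group mean profile; `Inf` disables it.
#' @param baseline List: `modes` (two means of the bimodal baseline),
#'   `concentration`, `weight` (mixture weight of the low mode).
#' @param n_lump Number of designated LUMP probes (methylated in tissue,
#'   unmethylated in leukocytes).
#' @param lump_beta Named vector `c(tissue=, leukocyte=)` of LUMP-probe
#'   baseline means.
#' @param purity Optional purity in \[0, 1\] for tumor and AH samples: a
#'   scalar, or a vector named by sample id. Latent tumor/AH means are mixed
#'   with the leukocyte mean profile at that proportion.
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return `list(betas = BetaSet, sheet = data.frame, truth = CohortTruth)`.
#' @examples
#' ann <- simulateAnnotation(2000, 200, seed = 1)
#' sim <- simulateCohort(ann, design = c(retina = 4, tumor_subtype1 = 3),
#'                       effects = list(tumor = list(n_probes = 50,
#'                                                   delta = 0.4)),
#'                       seed = 1)
#' sim$betas
#' @export
simulateCohort <- function(annotation,
                           design = c(retina = 12, tumor_subtype1 = 8,
                                      tumor_subtype2 = 0, AH_paired = 0,
                                      leukocyte = 0),
                           effects = list(tumor = list(n_probes = 500,
                                                       delta = 0.4),
                                          subtype = list(n_probes = 0,
                                                         delta = 0.5)),
                           regulation = NULL,
                           kappa = c(retina = 200, tumor = 200, AH = 200,
                                     leukocyte = 200),
                           kappa_individual = 200,
                           baseline = list(modes = c(0.1, 0.9),
                                           concentration = 30,
                                           weight = 0.5),
                           n_lump = 44,
                           lump_beta = c(tissue = 0.85, leukocyte = 0.02),
                           purity = NULL,
                           seed = 1) {
  roles <- c("retina", "tumor_subtype1", "tumor_subtype2", "AH_paired",
             "leukocyte")
  if (is.null(names(design)) || !all(names(design) %in% roles))
    .stopf("design must be named over: %s", paste(roles, collapse = ", "))
  full <- stats::setNames(integer(length(roles)), roles)
  full[names(design)] <- as.integer(design)
  design <- full
  if (any(design < 0)) .stopf("group sizes must be >= 0")
  n_tum <- design[["tumor_subtype1"]] + design[["tumor_subtype2"]]
  if (design[["AH_paired"]] > n_tum)
    .stopf("AH_paired (%d) exceeds the tumor count (%d)",
           design[["AH_paired"]], n_tum)
  if (any(kappa <= 0) || kappa_individual <= 0)
    .stopf("noise precisions kappa must be > 0")
  eff_t <- if (!is.null(effects$tumor)) effects$tumor
           else list(n_probes = 0, delta = 0.4)
  eff_s <- if (!is.null(effects$subtype)) effects$subtype
           else list(n_probes = 0, delta = 0.5)
  n_probes <- nrow(annotation)
  if (eff_t$n_probes + eff_s$n_probes + n_lump > n_probes)
    .stopf("panel sizes plus LUMP set exceed the probe count")

  set.seed(childSeed(seed, 1))

  ## bimodal genome-wide baseline
  comp <- stats::runif(n_probes) < baseline$weight
  m <- ifelse(comp, baseline$modes[1], baseline$modes[2])
  conc <- baseline$concentration
  mu0 <- stats::rbeta(n_probes, m * conc, (1 - m) * conc)
  names(mu0) <- annotation$probe_id

  ## designated LUMP probes: methylated in tissue, unmethylated in leukocytes
  clean <- which(!annotation$flag_snp & !annotation$flag_sexchrom &
                   !annotation$flag_age)
  if (length(clean) < n_lump) .stopf("not enough unflagged probes for LUMP")
  lump_idx <- sample(clean, n_lump)
  mu0[lump_idx] <- lump_beta[["tissue"]]
  leuk_mean <- mu0
  leuk_mean[lump_idx] <- lump_beta[["leukocyte"]]

  ## planted panels (disjoint; never on LUMP probes)
  avail <- setdiff(seq_len(n_probes), lump_idx)
  planted <- list()
  plant_panel <- function(n, delta, avail) {
    n_hyper <- floor(n / 2)
    n_hypo <- n - n_hyper
    hyper <- .pick_plantable(avail, mu0, +delta, n_hyper)
    avail <- setdiff(avail, hyper)
    hypo <- .pick_plantable(avail, mu0, -delta, n_hypo)
    list(idx = c(hyper, hypo),
         delta = c(rep(+delta, n_hyper), rep(-delta, n_hypo)),
         avail = setdiff(avail, hypo))
  }
  tum_shift <- numeric(n_probes)
  if (eff_t$n_probes > 0) {
    p <- plant_panel(eff_t$n_probes, eff_t$delta, avail)
    avail <- p$avail
    tum_shift[p$idx] <- p$delta
    planted$tumor <- data.frame(probe_id = annotation$probe_id[p$idx],
                                delta = p$delta, stringsAsFactors = FALSE)
  } else {
    planted$tumor <- data.frame(probe_id = character(), delta = numeric(),
                                stringsAsFactors = FALSE)
  }

  ## planted methylation-regulated genes feed extra tumor-contrast shifts
  reg_df <- data.frame(gene = character(), category = character(),
                       probe_id = character(), delta = numeric(),
                       stringsAsFactors = FALSE)
  if (!is.null(regulation)) {
    npc <- regulation$n_per_category
    dreg <- regulation$delta
    cats <- data.frame(
      category = c("promoter_hypo_up", "body_hyper_up",
                   "promoter_hyper_down", "body_hypo_down"),
      class = c("promoter", "body", "promoter", "body"),
      sign = c(-1, +1, +1, -1), stringsAsFactors = FALSE)
    used_genes <- character()
    for (i in seq_len(nrow(cats))) {
      pool <- avail[annotation$region_class[avail] == cats$class[i] &
                      annotation$gene[avail] != "" &
                      !(annotation$gene[avail] %in% used_genes)]
      d <- cats$sign[i] * dreg
      ok <- if (d >= 0) pool[mu0[pool] <= 1 - d - 0.02]
            else pool[mu0[pool] >= -d + 0.02]
      ## one probe per distinct gene
      ok <- ok[!duplicated(annotation$gene[ok])]
      if (length(ok) < npc)
        .stopf("cannot plant %d genes for category %s", npc, cats$category[i])
      pick <- sample(ok, npc)
      avail <- setdiff(avail, pick)
      used_genes <- c(used_genes, annotation$gene[pick])
      tum_shift[pick] <- d
      reg_df <- rbind(reg_df, data.frame(
        gene = annotation$gene[pick], category = cats$category[i],
        probe_id = annotation$probe_id[pick], delta = d,
        stringsAsFactors = FALSE))
      planted$tumor <- rbind(planted$tumor, data.frame(
        probe_id = annotation$probe_id[pick], delta = d,
        stringsAsFactors = FALSE))
    }
  }

  sub_shift <- numeric(n_probes)
  if (eff_s$n_probes > 0) {
    p <- plant_panel(eff_s$n_probes, eff_s$delta, avail)
    avail <- p$avail
    sub_shift[p$idx] <- p$delta
    planted$subtype <- data.frame(probe_id = annotation$probe_id[p$idx],
                                  delta = p$delta, stringsAsFactors = FALSE)
  } else {
    planted$subtype <- data.frame(probe_id = character(), delta = numeric(),
                                  stringsAsFactors = FALSE)
  }

  mean_retina <- mu0
  mean_t1 <- pmin(1, pmax(0, mu0 + tum_shift))
  mean_t2 <- pmin(1, pmax(0, mean_t1 + sub_shift))

  ## sample bookkeeping
  ids_ret <- sprintf("Retina_%02d", seq_len(design[["retina"]]))
  ids_t1 <- sprintf("Tumor_S1_%02d", seq_len(design[["tumor_subtype1"]]))
  ids_t2 <- sprintf("Tumor_S2_%02d", seq_len(design[["tumor_subtype2"]]))
  ids_tum <- c(ids_t1, ids_t2)
  ids_ah <- sprintf("AH_%02d", seq_len(design[["AH_paired"]]))
  ids_lk <- sprintf("Leuk_%02d", seq_len(design[["leukocyte"]]))
  tum_subtype <- c(rep(1L, length(ids_t1)), rep(2L, length(ids_t2)))
  tum_mean <- cbind(
    if (length(ids_t1)) matrix(mean_t1, n_probes, length(ids_t1)) else NULL,
    if (length(ids_t2)) matrix(mean_t2, n_probes, length(ids_t2)) else NULL)

  ## latent per-sample profiles (biological heterogeneity), then purity
  ## mixing, then observation noise
  latent <- function(mean_vec) .rbeta_mu(mean_vec, kappa_individual)
  lat_ret <- vapply(seq_along(ids_ret), function(i) latent(mean_retina),
                    numeric(n_probes))
  lat_tum <- vapply(seq_along(ids_tum), function(i) latent(tum_mean[, i]),
                    numeric(n_probes))
  lat_lk <- vapply(seq_along(ids_lk), function(i) latent(leuk_mean),
                   numeric(n_probes))

  all_ids <- c(ids_ret, ids_tum, ids_ah, ids_lk)
  pur <- stats::setNames(rep(1, length(all_ids)), all_ids)
  if (!is.null(purity)) {
    if (is.null(names(purity))) {
      pur[c(ids_tum, ids_ah)] <- purity
    } else {
      if (!all(names(purity) %in% all_ids))
        .stopf("purity names must be cohort sample ids")
      pur[names(purity)] <- purity
    }
    if (any(pur < 0 | pur > 1)) .stopf("purity must lie in [0, 1]")
  }
  mix <- function(v, a) a * v + (1 - a) * leuk_mean

  pairing <- stats::setNames(ids_tum[seq_along(ids_ah)], ids_ah)
  obs <- matrix(NA_real_, n_probes, length(all_ids),
                dimnames = list(annotation$probe_id, all_ids))
  for (i in seq_along(ids_ret))
    obs[, ids_ret[i]] <- .rbeta_mu(lat_ret[, i], kappa[["retina"]])
  for (i in seq_along(ids_tum))
    obs[, ids_tum[i]] <- .rbeta_mu(mix(lat_tum[, i], pur[[ids_tum[i]]]),
                                   kappa[["tumor"]])
  for (i in seq_along(ids_ah)) {
    v <- mix(lat_tum[, match(pairing[[ids_ah[i]]], ids_tum)],
             pur[[ids_ah[i]]])
    obs[, ids_ah[i]] <- .rbeta_mu(v, kappa[["AH"]])
  }
  for (i in seq_along(ids_lk))
    obs[, ids_lk[i]] <- .rbeta_mu(lat_lk[, i], kappa[["leukocyte"]])

  ah_sub <- tum_subtype[match(pairing, ids_tum)]
  outcome_of <- function(st) ifelse(st == 1L, "SV", "PE")
  sheet <- data.frame(
    sample_id = all_ids,
    role = c(rep("retina", length(ids_ret)), rep("tumor", length(ids_tum)),
             rep("AH", length(ids_ah)), rep("leukocyte", length(ids_lk))),
    pair_id = c(rep(NA_character_, length(ids_ret) + length(ids_tum)),
                unname(pairing), rep(NA_character_, length(ids_lk))),
    outcome = c(rep(NA_character_, length(ids_ret)),
                outcome_of(tum_subtype),
                if (length(ids_ah)) outcome_of(ah_sub) else character(),
                rep(NA_character_, length(ids_lk))),
    subtype = c(rep(NA_integer_, length(ids_ret)), tum_subtype,
                if (length(ids_ah)) ah_sub else integer(),
                rep(NA_integer_, length(ids_lk))),
    cohort = "synthetic",
    stringsAsFactors = FALSE)

  truth <- methods::new(
    "CohortTruth",
    plantedProbes = planted,
    subtypeLabels = stats::setNames(c(tum_subtype, ah_sub),
                                    c(ids_tum, ids_ah)),
    pairing = pairing,
    purity = pur,
    regulatedGenes = reg_df,
    noisePrecision = stats::setNames(
      c(rep(kappa[["retina"]], length(ids_ret)),
        rep(kappa[["tumor"]], length(ids_tum)),
        rep(kappa[["AH"]], length(ids_ah)),
        rep(kappa[["leukocyte"]], length(ids_lk))), all_ids),
    lumpProbes = annotation$probe_id[lump_idx])

  list(betas = BetaSet(obs, annotation = annotation, sampleSheet = sheet),
       sheet = sheet, truth = truth)
}

#' Mix a tumor and a leukocyte profile at a given purity
#'
#' Elementwise convex combination `alpha * tumor + (1 - alpha) * leukocyte`,
#' the mixture model underlying leukocyte-based purity (LUMP) estimation.
#'
#' @param tumor_profile,leukocyte_profile Numeric beta vectors of equal
#'   length.
#' @param alpha Purity in \[0, 1\].
#' @return Mixed beta vector.
#' @examples
#' mixPurity(c(0.85), c(0.05), 0.6)  # 0.53
#' @export
mixPurity <- function(tumor_profile, leukocyte_profile, alpha) {
  if (length(tumor_profile) != length(leukocyte_profile))
    .stopf("profiles must have the same length")
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    .stopf("alpha must be a scalar in [0, 1]")
  alpha * tumor_profile + (1 - alpha) * leukocyte_profile
}

#' Re-sample beta values under the low-input noise model
#'
#' Each unmasked beta is redrawn from the mean-preserving beta distribution
#' with its current value as the mean and concentration `kappa`, emulating
#' the extra dispersion of low-input-mass assays (kappa maps monotonically
#' to input DNA mass). The expected value of the output equals the input;
#' masks are preserved.
#'
#' @param betas A [BetaSet-class], matrix, or numeric vector.
#' @param kappa Precision, > 0; `Inf` returns the input unchanged.
#' @param seed Integer seed.
#' @return Same shape as the input.
#' @export
applyLowInputNoise <- function(betas, kappa, seed = 1) {
  if (length(kappa) != 1 || is.na(kappa) || kappa <= 0)
    .stopf("kappa must be a positive scalar")
  set.seed(childSeed(seed, 3))
  if (methods::is(betas, "SummarizedExperiment")) {
    b <- betaValues(betas)
    out <- betas
    SummarizedExperiment::assay(out, "beta") <- .rbeta_mu(b, kappa)
    return(out)
  }
  b <- if (is.matrix(betas)) betas else as.numeric(betas)
  .rbeta_mu(b, kappa)
}

#' Simulate paired differential-expression tables coupled to methylation
#'
#' Produces two independent noisy gene-level log2 fold-change tables
#' (emulating two expression datasets) in which planted
#' methylation-regulated genes receive a fold change of the sign dictated
#' by their category — promoter hypomethylation and gene-body
#' hypermethylation couple to up-regulation; promoter hypermethylation and
#' gene-body hypomethylation to down-regulation — with |log2FC| >= `lfc`,
#' while all other genes are centred at zero.
#'
#' @param truth [CohortTruth-class] holding the planted regulated genes.
#' @param annotation Probe annotation supplying the gene universe.
#' @param coupling Named sign vector per category (defaults encode the four
#'   rules above). An unknown planted category is an error.
#' @param lfc Minimum |log2FC| for planted genes (default 2).
#' @param noise_sd Standard deviation of the log2FC noise; 0 gives exactly
#'   +/- `lfc` at planted genes.
#' @param seed Integer seed.
#' @return `list(a = data.frame, b = data.frame)` each with columns `gene`,
#'   `log2FC`, `source`.
#' @export
simulateExpression <- function(truth, annotation,
                               coupling = c(promoter_hypo_up = +1,
                                            body_hyper_up = +1,
                                            promoter_hyper_down = -1,
                                            body_hypo_down = -1),
                               lfc = 2, noise_sd = 0.25, seed = 1) {
  if (noise_sd < 0) .stopf("noise_sd must be >= 0")
  reg <- regulatedGenes(truth)
  if (nrow(reg) && !all(reg$category %in% names(coupling)))
    .stopf("unknown regulated-gene category: %s",
           paste(setdiff(reg$category, names(coupling)), collapse = ", "))
  genes <- sort(unique(annotation$gene[annotation$gene != ""]))
  set.seed(childSeed(seed, 2))
  one <- function(label) {
    l2 <- stats::rnorm(length(genes), 0, noise_sd)
    names(l2) <- genes
    if (nrow(reg)) {
      sgn <- coupling[reg$category]
      l2[reg$gene] <- sgn * (lfc + abs(stats::rnorm(nrow(reg), 0, noise_sd)))
    }
    data.frame(gene = genes, log2FC = unname(l2), source = label,
               stringsAsFactors = FALSE)
  }
  list(a = one("datasetA"), b = one("datasetB"))
}
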