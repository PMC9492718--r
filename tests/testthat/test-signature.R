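mkb <- function(v, nr, nc, probes = sprintf("cg%03d", seq_len(nr)),
                samples = sprintf("s%02d", seq_len(nc))) {
  matrix(v, nr, nc, dimnames = list(probes, samples))
}

test_that("variance ranking is deterministic with lexicographic ties", {
  b <- mkb(0.5, 20, 4)
  expect_identical(topVariableProbes(b, k = 5), sprintf("cg%03d", 1:5))

  b2 <- mkb(0.5, 10, 4)
  b2["cg007", ] <- c(0.1, 0.4, 0.7, 0.9)
  expect_identical(topVariableProbes(b2, k = 1), "cg007")

  ## oracle comparison on a random matrix
  set.seed(61)
  b3 <- mkb(runif(400), 100, 4)
  want <- names(sort(apply(b3, 1, sd), decreasing = TRUE))
  expect_identical(topVariableProbes(b3, k = 100), want)

  expect_warning(out <- topVariableProbes(b3, k = 500), "eligible")
  expect_length(out, 100)
})

test_that("agglomerative clustering matches a brute-force oracle", {
  ## duplicated profiles merge first at height zero
  b <- mkb(runif(12), 6, 2)
  b <- cbind(b, s03 = b[, 1])
  tree <- clusterSamples(b)
  expect_equal(min(tree$height), 0)
  first <- rownames(b) # appease lint; labels checked via cut
  expect_true(same_partition(cutClusters(tree, 2),
                             c(1, 2, 1)))

  ## random <=6-leaf instances, complete and average linkage
  set.seed(62)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    m <- mkb(runif(8 * n), 8, n)
    for (link in c("complete", "average")) {
      tr <- clusterSamples(m, linkage = link)
      oracle <- naive_agglomerate(dist(t(m)), method = link)
      expect_equal(tr$height, oracle$heights, tolerance = 1e-12)
      for (mrg in seq_len(n - 1))
        expect_true(same_partition(cutree(tr, k = n - mrg),
                                   oracle$partitions[[mrg]]))
    }
  }

  ## a sample mostly masked over the panel is refused by name
  bm <- mkb(runif(40), 10, 4)
  bm[1:6, "s02"] <- NA
  expect_error(clusterSamples(bm), "s02")
})

test_that("tree cutting is validated and matches the tallest-merge cut", {
  set.seed(63)
  b <- mkb(runif(40), 8, 5)
  tree <- clusterSamples(b)
  expect_equal(unname(cutClusters(tree, 1)), rep(1L, 5))
  expect_length(unique(cutClusters(tree, 5)), 5)
  ## k = 2 equals splitting below the last (tallest) merge
  oracle <- naive_agglomerate(dist(t(b)))
  expect_true(same_partition(cutClusters(tree, 2),
                             oracle$partitions[[3]]))
  expect_error(cutClusters(tree, 0), "k must be")
  expect_error(cutClusters(tree, 9), "k must be")

  ml <- treeToMergeList(tree)
  expect_equal(dim(ml$merge), c(4, 2))
  expect_identical(ml$labels, colnames(b))
})

test_that("classical MDS reproduces embeddable geometries", {
  ## two identical profiles among three samples coincide in the embedding
  b <- mkb(c(0.2, 0.8, 0.2, 0.8, 0.6, 0.3), 2, 3)
  b[, 2] <- b[, 1]
  xy <- mdsEmbed(b, dims = 2)
  expect_lt(max(abs(xy[1, ] - xy[2, ])), 1e-6)

  ## a 3-4-5 triangle embeds exactly
  tri <- matrix(c(0, 0, 3, 0, 3, 4), nrow = 2,
                dimnames = list(c("d1", "d2"), c("a", "b", "c")))
  xy2 <- mdsEmbed(tri, dims = 2)
  expect_equal(as.numeric(dist(xy2)), c(3, 5, 4), tolerance = 1e-6)

  ## sign convention: the largest-|coordinate| sample is positive per axis
  for (j in 1:2) expect_gt(xy2[which.max(abs(xy2[, j])), j], 0)

  ## degenerate all-equal distances give zero coordinates with a warning
  bd <- mkb(0.4, 5, 4)
  expect_warning(xyz <- mdsEmbed(bd, dims = 2), "zero")
  expect_true(all(xyz == 0))

  ## planted two-group structure separates on axis 1
  ann <- tiny_annotation(800, seed = 64)
  sim <- simulateCohort(ann, design = c(retina = 5, tumor_subtype1 = 5),
                        effects = list(tumor = list(n_probes = 100,
                                                    delta = 0.4)),
                        seed = 64)
  xy3 <- mdsEmbed(sim$betas)
  grp <- sim$sheet$role[match(rownames(xy3), sim$sheet$sample_id)]
  rng_t <- range(xy3[grp == "tumor", 1])
  rng_r <- range(xy3[grp == "retina", 1])
  expect_true(rng_t[1] > rng_r[2] || rng_r[1] > rng_t[2])
})

test_that("panel derivation recovers planted probes and composes", {
  ann <- simulateAnnotation(4000, 300, seed = 65)
  sim <- simulateCohort(ann,
                        design = c(tumor_subtype1 = 4, tumor_subtype2 = 8),
                        effects = list(tumor = list(n_probes = 0),
                                       subtype = list(n_probes = 100,
                                                      delta = 0.5)),
                        seed = 65)
  sheet <- sim$sheet
  sv <- sheet$sample_id[sheet$outcome == "SV"]
  en <- sheet$sample_id[sheet$outcome == "PE"]
  panel <- derivePanel(sim$betas, arm_a = en, arm_b = sv,
                       contrast = "enucleated_vs_salvage")
  sp <- plantedProbes(sim$truth, "subtype")
  expect_gte(mean(sp$probe_id %in% panelProbes(panel)), 0.99)
  ## directions match the planted signs (delta oriented subtype2 - subtype1)
  st <- panelStats(panel)
  hyp <- intersect(sp$probe_id[sp$delta > 0], st$probe_id)
  expect_true(all(st$direction[match(hyp, st$probe_id)] == "hyper"))

  ## extreme thresholds on null arms give an empty panel, with a warning
  ann0 <- tiny_annotation(300, seed = 66)
  sim0 <- simulateCohort(ann0, design = c(retina = 4, tumor_subtype1 = 4),
                         effects = list(tumor = list(n_probes = 0)),
                         seed = 66)
  expect_warning(
    p0 <- derivePanel(sim0$betas,
                      sim0$sheet$sample_id[sim0$sheet$role == "tumor"],
                      sim0$sheet$sample_id[sim0$sheet$role == "retina"],
                      delta_thresh = 0.99, p_thresh = 1e-9),
    "empty panel")
  expect_length(panelProbes(p0), 0)

  ## second-round refinement between recovered clusters finds the subtype
  ## panel again
  asg <- assignClusters(sim$betas, panel)
  labs <- clusterLabels(asg)
  panel2 <- derivePanel(sim$betas,
                        arm_a = names(labs)[labs == "B"],
                        arm_b = names(labs)[labs == "A"],
                        contrast = "clusterB_vs_clusterA")
  expect_gte(mean(sp$probe_id %in% panelProbes(panel2)), 0.99)
})

test_that("cluster assignment recovers subtypes and flags weak cuts", {
  ann <- simulateAnnotation(3000, 300, seed = 67)
  sim <- simulateCohort(ann,
                        design = c(tumor_subtype1 = 6, tumor_subtype2 = 6),
                        effects = list(tumor = list(n_probes = 0),
                                       subtype = list(n_probes = 120,
                                                      delta = 0.5)),
                        seed = 67)
  sp <- plantedProbes(sim$truth, "subtype")
  asg <- assignClusters(sim$betas, sp$probe_id)
  labs <- clusterLabels(asg)
  truth <- subtypeLabels(sim$truth)[names(labs)]
  expect_true(same_partition(labs, truth))
  ## "A" is the salvage-enriched cluster (subtype 1 carries SV outcomes)
  expect_true(all(labs[truth == 1] == "A"))
  expect_false(asg@weakSeparation)

  ## duplicated cohort: duplicates always co-assigned
  b <- betaValues(sim$betas)
  bd <- cbind(b, `colnames<-`(b, paste0(colnames(b), "_dup")))
  asg2 <- assignClusters(bd, sp$probe_id)
  l2 <- clusterLabels(asg2)
  expect_identical(unname(l2[colnames(b)]),
                   unname(l2[paste0(colnames(b), "_dup")]))

  ## single-subtype cohort: forced 2-cut flagged as weak separation
  sim1 <- simulateCohort(ann, design = c(tumor_subtype1 = 8),
                         effects = list(tumor = list(n_probes = 0)),
                         seed = 68)
  expect_warning(
    asg1 <- assignClusters(sim1$betas,
                           sample(probeIds(sim1$betas), 100)),
    "weak separation")
  expect_true(asg1@weakSeparation)
  expect_lt(abs(asg1@silhouette), 0.2)

  expect_error(assignClusters(sim$betas, c(sp$probe_id, "cgNOPE")),
               "absent")
})

test_that("cluster-outcome exact test and containment statements", {
  labels <- setNames(rep(c("A", "B"), c(4, 8)), paste0("s", 1:12))
  outcomes <- setNames(rep(c("SV", "PE", "SE"), c(4, 4, 4)),
                       paste0("s", 1:12))
  res <- clusterOutcomeTest(labels, outcomes)
  expect_equal(unclass(res$table)[1:4], c(4, 0, 0, 8),
               ignore_attr = TRUE)  # PE+SE merged as enucleated
  expect_equal(res$p_value, 2 / choose(12, 4), tolerance = 1e-12)
  expect_identical(res$odds_ratio, Inf)
  expect_identical(unname(res$containment), c(TRUE, TRUE))

  ## Cluster A (19) inside subtype 1 (27), B (24) inside subtype 2 (37),
  ## cohort restricted to the 43 co-labelled samples
  labs2 <- setNames(rep(c("A", "B"), c(19, 24)), paste0("t", 1:43))
  subt <- setNames(rep(c("1", "2"), c(19, 24)), paste0("t", 1:43))
  res2 <- clusterOutcomeTest(labs2, subt)
  expect_identical(unname(res2$containment), c(TRUE, TRUE))
  expect_lt(res2$p_value, 0.01)

  ## independent labels: no containment, unremarkable p
  set.seed(69)
  labs3 <- setNames(sample(c("A", "B"), 40, TRUE), paste0("u", 1:40))
  out3 <- setNames(sample(c("SV", "PE"), 40, TRUE), paste0("u", 1:40))
  res3 <- clusterOutcomeTest(labs3, out3)
  expect_true(res3$p_value > 0.001)

  expect_error(clusterOutcomeTest(labels, outcomes[1:5]), "outcome")
})
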