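test_that("Welch's t matches the closed form and the numeric oracle", {
  w <- welchT(c(0.1, 0.2, 0.3), c(0.6, 0.7, 0.8))
  ## closed form: equal variances 0.01, n = 3 each
  expect_equal(w$t_stat, -0.5 / sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4.0, tolerance = 1e-12)
  expect_equal(round(w$t_stat, 3), -6.124)
  expect_equal(w$p_value, 2 * pt(-abs(w$t_stat), 4), tolerance = 1e-12)

  ## antisymmetry
  w2 <- welchT(c(0.6, 0.7, 0.8), c(0.1, 0.2, 0.3))
  expect_equal(w2$t_stat, -w$t_stat)
  expect_equal(w2$p_value, w$p_value)

  ## identical groups
  w0 <- welchT(c(0.4, 0.6), c(0.4, 0.6))
  expect_equal(w0$t_stat, 0)
  expect_equal(w0$p_value, 1)

  ## degenerate: both arms constant
  wd <- welchT(c(0.2, 0.2), c(0.7, 0.7, 0.7))
  expect_equal(wd$p_value, 0)
  expect_true(wd$degenerate)
  we <- welchT(c(0.2, 0.2), c(0.2, 0.2))
  expect_equal(we$p_value, 1)

  expect_error(welchT(0.5, c(0.1, 0.2)), ">= 2")

  ## random small inputs against stats::t.test
  set.seed(101)
  for (i in 1:200) {
    x <- runif(sample(2:8, 1)); y <- runif(sample(2:8, 1))
    w <- welchT(x, y)
    o <- t.test(x, y)
    expect_equal(w$t_stat, unname(o$statistic), tolerance = 1e-8)
    expect_equal(w$df, unname(o$parameter), tolerance = 1e-8)
    expect_equal(w$p_value, o$p.value, tolerance = 1e-8)
  }
})

test_that("dmTable orients delta, skips thin probes, attaches regions", {
  ann <- tiny_annotation(300, seed = 13)
  sim <- simulateCohort(ann, design = c(retina = 5, tumor_subtype1 = 5),
                        effects = list(tumor = list(n_probes = 30,
                                                    delta = 0.4)),
                        n_lump = 5, seed = 13)
  b <- betaValues(sim$betas)
  arm_t <- sim$sheet$sample_id[sim$sheet$role == "tumor"]
  arm_r <- sim$sheet$sample_id[sim$sheet$role == "retina"]

  ## mask one probe in the tumor arm; add one constant probe
  b["cg00000001", arm_t] <- NA
  b["cg00000002", ] <- 0.5
  dm <- dmTable(b, arm_t, arm_r, annotation = ann,
                contrast = "tumor_vs_retina")
  expect_identical(dmSkipped(dm)$probe_id, "cg00000001")
  expect_match(dmSkipped(dm)$reason, "unmasked values below")
  rec <- dmRecords(dm)
  const <- rec[rec$probe_id == "cg00000002", ]
  expect_equal(const$t_stat, 0)
  expect_equal(const$p_value, 1)
  expect_identical(const$direction, "none")
  expect_identical(rec$region_class,
                   ann$region_class[match(rec$probe_id, ann$probe_id)])

  ## delta oriented arm_a - arm_b: planted hyper probes are positive
  tp <- plantedProbes(sim$truth, "tumor")
  hyp <- tp$probe_id[tp$delta > 0]
  expect_true(all(rec$delta_beta[match(hyp, rec$probe_id)] > 0))

  expect_error(dmTable(b, arm_t, c(arm_r, arm_t[1])), "overlap")
})

test_that("DM selection uses strict thresholds and disjoint sets", {
  rec <- data.frame(
    probe_id = paste0("p", 1:6),
    mean_a = 0.5, mean_b = 0.3,
    delta_beta = c(0.31, 0.30, -0.45, 0.50, -0.29, 0.35),
    t_stat = 1, df = 4,
    p_value = c(0.04, 0.04, 0.001, 0.06, 0.04, 0.049),
    direction = "none")
  sel <- selectDM(rec, delta_thresh = 0.3, p_thresh = 0.05)
  expect_identical(sel$hyper, c("p1", "p6"))  # 0.30 excluded (strict >)
  expect_identical(sel$hypo, "p3")            # p4 fails p, p5 fails delta
  expect_length(intersect(sel$hyper, sel$hypo), 0)

  empty <- rec[0, ]
  sel0 <- selectDM(empty, delta_thresh = 0.3, p_thresh = 0.05)
  expect_length(sel0$hyper, 0)
  expect_length(sel0$hypo, 0)

  ## disjointness over random tables
  set.seed(7)
  rnd <- data.frame(probe_id = paste0("r", 1:500),
                    delta_beta = runif(500, -1, 1),
                    p_value = runif(500))
  for (d in c(0.1, 0.3, 0.5)) {
    s <- selectDM(rnd, delta_thresh = d, p_thresh = 0.05)
    expect_length(intersect(s$hyper, s$hypo), 0)
  }
  expect_error(selectDM(rnd, delta_thresh = 0, p_thresh = 0.05), "thresholds")
})

test_that("direction fractions partition the selected probes", {
  expect_equal(directionFractions(paste0("h", 1:19), paste0("l", 1:81)),
               c(hyper = 0.19, hypo = 0.81))
  expect_equal(directionFractions(character(0), paste0("l", 1:5)),
               c(hyper = 0, hypo = 1))
  expect_equal(directionFractions(paste0("h", 1:3), paste0("l", 1:9)),
               c(hyper = 0.25, hypo = 0.75))
  expect_error(directionFractions(character(0), character(0)), "empty")
})

test_that("region classification applies promoter > body > other precedence", {
  expect_identical(classifyRegion("TSS1500"), "promoter")
  expect_identical(classifyRegion("Body;3'UTR"), "body")
  expect_identical(classifyRegion(""), "other")
  expect_identical(classifyRegion("TSS200;Body"), "promoter")
  expect_warning(out <- classifyRegion("Body;Weird"), "unknown")
  expect_identical(out, "body")

  ## exhaustive enumeration over all subsets of the token vocabulary
  vocab <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body", "3'UTR",
             "ExonBnd")
  promoter <- vocab[1:4]; body <- vocab[5:6]
  subsets <- unlist(lapply(0:length(vocab), function(k)
    combn(vocab, k, simplify = FALSE)), recursive = FALSE)
  got <- classifyRegion(subsets)
  want <- vapply(subsets, function(s) {
    if (any(s %in% promoter)) "promoter"
    else if (any(s %in% body)) "body" else "other"
  }, character(1))
  expect_identical(got, want)
})

test_that("region enrichment reports fractions per collection", {
  ann <- data.frame(probe_id = paste0("p", 1:9),
                    region_class = rep(c("promoter", "body", "other"), 3),
                    enhancer = rep(c(TRUE, FALSE, FALSE), 3))
  u <- ann$probe_id
  body_ids <- ann$probe_id[ann$region_class == "body"]
  enr <- regionEnrichment(body_ids[1:2], character(0), u, ann)
  expect_equal(enr["hyper", "body"], 1.0)
  expect_equal(enr["total", "promoter"], 1 / 3)

  enr2 <- regionEnrichment(u, character(0), u, ann)
  expect_equal(unlist(enr2["hyper", 1:4]), unlist(enr2["total", 1:4]))
  expect_error(regionEnrichment("p1", character(0), character(0), ann),
               "empty")
  expect_error(regionEnrichment("zz", character(0), u, ann), "subsets")

  ## planted promoter-hypo enrichment exceeds the background fraction
  ann2 <- simulateAnnotation(2000, 200, seed = 31)
  prom <- ann2$probe_id[ann2$region_class == "promoter"]
  hypo <- sample(prom, 50)
  enr3 <- regionEnrichment(character(0), hypo, ann2$probe_id, ann2)
  expect_gt(enr3["hypo", "promoter"], enr3["total", "promoter"])
})

test_that("null data yields a calibrated type-I rate", {
  ## 5,000 null probes, 8 vs 8: p < alpha rate near alpha
  ann <- simulateAnnotation(5000, 200, seed = 41)
  sim <- simulateCohort(ann, design = c(retina = 8, tumor_subtype1 = 8),
                        effects = list(tumor = list(n_probes = 0)),
                        seed = 41)
  dm <- dmTable(sim$betas,
                sim$sheet$sample_id[sim$sheet$role == "tumor"],
                sim$sheet$sample_id[sim$sheet$role == "retina"])
  fpr <- mean(dmRecords(dm)$p_value < 0.05)
  expect_lt(abs(fpr - 0.05), 3 * sqrt(0.05 * 0.95 / 5000) + 0.005)
})
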