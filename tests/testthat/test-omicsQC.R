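test_that("pairwise correlations hit the exact identity cases", {
  set.seed(51)
  m <- matrix(rlnorm(200), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  m[, 4] <- 1 / (m[, 3] + 1)       # decreasing transform of s3
  pairing <- data.frame(
    sample_a = c("s1", "s3"), sample_b = c("s1", "s4"),
    relation = c("patient-PDX", "unmatched"), layer = "transcriptome")
  res <- pairwiseCorrelations(m, pairing)
  expect_equal(res$pearson_r[1], 1)
  expect_equal(res$spearman_rho[1], 1)
  expect_equal(res$spearman_rho[2], -1)    # monotone decreasing
  # symmetry
  rev <- pairwiseCorrelations(m, data.frame(
    sample_a = "s4", sample_b = "s3", relation = "unmatched",
    layer = "transcriptome"))
  expect_equal(rev$spearman_rho, res$spearman_rho[2])
  expect_equal(rev$pearson_r,
               pairwiseCorrelations(m, pairing)$pearson_r[2])
})

test_that("matched pairs correlate above unmatched, shrinking with noise", {
  sepFor <- function(rho) {
    cfg <- syntheticConfig(seed = 60, expression = list(
      sharedVariance = rho, effectD = 0))
    ex <- genExpression(cfg)
    m <- cbind(ex$matrices$patient, ex$matrices$PDX)
    models <- sprintf("M%02d", 1:9)
    matched <- data.frame(sample_a = paste0(models, "_patient"),
                          sample_b = paste0(models, "_PDX"),
                          relation = "patient-PDX", layer = "transcriptome")
    unmatched <- data.frame(sample_a = paste0(models[1:8], "_patient"),
                            sample_b = paste0(models[2:9], "_PDX"),
                            relation = "unmatched", layer = "transcriptome")
    res <- pairwiseCorrelations(m, rbind(matched, unmatched))
    mean(res$pearson_r[res$relation == "patient-PDX"]) -
      mean(res$pearson_r[res$relation == "unmatched"])
  }
  gapHigh <- sepFor(0.9)
  gapLow <- sepFor(0.3)
  expect_gt(gapHigh, 0)
  expect_gt(gapLow, 0)
  expect_gt(gapHigh, gapLow)   # separation monotone in shared variance
})

test_that("Tukey summary flags fence outliers and partitions the data", {
  s <- tukeySummary(c(1, 2, 3, 4, 100))
  expect_equal(s$outliers, 100)
  expect_equal(s$median, 3)
  expect_equal(s$whisker_hi, 4)
  base <- stats::quantile(c(1, 2, 3, 4, 100), c(0.25, 0.75), type = 7)
  expect_equal(unname(s$q1), unname(base[1]))

  const <- tukeySummary(rep(5, 4))
  expect_equal(const$q1, const$q3)
  expect_equal(length(const$outliers), 0L)

  single <- tukeySummary(42)
  expect_equal(single$median, 42)
  expect_equal(single$whisker_lo, 42)

  set.seed(52)
  v <- c(rnorm(50), 10, -12)
  s2 <- tukeySummary(v)
  inFence <- v[v >= s2$whisker_lo & v <= s2$whisker_hi]
  expect_equal(sort(c(inFence, s2$outliers)), sort(v))
})

test_that("variant concordance classifies maintained and gained mutations", {
  variants <- data.frame(
    gene = c("APC", "APC", "TP53", "KRAS"),
    sample = c("pat1", "pdx1", "pdx1", "pd3d1"),
    status = c("pathogenic", "pathogenic", "pathogenic", "pathogenic"))
  lineage <- data.frame(
    sample = c("pat1", "pdx1", "pd3d1"),
    lineage = "L1", role = c("patient", "PDX", "PD3D"))
  vc <- variantConcordance(variants, lineage)
  apc <- vc$byLineage[vc$byLineage$gene == "APC", ]
  expect_true(apc$maintained)
  tp53 <- vc$byLineage[vc$byLineage$gene == "TP53", ]
  expect_false(tp53$maintained)
  expect_true(tp53$gain_in_model)
  expect_equal(vc$statusGrid["KRAS", "pat1"], "reference")

  bad <- variants; bad$status[1] <- "benign"
  expect_error(variantConcordance(bad, lineage), "legal classes")

  empty <- variantConcordance(variants[0, ], lineage)
  expect_equal(nrow(empty$byLineage), 0L)
})
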