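test_that("noise-free growth curves reproduce td and T/C exactly", {
  cfg <- syntheticConfig(seed = 2, nModels = 3,
                         drugs = c("dA", "dB"),
                         growth = list(sigma = 0, nAnimals = 2L))
  gg <- genGrowth(cfg)
  tab <- validateMeasurementTable(gg$records, "growth")
  # doubling time from a control animal is exact
  ctl <- tab[tab$arm == "control" & tab$model == "PDX01", ]
  a1 <- ctl[ctl$animal == ctl$animal[1], ]
  dt <- doublingTime(a1$day, tumorVolume(a1$width_mm, a1$length_mm))
  expect_equal(dt$td, gg$truth$td[gg$truth$model == "PDX01"][1],
               tolerance = 1e-9)
  # pipeline T/C equals the analytic expectation without noise
  tc <- tcTable(tab)
  mg <- merge(tc, gg$truth, by = c("model", "drug"))
  expect_equal(mg$tc_percent, mg$expected_tc, tolerance = 1e-9)
})

test_that("pipeline T/C tracks the analytic expectation over seeds", {
  devs <- vapply(1:10, function(s) {
    cfg <- syntheticConfig(seed = s, nModels = 4, drugs = c("dA", "dB"))
    gg <- genGrowth(cfg)
    tc <- tcTable(gg$records)
    mg <- merge(tc, gg$truth, by = c("model", "drug"))
    median(abs(mg$tc_percent - mg$expected_tc) /
             pmax(mg$expected_tc, 1))
  }, numeric(1))
  # lognormal sigma 0.1 over 8 animals/arm: a few percent of MC error
  expect_lt(median(devs), 0.10)
})

test_that("noise-free viability plates return the generating 4PL curves", {
  cfg <- syntheticConfig(seed = 3, drugs = c("dA", "dB"),
                         doseResponse = list(sigma = 0))
  gv <- genViability(cfg, models = c("PD3D01", "PD3D02"))
  drt <- doseResponseTable(gv$records, gv$cmax)
  mg <- merge(drt$fitTable, gv$truth, by = c("model", "drug"))
  expect_equal(mg$ic50_uM, mg$ic50, tolerance = 1e-3)
  expect_equal(mg$hill.x, mg$hill.y, tolerance = 1e-3)
  cg <- merge(drt$cmaxTable, gv$truth, by = c("model", "drug"))
  expect_equal(cg$viability_at_cmax.x, 100 * cg$viability_at_cmax.y,
               tolerance = 1e-3)
})

test_that("the planted resistant model is categorized resistant at Cmax", {
  cfg <- syntheticConfig(seed = 4, doseResponse = list(sigma = 0))
  gv <- genViability(cfg)
  planted <- gv$truth[gv$truth$model == "PD3D01" &
                      gv$truth$drug == cfg$drugs[1], ]
  expect_gte(100 * planted$viability_at_cmax, 80)
  expect_equal(categorize(100 * planted$viability_at_cmax, "PD3D"), 3)
})

test_that("matched expression triplets carry the planted structure", {
  cfg <- syntheticConfig(seed = 5)
  ex <- genExpression(cfg)
  expect_length(ex$truth$markers, cfg$expression$nMarkers)
  expect_true(all(geneSets(ex$collection)$planted_response %in%
                  ex$truth$markers))
  expect_setequal(unique(unname(ex$labels)), c("responder", "resistant"))
  # responder shift visible in marker means
  m <- ex$matrices$PDX
  resp <- ex$labels == "responder"
  markerShift <- mean(log2(m[ex$truth$markers, resp])) -
    mean(log2(m[ex$truth$markers, !resp]))
  expect_gt(markerShift, cfg$expression$effectD / 2)
})

test_that("combination generator obeys Bliss at beta 0 and dose-0 margins", {
  cfg <- syntheticConfig(seed = 6, combination = list(sigma = 0))
  g0 <- genCombination(cfg, beta = 0)
  cm <- normalizeCytotoxicity(g0$records)
  e0 <- cfg$combination$baselineEffect
  # vehicle cell carries the baseline effect only
  expect_equal(unname(normCytotox(cm)[1, 1]), e0, tolerance = 1e-9)
  # noise-free excess reflects only the documented max-scaling offset
  bl <- plateBlissExcess(cm)
  expect_lt(abs(bl$meanExcess), 0.05)
})

test_that("generators are byte-deterministic given a seed", {
  md5Of <- function(seed) {
    d <- withr::local_tempdir()
    generateStudy(syntheticConfig(seed = seed,
                                  expression = list(nGenes = 100L)), d)
    files <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
    unname(tools::md5sum(files))
  }
  expect_identical(md5Of(123), md5Of(123))
  expect_false(identical(md5Of(123), md5Of(124)))
})
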