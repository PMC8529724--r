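test_that("categorization matches the printed platform thresholds", {
  # PDX: strong <=10, moderate (10,25], minor (25,50], resistant >50
  expect_equal(categorize(7, "PDX"), 0)
  expect_equal(categorize(c(10, 25, 50), "PDX"), c(0, 1, 2))
  expect_equal(categorize(c(10.01, 25.5, 50.1), "PDX"), c(1, 2, 3))
  # PD3D: strong <=30, moderate (30,60], minor (60,80], resistant >80
  expect_equal(categorize(c(30, 60, 80, 81), "PD3D"), c(0, 1, 2, 3))
  expect_equal(categoryLabel(categorize(81, "PD3D")), "resistant")
  expect_error(categorize(-1, "PDX"), "non-negative")
})

test_that("categorize is monotone in the raw value", {
  for (pf in c("PDX", "PD3D")) {
    v <- sort(runif(200, 0, 120))
    expect_true(all(diff(categorize(v, pf)) >= 0))
  }
})

test_that("pairs join platforms, compute distance, and drop unpaired", {
  resp <- data.frame(
    model = c("m1", "m1", "m2", "m2", "m3"),
    drug = "d1",
    platform = c("PDX", "PD3D", "PDX", "PD3D", "PDX"),
    response_value = c(5, 20, 8, 95, 30))
  expect_message(pairs <- concordancePairs(resp), "1 unpaired")
  expect_equal(nrow(pairs), 2L)
  expect_equal(pairs$distance[pairs$model == "m1"], 0)  # strong/strong
  expect_equal(pairs$distance[pairs$model == "m2"], 3)  # strong/resistant

  dup <- rbind(resp, resp[1, ])
  expect_error(concordancePairs(dup), "duplicate")
})

test_that("pair distance is symmetric and zero iff levels agree", {
  set.seed(11)
  resp <- expand.grid(model = paste0("m", 1:6), drug = paste0("d", 1:3),
                      platform = c("PDX", "PD3D"),
                      stringsAsFactors = FALSE)
  resp$response_value <- runif(nrow(resp), 0, 100)
  pairs <- concordancePairs(resp)
  expect_equal(pairs$distance, abs(pairs$pd3d_level - pairs$pdx_level))
  expect_equal(pairs$distance == 0, pairs$pdx_level == pairs$pd3d_level)
  expect_true(all(pairs$distance %in% 0:3))
})

test_that("summary equals hand computation and brute-force recount", {
  # drug A: 8 of 9 at distance <= 1, drug B: 5 of 9
  mkPair <- function(drug, n, nConc) {
    data.frame(model = paste0("m", 1:n), drug = drug,
               pdx_value = 5, pd3d_value = c(rep(20, nConc), rep(95, n - nConc)),
               pdx_level = 0L,
               pd3d_level = c(rep(0L, nConc), rep(3L, n - nConc)),
               distance = c(rep(0L, nConc), rep(3L, n - nConc)))
  }
  pairs <- rbind(mkPair("A", 9, 8), mkPair("B", 9, 5))
  s <- summarizeConcordance(pairs)
  expect_equal(s$overallMean, (8 / 9 + 5 / 9) / 2 * 100, tolerance = 1e-12)
  expect_equal(s$perDrug$n_dist_le1, c(8, 5))

  oracle <- concordanceOracle(pairs)
  expect_equal(s$perDrug$n_pairs, oracle$perDrug$n_pairs)
  expect_equal(s$perDrug$n_dist0, oracle$perDrug$n_dist0)
  expect_equal(s$perDrug$n_dist_le1, oracle$perDrug$n_dist_le1)
  expect_equal(s$overallMean, oracle$overallMean)
  expect_equal(s$overallSD, oracle$overallSD)

  one <- mkPair("A", 9, 9); one$distance <- 0L; one$pd3d_level <- 0L
  s1 <- summarizeConcordance(one)
  expect_equal(s1$overallMean, 100)
  expect_equal(s1$overallSD, 0)
})

test_that("bubble aggregation conserves pair counts", {
  set.seed(5)
  resp <- expand.grid(model = paste0("m", 1:9), drug = paste0("d", 1:4),
                      platform = c("PDX", "PD3D"),
                      stringsAsFactors = FALSE)
  resp$response_value <- runif(nrow(resp), 0, 110)
  pairs <- concordancePairs(resp)
  bub <- bubbleAggregate(pairs)
  for (d in names(bub$perDrug))
    expect_equal(sum(bub$perDrug[[d]]), sum(pairs$drug == d))
  expect_equal(sum(bub$total), nrow(pairs))

  empty <- pairs[0, ]
  expect_equal(sum(bubbleAggregate(empty)$total), 0L)

  three <- pairs[1:3, ]
  three$pdx_level <- 0L; three$pd3d_level <- 0L; three$distance <- 0L
  three$drug <- "dX"
  expect_equal(bubbleAggregate(three)$perDrug$dX["strong", "strong"], 3L)
})
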