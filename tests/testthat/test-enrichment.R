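test_that("ssGSEA equals the brute-force running-sum oracle", {
  expr <- c(A = 5, B = 4, C = 3, D = 2, E = 1)
  sc <- ssgseaScore(expr, c("A", "C"), alpha = 0.25)
  expect_equal(sc$es, ssgseaOracle(expr, c("A", "C"), 0.25),
               tolerance = 1e-12)

  # ties, alpha 0, larger vectors
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    v <- setNames(sample(1:6, n, replace = TRUE) + 0,
                  paste0("g", seq_len(n)))
    genes <- sample(names(v), sample(2:4, 1))
    for (a in c(0, 0.25, 1)) {
      expect_equal(ssgseaScore(v, genes, a)$es, ssgseaOracle(v, genes, a),
                   tolerance = 1e-12)
    }
  }
})

test_that("ssGSEA degenerate and missing sets are flagged", {
  expr <- c(A = 3, B = 2, C = 1)
  allGenes <- ssgseaScore(expr, c("A", "B", "C"), alpha = 0)
  expect_equal(allGenes$es, 0)
  expect_false(allGenes$evaluable)
  none <- ssgseaScore(expr, c("X", "Y"))
  expect_false(none$evaluable)
  expect_true(is.na(none$es))
})

test_that("ssGSEA is invariant under strictly monotone transforms", {
  set.seed(21)
  v <- setNames(rlnorm(50), paste0("g", 1:50))
  genes <- sample(names(v), 8)
  es1 <- ssgseaScore(v, genes)$es
  expect_equal(ssgseaScore(exp(v), genes)$es, es1, tolerance = 1e-12)
  expect_equal(ssgseaScore(rank(v), genes)$es, es1, tolerance = 1e-12)
})

test_that("ssGSEA matrix is consistent with the single-sample score", {
  set.seed(22)
  m <- matrix(rlnorm(18), 6, 3,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  sets <- list(S1 = c("g1", "g3"), S2 = c("g2", "g5", "g6"))
  scores <- ssgseaMatrix(m, sets)
  expect_equal(scores["S1", "s2"],
               ssgseaScore(setNames(m[, 2], rownames(m)), sets$S1)$es)
  for (s in names(sets)) for (j in 1:3)
    expect_equal(scores[s, j],
                 ssgseaOracle(setNames(m[, j], rownames(m)),
                              sets[[s]], 0.25),
                 tolerance = 1e-12)
  # duplicated sample column gives identical score columns
  m2 <- cbind(m, s4 = m[, 1])
  sc2 <- ssgseaMatrix(m2, sets)
  expect_equal(sc2[, "s4"], sc2[, "s1"])
})

test_that("GSEA running sum is bounded and hits the extreme-top case", {
  set.seed(30)
  nG <- 60
  m <- matrix(rnorm(nG * 8), nG, 8,
              dimnames = list(sprintf("g%02d", 1:nG), paste0("s", 1:8)))
  labels <- rep(c("responder", "resistant"), each = 4)
  # plant set genes with huge group separation: top of the ranking
  setGenes <- sprintf("g%02d", 1:6)
  m[setGenes, labels == "responder"] <- m[setGenes, labels == "responder"] + 50
  res <- gseaContrast(m, labels, setGenes, nPerm = 100, seed = 4,
                      positive = "responder")
  expect_true(res$evaluable)
  expect_lte(res$es, 1)
  expect_gt(res$es, 1 - 6 / nG - 0.05)   # within step-size of +1
  expect_gt(res$es, 0)
  # disjoint set is not evaluable
  expect_false(gseaContrast(m, labels, c("zz1", "zz2"),
                            nPerm = 100)$evaluable)
})

test_that("GSEA is bit-reproducible for a fixed seed", {
  set.seed(31)
  m <- matrix(rlnorm(400), 50, 8,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  labels <- rep(c("a", "b"), each = 4)
  genes <- paste0("g", 1:7)
  r1 <- gseaContrast(m, labels, genes, nPerm = 150, seed = 99)
  r2 <- gseaContrast(m, labels, genes, nPerm = 150, seed = 99)
  expect_identical(r1, r2)
  r3 <- gseaContrast(m, labels, genes, nPerm = 150, seed = 100)
  expect_false(identical(r1$p, r3$p) && identical(r1$nes, r3$nes))
})

test_that("phenotype permutation degenerates to gene-set permutation", {
  set.seed(32)
  m <- matrix(rlnorm(300), 50, 6,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  labels <- c("a", rep("b", 5))
  expect_message(
    r <- gseaContrast(m, labels, paste0("g", 1:5), nPerm = 100,
                      scheme = "phenotype"),
    "switching")
  expect_identical(r$scheme, "geneset")
})

test_that("permutation p-values use the add-one estimator", {
  set.seed(33)
  m <- matrix(rlnorm(200), 25, 8,
              dimnames = list(paste0("g", 1:25), paste0("s", 1:8)))
  labels <- rep(c("a", "b"), each = 4)
  # even a maximally extreme statistic cannot reach p = 0
  m[paste0("g", 1:5), labels == "a"] <- m[paste0("g", 1:5), labels == "a"] + 100
  r <- gseaContrast(m, labels, paste0("g", 1:5), nPerm = 100, seed = 1)
  expect_gte(r$p, 1 / 101)
  expect_lte(r$p, 1)
})

test_that("collection-level GSEA adds BH-adjusted q-values", {
  set.seed(34)
  m <- matrix(rlnorm(500), 50, 10,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  labels <- rep(c("a", "b"), each = 5)
  sets <- list(S1 = paste0("g", 1:6), S2 = paste0("g", 10:16),
               S3 = c("nope1", "nope2"))
  res <- gseaCollection(m, labels, sets, nPerm = 100, seed = 5)
  expect_equal(nrow(res), 3L)
  expect_false(res$evaluable[3])
  ev <- res$evaluable
  expect_equal(res$q_value[ev],
               p.adjust(res$p_value[ev], method = "BH"))
  expect_true(all(res$q_value[ev] >= res$p_value[ev] - 1e-12))
})
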