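# Independent brute-force oracles. These re-derive expected values by
# direct enumeration and stay deliberately naive; they must never call
# the package functions they check.

# ssGSEA: enumerate the running sum position by position.
ssgseaOracle <- function(expr, genes, alpha) {
  r <- rank(expr, ties.method = "average")
  ordered <- names(expr)[order(r, decreasing = TRUE)]
  inSet <- ordered %in% genes
  totIn <- sum(r[ordered[inSet]]^alpha)
  nOut <- sum(!inSet)
  pIn <- 0; pOut <- 0; es <- 0
  for (k in seq_along(ordered)) {
    g <- ordered[k]
    if (inSet[k]) pIn <- pIn + r[g]^alpha / totIn
    else pOut <- pOut + 1 / nOut
    es <- es + (pIn - pOut)
  }
  unname(es)
}

# ROC: exhaustive search over a dense threshold set, both orientations.
rocOracle <- function(values, labels, positive) {
  pos <- labels == positive
  cand <- sort(unique(c(values - 1e-9, values + 1e-9,
                        min(values) - 1, max(values) + 1)))
  best <- list(j = -Inf)
  for (dirHigh in c(TRUE, FALSE)) {
    v <- if (dirHigh) values else -values
    for (t in (if (dirHigh) cand else -cand)) {
      sens <- mean(v[pos] > t)
      spec <- mean(v[!pos] <= t)
      j <- sens + spec - 1
      if (j > best$j + 1e-12 ||
          (abs(j - best$j) <= 1e-12 && spec > best$spec + 1e-12)) {
        best <- list(j = j, sens = sens, spec = spec, dirHigh = dirHigh)
      }
    }
  }
  # AUC by counting correctly ordered pairs (ties half)
  vp <- values[pos]; vn <- values[!pos]
  cnt <- 0
  for (a in vp) for (b in vn)
    cnt <- cnt + (a > b) + 0.5 * (a == b)
  aucHigh <- cnt / (length(vp) * length(vn))
  best$auc <- max(aucHigh, 1 - aucHigh)
  best
}

# Concordance: naive recount over pairs.
concordanceOracle <- function(pairs) {
  drugs <- sort(unique(pairs$drug))
  frac <- numeric(length(drugs))
  perDrug <- data.frame(drug = drugs, n_pairs = 0L, n_dist0 = 0L,
                        n_dist_le1 = 0L)
  for (i in seq_along(drugs)) {
    n0 <- 0L; n1 <- 0L; np <- 0L
    for (k in seq_len(nrow(pairs))) {
      if (pairs$drug[k] != drugs[i]) next
      np <- np + 1L
      d <- abs(pairs$pdx_level[k] - pairs$pd3d_level[k])
      if (d == 0) n0 <- n0 + 1L
      if (d <= 1) n1 <- n1 + 1L
    }
    perDrug$n_pairs[i] <- np; perDrug$n_dist0[i] <- n0
    perDrug$n_dist_le1[i] <- n1
    frac[i] <- n1 / np
  }
  list(perDrug = perDrug, overallMean = 100 * mean(frac),
       overallSD = if (length(frac) > 1) 100 * sd(frac) else 0)
}

# Noise-free 4PL for constructing fixtures.
fourPLCurve <- function(c, top, bottom, ic50, hill)
  bottom + (top - bottom) / (1 + (c / ic50)^hill)
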