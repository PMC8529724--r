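## From-scratch ssGSEA and GSEA. These are the analysis core and are
## deliberately implemented here rather than delegated, so that every
## step (ranking, weighting, running sum, permutation) is testable
## against brute-force oracles.

#' Single-sample gene set enrichment score (ssGSEA)
#'
#' Genes are ranked by descending expression within the sample (ties
#' receive average ranks, so the score is invariant under strictly
#' monotone transforms of the expression values). Walking down the
#' ranked list, the enrichment score is the sum over positions of the
#' difference between the weighted in-set empirical CDF (weights
#' rank^alpha, normalized over the set) and the unweighted out-of-set
#' ECDF.
#'
#' @param expr named numeric vector: one sample's expression, names =
#'   gene symbols.
#' @param genes character vector of set member symbols; members absent
#'   from `expr` are dropped (counted in the result).
#' @param alpha rank-weighting exponent, >= 0; default 0.25, the
#'   standard choice for this score.
#' @return list: `es`, `nGenesUsed`, `nGenesDropped`, `evaluable`
#'   (FALSE when no set gene is present or the complement is empty —
#'   the degenerate all-genes set scores `es = 0`).
#' @export
ssgseaScore <- function(expr, genes, alpha = 0.25) {
  stopifnot(is.numeric(expr), !is.null(names(expr)), alpha >= 0)
  if (anyDuplicated(names(expr))) stop("duplicate gene symbols in sample")
  genes <- unique(genes)
  present <- genes[genes %in% names(expr)]
  dropped <- length(genes) - length(present)
  n <- length(expr)
  if (length(present) == 0L)
    return(list(es = NA_real_, nGenesUsed = 0L, nGenesDropped = dropped,
                evaluable = FALSE))
  if (length(present) == n)
    return(list(es = 0, nGenesUsed = n, nGenesDropped = dropped,
                evaluable = FALSE))
  r <- rank(expr, ties.method = "average")      # high expression = high rank
  ord <- order(r, decreasing = TRUE)
  inSet <- names(expr)[ord] %in% present
  w <- r[ord]^alpha
  pIn <- cumsum(ifelse(inSet, w, 0)) / sum(w[inSet])
  pOut <- cumsum(!inSet) / (n - length(present))
  list(es = sum(pIn - pOut), nGenesUsed = length(present),
       nGenesDropped = dropped, evaluable = TRUE)
}

#' ssGSEA scores for a collection over all samples
#'
#' @param x expression matrix (genes x samples), data.frame or
#'   SummarizedExperiment (assay 1).
#' @param gsc a [GeneSetCollection] or named list of gene vectors.
#' @param alpha rank-weighting exponent, see [ssgseaScore()].
#' @param normalize divide all scores by (max - min) over the whole
#'   score matrix (the standard projection normalization).
#' @return numeric matrix, sets x samples; `NA` where a set was not
#'   evaluable in a sample.
#' @export
ssgseaMatrix <- function(x, gsc, alpha = 0.25, normalize = FALSE) {
  m <- .asExprMatrix(x)
  sets <- if (is(gsc, "GeneSetCollection")) geneSets(gsc) else gsc
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- matrix(NA_real_, length(sets), ncol(m),
                dimnames = list(names(sets), colnames(m)))
  for (j in seq_len(ncol(m))) {
    v <- stats::setNames(m[, j], rownames(m))
    for (i in seq_along(sets)) {
      sc <- ssgseaScore(v, sets[[i]], alpha = alpha)
      out[i, j] <- if (sc$evaluable || sc$nGenesUsed == nrow(m)) sc$es
                   else NA_real_
    }
  }
  if (normalize) {
    rng <- range(out, na.rm = TRUE)
    if (diff(rng) > 0) out <- out / diff(rng)
  }
  out
}

## Signal-to-noise ranking metric per gene: (mean1 - mean2)/(sd1 + sd2),
## with the denominator floored to avoid division by zero on
## zero-variance genes.
.signal2noise <- function(m, grp1, grp2) {
  m1 <- rowMeans(m[, grp1, drop = FALSE])
  m2 <- rowMeans(m[, grp2, drop = FALSE])
  s1 <- apply(m[, grp1, drop = FALSE], 1, stats::sd)
  s2 <- apply(m[, grp2, drop = FALSE], 1, stats::sd)
  s1[is.na(s1)] <- 0                     # single-sample group
  s2[is.na(s2)] <- 0
  den <- s1 + s2
  den[den < .Machine$double.eps] <- .Machine$double.eps
  (m1 - m2) / den
}

## Weighted Kolmogorov-Smirnov running-sum extremum on a ranked metric.
## metric must be sorted decreasingly; inSet logical along it.
.ksRunningES <- function(metric, inSet, weightExp = 1) {
  w <- abs(metric)^weightExp
  wIn <- ifelse(inSet, w, 0)
  sumIn <- sum(wIn)
  nOut <- sum(!inSet)
  if (sumIn == 0 || nOut == 0) return(NA_real_)
  running <- cumsum(wIn / sumIn - (!inSet) / nOut)
  running[which.max(abs(running))]
}

#' Two-group GSEA with permutation significance
#'
#' Ranks genes by the signal-to-noise metric between the two phenotype
#' groups (stable sort, deterministic gene-name tiebreak), computes the
#' weighted Kolmogorov-Smirnov running-sum extremum (weight exponent 1
#' on the absolute metric) as the enrichment score, and assesses
#' significance by permutation. Gene-set permutation (random same-size
#' sets) is the default because phenotype permutation degenerates for
#' the tiny group sizes typical of PDX cohorts; phenotype permutation
#' is available when both groups have >= `minPhenotypeN` samples, and
#' a phenotype request with a group of < 2 samples falls back to
#' gene-set permutation with a message.
#'
#' The permutation p-value uses the add-one estimator
#' (b + 1) / (nPerm + 1), so it is never exactly 0; NES divides the
#' observed ES by the mean |ES| of same-sign permutations.
#'
#' @param x expression matrix (genes x samples) or
#'   SummarizedExperiment.
#' @param labels character/factor of length ncol(x) with exactly two
#'   levels; the first level sorted alphabetically is the "up" group
#'   unless `positive` says otherwise.
#' @param genes character vector: the gene set to test.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @param scheme `"geneset"` (default) or `"phenotype"`.
#' @param positive label treated as the first group (numerator of the
#'   metric); default: first sorted level.
#' @param minPhenotypeN minimal per-group size for phenotype
#'   permutation (default 7).
#' @return list: `es`, `nes`, `p`, `nPerm`, `scheme`, `evaluable`,
#'   `nGenesUsed`.
#' @export
gseaContrast <- function(x, labels, genes, nPerm = 1000, seed = 1,
                         scheme = c("geneset", "phenotype"),
                         positive = NULL, minPhenotypeN = 7) {
  scheme <- match.arg(scheme)
  m <- .asExprMatrix(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m), nPerm >= 100)
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("labels must have exactly two levels")
  if (is.null(positive)) positive <- lev[1]
  stopifnot(positive %in% lev)
  grp1 <- labels == positive
  grp2 <- !grp1
  if (scheme == "phenotype" && (sum(grp1) < 2 || sum(grp2) < 2)) {
    message("group size < 2: switching to gene-set permutation")
    scheme <- "geneset"
  }
  if (scheme == "phenotype" && (sum(grp1) < minPhenotypeN ||
                                sum(grp2) < minPhenotypeN)) {
    message("groups below minPhenotypeN: switching to gene-set permutation")
    scheme <- "geneset"
  }

  genes <- unique(genes)
  present <- genes[genes %in% rownames(m)]
  if (length(present) == 0L || length(present) == nrow(m))
    return(list(es = NA_real_, nes = NA_real_, p = NA_real_,
                nPerm = nPerm, scheme = scheme, evaluable = FALSE,
                nGenesUsed = length(present)))

  rankOrder <- function(metric) {
    # stable decreasing sort with deterministic gene-name tiebreak
    order(-metric, rownames(m), method = "radix")
  }
  metric <- .signal2noise(m, grp1, grp2)
  ord <- rankOrder(metric)
  inSet <- rownames(m)[ord] %in% present
  esObs <- .ksRunningES(metric[ord], inSet)

  set.seed(seed)
  esPerm <- numeric(nPerm)
  if (scheme == "geneset") {
    sortedMetric <- metric[ord]
    k <- length(present)
    for (b in seq_len(nPerm)) {
      idx <- sample.int(nrow(m), k)
      flag <- logical(nrow(m)); flag[idx] <- TRUE
      esPerm[b] <- .ksRunningES(sortedMetric, flag)
    }
  } else {
    for (b in seq_len(nPerm)) {
      permGrp1 <- logical(ncol(m))
      permGrp1[sample.int(ncol(m), sum(grp1))] <- TRUE
      pm <- .signal2noise(m, permGrp1, !permGrp1)
      po <- rankOrder(pm)
      esPerm[b] <- .ksRunningES(pm[po], rownames(m)[po] %in% present)
    }
  }
  p <- (sum(abs(esPerm) >= abs(esObs)) + 1) / (nPerm + 1)
  sameSign <- esPerm[sign(esPerm) == sign(esObs)]
  nes <- if (length(sameSign)) esObs / mean(abs(sameSign)) else NA_real_
  list(es = esObs, nes = nes, p = p, nPerm = nPerm, scheme = scheme,
       evaluable = TRUE, nGenesUsed = length(present))
}

#' GSEA over a gene-set collection with BH correction
#'
#' Runs [gseaContrast()] for every set in a collection and adjusts the
#' permutation p-values by Benjamini-Hochberg across sets.
#'
#' @inheritParams gseaContrast
#' @param gsc a [GeneSetCollection] or named list of gene vectors.
#' @return `data.frame`: `set`, `es`, `nes`, `p_value`, `q_value`,
#'   `n_perm`, `seed`, `n_genes_used`, `evaluable`.
#' @export
gseaCollection <- function(x, labels, gsc, nPerm = 1000, seed = 1,
                           scheme = c("geneset", "phenotype"),
                           positive = NULL) {
  scheme <- match.arg(scheme)
  sets <- if (is(gsc, "GeneSetCollection")) geneSets(gsc) else gsc
  rows <- lapply(seq_along(sets), function(i) {
    r <- gseaContrast(x, labels, sets[[i]], nPerm = nPerm,
                      seed = seed + i - 1L, scheme = scheme,
                      positive = positive)
    data.frame(set = names(sets)[i], es = r$es, nes = r$nes,
               p_value = r$p, n_perm = r$nPerm, seed = seed + i - 1L,
               n_genes_used = r$nGenesUsed, evaluable = r$evaluable)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q_value <- NA_real_
  ev <- out$evaluable
  out$q_value[ev] <- stats::p.adjust(out$p_value[ev], method = "BH")
  out[, c("set", "es", "nes", "p_value", "q_value", "n_perm", "seed",
          "n_genes_used", "evaluable")]
}
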