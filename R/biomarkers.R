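#' Responder-versus-resistant differential contrast
#'
#' Per-feature Welch two-sample t-test on log2 values with
#' Benjamini-Hochberg correction across features. The log2 fold change
#' is the responder-minus-resistant difference of group means on the
#' log2 scale. Linear-scale input is transformed as log2(x + 1).
#' Features with zero variance in both groups are flagged
#' not-evaluable (`NA` p).
#'
#' @param x expression matrix (features x samples) or
#'   SummarizedExperiment.
#' @param labels two-level character/factor of length ncol(x).
#' @param scale `"log2"` (values already log2) or `"linear"`.
#' @param positive label used as the first group (responders by
#'   convention); default: first sorted level.
#' @return `data.frame`: `feature`, `log2fc`, `p_value`, `q_value`,
#'   `n_group1`, `n_group2`.
#' @export
groupContrast <- function(x, labels, scale = c("log2", "linear"),
                          positive = NULL) {
  scale <- match.arg(scale)
  m <- .asExprMatrix(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m))
  lev <- sort(unique(labels))
  if (length(lev) != 2L) stop("labels must have exactly two levels")
  if (is.null(positive)) positive <- lev[1]
  g1 <- labels == positive; g2 <- !g1
  if (sum(g1) < 2 || sum(g2) < 2) stop("both groups need >= 2 samples")
  if (scale == "linear") m <- log2(m + 1)
  m1 <- m[, g1, drop = FALSE]; m2 <- m[, g2, drop = FALSE]
  lfc <- rowMeans(m1) - rowMeans(m2)
  v1 <- apply(m1, 1, stats::var); v2 <- apply(m2, 1, stats::var)
  n1 <- sum(g1); n2 <- sum(g2)
  p <- rep(NA_real_, nrow(m))
  ok <- v1 + v2 > 0
  se2 <- v1 / n1 + v2 / n2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(abs(tstat[ok]), df[ok], lower.tail = FALSE)
  q <- rep(NA_real_, nrow(m))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(feature = rownames(m), log2fc = lfc, p_value = p,
             q_value = q, n_group1 = n1, n_group2 = n2,
             row.names = NULL)
}

#' ROC-based biomarker cutoff selection
#'
#' Builds the empirical ROC over all midpoint thresholds between
#' sorted unique values, computes the AUC by the rank statistic
#' (probability of correct ordering, ties counting one half), orients
#' the marker so that AUC >= 0.5 (recording whether responders are
#' high or low), and selects the cutoff maximizing the Youden index
#' J = sensitivity + specificity - 1, breaking ties toward higher
#' specificity.
#'
#' @param values per-sample feature values.
#' @param labels two-level vector; `positive` names the responder
#'   class.
#' @param positive responder label; default: first sorted level.
#' @param feature,drug,sampleType identifiers carried into the record.
#' @return one-row `data.frame`: `feature`, `drug`, `sample_type`,
#'   `auc`, `direction` (`high_in_responder`/`low_in_responder`),
#'   `cutoff`, `sensitivity`, `specificity`.
#' @export
rocCutoff <- function(values, labels, positive = NULL,
                      feature = "feature", drug = "drug",
                      sampleType = "PDX") {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels))
  if (length(values) < 3L) stop("ROC needs >= 3 samples")
  lev <- sort(unique(labels))
  if (length(lev) != 2L)
    stop("both classes must be present; got: ", paste(lev, collapse = ", "))
  if (is.null(positive)) positive <- lev[1]
  pos <- labels == positive

  # AUC by rank statistic: P(value_pos > value_neg) + 0.5 P(tie)
  r <- rank(values)
  nPos <- sum(pos); nNeg <- sum(!pos)
  aucHigh <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  if (aucHigh >= 0.5) {
    direction <- "high_in_responder"; auc <- aucHigh; v <- values
  } else {
    direction <- "low_in_responder"; auc <- 1 - aucHigh; v <- -values
  }

  # thresholds: midpoints between sorted unique (oriented) values,
  # plus sentinels capturing the all-positive / all-negative calls
  u <- sort(unique(v))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(v[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(v[!pos] <= t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]         # ties -> higher specificity
  cutoff <- if (direction == "high_in_responder") thr[best] else -thr[best]
  data.frame(feature = feature, drug = drug, sample_type = sampleType,
             auc = auc, direction = direction, cutoff = cutoff,
             sensitivity = sens[best], specificity = spec[best])
}

#' ROC records for every feature of a matrix
#'
#' @inheritParams groupContrast
#' @param drug,sampleType identifiers stamped on every record.
#' @param positive responder label.
#' @return `data.frame` of [rocCutoff()] rows, one per feature.
#' @export
rocTable <- function(x, labels, drug = "drug", sampleType = "PDX",
                     positive = NULL) {
  m <- .asExprMatrix(x)
  do.call(rbind, c(lapply(rownames(m), function(f)
    rocCutoff(m[f, ], labels, positive = positive, feature = f,
              drug = drug, sampleType = sampleType)),
    list(make.row.names = FALSE)))
}

#' Match predictive biomarkers across sample types
#'
#' A feature counts as a matched biomarker for a drug when, in every
#' supplied sample type, its ROC record passes the sensitivity and
#' specificity floors with a consistent direction. Output is sorted by
#' decreasing mean AUC.
#'
#' @param records `data.frame` of [rocCutoff()] rows covering >= 2
#'   sample types.
#' @param minSens,minSpec floors applied in every sample type
#'   (defaults 0.8).
#' @return `data.frame`: `feature`, `drug`, `direction`, `mean_auc`,
#'   `n_sample_types`, plus per-type columns `auc_<type>`.
#' @export
matchBiomarkers <- function(records, minSens = 0.8, minSpec = 0.8) {
  types <- unique(records$sample_type)
  if (length(types) < 2L) stop("need records from >= 2 sample types")
  pass <- records[records$sensitivity >= minSens &
                  records$specificity >= minSpec, , drop = FALSE]
  out <- list()
  keys <- unique(pass[, c("feature", "drug")])
  for (k in seq_len(nrow(keys))) {
    sub <- pass[pass$feature == keys$feature[k] &
                pass$drug == keys$drug[k], , drop = FALSE]
    if (!all(types %in% sub$sample_type)) next
    if (length(unique(sub$direction)) != 1L) next
    row <- data.frame(feature = keys$feature[k], drug = keys$drug[k],
                      direction = sub$direction[1],
                      mean_auc = mean(sub$auc),
                      n_sample_types = length(types))
    for (ty in types)
      row[[paste0("auc_", ty)]] <- sub$auc[sub$sample_type == ty][1]
    out[[k]] <- row
  }
  if (length(out) == 0L) {
    res <- data.frame(feature = character(), drug = character(),
                      direction = character(), mean_auc = numeric(),
                      n_sample_types = integer())
    for (ty in types) res[[paste0("auc_", ty)]] <- numeric()
    return(res)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(-res$mean_auc), , drop = FALSE]
}
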