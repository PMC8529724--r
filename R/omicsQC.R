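#' Pairwise correlations of matched and unmatched samples
#'
#' For every row of the pairing table, Pearson correlation on
#' log2(x + 1)-scaled abundances and Spearman correlation on raw ranks
#' are computed over the features shared by the two samples. Pairs
#' with fewer shared features than the floor are flagged and excluded
#' from downstream summaries.
#'
#' @param x expression matrix (features x samples) or
#'   SummarizedExperiment; columns must cover the samples named in the
#'   pairing table.
#' @param pairing `data.frame`: `sample_a`, `sample_b`, `relation`
#'   (e.g. patient-PDX, PDX-PD3D, unmatched), `layer` (transcriptome /
#'   proteome / phosphoproteome).
#' @param minFeatures minimal shared-feature count (default 10).
#' @param log2Transform apply log2(x + 1) before Pearson (default
#'   TRUE; set FALSE when the matrix is already on log scale).
#' @return `data.frame`: pairing columns plus `pearson_r`,
#'   `spearman_rho`, `n_features`, `evaluable`.
#' @export
pairwiseCorrelations <- function(x, pairing, minFeatures = 10,
                                 log2Transform = TRUE) {
  m <- .asExprMatrix(x)
  need <- c("sample_a", "sample_b", "relation", "layer")
  stopifnot(all(need %in% names(pairing)))
  missing <- setdiff(unique(c(pairing$sample_a, pairing$sample_b)),
                     colnames(m))
  if (length(missing))
    stop("samples absent from matrix: ", paste(missing, collapse = ", "))
  ml <- if (log2Transform) log2(m + 1) else m
  rows <- lapply(seq_len(nrow(pairing)), function(i) {
    a <- pairing$sample_a[i]; b <- pairing$sample_b[i]
    ok <- is.finite(m[, a]) & is.finite(m[, b])
    n <- sum(ok)
    evaluable <- n >= minFeatures
    data.frame(
      sample_a = a, sample_b = b,
      relation = pairing$relation[i], layer = pairing$layer[i],
      pearson_r = if (evaluable)
        stats::cor(ml[ok, a], ml[ok, b], method = "pearson") else NA_real_,
      spearman_rho = if (evaluable)
        stats::cor(m[ok, a], m[ok, b], method = "spearman") else NA_real_,
      n_features = n, evaluable = evaluable)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Tukey box-plot summary
#'
#' Quartiles by linear interpolation (quantile type 7); whiskers reach
#' the most extreme data points within 1.5 x IQR of the quartiles;
#' points beyond the fences are outliers. Outliers and in-fence points
#' partition the input.
#'
#' @param values numeric vector, >= 1 finite value.
#' @return list: `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`.
#' @export
tukeySummary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("no finite values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  loFence <- q[1] - 1.5 * iqr
  hiFence <- q[3] + 1.5 * iqr
  inFence <- values >= loFence & values <= hiFence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[inFence]),
       whisker_hi = max(values[inFence]),
       outliers = values[!inFence])
}

.VARIANT_STATUS <- c("pathogenic", "non_pathogenic_or_uncertain", "reference")

#' Variant-status concordance along model lineages
#'
#' For every gene and model lineage (patient sample plus its derived
#' PDX/PD3D models) a mutation is "maintained" when pathogenic status
#' is present in the patient sample and in at least one derived model.
#' Pathogenic status appearing only in a derived model is flagged as a
#' gain. Matching is by gene and status class, not genomic coordinate.
#'
#' @param variants `data.frame`: `gene`, `sample`, `status` (one of
#'   pathogenic / non_pathogenic_or_uncertain / reference).
#' @param lineage `data.frame`: `sample`, `lineage`, `role`
#'   (`patient` or a derived-model role such as `PDX`, `PD3D`).
#' @return list: `byLineage` (`data.frame`: gene, lineage,
#'   patient_pathogenic, model_pathogenic, maintained, gain_in_model)
#'   and `statusGrid` (gene x sample character matrix, `reference`
#'   where no row was supplied).
#' @export
variantConcordance <- function(variants, lineage) {
  stopifnot(all(c("gene", "sample", "status") %in% names(variants)),
            all(c("sample", "lineage", "role") %in% names(lineage)))
  bad <- setdiff(unique(variants$status), .VARIANT_STATUS)
  if (length(bad))
    stop("unknown variant status: ", paste(bad, collapse = ", "),
         "; legal classes: ", paste(.VARIANT_STATUS, collapse = ", "))
  genes <- sort(unique(variants$gene))
  samples <- unique(lineage$sample)
  grid <- matrix("reference", length(genes), length(samples),
                 dimnames = list(genes, samples))
  known <- variants[variants$sample %in% samples, , drop = FALSE]
  for (i in seq_len(nrow(known)))
    grid[known$gene[i], known$sample[i]] <- known$status[i]
  rows <- list()
  for (ln in unique(lineage$lineage)) {
    pat <- lineage$sample[lineage$lineage == ln & lineage$role == "patient"]
    der <- lineage$sample[lineage$lineage == ln & lineage$role != "patient"]
    for (g in genes) {
      patPath <- length(pat) > 0 && any(grid[g, pat] == "pathogenic")
      modPath <- length(der) > 0 && any(grid[g, der] == "pathogenic")
      rows[[paste(ln, g)]] <- data.frame(
        gene = g, lineage = ln,
        patient_pathogenic = patPath, model_pathogenic = modPath,
        maintained = patPath && modPath,
        gain_in_model = !patPath && modPath)
    }
  }
  byLineage <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else data.frame(gene = character(), lineage = character(),
                  patient_pathogenic = logical(),
                  model_pathogenic = logical(),
                  maintained = logical(), gain_in_model = logical())
  list(byLineage = byLineage, statusGrid = grid)
}
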