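## Ordinal response scale shared by both platforms:
## 0 strong, 1 moderate, 2 minor, 3 resistant.
.CATEGORY_LEVELS <- c("strong", "moderate", "minor", "resistant")
.CATEGORY_BOUNDS <- list(PDX = c(10, 25, 50), PD3D = c(30, 60, 80))

#' Categorize a drug response on the four-level ordinal scale
#'
#' PDX T/C values map as strong <= 10 %, moderate (10, 25] %, minor
#' (25, 50] %, resistant > 50 %; PD3D viability at Cmax maps as strong
#' <= 30 %, moderate (30, 60] %, minor (60, 80] %, resistant > 80 %.
#' Boundaries are inclusive on the better-response side, so the printed
#' integer intervals (0-10, 11-25, ...) are preserved and real values
#' are well-defined. Vectorized over `value`.
#'
#' @param value raw response in percent (T/C or viability at Cmax),
#'   >= 0.
#' @param platform `"PDX"` or `"PD3D"`.
#' @return integer level(s) 0-3 with attribute-free labels available
#'   via [categoryLabel()].
#' @examples
#' categorize(7, "PDX")    # 0 (strong)
#' categorize(25, "PDX")   # 1 (moderate; boundary inclusive)
#' categorize(81, "PD3D")  # 3 (resistant)
#' @export
categorize <- function(value, platform = c("PDX", "PD3D")) {
  platform <- match.arg(platform)
  if (any(value < 0)) stop("response values must be non-negative")
  b <- .CATEGORY_BOUNDS[[platform]]
  findInterval(value, b, left.open = TRUE)
}

#' @rdname categorize
#' @param level integer level(s) in 0-3.
#' @export
categoryLabel <- function(level) {
  stopifnot(all(level %in% 0:3))
  .CATEGORY_LEVELS[level + 1L]
}

#' Pair PDX and PD3D responses of the same model x drug
#'
#' Joins a response-annotation table on (model, drug) across the two
#' platforms, categorizes each raw value on its platform's scale, and
#' reports the absolute ordinal distance. Entries present on only one
#' platform are excluded with a message; duplicate (model, drug,
#' platform) rows are an error.
#'
#' @param responses response-schema `data.frame`: columns `model`,
#'   `drug`, `platform` (`PDX`/`PD3D`), `response_value` (percent).
#' @return `data.frame`: `model`, `drug`, `pdx_value`, `pd3d_value`,
#'   `pdx_level`, `pd3d_level`, `distance`.
#' @export
concordancePairs <- function(responses) {
  need <- c("model", "drug", "platform", "response_value")
  stopifnot(all(need %in% names(responses)))
  key <- paste(responses$model, responses$drug, responses$platform,
               sep = "\r")
  if (anyDuplicated(key)) {
    dup <- responses[duplicated(key), c("model", "drug", "platform")]
    stop("duplicate response entries: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  }
  pdx <- responses[responses$platform == "PDX", ]
  pd3d <- responses[responses$platform == "PD3D", ]
  mk <- function(df) paste(df$model, df$drug, sep = "\r")
  merged <- merge(pdx, pd3d, by = c("model", "drug"),
                  suffixes = c("_pdx", "_pd3d"))
  nUnpaired <- nrow(pdx) + nrow(pd3d) - 2L * nrow(merged)
  if (nUnpaired > 0)
    message(sprintf("%d unpaired response entr%s excluded",
                    nUnpaired, if (nUnpaired == 1) "y" else "ies"))
  if (nrow(merged) == 0L)
    return(data.frame(model = character(), drug = character(),
                      pdx_value = numeric(), pd3d_value = numeric(),
                      pdx_level = integer(), pd3d_level = integer(),
                      distance = integer()))
  lv1 <- categorize(merged$response_value_pdx, "PDX")
  lv2 <- categorize(merged$response_value_pd3d, "PD3D")
  out <- data.frame(
    model = merged$model, drug = merged$drug,
    pdx_value = merged$response_value_pdx,
    pd3d_value = merged$response_value_pd3d,
    pdx_level = lv1, pd3d_level = lv2,
    distance = abs(lv1 - lv2)
  )
  out[order(out$drug, out$model), , drop = FALSE]
}

#' Summarize cross-platform concordance per drug and overall
#'
#' For each drug: the number of pairs, the count at ordinal distance 0
#' (identical category, "high concordance") and at distance <= 1
#' ("moderate or high"), and the moderate-or-high fraction. Overall,
#' the mean and sample SD (n - 1) of the per-drug fractions are
#' reported in percent; a pooled fraction over all pairs is reported
#' alongside.
#'
#' @param pairs output of [concordancePairs()].
#' @return list: `perDrug` (`data.frame`: drug, n_pairs, n_dist0,
#'   n_dist_le1, fraction), `overallMean`, `overallSD`,
#'   `pooledPercent`.
#' @export
summarizeConcordance <- function(pairs) {
  if (nrow(pairs) == 0L) stop("no concordance pairs to summarize")
  drugs <- sort(unique(pairs$drug))
  perDrug <- do.call(rbind, lapply(drugs, function(d) {
    p <- pairs[pairs$drug == d, ]
    data.frame(drug = d, n_pairs = nrow(p),
               n_dist0 = sum(p$distance == 0L),
               n_dist_le1 = sum(p$distance <= 1L),
               fraction = mean(p$distance <= 1L))
  }))
  rownames(perDrug) <- NULL
  fr <- perDrug$fraction
  list(perDrug = perDrug,
       overallMean = 100 * mean(fr),
       overallSD = if (length(fr) > 1) 100 * stats::sd(fr) else 0,
       pooledPercent = 100 * mean(pairs$distance <= 1L))
}

#' Category-pair counts per drug for bubble-plot rendering
#'
#' @param pairs output of [concordancePairs()].
#' @return list with `perDrug` (named list of 4 x 4 integer matrices,
#'   rows = PDX level, columns = PD3D level, labelled strong/moderate/
#'   minor/resistant; entries sum to the drug's pair count) and
#'   `total` (the sum over drugs; all-zero for an empty pair list).
#' @export
bubbleAggregate <- function(pairs) {
  grid0 <- function() matrix(0L, 4, 4,
                             dimnames = list(PDX = .CATEGORY_LEVELS,
                                             PD3D = .CATEGORY_LEVELS))
  drugs <- sort(unique(pairs$drug))
  perDrug <- lapply(drugs, function(d) {
    p <- pairs[pairs$drug == d, ]
    m <- grid0()
    for (i in seq_len(nrow(p)))
      m[p$pdx_level[i] + 1L, p$pd3d_level[i] + 1L] <-
        m[p$pdx_level[i] + 1L, p$pd3d_level[i] + 1L] + 1L
    m
  })
  total <- Reduce(`+`, perDrug, grid0())
  list(perDrug = stats::setNames(perDrug, drugs), total = total)
}
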