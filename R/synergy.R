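#' Confluence-normalized cytotoxicity matrix for a combination plate
#'
#' For every (doseA, doseB) cell the replicate mean of fluorescence /
#' same-well confluence is computed; wells with zero confluence are
#' flagged invalid and excluded from both the cell mean and the plate
#' median. The median-relative map subtracts the median over all valid
#' cells (the plate heatmap convention: blue below the median, red
#' above).
#'
#' @param plate combination-schema `data.frame` for one model and drug
#'   pair: columns `model`, `drugA`, `doseA_uM`, `drugB`, `doseB_uM`,
#'   `replicate`, `fluorescence`, `confluence`.
#' @return a [CombinationMatrix].
#' @export
normalizeCytotoxicity <- function(plate) {
  need <- c("model", "drugA", "doseA_uM", "drugB", "doseB_uM",
            "replicate", "fluorescence", "confluence")
  stopifnot(all(need %in% names(plate)))
  if (any(plate$fluorescence < 0)) stop("fluorescence must be non-negative")
  invalid <- plate$confluence <= 0
  nInvalid <- sum(invalid)
  if (nInvalid > 0)
    message(sprintf("%d well(s) with zero confluence flagged invalid",
                    nInvalid))
  ok <- plate[!invalid, , drop = FALSE]
  if (nrow(ok) == 0L) stop("no valid wells on plate")
  dosesA <- sort(unique(plate$doseA_uM))
  dosesB <- sort(unique(plate$doseB_uM))
  ratio <- ok$fluorescence / ok$confluence
  m <- matrix(NA_real_, length(dosesA), length(dosesB),
              dimnames = list(A = dosesA, B = dosesB))
  agg <- tapply(ratio, list(factor(ok$doseA_uM, levels = dosesA),
                            factor(ok$doseB_uM, levels = dosesB)), mean)
  m[, ] <- agg
  med <- stats::median(m, na.rm = TRUE)
  new("CombinationMatrix",
      model = as.character(plate$model[1]),
      drugA = as.character(plate$drugA[1]),
      drugB = as.character(plate$drugB[1]),
      dosesA = dosesA, dosesB = dosesB,
      normCytotox = m, medianRelative = m - med,
      nInvalid = as.integer(nInvalid))
}

#' Bliss excess of a drug combination
#'
#' Bliss independence expects a combined effect
#' \eqn{E_{AB} = E_A + E_B - E_A E_B}; the excess
#' \eqn{E_{AB}^{obs} - E_{AB}^{Bliss}} is positive for synergy and
#' negative for antagonism. Effects are fractions in [0, 1] (effect =
#' 1 - normalized viability, or scaled cytotoxicity); values straying
#' outside by at most 0.05 are clamped, larger excursions are an
#' error. Vectorized and symmetric in the two monotherapy effects.
#'
#' @param effectA,effectB monotherapy effect fractions.
#' @param effectAB observed combination effect fraction.
#' @return Bliss excess in [-1, 1].
#' @examples
#' blissExcess(0.5, 0.5, 0.75)  # 0: exact Bliss independence
#' blissExcess(0.5, 0.5, 0.9)   # 0.15: synergy
#' @export
blissExcess <- function(effectA, effectB, effectAB) {
  clamp <- function(e, nm) {
    if (any(e < -0.05 | e > 1.05))
      stop(nm, " effect outside [0, 1] beyond clamping tolerance 0.05")
    pmin(pmax(e, 0), 1)
  }
  a <- clamp(effectA, "drug A"); b <- clamp(effectB, "drug B")
  ab <- clamp(effectAB, "combination")
  ab - (a + b - a * b)
}

#' Per-cell Bliss excess over a combination plate
#'
#' Converts the plate's normalized cytotoxicity to effect fractions by
#' dividing by the maximal cell value (a documented scaling
#' convention; meaningful when the strongest condition approaches
#' complete kill), reads monotherapy effects off the dose-0 row and
#' column, and reports the Bliss excess for every true combination
#' cell plus the mean over those cells.
#'
#' @param cm a [CombinationMatrix].
#' @return list: `excess` (matrix over combination cells, `NA` in the
#'   monotherapy row/column), `meanExcess`, `effects` (scaled effect
#'   matrix).
#' @export
plateBlissExcess <- function(cm) {
  stopifnot(is(cm, "CombinationMatrix"))
  m <- cm@normCytotox
  mx <- max(m, na.rm = TRUE)
  if (mx <= 0) stop("plate has no positive cytotoxicity signal")
  eff <- pmin(pmax(m / mx, 0), 1)
  effA <- eff[, cm@dosesB == 0]
  effB <- eff[cm@dosesA == 0, ]
  excess <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in which(cm@dosesA > 0)) for (j in which(cm@dosesB > 0)) {
    if (is.na(eff[i, j]) || is.na(effA[i]) || is.na(effB[j])) next
    excess[i, j] <- blissExcess(effA[i], effB[j], eff[i, j])
  }
  list(excess = excess,
       meanExcess = mean(excess, na.rm = TRUE),
       effects = eff)
}

#' Combination gain over the best monotherapy at Cmax
#'
#' Highest-single-agent style readout for viability experiments at
#' Cmax: gain = min(monoA, monoB) - combo viability, in percent.
#' Positive gain means the combination outperforms the better
#' monotherapy.
#'
#' @param monoA,monoB monotherapy viabilities at Cmax, percent.
#' @param combo combination viability at Cmax, percent.
#' @return gain in percentage points.
#' @examples
#' cmaxCombinationGain(80, 90, 40)  # 40
#' @export
cmaxCombinationGain <- function(monoA, monoB, combo) {
  if (any(c(monoA, monoB, combo) < 0)) stop("viabilities must be >= 0")
  pmin(monoA, monoB) - combo
}

#' Per-cell and summary synergy results for a combination plate table
#'
#' @param records combination-schema `data.frame`, possibly several
#'   plates (model x drug pair).
#' @return list: `cells` (`data.frame`: model, drugA, drugB, doseA_uM,
#'   doseB_uM, norm_cytotox, median_relative, bliss_excess), `summary`
#'   (`data.frame`: model, drugA, drugB, mean_excess).
#' @export
synergyTable <- function(records) {
  keys <- unique(records[, c("model", "drugA", "drugB")])
  cells <- list(); summ <- list()
  for (k in seq_len(nrow(keys))) {
    sel <- records$model == keys$model[k] &
      records$drugA == keys$drugA[k] & records$drugB == keys$drugB[k]
    cm <- normalizeCytotoxicity(records[sel, , drop = FALSE])
    bl <- plateBlissExcess(cm)
    grid <- expand.grid(doseA_uM = cm@dosesA, doseB_uM = cm@dosesB,
                        KEEP.OUT.ATTRS = FALSE)
    cells[[k]] <- data.frame(
      model = keys$model[k], drugA = keys$drugA[k], drugB = keys$drugB[k],
      grid,
      norm_cytotox = as.vector(cm@normCytotox),
      median_relative = as.vector(cm@medianRelative),
      bliss_excess = as.vector(bl$excess))
    summ[[k]] <- data.frame(
      model = keys$model[k], drugA = keys$drugA[k], drugB = keys$drugB[k],
      mean_excess = bl$meanExcess)
  }
  list(cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
       summary = do.call(rbind, c(summ, list(make.row.names = FALSE))))
}
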