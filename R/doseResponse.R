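## 4PL viability model: v(c) = bottom + (top - bottom)/(1 + (c/ic50)^hill)
## hill > 0 means viability decreases with dose.
.fourPL <- function(c, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (c / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{v(c) = bottom + (top - bottom) / (1 + (c/IC50)^{hill})}
#' to individual replicate points (replicates are not pre-averaged, so
#' doses with more replicates carry proportionally more weight).
#' Bounds: 0 <= bottom <= top <= 1.2, hill in (0, 10], ic50 in
#' [min dose / 10, max dose x 10]. Initialisation takes top/bottom from
#' the extreme-dose means and ic50 from the dose bracketing the
#' half-range crossing, with hill = 1; up to 3 perturbed starts are
#' tried on non-convergence. Zero doses are excluded from the fit
#' domain (the curve is defined for c > 0); an all-identical viability
#' vector yields a flat fit with undefined ic50.
#'
#' @param conc concentrations in uM (>= 4 distinct positive values).
#' @param viability viability fractions, parallel to `conc`.
#' @param model,drug identifiers carried into the result.
#' @return a [DoseResponseFit].
#' @export
fit4PL <- function(conc, viability, model = "model", drug = "drug") {
  stopifnot(length(conc) == length(viability))
  keep <- conc > 0
  conc <- conc[keep]; viability <- viability[keep]
  doses <- sort(unique(conc))
  if (length(doses) < 4L)
    stop("4PL fit needs >= 4 distinct positive concentrations")
  if (any(viability < 0)) stop("viability must be non-negative")
  means <- vapply(doses, function(d) mean(viability[conc == d]), numeric(1))

  mk <- function(top, bottom, ic50v, hill, converged, flat, rss) {
    new("DoseResponseFit", model = model, drug = drug,
        top = top, bottom = bottom, ic50 = ic50v, hill = hill,
        rss = rss, converged = converged, flat = flat,
        doses = doses, means = means)
  }

  if (stats::sd(viability) == 0)
    return(mk(viability[1], viability[1], NA_real_, NA_real_,
              converged = TRUE, flat = TRUE, rss = 0))

  lo <- c(top = 0, bottom = 0, ic50 = min(doses) / 10, hill = 1e-3)
  hi <- c(top = 1.2, bottom = 1.2, ic50 = max(doses) * 10, hill = 10)

  topStart <- max(min(mean(viability[conc == min(doses)]), 1.2), 1e-3)
  botStart <- min(max(mean(viability[conc == max(doses)]), 0), topStart)
  half <- (topStart + botStart) / 2
  below <- which(means <= half)
  ic50Start <- if (length(below)) doses[below[1]] else sqrt(min(doses) * max(doses))
  ic50Start <- min(max(ic50Start, lo["ic50"]), hi["ic50"])

  starts <- list(
    c(top = topStart, bottom = botStart, ic50 = unname(ic50Start), hill = 1),
    c(top = topStart, bottom = botStart, ic50 = unname(ic50Start) * 3, hill = 2),
    c(top = topStart, bottom = botStart,
      ic50 = unname(sqrt(min(doses) * max(doses))), hill = 0.5)
  )

  df <- data.frame(c = conc, v = viability)
  best <- NULL
  for (st in starts) {
    fit <- try(suppressWarnings(stats::nls(
      v ~ bottom + (top - bottom) / (1 + (c / ic50)^hill),
      data = df, start = as.list(st), algorithm = "port",
      lower = lo[names(st)], upper = hi[names(st)],
      control = stats::nls.control(maxiter = 200, warnOnly = FALSE)
    )), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) {
    # interpolation-only fallback: keep replicate means, no curve
    message(sprintf("4PL fit did not converge for %s/%s; interpolation mode",
                    model, drug))
    return(mk(NA_real_, NA_real_, NA_real_, NA_real_,
              converged = FALSE, flat = FALSE, rss = NA_real_))
  }
  p <- best$coef
  if (p["bottom"] > p["top"]) p[c("top", "bottom")] <- p[c("bottom", "top")]
  mk(unname(p["top"]), unname(p["bottom"]), unname(p["ic50"]),
     unname(p["hill"]), converged = TRUE, flat = FALSE, rss = best$rss)
}

#' Predicted viability from a dose-response fit
#'
#' Evaluates the fitted 4PL curve, or interpolates the replicate means
#' linearly in log-dose when the fit did not converge (values beyond the
#' tested dose range are clamped to the terminal means).
#'
#' @param fit a [DoseResponseFit].
#' @param conc concentration(s) in uM.
#' @return predicted viability fraction(s).
#' @export
predictViability <- function(fit, conc) {
  stopifnot(is(fit, "DoseResponseFit"))
  if (fit@flat) return(rep(fit@top, length(conc)))
  if (fit@converged)
    return(.fourPL(conc, fit@top, fit@bottom, fit@ic50, fit@hill))
  lx <- log(fit@doses)
  stats::approx(lx, fit@means, xout = log(conc), rule = 2)$y
}

#' Viability at the maximal plasma concentration (Cmax)
#'
#' Reads viability off the fitted dose-response curve at the drug's
#' Cmax, in percent. `source = "interpolation"` instead interpolates
#' the raw replicate means in log-dose (and returns the replicate mean
#' exactly when Cmax coincides with a tested dose). Extrapolation
#' beyond twice the maximal tested dose is refused.
#'
#' @param fit a [DoseResponseFit].
#' @param cmax maximal plasma concentration, uM.
#' @param source `"curve"` (default) or `"interpolation"`.
#' @return one-row `data.frame`: `model`, `drug`, `cmax`,
#'   `viability_at_cmax` (percent).
#' @export
viabilityAtCmax <- function(fit, cmax, source = c("curve", "interpolation")) {
  source <- match.arg(source)
  stopifnot(is(fit, "DoseResponseFit"), cmax > 0)
  if (cmax > 2 * max(fit@doses))
    stop(sprintf("cmax %.4g uM exceeds 2x the maximal tested dose (%.4g uM)",
                 cmax, max(fit@doses)))
  v <- if (source == "interpolation" || !fit@converged) {
    i <- which(abs(fit@doses - cmax) < 1e-12)
    if (length(i)) fit@means[i[1]]
    else stats::approx(log(fit@doses), fit@means, xout = log(cmax),
                       rule = 2)$y
  } else predictViability(fit, cmax)
  data.frame(model = fit@model, drug = fit@drug, cmax = cmax,
             viability_at_cmax = 100 * v)
}

#' Fit curves and Cmax viabilities for a whole viability table
#'
#' @param records viability-schema `data.frame`.
#' @param cmaxTable named numeric vector or `data.frame` with columns
#'   `drug`, `cmax_uM` supplying each drug's Cmax.
#' @param source passed to [viabilityAtCmax()].
#' @return list with `fits` (list of [DoseResponseFit]), `fitTable`
#'   (`data.frame`: model, drug, top, bottom, ic50_uM, hill, rss,
#'   converged) and `cmaxTable` (`data.frame` of Cmax viabilities).
#' @export
doseResponseTable <- function(records, cmaxTable,
                              source = c("curve", "interpolation")) {
  source <- match.arg(source)
  if (is.data.frame(cmaxTable))
    cmaxTable <- stats::setNames(cmaxTable$cmax_uM, cmaxTable$drug)
  fits <- list(); rowsF <- list(); rowsC <- list()
  for (m in unique(records$model)) for (d in unique(records$drug)) {
    sub <- records[records$model == m & records$drug == d, ]
    if (nrow(sub) == 0L) next
    fit <- fit4PL(sub$concentration_uM, sub$viability, model = m, drug = d)
    key <- paste(m, d, sep = "|")
    fits[[key]] <- fit
    rowsF[[key]] <- data.frame(
      model = m, drug = d, top = fit@top, bottom = fit@bottom,
      ic50_uM = fit@ic50, hill = fit@hill, rss = fit@rss,
      converged = fit@converged)
    if (d %in% names(cmaxTable))
      rowsC[[key]] <- viabilityAtCmax(fit, cmaxTable[[d]], source = source)
  }
  list(fits = fits,
       fitTable = do.call(rbind, c(rowsF, list(make.row.names = FALSE))),
       cmaxTable = do.call(rbind, c(rowsC, list(make.row.names = FALSE))))
}
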