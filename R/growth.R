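#' Tumor volume from two-dimensional caliper measurement
#'
#' TV = 0.5 x width^2 x length, in mm^3. Calipers do not label axes, so
#' the convention width <= length is enforced: swapped inputs are
#' corrected with a warning. Vectorized.
#'
#' @param width,length caliper dimensions in mm, both > 0.
#' @return tumor volume(s) in mm^3.
#' @examples
#' tumorVolume(10, 20)   # 1000 mm^3 = 1.0 cm^3
#' @export
tumorVolume <- function(width, length) {
  if (any(width <= 0) || any(length <= 0))
    stop("caliper dimensions must be positive")
  swap <- width > length
  if (any(swap)) {
    warning(sprintf("%d measurement(s) had width > length; dimensions swapped",
                    sum(swap)))
    tmp <- width[swap]
    width[swap] <- length[swap]
    length[swap] <- tmp
  }
  0.5 * width^2 * length
}

#' Tumor doubling time by log-linear regression
#'
#' Fits ln(TV) against day by ordinary least squares and reports
#' td = ln(2) / slope together with the fit r^2 and the number of
#' points. A non-positive slope flags the curve as non-growing and td
#' is reported as `NA`.
#'
#' @param day measurement days (>= 3 distinct values).
#' @param volume tumor volumes in mm^3, all > 0.
#' @return a one-row `data.frame`: `td`, `fit_r2`, `n_points`,
#'   `growing`.
#' @export
doublingTime <- function(day, volume) {
  stopifnot(length(day) == length(volume))
  if (length(unique(day)) < 3L)
    stop("doubling time needs >= 3 distinct measurement days")
  if (any(volume <= 0)) stop("tumor volumes must be positive")
  fit <- stats::lm(log(volume) ~ day)
  slope <- unname(stats::coef(fit)[2])
  # noise-free exponentials fit perfectly; the summary warning is moot
  r2 <- suppressWarnings(summary(fit)$r.squared)
  growing <- slope > 0
  data.frame(
    td = if (growing) log(2) / slope else NA_real_,
    fit_r2 = r2,
    n_points = length(day),
    growing = growing
  )
}

#' Treated-over-control (T/C) tumor-volume ratio
#'
#' Computes per-animal tumor volumes at the evaluation day, averages
#' within each arm, and reports 100 x mean(treated TV) / mean(control
#' TV). By default the evaluation day is the last day on which both arms
#' were measured; `mode = "best"` instead reports the minimum T/C over
#' all common days. Animals without a measurement at the evaluation day
#' are dropped (and counted), not carried forward.
#'
#' @param records growth-schema `data.frame` (see
#'   [readMeasurementTable()]) for one model x drug, containing both
#'   arms.
#' @param evalDay evaluation day; `NULL` selects per `mode`.
#' @param mode `"final"` (default, last common day) or `"best"`
#'   (minimum T/C over common days).
#' @return one-row `data.frame`: `model`, `drug`, `tc_percent`,
#'   `eval_day`, `n_treated`, `n_control`.
#' @export
tcValue <- function(records, evalDay = NULL, mode = c("final", "best")) {
  mode <- match.arg(mode)
  need <- c("model", "drug", "arm", "animal", "day", "width_mm", "length_mm")
  stopifnot(all(need %in% names(records)))
  records$tv <- tumorVolume(records$width_mm, records$length_mm)
  dT <- sort(unique(records$day[records$arm == "treated"]))
  dC <- sort(unique(records$day[records$arm == "control"]))
  common <- intersect(dT, dC)
  if (length(common) == 0L)
    stop("no common measurement day between arms; treated days: ",
         paste(dT, collapse = ","), "; control days: ",
         paste(dC, collapse = ","))
  atDay <- function(d) {
    sub <- records[records$day == d, ]
    tv <- tapply(sub$tv, list(sub$arm, sub$animal), mean)
    tr <- tv["treated", ]; ct <- tv["control", ]
    tr <- tr[!is.na(tr)]; ct <- ct[!is.na(ct)]
    if (length(tr) < 1L || length(ct) < 1L) return(NULL)
    list(tc = 100 * mean(tr) / mean(ct), nT = length(tr), nC = length(ct))
  }
  if (!is.null(evalDay)) {
    if (!evalDay %in% common)
      stop("no common measurement at day ", evalDay,
           "; common days: ", paste(common, collapse = ","))
    res <- atDay(evalDay); d <- evalDay
  } else if (mode == "final") {
    d <- max(common)
    res <- atDay(d)
  } else {
    vals <- lapply(common, atDay)
    keep <- !vapply(vals, is.null, logical(1))
    common <- common[keep]; vals <- vals[keep]
    i <- which.min(vapply(vals, `[[`, numeric(1), "tc"))
    d <- common[i]; res <- vals[[i]]
  }
  if (is.null(res)) stop("no animals measured in both arms at day ", d)
  data.frame(
    model = records$model[1], drug = records$drug[1],
    tc_percent = res$tc, eval_day = d,
    n_treated = res$nT, n_control = res$nC
  )
}

#' T/C values for every model x drug in a growth table
#'
#' Applies [tcValue()] per (model, drug) group; the control arm may be
#' recorded either under the same drug label or under a shared
#' `"vehicle"` label per model.
#'
#' @inheritParams tcValue
#' @param controlDrug drug label identifying shared solvent-control
#'   animals (default `"vehicle"`); ignored when each drug carries its
#'   own control arm.
#' @return `data.frame` of [tcValue()] rows.
#' @export
tcTable <- function(records, evalDay = NULL, mode = c("final", "best"),
                    controlDrug = "vehicle") {
  mode <- match.arg(mode)
  out <- list()
  for (m in unique(records$model)) {
    sub <- records[records$model == m, ]
    ctlShared <- sub[sub$drug == controlDrug & sub$arm == "control", ]
    for (d in setdiff(unique(sub$drug), controlDrug)) {
      grp <- sub[sub$drug == d, ]
      if (!"control" %in% grp$arm && nrow(ctlShared)) {
        ctl <- ctlShared
        ctl$drug <- d
        grp <- rbind(grp, ctl)
      }
      if (!all(c("treated", "control") %in% grp$arm)) next
      out[[paste(m, d)]] <- tcValue(grp, evalDay = evalDay, mode = mode)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
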