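#' @import methods
NULL

#' GeneSetCollection: named gene sets with descriptions
#'
#' Container for a collection of gene sets as read from a GMT file
#' (one set per line: name, description, then member gene symbols).
#' Gene symbols are case-sensitive and matched exactly downstream;
#' no alias resolution is performed.
#'
#' @slot setNames character vector of unique set names.
#' @slot descriptions character vector, parallel to \code{setNames}.
#' @slot genes list of character vectors of member gene symbols,
#'   duplicates removed, parallel to \code{setNames}.
#'
#' @seealso [readGmt()], [ssgseaMatrix()], [gseaContrast()]
#' @export
setClass("GeneSetCollection",
  representation(
    setNames     = "character",
    descriptions = "character",
    genes        = "list"
  )
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  n <- length(object@setNames)
  if (length(object@descriptions) != n || length(object@genes) != n)
    msg <- c(msg, "setNames, descriptions and genes must have equal length")
  if (anyDuplicated(object@setNames))
    msg <- c(msg, sprintf("duplicate set name(s): %s",
      paste(unique(object@setNames[duplicated(object@setNames)]), collapse = ", ")))
  if (n > 0) {
    empty <- lengths(object@genes) == 0L
    if (any(empty))
      msg <- c(msg, sprintf("empty gene set(s): %s",
        paste(object@setNames[empty], collapse = ", ")))
    bad <- vapply(object@genes, function(g)
      !is.character(g) || any(!nzchar(g)) || anyNA(g), logical(1))
    if (any(bad))
      msg <- c(msg, "gene symbols must be non-empty strings")
  }
  if (length(msg)) msg else TRUE
})

#' DoseResponseFit: four-parameter logistic dose-response fit
#'
#' Result of fitting v(c) = bottom + (top - bottom) / (1 + (c/ic50)^hill)
#' to viability measurements of one model x drug combination. When the
#' nonlinear fit does not converge the object carries the raw replicate
#' means instead and downstream evaluation falls back to interpolation
#' in log-dose.
#'
#' @slot model,drug identifiers.
#' @slot top,bottom asymptotic viability fractions (bottom <= top).
#' @slot ic50 half-maximal concentration, uM; \code{NA} for flat fits.
#' @slot hill Hill slope (positive: viability decreases with dose).
#' @slot rss residual sum of squares over all fitted points.
#' @slot converged logical; \code{FALSE} selects interpolation mode.
#' @slot flat logical; all-identical viabilities, ic50 undefined.
#' @slot doses,means tested concentrations and per-dose replicate means
#'   (kept for interpolation mode and diagnostics).
#'
#' @seealso [fit4PL()], [viabilityAtCmax()]
#' @export
setClass("DoseResponseFit",
  representation(
    model = "character", drug = "character",
    top = "numeric", bottom = "numeric", ic50 = "numeric", hill = "numeric",
    rss = "numeric", converged = "logical", flat = "logical",
    doses = "numeric", means = "numeric"
  )
)

setValidity("DoseResponseFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged) && !isTRUE(object@flat)) {
    if (!is.na(object@ic50) && object@ic50 <= 0)
      msg <- c(msg, "ic50 must be positive when converged")
    if (object@bottom > object@top + 1e-9)
      msg <- c(msg, "bottom must not exceed top")
  }
  if (length(msg)) msg else TRUE
})

#' CombinationMatrix: confluence-normalized drug-combination plate
#'
#' Dose grid of two drugs (each grid including dose 0) with per-cell
#' cytotoxicity, computed as the replicate mean of fluorescence divided
#' by same-well confluence, and its deviation from the plate median.
#'
#' @slot model,drugA,drugB identifiers.
#' @slot dosesA,dosesB sorted dose grids in uM, both including 0.
#' @slot normCytotox matrix (dosesA x dosesB) of mean fluorescence /
#'   confluence; \code{NA} where every replicate well was invalid.
#' @slot medianRelative \code{normCytotox} minus the median over all
#'   valid cells.
#' @slot nInvalid number of wells dropped for zero confluence.
#'
#' @seealso [normalizeCytotoxicity()], [plateBlissExcess()]
#' @export
setClass("CombinationMatrix",
  representation(
    model = "character", drugA = "character", drugB = "character",
    dosesA = "numeric", dosesB = "numeric",
    normCytotox = "matrix", medianRelative = "matrix",
    nInvalid = "integer"
  )
)

setValidity("CombinationMatrix", function(object) {
  msg <- character()
  if (!0 %in% object@dosesA || !0 %in% object@dosesB)
    msg <- c(msg, "dose grids must include the vehicle dose 0")
  if (is.unsorted(object@dosesA) || is.unsorted(object@dosesB))
    msg <- c(msg, "dose grids must be sorted increasingly")
  if (!identical(dim(object@normCytotox),
                 c(length(object@dosesA), length(object@dosesB))))
    msg <- c(msg, "normCytotox dimensions must match dose grids")
  if (any(object@normCytotox < 0, na.rm = TRUE))
    msg <- c(msg, "normalized cytotoxicity must be non-negative")
  if (length(msg)) msg else TRUE
})
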