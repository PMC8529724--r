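#' Accessors for xenoScreen S4 classes
#'
#' `geneSets()` returns the member genes of a [GeneSetCollection] as a
#' named list; `setNames2()` is avoided — use `names(geneSets(x))`.
#' `nSets()` gives the number of sets. `ic50()`, `hillSlope()` and
#' `isConverged()` read a [DoseResponseFit]. `normCytotox()` and
#' `medianRelative()` read a [CombinationMatrix].
#'
#' @param x a xenoScreen S4 object.
#' @return see individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("nSets", function(x) standardGeneric("nSets"))

#' @rdname accessors
#' @export
setGeneric("ic50", function(x) standardGeneric("ic50"))

#' @rdname accessors
#' @export
setGeneric("hillSlope", function(x) standardGeneric("hillSlope"))

#' @rdname accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname accessors
#' @export
setGeneric("normCytotox", function(x) standardGeneric("normCytotox"))

#' @rdname accessors
#' @export
setGeneric("medianRelative", function(x) standardGeneric("medianRelative"))

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) {
  stats::setNames(x@genes, x@setNames)
})

#' @rdname accessors
#' @export
setMethod("nSets", "GeneSetCollection", function(x) length(x@setNames))

#' @rdname accessors
#' @export
setMethod("ic50", "DoseResponseFit", function(x) x@ic50)

#' @rdname accessors
#' @export
setMethod("hillSlope", "DoseResponseFit", function(x) x@hill)

#' @rdname accessors
#' @export
setMethod("isConverged", "DoseResponseFit", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("normCytotox", "CombinationMatrix", function(x) x@normCytotox)

#' @rdname accessors
#' @export
setMethod("medianRelative", "CombinationMatrix", function(x) x@medianRelative)

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@setNames), "set(s)\n")
  n <- min(5L, length(object@setNames))
  if (n > 0) {
    for (i in seq_len(n))
      cat(sprintf("  %s (%d genes)\n",
                  object@setNames[i], length(object@genes[[i]])))
    if (length(object@setNames) > n) cat("  ...\n")
  }
  invisible(object)
})

setMethod("show", "DoseResponseFit", function(object) {
  cat(sprintf("DoseResponseFit %s / %s\n", object@model, object@drug))
  if (object@flat) {
    cat("  flat response (ic50 undefined)\n")
  } else if (object@converged) {
    cat(sprintf("  top %.3f  bottom %.3f  ic50 %.4g uM  hill %.3f  rss %.4g\n",
                object@top, object@bottom, object@ic50, object@hill, object@rss))
  } else {
    cat("  not converged; interpolation mode on", length(object@doses),
        "dose(s)\n")
  }
  invisible(object)
})

setMethod("show", "CombinationMatrix", function(object) {
  cat(sprintf("CombinationMatrix %s: %s (%d doses) x %s (%d doses)\n",
              object@model, object@drugA, length(object@dosesA),
              object@drugB, length(object@dosesB)))
  cat(sprintf("  median norm. cytotoxicity %.4g; %d invalid well(s)\n",
              stats::median(object@normCytotox, na.rm = TRUE),
              object@nInvalid))
  invisible(object)
})
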