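#' @include AllClasses.R
NULL

#' Accessors for FractionCounts
#'
#' Column accessors returning the raw count vector of one fraction, and the
#' transcript lengths stored in \code{rowData}.
#'
#' @param object A \linkS4class{FractionCounts} object.
#' @return A named numeric vector (counts) or numeric vector of lengths.
#' @name fraction-accessors
#' @aliases totalCounts supCounts pelletCounts transcriptLengths
#' @examples
#' fc <- FractionCounts(total = 10, sup = 8, pellet = 3,
#'                      transcript_id = "t1", length_nt = 1000)
#' totalCounts(fc); transcriptLengths(fc)
NULL

#' @rdname fraction-accessors
#' @export
setGeneric("totalCounts", function(object) standardGeneric("totalCounts"))
#' @rdname fraction-accessors
#' @export
setGeneric("supCounts", function(object) standardGeneric("supCounts"))
#' @rdname fraction-accessors
#' @export
setGeneric("pelletCounts", function(object) standardGeneric("pelletCounts"))
#' @rdname fraction-accessors
#' @export
setGeneric("transcriptLengths",
           function(object) standardGeneric("transcriptLengths"))

.fraction_col <- function(object, what) {
  cts <- assay(object, "counts")[, what]
  names(cts) <- rownames(object)
  cts
}

#' @rdname fraction-accessors
setMethod("totalCounts", "FractionCounts",
          function(object) .fraction_col(object, "total"))
#' @rdname fraction-accessors
setMethod("supCounts", "FractionCounts",
          function(object) .fraction_col(object, "sup"))
#' @rdname fraction-accessors
setMethod("pelletCounts", "FractionCounts",
          function(object) .fraction_col(object, "pellet"))
#' @rdname fraction-accessors
setMethod("transcriptLengths", "FractionCounts", function(object) {
  rd <- rowData(object)
  if (!"length_nt" %in% colnames(rd)) return(NULL)
  stats::setNames(as.numeric(rd$length_nt), rownames(object))
})

#' Accessors for MixingRatios
#'
#' @param object A \linkS4class{MixingRatios} object.
#' @return Numeric scalar.
#' @name mixing-accessors
#' @aliases alphaS alphaP nbDispersion
NULL

#' @rdname mixing-accessors
#' @export
setGeneric("alphaS", function(object) standardGeneric("alphaS"))
#' @rdname mixing-accessors
#' @export
setGeneric("alphaP", function(object) standardGeneric("alphaP"))
#' @rdname mixing-accessors
#' @export
setGeneric("nbDispersion", function(object) standardGeneric("nbDispersion"))

#' @rdname mixing-accessors
setMethod("alphaS", "MixingRatios", function(object) object@alphaS)
#' @rdname mixing-accessors
setMethod("alphaP", "MixingRatios", function(object) object@alphaP)
#' @rdname mixing-accessors
setMethod("nbDispersion", "MixingRatios", function(object) object@dispersion)

#' @export
setMethod("show", "MixingRatios", function(object) {
  cat("MixingRatios (", object@method, " fit on ", object@nUsed,
      " transcripts)\n", sep = "")
  cat(sprintf("  alphaS = %.4g  alphaP = %.4g  (ratio %.4g)\n",
              object@alphaS, object@alphaP, object@alphaS / object@alphaP))
  cat(sprintf("  NB dispersion = %.4g\n", object@dispersion))
  conv <- object@diagnostics$converged
  if (!is.null(conv)) cat("  converged:", conv, "\n")
  invisible(object)
})

#' Coefficients of a sedimentation model fit
#'
#' @param object A \linkS4class{SedFit} object.
#' @param ... Ignored.
#' @return Named numeric vector \code{c(beta, chi, mu, nu)}.
#' @export
setMethod("coef", "SedFit", function(object, ...) {
  c(beta = object@beta, chi = object@chi, mu = object@mu, nu = object@nu)
})

#' @export
setMethod("show", "SedFit", function(object) {
  kind <- switch(as.character(object@nParams),
                 "2" = "baseline (beta, chi)",
                 "3" = "one condensation term",
                 "4" = "full (beta, chi, mu, nu)")
  cat("SedFit:", kind, "\n")
  cat(sprintf("  beta = %.4g  chi = %.4g  mu = %.4g  nu = %.4g\n",
              object@beta, object@chi, object@mu, object@nu))
  cat(sprintf("  RSS = %.6g on %d points (%d params), converged: %s\n",
              object@rss, object@nPoints, object@nParams, object@converged))
  invisible(object)
})
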