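#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData
NULL

#' Three-fraction sedimentation count container
#'
#' A \code{FractionCounts} object holds raw transcript counts for the Total,
#' Supernatant and Pellet fractions of one sedimentation fractionation
#' experiment. It extends \linkS4class{SummarizedExperiment}: rows are
#' transcripts, the three columns are the fractions (in the fixed order
#' \code{total}, \code{sup}, \code{pellet}), and \code{rowData} carries
#' transcript annotation (at minimum \code{length_nt}). Simulation truth, when
#' present, lives in \code{metadata()}.
#'
#' @slot .Data see \linkS4class{SummarizedExperiment}
#' @seealso \code{\link{FractionCounts}} (constructor),
#'   \code{\link{estimateMixingRatios}}, \code{\link{computePSup}}
#' @export
setClass("FractionCounts", contains = "SummarizedExperiment")

.validFractionCounts <- function(object) {
  msg <- NULL
  if (ncol(object) != 3L ||
      !identical(colnames(object), c("total", "sup", "pellet")))
    msg <- c(msg, "columns must be exactly 'total', 'sup', 'pellet'")
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "must contain a 'counts' assay")
  else {
    cts <- assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0))
      msg <- c(msg, "counts must be finite and non-negative")
  }
  if (is.null(rownames(object)))
    msg <- c(msg, "transcripts must be named (rownames)")
  if (is.null(msg)) TRUE else msg
}
setValidity("FractionCounts", .validFractionCounts)

#' Construct a FractionCounts object
#'
#' @param total,sup,pellet Non-negative integer count vectors, one entry per
#'   transcript, from the Total, Supernatant and Pellet libraries of one
#'   experiment. Counts are raw (not depth-normalized); mixing-ratio estimation
#'   handles fraction-to-fraction scale.
#' @param transcript_id Character vector of transcript identifiers.
#' @param length_nt Optional transcript lengths (nt, including UTRs), stored in
#'   \code{rowData}.
#' @param experiment_id Experiment label, stored in \code{metadata}.
#' @param rowData Optional extra per-transcript annotation (data.frame).
#' @param metadata Optional list of additional metadata.
#' @return A \linkS4class{FractionCounts} object.
#' @examples
#' fc <- FractionCounts(total = c(120, 30), sup = c(100, 10),
#'                      pellet = c(25, 22), transcript_id = c("t1", "t2"),
#'                      length_nt = c(900, 3100))
#' fc
#' @export
FractionCounts <- function(total, sup, pellet, transcript_id,
                           length_nt = NULL, experiment_id = "exp1",
                           rowData = NULL, metadata = list()) {
  n <- length(transcript_id)
  if (length(total) != n || length(sup) != n || length(pellet) != n)
    stop("count vectors and 'transcript_id' must have equal length",
         call. = FALSE)
  counts <- cbind(total = as.numeric(total), sup = as.numeric(sup),
                  pellet = as.numeric(pellet))
  rownames(counts) <- as.character(transcript_id)
  rd <- if (is.null(rowData)) DataFrame(row.names = rownames(counts))
        else DataFrame(rowData, row.names = rownames(counts))
  if (!is.null(length_nt)) rd$length_nt <- as.numeric(length_nt)
  md <- c(list(experiment_id = experiment_id), metadata)
  se <- SummarizedExperiment(
    assays = SimpleList(counts = counts),
    rowData = rd,
    colData = DataFrame(fraction = c("total", "sup", "pellet"),
                        row.names = c("total", "sup", "pellet")),
    metadata = md)
  new("FractionCounts", se)
}

#' Mixing-ratio estimates for one experiment
#'
#' Holds the per-experiment mixing ratios (alphaS, alphaP) that restore
#' conservation of mass T = alphaS*S + alphaP*P across the three sequenced
#' fractions, together with the negative-binomial dispersion and fit
#' diagnostics.
#'
#' @slot alphaS,alphaP Positive mixing ratios for the supernatant and pellet
#'   libraries.
#' @slot dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @slot nUsed Number of transcripts passing the count filter and used in the
#'   fit.
#' @slot method \code{"MAP"} or \code{"MCMC"}.
#' @slot diagnostics List of backend diagnostics (convergence flag, optimizer
#'   details or R-hat / acceptance rate).
#' @export
setClass("MixingRatios",
  representation(alphaS = "numeric", alphaP = "numeric",
                 dispersion = "numeric", nUsed = "integer",
                 method = "character", diagnostics = "list"))

setValidity("MixingRatios", function(object) {
  msg <- NULL
  if (length(object@alphaS) != 1L || object@alphaS <= 0)
    msg <- c(msg, "alphaS must be a single positive number")
  if (length(object@alphaP) != 1L || object@alphaP <= 0)
    msg <- c(msg, "alphaP must be a single positive number")
  if (length(object@dispersion) != 1L || object@dispersion <= 0)
    msg <- c(msg, "dispersion must be a single positive number")
  if (!object@method %in% c("MAP", "MCMC"))
    msg <- c(msg, "method must be 'MAP' or 'MCMC'")
  if (is.null(msg)) TRUE else msg
})

#' Fitted mass-based sedimentation model
#'
#' Parameters of the power-law sedimentation model on the log-odds pSup scale:
#' the baseline pelleted fraction is \eqn{\beta L^\chi} and, under a
#' condensation-inducing treatment, is multiplied by \eqn{e^{\mu + \nu L}}
#' (per-molecule term \eqn{\mu}, per-nucleotide term \eqn{\nu}).
#'
#' @slot beta,chi Baseline power-law parameters.
#' @slot mu,nu Condensation terms (0 in a baseline-only fit).
#' @slot rss Residual sum of squares on the log-odds scale.
#' @slot nPoints Number of fitted points.
#' @slot nParams Number of free parameters (2 baseline; 3 with one condensation
#'   term; 4 full).
#' @slot converged Logical convergence flag.
#' @slot details List with fit internals (starts tried, residuals, clamping).
#' @export
setClass("SedFit",
  representation(beta = "numeric", chi = "numeric", mu = "numeric",
                 nu = "numeric", rss = "numeric", nPoints = "integer",
                 nParams = "integer", converged = "logical",
                 details = "list"))

setValidity("SedFit", function(object) {
  msg <- NULL
  if (object@rss < 0) msg <- c(msg, "rss must be non-negative")
  if (!object@nParams %in% 2:4)
    msg <- c(msg, "nParams must be 2, 3 or 4")
  if (is.null(msg)) TRUE else msg
})
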