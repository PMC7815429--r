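#' @import methods
NULL

#' ScoringTimeline: frame-wise scored behaviour record for one video
#'
#' Dense per-frame record of the scoring ethogram for a single video:
#' leveled observations (camera movement, monkey count, face visibility,
#' ano-genital-area visibility, forage, aggression level) hold exactly one
#' level per frame, and event observations (drink, scratch, strike, ...)
#' are 0/1 per frame.
#'
#' @slot videoId character(1) video identifier.
#' @slot fps numeric(1) frames per second (default 30).
#' @slot levels data.frame with one factor column per leveled observation;
#'   one row per frame; every cell is a defined level (baseline included).
#' @slot events integer matrix (frames x event observations) with values
#'   in {0, 1}.
#'
#' @seealso [parseAnnotations()], [deriveAnalysisEthogram()]
#' @export
setClass("ScoringTimeline",
  slots = c(
    videoId = "character",
    fps = "numeric",
    levels = "data.frame",
    events = "matrix"
  )
)

setValidity("ScoringTimeline", function(object) {
  eth <- scoringEthogram()
  msgs <- character()
  if (length(object@videoId) != 1L || is.na(object@videoId))
    msgs <- c(msgs, "videoId must be a single non-NA string")
  if (length(object@fps) != 1L || object@fps <= 0)
    msgs <- c(msgs, "fps must be a single positive number")
  if (nrow(object@levels) != nrow(object@events))
    msgs <- c(msgs, "levels and events must cover the same frames")
  unknownLev <- setdiff(colnames(object@levels), names(eth$leveled))
  if (length(unknownLev))
    msgs <- c(msgs, paste0("unknown leveled observation(s): ",
                           paste(unknownLev, collapse = ", ")))
  for (obs in colnames(object@levels)) {
    col <- object@levels[[obs]]
    if (!is.factor(col)) {
      msgs <- c(msgs, paste0("levels column '", obs, "' must be a factor"))
      next
    }
    bad <- setdiff(levels(col), eth$leveled[[obs]])
    if (length(bad))
      msgs <- c(msgs, paste0("observation '", obs, "' has unknown level(s): ",
                             paste(bad, collapse = ", ")))
    if (anyNA(col))
      msgs <- c(msgs, paste0("observation '", obs,
                             "' has undefined frames (NA levels)"))
  }
  unknownEv <- setdiff(colnames(object@events), eth$events)
  if (length(unknownEv))
    msgs <- c(msgs, paste0("unknown event observation(s): ",
                           paste(unknownEv, collapse = ", ")))
  if (length(object@events) && !all(object@events %in% c(0L, 1L)))
    msgs <- c(msgs, "event values must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

#' AnalysisEthogram: per-frame binary analysis variables for one video
#'
#' The analysis-ready form of a [ScoringTimeline-class]: every variable is
#' binary per frame. Derived variables follow fixed membership rules on the
#' scoring levels (e.g. \emph{eye contact} implies \emph{direct face}
#' implies \emph{prominent face} implies \emph{visible face}), pooled
#' agonistic classes (attack / threaten / submit) union their constituent
#' events, and configurable pass-through events are copied unchanged.
#'
#' @slot videoId character(1) video identifier.
#' @slot fps numeric(1) frames per second.
#' @slot variables integer matrix (frames x variables), values in {0, 1}.
#'
#' @seealso [deriveAnalysisEthogram()], [windowAverageRegressors()]
#' @export
setClass("AnalysisEthogram",
  slots = c(
    videoId = "character",
    fps = "numeric",
    variables = "matrix"
  )
)

setValidity("AnalysisEthogram", function(object) {
  msgs <- character()
  if (length(object@videoId) != 1L || is.na(object@videoId))
    msgs <- c(msgs, "videoId must be a single non-NA string")
  if (length(object@variables) && !all(object@variables %in% c(0L, 1L)))
    msgs <- c(msgs, "variables must be binary (0/1)")
  if (is.null(colnames(object@variables)))
    msgs <- c(msgs, "variables must have column names")
  if (length(msgs)) msgs else TRUE
})

#' PenalizedFit: elastic-net GLM fit with penalty factors
#'
#' Result of [fitPenalizedGLM()] or [cvSelect()]: coefficients on the
#' original predictor scale, the elastic-net mixing parameter alpha and
#' regularization strength lambda, per-coefficient penalty factors
#' (0 = unpenalized), and, when produced by cross-validation, the CV
#' deviance curve and the one-standard-error lambda.
#'
#' @slot family character(1): "gaussian", "binomial" or "poisson".
#' @slot alpha numeric(1) elastic-net mixing parameter in [0, 1].
#' @slot lambda numeric(1) regularization strength of the returned fit.
#' @slot coefficients named numeric: slopes on the original predictor scale.
#' @slot intercept numeric(1) intercept on the original scale (0 when the
#'   model was fitted without an intercept).
#' @slot penaltyFactors named numeric, same order as coefficients.
#' @slot betaStd named numeric: slopes on the internally standardized scale
#'   (used for Karush-Kuhn-Tucker verification).
#' @slot interceptStd numeric(1) intercept on the standardized scale.
#' @slot center,scale named numeric: the standardization applied per column.
#' @slot cv list: CV diagnostics (lambda path, mean/SE deviance per lambda,
#'   per-alpha minima, selected lambda1se); empty for direct fits.
#' @slot converged logical(1).
#'
#' @seealso [fitPenalizedGLM()], [cvSelect()], [kktCheck()]
#' @export
setClass("PenalizedFit",
  slots = c(
    family = "character",
    alpha = "numeric",
    lambda = "numeric",
    coefficients = "numeric",
    intercept = "numeric",
    penaltyFactors = "numeric",
    betaStd = "numeric",
    interceptStd = "numeric",
    center = "numeric",
    scale = "numeric",
    cv = "list",
    converged = "logical"
  )
)

setValidity("PenalizedFit", function(object) {
  msgs <- character()
  if (!object@family %in% c("gaussian", "binomial", "poisson"))
    msgs <- c(msgs, "family must be gaussian, binomial or poisson")
  if (object@alpha < 0 || object@alpha > 1)
    msgs <- c(msgs, "alpha must lie in [0, 1]")
  if (object@lambda < 0)
    msgs <- c(msgs, "lambda must be non-negative")
  if (length(object@coefficients) != length(object@penaltyFactors))
    msgs <- c(msgs, "coefficients and penaltyFactors must align")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ScoringTimeline number of scored frames
#' @param x a ScoringTimeline or AnalysisEthogram
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setGeneric("videoId", function(x) standardGeneric("videoId"))

#' @export
setGeneric("framesPerSecond", function(x) standardGeneric("framesPerSecond"))

#' @export
setGeneric("variableMatrix", function(x) standardGeneric("variableMatrix"))

#' @export
setGeneric("eventMatrix", function(x) standardGeneric("eventMatrix"))

#' @export
setGeneric("levelFrame", function(x) standardGeneric("levelFrame"))

setMethod("nFrames", "ScoringTimeline", function(x) nrow(x@levels))
setMethod("nFrames", "AnalysisEthogram", function(x) nrow(x@variables))
setMethod("videoId", "ScoringTimeline", function(x) x@videoId)
setMethod("videoId", "AnalysisEthogram", function(x) x@videoId)
setMethod("framesPerSecond", "ScoringTimeline", function(x) x@fps)
setMethod("framesPerSecond", "AnalysisEthogram", function(x) x@fps)
setMethod("variableMatrix", "AnalysisEthogram", function(x) x@variables)
setMethod("eventMatrix", "ScoringTimeline", function(x) x@events)
setMethod("levelFrame", "ScoringTimeline", function(x) x@levels)

setMethod("show", "ScoringTimeline", function(object) {
  cat("ScoringTimeline for video '", object@videoId, "'\n", sep = "")
  cat("  ", nFrames(object), " frames @ ", object@fps, " fps (",
      signif(nFrames(object) / object@fps, 4), " s)\n", sep = "")
  cat("  leveled observations:", ncol(object@levels), "\n")
  cat("  event observations:  ", ncol(object@events), "\n")
})

setMethod("show", "AnalysisEthogram", function(object) {
  on <- colSums(object@variables) > 0
  cat("AnalysisEthogram for video '", object@videoId, "'\n", sep = "")
  cat("  ", nFrames(object), " frames @ ", object@fps, " fps, ",
      ncol(object@variables), " binary variables (",
      sum(on), " ever active)\n", sep = "")
})

#' @describeIn PenalizedFit coefficients on the original predictor scale
#' @param object a PenalizedFit
#' @export
setMethod("coef", "PenalizedFit", function(object, ...) {
  c("(Intercept)" = object@intercept, object@coefficients)
})

#' Names of penalized coefficients estimated nonzero
#'
#' @param fit a [PenalizedFit-class]
#' @param tol magnitudes at or below this count as zero; the default
#'   absorbs floating-point residue at the edge of the lambda path (exact
#'   zeros there can come back as ~1e-17) without masking any real
#'   selection
#' @return character vector of regressor names
#' @export
nonzeroCoefficients <- function(fit, tol = 1e-10) {
  stopifnot(is(fit, "PenalizedFit"))
  b <- fit@coefficients
  names(b)[fit@penaltyFactors > 0 & abs(b) > tol]
}

setMethod("show", "PenalizedFit", function(object) {
  cat("PenalizedFit (", object@family, " family)\n", sep = "")
  cat("  alpha = ", object@alpha, ", lambda = ",
      signif(object@lambda, 4), "\n", sep = "")
  np <- sum(object@penaltyFactors > 0)
  cat("  coefficients: ", length(object@coefficients), " (", np,
      " penalized, ", length(nonzeroCoefficients(object)),
      " nonzero penalized)\n", sep = "")
  if (length(object@cv))
    cat("  selected by ", object@cv$nFolds, "-fold CV (1SE rule)\n", sep = "")
})
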