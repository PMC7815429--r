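optionRanks <- c(Blank = 0, Repeat = 1, Continue = 2, Switch = 3)

#' Build the ranked two-alternative choice design
#'
#' Options carry the arbitrary ranking Blank = 0 < Repeat = 1 <
#' Continue = 2 < Switch = 3 (the ranking only orients the coding; fitted
#' choice probabilities are invariant to it). For each two-option trial the
#' response is 1 when the higher-ranked option was chosen. For each of
#' Repeat, Continue and Switch a menu regressor m_i is +1 when it is the
#' higher-ranked offered option, -1 when the lower-ranked, 0 when not
#' offered; Blank is the baseline and carries no regressor. Interaction
#' columns m_i * x_k use the binary occurrence x_k of each ethogram
#' variable during the previous trial's video (all zero when the previous
#' trial was Blank). Forced single-option trials and the first trial are
#' excluded.
#'
#' @param trials trial log from [simulateSession()] (or equivalent with
#'   columns \code{menu_a}, \code{menu_b}, \code{forced}, \code{chosen},
#'   \code{video_id})
#' @param ethogramOccurrence matrix (nrow = nrow(trials)) of binary
#'   occurrence of each ethogram variable during each trial's own video
#'   (rows for Blank trials are ignored and treated as zero); NULL fits a
#'   main-effects-only design
#' @return list: \code{X} (design matrix: 3 menu columns, then
#'   interactions), \code{y} (0/1 response), \code{penaltyFactors} (0 for
#'   menu columns, 1 for interactions), \code{trialIndex} (rows of
#'   \code{trials} used), \code{nExcluded}
#' @export
buildChoiceDesign <- function(trials, ethogramOccurrence = NULL) {
  opts <- c("Repeat", "Continue", "Switch")
  n <- nrow(trials)
  keep <- which(!trials$forced & seq_len(n) > 1L)
  nExcluded <- n - length(keep)
  if (!is.null(ethogramOccurrence)) {
    ethogramOccurrence <- as.matrix(ethogramOccurrence)
    stopifnot(nrow(ethogramOccurrence) == n)
    K <- ncol(ethogramOccurrence)
    if (is.null(colnames(ethogramOccurrence)))
      colnames(ethogramOccurrence) <- paste0("x", seq_len(K))
  } else K <- 0L

  M <- matrix(0, length(keep), 3L, dimnames = list(NULL, opts))
  y <- integer(length(keep))
  XI <- if (K) matrix(0, length(keep), 3L * K) else NULL
  if (K) colnames(XI) <- as.vector(outer(colnames(ethogramOccurrence), opts,
                                         function(k, i) paste(i, k,
                                                              sep = ":")))
  for (r in seq_along(keep)) {
    d <- keep[r]
    menu <- c(trials$menu_a[d], trials$menu_b[d])
    hi <- menu[which.max(optionRanks[menu])]
    lo <- menu[which.min(optionRanks[menu])]
    if (hi %in% opts) M[r, hi] <- 1
    if (lo %in% opts) M[r, lo] <- -1
    y[r] <- as.integer(trials$chosen[d] == hi)
    if (K) {
      prev <- d - 1L
      x <- if (is.na(trials$video_id[prev])) numeric(K)
           else as.numeric(ethogramOccurrence[prev, ] > 0)
      for (i in opts) if (M[r, i] != 0) {
        cols <- paste(i, colnames(ethogramOccurrence), sep = ":")
        XI[r, cols] <- M[r, i] * x
      }
    }
  }
  X <- if (K) cbind(M, XI) else M
  list(X = X, y = y,
       penaltyFactors = c(rep(0, 3L), rep(1, 3L * K)),
       trialIndex = keep, nExcluded = nExcluded)
}

#' Fit the ranked-choice utility model
#'
#' Binomial (logit) elastic-net fit of the design from
#' [buildChoiceDesign()]: the three option utilities v_i are unpenalized
#' (penalty factor 0), the option-by-ethogram interaction coefficients
#' beta_ik carry the elastic-net penalty, and the model has no intercept
#' (the +/-1 menu coding absorbs the comparison structure; Blank is the
#' zero-utility baseline). (alpha, lambda_1SE) are selected by [cvSelect()].
#'
#' @param design output of [buildChoiceDesign()]
#' @param config a [penaltyConfig()]; its family is forced to binomial and
#'   the intercept is dropped
#' @return list of class "choiceModelFit": \code{v} (named utilities
#'   relative to Blank = 0), \code{beta} (named interaction coefficients),
#'   \code{interactions} (names of nonzero interactions), \code{fit}
#'   (the underlying [PenalizedFit-class])
#' @export
fitChoiceModel <- function(design, config = penaltyConfig("binomial")) {
  config$family <- "binomial"
  config$intercept <- FALSE
  fit <- cvSelect(design$X, design$y, config,
                  penaltyFactors = design$penaltyFactors)
  co <- fit@coefficients
  v <- co[c("Repeat", "Continue", "Switch")]
  beta <- co[fit@penaltyFactors > 0]
  structure(list(v = v, beta = beta,
                 interactions = nonzeroCoefficients(fit), fit = fit),
            class = "choiceModelFit")
}

#' @export
print.choiceModelFit <- function(x, ...) {
  cat("Ranked 2AFC utility model (utilities relative to Blank = 0)\n")
  print(round(x$v, 4))
  cat(length(x$interactions), "nonzero option-by-ethogram interaction(s)\n")
  invisible(x)
}

#' Model gaze-onscreen probability from viewed behaviours
#'
#' Binomial (logit) elastic-net GLM of the per-frame-presentation in-frame
#' indicator on the analysis-ethogram variables; reports which behaviours
#' raise or lower the probability of looking at the video.
#'
#' @param inFrame 0/1 vector, one entry per frame presentation
#' @param ethogram numeric matrix of ethogram variables, rows aligned with
#'   \code{inFrame}
#' @param config a [penaltyConfig()]; family forced to binomial
#' @return a [PenalizedFit-class]
#' @export
fitGazeOnscreenModel <- function(inFrame, ethogram,
                                 config = penaltyConfig("binomial")) {
  config$family <- "binomial"
  inFrame <- as.integer(inFrame)
  if (length(unique(inFrame)) < 2L)
    stop("in-frame indicator is constant; the model is undefined")
  cvSelect(as.matrix(ethogram), inFrame, config)
}

#' Model gaze consistency from viewed behaviours
#'
#' Gaussian (identity link) elastic-net GLM of normalized per-frame gaze
#' consistency on the analysis-ethogram variables. Consistency values are
#' z-scored across frames before fitting; frames with undefined consistency
#' (fewer than the minimum in-frame observations) must be removed upstream
#' or are dropped here. Because the ethogram variables are nested, the
#' total prediction for a frame is the sum of the coefficients of all
#' active variables (e.g. a male-genitals frame adds the visible +
#' prominent + male genitals coefficients).
#'
#' @param consistency numeric vector of per-frame gaze consistency (NA
#'   allowed; dropped with the matching rows)
#' @param ethogram numeric matrix of ethogram variables, rows aligned with
#'   \code{consistency}
#' @param config a [penaltyConfig()]; family forced to gaussian
#' @return a [PenalizedFit-class] (coefficients on the z-scored consistency
#'   scale)
#' @export
fitGazeConsistencyModel <- function(consistency, ethogram,
                                    config = penaltyConfig("gaussian")) {
  config$family <- "gaussian"
  ok <- !is.na(consistency)
  if (sum(ok) < 2L) stop("need at least 2 frames with defined consistency")
  g <- consistency[ok]
  if (stats::sd(g) == 0) {
    z <- rep(0, length(g))
  } else {
    z <- (g - mean(g)) / stats::sd(g)
  }
  cvSelect(as.matrix(ethogram)[ok, , drop = FALSE], z, config)
}
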