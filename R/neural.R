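#' Bin spikes into fixed windows within free-viewing periods
#'
#' Counts spikes in non-overlapping windows left-aligned to each
#' free-viewing onset (25 windows of 200 ms per 5 s presentation at the
#' defaults). Spikes outside all periods are ignored; their count is
#' attached as an attribute.
#'
#' @param spikeTimes numeric vector of spike timestamps (seconds, session
#'   clock), non-decreasing
#' @param fvOnsets numeric vector of presentation onset times (seconds)
#' @param fvDurationS presentation duration (default 5)
#' @param windowMs window duration in ms; must divide the period (default
#'   200)
#' @return integer matrix (presentations x windows) with attribute
#'   \code{nOutside} = spikes falling in no period
#' @export
binSpikeCounts <- function(spikeTimes, fvOnsets, fvDurationS = 5,
                           windowMs = 200) {
  if (is.unsorted(spikeTimes)) stop("spike timestamps must be non-decreasing")
  if ((fvDurationS * 1000) %% windowMs != 0)
    stop("window duration must divide the presentation evenly")
  nW <- as.integer(fvDurationS * 1000 / windowMs)
  nP <- length(fvOnsets)
  counts <- matrix(0L, nP, nW)
  used <- logical(length(spikeTimes))
  wS <- windowMs / 1000
  for (p in seq_len(nP)) {
    rel <- spikeTimes - fvOnsets[p]
    inP <- rel >= 0 & rel < fvDurationS
    if (any(inP)) {
      w <- pmin(floor(rel[inP] / wS) + 1L, nW)
      counts[p, ] <- tabulate(w, nbins = nW)
      used[inP] <- TRUE
    }
  }
  attr(counts, "nOutside") <- sum(!used)
  counts
}

#' Estimate baseline rate, characteristic timecourse and per-trial drift
#'
#' Decomposes a unit's binned counts into a grand-mean baseline rate phi0
#' (spikes per window), a characteristic within-presentation timecourse
#' pi_t (the peri-stimulus time histogram across presentations, scaled to
#' mean 1) and a slow per-presentation drift delta_n (smoothed
#' per-presentation mean relative to baseline, scaled to mean 1). These
#' enter the encoding model multiplicatively as a fixed offset, so the
#' regression explains only departures from the unit's stimulus-locked and
#' slow-drift structure.
#'
#' @param counts matrix from [binSpikeCounts()] (presentations x windows)
#' @param smoothWidth centred running-mean width (presentations) for the
#'   drift estimate (default 21)
#' @param rateFloor lower bound applied to pi_t and delta_n so log-offsets
#'   stay finite (default 1e-3)
#' @return list: \code{phi0}, \code{pi} (length = windows, mean 1),
#'   \code{delta} (length = presentations, mean 1)
#' @export
estimateTimecourseAndDrift <- function(counts, smoothWidth = 21,
                                       rateFloor = 1e-3) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stop("need at least 2 presentations")
  phi0 <- mean(counts)
  if (phi0 <= 0) stop("unit has no spikes in any window; unmodellable")
  piT <- colMeans(counts) / phi0
  piT <- pmax(piT, rateFloor)
  piT <- piT / mean(piT)
  presMean <- rowMeans(counts) / phi0
  half <- floor(smoothWidth / 2)
  n <- length(presMean)
  delta <- vapply(seq_len(n), function(i) {
    mean(presMean[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  delta <- pmax(delta, rateFloor)
  delta <- delta / mean(delta)
  list(phi0 = phi0, pi = piT, delta = delta)
}

#' Per-observation log-offsets from a timecourse/drift decomposition
#'
#' @param tc output of [estimateTimecourseAndDrift()]
#' @return numeric vector ln(phi0 * pi_t * delta_n), ordered
#'   presentation-major (all windows of presentation 1, then 2, ...) to
#'   match [flattenCounts()] and [buildLaggedDesign()]
#' @export
encodingOffsets <- function(tc) {
  as.vector(t(outer(tc$delta, tc$pi, function(d, p) log(tc$phi0 * p * d))))
}

#' Flatten a counts matrix to the encoding model's observation order
#'
#' @param counts matrix (presentations x windows)
#' @return integer vector, presentation-major (window index fastest)
#' @export
flattenCounts <- function(counts) as.vector(t(as.matrix(counts)))

#' Build the lagged window-level design for the encoding model
#'
#' Window-averages the analysis-ethogram variables with the window grid
#' shifted \code{tauMs} earlier (the latency for visual information to
#' reach prefrontal cortex), appends the four gaze regressors when
#' supplied — per-frame gaze consistency and proportion gaze offscreen
#' (scene properties), per-view gaze typicality and gaze offscreen
#' (viewing-decision properties) — and drops ethogram variables present in
#' fewer than \code{minPresentations} distinct presentations.
#'
#' @param ethograms an [AnalysisEthogram-class] or named list of them
#' @param presentations data.frame with \code{presentation_id},
#'   \code{video_id}, \code{start_frame}
#' @param gaze optional result of [aggregateFrameGaze()]; its \code{frames}
#'   and \code{views} tables supply the gaze regressors (views matched by
#'   \code{presentation_id})
#' @param tauMs regressor lag in ms (default 100)
#' @param windowMs window duration (default 200)
#' @param fvDurationS presentation duration (default 5)
#' @param minPresentations distinct-presentation inclusion threshold
#'   (default 5)
#' @return list: \code{X} (matrix, rows presentation-major), \code{rows}
#'   (data.frame presentation_id/window), \code{included},
#'   \code{presentationCounts}
#' @export
buildLaggedDesign <- function(ethograms, presentations, gaze = NULL,
                              tauMs = 100, windowMs = 200, fvDurationS = 5,
                              minPresentations = 5) {
  wr <- windowAverageRegressors(ethograms, presentations,
                                windowMs = windowMs,
                                fvDurationS = fvDurationS, lagMs = tauMs)
  filt <- applyPresentationFilter(wr, minPresentations)
  X <- as.matrix(wr[, filt$included, drop = FALSE])
  rows <- wr[, c("presentation_id", "window")]

  if (!is.null(gaze)) {
    fps <- framesPerSecond(if (is(ethograms, "AnalysisEthogram")) ethograms
                           else ethograms[[1L]])
    nW <- as.integer(fvDurationS * 1000 / windowMs)
    gz <- matrix(NA_real_, nrow(rows), 4,
                 dimnames = list(NULL, c("gaze consistency",
                                         "proportion gaze offscreen",
                                         "gaze typicality",
                                         "gaze offscreen")))
    fr <- gaze$frames
    vw <- gaze$views
    frKey <- paste(fr$video_id, fr$frame)
    for (i in seq_len(nrow(presentations))) {
      pid <- presentations$presentation_id[i]
      vid <- as.character(presentations$video_id[i])
      sf <- presentations$start_frame[i]
      nFv <- as.integer(round(fvDurationS * fps))
      frames <- sf + seq_len(nFv) - 1L
      fIdx <- match(paste(vid, frames), frKey)
      vSel <- vw[vw$presentation_id == pid, , drop = FALSE]
      vIdx <- match(frames, vSel$frame)
      perFrame <- cbind(
        "gaze consistency" = fr$consistency[fIdx],
        "proportion gaze offscreen" = 1 - fr$proportion_onscreen[fIdx],
        "gaze typicality" = vSel$typicality[vIdx],
        "gaze offscreen" = as.numeric(vSel$gaze_offscreen[vIdx]))
      perFrame[is.na(perFrame)] <- 0   # undefined metrics contribute 0
      wm <- windowMeansForPresentation(perFrame, 0L, fps, windowMs,
                                       fvDurationS, tauMs)
      if (anyNA(wm[, 1L])) {
        firstOk <- which(!is.na(wm[, 1L]))[1L]
        for (w in seq_len(firstOk - 1L)) wm[w, ] <- wm[firstOk, ]
      }
      gz[rows$presentation_id == pid, ] <- wm[seq_len(nW), ]
    }
    X <- cbind(X, gz)
  }
  list(X = X, rows = rows, included = filt$included,
       presentationCounts = filt$counts)
}

#' Fit the free-viewing Poisson encoding model
#'
#' Poisson (log link) elastic-net GLM of window spike counts on the lagged
#' design, with the per-observation offset ln(phi0 * pi_t * delta_n) fixing
#' the unit's baseline, stimulus-locked timecourse and slow drift. All
#' regressor gains beta_k are penalized; (alpha, lambda_1SE) come from
#' [cvSelect()]. Gains are reported both as log-gains and multiplicative
#' fold-changes exp(beta).
#'
#' @param counts matrix from [binSpikeCounts()]
#' @param tc output of [estimateTimecourseAndDrift()] on the same counts
#' @param design output of [buildLaggedDesign()] (or any matrix with rows
#'   in presentation-major window order)
#' @param config a [penaltyConfig()]; family forced to poisson
#' @return list of class "encodingFit": \code{fit} ([PenalizedFit-class]),
#'   \code{logGain} (named), \code{gain} (exp of it), \code{nonzero}
#' @export
fitEncodingModel <- function(counts, tc, design,
                             config = penaltyConfig("poisson")) {
  config$family <- "poisson"
  X <- if (is.list(design) && !is.null(design$X)) design$X else design
  y <- flattenCounts(counts)
  stopifnot(nrow(X) == length(y))
  off <- encodingOffsets(tc)
  fit <- cvSelect(X, y, config, offset = off)
  structure(list(fit = fit, logGain = fit@coefficients,
                 gain = exp(fit@coefficients),
                 nonzero = nonzeroCoefficients(fit)),
            class = "encodingFit")
}

#' @export
print.encodingFit <- function(x, ...) {
  cat("Free-viewing Poisson encoding fit:", length(x$logGain),
      "regressors,", length(x$nonzero), "nonzero\n")
  if (length(x$nonzero)) {
    show <- sort(x$gain[x$nonzero])
    print(round(show, 3))
  }
  invisible(x)
}

#' Choice-phase overdispersed Poisson model for one unit
#'
#' Compares spike counts during choice-target presentation (0.1-0.6 s after
#' target onset) with baseline counts (0.0-0.5 s before trial start) in a
#' quasi-Poisson GLM with an epoch term (target presentation vs baseline)
#' and epoch-by-option terms contrasting Switch and Continue (and Repeat,
#' when present) against Blank, using either the chosen option or each
#' offered option. Significance is Bonferroni-corrected at 0.05 across the
#' tested terms; modulation is the fold-change exp(|coefficient|).
#'
#' @param spikeTimes spike timestamps (seconds)
#' @param trials data.frame with \code{trial_start_s}, \code{target_on_s},
#'   \code{chosen}, and for the offered variant \code{menu_a},
#'   \code{menu_b}
#' @param variant "chosen" or "offered"
#' @param level familywise significance level before correction (0.05)
#' @return list of class "choicePhaseFit": \code{coefficients} (data.frame
#'   with estimate, se, p, significant, modulation), \code{variant},
#'   \code{dispersion}, \code{flagged} (low power / degenerate)
#' @export
fitChoicePhaseModel <- function(spikeTimes, trials,
                                variant = c("chosen", "offered"),
                                level = 0.05) {
  variant <- match.arg(variant)
  stopifnot(all(c("trial_start_s", "target_on_s", "chosen") %in%
                names(trials)))
  nT <- nrow(trials)
  countIn <- function(a, b) {
    vapply(seq_len(nT), function(i)
      sum(spikeTimes >= a[i] & spikeTimes < b[i]), numeric(1))
  }
  base <- countIn(trials$trial_start_s - 0.5, trials$trial_start_s)
  targ <- countIn(trials$target_on_s + 0.1, trials$target_on_s + 0.6)

  optInd <- function(opt) {
    if (variant == "chosen") as.numeric(trials$chosen == opt)
    else as.numeric(trials$menu_a == opt |
                      (!is.na(trials$menu_b) & trials$menu_b == opt))
  }
  present <- intersect(c("Switch", "Continue", "Repeat"),
                       unique(c(trials$chosen, trials$menu_a,
                                trials$menu_b)))
  df <- data.frame(count = c(base, targ),
                   epoch = rep(c(0, 1), each = nT))
  for (opt in present) df[[opt]] <- rep(c(0, 1), each = nT) *
    rep(optInd(opt), 2)

  flagged <- character()
  if (sum(base) + sum(targ) == 0) {
    return(structure(list(coefficients = NULL, variant = variant,
                          dispersion = NA_real_,
                          flagged = "degenerate: zero counts throughout"),
                     class = "choicePhaseFit"))
  }
  for (opt in present)
    if (variant == "chosen" && sum(trials$chosen == opt) < 10)
      flagged <- c(flagged, paste0("low power: <10 '", opt, "' trials"))

  fml <- stats::as.formula(paste(
    "count ~ epoch",
    if (length(present))
      paste("+", paste0("epoch:`", present, "`", collapse = " + "))
    else ""))
  fit <- stats::glm(fml, data = df, family = stats::quasipoisson())
  sm <- stats::summary.glm(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  out <- data.frame(term = terms,
                    estimate = sm[terms, 1],
                    se = sm[terms, 2],
                    p = sm[terms, 4],
                    row.names = NULL)
  out$significant <- out$p < level / length(terms)
  out$modulation <- exp(abs(out$estimate))
  structure(list(coefficients = out, variant = variant,
                 dispersion = stats::summary.glm(fit)$dispersion,
                 flagged = flagged),
            class = "choicePhaseFit")
}

#' @export
print.choicePhaseFit <- function(x, ...) {
  cat("Choice-phase quasi-Poisson fit (", x$variant, " option model)\n",
      sep = "")
  if (!is.null(x$coefficients)) {
    print(cbind(x$coefficients[, c("term", "estimate", "p")],
                sig = x$coefficients$significant))
    cat("dispersion:", round(x$dispersion, 3), "\n")
  }
  if (length(x$flagged)) cat("flags:", paste(x$flagged, collapse = "; "),
                             "\n")
  invisible(x)
}

#' Autocorrelation-based analysis-window recommendation
#'
#' Computes the autocorrelation function of finely binned spike counts
#' (taken during Blank presentations, when no stimulus drives the rate) and
#' reports the first lag at which it falls below the threshold, plus the
#' recommended analysis window of twice that lag — windows of that size can
#' be treated as roughly independent observations.
#'
#' @param counts integer vector of spike counts in consecutive fine bins
#' @param binMs fine bin width in ms (default 10)
#' @param threshold ACF threshold (default 0.1)
#' @param maxLagMs largest lag examined (default 1000)
#' @return list: \code{lagMs} (first lag with ACF < threshold),
#'   \code{recommendedWindowMs} (2 x lagMs), \code{acf}, \code{reliable}
#'   (FALSE with a warning when fewer than 1000 bins)
#' @export
autocorrelationWindowCheck <- function(counts, binMs = 10, threshold = 0.1,
                                       maxLagMs = 1000) {
  reliable <- length(counts) >= 1000
  if (!reliable)
    warning("fewer than 1000 bins; ACF estimate is unreliable")
  maxLag <- min(length(counts) - 1L, ceiling(maxLagMs / binMs))
  a <- stats::acf(counts, lag.max = maxLag, plot = FALSE)$acf[-1L]
  below <- which(a < threshold)
  if (!length(below)) stop("ACF never falls below the threshold within ",
                           maxLagMs, " ms")
  lagMs <- below[1L] * binMs
  list(lagMs = lagMs, recommendedWindowMs = 2 * lagMs, acf = a,
       reliable = reliable)
}

#' Population summary of encoding-model coefficients
#'
#' Counts, per regressor and region, the units whose fitted gain is nonzero
#' (as a count and a proportion of units in the region), and per unit the
#' number and proportion of regressors with nonzero gain — the summaries
#' behind population heatmaps of regressor representation.
#'
#' @param fits list of "encodingFit" objects (or [PenalizedFit-class])
#' @param regions character vector of region labels, one per fit (e.g.
#'   "OFC"/"LPFC"); default puts all units in one region
#' @return list: \code{byRegressor} (regressor, region, n_nonzero,
#'   n_units, proportion), \code{byUnit} (unit, region, n_nonzero,
#'   n_regressors, proportion)
#' @export
populationCoefficientSummary <- function(fits,
                                         regions = rep("all", length(fits))) {
  stopifnot(length(fits) >= 1, length(regions) == length(fits))
  nz <- lapply(fits, function(f) {
    if (inherits(f, "encodingFit")) f$nonzero else nonzeroCoefficients(f)
  })
  allRegs <- unique(unlist(lapply(fits, function(f) {
    if (inherits(f, "encodingFit")) names(f$logGain)
    else names(f@coefficients)
  })))
  byRegressor <- do.call(rbind, lapply(unique(regions), function(rg) {
    idx <- which(regions == rg)
    cnt <- vapply(allRegs, function(r)
      sum(vapply(nz[idx], function(z) r %in% z, logical(1))), integer(1))
    data.frame(regressor = allRegs, region = rg, n_nonzero = cnt,
               n_units = length(idx), proportion = cnt / length(idx),
               row.names = NULL)
  }))
  byUnit <- data.frame(
    unit = seq_along(fits), region = regions,
    n_nonzero = vapply(nz, length, integer(1)),
    n_regressors = length(allRegs))
  byUnit$proportion <- byUnit$n_nonzero / byUnit$n_regressors
  list(byRegressor = byRegressor, byUnit = byUnit)
}
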