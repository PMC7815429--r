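#' Default configuration for the synthetic-data generator
#'
#' Central knobs for generating behavioural timelines, gaze traces, choices
#' and spike trains with known ground truth. All generation is a pure
#' function of this configuration and the session RNG (seed with
#' [set.seed()]).
#'
#' @param nTrials trials per simulated session (default 500)
#' @param nVideos library size (default 100)
#' @param videoDurationRange video durations, seconds (default 30-120)
#' @return nested list of class "GeneratorConfig" with components
#'   \code{session}, \code{ethogram} (semi-Markov dwell means, event bout
#'   rates/durations), \code{gaze} (attractor layout, spread, offscreen
#'   logit intercept and behaviour effects), \code{choice} (true utilities
#'   v and interactions beta) and \code{neural} (units per region, baseline
#'   rate range, gain sparsity and magnitude range)
#' @export
generatorConfig <- function(nTrials = 500, nVideos = 100,
                            videoDurationRange = c(30, 120)) {
  structure(list(
    session = list(nTrials = nTrials, nVideos = nVideos,
                   videoDurationRange = videoDurationRange,
                   fvDurationS = 5, fps = 30),
    ethogram = list(
      baselineDwellFrames = 90,   # ~3 s between bouts of a leveled state
      activeDwellFrames = 45,     # ~1.5 s bouts
      eventOnsetRate = 1 / 300,   # per frame, per event behaviour
      eventDurationFrames = 20,
      dwellOverrides = list()     # per-observation c(baseline=, active=)
    ),
    gaze = list(
      attractorsPerBlock = 2, blockFrames = 150, attractorSd = 0.05,
      offscreenIntercept = stats::qlogis(0.15),
      offscreenEffects = numeric(0),   # named: log-odds offsets per variable
      sdLogEffects = numeric(0),       # named: log-sd offsets per variable
      noiseSdPx = 1,
      videoPx = c(width = 610, height = 458),
      originPx = c(x = 207, y = 155)   # video centred on a 1024x768 monitor
    ),
    choice = list(v = c(Repeat = 0.5, Continue = 1, Switch = 2),
                  beta = NULL),
    neural = list(nUnitsPerRegion = 10, phi0Range = c(1, 4),
                  nActiveRange = c(5, 10), gainRange = c(1 / 3, 3),
                  interTrialS = 3)
  ), class = "GeneratorConfig")
}

# alternate baseline/active dwell times (exponential by default)
semiMarkovLevels <- function(nFrames, levels, baselineMean, activeMean) {
  out <- character(nFrames)
  pos <- 1L
  atBaseline <- TRUE
  while (pos <= nFrames) {
    dwellMean <- if (atBaseline) baselineMean else activeMean
    lev <- if (atBaseline) levels[1L]
           else sample(levels[-1L], 1L)
    if (!is.finite(dwellMean)) {        # absorbing state
      out[pos:nFrames] <- lev
      break
    }
    dwell <- max(1L, round(stats::rexp(1, 1 / dwellMean)))
    out[pos:min(nFrames, pos + dwell - 1L)] <- lev
    pos <- pos + dwell
    atBaseline <- !atBaseline
  }
  out
}

#' Generate a synthetic scoring timeline
#'
#' Semi-Markov bout structure: each leveled observation alternates between
#' baseline dwell periods and bouts of a uniformly chosen non-baseline
#' level, with exponential dwell times; each event behaviour gets Poisson
#' bout onsets with exponential durations. The derived analysis ethogram
#' satisfies all nesting invariants by construction.
#'
#' @param nFrames frames to generate
#' @param fps frames per second (default 30)
#' @param config a [generatorConfig()] (its \code{ethogram} block is used)
#' @param videoId identifier for the timeline
#' @return a [ScoringTimeline-class]
#' @export
generateEthogramTimeline <- function(nFrames, fps = 30,
                                     config = generatorConfig(),
                                     videoId = "synth") {
  eth <- scoringEthogram()
  ecfg <- config$ethogram
  levs <- lapply(names(eth$leveled), function(obs) {
    dw <- ecfg$dwellOverrides[[obs]]
    bl <- if (!is.null(dw)) dw[["baseline"]] else ecfg$baselineDwellFrames
    ac <- if (!is.null(dw)) dw[["active"]] else ecfg$activeDwellFrames
    semiMarkovLevels(nFrames, eth$leveled[[obs]], bl, ac)
  })
  names(levs) <- names(eth$leveled)
  evs <- lapply(eth$events, function(evName) {
    v <- integer(nFrames)
    nOn <- stats::rpois(1, ecfg$eventOnsetRate * nFrames)
    if (nOn > 0) {
      starts <- sample.int(nFrames, nOn, replace = TRUE)
      durs <- pmax(1L, round(stats::rexp(nOn, 1 / ecfg$eventDurationFrames)))
      for (b in seq_len(nOn))
        v[starts[b]:min(nFrames, starts[b] + durs[b] - 1L)] <- 1L
    }
    v
  })
  names(evs) <- eth$events
  ScoringTimeline(videoId, nFrames, fps = fps, levels = levs, events = evs)
}

#' Generate synthetic gaze-focus viewings of a video
#'
#' Per block of frames a small set of gaze attractors is placed inside the
#' video frame; on each viewing of each frame the gaze focus is either
#' offscreen — with probability given by a logistic function of the frame's
#' analysis-ethogram variables — or drawn from a Gaussian around one
#' attractor, whose spread can also depend on the ethogram (log-scale
#' effects). Optionally emits the corresponding raw 1000 Hz monitor-pixel
#' traces for exercising the downsampling front end.
#'
#' @param ethogram an [AnalysisEthogram-class] for the viewed video
#' @param nViews number of simulated viewings
#' @param config a [generatorConfig()] (its \code{gaze} block is used)
#' @param emitRaw also return 1000 Hz monitor-pixel traces (default FALSE)
#' @return list: \code{views} (data.frame presentation_id, video_id, frame,
#'   x, y, in_frame in normalized video coordinates), \code{raw} (list of
#'   data.frames t_ms/x_px/y_px, or NULL), \code{geometry},
#'   \code{truth} (attractor table and effect vectors)
#' @export
generateGazeTraces <- function(ethogram, nViews,
                               config = generatorConfig(),
                               emitRaw = FALSE) {
  stopifnot(is(ethogram, "AnalysisEthogram"), nViews >= 1)
  g <- config$gaze
  nf <- nFrames(ethogram)
  fps <- framesPerSecond(ethogram)
  vm <- variableMatrix(ethogram)
  nBlocks <- ceiling(nf / g$blockFrames)
  attractors <- data.frame(
    block = rep(seq_len(nBlocks), each = g$attractorsPerBlock),
    x = stats::runif(nBlocks * g$attractorsPerBlock, -0.55, 0.55),
    y = stats::runif(nBlocks * g$attractorsPerBlock, -0.40, 0.40))

  effCols <- function(eff) {
    if (!length(eff)) return(rep(0, nf))
    use <- intersect(names(eff), colnames(vm))
    drop(vm[, use, drop = FALSE] %*% eff[use])
  }
  offLogit <- g$offscreenIntercept + effCols(g$offscreenEffects)
  sdFrame <- g$attractorSd * exp(effCols(g$sdLogEffects))

  bounds <- gazeMetricConfig()
  views <- vector("list", nViews)
  for (v in seq_len(nViews)) {
    off <- stats::runif(nf) < stats::plogis(offLogit)
    blk <- ((seq_len(nf) - 1L) %/% g$blockFrames) + 1L
    pick <- (blk - 1L) * g$attractorsPerBlock +
      sample.int(g$attractorsPerBlock, nf, replace = TRUE)
    x <- attractors$x[pick] + stats::rnorm(nf, 0, sdFrame)
    y <- attractors$y[pick] + stats::rnorm(nf, 0, sdFrame)
    # offscreen gaze parks beyond the in-frame rectangle
    x[off] <- stats::runif(sum(off), bounds$frameHalfWidth + 0.1,
                           bounds$frameHalfWidth + 0.5) *
      sample(c(-1, 1), sum(off), replace = TRUE)
    y[off] <- stats::runif(sum(off), -0.5, 0.5)
    views[[v]] <- data.frame(
      presentation_id = paste0(videoId(ethogram), "_view", v),
      video_id = videoId(ethogram),
      frame = seq_len(nf) - 1L,
      x = x, y = y,
      in_frame = flagInFrame(x, y, bounds))
  }
  viewsDf <- do.call(rbind, views)

  raw <- NULL
  geometry <- list(video_px = unname(g$videoPx),
                   origin_px = unname(g$originPx), fps = fps, n_frames = nf)
  if (emitRaw) {
    h <- g$videoPx[["height"]]
    cx <- g$originPx[["x"]] + g$videoPx[["width"]] / 2
    cy <- g$originPx[["y"]] + h / 2
    raw <- lapply(views, function(vv) {
      tMs <- seq(0.5, nf * 1000 / fps - 0.5, by = 1)
      fIdx <- pmin(floor(tMs * fps / 1000) + 1L, nf)
      data.frame(
        t_ms = tMs,
        x_px = vv$x[fIdx] * h + cx + stats::rnorm(length(tMs), 0,
                                                  g$noiseSdPx),
        y_px = vv$y[fIdx] * h + cy + stats::rnorm(length(tMs), 0,
                                                  g$noiseSdPx))
    })
    names(raw) <- vapply(views, function(vv)
      as.character(vv$presentation_id[1L]), character(1))
  }
  list(views = viewsDf, raw = raw, geometry = geometry,
       truth = list(attractors = attractors,
                    offscreenIntercept = g$offscreenIntercept,
                    offscreenEffects = g$offscreenEffects,
                    sdLogEffects = g$sdLogEffects))
}

#' Generate spike trains from the generative encoding model
#'
#' Window rates are lambda_{n,t} = phi0 * pi_t * delta_n *
#' exp(sum_k beta_k x_{k,n,t}) with the design already lagged; counts are
#' Poisson and spike timestamps uniform within their window.
#'
#' @param design matrix of regressor values, rows presentation-major
#'   (window fastest), as from [buildLaggedDesign()]
#' @param tc list(phi0, pi, delta): the true baseline, timecourse (length =
#'   windows, mean 1) and drift (length = presentations, mean 1)
#' @param beta named numeric of true log-gains (names must be design
#'   columns; missing names get 0)
#' @param windowMs window duration (default 200)
#' @param fvDurationS presentation duration (default 5)
#' @param onsets optional presentation onset times (seconds); default
#'   spaces presentations \code{interTrialS} apart
#' @param interTrialS gap between presentations (default 3)
#' @return list: \code{spikeTimes}, \code{counts} (presentations x
#'   windows), \code{lambda}, \code{onsets}, \code{truth} (beta)
#' @export
generateSpikeTrains <- function(design, tc, beta, windowMs = 200,
                                fvDurationS = 5, onsets = NULL,
                                interTrialS = 3) {
  X <- if (is.list(design) && !is.null(design$X)) design$X else design
  nW <- length(tc$pi)
  nP <- length(tc$delta)
  stopifnot(nrow(X) == nW * nP)
  b <- stats::setNames(numeric(ncol(X)), colnames(X))
  b[intersect(names(beta), names(b))] <-
    beta[intersect(names(beta), names(b))]
  eta <- drop(X %*% b)
  lambdaVec <- tc$phi0 * rep(tc$pi, nP) * rep(tc$delta, each = nW) *
    exp(eta)
  if (any(lambdaVec > 1e4))
    stop("window rate exceeds 10^4 spikes; check the configured gains")
  cnt <- stats::rpois(length(lambdaVec), lambdaVec)
  counts <- matrix(cnt, nP, nW, byrow = TRUE)
  if (is.null(onsets))
    onsets <- (seq_len(nP) - 1L) * (fvDurationS + interTrialS)
  wS <- windowMs / 1000
  spikes <- unlist(lapply(seq_len(nP), function(p) {
    unlist(lapply(seq_len(nW), function(w) {
      k <- counts[p, w]
      if (k == 0) return(numeric(0))
      sort(stats::runif(k, onsets[p] + (w - 1) * wS, onsets[p] + w * wS))
    }))
  }))
  list(spikeTimes = spikes, counts = counts,
       lambda = matrix(lambdaVec, nP, nW, byrow = TRUE), onsets = onsets,
       truth = list(beta = b, tc = tc))
}

#' Generate a choice dataset from known utilities
#'
#' Simulates a session with the adaptive task engine and a choice policy
#' following the ranked-choice rule at the configured true utilities and
#' interactions. Ethogram occurrence during each video trial is drawn as
#' independent Bernoulli per variable (Blank trials have none), which is
#' all the choice model consumes.
#'
#' @param nTrials number of trials
#' @param v true utilities (named: Repeat, Continue, Switch)
#' @param beta true interaction matrix (3 x K, rownames
#'   Repeat/Continue/Switch) or NULL
#' @param pOccur named per-variable occurrence probabilities (defines K)
#' @param config a [menuConfig()]
#' @param library video catalogue; default 20 videos of 60 s
#' @return list: \code{trials}, \code{occurrence} (nTrials x K),
#'   \code{truth} (v, beta)
#' @export
generateChoiceData <- function(nTrials, v = c(Repeat = 0.5, Continue = 1,
                                              Switch = 2),
                               beta = NULL,
                               pOccur = stats::setNames(rep(0.3, 8),
                                                        paste0("beh", 1:8)),
                               config = menuConfig(), library = NULL) {
  if (is.null(library))
    library <- data.frame(video_id = paste0("v", 1:20), duration_s = 60)
  K <- length(pOccur)
  occ <- matrix(stats::rbinom(nTrials * K, 1, rep(pOccur, each = nTrials)),
                nTrials, K, dimnames = list(NULL, names(pOccur)))
  policy <- utilityChoicePolicy(v, beta)
  contextFn <- function(i, last) {
    if (i == 1L || is.null(last) || is.na(last$video_id))
      list(x = stats::setNames(numeric(K), names(pOccur)))
    else list(x = occ[i - 1L, ])
  }
  trials <- simulateSession(nTrials, config, library, policy, contextFn)
  occ[is.na(trials$video_id), ] <- 0L
  list(trials = trials, occurrence = occ, truth = list(v = v, beta = beta))
}

#' Generate a complete coherent synthetic session
#'
#' Composes the generators end-to-end: a video library with synthetic
#' scoring timelines and derived analysis ethograms, a simulated session
#' whose choices follow the ranked-choice rule at the configured true
#' utilities (with ethogram occurrence read from the actually viewed
#' segments), gaze viewings for each video presentation, and spike trains
#' for each unit from the generative encoding model on the session's own
#' lagged design.
#'
#' @param config a [generatorConfig()]
#' @param nUnits number of units to simulate (default 4; regions alternate
#'   OFC/LPFC)
#' @return list: \code{library}, \code{scoring}, \code{ethograms},
#'   \code{trials}, \code{presentations}, \code{design}, \code{gaze},
#'   \code{units} (list with counts, spikes, region, truth),
#'   \code{groundTruth}
#' @export
generateSession <- function(config = generatorConfig(), nUnits = 4) {
  s <- config$session
  fps <- s$fps
  library <- data.frame(
    video_id = sprintf("v%03d", seq_len(s$nVideos)),
    duration_s = round(stats::runif(s$nVideos, s$videoDurationRange[1],
                                    s$videoDurationRange[2])))
  scoring <- lapply(seq_len(s$nVideos), function(i)
    generateEthogramTimeline(library$duration_s[i] * fps, fps, config,
                             videoId = library$video_id[i]))
  names(scoring) <- library$video_id
  ethograms <- lapply(scoring, deriveAnalysisEthogram)

  occurrenceOf <- function(trial) {
    vm <- variableMatrix(ethograms[[trial$video_id]])
    f0 <- round(trial$seg_start_s * fps) + 1L
    f1 <- min(nrow(vm), round(trial$seg_end_s * fps))
    apply(vm[f0:f1, , drop = FALSE], 2, max)
  }
  contextFn <- function(i, last) {
    if (is.null(last) || is.na(last$video_id))
      list(x = NULL)
    else list(x = occurrenceOf(last))
  }
  policy <- utilityChoicePolicy(config$choice$v, config$choice$beta)
  trials <- simulateSession(s$nTrials, menuConfig(), library, policy,
                            contextFn, s$fvDurationS)

  vids <- which(!is.na(trials$video_id))
  presentations <- data.frame(
    presentation_id = trials$trial[vids],
    video_id = trials$video_id[vids],
    start_frame = round(trials$seg_start_s[vids] * fps))

  design <- buildLaggedDesign(ethograms, presentations, gaze = NULL)

  # a few viewings of the most-presented video exercise the gaze pipeline
  topVid <- names(sort(table(presentations$video_id), decreasing = TRUE))[1]
  gaze <- generateGazeTraces(ethograms[[topVid]], nViews = 8, config)

  n <- config$neural
  nP <- nrow(presentations)
  nW <- as.integer(s$fvDurationS * 1000 / 200)
  units <- lapply(seq_len(nUnits), function(u) {
    phi0 <- stats::runif(1, n$phi0Range[1], n$phi0Range[2])
    piT <- exp(0.3 * sin(seq(0, 2 * pi, length.out = nW)))
    piT <- piT / mean(piT)
    delta <- exp(seq(0, stats::runif(1, -0.3, 0.3), length.out = nP))
    delta <- delta / mean(delta)
    nAct <- sample(seq(n$nActiveRange[1], n$nActiveRange[2]), 1)
    act <- sample(colnames(design$X), min(nAct, ncol(design$X)))
    beta <- stats::setNames(
      log(stats::runif(length(act), n$gainRange[1], n$gainRange[2])), act)
    tc <- list(phi0 = phi0, pi = piT, delta = delta)
    gen <- generateSpikeTrains(design, tc, beta,
                               fvDurationS = s$fvDurationS,
                               interTrialS = n$interTrialS)
    list(region = if (u %% 2) "OFC" else "LPFC", counts = gen$counts,
         spikeTimes = gen$spikeTimes, onsets = gen$onsets,
         truth = list(beta = beta, tc = tc))
  })
  list(library = library, scoring = scoring, ethograms = ethograms,
       trials = trials, presentations = presentations, design = design,
       gaze = gaze, units = units,
       groundTruth = list(choice = config$choice,
                          neural = lapply(units, `[[`, "truth")))
}
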