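# Independent brute-force oracles for the gaze statistics: plain double
# loops, no shared code with the package implementation.

bruteConsistency <- function(x, y, d0 = 0.01) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) {
        d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        s <- s + 1 / max(d, d0)
      }
    }
  }
  2 * d0 / (n * (n - 1)) * s
}

bruteTypicality <- function(i, x, y, d0 = 0.01) {
  n <- length(x)
  s <- 0
  for (j in seq_len(n)) {
    if (j != i) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      s <- s + 1 / max(d, d0)
    }
  }
  d0 / (n - 1) * s
}

# Shared small synthetic stimulus set: analysis ethograms for a handful of
# videos plus a randomized presentation schedule (the task interleaves
# videos trial by trial, so consecutive presentations are near-independent).
makeStimulusSet <- function(nVideos, framesPerVideo, presPerVideo,
                            fps = 30) {
  eths <- lapply(seq_len(nVideos), function(i) deriveAnalysisEthogram(
    generateEthogramTimeline(framesPerVideo, fps,
                             videoId = paste0("v", i))))
  names(eths) <- paste0("v", seq_len(nVideos))
  pres <- data.frame(
    presentation_id = seq_len(nVideos * presPerVideo),
    video_id = rep(paste0("v", seq_len(nVideos)), each = presPerVideo),
    start_frame = rep((seq_len(presPerVideo) - 1L) * fps * 5, nVideos))
  pres <- pres[sample(nrow(pres)), ]
  pres$presentation_id <- seq_len(nrow(pres))
  rownames(pres) <- NULL
  list(ethograms = eths, presentations = pres)
}

# One synthetic unit from the generative encoding model on a given design.
makeSyntheticUnit <- function(design, nPres, nActive, gainRange = c(1/3, 3),
                              phi0 = NULL, drift = TRUE) {
  nW <- 25
  piT <- exp(0.3 * sin(seq(0, 2 * pi, length.out = nW)))
  piT <- piT / mean(piT)
  delta <- if (drift) exp(seq(0, runif(1, -0.3, 0.3), length.out = nPres))
           else rep(1, nPres)
  delta <- delta / mean(delta)
  if (is.null(phi0)) phi0 <- runif(1, 1, 4)
  act <- sample(colnames(design$X), nActive)
  beta <- setNames(log(runif(nActive, gainRange[1], gainRange[2])), act)
  tc <- list(phi0 = phi0, pi = piT, delta = delta)
  gen <- generateSpikeTrains(design, tc, beta)
  list(gen = gen, tc = tc, beta = beta)
}

# Reduced alpha grid used in the larger simulation studies (the default
# 6-point grid is exercised in the unit tests; two points keep the
# multi-unit recovery studies fast without changing the 1SE machinery).
simAlphaGrid <- c(0.5, 1)
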