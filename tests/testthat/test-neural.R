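test_that("spike binning conserves counts over 25 windows", {
  set.seed(601)
  onsets <- c(10, 30, 55)
  # homogeneous 10 Hz train over 80 s
  spikes <- sort(runif(800, 0, 80))
  counts <- binSpikeCounts(spikes, onsets)
  expect_equal(dim(counts), c(3L, 25L))
  expect_equal(mean(counts), 2, tolerance = 0.15)     # 10 Hz x 0.2 s
  # window count conservation
  for (p in 1:3) {
    inP <- sum(spikes >= onsets[p] & spikes < onsets[p] + 5)
    expect_equal(sum(counts[p, ]), inP)
  }
  expect_equal(attr(counts, "nOutside"),
               sum(!(spikes >= 10 & spikes < 15) &
                   !(spikes >= 30 & spikes < 35) &
                   !(spikes >= 55 & spikes < 60)))
  # empty train
  empty <- binSpikeCounts(numeric(0), onsets)
  expect_true(all(empty == 0L))
  expect_error(binSpikeCounts(c(2, 1), onsets), "non-decreasing")
  expect_error(binSpikeCounts(spikes, onsets, windowMs = 300), "divide")
})

test_that("timecourse and drift are recovered from structured units", {
  set.seed(602)
  nP <- 100; nW <- 25
  # stationary homogeneous unit: pi and delta near 1
  flat <- matrix(rpois(nP * nW, 2), nP, nW)
  tc <- estimateTimecourseAndDrift(flat)
  expect_equal(tc$phi0, mean(flat))
  expect_true(all(abs(tc$pi - 1) < 0.2))
  expect_true(all(abs(tc$delta - 1) < 0.2))
  expect_equal(mean(tc$pi), 1)
  expect_equal(mean(tc$delta), 1)
  # onset transient in pi recovered (r > 0.9 at 100 presentations)
  piTrue <- c(rep(2.2, 5), rep(0.85, 20)); piTrue <- piTrue / mean(piTrue)
  lam <- outer(rep(3, nP), piTrue)
  cnt <- matrix(rpois(length(lam), lam), nP, nW)
  tc2 <- estimateTimecourseAndDrift(cnt)
  expect_gt(cor(tc2$pi, piTrue), 0.9)
  # 2x linear drift across the session: monotone increasing estimate
  drift <- seq(1, 2, length.out = nP); drift <- drift / mean(drift)
  lam3 <- outer(drift, rep(2.5, nW))
  cnt3 <- matrix(rpois(length(lam3), lam3), nP, nW)
  tc3 <- estimateTimecourseAndDrift(cnt3)
  expect_gt(cor(tc3$delta, drift, method = "spearman"), 0.9)
  expect_error(estimateTimecourseAndDrift(matrix(0L, 10, 25)),
               "unmodellable")
})

test_that("offsets are identifiable up to the phi0/delta trade-off", {
  set.seed(603)
  tc <- list(phi0 = 2, pi = rep(1, 25), delta = rep(1, 40))
  tcScaled <- list(phi0 = 2 * 3, pi = tc$pi, delta = tc$delta / 3)
  expect_equal(encodingOffsets(tc), encodingOffsets(tcScaled))
})

test_that("lagged design shifts window means by tau", {
  # a step regressor rising at 1.0 s into the presentation
  vm <- matrix(0L, 300, 2, dimnames = list(NULL, c("step", "const")))
  vm[31:300, "step"] <- 1L   # frame 30 (0-based) onward = 1.0 s onward
  vm[, "const"] <- 1L
  ae <- new("AnalysisEthogram", videoId = "s", fps = 30, variables = vm)
  pres <- data.frame(presentation_id = 1:5, video_id = "s",
                     start_frame = (0:4) * 0)
  des <- buildLaggedDesign(ae, pres, tauMs = 100, minPresentations = 5)
  x <- des$X[des$rows$presentation_id == 1, ]
  # constant regressor is unaffected by the lag
  expect_equal(unname(x[, "const"]), rep(1, 25))
  # window 5 (0-based) spans stimulus time [0.9, 1.1) s: half the frames
  # are past the step, so the lagged mean crosses 0.5 exactly there
  expect_equal(unname(x[6, "step"]), 0.5)
  expect_equal(unname(x[5, "step"]), 0)
  expect_equal(unname(x[7, "step"]), 1)
  # brute-force oracle for the lagged window means
  for (w in 0:24) {
    tMid <- ((0:149) + 0.5) * 1000 / 30
    inWin <- tMid >= w * 200 - 100 & tMid < (w + 1) * 200 - 100
    if (any(inWin))
      expect_equal(unname(x[w + 1, "step"]),
                   mean(vm[which(inWin), "step"]), tolerance = 1e-12)
  }
})

test_that("rare variables are dropped from the lagged design", {
  set.seed(604)
  vm <- matrix(0L, 1500, 2, dimnames = list(NULL, c("common", "rare")))
  vm[, "common"] <- rbinom(1500, 1, 0.4)
  vm[1:50, "rare"] <- 1L   # confined to presentation 1
  ae <- new("AnalysisEthogram", videoId = "r", fps = 30, variables = vm)
  pres <- data.frame(presentation_id = 1:10, video_id = "r",
                     start_frame = (0:9) * 150)
  des <- buildLaggedDesign(ae, pres)
  expect_true("common" %in% colnames(des$X))
  expect_false("rare" %in% colnames(des$X))
  expect_equal(unname(des$presentationCounts["rare"]), 1L)
})

test_that("encoding model recovers a planted gain and ignores offset scale", {
  set.seed(605)
  stim <- makeStimulusSet(nVideos = 8, framesPerVideo = 3000,
                          presPerVideo = 15)
  des <- buildLaggedDesign(stim$ethograms, stim$presentations)
  nP <- nrow(stim$presentations)
  piT <- rep(1, 25)
  tc <- list(phi0 = 3, pi = piT, delta = rep(1, nP))
  beta <- c("foraging" = log(2))
  gen <- generateSpikeTrains(des, tc, beta)
  est <- estimateTimecourseAndDrift(gen$counts)
  cfg <- penaltyConfig("poisson", alphaGrid = simAlphaGrid)
  set.seed(606)
  ef <- fitEncodingModel(gen$counts, est, des, cfg)
  expect_true("foraging" %in% ef$nonzero)
  expect_gt(ef$logGain["foraging"], log(1.4))
  expect_lt(ef$logGain["foraging"], log(2.8))
  # doubling all drift terms (with phi0 halved) leaves the fit unchanged
  est2 <- list(phi0 = est$phi0 / 2, pi = est$pi, delta = est$delta * 2)
  set.seed(606)
  ef2 <- fitEncodingModel(gen$counts, est2, des, cfg)
  expect_equal(ef$logGain, ef2$logGain, tolerance = 1e-8)
})

test_that("choice-phase model detects option modulation", {
  set.seed(607)
  nT <- 200
  trials <- data.frame(
    trial_start_s = (0:(nT - 1)) * 10 + 1,
    target_on_s = (0:(nT - 1)) * 10 + 2,
    chosen = sample(c("Blank", "Switch", "Continue"), nT, replace = TRUE),
    stringsAsFactors = FALSE)
  trials$menu_a <- trials$chosen
  trials$menu_b <- NA_character_
  # baseline 8 Hz; target epoch doubles the rate on Switch trials only
  spikes <- unlist(lapply(seq_len(nT), function(i) {
    rate <- 8
    base <- runif(rpois(1, rate * 0.5), trials$trial_start_s[i] - 0.5,
                  trials$trial_start_s[i])
    tRate <- if (trials$chosen[i] == "Switch") 2 * rate else rate
    targ <- runif(rpois(1, tRate * 0.5), trials$target_on_s[i] + 0.1,
                  trials$target_on_s[i] + 0.6)
    c(base, targ)
  }))
  fit <- fitChoicePhaseModel(sort(spikes), trials, "chosen")
  co <- fit$coefficients
  sw <- co[co$term == "epoch:Switch", ]
  expect_true(sw$significant)
  expect_equal(sw$modulation, 2, tolerance = 0.25)
  # forced menus make offered == chosen here, so both variants agree
  fitOff <- fitChoicePhaseModel(sort(spikes), trials, "offered")
  swOff <- fitOff$coefficients[fitOff$coefficients$term == "epoch:Switch", ]
  expect_true(swOff$significant)
  expect_equal(swOff$estimate, sw$estimate, tolerance = 1e-9)
  # degenerate all-zero unit is flagged, not fitted
  z <- fitChoicePhaseModel(numeric(0), trials)
  expect_null(z$coefficients)
  expect_match(z$flagged, "degenerate")
})

test_that("choice-phase false positives stay near the corrected level", {
  set.seed(608)
  nT <- 150
  anySig <- vapply(1:20, function(rep) {
    trials <- data.frame(
      trial_start_s = (0:(nT - 1)) * 10 + 1,
      target_on_s = (0:(nT - 1)) * 10 + 2,
      chosen = sample(c("Blank", "Switch", "Continue"), nT, replace = TRUE),
      stringsAsFactors = FALSE)
    spikes <- sort(runif(rpois(1, 8 * nT * 10), 0, nT * 10))
    fit <- fitChoicePhaseModel(spikes, trials, "chosen")
    any(fit$coefficients$significant)
  }, logical(1))
  # stationary unit: familywise error should sit near the 5% target
  expect_lte(mean(anySig), 0.15)
})

test_that("ACF window check recommends twice the decorrelation lag", {
  set.seed(609)
  # white Poisson counts decorrelate at the first lag
  white <- rpois(20000, 0.5)
  w <- autocorrelationWindowCheck(white, binMs = 10)
  expect_equal(w$lagMs, 10)
  expect_equal(w$recommendedWindowMs, 20)
  # bursty spiking holds correlation longer than the Poisson control
  burst <- white
  burst[2:20000] <- burst[2:20000] + rbinom(19999, burst[1:19999], 0.8)
  b <- autocorrelationWindowCheck(burst, binMs = 10)
  expect_gt(b$lagMs, w$lagMs)
  expect_warning(autocorrelationWindowCheck(rpois(500, 1), binMs = 10),
                 "unreliable")
})

test_that("population summaries count nonzero coefficients per region", {
  mkFit <- function(nz, all = paste0("r", 1:44)) {
    co <- setNames(rep(0, length(all)), all)
    co[nz] <- 1
    structure(list(nonzero = nz, logGain = co, gain = exp(co)),
              class = "encodingFit")
  }
  fits <- list(mkFit(character(0)), mkFit(paste0("r", 1:3)),
               mkFit(paste0("r", 1:6)), mkFit("r1"))
  regions <- c("OFC", "OFC", "LPFC", "LPFC")
  ps <- populationCoefficientSummary(fits, regions)
  expect_equal(ps$byUnit$proportion[2], 3 / 44)
  allNull <- populationCoefficientSummary(list(mkFit(character(0))), "OFC")
  expect_true(all(allNull$byRegressor$proportion == 0))
  # planted region contrast is reproduced
  r1 <- ps$byRegressor[ps$byRegressor$regressor == "r1", ]
  expect_equal(r1$proportion[r1$region == "OFC"], 0.5)
  expect_equal(r1$proportion[r1$region == "LPFC"], 1.0)
  lp <- ps$byUnit[ps$byUnit$region == "LPFC", ]
  of <- ps$byUnit[ps$byUnit$region == "OFC", ]
  expect_gt(mean(lp$n_nonzero), mean(of$n_nonzero))
})
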