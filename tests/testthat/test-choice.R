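mkTrials <- function(menuA, menuB, chosen, videoId = NULL) {
  n <- length(menuA)
  data.frame(trial = seq_len(n), menu_a = menuA, menu_b = menuB,
             forced = is.na(menuB), chosen = chosen,
             video_id = if (is.null(videoId)) rep("v1", n) else videoId,
             stringsAsFactors = FALSE)
}

test_that("choice design applies the ranked +/-1 coding", {
  trials <- mkTrials(
    menuA = c("Switch", "Switch", "Continue", "Blank"),
    menuB = c("Blank", "Blank", "Repeat", NA),
    chosen = c("Switch", "Switch", "Repeat", "Blank"))
  d <- buildChoiceDesign(trials)
  # first trial and the forced trial are excluded
  expect_equal(d$trialIndex, c(2L, 3L))
  expect_equal(d$nExcluded, 2L)
  # menu {Switch, Blank}, chose Switch
  expect_equal(unname(d$X[1, c("Repeat", "Continue", "Switch")]),
               c(0, 0, 1))
  expect_equal(d$y[1], 1L)
  # menu {Continue, Repeat}, chose Repeat (the lower-ranked option)
  expect_equal(unname(d$X[2, c("Repeat", "Continue", "Switch")]),
               c(-1, 1, 0))
  expect_equal(d$y[2], 0L)
  expect_equal(unname(d$penaltyFactors), rep(0, 3))
})

test_that("interactions carry the previous video's occurrence", {
  trials <- mkTrials(
    menuA = c("Switch", "Switch", "Switch"),
    menuB = c("Continue", "Blank", "Blank"),
    chosen = c("Switch", "Switch", "Switch"),
    videoId = c("v1", NA, "v2"))
  trials$chosen[2] <- "Blank"; trials$video_id[2] <- NA
  occ <- matrix(c(1, 0,
                  0, 0,
                  1, 1), 3, 2, byrow = TRUE,
                dimnames = list(NULL, c("any aggression", "foraging")))
  d <- buildChoiceDesign(trials, occ)
  # trial 2: previous video (trial 1) contained aggression; Switch offered
  # as the higher-ranked option
  expect_equal(unname(d$X[1, "Switch:any aggression"]), 1)
  expect_equal(unname(d$X[1, "Switch:foraging"]), 0)
  # Continue was not offered on that trial: its interaction stays 0
  expect_equal(unname(d$X[1, "Continue:any aggression"]), 0)
  # trial 3 follows a Blank choice: all interactions zero
  expect_true(all(d$X[2, -(1:3)] == 0))
  expect_equal(unname(d$penaltyFactors), c(rep(0, 3), rep(1, 6)))
})

test_that("null utilities are recovered near zero", {
  set.seed(501)
  cd <- generateChoiceData(6000, v = c(Repeat = 0, Continue = 0, Switch = 0),
                           pOccur = setNames(rep(0.3, 4), paste0("b", 1:4)))
  # with v = 0 every two-option choice is a fair coin
  twoOpt <- !cd$trials$forced
  expect_equal(mean(cd$trials$chosen[twoOpt] ==
                    cd$trials$menu_a[twoOpt]), 0.5, tolerance = 0.05)
  d <- buildChoiceDesign(cd$trials, cd$occurrence)
  fit <- fitChoiceModel(d, penaltyConfig("binomial",
                                         alphaGrid = simAlphaGrid))
  expect_true(all(abs(fit$v) < 0.1))
})

test_that("a strong planted interaction enters the nonzero set", {
  set.seed(502)
  beta <- matrix(0, 3, 4,
                 dimnames = list(c("Repeat", "Continue", "Switch"),
                                 paste0("b", 1:4)))
  beta["Switch", "b1"] <- 1.5
  cd <- generateChoiceData(8000, v = c(Repeat = 0.5, Continue = 1,
                                       Switch = 2),
                           beta = beta,
                           pOccur = setNames(rep(0.4, 4), paste0("b", 1:4)))
  d <- buildChoiceDesign(cd$trials, cd$occurrence)
  fit <- fitChoiceModel(d, penaltyConfig("binomial",
                                         alphaGrid = simAlphaGrid))
  expect_true("Switch:b1" %in% fit$interactions)
  expect_gt(fit$beta["Switch:b1"], 0)
})

test_that("pairwise choice frequencies are monotone in utility differences", {
  set.seed(503)
  cd <- generateChoiceData(8000, v = c(Repeat = 0.5, Continue = 1,
                                       Switch = 2))
  tr <- cd$trials[!cd$trials$forced, ]
  pickRate <- function(a, b) {
    rows <- (tr$menu_a == a & tr$menu_b == b) |
            (tr$menu_a == b & tr$menu_b == a)
    mean(tr$chosen[rows] == a)
  }
  # Switch > Continue > Repeat > Blank, with larger gaps chosen more often
  expect_gt(pickRate("Switch", "Blank"), pickRate("Continue", "Blank"))
  expect_gt(pickRate("Continue", "Blank"), pickRate("Repeat", "Blank"))
  expect_gt(pickRate("Switch", "Blank"), pickRate("Switch", "Continue"))
  expect_gt(pickRate("Switch", "Repeat"), 0.5)
})

test_that("gaze-onscreen model recovers a planted behavioural effect", {
  set.seed(504)
  n <- 20000
  X <- cbind("any aggression" = rbinom(n, 1, 0.25),
             "foraging" = rbinom(n, 1, 0.3),
             "visible face" = rbinom(n, 1, 0.4))
  p <- plogis(0.8 + 1.2 * X[, "any aggression"])
  yin <- rbinom(n, 1, p)
  fit <- fitGazeOnscreenModel(yin, X,
                              penaltyConfig("binomial",
                                            alphaGrid = simAlphaGrid))
  expect_true("any aggression" %in% nonzeroCoefficients(fit))
  expect_gt(fit@coefficients["any aggression"], 0)
  expect_error(fitGazeOnscreenModel(rep(1, 100), X[1:100, ]), "constant")
})

test_that("gaze-onscreen null design yields an intercept-only model", {
  set.seed(505)
  n <- 5000
  X <- cbind(a = rbinom(n, 1, 0.3), b = rbinom(n, 1, 0.3))
  yin <- rbinom(n, 1, 0.7)
  fit <- fitGazeOnscreenModel(yin, X,
                              penaltyConfig("binomial",
                                            alphaGrid = simAlphaGrid))
  expect_length(nonzeroCoefficients(fit), 0)
  expect_equal(plogis(fit@intercept), mean(yin), tolerance = 0.02)
})

test_that("gaze-consistency model works end-to-end through the gaze module", {
  set.seed(506)
  cfg <- generatorConfig()
  cfg$ethogram$eventOnsetRate <- 1 / 150   # make 'submit' constituents common
  cfg$gaze$sdLogEffects <- c("submit" = -1.5)  # tighter gaze during submit
  ae <- deriveAnalysisEthogram(generateEthogramTimeline(2400, config = cfg))
  gz <- generateGazeTraces(ae, nViews = 10, config = cfg)
  agg <- aggregateFrameGaze(gz$views)
  vm <- variableMatrix(ae)[agg$frames$frame + 1L, , drop = FALSE]
  keep <- colSums(vm) > 0
  fit <- fitGazeConsistencyModel(agg$frames$consistency,
                                 vm[, keep, drop = FALSE],
                                 penaltyConfig("gaussian",
                                               alphaGrid = simAlphaGrid))
  expect_true("submit" %in% nonzeroCoefficients(fit))
  expect_gt(fit@coefficients["submit"], 0)
  # constant consistency: every coefficient is zero
  fitConst <- fitGazeConsistencyModel(rep(0.5, nrow(vm)),
                                      vm[, keep, drop = FALSE],
                                      penaltyConfig("gaussian",
                                                    alphaGrid = simAlphaGrid))
  expect_length(nonzeroCoefficients(fitConst), 0)
  expect_error(fitGazeConsistencyModel(c(0.2, rep(NA, 10)),
                                       matrix(0, 11, 2)), "2 frames")
})
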