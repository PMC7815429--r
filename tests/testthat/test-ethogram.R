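test_that("annotation intervals fill a dense baseline-padded timeline", {
  tab <- data.frame(
    video_id = "v1",
    observation = "aggression level",
    level = "unidirectional",
    start_frame = 10, end_frame = 40)
  st <- parseAnnotations(tab, nFrames = 60)
  lv <- as.character(levelFrame(st)[["aggression level"]])
  expect_equal(lv[11:40], rep("unidirectional", 30))  # frames 10-39, 0-based
  expect_equal(lv[c(1:10, 41:60)], rep("none", 30))
  expect_equal(nFrames(st), 60L)
  # events outside intervals are zero-filled
  expect_true(all(eventMatrix(st) == 0L))
})

test_that("unknown observations, levels and overlaps are rejected", {
  bad <- data.frame(video_id = "v1", observation = "flying", level = ".",
                    start_frame = 0, end_frame = 10)
  expect_error(parseAnnotations(bad), "flying")
  badLev <- data.frame(video_id = "v1", observation = "count",
                       level = "many", start_frame = 0, end_frame = 10)
  expect_error(parseAnnotations(badLev), "many")
  overlap <- data.frame(video_id = "v1",
                        observation = c("count", "count"),
                        level = c("1", "2"),
                        start_frame = c(0, 15), end_frame = c(20, 30))
  expect_error(parseAnnotations(overlap), "15-19")
})

test_that("annotation round-trip is the identity on the dense timeline", {
  set.seed(101)
  for (rep in 1:3) {
    st <- generateEthogramTimeline(400, videoId = "rt")
    tab <- writeAnnotations(st)
    st2 <- parseAnnotations(tab, nFrames = 400)
    expect_identical(levelFrame(st2), levelFrame(st))
    expect_identical(eventMatrix(st2), eventMatrix(st))
  }
})

test_that("analysis derivation follows the membership rules", {
  st <- ScoringTimeline("v1", 4,
    levels = list("face visibility" = c("eye contact", "none", "small",
                                        "direct"),
                  "count" = c("3-5", "0", "0", "0")),
    events = list(strike = c(0, 0, 0, 1)))
  vm <- variableMatrix(deriveAnalysisEthogram(st))
  # eye contact frame implies the whole face chain
  expect_equal(unname(vm[1, c("visible face", "prominent face",
                              "direct face", "eye contact")]),
               c(1L, 1L, 1L, 1L))
  # count 3-5 sets thresholds 1..3, not 6 or 11
  expect_equal(unname(vm[1, c("count >= 1", "count >= 2", "count >= 3",
                              "count >= 6", "count >= 11")]),
               c(1L, 1L, 1L, 0L, 0L))
  # small face: visible only
  expect_equal(unname(vm[3, c("visible face", "prominent face")]),
               c(1L, 0L))
  # no aggression level and no agonistic events on frame 2
  aggCols <- c("any aggression", "mutual aggression", "joint aggression",
               "intercoalition aggression", "attack", "threaten", "submit")
  expect_true(all(vm[2, aggCols] == 0L))
  # strike event feeds the pooled attack class
  expect_equal(unname(vm[4, "attack"]), 1L)
})

test_that("nesting invariants hold on randomized timelines", {
  set.seed(102)
  chains <- list(
    c("eye contact", "direct face", "prominent face", "visible face"),
    c("count >= 11", "count >= 6", "count >= 3", "count >= 2",
      "count >= 1"),
    c("intercoalition aggression", "joint aggression", "mutual aggression",
      "any aggression"),
    c("prominent genitals", "visible genitals"),
    c("male genitals", "prominent genitals"),
    c("female genitals", "prominent genitals"),
    c("group foraging", "foraging"))
  for (rep in 1:5) {
    ae <- deriveAnalysisEthogram(generateEthogramTimeline(600))
    vm <- variableMatrix(ae)
    for (ch in chains) {
      for (k in seq_len(length(ch) - 1L)) {
        expect_true(all(vm[, ch[k]] <= vm[, ch[k + 1L]]),
                    info = paste(ch[k], "=>", ch[k + 1L]))
      }
    }
  }
})

test_that("derivation is deterministic and idempotent", {
  set.seed(103)
  st <- generateEthogramTimeline(300)
  a <- deriveAnalysisEthogram(st)
  b <- deriveAnalysisEthogram(st)
  expect_identical(variableMatrix(a), variableMatrix(b))
})

test_that("window averaging yields 25 window means matching brute force", {
  set.seed(104)
  ae <- deriveAnalysisEthogram(generateEthogramTimeline(600))
  pres <- data.frame(presentation_id = 1:3, video_id = "synth",
                     start_frame = c(0, 150, 300))
  wr <- windowAverageRegressors(ae, pres)
  expect_equal(nrow(wr), 75L)                       # 25 windows x 3
  expect_equal(sort(unique(wr$window)), 0:24)
  expect_true(all(wr[, -(1:2)] >= 0 & wr[, -(1:2)] <= 1))
  # brute-force oracle: 6 frames per 200 ms window at 30 fps
  vm <- variableMatrix(ae)
  for (p in 1:3) {
    for (w in c(0, 7, 24)) {
      frames <- pres$start_frame[p] + w * 6 + 1:6
      expect_equal(
        unname(as.numeric(wr[wr$presentation_id == p & wr$window == w,
                             colnames(vm)])),
        unname(colMeans(vm[frames, ])), tolerance = 1e-12)
    }
  }
})

test_that("window averaging handles constant and half-on variables", {
  vm <- matrix(0L, 150, 2, dimnames = list(NULL, c("alwaysOn", "halfOn")))
  vm[, "alwaysOn"] <- 1L
  vm[rep(c(TRUE, FALSE), 75), "halfOn"] <- 1L  # alternating frames
  ae <- new("AnalysisEthogram", videoId = "c", fps = 30, variables = vm)
  wr <- windowAverageRegressors(ae, data.frame(presentation_id = 1,
                                               video_id = "c",
                                               start_frame = 0))
  expect_equal(wr$alwaysOn, rep(1, 25))
  expect_equal(wr$halfOn, rep(0.5, 25))
  expect_error(
    windowAverageRegressors(ae, data.frame(presentation_id = 1,
                                           video_id = "c",
                                           start_frame = 0),
                            windowMs = 300),
    "divide")
})

test_that("presentation filter counts distinct presentations only", {
  mk <- function(nPres, onPres) {
    do.call(rbind, lapply(seq_len(nPres), function(p) {
      data.frame(presentation_id = p, window = 0:24,
                 v = as.numeric(p %in% onPres))
    }))
  }
  expect_true("v" %in% applyPresentationFilter(mk(8, 1:5))$included)
  expect_false("v" %in% applyPresentationFilter(mk(8, 1:4))$included)
  # on in all 25 windows of a single presentation: still one presentation
  one <- mk(8, 1)
  f <- applyPresentationFilter(one)
  expect_equal(unname(f$counts["v"]), 1L)
  expect_false("v" %in% f$included)
  # empty input is an empty inclusion set, not an error
  empty <- applyPresentationFilter(mk(8, 1:5)[0, ])
  expect_length(empty$included, 0)
})
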