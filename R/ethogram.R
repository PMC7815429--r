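#' The scoring ethogram: observations, levels and events
#'
#' Catalogue of observations used to score videos frame-by-frame. Leveled
#' observations take exactly one level per frame (the first listed level is
#' the baseline used to fill unannotated frames); event observations are
#' 0/1 per frame. Besides behaviours proper, the catalogue includes
#' descriptors of the scene: camera movement, the number of monkeys visible
#' (in roughly log-spaced levels), and the visibility of faces and of the
#' ano-genital area (AGA), two highly salient sources of social information
#' for macaques.
#'
#' @return list with elements \code{leveled} (named list of level vectors,
#'   baseline first) and \code{events} (character vector of event names).
#' @export
scoringEthogram <- function() {
  list(
    leveled = list(
      "camera movement" = c("holding", "zooming in", "zooming out",
                            "tracking", "panning", "slewing"),
      "count" = c("0", "1", "2", "3-5", "6-10", ">10"),
      "face visibility" = c("none", "small", "away", "direct", "eye contact"),
      "AGA visibility" = c("none", "small", "unsexed", "male", "female",
                           "both"),
      "forage" = c("no", "few", "many"),
      "aggression level" = c("none", "unidirectional", "bidirectional",
                             "joint", "intercoalition")
    ),
    events = c(
      "human visible", "drink",
      "search", "grasp food", "hold food", "hold food in mouth",
      "manipulate food", "ingest food", "ingest grooming manipuland",
      "chew", "retrieve from pouch", "heave",
      "scratch", "autogroom", "allogroom", "solicit allogroom",
      "strike", "grapple", "lunge", "withdraw", "charge", "flee", "chase",
      "threaten", "mounted threaten", "submit", "displace", "lean away",
      "avoid", "branch display"
    )
  )
}

# Membership rules mapping scoring levels/events to binary analysis
# variables. Level rules are cumulative ("count >= 2" is any of the levels
# at or above 2), which makes the nesting chains hold by construction.
analysisDerivationRules <- function() {
  lv <- function(obs, lev) list(kind = "level", obs = obs, levels = lev)
  ev <- function(members) list(kind = "event", members = members)
  list(
    "camera zooming in"  = lv("camera movement", "zooming in"),
    "camera zooming out" = lv("camera movement", "zooming out"),
    "camera tracking"    = lv("camera movement", "tracking"),
    "camera panning"     = lv("camera movement", "panning"),
    "camera slewing"     = lv("camera movement", "slewing"),
    "count >= 1"  = lv("count", c("1", "2", "3-5", "6-10", ">10")),
    "count >= 2"  = lv("count", c("2", "3-5", "6-10", ">10")),
    "count >= 3"  = lv("count", c("3-5", "6-10", ">10")),
    "count >= 6"  = lv("count", c("6-10", ">10")),
    "count >= 11" = lv("count", ">10"),
    "visible face"   = lv("face visibility",
                          c("small", "away", "direct", "eye contact")),
    "prominent face" = lv("face visibility",
                          c("away", "direct", "eye contact")),
    "direct face"    = lv("face visibility", c("direct", "eye contact")),
    "eye contact"    = lv("face visibility", "eye contact"),
    "visible genitals"   = lv("AGA visibility",
                              c("small", "unsexed", "male", "female", "both")),
    "prominent genitals" = lv("AGA visibility",
                              c("unsexed", "male", "female", "both")),
    "male genitals"   = lv("AGA visibility", c("male", "both")),
    "female genitals" = lv("AGA visibility", c("female", "both")),
    "foraging"       = lv("forage", c("few", "many")),
    "group foraging" = lv("forage", "many"),
    "any aggression" = lv("aggression level",
                          c("unidirectional", "bidirectional", "joint",
                            "intercoalition")),
    "mutual aggression" = lv("aggression level",
                             c("bidirectional", "joint", "intercoalition")),
    "joint aggression"  = lv("aggression level",
                             c("joint", "intercoalition")),
    "intercoalition aggression" = lv("aggression level", "intercoalition"),
    "attack"   = ev(c("strike", "grapple", "charge", "lunge", "chase")),
    "threaten" = ev(c("threaten", "mounted threaten", "branch display")),
    "submit"   = ev(c("withdraw", "flee", "chase", "submit", "displace",
                      "lean away", "avoid"))
  )
}

#' Default pass-through event behaviours
#'
#' Event observations copied unchanged into the analysis ethogram alongside
#' the derived variables. By default these are the events NOT absorbed into
#' the pooled agonistic classes (attack / threaten / submit); constituents
#' of a pooled class are represented only through the class, because they
#' were too rare to analyse individually. Pass a different character vector
#' to [deriveAnalysisEthogram()] to change the composition.
#'
#' @return character vector of event names
#' @export
defaultPassthroughEvents <- function() {
  eth <- scoringEthogram()
  rules <- analysisDerivationRules()
  pooled <- unique(unlist(lapply(
    Filter(function(r) r$kind == "event", rules), `[[`, "members"
  )))
  setdiff(eth$events, pooled)
}

#' Construct a ScoringTimeline
#'
#' @param videoId video identifier
#' @param nFrames number of frames
#' @param fps frames per second
#' @param levels optional named list (leveled observation -> per-frame level
#'   character/factor vector); observations omitted are baseline-filled
#' @param events optional named list (event -> 0/1 per-frame vector) or a
#'   0/1 matrix with event column names; events omitted are zero-filled
#' @return a [ScoringTimeline-class]
#' @export
ScoringTimeline <- function(videoId, nFrames, fps = 30,
                            levels = list(), events = list()) {
  eth <- scoringEthogram()
  nFrames <- as.integer(nFrames)
  stopifnot(nFrames >= 0L)
  lvdf <- as.data.frame(lapply(names(eth$leveled), function(obs) {
    levs <- eth$leveled[[obs]]
    col <- if (obs %in% names(levels)) as.character(levels[[obs]])
           else rep(levs[1L], nFrames)
    if (length(col) != nFrames)
      stop("levels for '", obs, "' must have one value per frame")
    factor(col, levels = levs)
  }), optional = TRUE)
  names(lvdf) <- names(eth$leveled)
  if (is.matrix(events)) events <- as.data.frame(events)
  evm <- matrix(0L, nrow = nFrames, ncol = length(eth$events),
                dimnames = list(NULL, eth$events))
  for (evName in names(events)) {
    if (!evName %in% eth$events)
      stop("unknown event observation: '", evName, "'")
    v <- as.integer(events[[evName]])
    if (length(v) != nFrames)
      stop("event '", evName, "' must have one value per frame")
    evm[, evName] <- v
  }
  new("ScoringTimeline", videoId = as.character(videoId), fps = fps,
      levels = lvdf, events = evm)
}

#' Parse an annotation interval table into dense scoring timelines
#'
#' Reads a table of half-open annotation intervals
#' \code{[start_frame, end_frame)} in 0-based frame indices and fills a
#' dense per-frame [ScoringTimeline-class] per video. Leveled observations
#' are baseline-filled outside annotated intervals; events are zero-filled.
#' Overlapping intervals for the same leveled observation are an error.
#'
#' @param annotations path to a TSV file with header
#'   \code{video_id, observation, level, start_frame, end_frame}
#'   (\code{level} is "." for binary events), or an equivalent data.frame.
#' @param nFrames named integer vector giving the frame count per video;
#'   defaults to the largest \code{end_frame} seen for each video.
#' @param fps frames per second (applied to all videos)
#' @return a [ScoringTimeline-class] if the table holds one video, else a
#'   named list of them
#' @export
parseAnnotations <- function(annotations, nFrames = NULL, fps = 30) {
  if (is.character(annotations)) {
    annotations <- utils::read.delim(annotations, sep = "\t",
                                     stringsAsFactors = FALSE,
                                     check.names = FALSE)
  }
  req <- c("video_id", "observation", "level", "start_frame", "end_frame")
  missing <- setdiff(req, names(annotations))
  if (length(missing))
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  eth <- scoringEthogram()
  known <- c(names(eth$leveled), eth$events)
  bad <- setdiff(unique(annotations$observation), known)
  if (length(bad))
    stop("unknown observation(s): ", paste(sQuote(bad), collapse = ", "))
  if (any(annotations$start_frame < 0) ||
      any(annotations$end_frame <= annotations$start_frame))
    stop("intervals must satisfy 0 <= start_frame < end_frame")

  perVideo <- split(annotations, annotations$video_id)
  out <- lapply(names(perVideo), function(vid) {
    tab <- perVideo[[vid]]
    nf <- if (!is.null(nFrames)) {
      if (is.null(names(nFrames)) && length(perVideo) == 1L) nFrames
      else nFrames[[vid]]
    } else max(tab$end_frame)
    nf <- as.integer(nf)
    levelsList <- list()
    eventsList <- list()
    for (obs in unique(tab$observation)) {
      rows <- tab[tab$observation == obs, , drop = FALSE]
      if (obs %in% names(eth$leveled)) {
        levs <- eth$leveled[[obs]]
        badLev <- setdiff(unique(rows$level), levs)
        if (length(badLev))
          stop("observation '", obs, "' has unknown level(s): ",
               paste(sQuote(badLev), collapse = ", "))
        cover <- integer(nf)
        col <- rep(levs[1L], nf)
        rows <- rows[order(rows$start_frame), , drop = FALSE]
        for (r in seq_len(nrow(rows))) {
          idx <- seq.int(rows$start_frame[r] + 1L,
                         min(rows$end_frame[r], nf))
          if (any(cover[idx] > 0L)) {
            ov <- idx[cover[idx] > 0L] - 1L
            stop("overlapping intervals for leveled observation '", obs,
                 "' in video '", vid, "' over frames ", min(ov), "-", max(ov))
          }
          cover[idx] <- 1L
          col[idx] <- rows$level[r]
        }
        levelsList[[obs]] <- col
      } else {
        v <- integer(nf)
        for (r in seq_len(nrow(rows))) {
          idx <- seq.int(rows$start_frame[r] + 1L,
                         min(rows$end_frame[r], nf))
          v[idx] <- 1L
        }
        eventsList[[obs]] <- v
      }
    }
    ScoringTimeline(vid, nf, fps = fps, levels = levelsList,
                    events = eventsList)
  })
  names(out) <- names(perVideo)
  if (length(out) == 1L) out[[1L]] else out
}

#' Write a ScoringTimeline back to an annotation interval table
#'
#' Run-length encodes the dense timeline into half-open intervals
#' (baseline level runs and zero event runs are omitted) in the format
#' accepted by [parseAnnotations()].
#'
#' @param timeline a [ScoringTimeline-class]
#' @param path optional file path; when NULL the table is returned invisibly
#'   without writing
#' @return the interval data.frame, invisibly
#' @export
writeAnnotations <- function(timeline, path = NULL) {
  stopifnot(is(timeline, "ScoringTimeline"))
  eth <- scoringEthogram()
  rows <- list()
  rle1 <- function(v) {
    r <- rle(as.character(v))
    ends <- cumsum(r$lengths)
    data.frame(value = r$values, start = ends - r$lengths, end = ends,
               stringsAsFactors = FALSE)
  }
  for (obs in colnames(timeline@levels)) {
    runs <- rle1(timeline@levels[[obs]])
    runs <- runs[runs$value != eth$leveled[[obs]][1L], , drop = FALSE]
    if (nrow(runs))
      rows[[length(rows) + 1L]] <- data.frame(
        video_id = timeline@videoId, observation = obs, level = runs$value,
        start_frame = runs$start, end_frame = runs$end,
        stringsAsFactors = FALSE)
  }
  for (evName in colnames(timeline@events)) {
    runs <- rle1(timeline@events[, evName])
    runs <- runs[runs$value == "1", , drop = FALSE]
    if (nrow(runs))
      rows[[length(rows) + 1L]] <- data.frame(
        video_id = timeline@videoId, observation = evName, level = ".",
        start_frame = runs$start, end_frame = runs$end,
        stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(video_id = character(), observation = character(),
               level = character(), start_frame = integer(),
               end_frame = integer())
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(tab)
}

#' Derive the binary analysis ethogram from a scoring timeline
#'
#' Applies the fixed membership rules (cumulative level thresholds for
#' counts, faces, genital visibility, foraging and aggression intensity;
#' unions for the pooled attack/threaten/submit classes) and copies the
#' pass-through event behaviours unchanged. Nesting implications (e.g.
#' eye contact => direct face => prominent face => visible face) hold by
#' construction because the level rules are cumulative.
#'
#' @param scoring a [ScoringTimeline-class]
#' @param passthrough event names to copy unchanged; defaults to
#'   [defaultPassthroughEvents()]
#' @return an [AnalysisEthogram-class]
#' @export
deriveAnalysisEthogram <- function(scoring,
                                   passthrough = defaultPassthroughEvents()) {
  stopifnot(is(scoring, "ScoringTimeline"))
  rules <- analysisDerivationRules()
  nf <- nFrames(scoring)
  cols <- lapply(rules, function(rule) {
    if (rule$kind == "level") {
      as.integer(scoring@levels[[rule$obs]] %in% rule$levels)
    } else {
      members <- intersect(rule$members, colnames(scoring@events))
      as.integer(rowSums(scoring@events[, members, drop = FALSE]) > 0)
    }
  })
  vm <- do.call(cbind, cols)
  colnames(vm) <- names(rules)
  if (length(passthrough)) {
    bad <- setdiff(passthrough, scoringEthogram()$events)
    if (length(bad))
      stop("pass-through names not in the scoring ethogram: ",
           paste(sQuote(bad), collapse = ", "))
    pt <- scoring@events[, passthrough, drop = FALSE]
    clash <- intersect(colnames(pt), colnames(vm))
    if (length(clash))
      stop("pass-through event(s) collide with derived variable names: ",
           paste(sQuote(clash), collapse = ", "))
    vm <- cbind(vm, pt)
  }
  if (nf == 0L) vm <- matrix(integer(), 0L, ncol(vm),
                             dimnames = list(NULL, colnames(vm)))
  new("AnalysisEthogram", videoId = scoring@videoId, fps = scoring@fps,
      variables = vm)
}

# Window means for one presentation: frames are attributed to the window
# containing their draw-time midpoint; the window grid may be shifted
# earlier by lagMs to model a fixed neural latency.
windowMeansForPresentation <- function(frameValues, startFrame, fps,
                                       windowMs = 200, fvDurationS = 5,
                                       lagMs = 0) {
  nWindows <- as.integer(round(fvDurationS * 1000 / windowMs))
  framesPerFv <- as.integer(round(fvDurationS * fps))
  nfVideo <- nrow(frameValues)
  out <- matrix(NA_real_, nWindows, ncol(frameValues),
                dimnames = list(NULL, colnames(frameValues)))
  for (w in seq_len(nWindows)) {
    t0 <- (w - 1L) * windowMs - lagMs
    t1 <- w * windowMs - lagMs
    # frame f (0-based, relative to onset) has draw-time midpoint
    # (f + 0.5) / fps * 1000 ms
    fLo <- ceiling(t0 * fps / 1000 - 0.5)
    fHi <- ceiling(t1 * fps / 1000 - 0.5) - 1L
    fRel <- seq.int(max(fLo, 0L), min(fHi, framesPerFv - 1L))
    fAbs <- startFrame + fRel + 1L      # 1-based row index into the video
    fAbs <- fAbs[fAbs >= 1L & fAbs <= nfVideo]
    if (length(fAbs))
      out[w, ] <- colMeans(frameValues[fAbs, , drop = FALSE])
  }
  out
}

#' Average analysis-ethogram variables over presentation windows
#'
#' Divides each 5 s free-viewing presentation into windows of
#' \code{windowMs} and averages each binary variable over the frames whose
#' draw-time midpoints fall in each window, yielding values in [0, 1]
#' (25 windows per presentation at the 200 ms default).
#'
#' @param ethograms an [AnalysisEthogram-class] or named list of them
#'   (names = video ids)
#' @param presentations data.frame with columns \code{presentation_id},
#'   \code{video_id}, \code{start_frame} (0-based first frame of the
#'   presented segment)
#' @param windowMs window duration, must divide the presentation evenly
#' @param fvDurationS presentation duration in seconds
#' @param lagMs shift the window grid this many ms earlier (visual response
#'   latency); windows with no covered frames after clipping at the video
#'   start carry the mean of the available overlap
#' @return data.frame: \code{presentation_id}, \code{window} (0-based),
#'   then one column per variable
#' @export
windowAverageRegressors <- function(ethograms, presentations,
                                    windowMs = 200, fvDurationS = 5,
                                    lagMs = 0) {
  if (is(ethograms, "AnalysisEthogram")) {
    ethograms <- stats::setNames(list(ethograms), videoId(ethograms))
  }
  stopifnot(all(c("presentation_id", "video_id", "start_frame") %in%
                names(presentations)))
  if ((fvDurationS * 1000) %% windowMs != 0)
    stop("window duration must divide the presentation evenly")
  if (fvDurationS * 1000 < windowMs)
    stop("presentation shorter than one window")
  nWindows <- as.integer(fvDurationS * 1000 / windowMs)
  blocks <- lapply(seq_len(nrow(presentations)), function(i) {
    vid <- as.character(presentations$video_id[i])
    eg <- ethograms[[vid]]
    if (is.null(eg))
      stop("no analysis ethogram supplied for video '", vid, "'")
    wm <- windowMeansForPresentation(variableMatrix(eg),
                                     presentations$start_frame[i],
                                     framesPerSecond(eg),
                                     windowMs, fvDurationS, lagMs)
    # first windows clipped away entirely by the lag inherit the earliest
    # available window's value
    if (anyNA(wm[, 1L])) {
      firstOk <- which(!is.na(wm[, 1L]))[1L]
      if (is.na(firstOk)) stop("presentation '",
                               presentations$presentation_id[i],
                               "' covers no frames")
      for (w in seq_len(firstOk - 1L)) wm[w, ] <- wm[firstOk, ]
    }
    cbind(data.frame(presentation_id = presentations$presentation_id[i],
                     window = seq_len(nWindows) - 1L),
          as.data.frame(wm))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Filter variables by distinct-presentation support
#'
#' A variable's regressor is included only if the variable is non-zero in
#' at least \code{minPresentations} distinct presentations; rarer variables
#' cannot be distinguished from one-off co-occurring events.
#'
#' @param windowed output of [windowAverageRegressors()] (or any data.frame
#'   with \code{presentation_id} plus variable columns)
#' @param minPresentations inclusion threshold (default 5)
#' @return list with \code{included} (character vector) and \code{counts}
#'   (named integer: distinct presentations in which each variable occurs)
#' @export
applyPresentationFilter <- function(windowed, minPresentations = 5) {
  varCols <- setdiff(names(windowed), c("presentation_id", "window"))
  if (!nrow(windowed) || !length(varCols))
    return(list(included = character(),
                counts = stats::setNames(integer(length(varCols)), varCols)))
  pres <- windowed$presentation_id
  counts <- vapply(varCols, function(v) {
    length(unique(pres[windowed[[v]] > 0]))
  }, integer(1))
  list(included = varCols[counts >= minPresentations], counts = counts)
}
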