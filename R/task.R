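#' Menu configuration for the channel-surfing task
#'
#' A menu is the set of one or two option targets offered on a trial, drawn
#' from Blank (static grey screen), Switch (a new random clip), Continue
#' (the next 5 s of the previous clip) and Repeat (the previous clip
#' again). Every unordered pair and every singleton (forced choice) is a
#' candidate menu with a target weight b_k: the singletons share
#' \code{forcedMass} of the total and the pairs share the remainder
#' uniformly.
#'
#' @param options option types in play; some sessions drop "Repeat"
#' @param forcedMass total target weight of single-option menus (default
#'   0.10)
#' @param reweightRate the adaptive reweighting rate constant (default 0.2)
#' @return list of class "MenuConfig" with \code{menus} (list of character
#'   vectors), \code{b} (target weights, summing to 1), \code{rate}
#' @export
menuConfig <- function(options = c("Blank", "Switch", "Continue", "Repeat"),
                       forcedMass = 0.10, reweightRate = 0.2) {
  allOptions <- c("Blank", "Switch", "Continue", "Repeat")
  stopifnot(all(options %in% allOptions), length(options) >= 2,
            forcedMass > 0, forcedMass < 1, reweightRate > 0)
  pairs <- utils::combn(options, 2, simplify = FALSE)
  singles <- as.list(options)
  menus <- c(pairs, singles)
  names(menus) <- vapply(menus, paste, character(1), collapse = "+")
  b <- c(rep((1 - forcedMass) / length(pairs), length(pairs)),
         rep(forcedMass / length(singles), length(singles)))
  names(b) <- names(menus)
  structure(list(menus = menus, b = b, rate = reweightRate,
                 options = options),
            class = "MenuConfig")
}

#' Fresh adaptive-weighting state
#'
#' Tracks how many times each candidate menu has been presented (n_k) out
#' of the trials so far (N).
#'
#' @param config a [menuConfig()]
#' @return list of class "AdaptiveState" with \code{n} (named counts) and
#'   \code{N}
#' @export
adaptiveState <- function(config) {
  structure(list(n = stats::setNames(integer(length(config$menus)),
                                     names(config$menus)),
                 N = 0L),
            class = "AdaptiveState")
}

#' Per-trial adaptive menu weight
#'
#' \deqn{a_k = b_k \, 2^{(1 - n_k/(N b_k))/r}}
#' where r is the reweighting rate. A menu presented exactly at its target
#' rate (n_k = N b_k) keeps its target weight; under-presented menus are
#' up-weighted and over-presented menus down-weighted, which keeps
#' Continue/Repeat menus near their target frequencies even though validity
#' rules periodically block them. Before any trial (N = 0) the target
#' weight is returned unchanged.
#'
#' @param b target weight(s), > 0
#' @param n presentation count(s) for the menu(s)
#' @param N total trials so far
#' @param rate the reweighting rate (default 0.2)
#' @return adaptive weight(s) a_k
#' @export
adaptiveWeight <- function(b, n, N, rate = 0.2) {
  if (any(b <= 0)) stop("target weights must be positive")
  stopifnot(N >= 0, rate > 0)
  if (N == 0) return(b)
  b * 2^((1 - n / (N * b)) / rate)
}

# Menus valid given the previous trial. Continue/Repeat are invalid with no
# previous video (session start or previous Blank); Continue additionally
# requires >= 5 s remaining in the source file.
validMenus <- function(config, lastTrial, library, fvDurationS = 5) {
  noPrev <- is.null(lastTrial) || lastTrial$chosen == "Blank" ||
    is.na(lastTrial$video_id)
  canContinue <- FALSE
  if (!noPrev) {
    dur <- library$duration_s[match(lastTrial$video_id, library$video_id)]
    canContinue <- (dur - lastTrial$seg_end_s) >= fvDurationS
  }
  vapply(config$menus, function(m) {
    if (noPrev && any(c("Continue", "Repeat") %in% m)) return(FALSE)
    if (!canContinue && "Continue" %in% m) return(FALSE)
    TRUE
  }, logical(1))
}

#' Sample the next trial's menu with adaptive weighting
#'
#' Draws a menu with probability proportional to its adaptive weight a_k
#' among the menus valid after the previous trial, and updates the
#' presentation counts. Uses the session RNG (seed with [set.seed()]).
#'
#' @param state an [adaptiveState()]
#' @param config a [menuConfig()]
#' @param lastTrial previous trial record (one-row list/data.frame with
#'   \code{chosen}, \code{video_id}, \code{seg_end_s}) or NULL at session
#'   start
#' @param library video catalogue data.frame (\code{video_id},
#'   \code{duration_s})
#' @param fvDurationS free-viewing duration (default 5)
#' @return list with \code{menu} (character vector of 1-2 options) and the
#'   updated \code{state}
#' @export
sampleMenu <- function(state, config, lastTrial, library, fvDurationS = 5) {
  valid <- validMenus(config, lastTrial, library, fvDurationS)
  if (!any(valid)) stop("no valid menu under this configuration")
  a <- adaptiveWeight(config$b, state$n, state$N, config$rate)
  a[!valid] <- 0
  k <- sample.int(length(a), 1L, prob = a)
  state$n[k] <- state$n[k] + 1L
  state$N <- state$N + 1L
  list(menu = config$menus[[k]], menuName = names(config$menus)[k],
       state = state)
}

#' Resolve the outcome of a chosen option
#'
#' Switch draws a file with probability proportional to its duration and a
#' uniform start time leaving at least one full presentation; Continue
#' plays the next 5 s of the previous clip; Repeat replays the previous
#' segment; Blank is a static grey screen.
#'
#' @param chosen "Blank", "Switch", "Continue" or "Repeat"
#' @param lastTrial previous trial record or NULL
#' @param library video catalogue data.frame (\code{video_id},
#'   \code{duration_s}), durations >= \code{fvDurationS}
#' @param fvDurationS presentation duration (default 5)
#' @return list: \code{video_id} (NA for Blank), \code{seg_start_s},
#'   \code{seg_end_s}
#' @export
resolveOutcome <- function(chosen, lastTrial, library, fvDurationS = 5) {
  if (chosen == "Blank")
    return(list(video_id = NA_character_, seg_start_s = NA_real_,
                seg_end_s = NA_real_))
  if (chosen == "Switch") {
    stopifnot(nrow(library) > 0, all(library$duration_s >= fvDurationS))
    i <- sample.int(nrow(library), 1L, prob = library$duration_s)
    start <- stats::runif(1, 0, library$duration_s[i] - fvDurationS)
    return(list(video_id = as.character(library$video_id[i]),
                seg_start_s = start, seg_end_s = start + fvDurationS))
  }
  if (is.null(lastTrial) || is.na(lastTrial$video_id))
    stop("'", chosen, "' requires a previous video trial")
  if (chosen == "Repeat")
    return(list(video_id = lastTrial$video_id,
                seg_start_s = lastTrial$seg_start_s,
                seg_end_s = lastTrial$seg_end_s))
  if (chosen == "Continue") {
    dur <- library$duration_s[match(lastTrial$video_id, library$video_id)]
    if (dur - lastTrial$seg_end_s < fvDurationS)
      stop("'Continue' requested with less than one presentation remaining")
    return(list(video_id = lastTrial$video_id,
                seg_start_s = lastTrial$seg_end_s,
                seg_end_s = lastTrial$seg_end_s + fvDurationS))
  }
  stop("unknown option: '", chosen, "'")
}

#' Choice policy: uniform random valid choice
#'
#' @return a policy function(menu, context) -> chosen option
#' @export
randomChoicePolicy <- function() {
  function(menu, context = NULL) {
    if (length(menu) == 1L) menu else menu[sample.int(length(menu), 1L)]
  }
}

#' Choice policy driven by ranked-option utilities
#'
#' Implements the ranked two-alternative choice rule: options are ranked
#' Blank < Repeat < Continue < Switch, and the probability of taking the
#' higher-ranked of the two offered options is
#' \code{plogis(sum_i v_i m_i + sum_ik beta_ik m_i x_k)} with m_i = +1 for
#' the higher-ranked offered option, -1 for the lower-ranked, 0 otherwise
#' (Blank is the baseline and carries no term). The context's \code{x} is
#' the binary occurrence vector of ethogram variables in the previous
#' trial's video (all zero after a Blank).
#'
#' @param v named utilities for "Repeat", "Continue", "Switch" (relative to
#'   Blank = 0)
#' @param beta optional interaction matrix (3 x K, rownames Repeat /
#'   Continue / Switch, colnames = ethogram variables) or NULL
#' @return a policy function(menu, context) -> chosen option
#' @export
utilityChoicePolicy <- function(v, beta = NULL) {
  stopifnot(all(c("Repeat", "Continue", "Switch") %in% names(v)))
  rank <- c(Blank = 0, Repeat = 1, Continue = 2, Switch = 3)
  function(menu, context = NULL) {
    if (length(menu) == 1L) return(menu)
    hi <- menu[which.max(rank[menu])]
    lo <- menu[which.min(rank[menu])]
    eta <- 0
    for (opt in c(hi, lo)) {
      if (opt == "Blank") next
      m <- if (opt == hi) 1 else -1
      eta <- eta + m * v[[opt]]
      if (!is.null(beta) && !is.null(context$x)) {
        x <- context$x[colnames(beta)]
        eta <- eta + m * sum(beta[opt, ] * x)
      }
    }
    if (stats::runif(1) < stats::plogis(eta)) hi else lo
  }
}

#' Simulate a channel-surfing session
#'
#' Runs the trial loop: adaptive menu sampling under the validity rules,
#' a choice from the supplied policy, outcome resolution against the video
#' library, and the randomized task delays. Deterministic given the RNG
#' state (seed with [set.seed()]).
#'
#' @param nTrials number of trials
#' @param config a [menuConfig()]
#' @param library video catalogue data.frame (\code{video_id},
#'   \code{duration_s})
#' @param policy a choice policy, e.g. [randomChoicePolicy()] or
#'   [utilityChoicePolicy()]
#' @param contextFn optional function(trialIndex, lastTrial) returning the
#'   policy context (e.g. the previous video's ethogram occurrence vector)
#' @param fvDurationS presentation duration (default 5)
#' @return data.frame with one row per trial: \code{trial}, \code{menu_a},
#'   \code{menu_b} (NA on forced trials), \code{forced}, \code{chosen},
#'   \code{video_id}, \code{seg_start_s}, \code{seg_end_s},
#'   \code{delay_choice_video_ms}, \code{delay_video_reward_ms}
#' @export
simulateSession <- function(nTrials, config = menuConfig(),
                            library, policy = randomChoicePolicy(),
                            contextFn = NULL, fvDurationS = 5) {
  state <- adaptiveState(config)
  last <- NULL
  menuA <- character(nTrials); menuB <- rep(NA_character_, nTrials)
  chosenV <- character(nTrials); vidV <- rep(NA_character_, nTrials)
  segS <- rep(NA_real_, nTrials); segE <- rep(NA_real_, nTrials)
  for (i in seq_len(nTrials)) {
    drawn <- sampleMenu(state, config, last, library, fvDurationS)
    state <- drawn$state
    menu <- drawn$menu
    context <- if (!is.null(contextFn)) contextFn(i, last) else NULL
    chosen <- policy(menu, context)
    if (!chosen %in% menu) stop("policy chose an option not on the menu")
    outcome <- resolveOutcome(chosen, last, library, fvDurationS)
    menuA[i] <- menu[1L]
    if (length(menu) == 2L) menuB[i] <- menu[2L]
    chosenV[i] <- chosen
    vidV[i] <- outcome$video_id
    segS[i] <- outcome$seg_start_s
    segE[i] <- outcome$seg_end_s
    last <- list(chosen = chosen, video_id = outcome$video_id,
                 seg_start_s = outcome$seg_start_s,
                 seg_end_s = outcome$seg_end_s)
  }
  data.frame(
    trial = seq_len(nTrials), menu_a = menuA, menu_b = menuB,
    forced = is.na(menuB), chosen = chosenV, video_id = vidV,
    seg_start_s = segS, seg_end_s = segE,
    delay_choice_video_ms = stats::runif(nTrials, 100, 600),
    delay_video_reward_ms = stats::runif(nTrials, 50, 500),
    stringsAsFactors = FALSE)
}
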