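## paradigm definition and frame-accurate stimulus schedule

#' Construct a paradigm configuration
#'
#' Defaults reproduce the dual-flicker motion-detection design: a 60 Hz
#' display, a random-dot target flickering with a 14-frame cycle (6 frames =
#' 100 ms on, 8 frames = 133.33 ms off, i.e. 60/14 = 4.2857 Hz, labeled
#' "4.29 Hz"), an affective-picture distractor with a 10-frame cycle (6 on,
#' 4 off, 6 Hz), 11.667 s trials holding exactly 50 target and 70 distractor
#' cycles, and 28 trials per emotion category. Coherent-motion events span
#' `motionCycles` target cycles (4 x 14/60 s = 933 ms) and are confined to
#' `motionWindow`.
#'
#' @param refreshRate display refresh rate, Hz.
#' @param targetOnFrames,targetOffFrames target flicker cycle frames.
#' @param distractorOnFrames,distractorOffFrames distractor flicker cycle frames.
#' @param trialDuration trial length, s.
#' @param nTrialsPerCategory trials per category.
#' @param categories emotion labels in fixed order.
#' @param motionWindow interval (s) containing coherent-motion events.
#' @param motionCycles motion-event duration in target cycles.
#' @return A validated [ParadigmConfig-class].
#' @examples
#' cfg <- paradigmConfig()
#' tagFrequency(cfg, "target")      # 60/14 = 4.2857 Hz
#' tagFrequency(cfg, "distractor")  # 6 Hz
#' @export
paradigmConfig <- function(refreshRate = 60,
                           targetOnFrames = 6L, targetOffFrames = 8L,
                           distractorOnFrames = 6L, distractorOffFrames = 4L,
                           trialDuration = 11.667,
                           nTrialsPerCategory = 28L,
                           categories = c("pleasant", "neutral", "unpleasant"),
                           motionWindow = c(2.3, 10.4),
                           motionCycles = 4L) {
  new("ParadigmConfig",
      refreshRate = refreshRate,
      targetOnFrames = as.integer(targetOnFrames),
      targetOffFrames = as.integer(targetOffFrames),
      distractorOnFrames = as.integer(distractorOnFrames),
      distractorOffFrames = as.integer(distractorOffFrames),
      trialDuration = trialDuration,
      nTrialsPerCategory = as.integer(nTrialsPerCategory),
      categories = categories,
      motionWindow = motionWindow,
      motionCycles = as.integer(motionCycles))
}

#' Flicker period of a stimulus stream
#'
#' @param config a [ParadigmConfig-class].
#' @param stream `"target"` or `"distractor"`.
#' @return Period in seconds (an exact frame-count ratio of the refresh rate).
#' @export
periodSeconds <- function(config, stream = c("target", "distractor")) {
  stream <- match.arg(stream)
  frames <- if (stream == "target")
    config@targetOnFrames + config@targetOffFrames
  else
    config@distractorOnFrames + config@distractorOffFrames
  frames / config@refreshRate
}

#' Tag frequency of a stimulus stream
#'
#' Tag frequencies are exact refresh-rate ratios (60/14 and 60/10 Hz for the
#' defaults); decimal labels such as "4.29 Hz" are display rounding.
#'
#' @inheritParams periodSeconds
#' @return Flicker frequency in Hz.
#' @export
tagFrequency <- function(config, stream = c("target", "distractor")) {
  1 / periodSeconds(config, stream)
}

#' Build the stimulus schedule for one trial
#'
#' Lays out the on/off cycle onsets of both flicker streams over one trial
#' and places 0, 1 or 2 non-overlapping coherent-motion events, each lasting
#' `motionCycles` target cycles and aligned to target cycle onsets inside
#' `motionWindow`.
#'
#' @param config a [ParadigmConfig-class].
#' @param nMotionEvents 0, 1 or 2 coherent-motion events.
#' @param seed optional RNG seed for event placement.
#' @return A [StimulusSchedule-class].
#' @examples
#' sched <- makeSchedule(paradigmConfig(), nMotionEvents = 1, seed = 1)
#' sched@nTargetCycles      # 50
#' sched@nDistractorCycles  # 70
#' @export
makeSchedule <- function(config, nMotionEvents = 1L, seed = NULL) {
  validObject(config)
  stopifnot(nMotionEvents %in% 0:2)
  perT <- periodSeconds(config, "target")
  perD <- periodSeconds(config, "distractor")
  nT <- as.integer(round(config@trialDuration / perT))
  nD <- as.integer(round(config@trialDuration / perD))
  tol <- 1 / config@refreshRate
  if (abs(config@trialDuration - nT * perT) > tol ||
      abs(config@trialDuration - nD * perD) > tol)
    stop(sprintf(
      "trialDuration %.4f s is not a common multiple of both flicker periods (implies %.3f target and %.3f distractor cycles)",
      config@trialDuration, config@trialDuration / perT, config@trialDuration / perD))
  onT <- (seq_len(nT) - 1L) * perT
  onD <- (seq_len(nD) - 1L) * perD
  dur <- config@motionCycles * perT
  events <- data.frame(onset = numeric(0), duration = numeric(0))
  if (nMotionEvents > 0) {
    mw <- config@motionWindow
    eligible <- onT[onT >= mw[1] & onT + dur <= mw[2]]
    if (length(eligible) < nMotionEvents * config@motionCycles)
      stop("motionWindow too short for the requested motion events")
    pick <- withSeed(seed, {
      chosen <- numeric(0)
      pool <- eligible
      for (k in seq_len(nMotionEvents)) {
        if (!length(pool)) stop("cannot place non-overlapping motion events")
        o <- sample(pool, 1L)
        chosen <- c(chosen, o)
        pool <- pool[pool >= o + dur | pool + dur <= o]
      }
      sort(chosen)
    })
    events <- data.frame(onset = pick, duration = rep(dur, length(pick)))
  }
  new("StimulusSchedule",
      targetCycleOnsets = onT, distractorCycleOnsets = onD,
      nTargetCycles = nT, nDistractorCycles = nD,
      motionEvents = events, config = config)
}
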