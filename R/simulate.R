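## synthetic EEG cohorts with known ground truth

#' Standard 31-channel 10-20 montage labels
#' @return Character vector of 31 channel names.
#' @export
standardChannels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6",
    "P7", "P3", "Pz", "P4", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "Oz")
}

## Occipitally weighted gain templates. Values rise monotonically from
## frontal to occipital rows, mimicking the posterior concentration of
## visual SSVEP topographies; the target peaks at Oz, the distractor at POz
## so the two components are spatially distinct but overlapping.
.rowGain <- function(weights) {
  rows <- c(Fp1 = "Fp", Fp2 = "Fp", F7 = "F", F3 = "F", Fz = "F", F4 = "F",
            F8 = "F", FC5 = "FC", FC1 = "FC", FC2 = "FC", FC6 = "FC",
            T7 = "C", C3 = "C", Cz = "C", C4 = "C", T8 = "C",
            CP5 = "CP", CP1 = "CP", CP2 = "CP", CP6 = "CP",
            P7 = "P", P3 = "P", Pz = "P", P4 = "P", P8 = "P",
            PO7 = "PO", PO3 = "PO", POz = "PO", PO4 = "PO", PO8 = "PO",
            Oz = "O")
  unname(weights[rows])
}

#' Occipitally weighted topography templates
#'
#' @param component `"target"` (peak at Oz) or `"distractor"` (peak at POz).
#' @return Named numeric gain vector over [standardChannels()].
#' @export
defaultTopography <- function(component = c("target", "distractor")) {
  component <- match.arg(component)
  g <- if (component == "target")
    .rowGain(c(Fp = 0.05, F = 0.10, FC = 0.15, C = 0.20, CP = 0.35,
               P = 0.55, PO = 0.85, O = 1.00))
  else
    .rowGain(c(Fp = 0.06, F = 0.12, FC = 0.18, C = 0.25, CP = 0.40,
               P = 0.60, PO = 0.95, O = 0.90))
  if (component == "distractor") g[standardChannels() == "POz"] <- 1.00
  names(g) <- standardChannels()
  g
}

#' Construct a synthetic-EEG generator configuration
#'
#' Defaults define the reference simulation conditions: 500 Hz sampling, 31
#' channels, a 1 Hz sampling rhythm with modulation depth 0.5, target
#' carrier amplitude 1.5 x the distractor's, SNR 1 (tagged-signal RMS equals
#' noise RMS at the best channel), 1/f noise, and a behavioral model whose
#' accuracy rises linearly with the injected relative phase
#' (base 0.35, gain 0.45, noise sd 0.15, clipped to [0, 1]).
#'
#' @param fs sampling rate, Hz.
#' @param channels channel labels.
#' @param fSamp injected sampling-rhythm frequency, Hz.
#' @param modDepth modulation depth m in [0, 1].
#' @param relPhase injected target-distractor envelope phase offset, rad in [0, pi].
#' @param targetAmp,distractorAmp carrier amplitudes, uV.
#' @param targetTopography,distractorTopography per-channel gains.
#' @param patternSeparability scale of category-specific pattern perturbations.
#' @param snr tagged-signal/noise RMS ratio at the best channel (Inf = noiseless).
#' @param noiseExponent 1/f^alpha slope.
#' @param flickerMode `"sine"` or `"square"`.
#' @param behaviorBase,behaviorGain,behaviorNoiseSd behavioral accuracy model.
#' @param seed integer seed; generation is a pure function of it.
#' @return A validated [SynthConfig-class].
#' @export
synthConfig <- function(fs = 500,
                        channels = standardChannels(),
                        fSamp = 1.0,
                        modDepth = 0.5,
                        relPhase = pi / 2,
                        targetAmp = 1.5,
                        distractorAmp = 1.0,
                        targetTopography = defaultTopography("target"),
                        distractorTopography = defaultTopography("distractor"),
                        patternSeparability = 0.02,
                        snr = 1,
                        noiseExponent = 1,
                        flickerMode = c("sine", "square"),
                        behaviorBase = 0.35,
                        behaviorGain = 0.45,
                        behaviorNoiseSd = 0.15,
                        seed = 1L) {
  new("SynthConfig",
      fs = fs, channels = channels, fSamp = fSamp, modDepth = modDepth,
      relPhase = relPhase, targetAmp = targetAmp, distractorAmp = distractorAmp,
      targetTopography = unname(targetTopography),
      distractorTopography = unname(distractorTopography),
      patternSeparability = patternSeparability, snr = snr,
      noiseExponent = noiseExponent, flickerMode = match.arg(flickerMode),
      behaviorBase = behaviorBase, behaviorGain = behaviorGain,
      behaviorNoiseSd = behaviorNoiseSd, seed = as.integer(seed))
}

## Periodic flicker response at frequency f over time axis t: unit sinusoid
## at the tag fundamental, or a zero-mean on/off square wave (duty cycle from
## the frame counts) that adds harmonics.
.flickerResponse <- function(t, f, mode, duty = 0.5) {
  if (mode == "sine") return(sin(2 * pi * f * t))
  phase <- (t * f) %% 1
  ifelse(phase < duty, 1, 0) - duty
}

#' Simulate one subject's epoch-format EEG
#'
#' Forward model, per trial of category c, channel ch and time t:
#' \deqn{x(ch,t) = w_T(ch) A_T [1 + m cos(2\pi f_s t + \phi)] p_T(t) +
#'   [w_D(ch) + \delta_c(ch)] A_D [1 + m cos(2\pi f_s t + \phi + \Delta\phi)]
#'   p_D(t) + noise}
#' where \eqn{p_T, p_D} are the flicker responses at the two tag frequencies,
#' \eqn{\phi} is one uniformly drawn envelope phase per subject,
#' \eqn{\Delta\phi} the injected relative phase, \eqn{\delta_c} fixed
#' unit-norm random category patterns scaled by `patternSeparability`, and
#' the noise is per-channel 1/f^alpha with RMS set so that the tagged
#' deterministic signal at its best channel has RMS `snr` times the noise
#' RMS. Behavioral accuracy is drawn per category as
#' clip(base + gain * relPhase/pi + N(0, sd), 0, 1).
#'
#' @param paradigm a [ParadigmConfig-class].
#' @param synth a [SynthConfig-class].
#' @param subjectId identifier stored in the dataset.
#' @return An [EEGDataset-class]; the injected parameters are retrievable
#'   with [groundTruth()].
#' @examples
#' ds <- simulateSubject(paradigmConfig(), synthConfig(seed = 7))
#' table(trialLabels(ds))
#' @export
simulateSubject <- function(paradigm, synth, subjectId = "synthetic") {
  validObject(paradigm); validObject(synth)
  fT <- tagFrequency(paradigm, "target")
  fD <- tagFrequency(paradigm, "distractor")
  if (synth@fs <= 2 * max(fT, fD)) stop("fs must exceed twice the tag frequencies")
  nS <- floor(paradigm@trialDuration * synth@fs)
  t <- (seq_len(nS) - 1) / synth@fs
  nC <- length(synth@channels)
  cats <- paradigm@categories
  nPer <- paradigm@nTrialsPerCategory
  nTr <- nPer * length(cats)

  withSeed(synth@seed, {
    phi <- stats::runif(1, 0, 2 * pi)
    delta <- sapply(cats, function(cc) {
      v <- stats::rnorm(nC)
      v / sqrt(sum(v^2)) * synth@patternSeparability
    })
    dutyT <- paradigm@targetOnFrames /
      (paradigm@targetOnFrames + paradigm@targetOffFrames)
    dutyD <- paradigm@distractorOnFrames /
      (paradigm@distractorOnFrames + paradigm@distractorOffFrames)
    pT <- .flickerResponse(t, fT, synth@flickerMode, dutyT)
    pD <- .flickerResponse(t, fD, synth@flickerMode, dutyD)
    envT <- synth@targetAmp * (1 + synth@modDepth * cos(2 * pi * synth@fSamp * t + phi)) * pT
    envD <- synth@distractorAmp *
      (1 + synth@modDepth * cos(2 * pi * synth@fSamp * t + phi + synth@relPhase)) * pD

    ## deterministic part per category: channels x samples
    detSig <- lapply(cats, function(cc) {
      outer(synth@targetTopography, envT) +
        outer(synth@distractorTopography + delta[, cc], envD)
    })
    names(detSig) <- cats

    ## noise RMS from SNR at the best (largest-RMS) channel
    bestRMS <- max(sqrt(rowMeans(detSig[[1]]^2)))
    sigmaN <- if (is.finite(synth@snr)) bestRMS / synth@snr else 0

    labels <- factor(rep(cats, each = nPer), levels = cats)
    ord <- sample.int(nTr)           # shuffle trial order
    labels <- labels[ord]
    data <- array(0, dim = c(nTr, nC, nS))
    for (i in seq_len(nTr)) {
      x <- detSig[[as.character(labels[i])]]
      if (sigmaN > 0)
        x <- x + t(pinkNoise(nS, synth@fs, synth@noiseExponent, nC)) * sigmaN
      data[i, , ] <- x
    }

    ## subject-level accuracy is linear in relPhase/pi with subject noise;
    ## per-category accuracies add only a small jitter (the design predicts
    ## no category effect on behavior)
    behOverall <- min(max(synth@behaviorBase +
                            synth@behaviorGain * synth@relPhase / pi +
                            stats::rnorm(1, 0, synth@behaviorNoiseSd), 0), 1)
    behPer <- pmin(pmax(behOverall +
                          stats::rnorm(length(cats), 0, 0.03), 0), 1)
    names(behPer) <- cats

    truth <- list(
      fSamp = synth@fSamp, relPhase = synth@relPhase, envelopePhase = phi,
      modDepth = synth@modDepth, snr = synth@snr,
      categoryPatterns = delta,
      targetTopography = synth@targetTopography,
      distractorTopography = synth@distractorTopography,
      behavior = list(overall = behOverall, perCategory = behPer),
      seed = synth@seed)

    new("EEGDataset", data = data, labels = labels, fs = synth@fs,
        channels = synth@channels,
        behavior = list(overall = behOverall, perCategory = behPer),
        groundTruth = truth, subjectId = subjectId)
  })
}

## Per-subject relative-phase and seed draws for a cohort: one block of RNG
## consumption so that cohort composition is a pure function of the master
## seed regardless of whether subjects are materialized together
## (simulateCohort) or streamed one at a time (runPipeline, which avoids
## holding an entire cohort of epoch arrays in memory).
cohortDraws <- function(nSubjects, phaseSampler, seed) {
  draws <- withSeed(seed, {
    ph <- phaseSampler(nSubjects)
    list(ph = ph, seeds = sample.int(.Machine$integer.max - 1L, nSubjects))
  })
  if (any(draws$ph < 0 | draws$ph > pi))
    stop("phaseSampler must return values in [0, pi]")
  draws
}

subjectConfig <- function(template, draws, i) {
  template@relPhase <- draws$ph[i]
  template@seed <- draws$seeds[i]
  template
}

#' Simulate a cohort of subjects
#'
#' Draws one relative phase per subject from `phaseSampler` (default uniform
#' on [0, pi], mirroring an unconstrained cohort), simulates each subject
#' with an independent derived seed, and records every draw in a ground-truth
#' table.
#'
#' @param nSubjects cohort size (>= 2; the reference study has 27).
#' @param paradigm a [ParadigmConfig-class].
#' @param synthTemplate a [SynthConfig-class]; its `relPhase` and `seed` are
#'   overridden per subject.
#' @param phaseSampler function(n) returning n draws in [0, pi].
#' @param seed master seed for the phase draws and subject seeds.
#' @return List with `subjects` (list of [EEGDataset-class]) and `truth`
#'   (data.frame: subject, relPhase, fSamp, behavior, seed).
#' @export
simulateCohort <- function(nSubjects, paradigm = paradigmConfig(),
                           synthTemplate = synthConfig(),
                           phaseSampler = function(n) stats::runif(n, 0, pi),
                           seed = 1L) {
  stopifnot(nSubjects >= 2)
  draws <- cohortDraws(nSubjects, phaseSampler, seed)
  subjects <- vector("list", nSubjects)
  for (i in seq_len(nSubjects))
    subjects[[i]] <- simulateSubject(paradigm,
                                     subjectConfig(synthTemplate, draws, i),
                                     subjectId = sprintf("S%02d", i))
  truth <- data.frame(
    subject = vapply(subjects, function(s) s@subjectId, character(1)),
    relPhase = draws$ph,
    fSamp = synthTemplate@fSamp,
    behavior = vapply(subjects, function(s) s@behavior$overall, numeric(1)),
    seed = draws$seeds)
  list(subjects = subjects, truth = truth)
}
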