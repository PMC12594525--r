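# shared fixtures, built in code

FT <- 60 / 14   # target tag frequency
FD <- 6         # distractor tag frequency

# wrap a raw signal (vector or channels x samples matrix) as a
# NarrowbandSignal without filtering, for closed-form envelope tests
asNarrowband <- function(v, fs = 500, center = FT, channels = NULL) {
  m <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(m)))
  new("NarrowbandSignal", values = m, fs = fs, channels = channels,
      center = center, halfWidth = 0.5, analysisInterval = c(2, 11))
}

# small synthetic configurations: 3 posterior channels, fewer trials
quickParadigm <- function(nPer = 6L) paradigmConfig(nTrialsPerCategory = nPer)

quickSynth <- function(seed = 1L, ...) {
  synthConfig(channels = c("Pz", "POz", "Oz"),
              targetTopography = c(0.55, 0.85, 1.0),
              distractorTopography = c(0.6, 1.0, 0.9),
              seed = seed, ...)
}

# a full-size reference subject at the default conditions, built once per
# test run and reused
refSubject <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulateSubject(paradigmConfig(), synthConfig(seed = 101L))
    cache
  }
})

# build an EEGDataset directly from an array (white-noise or hand-made data)
makeDataset <- function(data, labels, fs = 500,
                        channels = paste0("ch", seq_len(dim(data)[2]))) {
  new("EEGDataset", data = data, labels = as.factor(labels), fs = fs,
      channels = channels,
      behavior = list(overall = NA_real_, perCategory = numeric()),
      groundTruth = list(), subjectId = "fixture")
}

timeAxis <- function(duration = 11.666, fs = 500) (0:(floor(duration * fs) - 1)) / fs
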