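## Internal signal-processing primitives shared across modules.

## Evaluate expr with a temporarily fixed RNG state; restores the caller's
## stream so analyses stay pure functions of their seed arguments.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(force(expr))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(as.integer(seed))
  force(expr)
}

## sqrt(2) x RMS: equals the peak amplitude of a pure sinusoid.
sineAmplitude <- function(x) sqrt(2 * mean(x^2))

## Zero-phase narrowband filter, applied in the frequency domain.
## Response: 1 for |f - center| <= halfWidth, cosine taper down to 0 at
## halfWidth + transWidth, 0 beyond. Exactly zero phase by construction.
## The default transition (0.75 Hz) is deliberately gentle: amplitude
## modulation of the tagged carrier at ~1 Hz lives in sidebands at center
## +/- 1 Hz, and a brick-wall band edge would remove the very modulation the
## envelope analysis measures; the cosine taper keeps those sidebands at
## half amplitude while still fully rejecting the other tag (offset 1.71 Hz)
## and concentrating >= 80% of broadband power within center +/- 0.75 Hz.
## Reflection padding (2 s) suppresses boundary transients; the FFT length is
## rounded up to a 2-3-5-smooth number for speed.
##
## x: samples x channels matrix (or vector). Returns same shape.
nbFilterMatrix <- function(x, fs, center, halfWidth = 0.5, transWidth = 0.75) {
  x <- as.matrix(x)
  n <- nrow(x)
  pad <- min(n - 1L, round(2 * fs))
  xi <- rbind(x[pad:1, , drop = FALSE], x, x[n:(n - pad + 1), , drop = FALSE])
  m0 <- nrow(xi)
  m <- stats::nextn(m0, c(2, 3, 5))
  if (m > m0) xi <- rbind(xi, matrix(0, m - m0, ncol(xi)))
  f <- (seq_len(m) - 1) / m * fs
  f <- ifelse(f > fs / 2, fs - f, f)         # fold to [0, fs/2]
  off <- abs(f - center)
  H <- ifelse(off <= halfWidth, 1,
              ifelse(off <= halfWidth + transWidth,
                     cos(pi * (off - halfWidth) / (2 * transWidth)), 0))
  y <- Re(stats::mvfft(stats::mvfft(xi) * H, inverse = TRUE)) / m
  y[(pad + 1):(pad + n), , drop = FALSE]
}

## Analytic signal via the frequency-domain construction; Mod() of the
## result is the instantaneous-amplitude (Hilbert) envelope.
analyticSignal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## 1/f^alpha noise, n samples x nc independent channels, unit RMS per
## channel. White noise is spectrally shaped (amplitude ~ f^(-alpha/2), zero
## DC) at a 2-3-5-smooth FFT length and cropped; cropping a stationary
## process changes nothing.
pinkNoise <- function(n, fs, alpha = 1, nc = 1L) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- matrix(stats::rnorm(m * nc), m, nc)
  W <- stats::mvfft(w)
  f <- (seq_len(m) - 1) / m * fs
  f <- ifelse(f > fs / 2, fs - f, f)
  shape <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::mvfft(W * shape, inverse = TRUE)) / m
  x <- x[seq_len(n), , drop = FALSE]
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

## Remove mean (and optionally a linear trend) from a series.
detrendSeries <- function(v, linear = TRUE) {
  n <- length(v)
  if (!linear) return(v - mean(v))
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), v)$residuals
}

## One-sided amplitude spectrum of a (pre-detrended) series sampled at
## `rate` Hz, zero padded to at least `padMin` points and at least
## `padFactor` times the series length (2-3-5-smooth). Scaled so that a unit
## sinusoid has amplitude 1.
amplitudeSpectrumCore <- function(v, rate, padMin = 512L, padFactor = 4L) {
  n <- length(v)
  np <- stats::nextn(max(padMin, padFactor * n), c(2, 3, 5))
  X <- stats::fft(c(v, numeric(np - n)))
  nk <- floor(np / 2) + 1L
  amp <- Mod(X[seq_len(nk)]) * 2 / n
  amp[1] <- amp[1] / 2
  new("AmplitudeSpectrum",
      freqs = (seq_len(nk) - 1) * rate / np,
      amplitudes = amp,
      resolution = rate / np)
}

## Sample index range [i0, i1] covering [start, start + len) at rate fs with
## t = (0:(n-1))/fs. Used by every windowed operation so that windows and
## whole-trial intervals select identical samples.
sampleRange <- function(start, len, fs, nSamples, origin = 0) {
  i0 <- round((start - origin) * fs) + 1L
  i1 <- i0 + round(len * fs) - 1L
  c(max(1L, i0), min(nSamples, i1))
}

## Moving-window start times for a WindowSpec: floor((span - length)/step) + 1
## windows beginning at interval[1].
windowStarts <- function(spec) {
  span <- diff(spec@interval)
  k <- floor((span - spec@length) / spec@step + 1e-9) + 1L
  if (k < 2L) stop("fewer than 2 windows fit the interval")
  spec@interval[1] + (seq_len(k) - 1L) * spec@step
}
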