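## subset-averaged ("ERP") linear-SVM decoding of distractor category

#' Decoding specification
#'
#' @param nSubsets subsets per category (>= 3).
#' @param nIterations random re-partitions to average over.
#' @param cost linear-SVM cost C.
#' @param standardize standardize features using training-fold statistics.
#' @param rotateFolds evaluate all leave-one-subset-out folds per iteration
#'   (default); `FALSE` draws a single fold, matching the narrower reading
#'   of the original scheme.
#' @param center,halfWidth feature band, Hz (distractor tag 6 +/- 0.5).
#' @param interval whole-trial scoring interval, s.
#' @param seed RNG seed for the random partitions.
#' @return A validated [DecodingSpec-class].
#' @export
decodingSpec <- function(nSubsets = 3L, nIterations = 100L, cost = 1,
                         standardize = TRUE, rotateFolds = TRUE,
                         center = 6, halfWidth = 0.5, interval = c(2, 11),
                         seed = 1L) {
  new("DecodingSpec", nSubsets = as.integer(nSubsets),
      nIterations = as.integer(nIterations), cost = cost,
      standardize = standardize, rotateFolds = rotateFolds,
      center = center, halfWidth = halfWidth, interval = interval,
      seed = as.integer(seed))
}

## Narrowband-filter every trial (linear, so subset-averaging commutes with
## filtering). Returns trials x channels x samples array.
nbFilterTrials <- function(dataset, center, halfWidth = 0.5) {
  d <- dim(dataset@data)
  out <- array(0, d)
  for (i in seq_len(d[1]))
    out[i, , ] <- t(nbFilterMatrix(t(dataset@data[i, , ]), dataset@fs,
                                   center, halfWidth))
  out
}

## Per-channel trial Gram matrices over a sample window:
## G[i, j, c] = mean_t x_i(c, t) x_j(c, t). The sqrt(2) RMS feature of a
## subset average is then sqrt(2 sum_{i,j in S} G[i,j,c]) / |S|, so random
## partitions cost O(|S|^2) instead of re-averaging waveforms.
trialGram <- function(nbArr, fs, start, len) {
  d <- dim(nbArr)
  rg <- sampleRange(start, len, fs, d[3])
  idx <- rg[1]:rg[2]
  G <- array(0, c(d[1], d[1], d[2]))
  for (c in seq_len(d[2]))
    G[, , c] <- tcrossprod(nbArr[, c, idx]) / length(idx)
  G
}

featuresFromGram <- function(G, subset) {
  k <- length(subset)
  Gs <- G[subset, subset, , drop = FALSE]
  sqrt(2 * pmax(.colSums(Gs, k * k, dim(G)[3]), 0)) / k
}

## Random partition of idx into k near-equal subsets (sizes differ by <= 1;
## the first n %% k subsets get the extra trial).
partitionIndices <- function(idx, k) {
  n <- length(idx)
  if (n < k) stop(sprintf("cannot split %d trials into %d subsets", n, k))
  idx <- sample(idx)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(idx, rep(seq_len(k), sizes))
}

## Standardize features with training statistics; zero-variance features are
## left unscaled (flagged via a warning by the caller once per decode call).
standardizeFold <- function(train, test) {
  mu <- colMeans(train)
  sd <- apply(train, 2, stats::sd)
  degenerate <- sd < 1e-12
  sd[degenerate] <- 1
  list(train = scale(train, mu, sd), test = scale(test, mu, sd),
       degenerate = any(degenerate))
}

.linearSVM <- function(x, y, cost) {
  e1071::svm(x, y, type = "C-classification", kernel = "linear",
             cost = cost, scale = FALSE)
}

## One-vs-rest decision values, sign-fixed so that the positive class's own
## training rows score positive; columns ordered by `classes`.
.ovrDecisionValues <- function(train, yTrain, test, classes, cost) {
  vapply(classes, function(cl) {
    y <- factor(ifelse(yTrain == cl, "pos", "rest"), levels = c("pos", "rest"))
    m <- .linearSVM(train, y, cost)
    dvTr <- attr(stats::predict(m, train, decision.values = TRUE),
                 "decision.values")[, 1]
    s <- if (mean(dvTr[y == "pos"]) >= 0) 1 else -1
    s * attr(stats::predict(m, test, decision.values = TRUE),
             "decision.values")[, 1]
  }, numeric(nrow(test)))
}

## Core decoder. gramList: one Gram array per scoring window. labels: trial
## labels; classes: categories in fixed tie-break order. Uses the *current*
## RNG stream (callers wrap in withSeed). Returns accuracy matrix
## [nIterations x nWindows] plus a degenerate-feature flag.
decodeCore <- function(gramList, labels, classes, spec, mode) {
  k <- spec@nSubsets
  nW <- length(gramList)
  classIdx <- lapply(classes, function(cl) which(labels == cl))
  short <- lengths(classIdx) < k
  if (any(short))
    stop(sprintf("category '%s' has fewer trials than nSubsets = %d",
                 classes[which(short)[1]], k))
  acc <- matrix(0, spec@nIterations, nW)
  sawDegenerate <- FALSE
  nCl <- length(classes)
  yAll <- factor(rep(classes, each = k), levels = classes)
  for (it in seq_len(spec@nIterations)) {
    parts <- lapply(classIdx, partitionIndices, k = k)  # shared across windows
    folds <- if (spec@rotateFolds) seq_len(k) else sample.int(k, 1L)
    for (w in seq_len(nW)) {
      G <- gramList[[w]]
      feats <- do.call(rbind, lapply(seq_len(nCl), function(ci)
        t(vapply(parts[[ci]], function(s) featuresFromGram(G, s),
                 numeric(dim(G)[3])))))
      ## rows: class-major, subset-minor; yAll matches
      foldAcc <- vapply(folds, function(f) {
        testRows <- (seq_len(nCl) - 1L) * k + f
        trainRows <- setdiff(seq_len(nCl * k), testRows)
        tr <- feats[trainRows, , drop = FALSE]
        te <- feats[testRows, , drop = FALSE]
        if (spec@standardize) {
          st <- standardizeFold(tr, te)
          if (st$degenerate) sawDegenerate <<- TRUE
          tr <- st$train; te <- st$test
        }
        yTr <- yAll[trainRows]
        yTe <- yAll[testRows]
        if (mode == "pairwise") {
          m <- .linearSVM(tr, factor(yTr, levels = classes), spec@cost)
          mean(as.character(stats::predict(m, te)) == as.character(yTe))
        } else {
          dv <- .ovrDecisionValues(tr, yTr, te, classes, spec@cost)
          pred <- classes[apply(dv, 1, which.max)]  # ties -> first class
          mean(pred == as.character(yTe))
        }
      }, numeric(1))
      acc[it, w] <- mean(foldAcc)
    }
  }
  list(acc = acc, degenerate = sawDegenerate)
}

#' Subset-averaged feature vectors
#'
#' Randomly partitions the trials of one category into `nSubsets` near-equal
#' subsets, trial-averages each subset into a subset SSVEP, and returns the
#' per-channel sqrt(2) x RMS amplitudes of its narrowband (default
#' 6 +/- 0.5 Hz) component over the given window.
#'
#' @param dataset an [EEGDataset-class].
#' @param category category label.
#' @param spec a [DecodingSpec-class].
#' @param window `"whole"` (use `spec@interval`) or a c(start, end) pair, s.
#' @param seed RNG seed for the partition (default the spec's).
#' @return Matrix nSubsets x nChannels.
#' @export
subsetFeatures <- function(dataset, category, spec = decodingSpec(),
                           window = "whole", seed = spec@seed) {
  validObject(dataset); validObject(spec)
  idx <- which(dataset@labels == category)
  if (length(idx) < spec@nSubsets)
    stop(sprintf("category '%s' has fewer trials than nSubsets = %d",
                 category, spec@nSubsets))
  win <- if (identical(window, "whole")) spec@interval else window
  parts <- withSeed(seed, partitionIndices(idx, spec@nSubsets))
  nS <- dim(dataset@data)[3]
  rg <- sampleRange(win[1], diff(win), dataset@fs, nS)
  t(vapply(parts, function(s) {
    avg <- colMeans(dataset@data[s, , , drop = FALSE], dims = 1)
    nbf <- nbFilterMatrix(t(avg), dataset@fs, spec@center, spec@halfWidth)
    sqrt(2 * colMeans(nbf[rg[1]:rg[2], , drop = FALSE]^2))
  }, numeric(length(dataset@channels))))
}

.decodeWhole <- function(dataset, classes, spec, mode, nbArr = NULL) {
  validObject(dataset); validObject(spec)
  if (is.null(nbArr)) nbArr <- nbFilterTrials(dataset, spec@center, spec@halfWidth)
  G <- trialGram(nbArr, dataset@fs, spec@interval[1], diff(spec@interval))
  res <- withSeed(spec@seed,
                  decodeCore(list(G), dataset@labels, classes, spec, mode))
  if (res$degenerate)
    warning("zero-variance features encountered; left unstandardized")
  perIt <- res$acc[, 1]
  new("DecodingResult", accuracy = mean(perIt),
      chance = 1 / length(classes), perIteration = perIt,
      mode = mode, level = "whole_trial", classes = classes)
}

#' Whole-trial pairwise decoding
#'
#' Linear-SVM decoding between two emotion categories from the per-channel
#' 6 Hz SSVEP amplitude pattern of subset-averaged trials: per iteration a
#' fresh random partition per category, training on `nSubsets - 1` subset
#' vectors per class and testing on the held-out ones (all folds rotated by
#' default), accuracy averaged over folds then iterations.
#'
#' @param dataset an [EEGDataset-class].
#' @param catA,catB category labels.
#' @param spec a [DecodingSpec-class].
#' @return A [DecodingResult-class] with chance 0.5.
#' @export
decodePairwise <- function(dataset, catA, catB, spec = decodingSpec()) {
  .decodeWhole(dataset, c(catA, catB), spec, "pairwise")
}

#' Whole-trial three-way decoding
#'
#' One-vs-rest linear SVMs over all three categories; a test vector is
#' assigned to the class with the largest sign-fixed decision value, ties
#' broken by the dataset's category order.
#'
#' @param dataset an [EEGDataset-class].
#' @param spec a [DecodingSpec-class].
#' @return A [DecodingResult-class] with chance 1/3.
#' @export
decodeThreeway <- function(dataset, spec = decodingSpec()) {
  .decodeWhole(dataset, levels(dataset@labels), spec, "threeway")
}

#' Moving-window three-way decoding series
#'
#' Three-way decoding repeated per moving window, with the same partition
#' schedule reused across windows within an iteration so that temporal
#' fluctuation reflects signal rather than partition noise. Feature
#' amplitudes use the narrowband RMS within each window (a 0.5 s window
#' cannot resolve 6 Hz on its FFT grid; narrowband RMS is the grid-free
#' equivalent).
#'
#' @param dataset an [EEGDataset-class].
#' @param spec a [DecodingSpec-class].
#' @param window a [WindowSpec-class].
#' @return A [DecodingSeries-class] (times = window centers, chance = 1/3).
#' @export
windowedDecoding <- function(dataset, spec = decodingSpec(),
                             window = windowSpec()) {
  validObject(dataset); validObject(spec); validObject(window)
  classes <- levels(dataset@labels)
  nbArr <- nbFilterTrials(dataset, spec@center, spec@halfWidth)
  starts <- windowStarts(window)
  gramList <- lapply(starts, function(s)
    trialGram(nbArr, dataset@fs, s, window@length))
  res <- withSeed(spec@seed,
                  decodeCore(gramList, dataset@labels, classes, spec,
                             "threeway"))
  if (res$degenerate)
    warning("zero-variance features encountered; left unstandardized")
  new("DecodingSeries", times = starts + window@length / 2,
      values = colMeans(res$acc), rate = 1 / window@step,
      source = "distractor_decoding", chance = 1 / length(classes))
}

#' Label-permutation null for decoding
#'
#' Shuffles category labels across trials and reruns the decoder per
#' permutation; the empirical p-value is (1 + #\{null >= observed\}) /
#' (1 + nPerm).
#'
#' @param dataset an [EEGDataset-class].
#' @param spec a [DecodingSpec-class] (use a reduced `nIterations` for large
#'   `nPerm`; the value used is recorded in the result).
#' @param mode `"threeway"` or `"pairwise"`.
#' @param catA,catB categories for pairwise mode (labels are shuffled among
#'   these trials only).
#' @param nPerm number of permutations.
#' @return List: `observed` ([DecodingResult-class]), `null` (numeric
#'   vector of permuted accuracies), `p`, `nPerm`, `nIterations`.
#' @export
permutationNull <- function(dataset, spec = decodingSpec(nIterations = 20L),
                            mode = c("threeway", "pairwise"),
                            catA = NULL, catB = NULL, nPerm = 1000L) {
  mode <- match.arg(mode)
  validObject(dataset); validObject(spec)
  if (nPerm < 100) warning("nPerm < 100 gives a coarse null distribution")
  classes <- if (mode == "threeway") levels(dataset@labels) else c(catA, catB)
  if (mode == "pairwise" && (is.null(catA) || is.null(catB)))
    stop("pairwise mode needs catA and catB")
  nbArr <- nbFilterTrials(dataset, spec@center, spec@halfWidth)
  G <- trialGram(nbArr, dataset@fs, spec@interval[1], diff(spec@interval))
  labels <- dataset@labels
  involved <- which(labels %in% classes)
  withSeed(spec@seed, {
    obs <- decodeCore(list(G), labels, classes, spec, mode)
    null <- vapply(seq_len(nPerm), function(p) {
      perm <- labels
      perm[involved] <- perm[sample(involved)]
      mean(decodeCore(list(G), perm, classes, spec, mode)$acc)
    }, numeric(1))
    obsAcc <- mean(obs$acc)
    list(observed = new("DecodingResult", accuracy = obsAcc,
                        chance = 1 / length(classes),
                        perIteration = obs$acc[, 1], mode = mode,
                        level = "whole_trial", classes = classes),
         null = null,
         p = (1 + sum(null >= obsAcc)) / (1 + nPerm),
         nPerm = nPerm, nIterations = spec@nIterations)
  })
}
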