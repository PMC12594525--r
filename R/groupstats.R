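## cohort-level statistics

#' Summary of a relative-phase distribution
#'
#' Arithmetic mean and sd on the bounded [0, pi] domain, reported both in
#' radians and in pi units (as phases are conventionally printed, e.g.
#' "0.51 pi").
#'
#' @param phases numeric vector of folded relative phases in [0, pi], n >= 2.
#' @return List: `mean`, `sd` (rad); `meanPi`, `sdPi` (units of pi); `n`.
#' @export
phaseSummary <- function(phases) {
  if (length(phases) < 2) stop("need n >= 2 phases")
  if (any(phases < 0 | phases > pi + 1e-12))
    stop("phases must lie in [0, pi]")
  list(mean = mean(phases), sd = stats::sd(phases),
       meanPi = mean(phases) / pi, sdPi = stats::sd(phases) / pi,
       n = length(phases))
}

#' Kolmogorov-Smirnov test of phase uniformity
#'
#' One-sample two-sided K-S test of phases/pi against the uniform
#' distribution on [0, 1], assessing whether the cohort shows a systematic
#' relative phase. The asymptotic p-value is the default (adequate at
#' n = 27); `exact = TRUE` requests the small-sample p.
#'
#' @param phases numeric vector in [0, pi], n >= 5.
#' @param exact use the exact small-sample p-value.
#' @return List: `statistic` (sup-norm CDF distance, in [0, 1]), `p`.
#' @export
ksUniform <- function(phases, exact = FALSE) {
  if (length(phases) < 5) stop("need n >= 5 phases")
  if (any(phases < 0 | phases > pi + 1e-12))
    stop("phases must lie in [0, pi]")
  ht <- suppressWarnings(
    stats::ks.test(phases / pi, "punif", exact = exact))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Correlation between relative phase and behavior
#'
#' Pearson correlation (two-sided) between per-subject relative phase and
#' behavioral accuracy; a positive r means that more antiphase sampling of
#' target and distractor predicts better performance.
#'
#' @param summaries data.frame with columns `relPhase` and `behavior`
#'   (as produced by [summarizeSubject()]), n >= 4 rows.
#' @return List: `r`, `p`, `n`.
#' @export
phaseBehaviorCorrelation <- function(summaries) {
  x <- summaries$relPhase
  y <- summaries$behavior
  if (length(x) < 4) stop("need n >= 4 subjects")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in phase or behavior")
  ht <- stats::cor.test(x, y)
  list(r = unname(ht$estimate), p = ht$p.value, n = length(x))
}

#' One-sample test of decoding accuracy against chance
#'
#' @param accuracies per-subject decoding accuracies (fractions), n >= 3.
#' @param chance chance level (0.5 pairwise, 1/3 three-way).
#' @return List: `t`, `df`, `p`, `mean`.
#' @export
decodingVsChance <- function(accuracies, chance) {
  if (length(accuracies) < 3) stop("need n >= 3 subjects")
  if (stats::sd(accuracies) < 1e-12) {
    d <- mean(accuracies) - chance
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                df = length(accuracies) - 1,
                p = if (d == 0) 1 else 0, mean = mean(accuracies)))
  }
  ht <- stats::t.test(accuracies, mu = chance)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean = mean(accuracies))
}

#' One-way ANOVA of behavior across emotion categories
#'
#' Treats the 3 x n per-subject per-category accuracies as independent
#' groups, giving df = (2, 3n - 3) — between-subjects accounting, even
#' though the design is within-subject (noted deliberately: it matches the
#' headline degrees of freedom convention, F(2, 78) at n = 27).
#'
#' @param accuracies matrix or data.frame, subjects x categories (equal
#'   group sizes; 3 columns).
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
behaviorAnova <- function(accuracies) {
  accuracies <- as.matrix(accuracies)
  if (ncol(accuracies) != 3) stop("expected 3 category columns")
  if (any(!is.finite(accuracies))) stop("non-finite accuracies")
  n <- nrow(accuracies)
  df <- data.frame(acc = as.vector(accuracies),
                   grp = factor(rep(seq_len(3), each = n)))
  fit <- stats::anova(stats::aov(acc ~ grp, data = df))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1])
}

#' Assemble cohort-level statistics from per-subject summaries
#'
#' @param summaries data.frame of [summarizeSubject()] rows.
#' @param behaviorPerCategory optional subjects x 3 matrix for the ANOVA.
#' @return A [GroupResult-class].
#' @export
groupStatistics <- function(summaries, behaviorPerCategory = NULL) {
  ps <- phaseSummary(summaries$relPhase)
  ks <- ksUniform(summaries$relPhase)
  pb <- phaseBehaviorCorrelation(summaries)
  dv <- list(threeway = decodingVsChance(summaries$acc3way, 1 / 3))
  ac <- compareAmplitudes(summaries$ampTarget, summaries$ampDistractor)
  an <- if (is.null(behaviorPerCategory))
    list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_, p = NA_real_)
  else behaviorAnova(behaviorPerCategory)
  new("GroupResult", nSubjects = nrow(summaries), summaries = summaries,
      meanRelPhase = ps$mean, sdRelPhase = ps$sd,
      ksStatistic = ks$statistic, ksP = ks$p,
      phaseBehaviorR = pb$r, phaseBehaviorP = pb$p,
      decodingVsChance = dv, amplitudeComparison = ac, behaviorAnova = an)
}
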