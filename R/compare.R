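#' @include AllClasses.R
NULL

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test with the conventions: zero differences
#' are dropped, tied absolute differences receive mid-ranks, the exact null
#' distribution is used for n <= 25 remaining pairs (computed by
#' generating-function convolution, valid with mid-ranks), and a normal
#' approximation with continuity correction and tie-corrected variance is
#' used above. If all differences are zero the p-value is 1 by convention
#' and flagged.
#'
#' @param x,y paired numeric vectors (the test considers `x - y`).
#' @return List with `statistic` (V, sum of positive-difference ranks), `p`
#'   (two-sided), `n` (pairs after dropping zeros), `exact`, `allZero`.
#' @export
wilcoxonSignedRank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p = 1, n = 0L, exact = TRUE, allZero = TRUE))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25L) {
    ## exact null: V is a sum over pairs of r_i * Bernoulli(1/2).
    ## Doubling the (possibly half-integer) mid-ranks gives integer support.
    s <- as.integer(round(2 * r))
    maxS <- sum(s)
    f <- numeric(maxS + 1L)   # f[k+1] = P(2V = k)
    f[1] <- 1
    for (si in s) {
      g <- f / 2
      g[(si + 1L):(maxS + 1L)] <- g[(si + 1L):(maxS + 1L)] +
        f[1:(maxS + 1L - si)] / 2
      f <- g
    }
    v2 <- round(2 * V)
    pLe <- sum(f[seq_len(v2 + 1L)])
    pGe <- sum(f[(v2 + 1L):(maxS + 1L)])
    p <- min(1, 2 * min(pLe, pGe))
    return(list(statistic = V, p = p, n = n, exact = TRUE, allZero = FALSE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(V - mu) * 0.5
  z <- (V - mu - cc) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  p <- max(p, .Machine$double.xmin)
  list(statistic = V, p = p, n = n, exact = FALSE, allZero = FALSE)
}

#' Bland-Altman percent bias between paired series
#'
#' Mean and standard deviation (n-1 denominator) of per-pair percent
#' differences. Usable when the regression in [agreement()] is not (e.g. a
#' constant reference).
#'
#' @param reference,test paired numeric vectors; reference must be positive.
#' @param denominator `"reference"` (default) or `"pairmean"`.
#' @return List with `mean`, `sd`, `differences`.
#' @export
percentBias <- function(reference, test,
                        denominator = c("reference", "pairmean")) {
  denominator <- match.arg(denominator)
  stopifnot(length(reference) == length(test), all(reference > 0))
  den <- if (denominator == "reference") reference
         else (reference + test) / 2
  d <- 100 * (test - reference) / den
  list(mean = mean(d), sd = stats::sd(d), differences = d)
}

#' Method agreement between a reference and a test series
#'
#' The statistical comparison used for validating one flow-measurement
#' method against a reference: ordinary least-squares regression of test on
#' reference (slope, intercept, r^2), Bland-Altman percent bias (mean and SD
#' of per-pair percent differences, n-1 denominator), and the paired
#' two-sided Wilcoxon signed-rank test of [wilcoxonSignedRank()].
#'
#' Percent differences are `100 (test_i - reference_i) / reference_i`: the
#' reference method serves as denominator, since one method is designated
#' the reference. The classical Bland-Altman pair-mean denominator
#' `100 (test_i - reference_i) / ((test_i + reference_i)/2)` is reported
#' alongside (`biasPercentMeanPairDenom`).
#'
#' @param reference numeric, reference values (> 0).
#' @param test numeric, same length, n >= 3.
#' @return An [AgreementReport-class].
#' @examples
#' agreement(c(100, 100, 100, 100), c(90, 90, 90, 90))  # bias -10 +/- 0 %
#' @export
agreement <- function(reference, test) {
  if (length(reference) != length(test))
    stop("reference and test must have equal length")
  n <- length(reference)
  if (n < 3L) stop("at least 3 pairs are required")
  if (any(reference <= 0))
    stop("reference values must be positive")
  if (stats::var(reference) == 0)
    stop("regression error: reference has zero variance")
  fit <- stats::lm(test ~ reference)
  co <- stats::coef(fit)
  r2 <- summary(fit)$r.squared
  dRef <- 100 * (test - reference) / reference
  dPm <- 100 * (test - reference) / ((test + reference) / 2)
  wt <- wilcoxonSignedRank(test, reference)
  new("AgreementReport",
      n = as.integer(n), slope = unname(co[2]), intercept = unname(co[1]),
      rSquared = r2,
      biasPercentMean = mean(dRef), biasPercentSd = stats::sd(dRef),
      biasPercentMeanPairDenom = mean(dPm),
      biasPercentSdPairDenom = stats::sd(dPm),
      denominator = "reference",
      wilcoxonStatistic = wt$statistic, wilcoxonP = wt$p,
      wilcoxonExact = wt$exact, allZero = wt$allZero)
}

#' Serialise an agreement report to a plain list
#'
#' @param report an [AgreementReport-class].
#' @return Named list suitable for JSON output.
#' @export
agreementAsList <- function(report) {
  list(
    n = report@n, slope = report@slope, intercept = report@intercept,
    r_squared = report@rSquared,
    bias_percent_mean = report@biasPercentMean,
    bias_percent_sd = report@biasPercentSd,
    bias_percent_denominator = report@denominator,
    bias_percent_mean_pair_denom = report@biasPercentMeanPairDenom,
    bias_percent_sd_pair_denom = report@biasPercentSdPairDenom,
    wilcoxon_statistic = report@wilcoxonStatistic,
    wilcoxon_p_two_sided = report@wilcoxonP,
    wilcoxon_exact = report@wilcoxonExact,
    all_differences_zero = report@allZero)
}
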