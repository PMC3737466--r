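#' Paired t test with a pooled trimmed variance
#'
#' For each signal probe the dye-swap-averaged log-ratios of the biological
#' replicates are tested against zero. Per-probe sample variances are
#' computed across replicates, rescaled to the spot-noise scale according
#' to how many technical spots each replicate averaged; probes whose
#' rescaled variance falls inside an empirical quantile band (probes that
#' do not display extreme variance) contribute to a pooled trimmed
#' variance, and each probe's statistic is its mean log-ratio divided by
#' its pooled standard error, which accounts for missing technical
#' replicates. Raw p-values come, by default, from a Student t reference
#' whose degrees of freedom match the sampling variability of the pooled
#' trimmed variance (Satterthwaite-style; about `1.33 * m` for the default
#' band with two replicates, i.e. thousands of df and hence nearly normal,
#' but with exactly the extreme-tail correction that Bonferroni thresholds
#' are sensitive to). `df = Inf` selects the standard normal reference and
#' any fixed df can be supplied. Raw p-values are Bonferroni-adjusted with
#' m = number of signal probes.
#'
#' With few replicates, trimming biases the pooled variance low (the upper
#' tail of the chi-squared variance distribution carries much of its mean),
#' which would inflate the family-wise error; by default the trimmed mean is
#' rescaled by its expectation under normality (closed form via the
#' chi-squared distribution) so the estimator is unbiased. Set
#' `calibrate = FALSE` for the raw trimmed mean.
#'
#' @param norm A `"normalized_matrix"` from [normalize_comparison()].
#' @param trim Lower and upper quantiles of the variance band retained for
#'   pooling (default `c(0.025, 0.975)`).
#' @param alpha Family-wise significance level for classification.
#' @param df Degrees of freedom of the reference distribution; `NULL`
#'   (default) matches the effective df of the pooled trimmed variance,
#'   `Inf` uses the standard normal.
#' @param calibrate Rescale the trimmed variance to be unbiased under
#'   normality (default `TRUE`).
#' @return Data frame of class `"differential_calls"` with one row per
#'   signal probe: `probe`, `mean_M`, `A_mean`, `stat`, `p_raw`,
#'   `p_bonferroni`, `class` (`UP`/`NC`/`DOWN`), `has_signal`. Attributes:
#'   `m` (number of tests), `alpha`, `s2_trim` (pooled variance used).
#' @export
trimmed_variance_test <- function(norm, trim = c(0.025, 0.975),
                                  alpha = 0.05, df = NULL, calibrate = TRUE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  n <- ncol(norm$M)
  if (n < 2) stop("at least 2 biological replicates are required",
                  call. = FALSE)
  if (!(trim[1] >= 0 && trim[2] <= 1 && trim[1] < trim[2]))
    stop("trim quantiles must satisfy 0 <= lo < hi <= 1", call. = FALSE)
  M <- norm$M[norm$signal, , drop = FALSE]
  A <- norm$A[norm$signal, , drop = FALSE]
  k <- norm$n_spots[norm$signal, , drop = FALSE]
  m <- nrow(M)
  if (m == 0) stop("no signal probes", call. = FALSE)

  mean_m <- rowMeans(M)
  # Per-probe variances are pooled on the spot-noise scale: a replicate
  # averaging k spots has variance sigma^2/k, so the probe's sample variance
  # across replicates estimates (sigma^2/n) * sum_i 1/k_i and is rescaled by
  # n / sum_i 1/k_i before pooling. For complete dye-swap data (all k equal)
  # this reduces exactly to t = mean(M) / sqrt(s2_trim / n); probes with a
  # missing technical replicate get a correspondingly wider standard error.
  w <- rowSums(1 / k)
  s2 <- rowSums((M - mean_m)^2) / (n - 1)
  s2_spot <- s2 * n / w
  band <- quantile(s2_spot, trim)
  s2_trim <- mean(s2_spot[s2_spot >= band[1] & s2_spot <= band[2]])
  if (calibrate) s2_trim <- s2_trim / trim_attenuation(n - 1, trim)

  if (s2_trim == 0) {
    if (all(mean_m == 0)) {
      stat <- rep(0, m)
      p_raw <- rep(1, m)
    } else {
      stop("pooled trimmed variance is zero but some means are non-zero",
           call. = FALSE)
    }
  } else {
    stat <- mean_m / sqrt(s2_trim * w / n^2)
    if (is.null(df)) df <- trim_effective_df(n - 1, trim, sum(
      s2_spot >= band[1] & s2_spot <= band[2]))
    p_raw <- if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  }
  p_bonf <- pmin(1, p_raw * m)
  cls <- ifelse(p_bonf < alpha & mean_m > 0, "UP",
                ifelse(p_bonf < alpha & mean_m < 0, "DOWN", "NC"))
  out <- data.frame(probe = rownames(M), mean_M = unname(mean_m),
                    A_mean = unname(rowMeans(A)), stat = unname(stat),
                    p_raw = unname(p_raw), p_bonferroni = unname(p_bonf),
                    class = unname(cls), has_signal = TRUE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "s2_trim") <- s2_trim
  attr(out, "df") <- if (s2_trim == 0) NA_real_ else df
  class(out) <- c("differential_calls", "data.frame")
  out
}

#' Expected retained fraction of a trimmed chi-squared variance
#'
#' `E[s^2 | s^2 inside the (lo, hi) quantile band] / sigma^2` for a sample
#' variance with `k` degrees of freedom under normality, using the identity
#' `x f_k(x) = k f_{k+2}(x)` for the chi-squared density.
#'
#' @param k Degrees of freedom of the per-probe variance (replicates - 1).
#' @param trim Quantile band `c(lo, hi)`.
#' @return The attenuation factor in (0, 1].
#' @export
trim_attenuation <- function(k, trim = c(0.025, 0.975)) {
  q <- qchisq(trim, df = k)
  (pchisq(q[2], df = k + 2) - pchisq(q[1], df = k + 2)) / (trim[2] - trim[1])
}

#' Effective degrees of freedom of the pooled trimmed variance
#'
#' Satterthwaite-style matching: the pooled trimmed variance is a mean of
#' `n_kept` truncated chi-squared variables; its relative variance under
#' normality is matched to that of `chi^2_df / df`, giving
#' `df = 2 * n_kept / (E[X^2|band]/E[X|band]^2 - 1)` with moments of the
#' truncated chi-squared in closed form. The resulting df is of order
#' `1.3 * n_kept`, so the reference is close to normal but carries the
#' correct extreme-tail behaviour.
#'
#' @param k Degrees of freedom of the per-probe variance (replicates - 1).
#' @param trim Quantile band `c(lo, hi)`.
#' @param n_kept Number of probes retained in the band.
#' @return Effective degrees of freedom.
#' @export
trim_effective_df <- function(k, trim = c(0.025, 0.975), n_kept) {
  q <- qchisq(trim, df = k)
  mass <- trim[2] - trim[1]
  e1 <- k * (pchisq(q[2], df = k + 2) - pchisq(q[1], df = k + 2)) / mass
  e2 <- k * (k + 2) *
    (pchisq(q[2], df = k + 4) - pchisq(q[1], df = k + 4)) / mass
  rel_var <- e2 / e1^2 - 1
  2 * n_kept / rel_var
}

#' Classify probes from a differential call table
#'
#' `UP` iff the Bonferroni-adjusted p-value is below `alpha` and the mean
#' log-ratio is positive, `DOWN` iff below `alpha` and negative, `NC`
#' otherwise (a significant probe with mean exactly zero has no direction
#' and is classified `NC`).
#'
#' @param calls A `"differential_calls"` table.
#' @param alpha Significance level (defaults to the level used in the test).
#' @return Named character vector probe -> class.
#' @export
classify_probes <- function(calls, alpha = attr(calls, "alpha")) {
  if (is.null(alpha)) alpha <- 0.05
  cls <- ifelse(calls$p_bonferroni < alpha & calls$mean_M > 0, "UP",
                ifelse(calls$p_bonferroni < alpha & calls$mean_M < 0,
                       "DOWN", "NC"))
  setNames(cls, calls$probe)
}

#' Run the normalization and testing chain for one comparison
#'
#' Convenience wrapper: [normalize_comparison()] then
#' [trimmed_variance_test()].
#'
#' @param spots Raw spot table of one comparison.
#' @inheritParams normalize_comparison
#' @inheritParams trimmed_variance_test
#' @return A `"differential_calls"` table.
#' @export
differential_calls <- function(spots, span = 0.3, iterations = 4L,
                               min_spots = 100L, trim = c(0.025, 0.975),
                               alpha = 0.05, df = NULL, calibrate = TRUE) {
  trimmed_variance_test(
    normalize_comparison(spots, span = span, iterations = iterations,
                         min_spots = min_spots),
    trim = trim, alpha = alpha, df = df, calibrate = calibrate)
}
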