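#' Per-sample tracking success rate
#'
#' Fraction of non-excluded frames whose ITP error is strictly below the
#' threshold; an error exactly at the threshold counts as failure
#' (success if `< 5` mm, failure if `>= 5` mm). Excluded frames are removed
#' from both numerator and denominator.
#'
#' @param errors Numeric vector of per-frame ITP errors in mm (`Inf`
#'   allowed for dropout frames).
#' @param threshold Success threshold in mm. Default 5.
#' @param excluded Integer indices of excluded frames. Default none.
#' @return Fraction in `[0, 1]`.
#' @export
success_rate <- function(errors, threshold = 5, excluded = integer(0)) {
  stopifnot(threshold > 0)
  keep <- setdiff(seq_along(errors), excluded)
  if (length(keep) == 0) {
    stop("all frames are excluded; success rate is undefined")
  }
  mean(errors[keep] < threshold)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The Wilson score interval has better small-sample behaviour than the
#' Wald interval and is used here to summarize per-frame tracking success.
#' For `k` successes in `n` trials at confidence `1 - a` with normal
#' quantile `z`:
#' `(p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `>= 1`.
#' @param confidence Confidence level. Default 0.95.
#' @return An object of class `wilson_interval` with fields `lo`, `hi`,
#'   `k`, `n`, `confidence`.
#' @examples
#' wilson_interval(10, 10) # lower bound 0.7225
#' @export
wilson_interval <- function(k, n, confidence = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, confidence > 0, confidence < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  structure(
    list(lo = if (k == 0) 0 else max(0, (centre - half) / denom),
         hi = if (k == n) 1 else min(1, (centre + half) / denom),
         k = k, n = n, confidence = confidence),
    class = "wilson_interval"
  )
}

#' @export
print.wilson_interval <- function(x, ...) {
  cat("<wilson_interval> ", x$k, "/", x$n, ": [",
      sprintf("%.4f", x$lo), ", ", sprintf("%.4f", x$hi), "] at ",
      100 * x$confidence, "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.wilson_interval <- function(x, ...) {
  tibble::tibble(estimate = x$k / x$n, conf.low = x$lo, conf.high = x$hi,
                 k = x$k, n = x$n, confidence = x$confidence)
}

#' t-based confidence interval for a sample mean
#'
#' `mean +/- t_{n-1} * sd / sqrt(n)`: the standard interval used to report
#' the mean ITP error of the segmentation validation.
#'
#' @param mean Sample mean.
#' @param sd Sample standard deviation (`>= 0`).
#' @param n Sample size (`>= 2`).
#' @param confidence Confidence level. Default 0.95.
#' @return Named numeric vector `c(lo, hi)`.
#' @examples
#' round(t_confidence_interval(1.55, 1.01, 201), 2) # 1.41, 1.69
#' @export
t_confidence_interval <- function(mean, sd, n, confidence = 0.95) {
  stopifnot(n >= 2, sd >= 0, confidence > 0, confidence < 1)
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) * sd / sqrt(n)
  c(lo = mean - half, hi = mean + half)
}

#' One-sided one-sample t-test against an error bound
#'
#' Tests whether the mean ITP error is significantly below `mu0` (5 mm by
#' default): the alternative is `mean < mu0` and a one-sided p value is
#' returned, with the conventional 0.05 significance threshold attached.
#' A zero-variance sample yields an error flag carrying the sign of
#' `mean - mu0` instead of a statistic.
#'
#' @param errors Numeric vector of ITP errors in mm (`n >= 2`).
#' @param mu0 Null mean in mm. Default 5.
#' @return A tibble with `statistic`, `p.value`, `mean`, `mu0`, `n`,
#'   `significant` (at 0.05), and `degenerate` (zero-variance flag; when
#'   set, `statistic` is `NA` and `p.value` is 0 or 1 by the sign of
#'   `mean - mu0`).
#' @export
one_sample_t_test <- function(errors, mu0 = 5) {
  stopifnot(length(errors) >= 2)
  m <- mean(errors)
  if (stats::sd(errors) == 0) {
    p <- if (m < mu0) 0 else if (m > mu0) 1 else 0.5
    stat <- if (m == mu0) 0 else NA_real_
    return(tibble::tibble(statistic = stat, p.value = p, mean = m,
                          mu0 = mu0, n = length(errors),
                          significant = p < 0.05, degenerate = TRUE))
  }
  tt <- stats::t.test(errors, mu = mu0, alternative = "less")
  tibble::tibble(statistic = unname(tt$statistic),
                 p.value = tt$p.value, mean = m, mu0 = mu0,
                 n = length(errors), significant = tt$p.value < 0.05,
                 degenerate = FALSE)
}

# adjusted Fisher-Pearson sample skewness
sample_skewness <- function(x) {
  n <- length(x)
  stopifnot(n >= 3)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Moment-matched gamma fit to an error distribution
#'
#' Fits `Gamma(shape = alpha, scale = theta)` by matching the sample mean
#' and the (adjusted Fisher-Pearson) sample skewness `g`:
#' `alpha = 4 / g^2`, `theta = mean / alpha`. Positively skewed error
#' distributions are required; non-positive skewness is an error.
#'
#' @param errors Numeric vector (`n >= 3`) of ITP errors in mm.
#' @return An object of class `gamma_fit` with fields `alpha`, `theta`,
#'   `mean`, `skewness`, `n`.
#' @export
gamma_moment_fit <- function(errors) {
  g <- sample_skewness(errors)
  if (g <= 0) {
    stop("sample skewness is not positive (", signif(g, 4),
         "); the gamma moment fit requires a right-skewed sample")
  }
  alpha <- 4 / g^2
  structure(
    list(alpha = alpha, theta = mean(errors) / alpha, mean = mean(errors),
         skewness = g, n = length(errors)),
    class = "gamma_fit"
  )
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat("<gamma_fit> shape ", signif(x$alpha, 4), ", scale ",
      signif(x$theta, 4), " mm (mean ", signif(x$mean, 4), ", skewness ",
      signif(x$skewness, 4), ", n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.gamma_fit <- function(x, ...) {
  tibble::tibble(term = c("shape", "scale"),
                 estimate = c(x$alpha, x$theta))
}

#' @export
glance.gamma_fit <- function(x, ...) {
  tibble::tibble(mean = x$mean, skewness = x$skewness, shape = x$alpha,
                 scale = x$theta, nobs = x$n)
}

#' Summarize a tracking experiment across acceleration factors
#'
#' Aggregates per-frame tracking results into the feasibility report: for
#' every acceleration factor and reconstruction method, the mean and sample
#' standard deviation of the per-sample success rates, plus a Wilson score
#' interval on the frames pooled across samples at that acceleration
#' (non-excluded frames only).
#'
#' @param results Tibble as returned by [run_tracking_experiment()]:
#'   columns `sample_id`, `R`, `method`, `frame`, `error_mm`, `excluded`.
#' @param threshold Success threshold in mm. Default 5.
#' @param confidence Wilson interval confidence. Default 0.95.
#' @return Tibble with one row per `(R, method)`: `n_samples`, `n_frames`,
#'   `mean_success`, `sd_success`, `wilson_lo`, `wilson_hi`.
#' @export
summarize_experiment <- function(results, threshold = 5, confidence = 0.95) {
  stopifnot(all(c("sample_id", "R", "method", "error_mm", "excluded") %in%
                  names(results)))
  per_sample <- results |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$R, .data$method, .data$sample_id) |>
    dplyr::summarise(
      success_rate = mean(.data$error_mm < threshold),
      k = sum(.data$error_mm < threshold),
      n = dplyr::n(), .groups = "drop"
    )
  per_sample |>
    dplyr::group_by(.data$R, .data$method) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      n_frames = sum(.data$n),
      mean_success = mean(.data$success_rate),
      sd_success = if (dplyr::n() > 1) stats::sd(.data$success_rate) else 0,
      wilson_lo = wilson_interval(sum(.data$k), sum(.data$n), confidence)$lo,
      wilson_hi = wilson_interval(sum(.data$k), sum(.data$n), confidence)$hi,
      .groups = "drop"
    )
}
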