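test_that("success rate uses a strict threshold and honours exclusions", {
  expect_equal(success_rate(rep(0, 10)), 1)
  expect_equal(success_rate(c(4, 6)), 0.5)
  # an error of exactly 5 mm is a failure
  expect_equal(success_rate(c(5, 5, 1)), 1 / 3)
  expect_equal(success_rate(c(Inf, 1)), 0.5)
  # excluded frames leave numerator and denominator
  expect_equal(success_rate(c(1, 1, 100, 100), excluded = c(3, 4)), 1)
  expect_error(success_rate(c(1, 2), excluded = 1:2), "excluded")
  # order invariance
  set.seed(71)
  e <- runif(50, 0, 10)
  expect_equal(success_rate(e), success_rate(sample(e)))
})

test_that("Wilson intervals match the closed form and its symmetries", {
  w <- wilson_interval(10, 10)
  expect_equal(round(w$lo, 4), 0.7225)
  expect_equal(w$hi, 1)
  for (kn in list(c(0, 5), c(3, 7), c(17, 60), c(599, 600))) {
    w <- wilson_interval(kn[1], kn[2])
    o <- oracle_wilson(kn[1], kn[2])
    expect_equal(c(w$lo, w$hi), o, tolerance = 1e-12)
    # the interval contains the point estimate
    expect_lte(w$lo, kn[1] / kn[2])
    expect_gte(w$hi, kn[1] / kn[2])
    # mirror symmetry: lo(k, n) == 1 - hi(n - k, n)
    m <- wilson_interval(kn[2] - kn[1], kn[2])
    expect_equal(w$lo, 1 - m$hi, tolerance = 1e-12)
  }
  expect_equal(wilson_interval(0, 8)$lo, 0)
  # width shrinks with n at fixed proportion
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    w <- wilson_interval(0.9 * n, n)
    w$hi - w$lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(wilson_interval(5, 0))
  td <- tidy(wilson_interval(9, 12))
  expect_equal(td$estimate, 0.75)
  expect_named(td, c("estimate", "conf.low", "conf.high", "k", "n",
                     "confidence"))
})

test_that("t-based intervals reproduce the published segmentation summary", {
  ci <- t_confidence_interval(1.55, 1.01, 201)
  expect_equal(unname(round(ci, 2)), c(1.41, 1.69))
  expect_equal(unname(t_confidence_interval(3, 0, 10)), c(3, 3))
  # large-n limit approaches the normal interval
  ci_t <- t_confidence_interval(0, 1, 1e6)
  z <- qnorm(0.975) / sqrt(1e6)
  expect_lt(abs(ci_t["hi"] - z), 1e-4)
  expect_error(t_confidence_interval(1, 1, 1))
})

test_that("the one-sided t-test behaves at, below and around the bound", {
  at <- one_sample_t_test(rep(5, 10))
  expect_equal(at$statistic, 0)
  expect_equal(at$p.value, 0.5)
  expect_true(at$degenerate)
  set.seed(72)
  low <- rnorm(100, 1, 0.1)
  r <- one_sample_t_test(low)
  expect_lt(r$p.value, 1e-10)
  expect_true(r$significant)
  # closed-form cross-check of the t statistic
  tstat <- (mean(low) - 5) / (sd(low) / sqrt(100))
  expect_equal(r$statistic, tstat, tolerance = 1e-12)
  # reflection about mu0 flips the one-sided p value
  flipped <- one_sample_t_test(10 - low)
  expect_equal(flipped$p.value, 1 - r$p.value, tolerance = 1e-12)
})

test_that("the gamma moment fit obeys its defining identities", {
  set.seed(73)
  x <- rgamma(500, shape = 3, scale = 0.8)
  fit <- gamma_moment_fit(x)
  g <- needletrack:::sample_skewness(x)
  expect_equal(fit$alpha, 4 / g^2, tolerance = 1e-12)
  expect_equal(fit$theta, mean(x) / fit$alpha, tolerance = 1e-12)
  # skewness 2 with mean 1 corresponds to the unit exponential: a large
  # exponential sample must recover shape and scale near 1
  y <- rexp(2e5)
  fit2 <- gamma_moment_fit(y)
  expect_equal(fit2$alpha, 1, tolerance = 0.1)
  expect_equal(fit2$theta, 1, tolerance = 0.1)
  # left-skewed input is rejected
  expect_error(gamma_moment_fit(c(1, 10, 10, 10, 10)), "skew")
  expect_equal(tidy(fit)$term, c("shape", "scale"))
  expect_equal(glance(fit)$nobs, 500)
})

test_that("experiment summaries aggregate per-sample rates correctly", {
  res <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 4),
    R = 8, method = "zero_filled", frame = rep(1:4, 2),
    error_mm = c(1, 1, 6, 6, 1, 1, 1, 1),
    excluded = FALSE
  )
  s <- summarize_experiment(res)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_success, 0.75)
  expect_equal(s$sd_success, sd(c(0.5, 1)))
  expect_equal(round(s$sd_success, 4), 0.3536)
  w <- oracle_wilson(6, 8)
  expect_equal(c(s$wilson_lo, s$wilson_hi), w, tolerance = 1e-12)
  # one row per (R, method)
  res2 <- dplyr::mutate(res, method = rep(c("zero_filled", "crnn"), 4))
  res3 <- dplyr::bind_rows(res2, dplyr::mutate(res2, R = 16))
  expect_equal(nrow(summarize_experiment(res3)), 4)
  # excluded frames drop from the pooled denominator
  res$excluded[3:4] <- TRUE
  s2 <- summarize_experiment(res)
  expect_equal(s2$n_frames, 6)
  expect_equal(s2$mean_success, 1)
})
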