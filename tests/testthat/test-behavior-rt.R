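test_that("the log-RT percentile filter removes only the strict upper tail", {
  same <- tibble::tibble(rt_s = rep(0.4, 12))
  expect_equal(nrow(filter_rts(same)), 12)

  df <- tibble::tibble(rt_s = seq(10, 100, 10))
  kept <- filter_rts(df)$rt_s
  expect_setequal(kept, seq(10, 90, 10))

  # monotone unit change leaves the removed set unchanged
  kept_ms <- filter_rts(tibble::tibble(rt_s = df$rt_s * 1000))$rt_s
  expect_setequal(kept_ms / 1000, kept)
})

test_that("the filter is applied within blocks and is near-idempotent", {
  withr::with_seed(8, {
    df <- tibble::tibble(
      participant_id = rep(c("a", "b"), each = 100),
      stim_id = "s1",
      rt_s = c(stats::rlnorm(100, -1, 0.4), stats::rlnorm(100, 0.5, 0.4))
    )
    f1 <- filter_rts(df)
    # per-block: each block loses its own upper tail
    expect_equal(unname(table(f1$participant_id)), c(90L, 90L),
                 ignore_attr = TRUE)
    for (s in 1:20) {
      x <- tibble::tibble(rt_s = stats::rlnorm(50, 0, 0.5))
      once <- filter_rts(x)
      twice <- filter_rts(once)
      expect_gte(nrow(twice), nrow(once) - 5)
    }
  })
})

test_that("bootstrap median CIs behave on degenerate and tiny inputs", {
  cst <- median_rt_ci(rep(0.5, 20), n_boot = 199, seed = 1)
  expect_equal(cst$median, 0.5)
  expect_equal(cst$ci_hi - cst$ci_lo, 0)
  expect_equal(median_rt_ci(c(1, 2, 3), n_boot = 99, seed = 1)$median, 2)
  # reorder invariance
  x <- stats::rlnorm(50)
  expect_identical(median_rt_ci(x, n_boot = 199, seed = 3),
                   median_rt_ci(rev(x), n_boot = 199, seed = 3))
})

test_that("bootstrap CI covers the true lognormal median about 95% of the time", {
  true_med <- exp(-0.5)
  cover <- vapply(1:200, function(s) {
    x <- withr::with_seed(s, stats::rlnorm(200, -0.5, 0.6))
    ci <- median_rt_ci(x, n_boot = 399, seed = 1000 + s)
    ci$ci_lo <= true_med && true_med <= ci$ci_hi
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("z-scoring standardizes each block and flags zero variance", {
  withr::with_seed(2, {
    df <- tibble::tibble(
      participant_id = rep(c("a", "b", "c"), each = 30),
      stim_id = "s",
      rt_s = c(stats::rlnorm(30, -1, 0.3), stats::rlnorm(30, 1, 0.8),
               rep(0.7, 30))
    )
  })
  z <- zscore_by_block(df)
  for (p in c("a", "b")) {
    v <- z$rt_z[z$participant_id == p]
    expect_equal(mean(v), 0, tolerance = 1e-9)
    expect_equal(stats::sd(v), 1, tolerance = 1e-9)
  }
  expect_true(all(!z$z_ok[z$participant_id == "c"]))
  expect_true(all(is.na(z$rt_z[z$participant_id == "c"])))
})

test_that("sliding means track constants, linear trends, and noise theory", {
  cst <- sliding_mean(tibble::tibble(trial_index = 1:800, rt_s = 0.5),
                      window = 500)
  expect_true(all(abs(cst$mean - 0.5) < 1e-12))
  expect_true(all(cst$sem == 0))

  lin <- sliding_mean(tibble::tibble(trial_index = 1:700,
                                     rt_s = (1:700) / 100), window = 100)
  expect_equal(diff(lin$mean), rep(0.01, length(lin$mean) - 1),
               tolerance = 1e-9)

  wn <- withr::with_seed(4, tibble::tibble(trial_index = 1:3000,
                                           rt_s = stats::rnorm(3000, 1, 0.2)))
  sm <- sliding_mean(wn, window = 500)
  expect_equal(mean(sm$sem), 0.2 / sqrt(500), tolerance = 0.1)

  expect_warning(sliding_mean(tibble::tibble(trial_index = 1:10, rt_s = 1),
                              window = 500), "window")
})

test_that("the trial-constant fit is exact on noiseless data", {
  t <- 1:100
  f <- fit_trial_constant(t = t, rt = 2^(-t / 20))
  expect_equal(f$tau, 20, tolerance = 1e-6)
  expect_equal(f$alpha, 1, tolerance = 1e-6)
  # at t = tau the model halves the starting scale
  expect_equal(f$alpha * 2^(-f$tau / f$tau), f$alpha / 2)
  expect_error(fit_trial_constant(t = c(1, 1, 1), rt = c(1, 1, 1)),
               "distinct")
  expect_error(fit_trial_constant(t = 1:3, rt = c(1, -1, 1)), "positive")
})

test_that("the trial-constant fit is scale-equivariant", {
  withr::with_seed(6, {
    t <- 1:200
    rt <- 0.8 * 2^(-t / 25) * exp(stats::rnorm(200, sd = 0.05))
    f1 <- fit_trial_constant(t = t, rt = rt)
    f2 <- fit_trial_constant(t = t, rt = rt * 3.7)
    expect_equal(f2$tau, f1$tau, tolerance = 1e-8)
    expect_equal(f2$alpha, f1$alpha * 3.7, tolerance = 1e-8)
  })
})

test_that("tau is recovered within 10% under lognormal noise", {
  errs <- vapply(1:30, function(s) {
    t <- 1:450
    rt <- withr::with_seed(s, 2^(-t / 20) * exp(stats::rnorm(450, sd = 0.1)))
    abs(fit_trial_constant(t = t, rt = rt)$tau - 20) / 20
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("inconsistency delay recovers injected shifts", {
  withr::with_seed(10, {
    n <- 400
    df0 <- tibble::tibble(
      rt_s = stats::rlnorm(n, -1, 0.3),
      consistent = rep(c(TRUE, FALSE), n / 2)
    )
    d0 <- inconsistency_delay(df0, n_boot = 499, seed = 1)
    expect_lte(d0$ci_lo, 0)
    expect_gte(d0$ci_hi, 0)

    df1 <- df0
    df1$rt_s[!df1$consistent] <- df1$rt_s[!df1$consistent] + 0.05
    d1 <- inconsistency_delay(df1, n_boot = 499, seed = 1)
    expect_gte(d1$ci_lo, 0)
    expect_lte(d1$ci_lo, 0.05 + 1e-9)
    expect_gte(d1$ci_hi, 0.05 - 1e-9)
  })
  one <- tibble::tibble(rt_s = c(0.5, 0.6), consistent = c(TRUE, FALSE))
  d <- inconsistency_delay(one, n_boot = 9, seed = 1)
  expect_true(d$degenerate)
  expect_error(inconsistency_delay(
    tibble::tibble(rt_s = 1, consistent = TRUE)), "required")
})
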