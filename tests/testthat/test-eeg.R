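make_plain_epochs <- function(data, rts = NULL) {
  d <- dim(data)
  lay <- channel_layout_64()[seq_len(d[1]), ]
  times <- seq(-500, 1000, length.out = d[2])
  epoch_set(data, lay, times, rts %||% rep(0.5, d[3]))
}

test_that("RT-based epoch exclusion applies its two stages in order", {
  arr <- array(0, dim = c(4, 10, 20))
  rts <- seq(0.1, 2.0, by = 0.1)
  ep <- make_plain_epochs(arr, rts)
  kept <- exclude_by_rt(ep)
  expect_equal(length(kept$rt_s), 18)
  expect_equal(max(kept$rt_s), 1.8)

  # ties: ceil(0.1 * n) epochs dropped even when all RTs equal
  ep_ties <- make_plain_epochs(array(0, dim = c(4, 10, 20)), rep(1, 20))
  expect_equal(length(exclude_by_rt(ep_ties)$rt_s), 18)

  # an RT surviving stage one is still capped at stage two
  rts2 <- c(rep(0.3, 17), 2.6, 3.0, 8.0)
  ep2 <- make_plain_epochs(array(0, dim = c(4, 10, 20)), rts2)
  kept2 <- exclude_by_rt(ep2)
  expect_true(all(kept2$rt_s <= 2.5))
  expect_equal(length(kept2$rt_s), 17)
})

test_that("average re-referencing zeroes the channel mean everywhere", {
  withr::with_seed(1, {
    arr <- array(stats::rnorm(8 * 30 * 5), dim = c(8, 30, 5))
  })
  rr <- rereference_average(make_plain_epochs(arr))
  mu <- apply(rr$data, c(2, 3), mean)
  expect_true(all(abs(mu) < 1e-9))

  # identical signal on all channels collapses to zero
  same <- array(rep(sin(1:30), each = 8), dim = c(8, 30, 1))
  rs <- rereference_average(make_plain_epochs(same))
  expect_true(all(abs(rs$data) < 1e-12))

  # an already zero-mean montage is unchanged
  pm <- array(0, dim = c(2, 30, 1))
  pm[1, , 1] <- 3
  pm[2, , 1] <- -3
  expect_equal(rereference_average(make_plain_epochs(pm))$data, pm)
})

test_that("baseline correction zeroes the pre-stimulus window", {
  withr::with_seed(2, {
    arr <- array(stats::rnorm(6 * 100 * 4, mean = 5), dim = c(6, 100, 4))
  })
  ep <- make_plain_epochs(arr)
  bc <- baseline_correct(ep, c(-100, 0))
  sel <- bc$times_ms >= -100 & bc$times_ms <= 0
  bmeans <- apply(bc$data[, sel, , drop = FALSE], c(1, 3), mean)
  expect_true(all(abs(bmeans) < 1e-9))

  cstv <- baseline_correct(make_plain_epochs(array(7, c(6, 100, 2))))
  expect_true(all(abs(cstv$data) < 1e-12))

  # alternative windows differ only by a per-channel constant per epoch
  b1 <- baseline_correct(ep, c(-100, 0))
  b2 <- baseline_correct(ep, c(-25, 0))
  diffs <- b1$data - b2$data
  spread <- apply(diffs, c(1, 3), function(v) diff(range(v)))
  expect_true(all(spread < 1e-9))
  expect_error(baseline_correct(ep, c(-900, -800)), "no samples")
})

test_that("ERPs average epochs and subset channels as requested", {
  arr <- array(0, dim = c(64, 20, 2))
  arr[, , 1] <- 4
  arr[, , 2] <- -4
  ep <- make_plain_epochs(arr)
  expect_true(all(compute_erp(ep)$data == 0))

  one <- make_plain_epochs(array(2, dim = c(64, 20, 1)))
  expect_equal(compute_erp(one)$data, matrix(2, 64, 20))

  sub <- compute_erp(one, channels = opo_channels, collapse = TRUE)
  expect_equal(dim(sub$data), c(1L, 20L))
  expect_error(compute_erp(one, channels = c("O1", "nope")), "unknown")

  # linearity across epoch sets (equal weights)
  a1 <- array(1, dim = c(64, 20, 1))
  a2 <- array(3, dim = c(64, 20, 1))
  avg <- average_erps(list(compute_erp(make_plain_epochs(a1)),
                           compute_erp(make_plain_epochs(a2))))
  expect_equal(avg$data, matrix(2, 64, 20))
})

test_that("GFP matches the printed formula and its invariances", {
  flat <- matrix(5, 4, 10)
  expect_true(all(gfp(flat)$gfp == 0))

  pm <- rbind(rep(1, 10), rep(-1, 10))
  expect_true(all(gfp(pm)$gfp == 1))
  expect_equal(gfp(pm * 3.2)$gfp, rep(3.2, 10))

  # invariance to a common time-varying offset (re-referencing)
  withr::with_seed(3, {
    M <- matrix(stats::rnorm(16 * 40), 16, 40)
  })
  off <- sweep(M, 2, stats::rnorm(40), `+`)
  expect_equal(gfp(M)$gfp, gfp(off)$gfp, tolerance = 1e-12)
})

test_that("pointwise windows require both significance and 50 ms duration", {
  times <- seq(0, 998, by = 2)  # 500 Hz
  n_t <- length(times)
  withr::with_seed(4, {
    ga <- matrix(stats::rnorm(8 * n_t, sd = 1), 8, n_t)
    gb <- matrix(stats::rnorm(8 * n_t, sd = 1), 8, n_t)
  })
  none <- pointwise_ttest_windows(ga, ga + 0, times_ms = times)
  expect_equal(nrow(none), 0)

  # a strong but brief (30 ms) effect is discarded
  brief <- gb
  brief[, times >= 300 & times < 330] <- brief[, times >= 300 &
                                                 times < 330] + 10
  w30 <- pointwise_ttest_windows(ga, brief, times_ms = times)
  expect_false(any(w30$start_ms >= 280 & w30$start_ms <= 340))

  # a sustained effect is found where injected
  sust <- gb
  sust[, times >= 250 & times <= 400] <- sust[, times >= 250 &
                                                times <= 400] + 3
  ws <- pointwise_ttest_windows(ga, sust, times_ms = times)
  expect_gte(nrow(ws), 1)
  expect_true(any(ws$start_ms <= 400 & ws$end_ms >= 250))
  expect_true(all(ws$duration_ms >= 50))
})

test_that("detected windows are invariant to channel and epoch order", {
  ep <- sim_small_epochs("NT", seed = 11, n_epochs = 8)
  perm_ch <- withr::with_seed(1, sample(64))
  perm_ep <- withr::with_seed(2, sample(8))
  ep_perm <- epoch_set(ep$data[perm_ch, , perm_ep],
                       ep$channels[perm_ch, ], ep$times_ms,
                       ep$rt_s[perm_ep])
  g1 <- gfp(compute_erp(ep))$gfp
  g2 <- gfp(compute_erp(ep_perm))$gfp
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("GFP interval tests flag only where the effect lives", {
  times <- seq(-500, 1000, by = 1000 / 512)
  n_t <- length(times)
  withr::with_seed(6, {
    base_a <- matrix(stats::rlnorm(8 * n_t, 0, 0.1), 8, n_t)
    base_b <- matrix(stats::rlnorm(8 * n_t, 0, 0.1), 8, n_t)
  })
  none <- gfp_interval_tests(base_a, base_a, times)
  expect_false(any(none$significant))

  eff <- base_b
  eff[, times >= 250 & times <= 400] <- eff[, times >= 250 &
                                              times <= 400] + 2
  res <- gfp_interval_tests(base_a, eff, times)
  sig_t <- res$time_ms[res$significant]
  expect_gte(length(sig_t), 1)
  expect_true(all(sig_t >= 200 & sig_t <= 450))

  # constant difference flags every sampled time
  allres <- gfp_interval_tests(base_a, base_a + 2, times)
  expect_true(all(allres$significant))
  expect_equal(diff(allres$time_ms)[1], 50, tolerance = 1)
})

test_that("topographic frames clip for display but keep raw values", {
  arr <- array(0, dim = c(64, 20, 1))
  arr[1, , 1] <- 12
  erp <- compute_erp(make_plain_epochs(arr))
  fr <- topomap_frame(erp, time_ms = 0)
  expect_equal(fr$value_uv[1], 12)
  expect_equal(fr$display_uv[1], 10)
  expect_error(topomap_frame(erp, time_ms = 5000), "outside")

  dd <- topomap_frame(erp, 0, b = erp)
  expect_true(all(dd$value_uv == 0))
})
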