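test_that("ground-truth maps are compact, complete, and reproducible", {
  m <- make_ground_truth_map(3, seed = 4)
  expect_setequal(unique(m$labels), 1:3)
  expect_identical(m, make_ground_truth_map(3, seed = 4))
  expect_false(identical(m$labels, make_ground_truth_map(3, seed = 5)$labels))

  # within-region adjacency exceeds the spatially shuffled baseline
  adj_frac <- function(labels) {
    M <- matrix(labels, 15, 15, byrow = TRUE)
    same_h <- M[, -15] == M[, -1]
    same_v <- M[-15, ] == M[-1, ]
    mean(c(same_h, same_v))
  }
  obs <- adj_frac(m$labels)
  base <- withr::with_seed(1, {
    mean(vapply(1:50, function(i) adj_frac(sample(m$labels)), numeric(1)))
  })
  expect_gt(obs, base)
  expect_error(make_ground_truth_map(6, seed = 1), "2..5")
})

test_that("textures carry the requested per-region orientation", {
  gt <- make_ground_truth_map(2, seed = 1)
  tex <- make_texture_stimulus(gt, orientation_deg = c(0, 90),
                               freq_cpi = c(32, 32), seed = 5)
  expect_equal(dim(tex), c(256L, 256L))
  expect_identical(tex, make_texture_stimulus(gt, c(0, 90), c(32, 32),
                                              seed = 5))

  lab_px <- matrix(gt$labels, 15, 15, byrow = TRUE)[
    pmin(floor(seq(0, 15 - 1e-9, length.out = 256)) + 1L, 15),
    pmin(floor(seq(0, 15 - 1e-9, length.out = 256)) + 1L, 15)]
  dominant_angle <- function(img) {
    S <- Mod(stats::fft(img))^2
    f1 <- c(0:128, -127:-1)
    fx <- matrix(f1, 256, 256, byrow = TRUE)
    fy <- matrix(f1, 256, 256)
    rho <- sqrt(fx^2 + fy^2)
    sel <- rho > 10 & rho < 100
    ang <- (atan2(fy, fx) * 180 / pi) %% 180
    ang[sel][which.max(S[sel])]
  }
  ang_diff <- function(a, b) min(abs(a - b), 180 - abs(a - b))
  a1 <- dominant_angle(tex * (lab_px == 1))
  a2 <- dominant_angle(tex * (lab_px == 2))
  expect_lte(ang_diff(a1, 90), 5)   # stripes at 0 deg -> spectrum at 90
  expect_lte(ang_diff(a2, 0), 5)

  # identical parameters leave no orientation contrast between regions
  hom <- make_texture_stimulus(gt, c(45, 45), c(32, 32), seed = 6)
  h1 <- dominant_angle(hom * (lab_px == 1))
  h2 <- dominant_angle(hom * (lab_px == 2))
  expect_lte(ang_diff(h1, h2), 10)
  expect_error(make_texture_stimulus(gt, c(0, 90), c(0, 32)), "frequencies")
})

test_that("the observer model honours certainty, lapse, and the RT curve", {
  fx <- sim_block(K = 2, seed = 2, certainty = 1, lapse = 0, n_mult = 1)
  expect_equal(classify_consistency(fx$block, fx$gt)$rate, 0)

  gt <- make_ground_truth_map(2, seed = 2)
  st <- stimulus("s", K = 2, category = "texture")
  lapsed <- simulate_observer_block(
    observer_params(gt, certainty = 0.5, lapse = 1, seed = 9), st,
    n_trials = 900)
  frac_same <- mean(lapsed$response == "same")
  expect_lt(abs(frac_same - 0.5), 3 * sqrt(0.25 / 900) + 0.02)

  b1 <- simulate_observer_block(observer_params(gt, seed = 7), st,
                                n_trials = 100)
  b2 <- simulate_observer_block(observer_params(gt, seed = 7), st,
                                n_trials = 100)
  expect_identical(tibble::as_tibble(b1), tibble::as_tibble(b2))
  expect_true(all(b1$rt_s > 0))
  expect_error(observer_params(gt, certainty = 0.2), "certainty")
})

test_that("gaze simulation is seeded and concentrates with zero spread", {
  g <- simulate_gaze(2, spread_px = 0, n_fixations = 1, blink_rate = 0,
                     seed = 3)
  expect_identical(g, simulate_gaze(2, spread_px = 0, n_fixations = 1,
                                    blink_rate = 0, seed = 3))
  expect_equal(nrow(g), 1000)
  expect_equal(coverage(clean_gaze(g), 2), 100 / 225)
  expect_error(simulate_gaze(0), "positive")
})

test_that("simulated epochs place the evoked component where requested", {
  pr <- eeg_sim_params(components = tibble::tibble(latency_ms = 350,
                                                   amplitude_uv = 5,
                                                   width_ms = 50),
                       n_epochs = 2, noise_rms_uv = 0, seed = 1)
  ep <- simulate_epochs(pr, c(0.5, 0.6))
  erp <- compute_erp(ep)
  best_ch <- which.max(apply(erp$data, 1, max))
  peak_t <- erp$times_ms[which.max(erp$data[best_ch, ])]
  expect_equal(peak_t, 350, tolerance = 2)
  # max-weighted channel is posterior
  expect_lt(ep$channels$y[best_ch], -0.5)

  ep2 <- simulate_epochs(pr, c(0.5, 0.6))
  expect_equal(ep$data, ep2$data)
  expect_error(simulate_epochs(pr, 0.5), "one reaction time")
  expect_error(eeg_sim_params(components = tibble::tibble(
    latency_ms = 2000, amplitude_uv = 1, width_ms = 10)), "inside")
})

test_that("the cohort amplitude ratio propagates to grand-average GFP", {
  mk <- function(cohort, s) {
    pr <- cohort_preset(cohort)$eeg
    pr$n_epochs <- 20L
    pr$noise_rms_uv <- 2
    pr$seed <- s
    compute_erp(simulate_epochs(pr, rep(0.5, 20), cohort = cohort))
  }
  g_nt <- gfp(average_erps(lapply(1:4, function(s) mk("NT", s))))
  g_as <- gfp(average_erps(lapply(1:4, function(s) mk("ASD", 50 + s))))
  expect_equal(max(g_as$gfp) / max(g_nt$gfp), 0.7, tolerance = 0.1)
})

test_that("cohort presets reproduce the qualitative behavioural contrasts", {
  nt <- cohort_preset("NT")
  asd <- cohort_preset("ASD")
  expect_lt(nt$observer$rt_tau, asd$observer$rt_tau)
  expect_lt(nt$gaze$spread_px, asd$gaze$spread_px)
  ok_rt <- ok_cov <- 0
  for (s in 1:10) {
    gt <- make_ground_truth_map(2, seed = s)
    st <- stimulus("s", K = 2, category = "texture")
    mk_rt <- function(p) {
      b <- simulate_observer_block(
        observer_params(gt, rt_alpha = p$observer$rt_alpha,
                        rt_tau = p$observer$rt_tau, seed = 400 + s), st,
        n_trials = 225)
      stats::median(filter_rts(tibble::as_tibble(b))$rt_s)
    }
    ok_rt <- ok_rt + (mk_rt(nt) < mk_rt(asd))
    cov_nt <- coverage(clean_gaze(simulate_gaze(
      nt$gaze$duration_s, nt$gaze$spread_px, seed = 500 + s)), 5)
    cov_as <- coverage(clean_gaze(simulate_gaze(
      asd$gaze$duration_s, asd$gaze$spread_px, seed = 500 + s)), 5)
    ok_cov <- ok_cov + (cov_as > cov_nt)
  }
  expect_gte(ok_rt, 9)
  expect_gte(ok_cov, 9)
})
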