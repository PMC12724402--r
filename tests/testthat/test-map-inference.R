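test_that("trial schedule follows cells * (K - 1)", {
  expect_identical(trial_schedule(2), 225L)
  expect_identical(trial_schedule(3), 450L)
  expect_identical(trial_schedule(4), 675L)
  expect_identical(trial_schedule(5), 900L)
  expect_identical(trial_schedule(3, 10, 10), 200L)
  expect_error(trial_schedule(1), "2..5")
  expect_error(trial_schedule(6), "2..5")
})

test_that("pixels map to half-open grid cells with closed outer edge", {
  st <- stimulus("s", 256, 256, K = 2)
  expect_equal(cue_to_cell(0, 0, st)[1, ],
               tibble::tibble(cell_row = 0L, cell_col = 0L, cell = 1L))
  c2 <- cue_to_cell(255, 255, st)
  expect_equal(c(c2$cell_row, c2$cell_col), c(14L, 14L))
  expect_equal(cue_to_cell(128, 0, st)$cell_col, 7L)
  expect_error(cue_to_cell(256, 0, st), "outside")
  expect_error(cue_to_cell(-1, 0, st), "outside")
})

test_that("cue-pair schedules are balanced, distinct, and reproducible", {
  st <- stimulus("s", K = 2)
  p <- generate_cue_pairs(225, st, seed = 4)
  expect_equal(nrow(p), 225)
  expect_true(all(p$cell_a != p$cell_b))
  counts <- tabulate(c(p$cell_a, p$cell_b), 225)
  expect_lte(max(counts) - min(counts), 2)
  expect_identical(p, generate_cue_pairs(225, st, seed = 4))
  expect_false(identical(p, generate_cue_pairs(225, st, seed = 5)))
  p1 <- generate_cue_pairs(1, st, seed = 1)
  expect_equal(nrow(p1), 1)
  expect_true(p1$cell_a != p1$cell_b)
})

test_that("a noiseless observer's map is recovered almost exactly", {
  fx <- sim_block(K = 2, seed = 3, certainty = 1, lapse = 0, n_mult = 3)
  fit <- fit_prob_map(fx$block, fit_config(seed = 7))
  expect_true(fit$converged)
  expect_true(all(abs(rowSums(fit$pmap$probs) - 1) < 1e-9))
  agree <- match_labels(argmax_map(fit$pmap), fx$gt)$agreement
  expect_gte(agree, 0.95)
  # consistency against the true map is exactly zero without noise
  expect_equal(classify_consistency(fx$block, fx$gt)$rate, 0)
})

test_that("all-same responses collapse to a single-label map", {
  fx <- sim_block(K = 2, seed = 5, n_mult = 1)
  trials <- tibble::as_tibble(fx$block)
  trials$response <- "same"
  blk <- block_data(trials, "p1", "NT", fx$stim)
  fit <- fit_prob_map(blk, fit_config(seed = 1))
  expect_equal(length(unique(argmax_map(fit$pmap)$labels)), 1L)
})

test_that("the fitted map is stable under relabeled initializations", {
  fx <- sim_block(K = 2, seed = 9, n_mult = 2)
  segs <- lapply(1:5, function(s) {
    argmax_map(fit_prob_map(fx$block, fit_config(seed = s))$pmap)
  })
  for (i in 2:5) {
    expect_gte(match_labels(segs[[i]], segs[[1]])$agreement, 0.95)
  }
})

test_that("parameter recovery holds across seeds and K", {
  agree <- vapply(1:8, function(s) {
    K <- 2L + (s %% 2L)
    fx <- sim_block(K = K, seed = 200 + s, n_mult = 2)
    match_labels(argmax_map(fit_prob_map(fx$block,
                                         fit_config(seed = s))$pmap),
                 fx$gt)$agreement
  }, numeric(1))
  expect_gte(median(agree), 0.85)
})

test_that("consistency classification matches the response/map contract", {
  st <- stimulus("s", K = 2)
  seg <- half_map()
  trials <- tibble::tibble(
    trial_index = 1:4,
    cue_a_x = c(10, 10, 10, 200), cue_a_y = c(10, 10, 10, 10),
    cue_b_x = c(30, 30, 200, 240), cue_b_y = c(30, 30, 10, 10),
    response = c("different", "same", "different", "different"),
    rt_s = rep(0.5, 4)
  )
  blk <- block_data(trials, "p1", "NT", st)
  cc <- classify_consistency(blk, seg)
  # trials 1-2: both cues left half (same segment)
  expect_equal(cc$trials$consistent, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(cc$rate, 0.5)
})

test_that("inconsistency rate is monotone in lapse", {
  rates <- vapply(c(0, 0.2, 0.4), function(lp) {
    fx <- sim_block(K = 2, seed = 31, certainty = 1, lapse = lp, n_mult = 1)
    classify_consistency(fx$block, fx$gt)$rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
})

test_that("pooled inconsistency counts reproduce the published-style rate", {
  expect_equal(round(inconsistency_rate(c(21453, 14122),
                                        c(60722, 39521)), 2), 0.35)
})

test_that("response shuffling preserves marginals and is seeded", {
  fx <- sim_block(K = 2, seed = 13, n_mult = 1)
  s1 <- shuffle_responses(fx$block, seed = 5)
  s2 <- shuffle_responses(fx$block, seed = 5)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_equal(sort(table(s1$response)), sort(table(fx$block$response)))
  expect_identical(s1$cue_a_x, fx$block$cue_a_x)
  expect_identical(s1$rt_s, fx$block$rt_s)
  # identical responses: shuffling is a no-op
  trials <- tibble::as_tibble(fx$block)
  trials$response <- "same"
  blk <- block_data(trials, "p1", "NT", fx$stim)
  expect_identical(shuffle_responses(blk, seed = 3)$response,
                   blk$response)
})

test_that("structureless blocks are flagged, genuine segmenters are not", {
  fx <- sim_block(K = 2, seed = 21, n_mult = 2)
  good <- flag_structureless_block(fx$block, fit_config(seed = 2),
                                   n_perm = 199, seed = 50)
  expect_false(good$flagged)
  shuf <- shuffle_responses(fx$block, seed = 99)
  bad <- flag_structureless_block(shuf, fit_config(seed = 2),
                                  n_perm = 199, seed = 50)
  expect_true(bad$flagged)
  expect_gt(bad$p_value, 0.05)
})

test_that("a degenerate single-label map is flagged without refitting", {
  fx <- sim_block(K = 2, seed = 5, n_mult = 1)
  trials <- tibble::as_tibble(fx$block)
  trials$response <- "same"
  blk <- block_data(trials, "p1", "NT", fx$stim)
  fl <- flag_structureless_block(blk, fit_config(seed = 1), n_perm = 19,
                                 seed = 1)
  expect_true(fl$flagged)
})

test_that("block exclusion percentages compute as printed", {
  expect_equal(round(exclusion_percent(4, 143), 1), 2.8)
  expect_equal(round(exclusion_percent(9, 76), 1), 11.8)
})
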