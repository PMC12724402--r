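# Fixtures built in code; everything is seeded.

# A 15x15 two-label map split into left/right halves.
half_map <- function(grid_h = 15L, grid_w = 15L) {
  cols <- rep(seq_len(grid_w), times = grid_h)
  seg_map(ifelse(cols <= grid_w / 2, 1L, 2L), grid_h, grid_w, K = 2L)
}

# Random prob map with valid rows.
random_pmap <- function(grid_h = 5L, grid_w = 5L, K = 3L, seed = 1L) {
  withr::with_seed(seed, {
    p <- matrix(stats::rexp(grid_h * grid_w * K), grid_h * grid_w, K)
    prob_seg_map(p / rowSums(p), grid_h, grid_w)
  })
}

# Brute-force MI oracle: explicit double sum over the joint histogram.
mi_bruteforce <- function(la, lb) {
  n <- length(la)
  ua <- sort(unique(la))
  ub <- sort(unique(lb))
  mi <- 0
  for (a in ua) {
    for (b in ub) {
      pab <- sum(la == a & lb == b) / n
      if (pab > 0) {
        mi <- mi + pab * log2(pab / ((sum(la == a) / n) * (sum(lb == b) / n)))
      }
    }
  }
  mi
}

sim_block <- function(K = 2L, seed = 1L, certainty = 0.85, lapse = 0.05,
                      n_mult = 2, cohort = "NT") {
  gt <- make_ground_truth_map(K, seed = seed)
  op <- observer_params(gt, certainty = certainty, lapse = lapse,
                        seed = seed + 1000L)
  st <- stimulus(paste0("fix", K), K = K, category = "texture")
  blk <- simulate_observer_block(op, st,
                                 n_trials = round(n_mult * trial_schedule(K)),
                                 cohort = cohort)
  list(gt = gt, block = blk, stim = st)
}

# Small epoch set with a known posterior bump, light noise.
sim_small_epochs <- function(cohort = "NT", seed = 1L, n_epochs = 12L,
                             noise_rms = 4) {
  pr <- cohort_preset(cohort)$eeg
  pr$n_epochs <- as.integer(n_epochs)
  pr$noise_rms_uv <- noise_rms
  pr$seed <- as.integer(seed)
  rts <- withr::with_seed(seed + 7L,
                          stats::rlnorm(n_epochs, log(0.5), 0.3))
  simulate_epochs(pr, rts, cohort = cohort)
}

opo_channels <- c("O1", "Oz", "O2", "PO7", "PO3", "POz", "PO4", "PO8")
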