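#' 64-channel scalp layout
#'
#' A BioSemi-style 64-channel 10-20 layout with 2-D positions on the unit
#' head disk (nose up, left negative x). Positions are schematic — derived
#' from the row/column structure of the electrode names — and are intended
#' for simulation, posterior weighting, and adjacency, not for source
#' analysis.
#'
#' @return a tibble `channel`, `x`, `y`.
#' @export
channel_layout_64 <- function() {
  nm <- c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
          "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
          "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
          "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
          "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
          "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
          "P10", "PO8", "PO4", "O2")
  row_y <- c(Fp = 0.85, AF = 0.70, F = 0.50, FT = 0.25, FC = 0.25, C = 0,
             T = 0, TP = -0.25, CP = -0.25, P = -0.50, PO = -0.70,
             O = -0.85, I = -0.95)
  col_x <- c("0" = 0, "1" = 0.20, "2" = 0.20, "3" = 0.40, "4" = 0.40,
             "5" = 0.62, "6" = 0.62, "7" = 0.85, "8" = 0.85, "9" = 1.0,
             "10" = 1.0)
  prefix <- gsub("[0-9z]+$", "", nm)
  digit <- gsub("^[A-Za-z]*?([0-9]*)z?$", "\\1", nm)
  y <- unname(row_y[prefix])
  xm <- ifelse(digit == "", 0, unname(col_x[digit]))
  xm[prefix %in% c("T")] <- 1.0
  side <- ifelse(digit == "", 0,
                 ifelse(as.integer(ifelse(digit == "", "0", digit)) %% 2 == 1,
                        -1, 1))
  x <- side * xm * sqrt(pmax(1 - 0.72 * y^2, 0.05))
  tibble::tibble(channel = nm, x = x, y = y)
}

#' Seeded ground-truth segmentation map
#'
#' Generates a spatially compact K-region partition of the analysis grid by
#' a Voronoi tessellation over randomly placed sites, guaranteeing every
#' label is present.
#'
#' @param K number of segments (2..5).
#' @param grid_h,grid_w grid dimensions.
#' @param seed integer seed.
#' @return a [seg_map()].
#' @export
make_ground_truth_map <- function(K, grid_h = 15L, grid_w = 15L, seed = 1L) {
  K <- as.integer(K)
  if (K < 2L || K > 5L) stop("K must be in 2..5", call. = FALSE)
  if (grid_h * grid_w < K) stop("grid too small for K regions",
                                call. = FALSE)
  withr::with_seed(seed, {
    for (try in seq_len(100)) {
      sites <- cbind(stats::runif(K, 0, grid_h), stats::runif(K, 0, grid_w))
      cells <- map_cell_index(grid_h, grid_w)
      d <- outer(cells$row + 0.5, sites[, 1], `-`)^2 +
        outer(cells$col + 0.5, sites[, 2], `-`)^2
      labels <- max.col(-d, ties.method = "first")
      if (length(unique(labels)) == K) {
        return(seg_map(labels, grid_h, grid_w, K = K))
      }
    }
    stop("failed to place K non-empty regions", call. = FALSE)
  })
}

#' Synthetic oriented-noise texture stimulus
#'
#' Renders a texture image from a region partition: a single white Gaussian
#' noise image is band-pass filtered with a spatially dependent oriented
#' filter, giving each region a controlled dominant orientation and spatial
#' frequency while keeping seams continuous (region masks are smoothed
#' before compositing).
#'
#' @param partition a [seg_map()] defining the regions.
#' @param orientation_deg stripe orientation per region (degrees).
#' @param freq_cpi centre spatial frequency per region (cycles per image).
#' @param size image side in pixels (default 256).
#' @param bw_freq,bw_theta_deg frequency / orientation bandwidths.
#' @param seam_sigma region-mask smoothing in pixels.
#' @param seed integer seed.
#' @return `size` x `size` numeric matrix (zero mean, unit variance).
#' @export
make_texture_stimulus <- function(partition, orientation_deg, freq_cpi,
                                  size = 256L, bw_freq = 8,
                                  bw_theta_deg = 12, seam_sigma = 3,
                                  seed = 1L) {
  stopifnot(inherits(partition, "seg_map"))
  K <- partition$K
  if (length(orientation_deg) != K || length(freq_cpi) != K) {
    stop("need one orientation and frequency per region", call. = FALSE)
  }
  if (any(freq_cpi <= 0) || any(freq_cpi >= size / 2)) {
    stop("frequencies must lie in (0, size/2) cycles per image",
         call. = FALSE)
  }
  lab_px <- matrix(partition$labels, partition$grid_h, partition$grid_w,
                   byrow = TRUE)
  ri <- pmin(floor(seq(0, partition$grid_h - 1e-9,
                       length.out = size)) + 1L, partition$grid_h)
  ci <- pmin(floor(seq(0, partition$grid_w - 1e-9,
                       length.out = size)) + 1L, partition$grid_w)
  lab_px <- lab_px[ri, ci]

  f1 <- c(0:(size / 2), -(size / 2 - 1):-1)  # cycles per image
  fx <- matrix(f1, size, size, byrow = TRUE)
  fy <- matrix(f1, size, size)
  rho <- sqrt(fx^2 + fy^2)
  ang <- atan2(fy, fx)  # spectral angle

  noise <- withr::with_seed(seed, matrix(stats::rnorm(size^2), size, size))
  NF <- stats::fft(noise)
  Ky <- gauss_band_matrix(size, seam_sigma)
  Ky <- sweep(Ky, 2, colSums(Ky), "/")

  img <- matrix(0, size, size)
  for (k in seq_len(K)) {
    phi <- (orientation_deg[k] + 90) * pi / 180  # spectral orientation
    dth <- atan2(sin(2 * (ang - phi)), cos(2 * (ang - phi))) / 2
    H <- exp(-(rho - freq_cpi[k])^2 / (2 * bw_freq^2)) *
      exp(-dth^2 / (2 * (bw_theta_deg * pi / 180)^2))
    Fk <- Re(stats::fft(NF * H, inverse = TRUE)) / size^2
    Fk <- Fk / stats::sd(Fk)
    mask <- Ky %*% (lab_px == k) %*% t(Ky)
    img <- img + mask * Fk
  }
  (img - mean(img)) / stats::sd(img)
}

#' Synthetic observer parameters
#'
#' The observer model behind the same/different trials: each cue
#' independently samples a label for its grid cell (the true label with
#' probability `certainty`, the remaining labels uniformly), responds
#' "same" iff the two sampled labels match, and with probability `lapse`
#' replaces the response by a fair coin. Reaction times follow the
#' learning curve `rt_alpha * 2^(-t / rt_tau)` with multiplicative
#' lognormal noise.
#'
#' @param ground_truth a [seg_map()].
#' @param certainty probability mass on the true label (in `[1/K, 1]`).
#' @param lapse probability of a random response.
#' @param rt_alpha RT scale at t = 0 (seconds).
#' @param rt_tau trial constant (trials to halve RT).
#' @param rt_noise_sd lognormal noise sd (log scale).
#' @param seed integer seed.
#' @return an `observer_params` list.
#' @export
observer_params <- function(ground_truth, certainty = 0.85, lapse = 0.05,
                            rt_alpha = 0.9, rt_tau = 18.4,
                            rt_noise_sd = 0.1, seed = 1L) {
  stopifnot(inherits(ground_truth, "seg_map"))
  if (certainty < 1 / ground_truth$K || certainty > 1) {
    stop("certainty must lie in [1/K, 1]", call. = FALSE)
  }
  if (lapse < 0 || lapse > 1) stop("lapse must lie in [0, 1]", call. = FALSE)
  structure(list(ground_truth = ground_truth, certainty = certainty,
                 lapse = lapse, rt_alpha = rt_alpha, rt_tau = rt_tau,
                 rt_noise_sd = rt_noise_sd, seed = as.integer(seed)),
            class = "observer_params")
}

#' Simulate one experimental block from a synthetic observer
#'
#' Generates a balanced cue-pair schedule and plays it through the
#' observer model in [observer_params()].
#'
#' @param params an [observer_params()].
#' @param stim a [stimulus()] with K matching the ground truth.
#' @param n_trials number of trials (default: the [trial_schedule()] for
#'   K).
#' @param participant_id,cohort metadata for the block.
#' @return a [block_data()] block.
#' @export
simulate_observer_block <- function(params, stim = NULL, n_trials = NULL,
                                    participant_id = "sim1",
                                    cohort = "NT") {
  stopifnot(inherits(params, "observer_params"))
  gt <- params$ground_truth
  if (is.null(stim)) {
    stim <- stimulus("sim-stim", K = gt$K,
                     category = "texture")
  }
  if (stim$K != gt$K) stop("stimulus K must match the ground truth",
                           call. = FALSE)
  n_trials <- n_trials %||% trial_schedule(gt$K, gt$grid_h, gt$grid_w)
  pairs <- generate_cue_pairs(n_trials, stim, gt$grid_h, gt$grid_w,
                              seed = params$seed)
  K <- gt$K
  withr::with_seed(params$seed + 1L, {
    sample_label <- function(true_lab) {
      n <- length(true_lab)
      hit <- stats::runif(n) < params$certainty
      other <- (true_lab - 1L +
                  sample.int(K - 1L, n, replace = TRUE)) %% K + 1L
      ifelse(hit, true_lab, other)
    }
    la <- sample_label(gt$labels[pairs$cell_a])
    lb <- sample_label(gt$labels[pairs$cell_b])
    resp <- ifelse(la == lb, "same", "different")
    lapse_hit <- stats::runif(n_trials) < params$lapse
    coin <- sample(c("same", "different"), n_trials, replace = TRUE)
    resp[lapse_hit] <- coin[lapse_hit]
    t <- pairs$trial_index
    rt <- params$rt_alpha * 2^(-t / params$rt_tau) *
      exp(stats::rnorm(n_trials, sd = params$rt_noise_sd))
    trials <- dplyr::mutate(
      pairs[c("trial_index", "cue_a_x", "cue_a_y", "cue_b_x", "cue_b_y")],
      response = resp, rt_s = rt
    )
    block_data(trials, participant_id, cohort, stim)
  })
}

#' Simulate a fixation-and-saccade gaze stream
#'
#' Fixation centers are drawn from an isotropic Gaussian around the image
#' center with dispersion `spread`; consecutive fixations are joined by
#' constant-velocity saccades, and the stream is sampled at 500 Hz with
#' small within-fixation jitter — as an eye tracker would record it,
#' saccade samples included. Wider spread therefore yields both more
#' dispersed fixations and longer saccade paths, and so greater image
#' coverage.
#'
#' @param duration_s total viewing duration in seconds.
#' @param spread_px fixation-center dispersion in pixels
#'   (cohort-dependent).
#' @param n_fixations number of fixations; default is a typical
#'   free-viewing rate of 3 per second.
#' @param width,height image size in pixels.
#' @param jitter_px within-fixation sample jitter (sd, pixels).
#' @param blink_rate fraction of samples marked invalid.
#' @param saccade_v_px_s saccade velocity (pixels per second).
#' @param srate sampling rate (default 500 Hz).
#' @param seed integer seed.
#' @return a gaze tibble `t_s`, `x_px`, `y_px`, `valid`.
#' @export
simulate_gaze <- function(duration_s, spread_px = 55, n_fixations = NULL,
                          width = 256L, height = 256L, jitter_px = 1,
                          blink_rate = 0.02, saccade_v_px_s = 3000,
                          srate = 500, seed = 1L) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  withr::with_seed(seed, {
    n_fix <- max(1L, as.integer(n_fixations %||% round(3 * duration_s)))
    cx <- (width - 1) / 2
    cy <- (height - 1) / 2
    fx <- pmin(pmax(stats::rnorm(n_fix, cx, spread_px), 0), width - 1)
    fy <- pmin(pmax(stats::rnorm(n_fix, cy, spread_px), 0), height - 1)

    # saccade time is set by path length; fixations share the remainder
    dist <- if (n_fix > 1) sqrt(diff(fx)^2 + diff(fy)^2) else numeric(0)
    sac_dur <- dist / saccade_v_px_s
    sac_total <- min(sum(sac_dur), 0.3 * duration_s)
    if (sum(sac_dur) > 0) sac_dur <- sac_dur * sac_total / sum(sac_dur)
    share <- stats::rexp(n_fix) + 0.1
    fix_dur <- share / sum(share) * (duration_s - sac_total)

    # piecewise timeline: fixation 1, saccade 1, fixation 2, ...
    seg_dur <- c(rbind(fix_dur, c(sac_dur, 0)))[seq_len(2 * n_fix - 1)]
    seg_end <- cumsum(seg_dur)
    n_samp <- max(1L, round(duration_s * srate))
    t_s <- (seq_len(n_samp) - 1L) / srate
    seg <- findInterval(t_s, seg_end, left.open = TRUE) + 1L
    seg <- pmin(seg, length(seg_dur))
    fix_of <- (seg + 1L) %/% 2L          # fixation index for odd segments
    is_sac <- seg %% 2L == 0L
    x <- fx[fix_of]
    y <- fy[fix_of]
    if (any(is_sac)) {
      i <- seg[is_sac] %/% 2L            # saccade i joins fixation i, i+1
      t0 <- c(0, seg_end)[seg[is_sac]]
      frac <- (t_s[is_sac] - t0) / pmax(seg_dur[seg[is_sac]], 1e-9)
      frac <- pmin(pmax(frac, 0), 1)
      x[is_sac] <- fx[i] + frac * (fx[i + 1L] - fx[i])
      y[is_sac] <- fy[i] + frac * (fy[i + 1L] - fy[i])
    }
    tibble::tibble(
      t_s = t_s,
      x_px = pmin(pmax(x + stats::rnorm(n_samp, sd = jitter_px), 0),
                  width - 1e-9),
      y_px = pmin(pmax(y + stats::rnorm(n_samp, sd = jitter_px), 0),
                  height - 1e-9),
      valid = stats::runif(n_samp) >= blink_rate
    )
  })
}

#' EEG simulation parameters
#'
#' Defines the evoked components and noise model for [simulate_epochs()].
#' Components are Gaussian bumps in time, weighted across channels by a
#' posterior (occipital) scalp profile; noise is 1/f-shaped with a white
#' floor.
#'
#' @param components tibble `latency_ms`, `amplitude_uv`, `width_ms`.
#' @param channels channel layout (default [channel_layout_64()]).
#' @param n_epochs epochs per block.
#' @param srate sampling rate, Hz.
#' @param t_range_ms epoch window.
#' @param noise_rms_uv total noise RMS per sample.
#' @param noise_slope spectral slope of the 1/f component.
#' @param white_frac fraction of noise power in the white floor.
#' @param posterior_center,posterior_width center (x, y) and width of the
#'   posterior weighting profile on the unit head disk.
#' @param seed integer seed.
#' @return an `eeg_sim_params` list.
#' @export
eeg_sim_params <- function(components = tibble::tibble(
                             latency_ms = c(200, 350),
                             amplitude_uv = c(1.5, 6),
                             width_ms = c(40, 60)),
                           channels = channel_layout_64(),
                           n_epochs = 40L, srate = 512,
                           t_range_ms = c(-500, 1000),
                           noise_rms_uv = 8, noise_slope = 1,
                           white_frac = 0.3,
                           posterior_center = c(0, -0.8),
                           posterior_width = 0.4, seed = 1L) {
  if (any(components$latency_ms < t_range_ms[1] |
          components$latency_ms > t_range_ms[2])) {
    stop("component latencies must lie inside the epoch", call. = FALSE)
  }
  if (any(!is.finite(components$amplitude_uv))) {
    stop("component amplitudes must be finite", call. = FALSE)
  }
  structure(list(components = components, channels = channels,
                 n_epochs = as.integer(n_epochs), srate = srate,
                 t_range_ms = t_range_ms, noise_rms_uv = noise_rms_uv,
                 noise_slope = noise_slope, white_frac = white_frac,
                 posterior_center = posterior_center,
                 posterior_width = posterior_width,
                 seed = as.integer(seed)),
            class = "eeg_sim_params")
}

# 1/f + white noise, one column per series; scaled to unit RMS.
colored_noise <- function(n, n_series, slope, white_frac) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k)
  amp <- sqrt((1 - white_frac) / pmax(f, 1)^slope + white_frac)
  amp[1] <- 0  # no DC
  ph <- matrix(stats::runif(n * n_series, 0, 2 * pi), n, n_series)
  spec <- amp * exp(1i * ph)
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n
  sweep(x, 2, sqrt(colMeans(x^2)), "/")
}

#' Simulate an epoch set with posterior evoked components
#'
#' Each epoch is the sum of the deterministic evoked components (identical
#' across epochs) and seeded 1/f-plus-white channel noise. Cohort presets
#' differ by a latency shift and an amplitude ratio of the components.
#'
#' @param params an [eeg_sim_params()].
#' @param rt_s per-epoch reaction times (length `n_epochs`).
#' @param cohort,participant_id,block_id metadata.
#' @return an [epoch_set()].
#' @export
simulate_epochs <- function(params, rt_s, cohort = "NT",
                            participant_id = "sim1", block_id = "b1") {
  stopifnot(inherits(params, "eeg_sim_params"))
  if (length(rt_s) != params$n_epochs) {
    stop("need one reaction time per epoch", call. = FALSE)
  }
  times_ms <- seq(params$t_range_ms[1], params$t_range_ms[2],
                  by = 1000 / params$srate)
  n_t <- length(times_ms)
  ch <- params$channels
  n_ch <- nrow(ch)
  wgt <- exp(-((ch$x - params$posterior_center[1])^2 +
                 (ch$y - params$posterior_center[2])^2) /
               (2 * params$posterior_width^2))
  sig_t <- rowSums(vapply(seq_len(nrow(params$components)), function(i) {
    co <- params$components[i, ]
    co$amplitude_uv * exp(-(times_ms - co$latency_ms)^2 /
                            (2 * co$width_ms^2))
  }, numeric(n_t)))
  signal <- outer(wgt, sig_t)  # channels x time

  data <- withr::with_seed(params$seed, {
    arr <- array(0, dim = c(n_ch, n_t, params$n_epochs))
    for (e in seq_len(params$n_epochs)) {
      noise <- t(colored_noise(n_t, n_ch, params$noise_slope,
                               params$white_frac)) * params$noise_rms_uv
      arr[, , e] <- signal + noise
    }
    arr
  })
  epoch_set(data, ch, times_ms, rt_s, srate = params$srate,
            cohort = cohort, participant_id = participant_id,
            block_id = block_id)
}

#' Cohort parameter presets for the synthetic generators
#'
#' Bundles the study conditions emulated by the generators: the NT-like
#' preset has a faster RT learning curve, narrower gaze spread, and an
#' earlier/larger posterior evoked component than the ASD-like preset
#' (latency +75 ms, amplitude x0.7, slower RTs, wider gaze spread).
#'
#' @param cohort `"NT"` or `"ASD"`.
#' @param seed integer seed threaded into the sub-generators.
#' @return a list with `observer` (certainty/lapse/RT parameters), `gaze`
#'   (spread, duration), and `eeg` (an [eeg_sim_params()]).
#' @export
cohort_preset <- function(cohort = c("NT", "ASD"), seed = 1L) {
  cohort <- match.arg(cohort)
  asd <- cohort == "ASD"
  comp <- tibble::tibble(
    latency_ms = c(200, 350) + if (asd) 75 else 0,
    amplitude_uv = c(1.5, 6) * if (asd) 0.7 else 1,
    width_ms = c(40, 60)
  )
  list(
    cohort = cohort,
    observer = list(certainty = 0.85, lapse = 0.05,
                    rt_alpha = if (asd) 1.2 else 0.9,
                    rt_tau = if (asd) 21.9 else 18.4,
                    rt_noise_sd = 0.1),
    gaze = list(spread_px = if (asd) 85 else 55,
                duration_s = if (asd) 10.5 else 9),
    eeg = eeg_sim_params(components = comp, seed = seed)
  )
}
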