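#' Epoched multichannel EEG container
#'
#' Holds cleaned, epoched EEG for one block: a channels x time x epochs
#' array in microvolts, channel names with 2-D scalp positions, the time
#' axis, and the per-epoch reaction times used for attention-based epoch
#' exclusion. Raw-acquisition preprocessing (filtering, artifact removal,
#' epoch repair) is assumed already done upstream.
#'
#' @param data numeric array channels x time x epochs (microvolts).
#' @param channels tibble with `channel`, `x`, `y` (2-D scalp layout,
#'   nose-up, unit head radius).
#' @param times_ms time axis in ms relative to trial onset.
#' @param rt_s per-epoch reaction times in seconds.
#' @param srate sampling rate in Hz (default 512).
#' @param cohort,participant_id,block_id metadata keys.
#' @return an `epoch_set`.
#' @export
epoch_set <- function(data, channels, times_ms, rt_s, srate = 512,
                      cohort = "NT", participant_id = "p1",
                      block_id = "b1") {
  data <- unclass(data)
  if (length(dim(data)) != 3L) {
    stop("`data` must be a channels x time x epochs array", call. = FALSE)
  }
  channels <- tibble::as_tibble(channels)
  if (dim(data)[1] != nrow(channels)) {
    stop("channel metadata does not match the data's first dimension",
         call. = FALSE)
  }
  if (dim(data)[2] != length(times_ms)) {
    stop("time axis does not match the data's second dimension",
         call. = FALSE)
  }
  if (dim(data)[3] != length(rt_s)) {
    stop("need one reaction time per epoch", call. = FALSE)
  }
  if (any(rt_s <= 0)) stop("reaction times must be positive", call. = FALSE)
  structure(list(data = data, channels = channels,
                 times_ms = as.numeric(times_ms), rt_s = as.numeric(rt_s),
                 srate = srate, cohort = cohort,
                 participant_id = participant_id, block_id = block_id),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %s/%s (%s): %d channels x %d samples x %d epochs @ %g Hz\n",
    x$participant_id, x$block_id, x$cohort, d[1], d[2], d[3], x$srate))
  cat(sprintf("  time %g..%g ms\n", min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Exclude epochs with unusually long reaction times
#'
#' Two-stage exclusion, in order: first the slowest 10 percent of reaction
#' times (`ceiling(0.1 * n)` epochs, ties broken by epoch order), then any
#' remaining epoch with RT above the hard cap.
#'
#' @param epochs an [epoch_set()].
#' @param slow_frac fraction excluded in stage one (default 0.1).
#' @param rt_cap hard reaction-time cap in seconds (default 2.5).
#' @return the reduced `epoch_set`.
#' @export
exclude_by_rt <- function(epochs, slow_frac = 0.1, rt_cap = 2.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- length(epochs$rt_s)
  n_drop <- ceiling(slow_frac * n)
  ord <- order(epochs$rt_s, seq_len(n), decreasing = TRUE)
  keep <- setdiff(seq_len(n), ord[seq_len(n_drop)])
  keep <- keep[epochs$rt_s[keep] <= rt_cap]
  if (length(keep) == 0L) stop("all epochs excluded by reaction time",
                               call. = FALSE)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$rt_s <- epochs$rt_s[keep]
  epochs
}

#' Re-reference epochs to the global average
#'
#' Subtracts the mean over all channels at every time point of every epoch,
#' so the channel mean is 0 everywhere.
#'
#' @param epochs an [epoch_set()].
#' @return the re-referenced `epoch_set`.
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (dim(epochs$data)[1] < 2L) stop("need at least 2 channels",
                                     call. = FALSE)
  mu <- apply(epochs$data, c(2, 3), mean)
  epochs$data <- epochs$data - rep(mu, each = dim(epochs$data)[1])
  epochs
}

#' Baseline-correct epochs against a pre-stimulus window
#'
#' Per channel and epoch, subtracts the mean amplitude within the baseline
#' window (default -100..0 ms; a -25..0 ms window avoids contamination by
#' the previous trial's response when inter-trial intervals are short).
#'
#' @param epochs an [epoch_set()].
#' @param window length-2 numeric, baseline window in ms.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$times_ms >= window[1] & epochs$times_ms <= window[2]
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  d <- dim(epochs$data)
  base <- apply(epochs$data[, sel, , drop = FALSE], c(1, 3), mean)
  epochs$data <- epochs$data -
    aperm(array(base, dim = c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs
}

#' Event-related potential from an epoch set
#'
#' Averages across epochs; optionally restricts to (and averages over) a
#' named channel subset, e.g. the occipital/parieto-occipital cluster
#' `c("O1","Oz","O2","PO7","PO3","POz","PO4","PO8")`.
#'
#' @param epochs an [epoch_set()].
#' @param channels optional character vector of channel names to keep; if
#'   `collapse = TRUE` they are averaged into a single trace.
#' @param collapse average the channel subset into one trace?
#' @return an `erp` object: `data` (channels x time matrix), `channels`,
#'   `times_ms`, `n_epochs`, `cohort`, `participant_id`.
#' @export
compute_erp <- function(epochs, channels = NULL, collapse = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  M <- apply(epochs$data, c(1, 2), mean)
  chan <- epochs$channels
  if (!is.null(channels)) {
    idx <- match(channels, chan$channel)
    if (anyNA(idx)) {
      stop("unknown channels: ",
           paste(channels[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    if (length(idx) == 0L) stop("empty channel subset", call. = FALSE)
    M <- M[idx, , drop = FALSE]
    chan <- chan[idx, , drop = FALSE]
    if (collapse) {
      M <- matrix(colMeans(M), 1L, ncol(M))
      chan <- tibble::tibble(channel = "subset_mean",
                             x = mean(chan$x), y = mean(chan$y))
    }
  }
  structure(list(data = M, channels = chan, times_ms = epochs$times_ms,
                 n_epochs = dim(epochs$data)[3], cohort = epochs$cohort,
                 participant_id = epochs$participant_id),
            class = "erp")
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp> %d channels x %d samples (mean of %d epochs, %s)\n",
              nrow(x$data), ncol(x$data), x$n_epochs, x$cohort))
  invisible(x)
}

#' Equal-weight average of ERPs
#'
#' Aggregates block-level ERPs up the hierarchy (block to participant to
#' cohort) with equal weight per unit, so participants with more blocks do
#' not dominate cohort averages.
#'
#' @param erps list of `erp` objects on identical channel/time axes.
#' @return an `erp` whose `n_epochs` is the number of units averaged.
#' @export
average_erps <- function(erps) {
  stopifnot(length(erps) >= 1L)
  M <- Reduce(`+`, lapply(erps, `[[`, "data")) / length(erps)
  out <- erps[[1]]
  out$data <- M
  out$n_epochs <- length(erps)
  out
}

#' @rdname compute_erp
#' @param x an `erp`.
#' @param ... unused.
#' @export
tidy.erp <- function(x, ...) {
  tibble::tibble(
    channel = rep(x$channels$channel, times = ncol(x$data)),
    time_ms = rep(x$times_ms, each = nrow(x$data)),
    amplitude_uv = as.vector(x$data)
  )
}

# Welch two-sample t-test, vectorized over columns of unit x value
# matrices. Degenerate variance at a point yields p = 1.
welch_cols <- function(A, B) {
  nA <- nrow(A)
  nB <- nrow(B)
  mA <- colMeans(A)
  mB <- colMeans(B)
  vA <- apply(A, 2, stats::var)
  vB <- apply(B, 2, stats::var)
  se2 <- vA / nA + vB / nB
  t <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(t), df)
  bad <- !is.finite(t) | !is.finite(p)
  t[bad] <- 0
  p[bad] <- 1
  list(t = t, p = p, df = df)
}

#' Pointwise two-sample t-test significance windows
#'
#' Runs an independent-samples (Welch) t-test at every time sample between
#' two groups of subject-level ERP traces and returns the contiguous runs
#' of p < alpha lasting at least `min_dur_ms` (shorter runs are discarded
#' to suppress transient fluctuations).
#'
#' @param group_a,group_b numeric matrices, one row per unit (subject), one
#'   column per time sample; or lists of single-trace `erp` objects.
#' @param times_ms shared time axis (taken from the ERPs if lists given).
#' @param alpha pointwise significance level.
#' @param min_dur_ms minimum run duration in ms (default 50).
#' @return a tibble of windows `start_ms`, `end_ms`, `duration_ms`, with
#'   the full pointwise `t`/`p` series attached as attribute `pointwise`.
#' @export
pointwise_ttest_windows <- function(group_a, group_b, times_ms = NULL,
                                    alpha = 0.05, min_dur_ms = 50) {
  ga <- as_trace_matrix(group_a)
  gb <- as_trace_matrix(group_b)
  times_ms <- times_ms %||% attr(ga, "times_ms") %||% attr(gb, "times_ms")
  if (is.null(times_ms)) stop("supply `times_ms`", call. = FALSE)
  if (nrow(ga$m) < 2L || nrow(gb$m) < 2L) {
    stop("need at least 2 units per group", call. = FALSE)
  }
  w <- welch_cols(ga$m, gb$m)
  sig <- w$p < alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  wins <- tibble::tibble(
    start_ms = times_ms[starts[keep]],
    end_ms = times_ms[ends[keep]]
  )
  wins$duration_ms <- wins$end_ms - wins$start_ms
  wins <- wins[wins$duration_ms >= min_dur_ms, , drop = FALSE]
  attr(wins, "pointwise") <- tibble::tibble(time_ms = times_ms,
                                            t = w$t, p = w$p)
  wins
}

as_trace_matrix <- function(g) {
  if (is.list(g) && !is.data.frame(g) && !is.matrix(g)) {
    m <- do.call(rbind, lapply(g, function(e) {
      stopifnot(inherits(e, "erp"), nrow(e$data) == 1L)
      e$data[1, ]
    }))
    out <- list(m = m)
    attr(out, "times_ms") <- g[[1]]$times_ms
    return(out)
  }
  list(m = as.matrix(g))
}

#' Global Field Power
#'
#' The spatial standard deviation of the scalp potential across all
#' electrodes at each time point,
#' `sqrt(mean((amplitude - mean(amplitude))^2))` (population convention),
#' a reference-free index of overall response strength.
#'
#' @param x an `erp`, an `epoch_set` (epoch mean is taken), or a channels x
#'   time matrix.
#' @return a tibble `time_ms` (sample index if no axis known), `gfp`.
#' @export
gfp <- function(x) {
  if (inherits(x, "epoch_set")) x <- compute_erp(x)
  if (inherits(x, "erp")) {
    M <- x$data
    times_ms <- x$times_ms
  } else {
    M <- as.matrix(x)
    times_ms <- seq_len(ncol(M))
  }
  if (nrow(M) < 2L) stop("need at least 2 channels", call. = FALSE)
  g <- sqrt(colMeans(sweep(M, 2, colMeans(M))^2))
  tibble::tibble(time_ms = times_ms, gfp = g)
}

#' GFP cohort tests at fixed time intervals
#'
#' Samples each participant's GFP series at regular intervals (default
#' every 50 ms, nearest sample) and runs an independent-samples Welch
#' t-test per sampled time. Flags are uncorrected by design.
#'
#' @param group_a,group_b matrices of per-participant GFP series (rows =
#'   participants, columns = time samples).
#' @param times_ms shared time axis in ms.
#' @param step_ms sampling interval (default 50 ms).
#' @param alpha significance level.
#' @return a tibble `time_ms`, `t`, `p`, `significant`.
#' @export
gfp_interval_tests <- function(group_a, group_b, times_ms, step_ms = 50,
                               alpha = 0.05) {
  A <- as.matrix(group_a)
  B <- as.matrix(group_b)
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("need at least 2 participants per group", call. = FALSE)
  }
  targets <- seq(min(times_ms), max(times_ms), by = step_ms)
  idx <- vapply(targets, function(tt) which.min(abs(times_ms - tt)),
                integer(1))
  w <- welch_cols(A[, idx, drop = FALSE], B[, idx, drop = FALSE])
  tibble::tibble(time_ms = times_ms[idx], t = w$t, p = w$p,
                 significant = w$p < alpha)
}

#' Topographic frame at a time point
#'
#' Channel values at the sample nearest the requested time, with a clipped
#' copy for display on a fixed color scale (raw values are retained). For
#' cohort contrasts pass `b` to get an A - B difference frame.
#'
#' @param erp an `erp` (all channels).
#' @param time_ms requested time point (must lie inside the epoch).
#' @param b optional second `erp` for a difference frame.
#' @param clip_uv display clip (default +/- 10 microvolts).
#' @return a tibble `channel`, `x`, `y`, `value_uv`, `display_uv`,
#'   `time_ms`.
#' @export
topomap_frame <- function(erp, time_ms, b = NULL, clip_uv = 10) {
  stopifnot(inherits(erp, "erp"))
  if (time_ms < min(erp$times_ms) || time_ms > max(erp$times_ms)) {
    stop("time point outside the epoch", call. = FALSE)
  }
  i <- which.min(abs(erp$times_ms - time_ms))
  v <- erp$data[, i]
  if (!is.null(b)) v <- v - b$data[, i]
  tibble::tibble(
    channel = erp$channels$channel, x = erp$channels$x, y = erp$channels$y,
    value_uv = v, display_uv = pmin(pmax(v, -clip_uv), clip_uv),
    time_ms = erp$times_ms[i]
  )
}
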