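#' Drop slow-tail trials by the 90th percentile of log reaction times
#'
#' Removes trials whose log-transformed RT lies strictly above the 90th
#' percentile of the log-RT distribution, computed within each block
#' (`by` grouping) by default. Linear interpolation between order statistics
#' is used for the percentile; because the log is monotone, the removed set
#' is invariant to the time unit and to the log base.
#'
#' @param trials a tibble with an `rt_s` column (e.g. a block or a pooled
#'   trial table).
#' @param by character vector of grouping columns defining the distribution
#'   the percentile is taken over; columns absent from `trials` are ignored.
#'   Use `by = character()` for a single pooled distribution.
#' @param prob percentile (default 0.9).
#' @return the filtered tibble (attributes preserved for blocks).
#' @export
filter_rts <- function(trials,
                       by = c("participant_id", "stim_id", "block_id"),
                       prob = 0.9) {
  df <- tibble::as_tibble(trials)
  if (nrow(df) == 0L) return(df)
  by <- intersect(by, names(df))
  keep <- if (length(by) == 0L) {
    df$rt_s <= exp(stats::quantile(log(df$rt_s), prob, type = 7,
                                   names = FALSE))
  } else {
    grp <- interaction(df[by], drop = TRUE)
    thr <- tapply(log(df$rt_s), grp, stats::quantile, probs = prob,
                  type = 7, names = FALSE)
    log(df$rt_s) <= thr[as.character(grp)]
  }
  out <- df[keep, , drop = FALSE]
  if (inherits(trials, "perceptseg_block")) {
    m <- block_meta(trials)
    out <- block_data(out, m$participant_id, m$cohort, m$stimulus)
  }
  out
}

#' Median reaction time with a percentile bootstrap confidence interval
#'
#' Medians are used because RT distributions are right-skewed; the 95%
#' interval is the percentile bootstrap over `n_boot` resamples.
#'
#' @param rt_s numeric vector of reaction times (or any statistic input).
#' @param n_boot bootstrap resamples (default 9999).
#' @param conf confidence level.
#' @param seed integer seed.
#' @return a one-row tibble: `median`, `ci_lo`, `ci_hi`, `n`, `n_boot`.
#' @export
median_rt_ci <- function(rt_s, n_boot = 9999L, conf = 0.95, seed = 1L) {
  rt_s <- sort(rt_s[!is.na(rt_s)])  # order-invariant given the seed
  if (length(rt_s) < 1L) stop("need at least one trial", call. = FALSE)
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stats::median(sample(rt_s, replace = TRUE))
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  tibble::tibble(median = stats::median(rt_s), ci_lo = qs[1], ci_hi = qs[2],
                 n = length(rt_s), n_boot = as.integer(n_boot))
}

#' Z-score reaction times within each participant-by-stimulus block
#'
#' Standardizes RTs so every block has mean 0 and standard deviation 1,
#' removing stimulus- and presentation-specific scale confounds before
#' pooling trials across blocks. Blocks with zero variance (or fewer than
#' 2 trials) cannot be standardized: they are flagged in `z_ok` and their
#' `rt_z` is `NA`.
#'
#' @param trials tibble with `rt_s` and grouping columns.
#' @param by grouping columns defining a block; missing ones are ignored.
#' @return the tibble with `rt_z` and `z_ok` columns added.
#' @export
zscore_by_block <- function(trials,
                            by = c("participant_id", "stim_id", "block_id")) {
  df <- tibble::as_tibble(trials)
  by <- intersect(by, names(df))
  grp <- if (length(by)) interaction(df[by], drop = TRUE) else
    factor(rep(1L, nrow(df)))
  mu <- tapply(df$rt_s, grp, mean)
  sdv <- tapply(df$rt_s, grp, stats::sd)
  g <- as.character(grp)
  ok <- !is.na(sdv[g]) & sdv[g] > 0
  df$rt_z <- ifelse(ok, (df$rt_s - mu[g]) / sdv[g], NA_real_)
  df$z_ok <- as.vector(ok)
  df
}

#' Sliding-window mean of pooled reaction times across trial index
#'
#' Trials are ordered by their within-block trial index (so many trials
#' share each index across blocks) and a running mean with standard error
#' is computed over a window of consecutive trials.
#'
#' @param trials tibble with `trial_index` and a value column.
#' @param value column to average (default `rt_z`, falling back to `rt_s`).
#' @param window window length in trials (default 500).
#' @return a tibble `position`, `mean`, `sem`, `n` per window.
#' @export
sliding_mean <- function(trials, value = NULL, window = 500L) {
  df <- tibble::as_tibble(trials)
  value <- value %||% if ("rt_z" %in% names(df)) "rt_z" else "rt_s"
  df <- df[order(df$trial_index), , drop = FALSE]
  v <- df[[value]]
  v <- v[!is.na(v)]
  n <- length(v)
  window <- as.integer(window)
  if (window > n) {
    warning("window exceeds the number of trials; returning one aggregate",
            call. = FALSE)
    return(tibble::tibble(position = 1L, mean = mean(v),
                          sem = stats::sd(v) / sqrt(n), n = n))
  }
  cs <- cumsum(c(0, v))
  cs2 <- cumsum(c(0, v^2))
  i <- seq_len(n - window + 1L)
  s <- cs[i + window] - cs[i]
  s2 <- cs2[i + window] - cs2[i]
  mu <- s / window
  varw <- pmax((s2 - window * mu^2) / (window - 1L), 0)
  tibble::tibble(position = i, mean = mu, sem = sqrt(varw / window),
                 n = window)
}

#' Fit the trial-constant model RT = alpha * 2^(-t / tau)
#'
#' Nonlinear least squares on the original RT scale for the exponential
#' learning curve; `tau` (the trial constant) is the number of trials over
#' which the reaction time halves and `alpha` is the RT scale at t = 0.
#' The fit is initialized from the exact log-linear regression (which is
#' the global optimum for noiseless data) and refined by Levenberg-
#' Marquardt least squares; if the refinement fails the initializer is
#' returned.
#'
#' @param trials tibble with `trial_index` and `rt_s`, or two numeric
#'   vectors via `t` and `rt`.
#' @param t,rt optional explicit vectors overriding `trials`.
#' @return an `rt_fit` list: `alpha` (s), `tau` (trials), `residual_norm`,
#'   `n`, `method`.
#' @export
fit_trial_constant <- function(trials = NULL, t = trials$trial_index,
                               rt = trials$rt_s) {
  t <- as.numeric(t)
  rt <- as.numeric(rt)
  if (length(t) != length(rt) || length(t) < 3L) {
    stop("need at least 3 trials", call. = FALSE)
  }
  if (length(unique(t)) < 2L) {
    stop("need at least 2 distinct trial indices", call. = FALSE)
  }
  if (any(rt <= 0)) stop("reaction times must be positive", call. = FALSE)

  # log2(RT) = log2(alpha) - t / tau: exact on noiseless data
  lin <- stats::lm(log2(rt) ~ t)
  slope <- stats::coef(lin)[[2]]
  if (slope >= 0) slope <- -1e-6  # guard: non-decaying data
  start <- c(alpha = 2^stats::coef(lin)[[1]], tau = -1 / slope)

  refined <- tryCatch({
    fit <- minpack.lm::nlsLM(
      rt ~ alpha * 2^(-t / tau),
      start = as.list(start),
      lower = c(alpha = 1e-12, tau = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- stats::coef(fit)
    list(alpha = cf[["alpha"]], tau = cf[["tau"]],
         resid = sqrt(sum(stats::resid(fit)^2)), method = "nlsLM")
  }, error = function(e) NULL)
  if (is.null(refined)) {
    opt <- stats::optim(log(start), function(p) {
      sum((rt - exp(p[1]) * 2^(-t / exp(p[2])))^2)
    }, method = "Nelder-Mead")
    refined <- list(alpha = exp(opt$par[[1]]), tau = exp(opt$par[[2]]),
                    resid = sqrt(opt$value), method = "optim")
  }
  structure(list(alpha = refined$alpha, tau = refined$tau,
                 residual_norm = refined$resid, n = length(t),
                 method = refined$method),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("<rt_fit> alpha = %.4f s, tau = %.2f trials (n = %d, %s)\n",
              x$alpha, x$tau, x$n, x$method))
  invisible(x)
}

#' @rdname fit_trial_constant
#' @param x an `rt_fit`.
#' @param ... unused.
#' @export
tidy.rt_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "tau"),
                 estimate = c(x$alpha, x$tau))
}

#' @rdname fit_trial_constant
#' @export
glance.rt_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, tau = x$tau,
                 residual_norm = x$residual_norm, n = x$n, method = x$method)
}

#' Reaction-time cost of inconsistent responses
#'
#' Difference in mean RT between trials inconsistent and consistent with
#' the observer's own segmentation map, with a percentile bootstrap CI.
#'
#' @param trials tibble with `rt_s` and logical `consistent` (as returned
#'   by [classify_consistency()]).
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return a one-row tibble: `delay` (s, inconsistent minus consistent),
#'   `ci_lo`, `ci_hi`, `n_consistent`, `n_inconsistent`, `degenerate`
#'   (TRUE when either class has a single trial).
#' @export
inconsistency_delay <- function(trials, n_boot = 9999L, conf = 0.95,
                                seed = 1L) {
  df <- tibble::as_tibble(trials)
  rt_in <- df$rt_s[!df$consistent]
  rt_co <- df$rt_s[df$consistent]
  if (length(rt_in) == 0L || length(rt_co) == 0L) {
    stop("both consistent and inconsistent trials are required",
         call. = FALSE)
  }
  delay <- mean(rt_in) - mean(rt_co)
  degenerate <- length(rt_in) < 2L || length(rt_co) < 2L
  if (degenerate) {
    ci <- c(NA_real_, NA_real_)
  } else {
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        mean(sample(rt_in, replace = TRUE)) -
          mean(sample(rt_co, replace = TRUE))
      }, numeric(1))
    })
    ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE)
  }
  tibble::tibble(delay = delay, ci_lo = ci[1], ci_hi = ci[2],
                 n_consistent = length(rt_co),
                 n_inconsistent = length(rt_in), degenerate = degenerate)
}
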