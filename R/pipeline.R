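#' Pipeline run configuration
#'
#' A single declarative configuration for the simulate / infer / analyze
#' pipeline. Every stochastic stage derives its seed deterministically from
#' the master seed (`seed_for(seed, stage_counter)`), so one number
#' reproduces a run. Unknown keys raise an error naming the key.
#'
#' @param seed master seed.
#' @param n_participants participants simulated per cohort.
#' @param K number of segments.
#' @param grid_h,grid_w analysis grid.
#' @param lambda_smooth map-fit smoothing weight.
#' @param schedule_multiplier trials per block as a multiple of the
#'   [trial_schedule()].
#' @param n_perm_ig permutations for Information Gain nulls.
#' @param n_boot bootstrap resamples for RT statistics.
#' @param gaze_windows_s coverage-curve windows (seconds).
#' @param eeg_n_epochs epochs per simulated block.
#' @param stages character vector of stages to run, a subset of
#'   `c("maps", "rt", "gaze", "eeg")`.
#' @param out_dir optional directory for artifacts (summary JSON + log).
#' @param overrides named list overriding any of the above (e.g. parsed
#'   from a YAML file via [read_run_config()]).
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_participants = 3L, K = 2L,
                       grid_h = 15L, grid_w = 15L, lambda_smooth = 5,
                       schedule_multiplier = 2, n_perm_ig = 200L,
                       n_boot = 999L, gaze_windows_s = 1:10,
                       eeg_n_epochs = 30L,
                       stages = c("maps", "rt", "gaze", "eeg"),
                       out_dir = NULL, overrides = list()) {
  cfg <- list(seed = as.integer(seed),
              n_participants = as.integer(n_participants), K = as.integer(K),
              grid_h = as.integer(grid_h), grid_w = as.integer(grid_w),
              lambda_smooth = lambda_smooth,
              schedule_multiplier = schedule_multiplier,
              n_perm_ig = as.integer(n_perm_ig),
              n_boot = as.integer(n_boot),
              gaze_windows_s = gaze_windows_s,
              eeg_n_epochs = as.integer(eeg_n_epochs),
              stages = stages, out_dir = out_dir)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  bad_stage <- setdiff(cfg$stages, c("maps", "rt", "gaze", "eeg"))
  if (length(bad_stage)) {
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Deterministic per-stage seed derivation
#'
#' @param seed master seed.
#' @param counter stage counter (>= 1).
#' @return a derived integer seed below 2^31.
#' @export
seed_for <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1009 + counter * 9973) %% 2147483647)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file whose keys override [run_config()] defaults.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(overrides = yaml::read_yaml(path))
}

#' Validate pipeline input files
#'
#' Schema and invariant checks for declared inputs: block trial tables
#' (columns, positive RTs, valid responses, unique trial indices) and gaze
#' streams (columns, strictly increasing timestamps). Problems are
#' itemized with `level` "error" or "warning"; malformed files never
#' raise.
#'
#' @param paths named list/vector of file paths; names starting with
#'   "block" are validated as blocks, "gaze" as gaze streams.
#' @return a tibble `file`, `level`, `message` (zero rows when clean).
#' @export
validate_inputs <- function(paths) {
  out <- list()
  note <- function(file, level, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(file = file, level = level,
                                               message = message)
  }
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    kind <- if (grepl("^gaze", names(paths)[i] %||% "") ||
                grepl("gaze", basename(p))) "gaze" else "block"
    if (!file.exists(p)) {
      note(p, "error", "file does not exist")
      next
    }
    if (kind == "block") {
      tryCatch({
        b <- read_block(p)
        df <- tibble::as_tibble(b)
        bad_rt <- which(df$rt_s <= 0)
        if (length(bad_rt)) {
          note(p, "error", paste0("non-positive rt_s at row(s) ",
                                  paste(utils::head(bad_rt, 5),
                                        collapse = ", ")))
        }
      }, error = function(e) note(p, "error", conditionMessage(e)))
    } else {
      tryCatch({
        g <- read_gaze(p)
        need <- c("t_s", "x_px", "y_px", "valid")
        miss <- setdiff(need, names(g))
        if (length(miss)) {
          note(p, "error", paste("missing columns:",
                                 paste(miss, collapse = ", ")))
        } else if (any(diff(g$t_s) <= 0)) {
          note(p, "error", "timestamps not strictly increasing")
        }
      }, error = function(e) note(p, "error", conditionMessage(e)))
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(file = character(0), level = character(0),
                   message = character(0))
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulates NT-like and ASD-like cohorts with [cohort_preset()], then runs
#' every enabled analysis stage in dependency order: map inference with
#' structureless-block flagging, uncertainty and Information-Gain
#' similarity statistics, reaction-time summaries and the trial-constant
#' fit, gaze coverage curves, and the EEG cohort contrasts (O/PO pointwise
#' windows and GFP interval tests). Identical configurations give
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return a `pipeline_report` list: `config`, per-stage result tibbles
#'   under `maps`, `similarity`, `rt`, `gaze`, `eeg`, and a `log` tibble
#'   of stage timings, seeds, and parameters.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  log <- list()
  stamp <- function(stage, detail) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, detail = detail,
      elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  }
  res <- list(config = config)
  ctr <- 0L
  next_seed <- function() {
    ctr <<- ctr + 1L
    seed_for(config$seed, ctr)
  }
  stamp("init", sprintf("master seed %d; stages: %s", config$seed,
                        paste(config$stages, collapse = ",")))

  n_trials <- round(config$schedule_multiplier *
                      trial_schedule(config$K, config$grid_h, config$grid_w))
  gt <- make_ground_truth_map(config$K, config$grid_h, config$grid_w,
                              seed = next_seed())
  cohorts <- c("NT", "ASD")
  blocks <- list()
  for (co in cohorts) {
    preset <- cohort_preset(co)
    for (p in seq_len(config$n_participants)) {
      id <- sprintf("%s%02d", tolower(co), p)
      op <- observer_params(gt, certainty = preset$observer$certainty,
                            lapse = preset$observer$lapse,
                            rt_alpha = preset$observer$rt_alpha,
                            rt_tau = preset$observer$rt_tau,
                            rt_noise_sd = preset$observer$rt_noise_sd,
                            seed = next_seed())
      blocks[[id]] <- simulate_observer_block(
        op, stimulus("sim-stim", K = config$K, category = "texture"),
        n_trials = n_trials, participant_id = id, cohort = co)
    }
  }
  stamp("simulate", sprintf("%d blocks x %d trials (K = %d)",
                            length(blocks), n_trials, config$K))

  if ("maps" %in% config$stages) {
    fits <- list()
    map_rows <- list()
    for (id in names(blocks)) {
      cfg <- fit_config(config$grid_h, config$grid_w,
                        config$lambda_smooth, seed = next_seed())
      flag <- flag_structureless_block(blocks[[id]], cfg,
                                       n_perm = config$n_perm_ig,
                                       seed = next_seed())
      fits[[id]] <- flag$fit
      seg <- argmax_map(flag$fit$pmap)
      cons <- classify_consistency(blocks[[id]], seg)
      emap <- entropy_map(flag$fit$pmap)
      blocks[[id]] <- block_data(cons$trials,
                                 attr(blocks[[id]], "participant_id"),
                                 attr(blocks[[id]], "cohort"),
                                 attr(blocks[[id]], "stimulus"))
      map_rows[[id]] <- tibble::tibble(
        participant_id = id, cohort = attr(blocks[[id]], "cohort"),
        flagged = flag$flagged, structure_p = flag$p_value,
        mean_uncertainty_pct = mean_uncertainty(emap),
        inconsistency_rate = cons$rate,
        converged = flag$fit$converged,
        agreement_truth = match_labels(seg, gt)$agreement)
    }
    res$maps <- dplyr::bind_rows(map_rows)
    stamp("maps", sprintf("%d fits, %d flagged", length(fits),
                          sum(res$maps$flagged)))

    ig_rows <- list()
    for (co in cohorts) {
      ids <- names(blocks)[vapply(blocks, attr, "", which = "cohort") == co]
      if (length(ids) >= 2L) {
        prs <- utils::combn(ids, 2L)
        for (j in seq_len(ncol(prs))) {
          ig <- information_gain(argmax_map(fits[[prs[1, j]]]$pmap),
                                 argmax_map(fits[[prs[2, j]]]$pmap),
                                 n_perm = config$n_perm_ig,
                                 seed = next_seed())
          ig_rows[[length(ig_rows) + 1L]] <- dplyr::mutate(
            tidy(ig), cohort = co, a = prs[1, j], b = prs[2, j],
            .before = 1)
        }
      }
    }
    res$similarity <- dplyr::bind_rows(ig_rows)
    stamp("similarity", sprintf("%d map pairs", nrow(res$similarity)))
  }

  if ("rt" %in% config$stages) {
    pooled <- dplyr::bind_rows(lapply(names(blocks), function(id) {
      dplyr::mutate(tibble::as_tibble(blocks[[id]]), participant_id = id,
                    cohort = attr(blocks[[id]], "cohort"),
                    stim_id = attr(blocks[[id]], "stimulus")$stim_id)
    }))
    filtered <- filter_rts(pooled)
    med <- dplyr::bind_rows(lapply(cohorts, function(co) {
      dplyr::mutate(
        median_rt_ci(filtered$rt_s[filtered$cohort == co],
                     n_boot = config$n_boot, seed = next_seed()),
        cohort = co, .before = 1)
    }))
    fit_tau <- dplyr::bind_rows(lapply(cohorts, function(co) {
      sub <- filtered[filtered$cohort == co, ]
      dplyr::mutate(glance(fit_trial_constant(sub)), cohort = co,
                    .before = 1)
    }))
    delay <- if ("consistent" %in% names(filtered)) {
      dplyr::bind_rows(lapply(cohorts, function(co) {
        dplyr::mutate(
          inconsistency_delay(filtered[filtered$cohort == co, ],
                              n_boot = config$n_boot, seed = next_seed()),
          cohort = co, .before = 1)
      }))
    } else NULL
    res$rt <- list(medians = med, trial_constant = fit_tau,
                   inconsistency_delay = delay)
    stamp("rt", sprintf("%d trials after filtering", nrow(filtered)))
  }

  if ("gaze" %in% config$stages) {
    gz_rows <- list()
    for (id in names(blocks)) {
      co <- attr(blocks[[id]], "cohort")
      preset <- cohort_preset(co)
      stream <- clean_gaze(simulate_gaze(preset$gaze$duration_s,
                                         preset$gaze$spread_px,
                                         seed = next_seed()))
      cc <- coverage_curve(stream, config$gaze_windows_s,
                           grid_h = config$grid_h, grid_w = config$grid_w)
      gz_rows[[id]] <- dplyr::mutate(cc, participant_id = id, cohort = co,
                                     .before = 1)
    }
    res$gaze <- dplyr::bind_rows(gz_rows)
    stamp("gaze", sprintf("%d coverage curves", length(gz_rows)))
  }

  if ("eeg" %in% config$stages) {
    opo <- c("O1", "Oz", "O2", "PO7", "PO3", "POz", "PO4", "PO8")
    erps <- list(NT = list(), ASD = list())
    gfps <- list(NT = list(), ASD = list())
    for (co in cohorts) {
      preset <- cohort_preset(co, seed = next_seed())
      for (p in seq_len(config$n_participants)) {
        pr <- preset$eeg
        pr$n_epochs <- config$eeg_n_epochs
        pr$seed <- next_seed()
        rts <- withr::with_seed(next_seed(), {
          stats::rlnorm(config$eeg_n_epochs, log(0.5), 0.3)
        })
        ep <- simulate_epochs(pr, rts, cohort = co,
                              participant_id = sprintf("%s%02d",
                                                       tolower(co), p))
        ep <- baseline_correct(rereference_average(exclude_by_rt(ep)))
        erps[[co]][[p]] <- compute_erp(ep, channels = opo, collapse = TRUE)
        gfps[[co]][[p]] <- gfp(compute_erp(ep))$gfp
      }
    }
    times_ms <- erps$NT[[1]]$times_ms
    windows <- pointwise_ttest_windows(erps$NT, erps$ASD)
    gfp_tests <- gfp_interval_tests(do.call(rbind, gfps$NT),
                                    do.call(rbind, gfps$ASD), times_ms)
    res$eeg <- list(windows = windows, gfp_tests = gfp_tests)
    stamp("eeg", sprintf("%d significant windows, %d significant GFP times",
                         nrow(windows), sum(gfp_tests$significant)))
  }

  res$log <- dplyr::bind_rows(log)
  class(res) <- "pipeline_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report_summary(res),
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_tsv(res$log, file.path(config$out_dir, "run_log.tsv"))
  }
  res
}

# Machine-readable flat summary of a pipeline report.
report_summary <- function(res) {
  out <- list(seed = res$config$seed,
              package_version = as.character(utils::packageVersion("perceptseg")))
  if (!is.null(res$maps)) {
    out$maps <- res$maps
    out$similarity <- res$similarity
  }
  if (!is.null(res$rt)) out$rt <- res$rt
  if (!is.null(res$gaze)) out$gaze <- res$gaze
  if (!is.null(res$eeg)) {
    out$eeg <- list(windows = res$eeg$windows,
                    gfp_tests = res$eeg$gfp_tests)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$log)
  invisible(x)
}
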