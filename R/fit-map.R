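#' Map-fitting configuration
#'
#' @param grid_h,grid_w analysis grid (default 15 x 15).
#' @param lambda_smooth spatial smoothing weight on the squared difference
#'   of neighbouring cells' label distributions (default 5).
#' @param max_iter optimizer iteration cap.
#' @param tol relative objective tolerance for convergence.
#' @param seed seed for the symmetry-breaking initialization noise.
#' @return a `fit_config` list.
#' @export
fit_config <- function(grid_h = 15L, grid_w = 15L, lambda_smooth = 5,
                       max_iter = 2000L, tol = 1e-9, seed = 1L) {
  if (lambda_smooth < 0) stop("lambda_smooth must be >= 0", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  structure(list(grid_h = as.integer(grid_h), grid_w = as.integer(grid_w),
                 lambda_smooth = lambda_smooth, max_iter = as.integer(max_iter),
                 tol = tol, seed = as.integer(seed)),
            class = "fit_config")
}

# Unordered 4-neighborhood edge list of a grid, as a 2-column matrix of
# row-major 1-based cell indices.
grid_edges <- function(grid_h, grid_w) {
  idx <- matrix(seq_len(grid_h * grid_w), nrow = grid_h, ncol = grid_w,
                byrow = TRUE)
  horiz <- cbind(as.vector(idx[, -grid_w]), as.vector(idx[, -1]))
  vert <- cbind(as.vector(idx[-grid_h, ]), as.vector(idx[-1, ]))
  rbind(horiz, vert)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' Fit a probabilistic segmentation map to a block of responses
#'
#' Reconstructs the per-cell label distribution most compatible with the
#' observer's same/different judgments by penalized maximum likelihood.
#' Each grid cell carries unconstrained scores mapped through a softmax to
#' label probabilities `p_i`; a trial cueing cells i and j is predicted
#' "same" with probability `sum_k p_{i,k} p_{j,k}`, scored by a Bernoulli
#' log-likelihood, and a smoothness penalty
#' `lambda * sum_edges ||p_i - p_j||^2` over the 4-neighbourhood regularizes
#' cells that few trials constrain. The objective is maximized with L-BFGS-B
#' using the analytic gradient; initialization is uniform plus small seeded
#' noise to break label symmetry, so the fit is deterministic given the seed.
#'
#' @param block a [block_data()] block.
#' @param config a [fit_config()]; the block stimulus supplies K.
#' @return a `prob_map_fit` list: `pmap` (the fitted [prob_seg_map()]),
#'   `objective` (final penalized log-likelihood), `iterations`,
#'   `converged`, and the `config` used.
#' @export
fit_prob_map <- function(block, config = fit_config()) {
  stopifnot(inherits(block, "perceptseg_block"))
  m <- block_meta(block)
  K <- m$stimulus$K
  gh <- config$grid_h
  gw <- config$grid_w
  n_cells <- gh * gw
  if (nrow(block) < 1L) stop("block has no trials", call. = FALSE)

  a <- cue_to_cell(block$cue_a_x, block$cue_a_y, m$stimulus, gh, gw)$cell
  b <- cue_to_cell(block$cue_b_x, block$cue_b_y, m$stimulus, gh, gw)$cell
  y <- as.numeric(block$response == "same")
  edges <- grid_edges(gh, gw)
  eu <- edges[, 1]
  ev <- edges[, 2]
  lam <- config$lambda_smooth
  eps <- 1e-12

  accumulate_rows <- function(values, idx) {
    out <- matrix(0, n_cells, K)
    agg <- rowsum(values, idx)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }

  neg_obj <- function(zvec) {
    P <- softmax_rows(matrix(zvec, n_cells, K))
    s <- pmin(pmax(rowSums(P[a, , drop = FALSE] * P[b, , drop = FALSE]),
                   eps), 1 - eps)
    ll <- sum(y * log(s) + (1 - y) * log1p(-s))
    D <- P[eu, , drop = FALSE] - P[ev, , drop = FALSE]
    -(ll - lam * sum(D * D))
  }

  neg_grad <- function(zvec) {
    P <- softmax_rows(matrix(zvec, n_cells, K))
    Pa <- P[a, , drop = FALSE]
    Pb <- P[b, , drop = FALSE]
    s <- pmin(pmax(rowSums(Pa * Pb), eps), 1 - eps)
    w <- y / s - (1 - y) / (1 - s)
    Gp <- accumulate_rows(rbind(Pb * w, Pa * w), c(a, b))
    D <- P[eu, , drop = FALSE] - P[ev, , drop = FALSE]
    Gp <- Gp + accumulate_rows(rbind(-2 * lam * D, 2 * lam * D), c(eu, ev))
    Gz <- P * (Gp - rowSums(P * Gp))
    -as.vector(Gz)
  }

  z0 <- withr::with_seed(config$seed,
                         matrix(stats::rnorm(n_cells * K, sd = 1e-2),
                                n_cells, K))
  fit <- stats::optim(
    as.vector(z0), fn = neg_obj, gr = neg_grad, method = "L-BFGS-B",
    control = list(maxit = config$max_iter,
                   factr = config$tol / .Machine$double.eps)
  )
  P <- softmax_rows(matrix(fit$par, n_cells, K))
  P <- P / rowSums(P)  # renormalization guard
  structure(
    list(pmap = prob_seg_map(P, gh, gw),
         objective = -fit$value,
         iterations = fit$counts[["function"]],
         converged = fit$convergence == 0L,
         config = config),
    class = "prob_map_fit"
  )
}

#' @export
print.prob_map_fit <- function(x, ...) {
  cat(sprintf(
    "<prob_map_fit> %dx%d grid, K = %d; objective %.2f; %s (%d evals)\n",
    x$pmap$grid_h, x$pmap$grid_w, x$pmap$K, x$objective,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @rdname fit_prob_map
#' @param x a `prob_map_fit`.
#' @param ... unused.
#' @export
glance.prob_map_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, iterations = x$iterations,
                 converged = x$converged, K = x$pmap$K,
                 lambda_smooth = x$config$lambda_smooth,
                 mean_entropy_bits = mean(entropy_map(x$pmap)$values))
}

#' @rdname fit_prob_map
#' @export
tidy.prob_map_fit <- function(x, ...) as_tibble(x$pmap)

#' Best label bijection between two segmentation maps
#'
#' Segment label indices carry no meaning across observers (or between a
#' fitted map and a ground truth), so maps are compared after finding the
#' label permutation maximizing cell agreement. Intended for evaluation
#' against simulated ground truth; with K <= 5 all permutations are
#' enumerated.
#'
#' @param fitted,truth `seg_map`s on the same grid.
#' @return a list: `perm` (label permutation applied to `fitted`),
#'   `agreement` (fraction of cells matching after relabeling), and
#'   `relabeled` (the relabeled `seg_map`).
#' @export
match_labels <- function(fitted, truth) {
  stopifnot(inherits(fitted, "seg_map"), inherits(truth, "seg_map"))
  if (length(fitted$labels) != length(truth$labels)) {
    stop("maps must have identical grid dimensions", call. = FALSE)
  }
  K <- max(fitted$K, truth$K)
  perms <- all_perms(K)
  best <- NULL
  best_agree <- -1
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    agree <- mean(p[fitted$labels] == truth$labels)
    if (agree > best_agree) {
      best_agree <- agree
      best <- p
    }
  }
  list(perm = best, agreement = best_agree,
       relabeled = seg_map(best[fitted$labels], fitted$grid_h,
                           fitted$grid_w, K = K))
}

# All permutations of 1..K (K <= 5 in practice, so enumeration is cheap).
all_perms <- function(K) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
  grid <- grid[apply(grid, 1, function(r) length(unique(r)) == K), ,
               drop = FALSE]
  dimnames(grid) <- NULL
  grid
}

#' Classify trials as consistent or inconsistent with a segmentation map
#'
#' A trial is consistent when the same/different response agrees with
#' whether the two cued cells share the argmax segment label of the map.
#'
#' @param block a [block_data()] block.
#' @param seg the `seg_map` derived for this block.
#' @return a list: `trials` (the block tibble with a `consistent` column)
#'   and `rate` (the inconsistency rate, inconsistent / total).
#' @export
classify_consistency <- function(block, seg) {
  stopifnot(inherits(block, "perceptseg_block"), inherits(seg, "seg_map"))
  m <- block_meta(block)
  a <- cue_to_cell(block$cue_a_x, block$cue_a_y, m$stimulus,
                   seg$grid_h, seg$grid_w)$cell
  b <- cue_to_cell(block$cue_b_x, block$cue_b_y, m$stimulus,
                   seg$grid_h, seg$grid_w)$cell
  same_map <- seg$labels[a] == seg$labels[b]
  consistent <- (block$response == "same") == same_map
  trials <- dplyr::mutate(tibble::as_tibble(block), consistent = consistent)
  list(trials = trials,
       rate = inconsistency_rate(sum(!consistent), length(consistent)))
}

#' Inconsistency rate from counts
#'
#' @param n_inconsistent,n_total trial counts (vectors are pooled).
#' @return pooled rate `sum(n_inconsistent) / sum(n_total)`.
#' @examples
#' inconsistency_rate(c(21453, 14122), c(60722, 39521))
#' @export
inconsistency_rate <- function(n_inconsistent, n_total) {
  sum(n_inconsistent) / sum(n_total)
}

#' Percentage of blocks excluded
#'
#' @param n_excluded,n_total block counts.
#' @return percentage, `100 * n_excluded / n_total`.
#' @export
exclusion_percent <- function(n_excluded, n_total) {
  100 * n_excluded / n_total
}

#' Shuffle responses across trials (surrogate block)
#'
#' Permutes the same/different responses uniformly across trials while
#' leaving cue positions and reaction times untouched, breaking any link
#' between responses and cue locations but preserving the response
#' marginals. Used to emulate random responding when screening for
#' structureless maps.
#'
#' @param block a [block_data()] block.
#' @param seed integer seed.
#' @return a surrogate `perceptseg_block`.
#' @export
shuffle_responses <- function(block, seed = 1L) {
  stopifnot(inherits(block, "perceptseg_block"))
  if (nrow(block) < 2L) stop("need at least 2 trials to shuffle",
                             call. = FALSE)
  m <- block_meta(block)
  trials <- tibble::as_tibble(block)
  trials$response <- withr::with_seed(seed, sample(trials$response))
  block_data(trials, m$participant_id, m$cohort, m$stimulus)
}

#' Flag a block whose fitted map lacks spatial structure
#'
#' Mirrors the exclusion rule for blocks where the observer responded
#' randomly: random responses are unrelated to the cue positions and yield
#' segmentation maps without meaningful spatial organization. Because the
#' smoothing prior makes even noise-fitted maps look spatially smooth, the
#' test is cross-validated: a map is fitted to the odd-numbered trials and
#' scored by the inconsistency rate of the held-out even-numbered trials,
#' compared (one-tailed, add-one convention) against the null distribution
#' obtained by shuffling the held-out responses relative to their cue
#' pairs. A genuine segmenter's map predicts held-out responses far better
#' than shuffled ones; a random responder's does not. The block is flagged
#' when the test is non-significant (p > alpha) or the full-data map is
#' degenerate (single label).
#'
#' @param block a [block_data()] block.
#' @param config a [fit_config()].
#' @param n_perm response shuffles for the null.
#' @param alpha significance level.
#' @param seed integer seed.
#' @param fit optionally, an existing full-data `prob_map_fit` for this
#'   block (skips one of the two fits).
#' @return a list: `flagged`, `p_value`, `stat_observed` (held-out
#'   inconsistency rate), `null_mean`, `fit` (full-data fit).
#' @export
flag_structureless_block <- function(block, config = fit_config(),
                                     n_perm = 1000L, alpha = 0.05,
                                     seed = 1L, fit = NULL) {
  if (is.null(fit)) fit <- fit_prob_map(block, config)
  seg_full <- argmax_map(fit$pmap)
  if (length(unique(seg_full$labels)) < 2L) {
    return(list(flagged = TRUE, p_value = 1, stat_observed = NA_real_,
                null_mean = NA_real_, fit = fit))
  }
  m <- block_meta(block)
  n <- nrow(block)
  train <- block_data(block[seq(1L, n, 2L), ], m$participant_id, m$cohort,
                      m$stimulus)
  test <- block_data(block[seq(2L, n, 2L), ], m$participant_id, m$cohort,
                     m$stimulus)
  cfg_train <- config
  cfg_train$seed <- config$seed + 1L
  # keep per-trial regularization constant on the half-sized training set
  sched <- trial_schedule(m$stimulus$K, config$grid_h, config$grid_w)
  cfg_train$lambda_smooth <- config$lambda_smooth * nrow(train) / sched
  seg <- argmax_map(fit_prob_map(train, cfg_train)$pmap)
  obs <- classify_consistency(test, seg)$rate
  null_rate <- vapply(seq_len(n_perm), function(i) {
    classify_consistency(shuffle_responses(test, seed = seed + i),
                         seg)$rate
  }, numeric(1))
  p <- (1 + sum(null_rate <= obs)) / (n_perm + 1)
  list(flagged = p > alpha, p_value = p, stat_observed = obs,
       null_mean = mean(null_rate), fit = fit)
}
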