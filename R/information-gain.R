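#' Mutual information between two label maps
#'
#' Computes the mutual information (bits) of the joint label histogram over
#' co-located grid cells of two segmentation maps. Empty joint cells
#' contribute 0. MI is symmetric and invariant to relabeling the segments
#' of either map, which makes it suitable for comparing maps whose label
#' indices carry no shared meaning across observers.
#'
#' @param a,b `seg_map` objects (or plain integer vectors of equal length).
#' @return mutual information in bits (scalar).
#' @examples
#' m <- seg_map(rep(c(1, 2), each = 8), grid_h = 4, grid_w = 4)
#' mutual_information(m, m)  # equals the map entropy, 1 bit
#' @export
mutual_information <- function(a, b) {
  la <- map_labels(a)
  lb <- map_labels(b)
  if (length(la) != length(lb)) {
    stop("maps must have identical grid dimensions", call. = FALSE)
  }
  mi_labels(la, lb)
}

map_labels <- function(x) {
  if (inherits(x, "seg_map")) return(x$labels)
  if (inherits(x, "entropy_map")) {
    stop("quantize entropy maps first (see information_gain)", call. = FALSE)
  }
  as.integer(x)
}

# MI in bits from two integer label vectors (levels need not be contiguous).
mi_labels <- function(la, lb) {
  la <- match(la, sort(unique(la)))
  lb <- match(lb, sort(unique(lb)))
  ka <- max(la)
  kb <- max(lb)
  joint <- tabulate((lb - 1L) * ka + la, ka * kb) / length(la)
  pa <- tabulate(la, ka) / length(la)
  pb <- tabulate(lb, kb) / length(lb)
  outer_p <- as.vector(outer(pa, pb))
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

# Quantize one or two continuous maps into equal-width bins over their
# pooled range; constant input collapses to a single bin.
quantize_pooled <- function(va, vb, n_bins = 8L) {
  rng <- range(c(va, vb))
  if (diff(rng) <= 0) {
    return(list(a = rep(1L, length(va)), b = rep(1L, length(vb))))
  }
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  cut_idx <- function(v) {
    i <- findInterval(v, brk, rightmost.closed = TRUE, all.inside = TRUE)
    as.integer(i)
  }
  list(a = cut_idx(va), b = cut_idx(vb))
}

#' Information Gain between two maps with a spatial-shuffle permutation null
#'
#' Measures how much more similar two maps are than random maps with the
#' same label composition. The observed mutual information is compared to a
#' null distribution obtained by uniformly permuting the spatial locations
#' of one map's values (the marginal distribution of values is preserved).
#' Information Gain is reported in percent,
#' `IG = 100 * (MI_obs - mean(MI_null)) / mean(MI_null)`:
#' 0% means the maps are no more similar than two random maps, and large
#' positive values (easily reaching thousands of percent for structured
#' maps) mean the spatial organization of one map predicts the other.
#'
#' Continuous maps (`entropy_map`) are first quantized into `n_bins`
#' equal-width bins over the pooled range of both maps, then treated as
#' label maps.
#'
#' @param a,b two `seg_map`s or two `entropy_map`s on the same grid.
#' @param n_perm number of spatial permutations for the null (default 10000).
#' @param alpha significance level for the one-tailed permutation test.
#' @param seed integer seed for the permutation null.
#' @param n_bins quantization bins for continuous maps.
#' @return an `ig_result` list: `mi_observed`, `null_mean`, `null_sd`,
#'   `ig_percent`, `p_value` (add-one permutation convention, always > 0),
#'   `significant`, `n_perm`, `seed`, and a `degenerate` flag set when the
#'   null mean is zero (e.g. a constant map), in which case `ig_percent = 0`.
#' @examples
#' m <- seg_map(rep(rep(1:2, each = 2), 4), grid_h = 4, grid_w = 4)
#' information_gain(m, m, n_perm = 99, seed = 1)
#' @export
information_gain <- function(a, b, n_perm = 10000L, alpha = 0.05,
                             seed = 1L, n_bins = 8L) {
  if (inherits(a, "entropy_map") != inherits(b, "entropy_map")) {
    stop("compare two label maps or two entropy maps, not a mixture",
         call. = FALSE)
  }
  if (inherits(a, "entropy_map")) {
    if (a$grid_h != b$grid_h || a$grid_w != b$grid_w) {
      stop("maps must have identical grid dimensions", call. = FALSE)
    }
    q <- quantize_pooled(a$values, b$values, n_bins = n_bins)
    la <- q$a
    lb <- q$b
  } else {
    la <- map_labels(a)
    lb <- map_labels(b)
    if (length(la) != length(lb)) {
      stop("maps must have identical grid dimensions", call. = FALSE)
    }
  }
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be at least 1", call. = FALSE)

  mi_obs <- mi_labels(la, lb)
  null_mi <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) mi_labels(sample(la), lb), numeric(1))
  })
  null_mean <- mean(null_mi)
  null_sd <- stats::sd(null_mi)
  degenerate <- null_mean <= .Machine$double.eps
  ig_percent <- if (degenerate) 0 else 100 * (mi_obs - null_mean) / null_mean
  p_value <- (1 + sum(null_mi >= mi_obs)) / (n_perm + 1)
  structure(
    list(mi_observed = mi_obs, null_mean = null_mean, null_sd = null_sd,
         ig_percent = ig_percent, p_value = p_value,
         significant = p_value <= alpha, n_perm = n_perm,
         seed = as.integer(seed), degenerate = degenerate),
    class = "ig_result"
  )
}

#' @export
print.ig_result <- function(x, ...) {
  cat(sprintf("<ig_result> MI = %.4f bits, null = %.4f +/- %.4f bits\n",
              x$mi_observed, x$null_mean, x$null_sd))
  cat(sprintf("  IG = %.1f%%, p = %.4g (%d permutations)%s\n",
              x$ig_percent, x$p_value, x$n_perm,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @rdname information_gain
#' @param x an `ig_result`.
#' @param ... unused.
#' @export
tidy.ig_result <- function(x, ...) {
  tibble::tibble(
    mi_observed = x$mi_observed, null_mean = x$null_mean,
    null_sd = x$null_sd, ig_percent = x$ig_percent,
    p_value = x$p_value, significant = x$significant,
    n_perm = x$n_perm, degenerate = x$degenerate
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
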