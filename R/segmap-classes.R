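#' Probabilistic segmentation map
#'
#' A probabilistic segmentation map stores, for every cell of a coarse
#' analysis grid laid over an image, a probability distribution over the
#' K segment labels the observer was asked to use. Cell (1,1) is the top-left
#' corner of the image; cells are stored in row-major order.
#'
#' @param probs numeric matrix with one row per grid cell (row-major) and one
#'   column per segment label. Rows must be non-negative and sum to 1.
#' @param grid_h,grid_w grid dimensions (default 15 x 15).
#' @return an object of class `prob_seg_map`.
#' @examples
#' p <- matrix(rep(c(0.9, 0.1), each = 4), 4, 2)
#' prob_seg_map(p, grid_h = 2, grid_w = 2)
#' @export
prob_seg_map <- function(probs, grid_h = 15L, grid_w = 15L) {
  probs <- as.matrix(probs)
  grid_h <- as.integer(grid_h)
  grid_w <- as.integer(grid_w)
  if (grid_h < 2L || grid_w < 2L) {
    stop("grid dimensions must be at least 2x2", call. = FALSE)
  }
  if (nrow(probs) != grid_h * grid_w) {
    stop("`probs` must have grid_h * grid_w rows", call. = FALSE)
  }
  if (ncol(probs) < 2L) {
    stop("K (number of segment labels) must be at least 2", call. = FALSE)
  }
  if (any(!is.finite(probs)) || any(probs < 0)) {
    stop("cell probabilities must be finite and non-negative", call. = FALSE)
  }
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("cell probabilities must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  structure(
    list(probs = probs, grid_h = grid_h, grid_w = grid_w, K = ncol(probs)),
    class = "prob_seg_map"
  )
}

#' Hard segmentation map
#'
#' Integer segment label per grid cell, usually obtained from a
#' [prob_seg_map()] via [argmax_map()].
#'
#' @param labels integer vector of cell labels in `1..K`, row-major.
#' @param K number of segment labels (defaults to `max(labels)`).
#' @inheritParams prob_seg_map
#' @return an object of class `seg_map`.
#' @export
seg_map <- function(labels, grid_h = 15L, grid_w = 15L, K = max(labels)) {
  labels <- as.integer(labels)
  grid_h <- as.integer(grid_h)
  grid_w <- as.integer(grid_w)
  K <- as.integer(K)
  if (grid_h < 2L || grid_w < 2L) {
    stop("grid dimensions must be at least 2x2", call. = FALSE)
  }
  if (length(labels) != grid_h * grid_w) {
    stop("`labels` must have grid_h * grid_w entries", call. = FALSE)
  }
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (anyNA(labels) || any(labels < 1L) || any(labels > K)) {
    stop("labels must lie in 1..K", call. = FALSE)
  }
  structure(
    list(labels = labels, grid_h = grid_h, grid_w = grid_w, K = K),
    class = "seg_map"
  )
}

#' Per-cell entropy (perceptual uncertainty) map
#'
#' @param values numeric vector of per-cell entropies in bits, row-major.
#' @param K number of segment labels the entropies refer to; values must lie
#'   in `[0, log2(K)]`.
#' @inheritParams prob_seg_map
#' @return an object of class `entropy_map`.
#' @export
entropy_map_values <- function(values, grid_h = 15L, grid_w = 15L, K = 2L) {
  values <- as.numeric(values)
  grid_h <- as.integer(grid_h)
  grid_w <- as.integer(grid_w)
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (length(values) != grid_h * grid_w) {
    stop("`values` must have grid_h * grid_w entries", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < -1e-12) ||
      any(values > log2(K) + 1e-9)) {
    stop("entropies must lie in [0, log2(K)]", call. = FALSE)
  }
  structure(
    list(values = pmin(pmax(values, 0), log2(K)),
         grid_h = grid_h, grid_w = grid_w, K = K),
    class = "entropy_map"
  )
}

#' @export
print.prob_seg_map <- function(x, ...) {
  cat(sprintf("<prob_seg_map> %dx%d grid, K = %d segments\n",
              x$grid_h, x$grid_w, x$K))
  cat(sprintf("  mean max-label probability: %.3f\n", mean(apply(x$probs, 1, max))))
  invisible(x)
}

#' @export
print.seg_map <- function(x, ...) {
  cat(sprintf("<seg_map> %dx%d grid, K = %d segments\n",
              x$grid_h, x$grid_w, x$K))
  tb <- tabulate(x$labels, x$K)
  cat("  label counts:", paste(tb, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.entropy_map <- function(x, ...) {
  cat(sprintf("<entropy_map> %dx%d grid, K = %d, mean %.3f bits (max %.3f)\n",
              x$grid_h, x$grid_w, x$K, mean(x$values), log2(x$K)))
  invisible(x)
}

map_cell_index <- function(grid_h, grid_w) {
  tibble::tibble(
    row = rep(seq_len(grid_h) - 1L, each = grid_w),
    col = rep(seq_len(grid_w) - 1L, times = grid_h)
  )
}

#' Tidy a map into one row per grid cell
#'
#' `row`/`col` are 0-based, matching the on-disk cell convention.
#'
#' @param x a `prob_seg_map`, `seg_map`, or `entropy_map`.
#' @param ... unused.
#' @return a tibble with one row per cell.
#' @export
as_tibble.seg_map <- function(x, ...) {
  dplyr::mutate(map_cell_index(x$grid_h, x$grid_w), label = x$labels)
}

#' @export
as_tibble.entropy_map <- function(x, ...) {
  dplyr::mutate(map_cell_index(x$grid_h, x$grid_w), entropy_bits = x$values)
}

#' @export
as_tibble.prob_seg_map <- function(x, ...) {
  out <- map_cell_index(x$grid_h, x$grid_w)
  pr <- tibble::as_tibble(x$probs, .name_repair = ~ paste0("p", seq_len(x$K)))
  dplyr::bind_cols(out, pr)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Assign each cell its most probable segment label
#'
#' Ties are broken toward the lowest label index so the result is
#' deterministic and stable under label reordering of the remaining mass.
#'
#' @param pmap a [prob_seg_map()].
#' @return a [seg_map()].
#' @examples
#' p <- matrix(c(0.1, 0.9, 0.5, 0.5), 2, 2, byrow = TRUE)
#' argmax_map(prob_seg_map(rbind(p, p), grid_h = 2, grid_w = 2))
#' @export
argmax_map <- function(pmap) {
  stopifnot(inherits(pmap, "prob_seg_map"))
  labels <- max.col(pmap$probs, ties.method = "first")
  seg_map(labels, pmap$grid_h, pmap$grid_w, K = pmap$K)
}

#' Per-cell Shannon entropy of the label distribution
#'
#' Entropy is computed in bits (base-2 logs); `0 * log 0` contributes 0.
#' High entropy marks cells where the observer's label assignment was
#' uncertain; the maximum possible value is `log2(K)`.
#'
#' @param pmap a [prob_seg_map()].
#' @return an `entropy_map`.
#' @export
entropy_map <- function(pmap) {
  stopifnot(inherits(pmap, "prob_seg_map"))
  p <- pmap$probs
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  entropy_map_values(h, pmap$grid_h, pmap$grid_w, K = pmap$K)
}

#' Mean perceptual uncertainty as percent of maximum
#'
#' Averages the per-cell entropy and rescales by the maximum attainable
#' entropy `log2(K)`, so 0% is full certainty everywhere and 100% is a
#' uniform label distribution in every cell.
#'
#' @param emap an `entropy_map`.
#' @param K number of segment labels (defaults to the map's own K).
#' @return mean uncertainty in percent (scalar).
#' @export
mean_uncertainty <- function(emap, K = emap$K) {
  stopifnot(inherits(emap, "entropy_map"))
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (any(emap$values > log2(K) + 1e-9)) {
    stop("entropy map exceeds log2(K) for the supplied K", call. = FALSE)
  }
  100 * mean(emap$values) / log2(K)
}
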