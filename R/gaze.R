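#' Clean a gaze sample stream
#'
#' Drops blink (invalid) samples and samples falling outside the image
#' rectangle, mirroring standard eye-tracking preprocessing. The retention
#' fraction is attached as an attribute; an empty result is flagged for
#' exclusion rather than raising.
#'
#' @param stream tibble with columns `t_s` (strictly increasing timestamps,
#'   seconds), `x_px`, `y_px`, `valid` (logical).
#' @param width,height image bounds in pixels.
#' @return the cleaned tibble with attributes `retention` and `excluded`.
#' @export
clean_gaze <- function(stream, width = 256L, height = 256L) {
  df <- tibble::as_tibble(stream)
  if (nrow(df) == 0L) stop("gaze stream is empty", call. = FALSE)
  if (any(diff(df$t_s) <= 0)) {
    stop("gaze timestamps must be strictly increasing", call. = FALSE)
  }
  keep <- df$valid & df$x_px >= 0 & df$x_px < width &
    df$y_px >= 0 & df$y_px < height
  out <- df[keep, , drop = FALSE]
  attr(out, "retention") <- mean(keep)
  attr(out, "excluded") <- nrow(out) == 0L
  out
}

# Column-wise 1-D convolution matrix for a truncated Gaussian (4 sigma).
gauss_band_matrix <- function(n, sigma) {
  half <- max(1L, ceiling(4 * sigma))
  offs <- -half:half
  kern <- exp(-offs^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    i <- j + offs
    ok <- i >= 1L & i <= n
    M[i[ok], j] <- kern[ok]
  }
  M
}

#' Gaze dwell-time density map
#'
#' Builds a per-pixel map of viewing time: each retained sample carries one
#' sampling interval of dwell and is spread by an isotropic Gaussian kernel
#' (sigma in pixels, truncated at 4 sigma). Each sample's kernel is
#' renormalized over the in-image pixels so total dwell time is conserved
#' exactly, including near the image border.
#'
#' @param stream a cleaned gaze tibble (see [clean_gaze()]).
#' @param sigma kernel standard deviation in pixels (default 10).
#' @param width,height image size in pixels.
#' @param dt sampling interval in seconds (default 0.002, i.e. 500 Hz).
#' @return a `gaze_density` object: `map` (height x width matrix of seconds),
#'   `sigma`, `total_s`.
#' @export
gaze_density <- function(stream, sigma = 10, width = 256L, height = 256L,
                         dt = 0.002) {
  df <- tibble::as_tibble(stream)
  H <- matrix(0, height, width)
  if (nrow(df) > 0L) {
    px <- pmin(pmax(floor(df$x_px), 0L), width - 1L) + 1L
    py <- pmin(pmax(floor(df$y_px), 0L), height - 1L) + 1L
    counts <- table(factor(py + (px - 1L) * height,
                           levels = seq_len(height * width)))
    H[] <- as.numeric(counts) * dt
    Ky <- gauss_band_matrix(height, sigma)
    Kx <- gauss_band_matrix(width, sigma)
    # in-image kernel mass for a source at each pixel (kernel is separable)
    W <- outer(colSums(Ky), colSums(Kx))
    H <- Ky %*% (H / W) %*% t(Kx)
  }
  structure(list(map = H, sigma = sigma, total_s = sum(H)),
            class = "gaze_density")
}

#' @export
print.gaze_density <- function(x, ...) {
  cat(sprintf("<gaze_density> %dx%d px, sigma = %g px, total dwell %.3f s\n",
              nrow(x$map), ncol(x$map), x$sigma, x$total_s))
  invisible(x)
}

#' Downsample a pixel-resolution density map to the analysis grid
#'
#' Cell value is the summed dwell of the contained pixels, so total mass is
#' preserved.
#'
#' @param density a `gaze_density` (or plain matrix).
#' @param grid_h,grid_w analysis grid (default 15 x 15).
#' @return `grid_h` x `grid_w` matrix of dwell seconds.
#' @export
downsample_density <- function(density, grid_h = 15L, grid_w = 15L) {
  M <- if (inherits(density, "gaze_density")) density$map else
    as.matrix(density)
  h <- nrow(M)
  w <- ncol(M)
  row_cell <- pmin(floor((seq_len(h) - 1L) * grid_h / h), grid_h - 1L) + 1L
  col_cell <- pmin(floor((seq_len(w) - 1L) * grid_w / w), grid_w - 1L) + 1L
  agg <- rowsum(t(rowsum(M, row_cell)), col_cell)
  t(agg)
}

#' Percent of the image area visited by gaze within a time window
#'
#' Coverage is the fraction of analysis-grid cells containing at least one
#' raw gaze sample in the cumulative window `[t0, t0 + window]`, where `t0`
#' is the first sample's timestamp. Threshold-free by design; see
#' [coverage_curve()] for the full time course.
#'
#' @param stream cleaned gaze tibble.
#' @param window cumulative window duration in seconds (> 0).
#' @param width,height image size in pixels.
#' @param grid_h,grid_w analysis grid.
#' @return coverage in percent (scalar).
#' @export
coverage <- function(stream, window, width = 256L, height = 256L,
                     grid_h = 15L, grid_w = 15L) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  df <- tibble::as_tibble(stream)
  if (nrow(df) == 0L) return(0)
  t0 <- df$t_s[1]
  df <- df[df$t_s <= t0 + window, , drop = FALSE]
  cells <- cue_to_cell(pmin(pmax(df$x_px, 0), width - 1e-9),
                       pmin(pmax(df$y_px, 0), height - 1e-9),
                       stimulus("cov", width, height, K = 2),
                       grid_h, grid_w)$cell
  100 * length(unique(cells)) / (grid_h * grid_w)
}

#' Image-coverage curve over cumulative viewing windows
#'
#' @param stream cleaned gaze tibble.
#' @param windows cumulative window durations in seconds (default 1..10).
#'   Windows extending past the end of the stream are truncated at the
#'   stream end (viewing duration is participant-determined).
#' @inheritParams coverage
#' @return a tibble `window_s`, `coverage_pct`, `truncated`.
#' @export
coverage_curve <- function(stream, windows = 1:10, width = 256L,
                           height = 256L, grid_h = 15L, grid_w = 15L) {
  df <- tibble::as_tibble(stream)
  dur <- if (nrow(df)) max(df$t_s) - df$t_s[1] else 0
  tibble::tibble(
    window_s = as.numeric(windows),
    coverage_pct = vapply(windows, function(w) {
      coverage(df, w, width, height, grid_h, grid_w)
    }, numeric(1)),
    truncated = windows > dur
  )
}
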