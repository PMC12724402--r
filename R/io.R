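#' Read and write maps as delimited text with a JSON sidecar
#'
#' Maps serialize to tab-separated text with one row per cell (0-based
#' `row`, `col` in row-major order, then either K probability columns, one
#' `label` column, or one `entropy_bits` column) plus a `.json` sidecar
#' recording `grid_h`, `grid_w`, `K`, and the map kind.
#'
#' @param map a `prob_seg_map`, `seg_map`, or `entropy_map`.
#' @param path output `.tsv` path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  kind <- class(map)[1]
  df <- as_tibble(map)
  readr::write_tsv(df, path)
  meta <- list(grid_h = map$grid_h, grid_w = map$grid_w, K = map$K,
               kind = kind)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  df <- df[order(df$row, df$col), , drop = FALSE]
  switch(meta$kind,
    prob_seg_map = prob_seg_map(
      unname(as.matrix(df[paste0("p", seq_len(meta$K))])),
      meta$grid_h, meta$grid_w),
    seg_map = seg_map(df$label, meta$grid_h, meta$grid_w, K = meta$K),
    entropy_map = entropy_map_values(df$entropy_bits, meta$grid_h,
                                     meta$grid_w, K = meta$K),
    stop("unknown map kind: ", meta$kind, call. = FALSE)
  )
}

#' Read and write experimental blocks
#'
#' Blocks serialize to tab-separated trial tables (`trial_index`,
#' `cue_a_x`, `cue_a_y`, `cue_b_x`, `cue_b_y`, `response`, `rt_s`) with a
#' JSON sidecar for the participant, cohort, and stimulus metadata.
#'
#' @param block a [block_data()] block.
#' @param path output `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_block <- function(block, path) {
  stopifnot(inherits(block, "perceptseg_block"))
  m <- block_meta(block)
  readr::write_tsv(tibble::as_tibble(block), path)
  jsonlite::write_json(
    list(participant_id = m$participant_id, cohort = m$cohort,
         stimulus = unclass(m$stimulus)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_block
#' @export
read_block <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trials <- readr::read_tsv(path, show_col_types = FALSE)
  stim <- stimulus(meta$stimulus$stim_id, meta$stimulus$width,
                   meta$stimulus$height, meta$stimulus$K,
                   meta$stimulus$category)
  block_data(trials, meta$participant_id, meta$cohort, stim)
}

#' Read and write gaze streams
#'
#' Delimited text with columns `t_s`, `x_px`, `y_px`, `valid`.
#'
#' @param stream gaze tibble.
#' @param path `.tsv` path.
#' @return `path` (write) / tibble (read).
#' @export
write_gaze <- function(stream, path) {
  readr::write_tsv(tibble::as_tibble(stream), path)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  df$valid <- as.logical(df$valid)
  df
}

#' Serialize an Information Gain result to JSON
#'
#' @param x an `ig_result`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_ig_result <- function(x, path) {
  stopifnot(inherits(x, "ig_result"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write epoch sets as delimited long-format text
#'
#' A plain-text adapter for small epoch fixtures: a long table with one
#' row per (channel, sample, epoch) value plus a JSON sidecar for the
#' channel layout, time axis, reaction times, and metadata. Intended for
#' interchange and testing, not for full-size recordings.
#'
#' @param epochs an [epoch_set()].
#' @param path output `.tsv` path.
#' @return `path` (write) / `epoch_set` (read).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  df <- tibble::tibble(
    channel = rep(epochs$channels$channel, times = d[2] * d[3]),
    sample = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    epoch = rep(seq_len(d[3]), each = d[1] * d[2]),
    uv = as.vector(epochs$data)
  )
  readr::write_tsv(df, path)
  jsonlite::write_json(
    list(channels = epochs$channels, times_ms = epochs$times_ms,
         rt_s = epochs$rt_s, srate = epochs$srate, cohort = epochs$cohort,
         participant_id = epochs$participant_id,
         block_id = epochs$block_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  n_ch <- nrow(meta$channels)
  n_t <- length(meta$times_ms)
  n_e <- length(meta$rt_s)
  df <- df[order(df$epoch, df$sample,
                 match(df$channel, meta$channels$channel)), ]
  data <- array(df$uv, dim = c(n_ch, n_t, n_e))
  epoch_set(data, tibble::as_tibble(meta$channels), meta$times_ms,
            meta$rt_s, srate = meta$srate, cohort = meta$cohort,
            participant_id = meta$participant_id,
            block_id = meta$block_id)
}
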