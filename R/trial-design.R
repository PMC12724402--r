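#' Stimulus metadata
#'
#' @param stim_id stimulus identifier.
#' @param width,height image size in pixels (default 256 x 256).
#' @param K number of segments the observer is instructed to use (2..5).
#' @param category `"natural"` or `"texture"`.
#' @return a `stimulus` list.
#' @export
stimulus <- function(stim_id, width = 256L, height = 256L, K = 2L,
                     category = c("natural", "texture")) {
  category <- match.arg(category)
  K <- as.integer(K)
  if (K < 2L || K > 5L) stop("K must be in 2..5", call. = FALSE)
  if (width < 1L || height < 1L) stop("image dimensions must be positive",
                                      call. = FALSE)
  structure(list(stim_id = as.character(stim_id), width = as.integer(width),
                 height = as.integer(height), K = K, category = category),
            class = "stimulus")
}

#' Number of trials required for a block
#'
#' A block's length is the minimum number of same/different trials needed to
#' reconstruct a segmentation map at the analysis-grid resolution for the
#' requested number of segments K: `cells * (K - 1)`. For the default
#' 15 x 15 grid this gives 225, 450, 675, and 900 trials for K = 2..5.
#'
#' @param K number of segments (2..5).
#' @param grid_h,grid_w analysis grid dimensions.
#' @return trial count (integer scalar).
#' @examples
#' trial_schedule(2)  # 225
#' trial_schedule(5)  # 900
#' @export
trial_schedule <- function(K, grid_h = 15L, grid_w = 15L) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L || K > 5L) stop("K must be in 2..5", call. = FALSE)
  as.integer(grid_h) * as.integer(grid_w) * (K - 1L)
}

#' Map an image pixel to its analysis-grid cell
#'
#' Pixels are 0-based with x = column and y = row; the image area is split
#' into a uniform grid of half-open cells, with the final row/column edge
#' closed so border pixels fall in the last cell.
#'
#' @param x,y pixel coordinates (vectors allowed).
#' @param stimulus a [stimulus()] giving the image extent.
#' @param grid_h,grid_w analysis grid dimensions.
#' @return a tibble with 0-based `cell_row`, `cell_col`, and the row-major
#'   1-based `cell` index.
#' @export
cue_to_cell <- function(x, y, stimulus, grid_h = 15L, grid_w = 15L) {
  if (any(x < 0 | x >= stimulus$width | y < 0 | y >= stimulus$height)) {
    stop("cue coordinates outside the image area", call. = FALSE)
  }
  col <- pmin(floor(x * grid_w / stimulus$width), grid_w - 1L)
  row <- pmin(floor(y * grid_h / stimulus$height), grid_h - 1L)
  tibble::tibble(
    cell_row = as.integer(row), cell_col = as.integer(col),
    cell = as.integer(row * grid_w + col + 1L)
  )
}

# Center pixel coordinate of a 1-based row-major cell index.
cell_center <- function(cell, stimulus, grid_h = 15L, grid_w = 15L) {
  row <- (cell - 1L) %/% grid_w
  col <- (cell - 1L) %% grid_w
  tibble::tibble(
    x = (col + 0.5) * stimulus$width / grid_w - 0.5,
    y = (row + 0.5) * stimulus$height / grid_h - 0.5
  )
}

#' Generate a balanced pseudorandom cue-pair schedule
#'
#' Draws `n_trials` pairs of distinct grid cells such that cue endpoints are
#' spread as evenly as possible over the grid (max and min per-cell endpoint
#' counts differ by at most 1 by construction), then renders each cell as
#' its center pixel coordinate. If self-pairs cannot be resolved by swapping
#' (pathological counts), the schedule degrades to uniform sampling of
#' distinct cells with a warning.
#'
#' @param n_trials number of trials (>= 1).
#' @param stimulus a [stimulus()].
#' @param grid_h,grid_w analysis grid dimensions.
#' @param seed integer seed.
#' @return a tibble with one row per trial: `trial_index`, `cue_a_x`,
#'   `cue_a_y`, `cue_b_x`, `cue_b_y` (pixels), and cell indices `cell_a`,
#'   `cell_b`.
#' @export
generate_cue_pairs <- function(n_trials, stimulus, grid_h = 15L,
                               grid_w = 15L, seed = 1L) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be at least 1", call. = FALSE)
  n_cells <- as.integer(grid_h) * as.integer(grid_w)
  if (n_cells < 2L) stop("grid must contain at least 2 cells", call. = FALSE)

  withr::with_seed(seed, {
    n_end <- 2L * n_trials
    base <- n_end %/% n_cells
    extra <- n_end %% n_cells
    counts <- rep(base, n_cells)
    if (extra > 0) counts[sample.int(n_cells, extra)] <- base + 1L
    pool <- sample(rep.int(seq_len(n_cells), counts))
    a <- pool[seq_len(n_trials)]
    b <- pool[n_trials + seq_len(n_trials)]
    # resolve self-pairs by swapping second endpoints between trials
    for (attempt in seq_len(50)) {
      bad <- which(a == b)
      if (length(bad) == 0) break
      j <- sample.int(n_trials, length(bad), replace = FALSE)
      tmp <- b[bad]
      b[bad] <- b[j]
      b[j] <- tmp
    }
    if (any(a == b)) {
      warning("balanced cue schedule infeasible; using uniform sampling",
              call. = FALSE)
      pairs <- replicate(n_trials, sample.int(n_cells, 2L))
      a <- pairs[1, ]
      b <- pairs[2, ]
    }
    ca <- cell_center(a, stimulus, grid_h, grid_w)
    cb <- cell_center(b, stimulus, grid_h, grid_w)
    tibble::tibble(
      trial_index = seq_len(n_trials),
      cue_a_x = ca$x, cue_a_y = ca$y,
      cue_b_x = cb$x, cue_b_y = cb$y,
      cell_a = a, cell_b = b
    )
  })
}

#' Assemble one experimental block
#'
#' A block is one participant segmenting one stimulus: an ordered trial
#' table carrying the cue-pair pixel coordinates, the same/different
#' response, and the reaction time, plus participant/cohort/stimulus
#' metadata stored as attributes.
#'
#' @param trials tibble with columns `trial_index`, `cue_a_x`, `cue_a_y`,
#'   `cue_b_x`, `cue_b_y`, `response` ("same"/"different"), `rt_s`.
#' @param participant_id participant identifier.
#' @param cohort `"NT"` or `"ASD"`.
#' @param stimulus a [stimulus()].
#' @return the trial tibble with class `perceptseg_block` and metadata
#'   attributes `participant_id`, `cohort`, `stimulus`.
#' @export
block_data <- function(trials, participant_id, cohort = c("NT", "ASD"),
                       stimulus) {
  cohort <- match.arg(cohort)
  trials <- tibble::as_tibble(trials)
  need <- c("trial_index", "cue_a_x", "cue_a_y", "cue_b_x", "cue_b_y",
            "response", "rt_s")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(trials$trial_index)) {
    stop("trial_index must be unique within a block", call. = FALSE)
  }
  if (!all(trials$response %in% c("same", "different"))) {
    stop("responses must be 'same' or 'different'", call. = FALSE)
  }
  if (any(trials$rt_s <= 0)) stop("reaction times must be positive",
                                  call. = FALSE)
  ok_x <- trials$cue_a_x >= 0 & trials$cue_a_x < stimulus$width &
    trials$cue_b_x >= 0 & trials$cue_b_x < stimulus$width
  ok_y <- trials$cue_a_y >= 0 & trials$cue_a_y < stimulus$height &
    trials$cue_b_y >= 0 & trials$cue_b_y < stimulus$height
  if (!all(ok_x & ok_y)) stop("cue coordinates outside the image",
                              call. = FALSE)
  structure(trials,
            class = c("perceptseg_block", class(trials)),
            participant_id = as.character(participant_id),
            cohort = cohort, stimulus = stimulus)
}

block_meta <- function(block) {
  list(participant_id = attr(block, "participant_id"),
       cohort = attr(block, "cohort"),
       stimulus = attr(block, "stimulus"))
}

#' @export
print.perceptseg_block <- function(x, ...) {
  m <- block_meta(x)
  cat(sprintf("<perceptseg_block> %s (%s), stimulus %s (K = %d), %d trials\n",
              m$participant_id, m$cohort, m$stimulus$stim_id, m$stimulus$K,
              nrow(x)))
  NextMethod()
}
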