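#' Channel adjacency from 2-D scalp positions
#'
#' Neighbourhood structure for cluster statistics, derived by Delaunay
#' triangulation of the 2-D channel layout (Bowyer-Watson incremental
#' construction); two channels are neighbours when they share a Delaunay
#' edge. A deterministic sub-nanometre jitter avoids degenerate cocircular
#' configurations.
#'
#' @param channels tibble with `channel`, `x`, `y`.
#' @return symmetric logical adjacency matrix with channel dimnames.
#' @export
delaunay_adjacency <- function(channels) {
  x <- channels$x
  y <- channels$y
  n <- length(x)
  if (n < 3L) stop("need at least 3 channels", call. = FALSE)
  scale <- max(diff(range(x)), diff(range(y)), 1e-9)
  jit <- seq_len(n)
  px <- x + scale * 1e-9 * sin(jit * 12.9898)
  py <- y + scale * 1e-9 * sin(jit * 78.233)

  # super-triangle well outside the point cloud
  cx <- mean(range(px))
  cy <- mean(range(py))
  r <- 10 * scale
  px <- c(px, cx - 2 * r, cx + 2 * r, cx)
  py <- c(py, cy - r, cy - r, cy + 2 * r)
  sup <- n + 1:3

  circum <- function(i, j, k) {
    ax <- px[i]; ay <- py[i]; bx <- px[j]; by <- py[j]
    cx_ <- px[k]; cy_ <- py[k]
    d <- 2 * (ax * (by - cy_) + bx * (cy_ - ay) + cx_ * (ay - by))
    if (abs(d) < 1e-14 * scale^2) return(NULL)
    a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx_^2 + cy_^2
    ux <- (a2 * (by - cy_) + b2 * (cy_ - ay) + c2 * (ay - by)) / d
    uy <- (a2 * (cx_ - bx) + b2 * (ax - cx_) + c2 * (bx - ax)) / d
    c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
  }

  tris <- list(list(v = sup, cc = circum(sup[1], sup[2], sup[3])))
  for (p in seq_len(n)) {
    bad <- vapply(tris, function(tr) {
      (px[p] - tr$cc[1])^2 + (py[p] - tr$cc[2])^2 <= tr$cc[3] * (1 + 1e-12)
    }, logical(1))
    # boundary of the cavity: edges of bad triangles appearing exactly once
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      v <- tr$v
      rbind(sort(c(v[1], v[2])), sort(c(v[2], v[3])), sort(c(v[1], v[3])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1L)), ,
                      drop = FALSE]
    tris <- tris[!bad]
    for (e in seq_len(nrow(boundary))) {
      v <- c(boundary[e, ], p)
      cc <- circum(v[1], v[2], v[3])
      if (!is.null(cc)) tris <- c(tris, list(list(v = v, cc = cc)))
    }
  }
  adj <- matrix(FALSE, n, n, dimnames = list(channels$channel,
                                             channels$channel))
  for (tr in tris) {
    v <- tr$v
    if (any(v %in% sup)) next
    adj[v[1], v[2]] <- adj[v[2], v[1]] <- TRUE
    adj[v[2], v[3]] <- adj[v[3], v[2]] <- TRUE
    adj[v[1], v[3]] <- adj[v[3], v[1]] <- TRUE
  }
  adj
}

# Connected components of the significant channel x time mask under
# space-time adjacency; returns cluster id per significant point and the
# summed-t mass per cluster.
cluster_masses <- function(tmat, mask, adj_pairs) {
  C <- nrow(mask)
  TT <- ncol(mask)
  sig <- which(mask)
  if (length(sig) == 0L) return(numeric(0))
  # temporal edges: same channel, consecutive samples
  te <- which(mask[, -TT, drop = FALSE] & mask[, -1, drop = FALSE])
  t_from <- te + 0L            # linear index in C x (TT-1) equals C x TT index
  t_to <- te + C
  # spatial edges: adjacent channels at the same sample
  se_from <- integer(0)
  se_to <- integer(0)
  if (nrow(adj_pairs)) {
    both <- mask[adj_pairs[, 1], , drop = FALSE] &
      mask[adj_pairs[, 2], , drop = FALSE]
    hit <- which(both)
    if (length(hit)) {
      pr <- (hit - 1L) %% nrow(adj_pairs) + 1L
      tc <- (hit - 1L) %/% nrow(adj_pairs)
      se_from <- adj_pairs[pr, 1] + tc * C
      se_to <- adj_pairs[pr, 2] + tc * C
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(c(t_from, se_from)),
               to = as.character(c(t_to, se_to))),
    directed = FALSE,
    vertices = data.frame(name = as.character(sig))
  )
  memb <- igraph::components(g)$membership
  tapply(tmat[as.integer(names(memb))], memb, sum)
}

#' Cluster-based permutation test across channels and time
#'
#' Corrects for multiple comparisons over the full spatiotemporal grid:
#' pointwise Welch t-tests form clusters of contiguous significant points
#' (neighbouring channels at a time sample, consecutive samples within a
#' channel; positive and negative effects clustered separately), each
#' cluster is scored by its summed t mass, and cluster p-values come from
#' the permutation distribution of the maximum absolute cluster mass under
#' random reassignment of units to groups (add-one convention).
#'
#' @param group_a,group_b lists of `erp` objects (full channel set), or
#'   3-D arrays units x channels x time.
#' @param adjacency channel adjacency matrix (see [delaunay_adjacency()]);
#'   derived from the first ERP's channel positions if omitted.
#' @param n_perm number of permutations (default 1000).
#' @param cluster_alpha cluster-forming pointwise threshold.
#' @param seed integer seed.
#' @return a tibble of clusters: `cluster`, `mass`, `n_points`, `p_value`,
#'   `significant`, with the pointwise t matrix as attribute `t_matrix`.
#' @export
cluster_permutation_test <- function(group_a, group_b, adjacency = NULL,
                                     n_perm = 1000L, cluster_alpha = 0.05,
                                     seed = 1L) {
  A <- as_unit_array(group_a)
  B <- as_unit_array(group_b)
  if (is.null(adjacency)) {
    if (is.list(group_a) && inherits(group_a[[1]], "erp")) {
      adjacency <- delaunay_adjacency(group_a[[1]]$channels)
    } else stop("supply `adjacency` for array input", call. = FALSE)
  }
  nA <- dim(A)[1]
  nB <- dim(B)[1]
  if (nA < 2L || nB < 2L) stop("need at least 2 units per group",
                               call. = FALSE)
  C <- dim(A)[2]
  TT <- dim(A)[3]
  adj_pairs <- which(adjacency & upper.tri(adjacency), arr.ind = TRUE)

  flat <- function(X) matrix(X, nrow = dim(X)[1])  # units x (C*T)
  all_units <- rbind(flat(A), flat(B))

  stat_masses <- function(rows_a) {
    w <- welch_cols(all_units[rows_a, , drop = FALSE],
                    all_units[-rows_a, , drop = FALSE])
    tmat <- matrix(w$t, C, TT)
    pmat <- matrix(w$p, C, TT)
    c(cluster_masses(tmat, pmat < cluster_alpha & tmat > 0, adj_pairs),
      cluster_masses(tmat, pmat < cluster_alpha & tmat < 0, adj_pairs))
  }

  obs_w <- welch_cols(all_units[seq_len(nA), , drop = FALSE],
                      all_units[-seq_len(nA), , drop = FALSE])
  tmat <- matrix(obs_w$t, C, TT)
  pmat <- matrix(obs_w$p, C, TT)
  pos <- cluster_masses(tmat, pmat < cluster_alpha & tmat > 0, adj_pairs)
  neg <- cluster_masses(tmat, pmat < cluster_alpha & tmat < 0, adj_pairs)
  obs <- c(pos, neg)

  null_max <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      rows <- sample.int(nA + nB, nA)
      m <- stat_masses(rows)
      if (length(m) == 0L) 0 else max(abs(m))
    }, numeric(1))
  })

  if (length(obs) == 0L) {
    out <- tibble::tibble(cluster = integer(0), mass = numeric(0),
                          n_points = integer(0), p_value = numeric(0),
                          significant = logical(0))
  } else {
    pv <- vapply(obs, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
    npts <- c(count_points(tmat, pmat < cluster_alpha & tmat > 0, adj_pairs),
              count_points(tmat, pmat < cluster_alpha & tmat < 0, adj_pairs))
    ord <- order(abs(obs), decreasing = TRUE)
    out <- tibble::tibble(cluster = seq_along(obs),
                          mass = as.numeric(obs)[ord],
                          n_points = as.integer(npts)[ord],
                          p_value = pv[ord],
                          significant = pv[ord] <= 0.05)
  }
  attr(out, "t_matrix") <- tmat
  attr(out, "null_max") <- null_max
  out
}

count_points <- function(tmat, mask, adj_pairs) {
  m <- cluster_masses(matrix(1, nrow(mask), ncol(mask)), mask, adj_pairs)
  as.integer(m)
}

as_unit_array <- function(g) {
  if (is.list(g) && !is.data.frame(g) && inherits(g[[1]], "erp")) {
    arr <- array(0, dim = c(length(g), nrow(g[[1]]$data),
                            ncol(g[[1]]$data)))
    for (i in seq_along(g)) arr[i, , ] <- g[[i]]$data
    return(arr)
  }
  stopifnot(length(dim(g)) == 3L)
  g
}
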