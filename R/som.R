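# Self-organizing map over compositional profiles. This is the automated
# stand-in for interactive ESOM curation: train a toroidal SOM on window
# profiles, compute the U-matrix, and delineate bins as connected
# low-U-matrix node regions.

#' Default SOM grid dimensions
#'
#' About `ceiling(sqrt(5 * n))` nodes arranged close to a 1:1.6 rectangle.
#' @param n_profiles number of training profiles.
#' @return integer c(rows, cols).
#' @export
som_grid_dims <- function(n_profiles) {
  n_nodes <- ceiling(sqrt(5 * n_profiles))
  rows <- max(2L, round(sqrt(n_nodes / 1.6)))
  cols <- max(2L, ceiling(n_nodes / rows))
  c(rows = rows, cols = cols)
}

# Squared toroidal grid distance between node coordinate matrices
torus_dist2 <- function(coords, rows, cols, toroidal) {
  dr <- abs(outer(coords[, 1], coords[, 1], "-"))
  dc <- abs(outer(coords[, 2], coords[, 2], "-"))
  if (toroidal) {
    dr <- pmin(dr, rows - dr)
    dc <- pmin(dc, cols - dc)
  }
  dr^2 + dc^2
}

#' Train a self-organizing map on profile vectors
#'
#' Online training with a Gaussian neighborhood; both the neighborhood
#' radius and the learning rate decay linearly over the run. The grid is
#' toroidal by default. Training is deterministic for a fixed seed and
#' invariant to the input row order: profiles are canonicalized
#' (lexicographically sorted) before the seeded presentation order is drawn.
#'
#' @param profiles numeric matrix, one profile per row (e.g. 136 canonical
#'   TNF classes per column).
#' @param grid_rows,grid_cols grid dimensions; default [som_grid_dims()].
#' @param epochs passes over the data (default 20).
#' @param alpha0,alpha1 initial/final learning rate.
#' @param radius0 initial neighborhood radius; default half the larger grid
#'   dimension.
#' @param radius1 final neighborhood radius (default 0.3: by the end of
#'   training essentially only the best-matching unit moves, so prototypes
#'   inside a cluster spread over its internal variance and interpolating
#'   nodes are left on the ridges between clusters — which is what U-matrix
#'   delineation needs).
#' @param toroidal wrap the grid edges (default TRUE).
#' @param seed integer seed.
#' @return object of class `som_grid`: list with `weights` (nodes x
#'   features), `rows`, `cols`, `coords`, `toroidal`, `qe` (mean
#'   quantization error recorded after each epoch) and the training
#'   metadata.
#' @export
train_som <- function(profiles, grid_rows = NULL, grid_cols = NULL,
                      epochs = 20, alpha0 = 0.25, alpha1 = 0.01,
                      radius0 = NULL, radius1 = 0.3, toroidal = TRUE,
                      seed = 1L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0) stop("cannot train a SOM on an empty profile set")
  if (any(!is.finite(profiles))) stop("profiles must be finite")
  if (is.null(grid_rows) || is.null(grid_cols)) {
    dims <- som_grid_dims(nrow(profiles))
    if (is.null(grid_rows)) grid_rows <- dims[["rows"]]
    if (is.null(grid_cols)) grid_cols <- dims[["cols"]]
  }
  if (grid_rows < 2 || grid_cols < 2) stop("grid must be at least 2x2")
  n_nodes <- grid_rows * grid_cols
  if (is.null(radius0)) radius0 <- max(grid_rows, grid_cols) / 2
  coords <- cbind(rep(seq_len(grid_rows), times = grid_cols),
                  rep(seq_len(grid_cols), each = grid_rows))
  nd2 <- torus_dist2(coords, grid_rows, grid_cols, toroidal)

  # canonical row order makes training independent of input permutation
  canon <- do.call(order, as.data.frame(unname(profiles)))
  X <- profiles[canon, , drop = FALSE]
  n <- nrow(X)

  qe_hist <- numeric(epochs)
  W <- NULL
  with_seed(seed, {
    init_idx <- sample.int(n, n_nodes, replace = n < n_nodes)
    W <- X[init_idx, , drop = FALSE] +
      matrix(stats::rnorm(n_nodes * ncol(X), sd = 1e-4), n_nodes)
    total <- epochs * n
    step <- 0
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i in ord) {
        frac <- step / max(1, total - 1)
        alpha <- alpha0 + (alpha1 - alpha0) * frac
        radius <- radius0 + (radius1 - radius0) * frac
        x <- X[i, ]
        d2 <- rowSums(sweep(W, 2, x)^2)
        bmu <- which.min(d2)  # which.min takes the lowest index on ties
        h <- exp(-nd2[, bmu] / (2 * radius^2))
        active <- h > 1e-3
        W[active, ] <- W[active, , drop = FALSE] +
          (alpha * h[active]) * sweep(-W[active, , drop = FALSE], 2, x, "+")
        step <- step + 1
      }
      bm <- best_matching_units(W, X)
      qe_hist[ep] <- mean(bm$dist)
    }
  })
  structure(list(weights = W, rows = as.integer(grid_rows),
                 cols = as.integer(grid_cols), coords = coords,
                 toroidal = toroidal, qe = qe_hist,
                 meta = list(epochs = epochs, alpha = c(alpha0, alpha1),
                             radius = c(radius0, radius1), seed = seed)),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("<som_grid %dx%d (%s), %d features, final QE %.4g>\n",
              x$rows, x$cols, if (x$toroidal) "toroidal" else "planar",
              ncol(x$weights), x$qe[length(x$qe)]))
  invisible(x)
}

# BMU index and Euclidean distance for each profile row; ties -> lowest index
best_matching_units <- function(W, X) {
  xw <- X %*% t(W)
  w2 <- rowSums(W^2)
  x2 <- rowSums(X^2)
  d2 <- sweep(-2 * xw, 2, w2, "+") + x2
  d2[d2 < 0] <- 0
  node <- max.col(-d2, ties.method = "first")
  list(node = node, dist = sqrt(d2[cbind(seq_len(nrow(X)), node)]))
}

#' U-matrix of a trained SOM
#'
#' Per node, the mean Euclidean weight-space distance to its (4-neighborhood)
#' grid neighbors; valleys are clusters, ridges are cluster boundaries.
#' @param som a `som_grid`.
#' @return numeric vector, one value per node.
#' @export
som_umatrix <- function(som) {
  vapply(seq_len(nrow(som$weights)), function(i) {
    nb <- grid_neighbors(i, som$rows, som$cols, som$toroidal)
    mean(sqrt(rowSums(sweep(som$weights[nb, , drop = FALSE], 2,
                            som$weights[i, ])^2)))
  }, 0)
}

# Otsu's threshold on a numeric vector: the cut maximizing between-class
# variance over all observed split points
otsu_threshold <- function(x) {
  xs <- sort(unique(x))
  if (length(xs) == 1) return(xs)
  best <- xs[1]; best_var <- -Inf
  for (t in xs[-length(xs)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    w <- length(lo) / length(x)
    v <- w * (1 - w) * (mean(lo) - mean(hi))^2
    if (v > best_var) { best_var <- v; best <- t }
  }
  best
}

# 4-neighborhood of node i (column-major grid), honoring toroidal wrap
grid_neighbors <- function(i, rows, cols, toroidal) {
  r <- (i - 1) %% rows + 1
  c <- (i - 1) %/% rows + 1
  nb <- list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
  keep <- list()
  for (x in nb) {
    if (toroidal) {
      x[1] <- (x[1] - 1) %% rows + 1
      x[2] <- (x[2] - 1) %% cols + 1
    } else if (x[1] < 1 || x[1] > rows || x[2] < 1 || x[2] > cols) next
    keep[[length(keep) + 1]] <- x
  }
  unique(vapply(keep, function(x) (x[2] - 1) * rows + x[1], 0))
}

#' Delineate bins from a trained SOM
#'
#' Automated replacement for manual ESOM curation: a node is cluster
#' interior when its U-matrix value is at or below the threshold AND at
#' least one profile maps to it (the data-density condition of U*-matrix
#' practice: unoccupied low-distance nodes are interpolation corridors
#' between clusters, not cluster interior, and must not connect them).
#' Connected components (4-connectivity on the grid, honoring the torus) of
#' interior nodes become bins, labeled `bin_001`, `bin_002`, ... in order of
#' their smallest node index. Profiles whose best-matching unit is a
#' boundary node are "unbinned". A best-matching-unit tie between nodes of
#' different bins resolves to the lowest bin id.
#'
#' @param som trained `som_grid`.
#' @param profiles the profile matrix to assign (rows keep their names).
#' @param u_percentile U-matrix percentile separating interior from boundary
#'   nodes, or `"auto"` (default) to place the threshold by a two-class
#'   Otsu split of the node U-values. A fixed percentile presumes a
#'   particular fraction of the grid is cluster interior, which varies with
#'   how densely the data occupy the map; the variance-based split adapts
#'   to it.
#' @return list with `assignment` (data.frame profile_id, node, bin_id),
#'   `node_bins` (per-node bin label or NA for boundary), `umatrix`,
#'   `threshold`.
#' @export
delineate_bins <- function(som, profiles, u_percentile = "auto") {
  stopifnot(inherits(som, "som_grid"))
  profiles <- as.matrix(profiles)
  u <- som_umatrix(som)
  thr <- if (identical(u_percentile, "auto")) otsu_threshold(u)
         else unname(quantile(u, u_percentile / 100))
  occupancy <- tabulate(best_matching_units(som$weights, profiles)$node,
                        nbins = nrow(som$weights))
  interior <- which(u <= thr & occupancy > 0)
  node_bins <- rep(NA_integer_, length(u))
  comp <- 0L
  visited <- logical(length(u))
  for (s in interior) {
    if (visited[s]) next
    comp <- comp + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      node_bins[cur] <- comp
      nb <- grid_neighbors(cur, som$rows, som$cols, som$toroidal)
      nb <- nb[nb %in% interior & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  labels <- ifelse(is.na(node_bins), NA_character_,
                   sprintf("bin_%03d", node_bins))
  bm <- best_matching_units(som$weights, profiles)
  # resolve exact BMU distance ties toward the lowest bin id
  xw <- profiles %*% t(som$weights)
  d2 <- sweep(-2 * xw, 2, rowSums(som$weights^2), "+") + rowSums(profiles^2)
  assign_bin <- character(nrow(profiles))
  node_pick <- integer(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    cand <- which(abs(d2[i, ] - min(d2[i, ])) < 1e-12)
    labs <- labels[cand]
    if (all(is.na(labs))) {
      pick <- cand[1]
    } else {
      binned <- cand[!is.na(labs)]
      pick <- binned[order(labels[binned], binned)][1]
    }
    node_pick[i] <- pick
    assign_bin[i] <- if (is.na(labels[pick])) "unbinned" else labels[pick]
  }
  list(assignment = data.frame(profile_id = rownames(profiles),
                               node = node_pick, bin_id = assign_bin,
                               stringsAsFactors = FALSE),
       node_bins = labels, umatrix = u, threshold = thr)
}

#' Majority vote from window assignments to a per-scaffold bin
#'
#' Each scaffold takes the majority bin of its windows; ties resolve to the
#' lowest bin id, with "unbinned" losing any tie against a real bin;
#' scaffolds whose majority is "unbinned" stay unbinned.
#'
#' @param window_assignment data.frame with columns `scaffold_id` and
#'   `bin_id` (one row per window).
#' @return data.frame scaffold_id, bin_id, n_windows, vote_fraction.
#' @export
scaffold_bin_vote <- function(window_assignment) {
  stopifnot(all(c("scaffold_id", "bin_id") %in% names(window_assignment)))
  res <- lapply(split(window_assignment$bin_id,
                      window_assignment$scaffold_id), function(v) {
    tab <- table(v)
    top <- max(tab)
    winners <- sort(names(tab)[tab == top])  # "unbinned" sorts after bin_*
    data.frame(bin_id = winners[1], n_windows = length(v),
               vote_fraction = top / length(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(scaffold_id = names(res), stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
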