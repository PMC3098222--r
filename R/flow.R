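#' Inward/outward weight fractions per cluster
#'
#' For each cluster, sums the weight it sends to other clusters
#' (`out`) and receives from them (`in`), diagonal excluded, and
#' reports the outward fraction `out / (out + in)`. Isolated clusters
#' (no inter-cluster weight) get `NA` fractions.
#'
#' @param cluster_graph An [aggregate_clusters()] result with k >= 2.
#' @return A tibble `cluster`, `w_out`, `w_in`, `outward_fraction`,
#'   `inward_fraction`.
#' @export
inout_ratio <- function(cluster_graph) {
  W <- cluster_graph$W
  if (nrow(W) < 2) abort("in/out ratios need at least two clusters")
  k <- nrow(W)
  off <- W; diag(off) <- 0
  w_out <- unname(colSums(off))  # weight sent by cluster c (column = sender)
  w_in <- unname(rowSums(off))
  tot <- w_out + w_in
  tibble::tibble(
    cluster = rownames(W) %||% as.character(seq_len(k)),
    w_out = w_out, w_in = w_in,
    outward_fraction = ifelse(tot > 0, w_out / tot, NA_real_),
    inward_fraction = ifelse(tot > 0, w_in / tot, NA_real_))
}

#' Hub and authority scores of the cluster network
#'
#' Power iteration of the mutually reinforcing recurrences: a cluster's
#' authority score sums the hub scores of its senders, and its hub
#' score sums the authority scores of its receivers. Scores are
#' L2-normalized every step and iterated to relative tolerance 1e-10;
#' both vectors are nonnegative with unit norm, and invariant to global
#' scaling of the weights. The diagonal (intra-cluster weight) is
#' excluded by default since the quantity of interest is between-cluster
#' flow.
#'
#' @param cluster_graph An [aggregate_clusters()] result.
#' @param exclude_diagonal Zero the diagonal before iterating?
#' @param max_iter Iteration cap.
#' @return A tibble `cluster`, `hub`, `authority`.
#' @export
hits_scores <- function(cluster_graph, exclude_diagonal = TRUE,
                        max_iter = 10000) {
  M <- cluster_graph$W  # M[i, j] = weight j -> i
  if (nrow(M) < 2) abort("hub/authority scores need at least two clusters")
  if (exclude_diagonal) diag(M) <- 0
  if (all(M == 0)) abort("cluster network has no (off-diagonal) weight")
  k <- nrow(M)
  h <- rep(1 / sqrt(k), k)
  a <- rep(1 / sqrt(k), k)
  for (it in seq_len(max_iter)) {
    a_new <- as.vector(M %*% h)
    if (sum(a_new^2) > 0) a_new <- a_new / sqrt(sum(a_new^2))
    h_new <- as.vector(crossprod(M, a_new))
    if (sum(h_new^2) > 0) h_new <- h_new / sqrt(sum(h_new^2))
    if (max(abs(a_new - a)) < 1e-10 && max(abs(h_new - h)) < 1e-10) {
      a <- a_new; h <- h_new
      break
    }
    a <- a_new; h <- h_new
  }
  tibble::tibble(cluster = rownames(cluster_graph$W) %||%
                   as.character(seq_len(k)),
                 hub = h, authority = a)
}

#' Mean pairwise 1-D distances within and between clusters
#'
#' Entry (i, j) is the mean absolute position difference over all pairs
#' with one node in cluster i and one in cluster j; the diagonal is the
#' mean over distinct pairs within the cluster (NA for singletons).
#'
#' @param positions Named numeric vector of 1-D positions in `[0, 1]`.
#' @param partition Partition over the same nodes.
#' @return A symmetric k x k matrix.
#' @export
intercluster_distances <- function(positions, partition) {
  p <- as_partition(partition)
  if (!is.null(names(positions))) positions <- positions[names(p)]
  if (anyNA(positions)) abort("positions must be available for all nodes")
  idx <- split(seq_along(p), p)
  k <- length(idx)
  D <- matrix(NA_real_, k, k, dimnames = list(names(idx), names(idx)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xi <- positions[idx[[i]]]; xj <- positions[idx[[j]]]
      dm <- abs(outer(xi, xj, "-"))
      if (i == j) {
        if (length(xi) < 2) next
        D[i, j] <- sum(dm) / (length(xi) * (length(xi) - 1))
      } else {
        D[i, j] <- mean(dm)
      }
    }
  }
  D
}

#' Per-cluster spatial density along the body axis
#'
#' Gaussian kernel density of each cluster's positions on a uniform
#' grid over `[0, 1]`, with boundary reflection at 0 and 1 so each
#' curve integrates to 1 (trapezoid rule, within 1e-2). Bandwidth
#' defaults to Silverman's rule per cluster.
#'
#' @inheritParams intercluster_distances
#' @param bandwidth Fixed kernel bandwidth, or `NULL` for Silverman's
#'   rule per cluster.
#' @param grid_n Number of grid points.
#' @return A tibble `cluster`, `x`, `density`.
#' @export
spatial_density <- function(positions, partition, bandwidth = NULL,
                            grid_n = 256) {
  p <- as_partition(partition)
  if (!is.null(names(positions))) positions <- positions[names(p)]
  if (any(positions < 0 | positions > 1, na.rm = TRUE)) {
    abort("positions must lie in [0, 1]")
  }
  grid <- seq(0, 1, length.out = grid_n)
  out <- list()
  for (cl in sort(unique(unname(p)))) {
    x <- positions[p == cl]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      warn(paste0("cluster ", cl, " has no positioned nodes; omitted"))
      next
    }
    bw <- bandwidth %||% {
      s <- stats::sd(x); iqr <- stats::IQR(x)
      spread <- if (is.na(s) || s == 0) 0 else min(s, iqr / 1.34)
      if (spread == 0) 0.02 else 0.9 * spread * length(x)^(-1 / 5)
    }
    kern <- function(g, pts) {
      rowMeans(stats::dnorm(outer(g, pts, "-"), sd = bw))
    }
    # reflect mass that leaks past the [0, 1] boundaries back inside
    dens <- kern(grid, x) + kern(grid, -x) + kern(grid, 2 - x)
    out[[length(out) + 1]] <- tibble::tibble(cluster = cl, x = grid,
                                             density = dens)
  }
  dplyr::bind_rows(out)
}

#' Density curves per cluster
#' @param x A [spatial_density()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_spatial_density <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$x, y = .data$density,
                                  color = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "anterior-posterior position", y = "density",
                  color = "cluster")
}
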