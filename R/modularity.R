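#' Directed weighted modularity of a partition
#'
#' The modularity of a partition of a directed weighted network is
#' \deqn{Q = \frac{1}{w} \sum_{ij : c_i = c_j}
#'   \left[ A_{ij} - \frac{S^{in}_i S^{out}_j}{w} \right],}
#' where `A[i, j]` is the weight from node `j` to node `i`,
#' `S_in`/`S_out` are row/column sums and `w` the grand total. The null
#' term pairs the receiver's in-strength with the sender's
#' out-strength, so `Q` measures how much within-cluster weight exceeds
#' the expectation of a strength-matched random network. Self-loops are
#' always within-cluster and are included in the double sum.
#'
#' @param network A [connectome][as_connectome] (or any object with a
#'   nonnegative adjacency matrix in `$A`).
#' @param partition Named integer vector of cluster labels, or a data
#'   frame with columns `name` and `cluster`.
#' @return A single numeric value.
#' @examples
#' conn <- tibble::tibble(
#'   source = c("a", "b", "c", "d"), target = c("b", "a", "d", "c"),
#'   type = "chemical", count = 1)
#' net <- as_connectome(conn, quiet = TRUE)
#' modularity_q(net, c(a = 1, b = 1, c = 2, d = 2))  # 0.5
#' @export
modularity_q <- function(network, partition) {
  A <- network$A
  if (sum(A) <= 0) abort("modularity is undefined for a network with zero total weight")
  p <- as_partition(partition, rownames(A))
  w <- sum(A)
  s_in <- rowSums(A)
  s_out <- colSums(A)
  q <- 0
  for (c_idx in split(seq_len(nrow(A)), p)) {
    q <- q + sum(A[c_idx, c_idx]) - sum(s_in[c_idx]) * sum(s_out[c_idx]) / w
  }
  q / w
}

#' Exact modularity change for moving one unit
#'
#' Computes the change in modularity from reassigning a move unit (a
#' single node, or a bilateral pair moved as one) to another cluster,
#' incrementally from the unit's rows and columns rather than by
#' re-evaluating the whole sum.
#'
#' @inheritParams modularity_q
#' @param unit Character vector of one or two node names (a pair's two
#'   members must currently share a cluster).
#' @param target_cluster Label of the destination cluster; may be a
#'   fresh (previously unused) label to split the unit off.
#' @return The change `dQ = Q(after) - Q(before)`.
#' @export
delta_q_move <- function(network, partition, unit, target_cluster) {
  A <- network$A
  nms <- rownames(A)
  p <- as_partition(partition, nms)
  u <- match(unit, nms)
  if (anyNA(u)) abort("unit names a node absent from the network")
  w <- sum(A)
  s_in <- rowSums(A)
  s_out <- colSums(A)
  from <- unique(p[u])
  if (length(from) != 1) abort("all members of the move unit must share a cluster")
  target_cluster <- as.integer(target_cluster)
  if (target_cluster == from) return(0)

  old_rest <- setdiff(which(p == from), u)
  new_mem <- setdiff(which(p == target_cluster), u)
  link <- function(members) {
    if (length(members) == 0) return(0)
    sum(A[u, members, drop = FALSE]) + sum(A[members, u, drop = FALSE])
  }
  s_in_u <- sum(s_in[u]); s_out_u <- sum(s_out[u])
  dqw <- link(new_mem) - link(old_rest) -
    (s_in_u * sum(s_out[new_mem]) + s_out_u * sum(s_in[new_mem])) / w +
    (s_in_u * sum(s_out[old_rest]) + s_out_u * sum(s_in[old_rest])) / w
  dqw / w
}

#' Canonicalize cluster labels
#'
#' Relabels clusters to contiguous integers `1..k` in order of first
#' appearance. Idempotent; names are preserved.
#'
#' @param partition Named integer vector or `name`/`cluster` data frame.
#' @return Named integer vector with labels `1..k`.
#' @examples
#' canonicalize_partition(c(a = 5, b = 5, c = 2))  # a=1 b=1 c=2
#' @export
canonicalize_partition <- function(partition) {
  p <- as_partition(partition)
  if (length(p) == 0) return(p)
  stats::setNames(match(p, unique(p)), names(p))
}

#' Count of non-empty clusters
#' @param partition A partition in any accepted form.
#' @return Integer number of distinct labels.
#' @export
n_clusters <- function(partition) {
  length(unique(as_partition(partition)))
}

#' Cluster sizes of a partition
#' @param partition A partition in any accepted form.
#' @return A tibble with columns `cluster` and `size`, largest first.
#' @export
cluster_sizes <- function(partition) {
  p <- canonicalize_partition(partition)
  tb <- table(p)
  tibble::tibble(cluster = as.integer(names(tb)), size = as.integer(tb)) |>
    dplyr::arrange(dplyr::desc(.data$size))
}
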