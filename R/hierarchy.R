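#' Aggregate a partition into a cluster-level network
#'
#' Builds the k x k weight matrix between clusters under the same
#' direction convention as the node-level adjacency: `W[c, d]` is the
#' summed weight of edges from cluster `d` to cluster `c`, and the
#' diagonal holds intra-cluster weight (including self-loops). Total
#' weight is conserved exactly.
#'
#' @inheritParams modularity_q
#' @return An object of class `cluster_graph`: matrix `W`, per-cluster
#'   node counts `sizes`, total `w`, and the canonical `partition` used.
#' @examples
#' conn <- tibble::tibble(
#'   source = c("a", "b", "c", "d"), target = c("b", "a", "d", "c"),
#'   type = "chemical", count = 1)
#' net <- as_connectome(conn, quiet = TRUE)
#' aggregate_clusters(net, c(a = 1, b = 1, c = 2, d = 2))$W
#' @export
aggregate_clusters <- function(network, partition) {
  A <- network$A
  p <- canonicalize_partition(as_partition(partition, rownames(A)))
  k <- length(unique(p))
  W <- matrix(0, k, k, dimnames = list(seq_len(k), seq_len(k)))
  idx <- split(seq_len(nrow(A)), p)
  for (c_i in seq_len(k)) {
    for (d_i in seq_len(k)) {
      W[c_i, d_i] <- sum(A[idx[[c_i]], idx[[d_i]], drop = FALSE])
    }
  }
  structure(list(W = W,
                 sizes = as.integer(lengths(idx)),
                 w = sum(W),
                 partition = p),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat(sprintf("<cluster_graph> %d clusters | w = %g\n", nrow(x$W), x$w))
  invisible(x)
}

#' Re-cluster the cluster-level network
#'
#' Runs the same annealing modularity maximization (without a pairing
#' constraint) on the aggregated cluster graph, self-loops included, to
#' obtain the next hierarchy level: a grouping of clusters into grand
#' clusters. Keeping the diagonal makes the modularity of the
#' super-partition on the cluster graph equal the modularity of the
#' corresponding merged partition on the original network.
#'
#' @param cluster_graph A [aggregate_clusters()] result (k >= 2).
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed.
#' @return Named integer vector grouping clusters into super-clusters.
#' @export
super_partition <- function(cluster_graph, schedule = anneal_schedule(),
                            seed = 1L) {
  W <- cluster_graph$W
  if (nrow(W) < 2) abort("super-partitioning needs at least two clusters")
  res <- anneal(list(A = W), pairing = NULL, schedule = schedule, seed = seed)
  res$partition
}

#' Two-level hierarchical nomenclature for clusters
#'
#' Labels each base cluster as a two-digit string: the left digit is
#' its grand (super) cluster, the right digit its index within the
#' grand cluster (e.g. `"11", "12", "13", "21", "22"`). Ordering is
#' deterministic: super-clusters by descending total intra-cluster
#' weight (descending member count if no cluster graph is supplied),
#' clusters within a super-cluster by descending node count.
#'
#' @param super Named grouping of clusters (from [super_partition()]).
#' @param cluster_graph Optional [aggregate_clusters()] result used for
#'   the ordering and cluster sizes.
#' @return Named character vector mapping cluster label -> nomenclature.
#' @export
assign_nomenclature <- function(super, cluster_graph = NULL) {
  super <- as_partition(super)
  cl <- names(super) %||% as.character(seq_along(super))
  sizes <- if (!is.null(cluster_graph)) cluster_graph$sizes else rep(1L, length(super))
  intra <- if (!is.null(cluster_graph)) diag(cluster_graph$W) else sizes
  sup_ids <- unique(super)
  sup_weight <- vapply(sup_ids, function(s) sum(intra[super == s]), numeric(1))
  sup_order <- sup_ids[order(-sup_weight)]
  out <- character(length(super))
  names(out) <- cl
  for (d in seq_along(sup_order)) {
    members <- which(super == sup_order[d])
    members <- members[order(-sizes[members])]
    out[members] <- paste0(d, seq_along(members))
  }
  out
}

#' Two-level hierarchy of a partition
#'
#' Convenience wrapper: aggregates the partition, re-clusters the
#' cluster graph, and assigns the two-digit nomenclature to nodes.
#'
#' @inheritParams modularity_q
#' @inheritParams super_partition
#' @return A list of class `cluster_hierarchy`: `cluster_graph`,
#'   `super` (grouping of clusters), `labels` (cluster -> nomenclature),
#'   `node_labels` (tibble `name`, `cluster`, `label`), and a Newick
#'   string of the two-level dendrogram.
#' @export
cluster_hierarchy <- function(network, partition,
                              schedule = anneal_schedule(), seed = 1L) {
  cg <- aggregate_clusters(network, partition)
  sup <- if (nrow(cg$W) >= 2) super_partition(cg, schedule, seed) else
    stats::setNames(1L, "1")
  labels <- assign_nomenclature(sup, cg)
  p <- cg$partition
  node_labels <- tibble::tibble(name = names(p), cluster = unname(p),
                                label = labels[as.character(p)])
  grands <- split(unname(labels), substr(labels, 1, 1))
  newick <- paste0("(", paste(vapply(grands, function(g) {
    if (length(g) == 1) g else paste0("(", paste(sort(g), collapse = ","), ")")
  }, character(1)), collapse = ","), ");")
  structure(list(cluster_graph = cg, super = sup, labels = labels,
                 node_labels = node_labels, newick = newick),
            class = "cluster_hierarchy")
}

#' @export
print.cluster_hierarchy <- function(x, ...) {
  cat("<cluster_hierarchy>", x$newick, "\n")
  invisible(x)
}

#' @method tidy cluster_hierarchy
#' @export
tidy.cluster_hierarchy <- function(x, ...) x$node_labels
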