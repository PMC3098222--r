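#' Out-strength-preserving rewiring null model
#'
#' Randomizes a network by target-exchange moves: two directed weighted
#' edges (j1 -> i1, w1) and (j2 -> i2, w2) swap their targets, giving
#' (j1 -> i2, w1) and (j2 -> i1, w2). A swap that would create a
#' self-loop is rejected. Weights stay attached to their source, so the
#' out-strength vector is preserved exactly; in-strengths redistribute.
#' Parallel edges arising from a swap have their weights summed in the
#' resulting adjacency matrix; the underlying edge list keeps its
#' length.
#'
#' @param network A [connectome][as_connectome].
#' @param n_swaps Number of attempted swaps (default 10 x edge count).
#' @param seed Integer seed.
#' @return A `connectome` with identical node set and out-strengths.
#' @export
rewire_out_strengths <- function(network, n_swaps = NULL, seed = 1L) {
  A <- network$A
  nz <- which(A > 0, arr.ind = TRUE)
  if (nrow(nz) < 2) abort("rewiring needs at least two edges")
  src <- nz[, 2]; tgt <- nz[, 1]; wgt <- A[nz]
  m <- length(src)
  n_swaps <- n_swaps %||% (10L * m)
  if (n_swaps < 0) abort("n_swaps must be nonnegative")
  withr::local_seed(as.integer(seed))
  if (n_swaps > 0) {
    e1 <- sample.int(m, n_swaps, replace = TRUE)
    e2 <- sample.int(m, n_swaps, replace = TRUE)
    for (s in seq_len(n_swaps)) {
      a <- e1[s]; b <- e2[s]
      if (a == b) next
      ta <- tgt[a]; tb <- tgt[b]
      if (src[a] == tb || src[b] == ta) next  # would create a self-loop
      tgt[a] <- tb; tgt[b] <- ta
    }
  }
  n <- nrow(A)
  B <- matrix(0, n, n, dimnames = dimnames(A))
  for (e in seq_len(m)) B[tgt[e], src[e]] <- B[tgt[e], src[e]] + wgt[e]
  out <- network
  out$A <- B
  out$s_in <- rowSums(B)
  out$s_out <- colSums(B)
  out$w <- sum(B)
  out$connections <- adjacency_to_connections(B)
  # rewired weights are no longer attributable to synapse classes
  out$n_chemical <- sum(B)
  out$n_electrical <- 0
  out$meta$isolated <- (out$s_in + out$s_out) == 0
  out
}

#' Null distribution of modularity under strength-preserving rewiring
#'
#' Generates `n_null` rewired networks (each by out-strength-preserving
#' target exchange) and runs the constrained annealer on each to obtain
#' the modularity a strength-matched random network supports. By
#' default the same pairing constraint as the real run is applied.
#'
#' @inheritParams anneal
#' @param n_null Number of null networks (>= 2).
#' @param swaps_per_edge Target-exchange attempts per edge.
#' @param n_restarts Restarts per null network (reduced relative to the
#'   real run).
#' @param seed Integer master seed.
#' @return A list of class `null_q`: `mean`, `sd`, `samples`.
#' @export
null_q_distribution <- function(network, pairing = NULL, n_null = 10,
                                schedule = anneal_schedule(),
                                swaps_per_edge = 10, n_restarts = 1,
                                seed = 1L) {
  if (n_null < 2) abort("n_null must be at least 2")
  m <- sum(network$A > 0)
  samples <- vapply(seq_len(n_null), function(b) {
    rn <- rewire_out_strengths(network, n_swaps = swaps_per_edge * m,
                               seed = stage_seed(seed, b))
    multi_restart(rn, pairing, schedule, n_restarts = n_restarts,
                  seed = stage_seed(seed, n_null + b))$best$best_q
  }, numeric(1))
  structure(list(mean = mean(samples), sd = stats::sd(samples),
                 samples = samples),
            class = "null_q")
}

#' @export
print.null_q <- function(x, ...) {
  cat(sprintf("<null_q> mean %.3f +/- %.3f over %d null networks\n",
              x$mean, x$sd, length(x$samples)))
  invisible(x)
}

#' Uniformly random partition with fixed cluster sizes
#'
#' @param sizes Integer cluster sizes; must sum to the number of nodes.
#' @param node_ids Node names.
#' @param seed Integer seed.
#' @return Named integer partition with exactly the given sizes.
#' @export
random_partition_fixed_sizes <- function(sizes, node_ids, seed = 1L) {
  sizes <- as.integer(sizes)
  node_ids <- as.character(node_ids)
  if (sum(sizes) != length(node_ids)) {
    abort("cluster sizes must sum to the number of nodes")
  }
  withr::local_seed(as.integer(seed))
  perm <- sample(node_ids)
  stats::setNames(rep(seq_along(sizes), sizes)[match(node_ids, perm)], node_ids)
}
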