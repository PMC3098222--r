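# Shared fixtures: tiny analytic networks and random instances.

# Four nodes with reciprocal unit edges a<->b and c<->d (w = 4).
# With partition {a,b}{c,d} modularity is exactly 0.5.
four_node_net <- function() {
  conn <- tibble::tibble(
    source = c("a", "b", "c", "d"),
    target = c("b", "a", "d", "c"),
    type = "chemical", count = 1)
  as_connectome(conn, quiet = TRUE)
}

# Random directed weighted network with Poisson weights; no self-loops.
random_network <- function(n, seed, density = 0.5, lambda = 2) {
  set.seed(seed)
  repeat {
    A <- matrix(stats::rpois(n * n, lambda) *
                  stats::rbinom(n * n, 1, density), n, n)
    diag(A) <- 0
    if (sum(A) > 0) break
  }
  dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
  conn <- tibble::tibble(
    source = colnames(A)[which(A > 0, arr.ind = TRUE)[, 2]],
    target = rownames(A)[which(A > 0, arr.ind = TRUE)[, 1]],
    type = "chemical",
    count = A[A > 0])
  as_connectome(conn, metadata = tibble::tibble(name = rownames(A)),
                quiet = TRUE)
}

# quick schedule for tests that only need a working optimizer
fast_schedule <- function() {
  anneal_schedule(T0 = 0.05, cool = 0.98, node_moves_factor = 10,
                  T_min = 1e-3, stall_limit = 60)
}
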