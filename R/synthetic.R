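#' Specification for a planted-partition connectome
#'
#' Describes a directed weighted benchmark network with known (planted)
#' modular blocks, heavy-tailed weight options, bilateral node pairs
#' that co-occur in planted clusters, and categorical node metadata.
#'
#' @param sizes Integer vector of planted cluster sizes.
#' @param mu_in,mu_out Mean weight per directed dyad within / between
#'   planted clusters; detectable structure needs `mu_in > mu_out >= 0`.
#' @param weight_model `"poisson"` (dyad weight ~ Poisson(mu)) or
#'   `"powerlaw"` (dyad present with probability chosen so the mean is
#'   `mu`; present weights follow a truncated zeta law).
#' @param alpha,cap Exponent and upper truncation of the discrete
#'   power-law weight distribution (used when `weight_model = "powerlaw"`).
#' @param pair_fraction Fraction of nodes placed into bilateral pairs;
#'   paired nodes share a planted cluster and carry names ending in
#'   `L`/`R` so [infer_bilateral_pairs()] recovers them.
#' @param mirror Probability that a paired node copies its partner's
#'   weight on each outside dyad (correlated connection profiles).
#' @param seed Integer seed; the generated network is a pure function
#'   of the spec.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(sizes, mu_in, mu_out,
                         weight_model = c("poisson", "powerlaw"),
                         alpha = 2.5, cap = 50,
                         pair_fraction = 0, mirror = 0.5, seed = 1L) {
  weight_model <- match.arg(weight_model)
  sizes <- as.integer(sizes)
  if (any(sizes < 1)) abort("cluster sizes must be positive")
  if (!(mu_in > mu_out && mu_out >= 0)) {
    abort("need mu_in > mu_out >= 0 for a detectable planted structure")
  }
  if (pair_fraction < 0 || pair_fraction > 1) abort("pair_fraction must lie in [0, 1]")
  structure(list(sizes = sizes, mu_in = mu_in, mu_out = mu_out,
                 weight_model = weight_model, alpha = alpha, cap = cap,
                 pair_fraction = pair_fraction, mirror = mirror,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

# mean of the zeta law truncated at `cap`
trunc_zeta_mean <- function(alpha, cap) {
  k <- seq_len(cap)
  p <- k^(-alpha); p <- p / sum(p)
  sum(k * p)
}

draw_weights <- function(nd, mu, spec) {
  if (spec$weight_model == "poisson") {
    stats::rpois(nd, mu)
  } else {
    k <- seq_len(spec$cap)
    p <- k^(-spec$alpha); p <- p / sum(p)
    pres <- stats::rbinom(nd, 1, min(1, mu / sum(k * p)))
    pres * sample(k, nd, replace = TRUE, prob = p)
  }
}

#' Generate a planted-partition directed weighted network
#'
#' For every ordered dyad (i, j), i != j, a weight is drawn from the
#' spec's weight model with mean `mu_in` when the planted clusters of i
#' and j coincide and `mu_out` otherwise. Bilateral pairs are planted
#' inside one cluster, receive an extra reciprocal edge of weight at
#' least 1, and (with probability `mirror` per dyad) copy each other's
#' connection weights. Metadata emulates a 1-D body plan: positions are
#' beta-distributed around each cluster's center `c/(k+1)`, ganglia are
#' position deciles `G1..G10`, and neuronal types are drawn from a
#' cluster-biased distribution over sensory/inter/motor/poly.
#'
#' @param spec A [planted_spec()].
#' @return A list with elements `network` (a `connectome`), `truth`
#'   (named planted partition) and `pairing` (a `bilateral_pairing`).
#' @examples
#' g <- generate_planted(planted_spec(c(4, 4), 3, 0, seed = 7))
#' modularity_q(g$network, g$truth) > 0
#' @export
generate_planted <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  withr::local_seed(spec$seed)
  sizes <- spec$sizes
  k <- length(sizes)
  n <- sum(sizes)
  truth_raw <- rep(seq_len(k), sizes)

  # pairs per cluster: consecutive slots, planted together
  n_pairs_c <- floor(sizes * spec$pair_fraction / 2)
  if (spec$pair_fraction > 0 && sum(n_pairs_c) == 0) {
    abort("pair_fraction too small to place any pair in these cluster sizes")
  }
  if (any(2 * n_pairs_c > sizes)) abort("impossible spec: pairs exceed cluster size")

  nms <- character(n)
  pair_a <- integer(0); pair_b <- integer(0)
  idx <- 1L; pid <- 1L
  for (c_i in seq_len(k)) {
    m <- sizes[c_i]
    np <- n_pairs_c[c_i]
    for (q in seq_len(np)) {
      nms[idx] <- sprintf("P%03dL", pid)
      nms[idx + 1L] <- sprintf("P%03dR", pid)
      pair_a <- c(pair_a, idx); pair_b <- c(pair_b, idx + 1L)
      idx <- idx + 2L; pid <- pid + 1L
    }
    n_single <- m - 2L * np
    if (n_single > 0) {
      nms[idx:(idx + n_single - 1L)] <- sprintf("N%03d", idx:(idx + n_single - 1L))
      idx <- idx + n_single
    }
  }

  same <- outer(truth_raw, truth_raw, "==")
  A <- matrix(0, n, n)
  off <- !diag(TRUE, n)
  A[off & same] <- draw_weights(sum(off & same), spec$mu_in, spec)
  A[off & !same] <- draw_weights(sum(off & !same), spec$mu_out, spec)

  # correlated profiles + guaranteed reciprocal edge for each pair
  for (q in seq_along(pair_a)) {
    u <- pair_a[q]; v <- pair_b[q]
    others <- setdiff(seq_len(n), c(u, v))
    copy <- stats::runif(length(others)) < spec$mirror
    A[v, others[copy]] <- A[u, others[copy]]
    A[others[copy], v] <- A[others[copy], u]
    A[v, u] <- A[v, u] + 1 + stats::rpois(1, spec$mu_in)
    A[u, v] <- A[u, v] + 1 + stats::rpois(1, spec$mu_in)
  }
  dimnames(A) <- list(nms, nms)

  centers <- seq_len(k) / (k + 1)
  conc <- 30
  position <- stats::rbeta(n, conc * centers[truth_raw],
                           conc * (1 - centers[truth_raw]))
  ganglion <- paste0("G", pmin(10L, 1L + floor(position * 10)))
  types <- c("sensory", "inter", "motor", "poly")
  type_probs <- function(c_i) {
    base <- c(0.3, 0.3, 0.3, 0.1)
    rot <- ((c_i - 1) %% 4)
    base[((seq_len(4) - 1 + rot) %% 4) + 1]
  }
  ntype <- vapply(truth_raw,
                  function(c_i) sample(types, 1, prob = type_probs(c_i)),
                  character(1))

  meta <- tibble::tibble(name = nms, position = position,
                         ganglion = ganglion, ntype = ntype)
  conn <- adjacency_to_connections(A)
  net <- as_connectome(conn, meta, quiet = TRUE)
  truth <- canonicalize_partition(stats::setNames(truth_raw, nms))[node_names(net)]
  pairing <- bilateral_pairing(nms[pair_a], nms[pair_b], net)
  list(network = net, truth = truth, pairing = pairing)
}

# internal: decompose an arbitrary nonnegative matrix (A[i,j] = j -> i)
# into canonical chemical connection rows
adjacency_to_connections <- function(A) {
  nz <- which(A > 0, arr.ind = TRUE)
  tibble::tibble(source = colnames(A)[nz[, 2]],
                 target = rownames(A)[nz[, 1]],
                 type = "chemical",
                 count = A[nz])
}

#' Generate a functional grouping correlated with a planted truth
#'
#' Emulates an experimentally derived functional labeling of a node
#' subset. At `scramble = 0` the grouping is a refinement of the planted
#' partition restricted to the subset; at `scramble = 1` every label is
#' uniform random. Intermediate values interpolate by relabeling each
#' node with probability `scramble`.
#'
#' @param truth Named planted partition.
#' @param n_groups Number of functional groups (>= 2).
#' @param scramble Probability in `[0, 1]` of randomizing each label.
#' @param seed Integer seed.
#' @param subset Character vector of node names to label (default: all).
#' @return Named integer grouping over `subset`; empty input gives an
#'   empty grouping.
#' @export
generate_functional_grouping <- function(truth, n_groups, scramble, seed = 1L,
                                         subset = names(truth)) {
  if (n_groups < 2) abort("n_groups must be at least 2")
  if (scramble < 0 || scramble > 1) abort("scramble must lie in [0, 1]")
  truth <- as_partition(truth)
  subset <- as.character(subset)
  if (length(subset) == 0) return(stats::setNames(integer(0), character(0)))
  if (!all(subset %in% names(truth))) abort("subset names nodes absent from truth")
  withr::local_seed(as.integer(seed))
  tr <- canonicalize_partition(truth[subset])
  k <- length(unique(tr))
  # allocate groups across truth clusters proportional to size (each >= 1)
  sz <- as.integer(table(tr))
  extra <- max(0L, n_groups - k)
  add <- rep(0L, k)
  if (extra > 0) {
    share <- floor(extra * sz / sum(sz))
    add <- share
    rem <- extra - sum(share)
    if (rem > 0) add[order(sz, decreasing = TRUE)[seq_len(rem)]] <-
        add[order(sz, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  lab <- integer(length(tr))
  next_lab <- 1L
  for (c_i in seq_len(k)) {
    members <- which(tr == c_i)
    n_sub <- min(length(members), 1L + add[c_i])
    sub <- 1L + (seq_along(members) %% n_sub)
    lab[members] <- next_lab + sub - 1L
    next_lab <- next_lab + n_sub
  }
  flip <- stats::runif(length(lab)) < scramble
  lab[flip] <- sample.int(n_groups, sum(flip), replace = TRUE)
  canonicalize_partition(stats::setNames(lab, subset))
}
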