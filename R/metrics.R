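#' Variation of information between two partitions
#'
#' VI is the sum of the two conditional entropies of the joint label
#' contingency table, `V = H(X|Y) + H(Y|X)`. It is a metric on
#' partitions: zero iff the partitions coincide, symmetric, and obeying
#' the triangle inequality. With `normalizer = "log_n"` the value is
#' divided by `log(n_norm)` (same base), which maps it into `[0, 1]`
#' when `n_norm` is the size of the compared node set; a larger
#' `n_norm` (e.g. the full-network size when comparing a subset
#' labeling) is also accepted for compatibility with analyses that
#' normalize by the whole network's capacity.
#'
#' @param p1,p2 Partitions over the same node set (named vectors or
#'   `name`/`cluster` data frames).
#' @param base Logarithm base: `"natural"` or `"2"`. Normalized values
#'   are base-invariant.
#' @param normalizer `"log_n"` or `"none"`.
#' @param n_norm Count whose log normalizes the value; defaults to the
#'   size of the compared node set.
#' @return A single numeric value.
#' @examples
#' p1 <- c(a = 1, b = 1, c = 2, d = 2)
#' p2 <- c(a = 1, b = 2, c = 2, d = 2)
#' variation_of_information(p1, p2, base = "2")
#' @export
variation_of_information <- function(p1, p2, base = c("natural", "2"),
                                     normalizer = c("log_n", "none"),
                                     n_norm = NULL) {
  base <- match.arg(base)
  normalizer <- match.arg(normalizer)
  p1 <- as_partition(p1); p2 <- as_partition(p2)
  if (length(p1) == 0 || length(p2) == 0) abort("partitions must be non-empty")
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      abort("partitions are defined over different node sets")
    }
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    abort("partitions are defined over different node sets")
  }
  n <- length(p1)
  lg <- if (base == "2") function(x) log2(x) else function(x) log(x)
  joint <- table(p1, p2) / n
  px <- rowSums(joint); py <- colSums(joint)
  ent <- function(p) { p <- p[p > 0]; -sum(p * lg(p)) }
  v <- 2 * ent(joint) - ent(px) - ent(py)  # H(X|Y) + H(Y|X)
  v <- max(v, 0)
  if (normalizer == "log_n") {
    n_norm <- n_norm %||% n
    if (n_norm < 2) abort("normalizer requires n_norm >= 2")
    v <- v / lg(n_norm)
  }
  v
}

#' Number of bilateral pairs split by a partition
#'
#' @param partition A partition covering the pairing's nodes.
#' @param pairing A [bilateral_pairing()].
#' @return Integer count of pairs whose members carry different labels.
#' @export
separated_pair_count <- function(partition, pairing) {
  if (is.null(pairing) || nrow(pairing) == 0) return(0L)
  p <- as_partition(partition)
  miss <- setdiff(c(pairing$a, pairing$b), names(p))
  if (length(miss) > 0) abort("pairing names nodes absent from the partition")
  sum(p[pairing$a] != p[pairing$b])
}

#' Bootstrap concordance test of a partition against a functional grouping
#'
#' Measures how consistent a community partition is with an independent
#' categorical grouping of a node subset. The observed statistic is the
#' normalized VI between the partition restricted to the subset and the
#' grouping. The null distribution is built from random partitions with
#' the same cluster size distribution as the full partition, restricted
#' to the subset. The one-sample t statistic compares the null sample's
#' mean against the observed value; an empirical tail probability
#' (fraction of null draws at or below the observed VI) is also
#' reported.
#'
#' @param partition Full-network partition.
#' @param grouping Named labeling of a non-empty node subset.
#' @param n_boot Number of bootstrap null draws (>= 100).
#' @param seed Integer seed for the null draws.
#' @inheritParams variation_of_information
#' @return A one-row tibble: `v_obs`, `null_mean`, `null_sd`, `t_stat`,
#'   `p_value` (two-sided t), `p_empirical`, `n_subset`, `n_boot`.
#' @export
concordance_test <- function(partition, grouping, n_boot = 1000, seed = 1L,
                             base = "natural", normalizer = "log_n",
                             n_norm = NULL) {
  p <- as_partition(partition)
  g <- as_partition(grouping)
  subset <- names(g)
  if (length(subset) == 0) abort("grouping covers no nodes")
  if (!all(subset %in% names(p))) abort("grouping names nodes absent from the partition")
  if (n_boot < 100) abort("n_boot must be at least 100")
  v_obs <- variation_of_information(p[subset], g, base = base,
                                    normalizer = normalizer, n_norm = n_norm)
  sizes <- as.integer(table(p))
  null_v <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      rp <- random_partition_fixed_sizes(sizes, names(p),
                                         seed = stage_seed(seed, b))
      variation_of_information(rp[subset], g, base = base,
                               normalizer = normalizer, n_norm = n_norm)
    }, numeric(1))
  })
  m <- mean(null_v); s <- stats::sd(null_v)
  t_stat <- (m - v_obs) / (s / sqrt(n_boot))
  tibble::tibble(
    v_obs = v_obs, null_mean = m, null_sd = s, t_stat = t_stat,
    p_value = 2 * stats::pt(-abs(t_stat), df = n_boot - 1),
    p_empirical = mean(null_v <= v_obs),
    n_subset = length(subset), n_boot = n_boot)
}
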