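#' Within-module weight (Z score)
#'
#' For node i with intra-cluster strength
#' `kappa_i` = total weight (incoming plus outgoing) between i and the
#' nodes of its own cluster, Z is the z-score of `kappa_i` within its
#' module, using the population standard deviation. Modules with zero
#' spread (including singletons) get Z = 0 for all members.
#'
#' @inheritParams modularity_q
#' @return A tibble with columns `name`, `cluster`, `kappa`, `z`.
#' @export
within_module_weight <- function(network, partition) {
  A <- network$A
  p <- as_partition(partition, rownames(A))
  n <- nrow(A)
  kappa <- numeric(n)
  idx <- split(seq_len(n), p)
  for (mem in idx) {
    kappa[mem] <- rowSums(A[mem, mem, drop = FALSE]) +
      colSums(A[mem, mem, drop = FALSE])
  }
  z <- numeric(n)
  for (mem in idx) {
    mu <- mean(kappa[mem])
    sdp <- sqrt(mean((kappa[mem] - mu)^2))
    z[mem] <- if (sdp > 0) (kappa[mem] - mu) / sdp else 0
  }
  tibble::tibble(name = rownames(A), cluster = unname(p),
                 kappa = kappa, z = z)
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (kappa_is / k_i)^2` where `kappa_is` is the total
#' weight (incoming plus outgoing) between node i and cluster s and
#' `k_i` its total strength. P is 0 when all of a node's weight stays
#' in one cluster and approaches `1 - 1/k` when spread evenly over k
#' clusters; isolated nodes get P = 0.
#'
#' @inheritParams modularity_q
#' @return A tibble with columns `name`, `cluster`, `p`.
#' @export
participation_coefficient <- function(network, partition) {
  A <- network$A
  p <- as_partition(partition, rownames(A))
  n <- nrow(A)
  idx <- split(seq_len(n), p)
  kis <- vapply(idx, function(mem) {
    rowSums(A[, mem, drop = FALSE]) + colSums(A[mem, , drop = FALSE])
  }, numeric(n))
  kis <- matrix(kis, nrow = n)
  k_tot <- rowSums(kis)
  part <- ifelse(k_tot > 0, 1 - rowSums((kis / pmax(k_tot, 1))^2), 0)
  part[k_tot == 0] <- 0
  tibble::tibble(name = rownames(A), cluster = unname(p), p = part)
}

#' Role classification thresholds
#'
#' Default cartography convention: hubs are nodes with `z >= z_hub`;
#' non-hubs split at participation breaks into ultra-peripheral (R1),
#' peripheral (R2), non-hub connector (R3) and non-hub kinless (R4)
#' classes; hubs split into provincial (R5), connector (R6) and kinless
#' (R7) hubs. Boundary values fall to the lower class.
#'
#' @param z_hub Hub threshold on Z.
#' @param p_breaks_nonhub Three increasing participation breaks.
#' @param p_breaks_hub Two increasing participation breaks.
#' @return A list of class `role_thresholds`.
#' @export
role_thresholds <- function(z_hub = 2.5,
                            p_breaks_nonhub = c(0.05, 0.62, 0.80),
                            p_breaks_hub = c(0.30, 0.75)) {
  if (is.unsorted(p_breaks_nonhub, strictly = TRUE) ||
      is.unsorted(p_breaks_hub, strictly = TRUE)) {
    abort("participation breaks must be strictly increasing")
  }
  structure(list(z_hub = z_hub, p_breaks_nonhub = p_breaks_nonhub,
                 p_breaks_hub = p_breaks_hub), class = "role_thresholds")
}

#' Classify nodes into cartographic roles R1-R7
#'
#' @param p,z Numeric vectors of participation coefficients and
#'   within-module weights (same length).
#' @param thresholds A [role_thresholds()].
#' @return Character vector of roles `"R1"`..`"R7"`.
#' @examples
#' classify_roles(c(0, 0.7, 0.5), c(0, 0, 3))
#' @export
classify_roles <- function(p, z, thresholds = role_thresholds()) {
  stopifnot(length(p) == length(z))
  hub <- z >= thresholds$z_hub
  bin_nh <- findInterval(p, thresholds$p_breaks_nonhub, left.open = TRUE) + 1L
  bin_h <- findInterval(p, thresholds$p_breaks_hub, left.open = TRUE) + 5L
  ifelse(hub, paste0("R", bin_h), paste0("R", bin_nh))
}

#' Index of qualitative variation
#'
#' `IQV = K/(K-1) * (1 - sum_c p_c^2)` over a categorical domain of K
#' possible categories: 0 when one category dominates completely, 1 for
#' a uniform composition.
#'
#' @param labels Vector of categorical observations.
#' @param levels Optional full category domain (defaults to the
#'   observed categories); `K = length(levels)` must be >= 2.
#' @return A number in `[0, 1]`.
#' @examples
#' iqv(c("a", "a", "b", "c"), levels = c("a", "b", "c"))
#' @export
iqv <- function(labels, levels = NULL) {
  labels <- as.character(labels)
  if (length(labels) == 0) abort("iqv needs at least one observation")
  levels <- levels %||% sort(unique(labels))
  k <- length(levels)
  if (k < 2) abort("iqv needs a category domain of at least 2")
  pr <- table(factor(labels, levels = levels)) / length(labels)
  (k / (k - 1)) * (1 - sum(pr^2))
}

#' Per-cluster composition and diversity of a categorical attribute
#'
#' Tabulates the proportion of each category within each cluster and
#' scores each cluster's heterogeneity by the IQV over the attribute's
#' global category domain. Missing attribute values become the
#' category `"unknown"`.
#'
#' @param partition Named partition.
#' @param attribute Named categorical vector over the same nodes (or a
#'   vector aligned with the partition).
#' @return A list with `composition` (tibble `cluster`, `category`,
#'   `n`, `prop`) and `iqv` (tibble `cluster`, `iqv`).
#' @export
cluster_composition <- function(partition, attribute) {
  p <- as_partition(partition)
  a <- attribute
  if (!is.null(names(a))) a <- a[names(p)]
  a <- as.character(a)
  a[is.na(a)] <- "unknown"
  stopifnot(length(a) == length(p))
  domain <- sort(unique(a))
  comp <- tibble::tibble(cluster = unname(p), category = a) |>
    dplyr::count(.data$cluster, .data$category, name = "n") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  iqv_tbl <- tibble::tibble(
    cluster = sort(unique(unname(p))),
    iqv = vapply(sort(unique(unname(p))),
                 function(cl) iqv(a[p == cl], levels = domain), numeric(1)))
  list(composition = comp, iqv = iqv_tbl)
}

#' Full cartography table for a clustered network
#'
#' Joins within-module weight, participation coefficient and role class
#' per node.
#'
#' @inheritParams modularity_q
#' @param thresholds A [role_thresholds()].
#' @return A tibble `name`, `cluster`, `kappa`, `z`, `p`, `role`.
#' @export
cartography <- function(network, partition, thresholds = role_thresholds()) {
  zt <- within_module_weight(network, partition)
  pt <- participation_coefficient(network, partition)
  out <- dplyr::left_join(zt, pt, by = c("name", "cluster"))
  out$role <- classify_roles(out$p, out$z, thresholds)
  out
}

#' P-Z cartography plane
#'
#' @param x A [cartography()] tibble.
#' @param thresholds The thresholds used (drawn as guide lines).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_cartography <- function(x, thresholds = role_thresholds(), ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$p, y = .data$z,
                                  color = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = thresholds$z_hub, linetype = 2) +
    ggplot2::geom_vline(xintercept = thresholds$p_breaks_nonhub,
                        linetype = 3, color = "grey50") +
    ggplot2::labs(x = "participation coefficient P",
                  y = "within-module weight Z")
}
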