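#' Annealing schedule
#'
#' Parameters of the metropolis simulated-annealing search. When `T0`
#' is `NULL` the initial temperature is calibrated from 100 probe moves
#' at the random start so that a median-magnitude unfavorable move is
#' accepted with probability about one half.
#'
#' @param T0 Initial temperature, or `NULL` to calibrate.
#' @param cool Multiplicative cooling factor per stage, in (0, 1).
#' @param node_moves_factor Unit-move proposals per stage are
#'   `node_moves_factor * n_units`.
#' @param T_min Stop temperature (> 0), or `NULL` for `T0 / 1000`
#'   (three decades of cooling below the calibrated start).
#' @param stall_limit Stages without best-Q improvement before stopping.
#' @return A list of class `anneal_schedule`.
#' @export
anneal_schedule <- function(T0 = NULL, cool = 0.995, node_moves_factor = 10,
                            T_min = NULL, stall_limit = 200) {
  if (!is.null(T0) && T0 <= 0) abort("T0 must be positive (or NULL to calibrate)")
  if (cool <= 0 || cool >= 1) abort("cool must lie strictly in (0, 1)")
  if (!is.null(T_min) && T_min <= 0) abort("T_min must be positive")
  if (!is.null(T0) && !is.null(T_min) && T0 <= T_min) abort("need T0 > T_min")
  structure(list(T0 = T0, cool = cool, node_moves_factor = node_moves_factor,
                 T_min = T_min, stall_limit = as.integer(stall_limit)),
            class = "anneal_schedule")
}

#' Metropolis acceptance rule
#'
#' Accepts a proposed move with probability 1 when the modularity gain
#' `dq` is nonnegative, and with probability `exp(dq / temp)` otherwise.
#'
#' @param dq Modularity change of the proposal.
#' @param temp Current temperature (> 0).
#' @return Logical: accept the move?
#' @export
metropolis_accept <- function(dq, temp) {
  if (temp <= 0) abort("temperature must be positive")
  dq >= 0 || stats::runif(1) < exp(dq / temp)
}

#' Constrained simulated-annealing modularity maximization
#'
#' Maximizes directed weighted modularity by a metropolis search whose
#' move units are single nodes or whole bilateral pairs: when a pairing
#' is supplied, both members of every pair are always reassigned
#' together, so no visited or returned partition ever separates a pair.
#' Each temperature stage proposes unit moves and then cluster merges;
#' the best partition ever visited is returned. Fully reproducible from
#' `seed` (the sampler has its own RNG and does not touch R's).
#'
#' @param network A [connectome][as_connectome] (or any object with a
#'   nonnegative adjacency matrix `$A` with positive total).
#' @param pairing Optional [bilateral_pairing()] of locked pairs.
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed.
#' @return An object of class `anneal_result`: `partition` (named,
#'   canonical labels), `best_q`, `q_trace` (per-stage best Q,
#'   non-decreasing), `acceptance_trace`, `separated_pairs` (always 0
#'   with a pairing), `sep_stage_trace` (separated pairs checked at
#'   every temperature stage), `n_stages`, `T0`, `seed`.
#' @examples
#' g <- generate_planted(planted_spec(c(5, 5), 4, 0, seed = 3))
#' res <- anneal(g$network, g$pairing, seed = 1)
#' glance(res)
#' @export
anneal <- function(network, pairing = NULL, schedule = anneal_schedule(),
                   seed = 1L) {
  A <- network$A
  nms <- rownames(A) %||% as.character(seq_len(nrow(A)))
  partner <- rep(-1L, nrow(A))
  if (!is.null(pairing) && nrow(pairing) > 0) {
    ia <- match(pairing$a, nms); ib <- match(pairing$b, nms)
    if (anyNA(ia) || anyNA(ib)) abort("pairing names nodes absent from the network")
    partner[ia] <- ib - 1L
    partner[ib] <- ia - 1L
  }
  res <- .cpp_anneal(A, partner,
                     T0 = schedule$T0 %||% -1,
                     cool = schedule$cool,
                     node_moves_factor = schedule$node_moves_factor,
                     T_min = schedule$T_min %||% -1,
                     stall_limit = schedule$stall_limit,
                     seed = as.numeric(seed))
  part <- canonicalize_partition(stats::setNames(res$assign + 1L, nms))
  structure(list(partition = part,
                 best_q = res$best_q,
                 q_trace = res$q_trace,
                 acceptance_trace = res$acceptance_trace,
                 separated_pairs = if (is.null(pairing)) NA_integer_ else
                   separated_pair_count(part, pairing),
                 sep_stage_trace = res$sep_trace,
                 n_stages = res$n_stages,
                 T0 = res$T0,
                 seed = as.integer(seed),
                 schedule = schedule),
            class = "anneal_result")
}

#' @export
print.anneal_result <- function(x, ...) {
  cat(sprintf("<anneal_result> Q = %.4f | k = %d | %d stages | seed %d\n",
              x$best_q, length(unique(x$partition)), x$n_stages, x$seed))
  invisible(x)
}

#' @method tidy anneal_result
#' @export
tidy.anneal_result <- function(x, ...) {
  tibble::tibble(name = names(x$partition), cluster = unname(x$partition))
}

#' @method glance anneal_result
#' @export
glance.anneal_result <- function(x, ...) {
  tibble::tibble(best_q = x$best_q,
                 k = length(unique(x$partition)),
                 n = length(x$partition),
                 separated_pairs = x$separated_pairs,
                 n_stages = x$n_stages,
                 seed = x$seed)
}

#' @method autoplot anneal_result
#' @export
autoplot.anneal_result <- function(object, ...) {
  df <- tibble::tibble(stage = seq_along(object$q_trace),
                       best_q = object$q_trace,
                       acceptance = object$acceptance_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$best_q)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "annealing stage", y = "best modularity Q")
}

#' Independent annealing restarts
#'
#' Runs `n_restarts` independent seeded annealing searches and returns
#' them sorted by modularity, together with the argmax result and the
#' pairwise normalized variation of information among the solutions in
#' the high-Q region (those within `q_window` of the best).
#'
#' @inheritParams anneal
#' @param n_restarts Number of restarts (>= 1).
#' @param q_window Solutions with `Q >= best_q - q_window` enter the
#'   stability summary.
#' @return An object of class `multi_anneal`: `results` (sorted list of
#'   [anneal()] results), `best`, and `vi_summary` (tibble with the
#'   number of high-Q solutions and mean/max pairwise normalized VI).
#' @export
multi_restart <- function(network, pairing = NULL,
                          schedule = anneal_schedule(),
                          n_restarts = 10, seed = 1L, q_window = 0.01) {
  stopifnot(n_restarts >= 1)
  results <- lapply(seq_len(n_restarts), function(i) {
    anneal(network, pairing, schedule, seed = stage_seed(seed, i))
  })
  qs <- vapply(results, function(r) r$best_q, numeric(1))
  results <- results[order(qs, decreasing = TRUE)]
  qs <- sort(qs, decreasing = TRUE)
  top <- which(qs >= qs[1] - q_window)
  vis <- numeric(0)
  if (length(top) >= 2) {
    cmb <- utils::combn(top, 2)
    vis <- vapply(seq_len(ncol(cmb)), function(j) {
      variation_of_information(results[[cmb[1, j]]]$partition,
                               results[[cmb[2, j]]]$partition)
    }, numeric(1))
  }
  structure(list(results = results, best = results[[1]],
                 vi_summary = tibble::tibble(
                   n_top = length(top),
                   mean_vi = if (length(vis)) mean(vis) else NA_real_,
                   max_vi = if (length(vis)) max(vis) else NA_real_)),
            class = "multi_anneal")
}

#' @export
print.multi_anneal <- function(x, ...) {
  cat(sprintf("<multi_anneal> %d restarts | best Q = %.4f | k = %d\n",
              length(x$results), x$best$best_q,
              length(unique(x$best$partition))))
  invisible(x)
}

#' @method glance multi_anneal
#' @export
glance.multi_anneal <- function(x, ...) {
  dplyr::bind_cols(glance(x$best), x$vi_summary)
}

#' @method tidy multi_anneal
#' @export
tidy.multi_anneal <- function(x, ...) {
  purrr::map_dfr(seq_along(x$results), function(i) {
    dplyr::mutate(glance(x$results[[i]]), restart = i)
  })
}
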