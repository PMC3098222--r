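#' End-to-end clustering pipeline
#'
#' Runs load -> constrained detection -> hierarchy -> null model ->
#' cartography -> flow on one configuration and returns (and optionally
#' writes) a machine-readable summary. A configuration fully determines
#' the run: the single master seed expands to per-stage seeds through a
#' counter-based splitter, so rerunning the same config reproduces the
#' same summary.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `connections`/`metadata` (paths to canonical TSVs) *or*
#'   `synthetic` (arguments to [planted_spec()]); optional `drop`
#'   (names to exclude), `pairs` (`"infer"`, `"none"`, or a path to a
#'   pairing TSV with columns `a`, `b`), `restarts`, `schedule`
#'   (arguments to [anneal_schedule()]), `null` (list with `n_null`,
#'   `swaps_per_edge`, `n_restarts`), `thresholds` (arguments to
#'   [role_thresholds()]), `seed`, `outdir`.
#' @return A list of class `pipeline_report` with the fitted pieces
#'   (`network`, `detection`, `hierarchy`, `null_q`, `cartography`,
#'   `flow`) and a flat `summary` list; when `outdir` is set, the
#'   partition TSV, cartography TSV and summary JSON are written there.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  schedule <- do.call(anneal_schedule, config$schedule %||% list())
  thresholds <- do.call(role_thresholds, config$thresholds %||% list())

  # --- load ---------------------------------------------------------
  truth <- NULL
  if (!is.null(config$synthetic)) {
    spec <- do.call(planted_spec, config$synthetic)
    g <- generate_planted(spec)
    network <- g$network
    truth <- g$truth
    pairing <- g$pairing
  } else {
    network <- read_wiring_tsv(config$connections, config$metadata,
                               drop = config$drop %||% character(),
                               quiet = TRUE)
    pairing <- NULL
  }
  pairs_cfg <- config$pairs %||% "infer"
  if (identical(pairs_cfg, "infer") && is.null(truth)) {
    pairing <- infer_bilateral_pairs(network)
  } else if (identical(pairs_cfg, "none")) {
    pairing <- NULL
  } else if (is.character(pairs_cfg) && file.exists(pairs_cfg)) {
    tb <- readr::read_tsv(pairs_cfg, show_col_types = FALSE)
    pairing <- bilateral_pairing(tb$a, tb$b, network)
  }

  # --- detect -------------------------------------------------------
  det <- multi_restart(network, pairing, schedule,
                       n_restarts = config$restarts %||% 10,
                       seed = stage_seed(seed, 1))
  best <- det$best

  # --- hierarchy ----------------------------------------------------
  hier <- cluster_hierarchy(network, best$partition, schedule,
                            seed = stage_seed(seed, 2))

  # --- null model ---------------------------------------------------
  null_cfg <- config$null %||% list()
  nq <- null_q_distribution(network, pairing,
                            n_null = null_cfg$n_null %||% 10,
                            schedule = schedule,
                            swaps_per_edge = null_cfg$swaps_per_edge %||% 10,
                            n_restarts = null_cfg$n_restarts %||% 1,
                            seed = stage_seed(seed, 3))

  # --- cartography & composition ------------------------------------
  carto <- cartography(network, best$partition, thresholds)
  ntype <- stats::setNames(network$meta$ntype, network$meta$name)
  comp <- cluster_composition(best$partition, ntype)

  # --- flow ---------------------------------------------------------
  cg <- hier$cluster_graph
  flow <- list(
    inout = if (nrow(cg$W) >= 2) inout_ratio(cg) else NULL,
    hits = if (nrow(cg$W) >= 2 && any(cg$W - diag(diag(cg$W)) > 0))
      hits_scores(cg) else NULL)
  pos <- stats::setNames(network$meta$position, network$meta$name)
  if (!anyNA(pos)) {
    flow$distances <- intercluster_distances(pos, best$partition)
    flow$density <- spatial_density(pos, best$partition)
  }

  sizes_tbl <- cluster_sizes(best$partition)
  summary <- list(
    seed = seed,
    n_nodes = length(best$partition),
    w = total_weight(network),
    best_q = best$best_q,
    k = length(unique(best$partition)),
    cluster_sizes = sizes_tbl$size,
    separated_pairs = separated_pair_count(best$partition, pairing),
    null_q_mean = nq$mean,
    null_q_sd = nq$sd,
    role_counts = as.list(table(carto$role)),
    iqv_ntype = stats::setNames(as.list(comp$iqv$iqv), comp$iqv$cluster),
    vi_top_mean = det$vi_summary$mean_vi,
    nomenclature = as.list(hier$labels))
  if (!is.null(truth)) {
    summary$vi_to_truth <- variation_of_information(best$partition, truth)
    summary$truth_k <- length(unique(truth))
  }

  report <- structure(list(network = network, pairing = pairing,
                           detection = det, hierarchy = hier, null_q = nq,
                           cartography = carto, composition = comp,
                           flow = flow, summary = summary,
                           config = config),
                      class = "pipeline_report")

  validate_summary(summary)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(tidy(best), file.path(config$outdir, "partition.tsv"))
    readr::write_tsv(carto, file.path(config$outdir, "cartography.tsv"))
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         auto_unbox = TRUE, digits = I(12))
  }
  report
}

# internal: enforce the shipped summary schema's required fields and
# scalar types before the JSON is written
validate_summary <- function(summary) {
  schema <- jsonlite::read_json(
    system.file("schema", "summary-schema.json", package = "connectoclust"))
  required <- unlist(schema$required)
  missing <- setdiff(required, names(summary))
  if (length(missing) > 0) {
    abort(paste0("pipeline summary lacks field(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (f in c("w", "best_q", "null_q_mean", "null_q_sd")) {
    if (!is.numeric(summary[[f]]) || length(summary[[f]]) != 1) {
      abort(paste0("summary field ", f, " must be a numeric scalar"))
    }
  }
  invisible(summary)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pipeline_report> n = %d | Q = %.4f | k = %d | null Q = %.3f +/- %.3f | separated pairs = %d\n",
    s$n_nodes, s$best_q, s$k, s$null_q_mean, s$null_q_sd, s$separated_pairs))
  invisible(x)
}

#' @method glance pipeline_report
#' @export
glance.pipeline_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n_nodes = s$n_nodes, best_q = s$best_q, k = s$k,
                 null_q_mean = s$null_q_mean,
                 separated_pairs = s$separated_pairs,
                 vi_to_truth = s$vi_to_truth %||% NA_real_)
}
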