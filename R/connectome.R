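#' Build a connectome network from wiring tables
#'
#' Assembles a directed weighted network from a table of synaptic
#' connections and a table of per-neuron metadata. Chemical synapses are
#' directed: a row `(source, target, chemical, count)` adds `count` to the
#' entry for source -> target. Electrical (gap) junctions are
#' bidirectional: each junction of multiplicity `g` adds `g` in both
#' directions, so the grand total weight is
#' (chemical count) + 2 x (electrical count).
#'
#' The adjacency convention throughout the package is
#' `A[i, j]` = total weight from node `j` to node `i` (rows receive,
#' columns send), so incoming strengths are row sums and outgoing
#' strengths are column sums.
#'
#' @param connections Data frame with columns `source`, `target`,
#'   `type` (`"chemical"` or `"electrical"`) and `count` (positive).
#' @param metadata Optional data frame with columns `name`, `position`
#'   (in `[0, 1]`, fraction of the anterior-posterior body axis),
#'   `ganglion`, `ntype` (one of sensory/inter/motor/poly) and
#'   optionally `partner`. When `NULL`, minimal metadata is derived from
#'   the connection endpoints.
#' @param include_types Connection types to keep.
#' @param drop Character vector of neuron names to exclude entirely
#'   (applied to both tables before assembly).
#' @param quiet Suppress the one-line summary message.
#'
#' @return An object of class `connectome`: adjacency matrix `A`, node
#'   metadata tibble `meta` (with an `isolated` flag for zero-strength
#'   nodes), canonical connection tibble `connections`, strengths
#'   `s_in`/`s_out`, total weight `w`, and synapse totals `n_chemical`,
#'   `n_electrical`.
#' @examples
#' conn <- tibble::tibble(source = "a", target = "b",
#'                        type = "chemical", count = 3)
#' net <- as_connectome(conn, quiet = TRUE)
#' total_weight(net)
#' @export
as_connectome <- function(connections, metadata = NULL,
                          include_types = c("chemical", "electrical"),
                          drop = character(), quiet = FALSE) {
  connections <- tibble::as_tibble(connections)
  need <- c("source", "target", "type", "count")
  if (!all(need %in% colnames(connections))) {
    abort("connections must have columns source, target, type, count")
  }
  connections$source <- as.character(connections$source)
  connections$target <- as.character(connections$target)
  connections$type <- as.character(connections$type)
  bad_type <- setdiff(unique(connections$type), c("chemical", "electrical"))
  if (length(bad_type) > 0) {
    abort(paste0("unknown connection type(s): ", paste(bad_type, collapse = ", ")))
  }
  if (any(!is.finite(connections$count) | connections$count <= 0)) {
    i <- which(!is.finite(connections$count) | connections$count <= 0)[1]
    abort(paste0("non-positive count in connection row ", i, " (",
                 connections$source[i], " -> ", connections$target[i], ")"))
  }

  if (length(drop) > 0) {
    connections <- connections[!(connections$source %in% drop |
                                   connections$target %in% drop), , drop = FALSE]
  }
  connections <- connections[connections$type %in% include_types, , drop = FALSE]

  if (is.null(metadata)) {
    metadata <- tibble::tibble(
      name = sort(unique(c(connections$source, connections$target))),
      position = NA_real_, ganglion = NA_character_, ntype = NA_character_
    )
  }
  metadata <- tibble::as_tibble(metadata)
  if (!"name" %in% colnames(metadata)) abort("metadata must have a name column")
  metadata$name <- as.character(metadata$name)
  for (col in c("ganglion", "ntype")) {
    if (!col %in% colnames(metadata)) metadata[[col]] <- NA_character_
  }
  if (!"position" %in% colnames(metadata)) metadata$position <- NA_real_
  if (length(drop) > 0) metadata <- metadata[!metadata$name %in% drop, , drop = FALSE]
  if (anyDuplicated(metadata$name)) abort("duplicate neuron names in metadata")
  pos <- metadata$position
  if (any(!is.na(pos) & (pos < 0 | pos > 1))) {
    abort("positions must lie in [0, 1]")
  }

  nodes <- metadata$name
  unknown <- setdiff(unique(c(connections$source, connections$target)), nodes)
  if (length(unknown) > 0) {
    i <- which(connections$source %in% unknown | connections$target %in% unknown)[1]
    abort(paste0("connection row ", i, " (", connections$source[i], " -> ",
                 connections$target[i], ") names a neuron absent from metadata"))
  }

  # canonical form: one row per (source, target, type); duplicates summed
  key <- paste(connections$source, connections$target, connections$type, sep = "\r")
  if (anyDuplicated(key)) {
    warn("duplicate (source, target, type) connection rows were summed")
    connections <- connections |>
      dplyr::group_by(.data$source, .data$target, .data$type) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop")
  }
  connections <- dplyr::arrange(connections, .data$source, .data$target, .data$type)

  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  si <- match(connections$source, nodes)
  ti <- match(connections$target, nodes)
  chem <- connections$type == "chemical"
  # A[target, source] accumulates; electrical rows add both directions
  for (r in seq_len(nrow(connections))) {
    A[ti[r], si[r]] <- A[ti[r], si[r]] + connections$count[r]
    if (!chem[r]) A[si[r], ti[r]] <- A[si[r], ti[r]] + connections$count[r]
  }

  s_in <- rowSums(A)
  s_out <- colSums(A)
  metadata$isolated <- unname((s_in + s_out) == 0)
  n_chem <- sum(connections$count[chem])
  n_elec <- sum(connections$count[!chem])

  net <- structure(
    list(A = A, meta = metadata, connections = connections,
         s_in = s_in, s_out = s_out, w = sum(A),
         n_chemical = n_chem, n_electrical = n_elec),
    class = "connectome"
  )
  if (!quiet) {
    inform(sprintf(
      "connectome: %d nodes, %d chemical synapses, %d electrical junctions, total weight %g",
      n, n_chem, n_elec, net$w))
  }
  net
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf(
    "<connectome> %d nodes | %g chemical + %g electrical | w = %g\n",
    nrow(x$A), x$n_chemical, x$n_electrical, x$w))
  invisible(x)
}

#' Node names of a connectome
#' @param x A `connectome`.
#' @return Character vector of node names in network order.
#' @export
node_names <- function(x) {
  stopifnot(inherits(x, "connectome"))
  x$meta$name
}

#' Total weight of a connectome
#' @param x A `connectome`.
#' @return The grand sum of the adjacency matrix (chemical counts plus
#'   twice the electrical counts).
#' @export
total_weight <- function(x) {
  stopifnot(inherits(x, "connectome"))
  x$w
}

#' Node strengths
#'
#' Incoming strength is the row sum of the adjacency matrix (total weight
#' received), outgoing strength the column sum (total weight sent);
#' both sum to the network's total weight.
#'
#' @param x A `connectome`.
#' @return A tibble with columns `name`, `s_in`, `s_out`.
#' @export
strengths <- function(x) {
  stopifnot(inherits(x, "connectome"))
  tibble::tibble(name = x$meta$name,
                 s_in = unname(x$s_in),
                 s_out = unname(x$s_out))
}

#' @method tidy connectome
#' @export
tidy.connectome <- function(x, ...) {
  dplyr::left_join(x$meta, strengths(x), by = "name")
}

#' @method glance connectome
#' @export
glance.connectome <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$A), n_chemical = x$n_chemical,
                 n_electrical = x$n_electrical, w = x$w,
                 n_isolated = sum(x$meta$isolated))
}

#' Read a network from canonical wiring TSVs
#'
#' The canonical connection table has columns
#' `source  target  type  count` (`type` is `chemical` or `electrical`)
#' and the metadata table `name  position  ganglion  ntype  partner`,
#' both UTF-8, tab-separated with a header row.
#'
#' @param connections_path,metadata_path File paths. `metadata_path`
#'   may be `NULL`.
#' @inheritParams as_connectome
#' @return A [connectome][as_connectome] object.
#' @export
read_wiring_tsv <- function(connections_path, metadata_path = NULL,
                            drop = character(), quiet = FALSE) {
  conn <- readr::read_tsv(connections_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            source = readr::col_character(),
                            target = readr::col_character(),
                            type = readr::col_character(),
                            count = readr::col_double()))
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  }
  as_connectome(conn, meta, drop = drop, quiet = quiet)
}

#' Write a network to canonical wiring TSVs
#'
#' Writes the canonical connection and metadata tables; reading them back
#' with [read_wiring_tsv()] reproduces the adjacency matrix exactly.
#'
#' @param x A `connectome`.
#' @param connections_path,metadata_path Output file paths
#'   (`metadata_path` may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_wiring_tsv <- function(x, connections_path, metadata_path = NULL) {
  stopifnot(inherits(x, "connectome"))
  readr::write_tsv(x$connections, connections_path)
  if (!is.null(metadata_path)) {
    meta <- x$meta
    meta$isolated <- NULL
    readr::write_tsv(meta, metadata_path)
  }
  invisible(x)
}

#' Convert a wormatlas-style "NeuronConnect" export to canonical rows
#'
#' Normalizes the raw connection codes of the public wiring export:
#' `S`/`Sp` rows are chemical synapses from `Neuron1` to `Neuron2`;
#' `R`/`Rp` rows are the reciprocal records of the same synapses and are
#' dropped to avoid double counting; `EJ` rows are electrical junctions
#' (listed in both orientations in the export, so only one orientation
#' is kept); `NMJ` rows target muscles and are excluded.
#'
#' @param raw Data frame with columns `Neuron1`, `Neuron2`, `Type`, `Nbr`.
#' @param drop Neuron names to exclude (defaults to the conventionally
#'   unconnected CANL/CANR/VC6).
#' @return A canonical connection tibble suitable for [as_connectome()].
#' @export
convert_neuron_connect <- function(raw, drop = c("CANL", "CANR", "VC6")) {
  raw <- tibble::as_tibble(raw)
  need <- c("Neuron1", "Neuron2", "Type", "Nbr")
  if (!all(need %in% colnames(raw))) {
    abort("raw table must have columns Neuron1, Neuron2, Type, Nbr")
  }
  raw$Type <- as.character(raw$Type)
  known <- c("S", "Sp", "R", "Rp", "EJ", "NMJ")
  bad <- setdiff(unique(raw$Type), known)
  if (length(bad) > 0) {
    abort(paste0("unknown connection code(s): ", paste(bad, collapse = ", ")))
  }
  chem <- raw[raw$Type %in% c("S", "Sp"), , drop = FALSE]
  ej <- raw[raw$Type == "EJ", , drop = FALSE]
  # EJ records appear once per orientation; keep a single orientation
  keep <- pmin(ej$Neuron1, ej$Neuron2) == ej$Neuron1
  # symmetric self-listings (identical pair both ways) deduplicate via keep
  ej <- ej[keep | ej$Neuron1 == ej$Neuron2, , drop = FALSE]
  out <- dplyr::bind_rows(
    tibble::tibble(source = chem$Neuron1, target = chem$Neuron2,
                   type = "chemical", count = chem$Nbr),
    tibble::tibble(source = ej$Neuron1, target = ej$Neuron2,
                   type = "electrical", count = ej$Nbr)
  )
  out <- out[!(out$source %in% drop | out$target %in% drop), , drop = FALSE]
  out |>
    dplyr::group_by(.data$source, .data$target, .data$type) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(.data$source, .data$target, .data$type)
}

#' Infer bilateral left/right pairs from neuron names
#'
#' Pairs every two names that differ only by a terminal `L` vs `R`
#' (e.g. `ALML`/`ALMR`). An optional override table can force pairs in
#' or out. The result is a disjoint pairing: no node belongs to more
#' than one pair.
#'
#' @param x A `connectome` or a character vector of names.
#' @param exceptions Optional data frame with columns `a`, `b`,
#'   `action` (`"pair"` or `"unpair"`).
#' @return A tibble of class `bilateral_pairing` with columns `a`, `b`.
#' @examples
#' infer_bilateral_pairs(c("ALML", "ALMR", "AVM"))
#' @export
infer_bilateral_pairs <- function(x, exceptions = NULL) {
  nms <- if (inherits(x, "connectome")) node_names(x) else as.character(x)
  stem <- sub("[LR]$", "", nms)
  side <- ifelse(grepl("L$", nms), "L", ifelse(grepl("R$", nms), "R", ""))
  lefts <- nms[side == "L"]
  pairs <- tibble::tibble(a = character(), b = character())
  for (ln in lefts) {
    rn <- paste0(sub("L$", "", ln), "R")
    if (rn %in% nms) {
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(a = ln, b = rn))
    }
  }
  if (!is.null(exceptions) && nrow(exceptions) > 0) {
    exceptions <- tibble::as_tibble(exceptions)
    unknown <- setdiff(unique(c(exceptions$a, exceptions$b)), c(nms, NA))
    if (length(unknown) > 0) {
      abort(paste0("override names unknown neuron(s): ",
                   paste(unknown, collapse = ", ")))
    }
    for (r in seq_len(nrow(exceptions))) {
      a <- exceptions$a[r]; b <- exceptions$b[r]
      hit <- (pairs$a %in% c(a, b)) | (pairs$b %in% c(a, b))
      pairs <- pairs[!hit, , drop = FALSE]
      if (identical(exceptions$action[r], "pair")) {
        pairs <- dplyr::bind_rows(pairs, tibble::tibble(a = a, b = b))
      }
    }
  }
  validate_pairing(pairs, nms)
}

# internal: check disjointness / membership and attach class
validate_pairing <- function(pairs, nms = NULL) {
  pairs <- tibble::as_tibble(pairs)[, c("a", "b")]
  if (any(pairs$a == pairs$b)) abort("a pair cannot contain a node twice")
  members <- c(pairs$a, pairs$b)
  if (anyDuplicated(members)) {
    abort("pairing is not disjoint: a node appears in more than one pair")
  }
  if (!is.null(nms)) {
    miss <- setdiff(members, nms)
    if (length(miss) > 0) {
      abort(paste0("pairing names unknown node(s): ", paste(miss, collapse = ", ")))
    }
  }
  class(pairs) <- c("bilateral_pairing", class(pairs))
  pairs
}

#' Construct a bilateral pairing explicitly
#'
#' @param a,b Character vectors: the two members of each pair.
#' @param network Optional `connectome` to validate names against.
#' @return A `bilateral_pairing` tibble.
#' @export
bilateral_pairing <- function(a, b, network = NULL) {
  validate_pairing(tibble::tibble(a = as.character(a), b = as.character(b)),
                   if (is.null(network)) NULL else node_names(network))
}
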