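#' @importFrom rlang %||% abort warn inform
#' @importFrom Rcpp sourceCpp
#' @useDynLib connectoclust, .registration = TRUE
NULL

# Derive a stage/restart seed from a master seed, kept inside 32-bit range.
stage_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483587) + 1L
}

# Coerce a partition given as a named integer vector or a two-column
# data frame (name, cluster) into a named integer vector aligned to `names`.
as_partition <- function(partition, names = NULL) {
  if (is.data.frame(partition)) {
    nm_col <- intersect(c("name", "neuron", "node"), colnames(partition))[1]
    cl_col <- intersect(c("cluster", "label", "community"), colnames(partition))[1]
    if (is.na(nm_col) || is.na(cl_col)) {
      abort("partition data frame needs a name column and a cluster column")
    }
    p <- stats::setNames(as.integer(as.factor(partition[[cl_col]])),
                         as.character(partition[[nm_col]]))
  } else {
    p <- partition
    if (is.factor(p) || is.character(p)) {
      p <- stats::setNames(as.integer(as.factor(p)), names(partition))
    }
    p <- stats::setNames(as.integer(p), names(p))
  }
  if (!is.null(names)) {
    if (is.null(names(p))) {
      if (length(p) != length(names)) {
        abort("unnamed partition has wrong length for this network")
      }
      names(p) <- names
    } else {
      missing <- setdiff(names, names(p))
      if (length(missing) > 0) {
        abort(paste0("partition lacks nodes: ", paste(utils::head(missing, 5), collapse = ", ")))
      }
      p <- p[names]
    }
  }
  p
}
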