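# Exhaustive oracle for modularity maximization on tiny networks:
# enumerate every set partition of n nodes (restricted growth strings)
# and evaluate Q directly from the definition. Independent of the
# annealer's incremental machinery.

all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, next_label) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      recurse(c(assign, lab), max(next_label, lab + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# direct double-sum Q, written independently of modularity_q()
q_direct <- function(A, assign) {
  w <- sum(A)
  s_in <- rowSums(A); s_out <- colSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (assign[i] == assign[j]) {
        q <- q + A[i, j] - s_in[i] * s_out[j] / w
      }
    }
  }
  as.numeric(q / w)
}

brute_best_q <- function(net) {
  A <- net$A
  w <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / w
  parts <- all_set_partitions(nrow(A))
  qs <- vapply(parts, function(p) {
    sum(B[outer(p, p, "==")]) / w
  }, numeric(1))
  best <- which.max(qs)
  list(q = qs[best],
       assign = stats::setNames(parts[[best]], rownames(A)))
}
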