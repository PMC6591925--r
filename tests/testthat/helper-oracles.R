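# Independent oracles used across the suite. These deliberately re-derive
# results through different routes (plain-R dense DP, exhaustive path
# enumeration, boolean transitive closure, stats::wilcox.test) from the
# implementations they check.

# plain-R Gotoh local-alignment score (affine gaps, gap of length k costs
# gap_open + k * gap_extend); score only, written independently of the
# compiled implementation
sw_oracle_score <- function(q, t, scheme = scoring_scheme()) {
  S <- scheme$substitution_matrix
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc); n <- length(tc)
  gi <- scheme$gap_open + scheme$gap_extend
  ge <- scheme$gap_extend
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  FF <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - gi, E[i, j - 1] - ge)
      FF[i, j] <- max(H[i - 1, j] - gi, FF[i - 1, j] - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + S[qc[i - 1], tc[j - 1]],
                     E[i, j], FF[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# exhaustive enumeration of every local alignment path (first column a
# match/mismatch, gaps interior); feasible only for very short sequences
sw_enumerate_score <- function(q, t, scheme = scoring_scheme()) {
  S <- scheme$substitution_matrix
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  gi <- scheme$gap_open + scheme$gap_extend
  ge <- scheme$gap_extend
  best <- 0
  rec <- function(i, j, score, last) {
    best <<- max(best, score)
    if (i <= length(qc) && j <= length(tc)) {
      rec(i + 1, j + 1, score + S[qc[i], tc[j]], "M")
    }
    if (j <= length(tc) && last != "D") {
      rec(i, j + 1, score - if (last == "I") ge else gi, "I")
    }
    if (i <= length(qc) && last != "I") {
      rec(i + 1, j, score - if (last == "D") ge else gi, "D")
    }
  }
  for (i in seq_along(qc)) {
    for (j in seq_along(tc)) {
      rec(i + 1, j + 1, S[qc[i], tc[j]], "M")
    }
  }
  best
}

random_protein <- function(n, alphabet = c("A", "R", "N", "D", "C", "Q",
                                           "E", "G", "H", "I", "L", "K",
                                           "M", "F", "P", "S", "T", "W",
                                           "Y", "V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# connected components by boolean transitive closure over the adjacency
# matrix; returns a canonical labeling (component id = smallest member
# index)
components_oracle <- function(nodes, edges) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  for (k in seq_len(nrow(edges))) {
    A[edges$from[k], edges$to[k]] <- TRUE
    A[edges$to[k], edges$from[k]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  apply(A, 1, function(r) which(r)[1])
}

# two partitions of the same node set are equal up to relabeling
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  blocks <- function(x) {
    unname(lapply(split(names(x), x), sort))
  }
  setequal(blocks(a), blocks(b))
}

random_graph <- function(n_nodes, p_edge = 0.2) {
  nodes <- paste0("n", seq_len(n_nodes))
  pairs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  data.frame(from = pairs[1, keep], to = pairs[2, keep],
             stringsAsFactors = FALSE)
}

# a hit table for explicit pairs with fixed statistics
make_pair_hits <- function(from, to, evalue, identity) {
  h <- data.frame(query_id = from, target_id = to,
                  percent_identity = identity, alignment_length = 100L,
                  evalue = evalue, bitscore = 50,
                  query_coverage = 1, target_coverage = 1,
                  q_start = 1L, q_end = 100L, t_start = 1L, t_end = 100L,
                  stringsAsFactors = FALSE)
  class(h) <- c("alignment_hits", "data.frame")
  h
}

# direct construction of separable / exchangeable control hit tables
make_hits <- function(n, identity, evalue_exp, coverage) {
  h <- data.frame(
    query_id = paste0("q", seq_len(n)), target_id = "ref",
    percent_identity = identity, alignment_length = 200L,
    evalue = 10^evalue_exp, bitscore = 100,
    query_coverage = coverage, target_coverage = coverage,
    q_start = 1L, q_end = 200L, t_start = 1L, t_end = 200L,
    stringsAsFactors = FALSE)
  class(h) <- c("alignment_hits", "data.frame")
  h
}

# a curve object built by hand for plateau-rule tests
make_curve <- function(thresholds, n_components,
                       n_edges = rev(seq_along(thresholds))) {
  curve <- data.frame(threshold = thresholds, n_components = n_components,
                      n_edges = n_edges)
  class(curve) <- c("threshold_curve", "data.frame")
  curve
}
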