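# Protein sequence similarity networks: all-vs-all alignment, e-value
# threshold sweep, plateau-based optimal-threshold selection, connected
# component clustering, and phylum co-localization metrics.

#' All-vs-all pairwise local alignment
#'
#' One hit per unordered sequence pair (self-comparisons excluded). The
#' scoring scheme is symmetric, so a single orientation is computed per
#' pair.
#'
#' @param sequences named character vector of >= 2 protein sequences with
#'   unique accessions.
#' @param scheme a [scoring_scheme()].
#' @return `alignment_hits` data.frame with choose(n, 2) rows.
#' @export
all_vs_all <- function(sequences, scheme = default_scheme()) {
  if (length(sequences) < 2L) stop("need at least 2 sequences",
                                   call. = FALSE)
  if (anyDuplicated(names(sequences))) {
    stop("duplicate accessions: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "), call. = FALSE)
  }
  ids <- names(sequences)
  pairs <- utils::combn(length(sequences), 2)
  hits <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    smith_waterman(sequences[[i]], sequences[[j]], scheme,
                   query_id = ids[i], target_id = ids[j])
  })
  out <- do.call(rbind, hits)
  class(out) <- c("alignment_hits", "data.frame")
  out
}

# component count on the edge subset passing (evalue, identity) rules;
# every accession in `nodes` counts, including singletons
component_count <- function(hits, nodes, keep) {
  g <- igraph::graph_from_data_frame(
    hits[keep, c("query_id", "target_id"), drop = FALSE],
    directed = FALSE, vertices = nodes)
  igraph::components(g)$no
}

#' E-value threshold sweep over a similarity network
#'
#' For each cutoff of the descending decade grid, counts edges (evalue <=
#' cutoff AND identity > `min_identity`) and connected components over the
#' full node set. Component count is non-decreasing, and edge count
#' non-increasing, as the cutoff becomes more stringent.
#'
#' @param hits `alignment_hits` from [all_vs_all()].
#' @param grid strictly decreasing e-value cutoffs; default decades
#'   1e-5 ... 1e-180.
#' @param min_identity identity floor applied at every cutoff (strict >).
#' @param nodes node accessions; default: all accessions in `hits`.
#' @return object of class `threshold_curve`: data.frame with columns
#'   threshold, n_components, n_edges.
#' @export
threshold_curve <- function(hits, grid = 10^seq(-5, -180, by = -5),
                            min_identity = 30, nodes = NULL) {
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  if (is.unsorted(rev(grid), strictly = TRUE)) {
    stop("grid must be strictly decreasing", call. = FALSE)
  }
  if (is.null(nodes)) nodes <- unique(c(hits$query_id, hits$target_id))
  id_ok <- hits$percent_identity > min_identity
  curve <- data.frame(
    threshold = grid,
    n_components = vapply(grid, function(cut) {
      component_count(hits, nodes, id_ok & hits$evalue <= cut)
    }, numeric(1)),
    n_edges = vapply(grid, function(cut) {
      sum(id_ok & hits$evalue <= cut)
    }, numeric(1)))
  class(curve) <- c("threshold_curve", "data.frame")
  curve
}

#' Optimal e-value cutoff from a threshold curve
#'
#' The component-count curve typically stabilizes over a range of cutoffs;
#' the optimal cutoff is taken as the most stringent point of the longest
#' plateau (maximal run of consecutive grid points with equal component
#' count). Equal-length plateaus tie-break toward the more stringent one.
#'
#' @param curve a [threshold_curve()].
#' @return the selected e-value cutoff.
#' @export
optimal_evalue_threshold <- function(curve) {
  stopifnot(nrow(curve) >= 1L)
  r <- rle(curve$n_components)
  ends <- cumsum(r$lengths)
  # last run among those of maximal length = most stringent plateau
  best_run <- max(which(r$lengths == max(r$lengths)))
  curve$threshold[ends[best_run]]
}

#' Build a protein sequence similarity network
#'
#' Nodes are sequences; an undirected edge joins a pair iff its e-value is
#' strictly below `evalue_cut` and its percent identity strictly above
#' `min_identity`. Connected components are assigned as cluster labels.
#'
#' @param hits `alignment_hits` from [all_vs_all()].
#' @param evalue_cut e-value cutoff (> 0, strict less-than).
#' @param min_identity percent-identity floor (strict greater-than),
#'   default 30.
#' @param phyla optional named character vector accession -> phylum label.
#' @param nodes node accessions; default all accessions in `hits`.
#' @return object of class `similarity_network`: list with `nodes`
#'   (data.frame accession, phylum, component), `edges` (data.frame from,
#'   to, evalue, percent_identity) and `components` (named membership
#'   vector).
#' @export
build_network <- function(hits, evalue_cut, min_identity = 30,
                          phyla = NULL, nodes = NULL) {
  if (evalue_cut <= 0) stop("evalue_cut must be positive", call. = FALSE)
  if (is.null(nodes)) nodes <- unique(c(hits$query_id, hits$target_id))
  keep <- hits$evalue < evalue_cut & hits$percent_identity > min_identity &
    hits$query_id != hits$target_id
  edges <- data.frame(from = hits$query_id[keep],
                      to = hits$target_id[keep],
                      evalue = hits$evalue[keep],
                      percent_identity = hits$percent_identity[keep],
                      stringsAsFactors = FALSE)
  # collapse duplicate reports of an unordered pair to the most permissive
  # (minimum) e-value
  key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                paste(edges$to, edges$from))
  if (anyDuplicated(key)) {
    ord <- order(key, edges$evalue)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  net <- structure(list(
    nodes = data.frame(accession = nodes,
                       phylum = if (is.null(phyla)) NA_character_
                                else unname(phyla[nodes]),
                       stringsAsFactors = FALSE),
    edges = edges), class = "similarity_network")
  net$components <- connected_components(net)
  net$nodes$component <- unname(net$components[net$nodes$accession])
  net
}

#' Connected components of a similarity network
#'
#' @param network a [build_network()] result.
#' @return named integer vector, accession -> component label.
#' @export
connected_components <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = network$nodes$accession)
  memb <- igraph::components(g)$membership
  stats::setNames(as.integer(memb), names(memb))
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("similarity_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges,", length(unique(x$components)), "components\n")
  invisible(x)
}

#' Phylum co-localization metrics of a network
#'
#' @param network a `similarity_network` whose nodes all carry a phylum
#'   label.
#' @return list with `same_phylum_edge_fraction` (NaN for an edgeless
#'   network) and `component_purity` (data.frame component, size,
#'   majority_phylum, purity).
#' @export
phylum_mixing <- function(network) {
  ph <- stats::setNames(network$nodes$phylum, network$nodes$accession)
  if (any(is.na(ph) | !nzchar(ph))) {
    stop("every node must carry a phylum label", call. = FALSE)
  }
  e <- network$edges
  frac <- if (nrow(e) == 0L) NaN else {
    mean(ph[e$from] == ph[e$to])
  }
  comp <- split(network$nodes$phylum, network$nodes$component)
  purity <- data.frame(
    component = as.integer(names(comp)),
    size = vapply(comp, length, integer(1)),
    majority_phylum = vapply(comp, function(p) {
      names(sort(table(p), decreasing = TRUE))[1]
    }, character(1)),
    purity = vapply(comp, function(p) {
      max(table(p)) / length(p)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(same_phylum_edge_fraction = frac, component_purity = purity)
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param network a `similarity_network`.
#' @param edges_path edge-list TSV path (source, target, evalue, identity,
#'   component).
#' @param graphml_path optional GraphML path.
#' @return invisibly, the written paths.
#' @export
write_network <- function(network, edges_path, graphml_path = NULL) {
  e <- network$edges
  e$component <- unname(network$components[e$from])
  names(e) <- c("source", "target", "evalue", "identity", "component")
  write_tsv_table(e, edges_path)
  written <- edges_path
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                       vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}
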