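# Internal pairwise local alignment and significance scoring. Stands in for
# an external BLASTp search at desk scale; the 12-column tabular reader lets
# an external aligner be swapped in.

.aa_standard <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V")
.aa_alphabet <- c(.aa_standard, "X")

.pkg_cache <- new.env(parent = emptyenv())

#' Construct an alignment scoring scheme
#'
#' Affine-gap scoring for protein local alignment plus Karlin-Altschul
#' parameters for E-value computation. A gap of length k costs
#' `gap_open + k * gap_extend`. Defaults are BLOSUM62 with gap open 11 /
#' extend 1 and the published gapped-BLOSUM62 constants K = 0.041,
#' lambda = 0.267 — the de-facto standard for protein database search.
#' The unknown residue `X` scores 0 against everything.
#'
#' @param substitution_matrix 21x21 integer matrix over the 20 standard amino
#'   acids plus X, with dimnames; default BLOSUM62 (from Biostrings) with the
#'   X row/column set to 0.
#' @param gap_open,gap_extend positive integer gap penalties.
#' @param K,lambda positive Karlin-Altschul parameters.
#' @return object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(substitution_matrix = NULL, gap_open = 11L,
                           gap_extend = 1L, K = 0.041, lambda = 0.267) {
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_matrix()
  stopifnot(is.matrix(substitution_matrix),
            !is.null(rownames(substitution_matrix)),
            identical(rownames(substitution_matrix),
                      colnames(substitution_matrix)))
  if (gap_open <= 0 || gap_extend <= 0) {
    stop("gap penalties must be positive", call. = FALSE)
  }
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive",
                                  call. = FALSE)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 K = K, lambda = lambda),
            class = "scoring_scheme")
}

#' BLOSUM62 over the 20 standard residues plus X (scoring 0)
#' @return 21x21 integer matrix.
#' @export
blosum62_matrix <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    m <- env$BLOSUM62[.aa_standard, .aa_standard]
    m <- rbind(cbind(m, X = 0L), X = 0L)
    rownames(m)[nrow(m)] <- "X"
    storage.mode(m) <- "integer"
    .pkg_cache$blosum62 <- m
  }
  .pkg_cache$blosum62
}

default_scheme <- function() {
  if (is.null(.pkg_cache$default_scheme)) {
    .pkg_cache$default_scheme <- scoring_scheme()
  }
  .pkg_cache$default_scheme
}

# map a protein string to 0-based indices into the scheme's matrix,
# validating the alphabet
aa_indices <- function(seq, alphabet, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop(what, " must be a non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    stop("non-amino-acid character '", chars[which(is.na(idx))[1]],
         "' in ", what, call. = FALSE)
  }
  idx - 1L
}

#' Smith-Waterman local alignment of two protein sequences
#'
#' Optimal local alignment under affine gap penalties. Percent identity is
#' identical columns over alignment columns (gaps included); coverage is the
#' aligned span divided by the full sequence length. When no positive-scoring
#' local alignment exists the empty-alignment convention applies: score 0,
#' alignment length 0, identity and coverages 0.
#'
#' @param query,target protein sequences (strings over the 20 standard amino
#'   acids; `X` allowed and scores 0).
#' @param scheme a [scoring_scheme()]; default BLOSUM62 11/1.
#' @param query_id,target_id accession labels carried into the hit.
#' @return one-row data.frame (class `alignment_hits`) with columns query_id,
#'   target_id, percent_identity, alignment_length, evalue, bitscore, score,
#'   query_coverage, target_coverage, q_start, q_end, t_start, t_end.
#' @export
smith_waterman <- function(query, target, scheme = default_scheme(),
                           query_id = "query", target_id = "target") {
  alphabet <- rownames(scheme$substitution_matrix)
  qi <- aa_indices(query, alphabet, "query")
  ti <- aa_indices(target, alphabet, "target")
  res <- sw_align_cpp(qi, ti, scheme$substitution_matrix,
                      scheme$gap_open, scheme$gap_extend)
  m <- length(qi); n <- length(ti)
  pid <- if (res$alignment_length > 0) {
    100 * res$n_identical / res$alignment_length
  } else 0
  qcov <- if (res$score > 0) (res$q_end - res$q_start + 1) / m else 0
  tcov <- if (res$score > 0) (res$t_end - res$t_start + 1) / n else 0
  hits <- data.frame(query_id = query_id, target_id = target_id,
                     percent_identity = pid,
                     alignment_length = res$alignment_length,
                     evalue = evalue_from_score(res$score, m, n, scheme),
                     bitscore = bitscore_from_score(res$score, scheme),
                     score = res$score,
                     query_coverage = qcov, target_coverage = tcov,
                     q_start = res$q_start, q_end = res$q_end,
                     t_start = res$t_start, t_end = res$t_end,
                     stringsAsFactors = FALSE)
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

#' Karlin-Altschul E-value from a raw alignment score
#'
#' E = K * m * n * exp(-lambda * S): the expected number of chance local
#' alignments scoring at least S between a length-m query and a length-n
#' search space. Monotone decreasing in S and linear in m and n.
#'
#' @param score raw alignment score(s).
#' @param m query length; `n` search-space length (both > 0).
#' @param n search-space length.
#' @param scheme a [scoring_scheme()] supplying K and lambda.
#' @return numeric E-value(s).
#' @export
evalue_from_score <- function(score, m, n, scheme = default_scheme()) {
  if (any(m <= 0) || any(n <= 0)) {
    stop("sequence/search-space lengths must be positive", call. = FALSE)
  }
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' Bit score from a raw alignment score
#'
#' S' = (lambda * S - ln K) / ln 2, the search-space-independent normalized
#' score.
#'
#' @inheritParams evalue_from_score
#' @return numeric bit score(s).
#' @export
bitscore_from_score <- function(score, scheme = default_scheme()) {
  (scheme$lambda * score - log(scheme$K)) / log(2)
}

#' Read a 12-column tabular alignment hit file
#'
#' The tab-delimited pairwise-hit dialect written by standard protein search
#' tools: query, target, percent identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, evalue, bitscore — coordinates 1-based
#' inclusive. Coverages are derived as (end - start + 1) / length from the
#' supplied full sequence lengths.
#'
#' @param path path to the hit file (no header row).
#' @param seq_lengths named integer vector of full sequence lengths covering
#'   every accession in the file.
#' @return data.frame of class `alignment_hits` (zero rows for an empty file).
#' @export
read_tabular_hits <- function(path, seq_lengths) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(query_id = character(), target_id = character(),
                      percent_identity = numeric(),
                      alignment_length = integer(), evalue = numeric(),
                      bitscore = numeric(),
                      query_coverage = numeric(), target_coverage = numeric(),
                      q_start = integer(), q_end = integer(),
                      t_start = integer(), t_end = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) {
    class(empty) <- c("alignment_hits", "data.frame")
    return(empty)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- vapply(fields, length, integer(1))
  if (any(nfield != 12L)) {
    stop("line ", which(nfield != 12L)[1], ": expected 12 tab-delimited ",
         "columns, found ", nfield[nfield != 12L][1], call. = FALSE)
  }
  mat <- do.call(rbind, fields)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(mat[, col]))
    if (anyNA(v)) {
      stop("line ", which(is.na(v))[1], ": unparseable ", name, " '",
           mat[which(is.na(v))[1], col], "'", call. = FALSE)
    }
    v
  }
  qid <- mat[, 1]; tid <- mat[, 2]
  need <- unique(c(qid, tid))
  missing_len <- setdiff(need, names(seq_lengths))
  if (length(missing_len) > 0) {
    stop("no sequence length supplied for: ",
         paste(utils::head(missing_len, 5), collapse = ", "), call. = FALSE)
  }
  qs <- num(7, "qstart"); qe <- num(8, "qend")
  ss <- num(9, "sstart"); se <- num(10, "send")
  hits <- data.frame(
    query_id = qid, target_id = tid,
    percent_identity = num(3, "percent identity"),
    alignment_length = as.integer(num(4, "alignment length")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    query_coverage = (qe - qs + 1) / unname(seq_lengths[qid]),
    target_coverage = (abs(se - ss) + 1) / unname(seq_lengths[tid]),
    q_start = as.integer(qs), q_end = as.integer(qe),
    t_start = as.integer(pmin(ss, se)), t_end = as.integer(pmax(ss, se)),
    stringsAsFactors = FALSE)
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

#' Write alignment hits in the 12-column tabular dialect
#'
#' @param hits an `alignment_hits` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tabular_hits <- function(hits, path) {
  mism <- round(hits$alignment_length *
                  (1 - hits$percent_identity / 100))
  out <- data.frame(hits$query_id, hits$target_id,
                    sprintf("%.3f", hits$percent_identity),
                    hits$alignment_length, mism, 0L,
                    hits$q_start, hits$q_end, hits$t_start, hits$t_end,
                    format(hits$evalue, digits = 6),
                    sprintf("%.1f", hits$bitscore))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
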