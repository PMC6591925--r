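#' @useDynLib bsbtools, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators are deterministic without clobbering the
# session stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Parse 7-rank lineage strings
#'
#' Lineages are semicolon-delimited with rank prefixes, e.g.
#' `"k__Bacteria;p__Firmicutes;c__Clostridia;o__;f__;g__;s__"`. Empty fields
#' after the prefix denote an unclassified rank.
#'
#' @param lineages character vector of 7-rank lineage strings.
#' @return data.frame with columns kingdom, phylum, class, order, family,
#'   genus, species (one row per input lineage).
#' @export
parse_lineage <- function(lineages) {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  if (length(lineages) == 0L) {
    out <- as.data.frame(matrix(character(), 0, 7))
    names(out) <- ranks
    return(out)
  }
  parts <- strsplit(lineages, ";", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 7L
  if (any(bad)) {
    stop("malformed lineage string (need 7 semicolon-delimited ranks): ",
         paste(utils::head(lineages[bad], 3), collapse = ", "),
         call. = FALSE)
  }
  mat <- do.call(rbind, parts)
  for (k in seq_along(prefixes)) {
    ok <- startsWith(mat[, k], prefixes[k])
    if (!any(is.na(ok)) && !all(ok)) {
      stop("malformed lineage string (missing rank prefix '", prefixes[k],
           "'): ", mat[which(!ok)[1], k], call. = FALSE)
    }
    mat[, k] <- sub(prefixes[k], "", mat[, k], fixed = TRUE)
  }
  out <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(out) <- ranks
  out
}

#' Build a 7-rank lineage string
#'
#' @param kingdom,phylum,class,order,family,genus,species character vectors
#'   (recycled); empty strings mark unclassified ranks.
#' @return character vector of lineage strings.
#' @export
make_lineage <- function(kingdom = "Bacteria", phylum = "", class = "",
                         order = "", family = "", genus = "", species = "") {
  paste0("k__", kingdom, ";p__", phylum, ";c__", class, ";o__", order,
         ";f__", family, ";g__", genus, ";s__", species)
}

# tab-delimited IO with one header row, the dialect every table in this
# package uses
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

write_tsv_table <- function(x, path, row_names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
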