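# Calibrated multi-filter homolog identification: threshold calibration on
# labeled controls (Youden's J), hit filtering, BSH/PVA discrimination by
# profile-HMM e-value comparison, domain-architecture and
# annotation-concordance filters, and presence/absence prevalence matrices.

#' Construct a threshold set for hit filtering
#'
#' @param min_identity minimum percent identity (0-100).
#' @param max_evalue maximum e-value.
#' @param min_query_coverage,min_target_coverage minimum coverages (0-1).
#' @param sensitivity,specificity fractions achieved on calibration controls
#'   (NA until calibrated).
#' @return object of class `threshold_set`.
#' @export
threshold_set <- function(min_identity, max_evalue, min_query_coverage,
                          min_target_coverage, sensitivity = NA_real_,
                          specificity = NA_real_) {
  stopifnot(min_identity >= 0, min_identity <= 100, max_evalue >= 0,
            min_query_coverage >= 0, min_query_coverage <= 1,
            min_target_coverage >= 0, min_target_coverage <= 1)
  structure(list(min_identity = min_identity, max_evalue = max_evalue,
                 min_query_coverage = min_query_coverage,
                 min_target_coverage = min_target_coverage,
                 sensitivity = sensitivity, specificity = specificity),
            class = "threshold_set")
}

#' Candidate threshold lattice for calibration
#'
#' Cartesian grid over candidate cutoffs, one [threshold_set()] per point.
#'
#' @param identities candidate minimum identities (percent).
#' @param evalues candidate maximum e-values.
#' @param coverages candidate minimum coverages, applied to both query and
#'   target coverage.
#' @return list of `threshold_set` objects.
#' @export
threshold_grid <- function(identities = c(25, 30, 40, 50, 60),
                           evalues = 10^c(-3, -5, -10, -20, -50),
                           coverages = c(0.5, 0.7, 0.8)) {
  g <- expand.grid(id = identities, ev = evalues, cov = coverages)
  lapply(seq_len(nrow(g)), function(i) {
    threshold_set(g$id[i], g$ev[i], g$cov[i], g$cov[i])
  })
}

# logical pass vector for a hit table under a threshold set; boundary
# values pass
hit_passes <- function(hits, thresholds) {
  hits$percent_identity >= thresholds$min_identity &
    hits$evalue <= thresholds$max_evalue &
    hits$query_coverage >= thresholds$min_query_coverage &
    hits$target_coverage >= thresholds$min_target_coverage
}

#' Calibrate filtering thresholds on labeled control hits
#'
#' Evaluates every grid point on the positive and negative control hits and
#' returns the point maximizing Youden's J = sensitivity + specificity - 1
#' (sensitivity = fraction of positives passing, specificity = fraction of
#' negatives rejected). Ties are broken toward the most stringent candidate:
#' highest identity, then lowest e-value, then highest query and target
#' coverage.
#'
#' @param positive_hits,negative_hits `alignment_hits` tables for the
#'   positive and negative controls (both non-empty).
#' @param grid list of candidate [threshold_set()]s (e.g. [threshold_grid()]).
#' @return the winning `threshold_set` with achieved sensitivity and
#'   specificity filled in.
#' @export
calibrate_thresholds <- function(positive_hits, negative_hits,
                                 grid = threshold_grid()) {
  if (NROW(positive_hits) == 0L || NROW(negative_hits) == 0L) {
    stop("both control hit sets must be non-empty", call. = FALSE)
  }
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  sens <- vapply(grid, function(th) mean(hit_passes(positive_hits, th)),
                 numeric(1))
  spec <- vapply(grid, function(th) mean(!hit_passes(negative_hits, th)),
                 numeric(1))
  J <- sens + spec - 1
  if (all(!is.finite(J))) stop("no finite Youden's J on the grid",
                               call. = FALSE)
  ids <- vapply(grid, `[[`, numeric(1), "min_identity")
  evs <- vapply(grid, `[[`, numeric(1), "max_evalue")
  qcs <- vapply(grid, `[[`, numeric(1), "min_query_coverage")
  tcs <- vapply(grid, `[[`, numeric(1), "min_target_coverage")
  ord <- order(-J, -ids, evs, -qcs, -tcs)
  best <- ord[1]
  out <- grid[[best]]
  out$sensitivity <- sens[best]
  out$specificity <- spec[best]
  out
}

#' Filter hits by a threshold set
#'
#' A hit passes iff identity >= min_identity AND evalue <= max_evalue AND
#' both coverages meet their minima; boundary values pass.
#'
#' @param hits an `alignment_hits` table.
#' @param thresholds a [threshold_set()].
#' @return character vector of unique query accessions with a passing hit.
#' @export
filter_hits <- function(hits, thresholds) {
  if (NROW(hits) == 0L) return(character())
  unique(hits$query_id[hit_passes(hits, thresholds)])
}

#' Discriminate BSH from PVA by profile-HMM e-value comparison
#'
#' BSH and PVA share the CBAH domain; candidates are classified by which
#' profile HMM matches more significantly. Default mode `better_bsh_evalue`
#' calls BSH when the BSH-model e-value is strictly lower (more significant)
#' than the PVA-model e-value. Mode `literal_paper_text` inverts the
#' comparison and is kept for auditability only, since selecting the *higher*
#' e-value contradicts e-value semantics. Ties or missing scores are
#' `ambiguous` and excluded from the BSH set downstream.
#'
#' @param bsh_evalue,pva_evalue numeric vectors of model e-values (NA =
#'   missing).
#' @param mode `"better_bsh_evalue"` (default) or `"literal_paper_text"`.
#' @return character vector in BSH / PVA / ambiguous.
#' @export
classify_bsh_pva <- function(bsh_evalue, pva_evalue,
                             mode = c("better_bsh_evalue",
                                      "literal_paper_text")) {
  mode <- match.arg(mode)
  if (any(bsh_evalue < 0, na.rm = TRUE) || any(pva_evalue < 0, na.rm = TRUE)) {
    stop("e-values must be >= 0", call. = FALSE)
  }
  out <- rep("ambiguous", length(bsh_evalue))
  lower <- !is.na(bsh_evalue) & !is.na(pva_evalue) & bsh_evalue < pva_evalue
  higher <- !is.na(bsh_evalue) & !is.na(pva_evalue) & bsh_evalue > pva_evalue
  if (mode == "better_bsh_evalue") {
    out[lower] <- "BSH"; out[higher] <- "PVA"
  } else {
    out[higher] <- "BSH"; out[lower] <- "PVA"
  }
  out
}

#' Exact domain-architecture concordance
#'
#' TRUE iff the candidate's ordered domain-accession sequence equals the
#' reference's exactly (no clan merging, no subset matching).
#'
#' @param candidate_architecture,reference_architecture character vectors of
#'   ordered domain accessions (reference non-empty).
#' @return logical scalar.
#' @export
domain_architecture_filter <- function(candidate_architecture,
                                       reference_architecture) {
  if (length(reference_architecture) == 0L) {
    stop("reference architecture must be non-empty", call. = FALSE)
  }
  identical(as.character(candidate_architecture),
            as.character(reference_architecture))
}

#' Orthology-annotation concordance
#'
#' Strict mode: the orthologous-group identifiers must be equal. Relaxed
#' mode: equal identifiers, or a non-empty intersection of the
#' single-letter functional-category codes.
#'
#' @param candidate_annotation,reference_annotation orthology identifiers
#'   (e.g. "COG2141"); reference must be non-empty.
#' @param mode `"strict"` (default) or `"relaxed"`.
#' @param candidate_categories,reference_categories functional-category code
#'   strings (e.g. "CI"), used in relaxed mode.
#' @return logical scalar.
#' @export
annotation_concordance_filter <- function(candidate_annotation,
                                          reference_annotation,
                                          mode = c("strict", "relaxed"),
                                          candidate_categories = "",
                                          reference_categories = "") {
  mode <- match.arg(mode)
  if (is.null(reference_annotation) || is.na(reference_annotation) ||
      !nzchar(reference_annotation)) {
    stop("reference annotation must be non-empty", call. = FALSE)
  }
  if (length(candidate_annotation) == 0L || is.na(candidate_annotation)) {
    return(FALSE)
  }
  same_id <- identical(as.character(candidate_annotation),
                       as.character(reference_annotation))
  if (mode == "strict" || same_id) return(same_id)
  cc <- strsplit(candidate_categories %||% "", "")[[1]]
  rc <- strsplit(reference_categories %||% "", "")[[1]]
  length(intersect(cc, rc)) > 0
}

#' The 13 BSB enzyme categories with illustrative reference metadata
#'
#' The category names are the field's standard ones (the bai operon enzymes
#' BaiA-BaiL, the bile salt hydrolase Bsh, and hydroxysteroid dehydrogenase
#' HSD). Reference accessions, domain architectures and orthology
#' annotations are illustrative defaults for pipeline plumbing and tests;
#' replace them with a curated catalog for real screens.
#'
#' @return data.frame with columns name, reference_accession,
#'   reference_architecture (comma-joined ordered domain accessions) and
#'   reference_annotation.
#' @export
enzyme_catalog <- function() {
  data.frame(
    name = c("BaiA", "BaiB", "BaiCD", "BaiE", "BaiF", "BaiG", "BaiH",
             "BaiI", "BaiJ", "BaiK", "BaiL", "Bsh", "HSD"),
    reference_accession = sprintf("REF_%02d", 1:13),
    reference_architecture = c(
      "PF00106", "PF00501", "PF00890", "PF07045", "PF02550", "PF07690",
      "PF00890", "PF07045", "PF00890", "PF02550", "PF00106", "PF02275",
      "PF00106"),
    reference_annotation = c(
      "COG1028", "COG0318", "COG1902", "COG4992", "COG1804", "COG2814",
      "COG1902", "COG4992", "COG1902", "COG1804", "COG1028", "COG3049",
      "COG1028"),
    stringsAsFactors = FALSE)
}

#' Compose the full homolog screen
#'
#' Runs the filter cascade in order: alignment hit filter, then (for the Bsh
#' category only) the BSH/PVA e-value rule, then the exact
#' domain-architecture filter, then the annotation-concordance filter. Every
#' stage records a per-record provenance flag; a record is retained iff it
#' passes all enabled stages.
#'
#' @param records data.frame of candidate proteins: accession, lineage
#'   (7-rank string), category (enzyme-category name).
#' @param hits `alignment_hits` table of candidate-vs-reference hits
#'   (query_id = candidate accession); every hit accession must appear in
#'   `records`.
#' @param hmm_scores data.frame accession/bsh_evalue/pva_evalue (needed when
#'   Bsh candidates are present and the bsh_pva stage is enabled).
#' @param architectures named character vector accession -> comma-joined
#'   ordered domain accessions.
#' @param annotations named character vector accession -> orthology id.
#' @param thresholds a [threshold_set()], or a named list of them keyed by
#'   category (a `"default"` entry is the fallback).
#' @param catalog enzyme catalog, see [enzyme_catalog()].
#' @param stages character subset of hit, bsh_pva, domain, annotation;
#'   disabled stages pass everything through.
#' @param annotation_mode passed to [annotation_concordance_filter()].
#' @param bsh_mode passed to [classify_bsh_pva()].
#' @return object of class `homolog_set`: list with `records` (with
#'   per-stage pass flags and `pass_all`) and `counts` (phylum x category
#'   matrix over retained records).
#' @export
build_homolog_set <- function(records, hits, hmm_scores = NULL,
                              architectures = NULL, annotations = NULL,
                              thresholds,
                              catalog = enzyme_catalog(),
                              stages = c("hit", "bsh_pva", "domain",
                                         "annotation"),
                              annotation_mode = "strict",
                              bsh_mode = "better_bsh_evalue") {
  stopifnot(all(c("accession", "lineage", "category") %in% names(records)))
  unknown <- setdiff(unique(hits$query_id), records$accession)
  if (length(unknown) > 0) {
    stop("hit accession(s) absent from the taxonomy/record table: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  th_for <- function(cat) {
    if (inherits(thresholds, "threshold_set")) return(thresholds)
    thresholds[[cat]] %||% thresholds[["default"]] %||%
      stop("no thresholds for category ", cat, call. = FALSE)
  }
  n <- nrow(records)
  res <- records
  res$phylum <- parse_lineage(records$lineage)$phylum

  # stage 1: alignment hit filter, per-category thresholds
  res$pass_hit <- rep(TRUE, n)
  if ("hit" %in% stages) {
    res$pass_hit <- vapply(seq_len(n), function(i) {
      h <- hits[hits$query_id == records$accession[i], , drop = FALSE]
      if (nrow(h) == 0L) return(FALSE)
      any(hit_passes(h, th_for(records$category[i])))
    }, logical(1))
  }

  # stage 2: BSH/PVA discrimination, Bsh category only
  res$pass_bsh <- rep(TRUE, n)
  if ("bsh_pva" %in% stages) {
    is_bsh_cat <- records$category == "Bsh"
    if (any(is_bsh_cat)) {
      idx <- match(records$accession, hmm_scores$accession %||% character())
      be <- rep(NA_real_, n); pe <- rep(NA_real_, n)
      ok <- !is.na(idx)
      be[ok] <- hmm_scores$bsh_evalue[idx[ok]]
      pe[ok] <- hmm_scores$pva_evalue[idx[ok]]
      cls <- classify_bsh_pva(be, pe, mode = bsh_mode)
      res$pass_bsh <- ifelse(is_bsh_cat, cls == "BSH", TRUE)
    }
  }

  # stage 3: exact domain-architecture filter
  res$pass_domain <- rep(TRUE, n)
  if ("domain" %in% stages) {
    ref_arch <- stats::setNames(catalog$reference_architecture, catalog$name)
    res$pass_domain <- vapply(seq_len(n), function(i) {
      cand <- architectures[[records$accession[i]]] %||% NA_character_
      if (is.na(cand)) return(FALSE)
      domain_architecture_filter(
        strsplit(cand, ",", fixed = TRUE)[[1]],
        strsplit(ref_arch[[records$category[i]]], ",", fixed = TRUE)[[1]])
    }, logical(1))
  }

  # stage 4: annotation concordance
  res$pass_annotation <- rep(TRUE, n)
  if ("annotation" %in% stages) {
    ref_ann <- stats::setNames(catalog$reference_annotation, catalog$name)
    res$pass_annotation <- vapply(seq_len(n), function(i) {
      cand <- annotations[[records$accession[i]]] %||% NA_character_
      if (is.na(cand)) return(FALSE)
      annotation_concordance_filter(cand, ref_ann[[records$category[i]]],
                                    mode = annotation_mode)
    }, logical(1))
  }

  res$pass_all <- res$pass_hit & res$pass_bsh & res$pass_domain &
    res$pass_annotation
  kept <- res[res$pass_all, , drop = FALSE]
  counts <- table(factor(kept$phylum), factor(kept$category,
                                              levels = catalog$name))
  counts <- unclass(counts)
  structure(list(records = res, counts = counts), class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat("homolog_set:", sum(x$records$pass_all), "of", nrow(x$records),
      "candidates retained across", ncol(x$counts), "categories\n")
  invisible(x)
}

#' Strain x category presence/absence matrix
#'
#' Cell = 1 iff the strain (species-level lineage field) carries at least one
#' retained homolog of that enzyme category.
#'
#' @param homolog_set a [build_homolog_set()] result.
#' @param catalog enzyme catalog defining the category columns.
#' @return binary integer matrix, strains x categories (0 rows if the
#'   homolog set is empty).
#' @export
prevalence_matrix <- function(homolog_set, catalog = enzyme_catalog()) {
  kept <- homolog_set$records[homolog_set$records$pass_all, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(matrix(0L, 0, nrow(catalog),
                  dimnames = list(character(), catalog$name)))
  }
  strain <- parse_lineage(kept$lineage)$species
  tab <- table(factor(strain), factor(kept$category, levels = catalog$name))
  mat <- unclass(tab)
  mat[mat > 0] <- 1L
  storage.mode(mat) <- "integer"
  mat
}

#' Select strains prevalent for a strict majority of enzyme categories
#'
#' Keeps strains carrying homologs of more than half of the categories
#' (strictly: with 13 categories, at least 7).
#'
#' @param matrix binary strain x category matrix.
#' @param n_categories total number of categories (default 13).
#' @return character vector of selected strain names.
#' @export
select_prevalent_strains <- function(matrix, n_categories = 13L) {
  if (n_categories <= 0L) stop("n_categories must be positive",
                               call. = FALSE)
  rs <- rowSums(matrix)
  rownames(matrix)[rs > n_categories / 2]
}

#' Write a homolog set and its phylum x category counts as TSV
#'
#' @param homolog_set a `homolog_set`.
#' @param records_path,counts_path output paths.
#' @return invisibly, the two paths.
#' @export
write_homolog_set <- function(homolog_set, records_path, counts_path) {
  write_tsv_table(homolog_set$records, records_path)
  counts <- data.frame(phylum = rownames(homolog_set$counts),
                       homolog_set$counts, check.names = FALSE)
  write_tsv_table(counts, counts_path)
  invisible(c(records_path, counts_path))
}
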