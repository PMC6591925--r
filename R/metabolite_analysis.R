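# Fecal bile-acid proportion analysis: proportion normalization,
# primary/secondary and conjugation classification, and group comparison of
# per-metabolite and per-class proportions.

.ba_vocab <- data.frame(
  name = c("cholate", "chenodeoxycholate",
           "glycocholate", "taurocholate",
           "glycochenodeoxycholate", "taurochenodeoxycholate",
           "deoxycholate", "lithocholate", "ursodeoxycholate",
           "glycodeoxycholate", "taurodeoxycholate",
           "glycolithocholate", "taurolithocholate",
           "glycoursodeoxycholate", "tauroursodeoxycholate"),
  class = c(rep("primary", 6), rep("secondary", 9)),
  conjugation = c("unconjugated", "unconjugated",
                  "glyco", "tauro", "glyco", "tauro",
                  "unconjugated", "unconjugated", "unconjugated",
                  "glyco", "tauro", "glyco", "tauro", "glyco", "tauro"),
  stringsAsFactors = FALSE)

#' The shipped bile-acid vocabulary
#'
#' Canonical lower-case names classified on two axes: class (primary vs
#' secondary — ursodeoxycholate is grouped with the secondary/tertiary BAs)
#' and conjugation (unconjugated, glyco, tauro). Extensible with a
#' user-supplied TSV carrying the same three columns.
#'
#' @param extra_path optional path to a TSV with columns name, class,
#'   conjugation to append (entries there override shipped ones).
#' @return data.frame with columns name, class, conjugation.
#' @export
ba_vocabulary <- function(extra_path = NULL) {
  vocab <- .ba_vocab
  if (!is.null(extra_path)) {
    extra <- read_tsv_table(extra_path)
    stopifnot(all(c("name", "class", "conjugation") %in% names(extra)))
    extra$name <- tolower(extra$name)
    if (!all(extra$class %in% c("primary", "secondary")) ||
        !all(extra$conjugation %in% c("unconjugated", "glyco", "tauro"))) {
      stop("vocabulary extension has entries off the controlled axes",
           call. = FALSE)
    }
    vocab <- rbind(extra, vocab[!vocab$name %in% extra$name, ])
  }
  vocab
}

#' Classify bile acids by name
#'
#' Case-insensitive lookup in the vocabulary; unknown names raise an error
#' listing the nearest vocabulary entries.
#'
#' @param name character vector of bile-acid names.
#' @param vocab vocabulary table, see [ba_vocabulary()].
#' @return data.frame: name, class, conjugation (one row per input).
#' @export
classify_ba <- function(name, vocab = ba_vocabulary()) {
  key <- tolower(name)
  idx <- match(key, vocab$name)
  if (anyNA(idx)) {
    bad <- key[is.na(idx)][1]
    near <- utils::head(vocab$name[order(utils::adist(bad, vocab$name))], 3)
    stop("unknown bile acid '", bad, "'; nearest vocabulary entries: ",
         paste(near, collapse = ", "), call. = FALSE)
  }
  data.frame(name = name, class = vocab$class[idx],
             conjugation = vocab$conjugation[idx],
             stringsAsFactors = FALSE)
}

#' Convert raw bile-acid levels to per-sample proportions
#'
#' Each metabolite level is divided by its sample's total, so every sample
#' column sums to 1; proportions are invariant to any positive rescaling of
#' a sample's raw levels.
#'
#' @param levels metabolite x sample matrix of non-negative levels with at
#'   least one positive entry per sample.
#' @return metabolite x sample matrix of proportions.
#' @export
to_proportions <- function(levels) {
  if (any(levels < 0)) stop("negative level encountered", call. = FALSE)
  totals <- colSums(levels)
  zero <- totals == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(levels)[zero], collapse = ", "), call. = FALSE)
  }
  sweep(levels, 2, totals, "/")
}

#' Per-sample bile-acid class totals
#'
#' Sums proportions per sample over the primary/secondary axis and over the
#' conjugated primary BAs. With full vocabulary coverage, primary_total +
#' secondary_total = 1.
#'
#' @param proportions metabolite x sample proportion matrix (rownames are
#'   bile-acid names).
#' @param vocab vocabulary table.
#' @return data.frame: sample_id, primary_total, secondary_total,
#'   conjugated_primary_total.
#' @export
class_proportions <- function(proportions, vocab = ba_vocabulary()) {
  cls <- classify_ba(rownames(proportions), vocab)
  prim <- cls$class == "primary"
  conj_prim <- prim & cls$conjugation != "unconjugated"
  data.frame(
    sample_id = colnames(proportions),
    primary_total = colSums(proportions[prim, , drop = FALSE]),
    secondary_total = colSums(proportions[!prim, , drop = FALSE]),
    conjugated_primary_total =
      colSums(proportions[conj_prim, , drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare bile-acid proportions between groups
#'
#' Per-metabolite and per-class group comparisons of proportions, star
#' annotated. With two groups present each row is a Mann-Whitney-Wilcoxon
#' comparison; with three, a Kruskal-Wallis omnibus p is reported per row
#' alongside all pairwise Mann-Whitney comparisons.
#'
#' @param proportions metabolite x sample proportion matrix.
#' @param metadata data.frame with sample_id and group columns.
#' @param vocab vocabulary table.
#' @return list with `per_metabolite` and `per_class` data.frames (columns
#'   name, group1, group2, mean1, mean2, p_value, stars, and omnibus_p when
#'   three groups are present).
#' @export
compare_metabolites <- function(proportions, metadata,
                                vocab = ba_vocabulary()) {
  md <- metadata[metadata$sample_id %in% colnames(proportions), ,
                 drop = FALSE]
  groups <- unique(md$group)
  scan_row <- function(values, label) {
    scan <- pairwise_group_scan(values, md)
    scan <- cbind(name = label, scan, stringsAsFactors = FALSE)
    if (length(groups) >= 3L) {
      scan$omnibus_p <- compare_groups(values, md)$p_value
    }
    scan
  }
  per_met <- do.call(rbind, lapply(rownames(proportions), function(m) {
    scan_row(stats::setNames(proportions[m, ], colnames(proportions)), m)
  }))
  cp <- class_proportions(proportions, vocab)
  per_cls <- do.call(rbind, lapply(
    c("primary_total", "secondary_total", "conjugated_primary_total"),
    function(cl) {
      scan_row(stats::setNames(cp[[cl]], cp$sample_id), cl)
    }))
  list(per_metabolite = per_met, per_class = per_cls)
}
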