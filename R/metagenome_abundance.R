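# Gene-set abundance from mapped-read counts: normalization to total paired
# reads, taxonomic aggregation, and nonparametric group statistics
# (Mann-Whitney-Wilcoxon for two groups, Kruskal-Wallis for three), plus the
# multivariable-regression confounder scan.

#' Normalize mapped-read counts to total paired reads
#'
#' Element-wise division of each sample column by that sample's total paired
#' reads, yielding unitless fractions (the paper-scale magnitudes are around
#' 1e-4 for a full BSB gene set).
#'
#' @param counts gene x sample matrix of non-negative mapped-read counts.
#' @param depths named numeric vector, sample -> total paired reads (> 0),
#'   covering every sample column.
#' @return gene x sample matrix of normalized abundances in `[0, 1]`.
#' @export
normalize_abundance <- function(counts, depths) {
  samples <- colnames(counts)
  missing <- setdiff(samples, names(depths))
  if (length(missing) > 0) {
    stop("missing depth for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(depths[samples] <= 0)) {
    stop("depths must be positive", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative count encountered", call. = FALSE)
  sweep(counts, 2, depths[samples], "/")
}

#' Total gene-set abundance per sample
#'
#' @param normalized gene x sample normalized abundance matrix.
#' @param gene_set character vector of gene ids (must all be rows of
#'   `normalized`).
#' @return named numeric vector, sample -> summed normalized abundance.
#' @export
total_bsbg_abundance <- function(normalized, gene_set) {
  unknown <- setdiff(gene_set, rownames(normalized))
  if (length(unknown) > 0) {
    stop("gene(s) not in the abundance table: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  colSums(normalized[gene_set, , drop = FALSE])
}

#' Aggregate normalized abundances by taxonomic rank
#'
#' Sums member-gene abundances per taxon at the requested rank; genes with
#' an empty rank field are collected under `"unclassified"`, so the taxon
#' sums always conserve the total.
#'
#' @param normalized gene x sample normalized abundance matrix.
#' @param lineages named character vector, gene -> 7-rank lineage string.
#' @param rank one of phylum, family, genus (also class, order, species).
#' @return taxon x sample matrix.
#' @export
aggregate_by_taxon <- function(normalized, lineages,
                               rank = c("phylum", "family", "genus",
                                        "class", "order", "species")) {
  rank <- match.arg(rank)
  genes <- rownames(normalized)
  missing <- setdiff(genes, names(lineages))
  if (length(missing) > 0) {
    stop("no lineage for gene(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  parsed <- tryCatch(parse_lineage(unname(lineages[genes])),
                     error = function(e) {
                       stop("while parsing lineages of the abundance ",
                            "table: ", conditionMessage(e), call. = FALSE)
                     })
  taxa <- parsed[[rank]]
  taxa[is.na(taxa) | !nzchar(taxa)] <- "unclassified"
  rowsum(normalized, group = taxa)
}

# exact two-sided Mann-Whitney p by enumeration of all assignments of the
# pooled values to the two groups; midranks make it tie-exact. The null U
# distribution is symmetric about m*n/2, so the two-sided p is the
# probability of a deviation at least as large as observed.
mw_exact_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  dev_obs <- abs(u_obs - m * n / 2)
  idx <- utils::combn(m + n, m)
  u_all <- colSums(matrix(r[idx], nrow = m)) - m * (m + 1) / 2
  stat <- u_obs
  p <- mean(abs(u_all - m * n / 2) >= dev_obs - 1e-9)
  list(statistic = stat, p_value = p)
}

#' Nonparametric comparison of a per-sample quantity between groups
#'
#' Two groups: two-sided Mann-Whitney-Wilcoxon, computed exactly (by
#' enumeration over all group assignments, tie-exact with midranks) when
#' both groups have <= 8 samples, otherwise by the normal approximation
#' with tie-corrected variance. Three groups: Kruskal-Wallis. Shapiro-Wilk
#' normality p-values and group means are reported alongside.
#'
#' @param values named numeric vector, sample -> value.
#' @param metadata data.frame with sample_id and group columns.
#' @param groups_to_compare groups to include; default: all groups present.
#' @return object of class `group_comparison`: list with test_name
#'   (mann_whitney or kruskal_wallis), statistic, p_value, group_means,
#'   group_n, normality_p.
#' @export
compare_groups <- function(values, metadata, groups_to_compare = NULL) {
  md <- metadata[metadata$sample_id %in% names(values), , drop = FALSE]
  if (is.null(groups_to_compare)) groups_to_compare <- unique(md$group)
  md <- md[md$group %in% groups_to_compare, , drop = FALSE]
  v <- split(unname(values[md$sample_id]), md$group)
  v <- v[intersect(groups_to_compare, names(v))]
  ns <- vapply(v, length, integer(1))
  if (length(v) < 2L || any(ns < 2L)) {
    stop("every requested group needs >= 2 samples; got: ",
         paste(names(ns), ns, sep = "=", collapse = ", "), call. = FALSE)
  }
  normality <- vapply(v, function(x) {
    if (length(x) >= 3L && length(unique(x)) > 1L) {
      stats::shapiro.test(x)$p.value
    } else NA_real_
  }, numeric(1))
  means <- vapply(v, mean, numeric(1))
  if (length(v) == 2L) {
    if (all(ns <= 8L)) {
      res <- mw_exact_p(v[[1]], v[[2]])
      stat <- res$statistic; p <- res$p_value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(v[[1]], v[[2]],
                                                exact = FALSE,
                                                correct = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
    test <- "mann_whitney"
  } else {
    kw <- stats::kruskal.test(v)
    stat <- unname(kw$statistic); p <- kw$p.value
    test <- "kruskal_wallis"
  }
  structure(list(test_name = test, statistic = stat, p_value = p,
                 group_means = means, group_n = ns,
                 normality_p = normality),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test_name, "on", paste(names(x$group_n), collapse = " vs "),
      ": statistic =", signif(x$statistic, 6),
      ", p =", signif(x$p_value, 6), "\n")
  invisible(x)
}

#' Significance stars at the conventional cutpoints
#'
#' ns: p > 0.05; *: p <= 0.05; **: p <= 0.01; ***: p <= 0.001;
#' ****: p <= 0.0001.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star annotations.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 1e-2) "**"
    else if (pi <= 5e-2) "*"
    else "ns"
  }, character(1))
}

#' All pairwise group comparisons
#'
#' One two-sided Mann-Whitney-Wilcoxon comparison per unordered pair of
#' groups present (each with >= 2 samples), with star annotations.
#'
#' @param values named numeric vector, sample -> value.
#' @param metadata data.frame with sample_id and group columns.
#' @return data.frame: group1, group2, n1, n2, mean1, mean2, statistic,
#'   p_value, stars.
#' @export
pairwise_group_scan <- function(values, metadata) {
  md <- metadata[metadata$sample_id %in% names(values), , drop = FALSE]
  groups <- names(which(table(md$group) >= 2L))
  groups <- intersect(c("H", "CD", "UC", sort(unique(md$group))), groups)
  if (length(groups) < 2L) stop("need >= 2 groups with >= 2 samples",
                                call. = FALSE)
  pairs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    cmp <- compare_groups(values, md, c(g1, g2))
    data.frame(group1 = g1, group2 = g2,
               n1 = cmp$group_n[[g1]], n2 = cmp$group_n[[g2]],
               mean1 = cmp$group_means[[g1]], mean2 = cmp$group_means[[g2]],
               statistic = cmp$statistic, p_value = cmp$p_value,
               stars = significance_stars(cmp$p_value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multivariable-regression confounder scan
#'
#' Ordinary least squares of the abundance on all covariates jointly;
#' per-coefficient two-sided p-values, flagged at p < `alpha` (default
#' 0.01). Constant covariates are excluded with a warning. Two-level
#' categorical covariates (e.g. gender) enter as factors.
#'
#' @param values named numeric vector, sample -> abundance.
#' @param metadata data.frame with sample_id and the covariate columns.
#' @param covariates covariate names; default age, bmi, gender.
#' @param alpha flagging threshold on the coefficient p-value.
#' @return data.frame: covariate, coefficient, p_value, flagged.
#' @export
confounder_scan <- function(values, metadata,
                            covariates = c("age", "bmi", "gender"),
                            alpha = 0.01) {
  md <- metadata[match(names(values), metadata$sample_id), , drop = FALSE]
  keep <- character()
  for (cv in covariates) {
    x <- md[[cv]]
    if (is.null(x)) stop("covariate not in metadata: ", cv, call. = FALSE)
    if (length(unique(x[!is.na(x)])) < 2L) {
      warning("covariate '", cv, "' is constant; excluded", call. = FALSE)
    } else {
      keep <- c(keep, cv)
    }
  }
  if (length(keep) == 0L) {
    return(data.frame(covariate = character(), coefficient = numeric(),
                      p_value = numeric(), flagged = logical()))
  }
  dat <- md[, keep, drop = FALSE]
  for (cv in keep) if (is.character(dat[[cv]])) dat[[cv]] <- factor(dat[[cv]])
  dat$.abundance <- unname(values)
  cc <- stats::complete.cases(dat)
  if (!all(cc)) {
    warning(sum(!cc), " sample(s) with missing covariates dropped",
            call. = FALSE)
    dat <- dat[cc, , drop = FALSE]
  }
  if (nrow(dat) <= length(keep) + 1L) {
    stop("too few samples (", nrow(dat), ") for ", length(keep),
         " covariates", call. = FALSE)
  }
  fit <- stats::lm(.abundance ~ ., data = dat)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  # map factor-expanded terms back to their covariate
  term_cov <- vapply(rownames(sm), function(tm) {
    keep[which(startsWith(tm, keep))[1]]
  }, character(1))
  data.frame(covariate = unname(term_cov),
             coefficient = unname(sm[, "Estimate"]),
             p_value = unname(sm[, "Pr(>|t|)"]),
             flagged = unname(sm[, "Pr(>|t|)"] < alpha),
             stringsAsFactors = FALSE)
}

#' Restrict samples to one country
#'
#' Comparative analyses are country-matched to avoid cross-country effects;
#' this filter applies that restriction to a metadata table.
#'
#' @param metadata data.frame with a country column.
#' @param country country to keep.
#' @return the filtered metadata.
#' @export
filter_country <- function(metadata, country) {
  metadata[metadata$country == country, , drop = FALSE]
}
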