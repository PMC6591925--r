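# End-to-end orchestration: simulate -> screen -> network -> abundance ->
# metabolites, with a single validated config, derived per-stage seeds, a
# run log and a checksummed output manifest.

#' Build a pipeline configuration
#'
#' @param outdir output directory (created if absent).
#' @param seed master integer seed; per-stage generator seeds are derived
#'   from it deterministically.
#' @param stages stages to run, in pipeline order, among simulate, screen,
#'   network, abundance, metabolites.
#' @param family a [family_spec()] for the screening family; default uses
#'   the derived seed.
#' @param cohort a [cohort_spec()] for the metagenome cohort; default uses
#'   the derived seed.
#' @param metabolites a [metabolite_spec()]; default uses the derived seed.
#' @param inputs named list of input paths used when `simulate` is disabled:
#'   counts, depths, lineages, metadata (TSV) and metabolite_levels (TSV)
#'   as produced by [run_pipeline()]'s simulate stage.
#' @param grid PSSN e-value decade grid.
#' @param min_identity PSSN identity floor (percent).
#' @param country optional country filter applied before group comparisons.
#' @param config_path optional YAML file; keys there override the defaults,
#'   and arguments given here override the file.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            stages = c("simulate", "screen", "network",
                                       "abundance", "metabolites"),
                            family = NULL, cohort = NULL,
                            metabolites = NULL, inputs = list(),
                            grid = 10^seq(-5, -120, by = -5),
                            min_identity = 30, country = NULL,
                            config_path = NULL) {
  if (!is.null(config_path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is required to read config files",
           call. = FALSE)
    }
    y <- yaml::read_yaml(config_path)
    if (!is.null(y$seed) && missing(seed)) seed <- y$seed
    if (!is.null(y$stages) && missing(stages)) stages <- y$stages
    if (!is.null(y$inputs) && missing(inputs)) inputs <- y$inputs
    if (!is.null(y$min_identity) && missing(min_identity)) {
      min_identity <- y$min_identity
    }
    if (!is.null(y$country) && missing(country)) country <- y$country
    if (!is.null(y$outdir) && missing(outdir)) outdir <- y$outdir
  }
  stages <- match.arg(stages, c("simulate", "screen", "network",
                                "abundance", "metabolites"),
                      several.ok = TRUE)
  seed <- as.integer(seed)
  structure(list(
    outdir = outdir, seed = seed, stages = stages,
    family = family %||% family_spec(seed = seed + 101L),
    cohort = cohort %||% cohort_spec(seed = seed + 202L),
    metabolites = metabolites %||% metabolite_spec(
      group_shift = list(primary = c(CD = 2, UC = 2),
                         secondary = c(CD = 0.25, UC = 0.25)),
      seed = seed + 303L),
    inputs = inputs, grid = grid, min_identity = min_identity,
    country = country), class = "pipeline_config")
}

# default per-family side tables for the screen stage: positives mirror the
# reference's Bsh architecture/annotation, decoys do not
screen_side_tables <- function(fam, catalog) {
  acc <- fam$truth$accession
  pos <- fam$truth$label == "positive"
  cat_row <- catalog[catalog$name == "Bsh", ]
  arch <- ifelse(pos, cat_row$reference_architecture, "PF00000")
  ann <- ifelse(pos, cat_row$reference_annotation, "COG0000")
  phyla <- ifelse(pos, "Firmicutes", "Proteobacteria")
  lineage <- make_lineage(phylum = phyla,
                          species = paste0("strain ", seq_along(acc)))
  list(architectures = stats::setNames(arch, acc),
       annotations = stats::setNames(ann, acc),
       records = data.frame(accession = acc, lineage = lineage,
                            category = "Bsh", stringsAsFactors = FALSE))
}

#' Run the analysis pipeline end to end
#'
#' Validates the configuration (required inputs for every enabled stage
#' must exist before anything is written), then executes the enabled
#' stages in order. Every output file is listed in the manifest with an
#' md5 checksum; identical config + seed reproduces identical checksums.
#' A stage failure marks all downstream stages skipped.
#'
#' @param config a [pipeline_config()].
#' @return run report (class `pipeline_report`): list with `status` (named
#'   character: done/failed/skipped/disabled), `manifest` (data.frame file,
#'   md5), `summary` (key numbers per stage) and `log` (path).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  # ---- validation before any work ----
  needs_cohort_files <- any(c("abundance", "metabolites") %in% st) &&
    !("simulate" %in% st)
  if (needs_cohort_files) {
    req <- c("counts", "depths", "lineages", "metadata")
    missing_keys <- setdiff(req, names(config$inputs))
    if (length(missing_keys) > 0) {
      stop("inputs missing for enabled stages (simulate disabled): ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    }
    bad <- !vapply(config$inputs[req], file.exists, logical(1))
    if (any(bad)) {
      stop("input file(s) not found: ",
           paste(unlist(config$inputs[req][bad]), collapse = ", "),
           call. = FALSE)
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...),
               log_con)
  }
  all_stages <- c("simulate", "screen", "network", "abundance",
                  "metabolites")
  status <- stats::setNames(ifelse(all_stages %in% st, "pending",
                                   "disabled"), all_stages)
  summary <- list()
  outputs <- character()
  state <- new.env(parent = emptyenv())
  catalog <- enzyme_catalog()

  out_file <- function(name) file.path(config$outdir, name)
  emit <- function(obj, name, writer = write_tsv_table, ...) {
    p <- out_file(name)
    writer(obj, p, ...)
    outputs <<- c(outputs, p)
    p
  }

  stage_fns <- list(
    simulate = function() {
      fam <- gen_protein_family(config$family)
      state$family <- fam
      emit(fam$sequences, "family.fasta", write_protein_fasta)
      emit(fam$truth, "family_truth.tsv")
      coh <- gen_metagenome_counts(config$cohort)
      state$cohort <- coh
      emit(data.frame(gene_id = rownames(coh$counts), coh$counts,
                      check.names = FALSE), "counts.tsv")
      emit(data.frame(sample_id = names(coh$depths),
                      total_paired_reads = unname(coh$depths)),
           "depths.tsv")
      emit(data.frame(gene_id = names(coh$lineages),
                      lineage = unname(coh$lineages)), "lineages.tsv")
      emit(coh$metadata, "metadata.tsv")
      lev <- gen_metabolite_table(config$metabolites, coh$metadata)
      state$levels <- lev
      emit(data.frame(metabolite = rownames(lev), lev,
                      check.names = FALSE), "metabolite_levels.tsv")
      summary$simulate <<- list(
        n_sequences = length(fam$sequences),
        n_samples = nrow(coh$metadata), n_genes = nrow(coh$counts))
    },
    screen = function() {
      fam <- state$family %||% gen_protein_family(config$family)
      state$family <- fam
      ref <- fam$sequences[[fam$reference_id]]
      cand <- fam$sequences[names(fam$sequences) != fam$reference_id]
      hits <- do.call(rbind, lapply(names(cand), function(a) {
        smith_waterman(cand[[a]], ref, query_id = a,
                       target_id = fam$reference_id)
      }))
      truth <- fam$truth[fam$truth$accession != fam$reference_id, ]
      pos_ids <- truth$accession[truth$label == "positive"]
      th <- calibrate_thresholds(hits[hits$query_id %in% pos_ids, ],
                                 hits[!hits$query_id %in% pos_ids, ])
      side <- screen_side_tables(list(truth = truth), catalog)
      labels <- stats::setNames(
        ifelse(truth$label == "positive", "BSH", "PVA"), truth$accession)
      hmm <- gen_hmm_scores(labels, separation = 10,
                            seed = config$seed + 404L)
      hs <- build_homolog_set(side$records, hits, hmm,
                              side$architectures, side$annotations, th,
                              catalog)
      state$homologs <- hs
      state$retained <- hs$records$accession[hs$records$pass_all]
      emit(hs$records, "homologs.tsv")
      emit(data.frame(phylum = rownames(hs$counts), hs$counts,
                      check.names = FALSE), "homolog_counts.tsv")
      summary$screen <<- list(
        sensitivity = th$sensitivity, specificity = th$specificity,
        n_retained = sum(hs$records$pass_all))
    },
    network = function() {
      fam <- state$family %||% gen_protein_family(config$family)
      keep <- state$retained %||%
        fam$truth$accession[fam$truth$label == "positive"]
      keep <- setdiff(keep, fam$reference_id)
      seqs <- fam$sequences[keep]
      hits <- all_vs_all(seqs)
      curve <- threshold_curve(hits, config$grid, config$min_identity)
      opt <- optimal_evalue_threshold(curve)
      phyla <- stats::setNames(rep("Firmicutes", length(seqs)),
                               names(seqs))
      net <- build_network(hits, opt, config$min_identity, phyla = phyla)
      mix <- phylum_mixing(net)
      emit(as.data.frame(curve), "threshold_curve.tsv")
      emit(net, "network_edges.tsv", function(obj, p) write_network(obj, p))
      summary$network <<- list(
        optimal_evalue = opt, n_components = length(unique(net$components)),
        same_phylum_edge_fraction = mix$same_phylum_edge_fraction)
    },
    abundance = function() {
      coh <- state$cohort %||% read_cohort_inputs(config$inputs)
      state$cohort <- coh
      md <- coh$metadata
      if (!is.null(config$country)) md <- filter_country(md, config$country)
      norm <- normalize_abundance(coh$counts, coh$depths)
      total <- total_bsbg_abundance(norm, coh$gene_set)
      by_phylum <- aggregate_by_taxon(norm, coh$lineages, "phylum")
      scan <- pairwise_group_scan(total[md$sample_id], md)
      conf <- confounder_scan(total[md$sample_id], md)
      emit(data.frame(sample_id = names(total),
                      total_abundance = unname(total)),
           "total_abundance.tsv")
      emit(data.frame(phylum = rownames(by_phylum), by_phylum,
                      check.names = FALSE), "phylum_abundance.tsv")
      emit(scan, "group_comparisons.tsv")
      emit(conf, "confounder_scan.tsv")
      means <- tapply(total[md$sample_id], md$group, mean)
      summary$abundance <<- list(group_means = as.list(means),
                                 comparisons = nrow(scan))
    },
    metabolites = function() {
      coh <- state$cohort %||% read_cohort_inputs(config$inputs)
      lev <- state$levels %||% read_levels_input(config$inputs)
      md <- coh$metadata
      if (!is.null(config$country)) md <- filter_country(md, config$country)
      props <- to_proportions(lev[, md$sample_id, drop = FALSE])
      cmp <- compare_metabolites(props, md)
      emit(data.frame(metabolite = rownames(props), props,
                      check.names = FALSE), "metabolite_proportions.tsv")
      emit(cmp$per_metabolite, "metabolite_comparisons.tsv")
      emit(cmp$per_class, "class_comparisons.tsv")
      cp <- class_proportions(props)
      means <- tapply(cp$secondary_total,
                      md$group[match(cp$sample_id, md$sample_id)], mean)
      summary$metabolites <<- list(secondary_means = as.list(means))
    })

  failed <- FALSE
  for (stage in all_stages) {
    if (status[[stage]] == "disabled") next
    if (failed) { status[[stage]] <- "skipped"; next }
    logmsg("stage ", stage, ": start")
    res <- tryCatch({ stage_fns[[stage]](); "done" },
                    error = function(e) {
                      logmsg("stage ", stage, ": FAILED: ",
                             conditionMessage(e))
                      "failed"
                    })
    status[[stage]] <- res
    if (res == "failed") failed <- TRUE
    logmsg("stage ", stage, ": ", res)
  }
  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  structure(list(status = status, manifest = manifest, summary = summary,
                 log = log_path), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline run:\n")
  for (s in names(x$status)) cat(" ", s, ":", x$status[[s]], "\n")
  cat(" ", nrow(x$manifest), "output files in manifest\n")
  invisible(x)
}

# read the cohort tables that the simulate stage writes
read_cohort_inputs <- function(inputs) {
  counts_df <- read_tsv_table(inputs$counts)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df[[1]]
  depths_df <- read_tsv_table(inputs$depths)
  lineages_df <- read_tsv_table(inputs$lineages)
  list(counts = counts,
       depths = stats::setNames(depths_df$total_paired_reads,
                                depths_df$sample_id),
       lineages = stats::setNames(lineages_df$lineage,
                                  lineages_df$gene_id),
       metadata = read_tsv_table(inputs$metadata),
       gene_set = counts_df[[1]])
}

read_levels_input <- function(inputs) {
  if (is.null(inputs$metabolite_levels)) {
    stop("inputs$metabolite_levels required when simulate is disabled",
         call. = FALSE)
  }
  df <- read_tsv_table(inputs$metabolite_levels)
  lev <- as.matrix(df[, -1, drop = FALSE])
  rownames(lev) <- df[[1]]
  lev
}
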