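# Seeded generators for every input the pipeline consumes: protein families
# with decoys (the homolog-search space), profile-HMM score tables for the
# BSH/PVA discrimination, two-group cohort metagenome count tables with a
# phylum-restricted depletion of BSB genes, and bile-acid level tables.
# All generators are deterministic given their spec's seed and restore the
# caller's RNG state.

#' Specification of a synthetic protein family
#'
#' Describes one reference protein plus mutated true homologs at controlled
#' percent identity and composition-matched shuffled decoys.
#'
#' @param reference_length reference protein length in residues (>= 20).
#' @param n_true_homologs number of mutated derivatives of the reference.
#' @param identity_range length-2 numeric, target global identity band
#'   (fractions in (0, 1]).
#' @param n_decoys number of residue-shuffled decoy sequences.
#' @param indel_rate indel events per residue per unit divergence; scaled by
#'   (1 - target identity) so fully identical homologs carry no indels.
#' @param seed integer RNG seed.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(reference_length = 300L, n_true_homologs = 50L,
                        identity_range = c(0.6, 0.9), n_decoys = 50L,
                        indel_rate = 0.02, seed = 1L) {
  stopifnot(length(identity_range) == 2L)
  lo <- identity_range[1]; hi <- identity_range[2]
  if (!(lo > 0 && lo <= hi && hi <= 1)) {
    stop("identity_range must satisfy 0 < lo <= hi <= 1", call. = FALSE)
  }
  if (reference_length < 20L) {
    stop("reference_length must be >= 20", call. = FALSE)
  }
  if (n_true_homologs < 0L || n_decoys < 0L) {
    stop("counts must be >= 0", call. = FALSE)
  }
  if (indel_rate < 0) stop("indel_rate must be >= 0", call. = FALSE)
  structure(list(reference_length = as.integer(reference_length),
                 n_true_homologs = as.integer(n_true_homologs),
                 identity_range = c(lo, hi),
                 n_decoys = as.integer(n_decoys),
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "family_spec")
}

# substitute k distinct positions, each to one of the 19 alternatives
mutate_substitutions <- function(chars, k) {
  if (k == 0L) return(chars)
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(.aa_standard, chars[p]), 1)
  }
  chars
}

# geometric-length (mean 2) insertion/deletion events
mutate_indels <- function(chars, n_events) {
  for (i in seq_len(n_events)) {
    len <- stats::rgeom(1, 0.5) + 1L
    if (stats::runif(1) < 0.5 && length(chars) > len + 10L) {
      start <- sample(length(chars) - len + 1L, 1)
      chars <- chars[-(start:(start + len - 1L))]
    } else {
      at <- sample(length(chars) + 1L, 1)
      ins <- sample(.aa_standard, len, replace = TRUE)
      chars <- append(chars, ins, after = at - 1L)
    }
  }
  chars
}

#' Generate a synthetic protein family with decoys
#'
#' Produces one reference sequence, `n_true_homologs` mutated derivatives
#' whose realized global identity to the reference falls in
#' `identity_range` +/- 0.05, and `n_decoys` residue-shuffled sequences with
#' the reference's length and composition but no homology. Substitutions are
#' sampled uniformly over the 19 alternative residues at distinct sites;
#' indel events have geometric length (mean 2).
#'
#' @param spec a [family_spec()].
#' @return list with `sequences` (named character vector, reference first),
#'   `truth` (data.frame accession/label, label in positive/decoy; the
#'   reference is a positive) and `reference_id`.
#' @export
gen_protein_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  L <- spec$reference_length
  lo <- spec$identity_range[1]; hi <- spec$identity_range[2]
  ks <- 0:L
  feasible <- ks[1 - ks / L >= lo - 0.05 & 1 - ks / L <= hi + 0.05]
  if (length(feasible) == 0L) {
    stop("identity_range [", lo, ", ", hi, "] is infeasible for ",
         "reference_length ", L, call. = FALSE)
  }
  with_seed(spec$seed, {
    ref <- sample(.aa_standard, L, replace = TRUE)
    homs <- character(spec$n_true_homologs)
    for (i in seq_len(spec$n_true_homologs)) {
      t <- stats::runif(1, lo, hi)
      k <- round((1 - t) * L)
      k <- feasible[which.min(abs(feasible - k))]
      chars <- mutate_substitutions(ref, k)
      n_ev <- stats::rpois(1, spec$indel_rate * L * (1 - t))
      chars <- mutate_indels(chars, n_ev)
      homs[i] <- paste(chars, collapse = "")
    }
    decs <- vapply(seq_len(spec$n_decoys),
                   function(i) paste(sample(ref), collapse = ""),
                   character(1))
    seqs <- c(paste(ref, collapse = ""), homs, decs)
    names(seqs) <- c("REF",
                     sprintf("HOM%04d", seq_len(spec$n_true_homologs)),
                     sprintf("DEC%04d", seq_len(spec$n_decoys)))
    truth <- data.frame(
      accession = names(seqs),
      label = c("positive", rep("positive", spec$n_true_homologs),
                rep("decoy", spec$n_decoys)),
      stringsAsFactors = FALSE)
    list(sequences = seqs, truth = truth, reference_id = "REF")
  })
}

#' Generate synthetic BSH/PVA profile-HMM score tables
#'
#' For each labeled sequence the matching model's e-value exponent is
#' `separation` decades stronger (smaller e-value) than the other model's,
#' with unit-normal noise on each exponent; at separation 0 the two scores
#' are exchangeable and downstream classification performs at chance.
#'
#' @param labels named character vector, accession -> "BSH" or "PVA".
#' @param separation non-negative decades of e-value separation.
#' @param seed integer RNG seed.
#' @return data.frame with columns accession, bsh_evalue, pva_evalue.
#' @export
gen_hmm_scores <- function(labels, separation, seed = 1L) {
  if (separation < 0) stop("separation must be >= 0", call. = FALSE)
  if (length(labels) == 0L) {
    return(data.frame(accession = character(), bsh_evalue = numeric(),
                      pva_evalue = numeric(), stringsAsFactors = FALSE))
  }
  bad <- !labels %in% c("BSH", "PVA")
  if (any(bad)) {
    stop("unknown label(s): ", paste(unique(labels[bad]), collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    n <- length(labels)
    base <- stats::runif(n, 20, 60)
    bsh_exp <- base + ifelse(labels == "BSH", separation, 0) +
      stats::rnorm(n)
    pva_exp <- base + ifelse(labels == "PVA", separation, 0) +
      stats::rnorm(n)
    data.frame(accession = names(labels),
               bsh_evalue = 10^(-bsh_exp), pva_evalue = 10^(-pva_exp),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Specification of a synthetic two-group metagenome cohort
#'
#' @param n_per_group named integer vector of sample counts, names a subset
#'   of H, CD, UC. Default mirrors a 14-healthy / 4-CD / 21-UC cohort.
#' @param n_genes number of BSB genes in the catalog (> 0).
#' @param frac_firmicutes fraction of genes assigned to Firmicutes.
#' @param depth_mean mean total paired reads per sample.
#' @param depth_dispersion coefficient of variation of sequencing depth.
#' @param log2_effect per-group log2 fold change applied to BSB genes of
#'   `effect_phylum` in that group; scalar = applied to every non-H group.
#' @param baseline_rel_abundance total relative abundance of the BSB gene set
#'   in the healthy group (fraction of paired reads).
#' @param effect_phylum phylum carrying the depletion (default Firmicutes).
#' @param nb_size negative-binomial size (inverse overdispersion) of gene
#'   counts.
#' @param sample_log_sd log-normal sd of the per-sample community factor
#'   emulating inter-individual variation in BSB carriage.
#' @param country country label written into the metadata.
#' @param seed integer RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(H = 14L, CD = 4L, UC = 21L),
                        n_genes = 150L, frac_firmicutes = 0.8,
                        depth_mean = 5e6, depth_dispersion = 0.2,
                        log2_effect = -1, baseline_rel_abundance = 1e-4,
                        effect_phylum = "Firmicutes", nb_size = 10,
                        sample_log_sd = 0.3, country = "ES", seed = 1L) {
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% c("H", "CD", "UC"))) {
    stop("n_per_group names must be a subset of H, CD, UC", call. = FALSE)
  }
  if (n_genes <= 0L) stop("n_genes must be positive", call. = FALSE)
  if (frac_firmicutes < 0 || frac_firmicutes > 1) {
    stop("frac_firmicutes must be in [0, 1]", call. = FALSE)
  }
  if (depth_mean <= 0) stop("depth_mean must be positive", call. = FALSE)
  if (baseline_rel_abundance <= 0 || baseline_rel_abundance >= 1) {
    stop("baseline_rel_abundance must be in (0, 1)", call. = FALSE)
  }
  groups <- setdiff(names(n_per_group), "H")
  if (length(log2_effect) == 1L && is.null(names(log2_effect))) {
    log2_effect <- stats::setNames(rep(log2_effect, length(groups)), groups)
  }
  structure(list(n_per_group = n_per_group, n_genes = as.integer(n_genes),
                 frac_firmicutes = frac_firmicutes, depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 log2_effect = log2_effect,
                 baseline_rel_abundance = baseline_rel_abundance,
                 effect_phylum = effect_phylum, nb_size = nb_size,
                 sample_log_sd = sample_log_sd, country = country,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# small fixed taxonomy used to hang genes on realistic lineages; three
# genera per phylum so family/genus aggregation has structure to find
.phylum_taxa <- list(
  Firmicutes = data.frame(
    class = "Clostridia", order = "Eubacteriales",
    family = c("Clostridiaceae", "Lachnospiraceae", "Ruminococcaceae"),
    genus = c("Clostridium", "Coprococcus", "Ruminococcus")),
  Bacteroidetes = data.frame(
    class = "Bacteroidia", order = "Bacteroidales",
    family = c("Bacteroidaceae", "Rikenellaceae"),
    genus = c("Bacteroides", "Alistipes")),
  Actinobacteria = data.frame(
    class = "Coriobacteriia", order = "Eggerthellales",
    family = c("Eggerthellaceae", "Bifidobacteriaceae"),
    genus = c("Eggerthella", "Bifidobacterium")),
  Proteobacteria = data.frame(
    class = "Gammaproteobacteria", order = "Enterobacterales",
    family = c("Enterobacteriaceae"), genus = c("Escherichia")))

#' Generate a synthetic cohort metagenome count table
#'
#' Gene counts follow a negative-binomial model with gene-specific means
#' proportional to `baseline_rel_abundance` x sample depth, modulated by a
#' per-sample log-normal community factor. In non-healthy groups the genes
#' assigned to `effect_phylum` are scaled by `2^log2_effect[group]`. Per
#' sample, the sum of gene counts never exceeds the declared depth.
#'
#' @param spec a [cohort_spec()].
#' @return list with `counts` (gene x sample integer matrix), `depths`
#'   (named numeric, total paired reads per sample), `lineages` (named
#'   character, gene -> 7-rank lineage), `metadata` (data.frame sample_id,
#'   group, country, age, bmi, gender) and `gene_set` (all gene ids; every
#'   gene in the table is a BSB gene).
#' @export
gen_metagenome_counts <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- rep(names(spec$n_per_group), spec$n_per_group)
    n_samp <- length(groups)
    sample_ids <- paste0(groups, "_",
                         sprintf("%02d", stats::ave(seq_len(n_samp), groups,
                                                    FUN = seq_along)))
    metadata <- data.frame(
      sample_id = sample_ids, group = groups, country = spec$country,
      age = round(stats::runif(n_samp, 20, 70)),
      bmi = round(stats::rnorm(n_samp, 24, 3), 1),
      gender = sample(c("F", "M"), n_samp, replace = TRUE),
      stringsAsFactors = FALSE)

    n_genes <- spec$n_genes
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    n_firm <- round(spec$frac_firmicutes * n_genes)
    other <- setdiff(names(.phylum_taxa), "Firmicutes")
    phyla <- c(rep("Firmicutes", n_firm),
               rep_len(other, n_genes - n_firm))
    lineages <- vapply(seq_len(n_genes), function(i) {
      tab <- .phylum_taxa[[phyla[i]]]
      row <- tab[sample(nrow(tab), 1), ]
      make_lineage(phylum = phyla[i], class = row$class, order = row$order,
                   family = row$family, genus = row$genus,
                   species = paste0(row$genus, " sp."))
    }, character(1))
    names(lineages) <- gene_ids

    # uneven gene weights within the BSB set, normalized to the baseline
    w <- stats::rlnorm(n_genes, 0, 1)
    w <- w / sum(w)
    sdlog_d <- sqrt(log(1 + spec$depth_dispersion^2))
    depths <- round(stats::rlnorm(n_samp,
                                  log(spec$depth_mean) - sdlog_d^2 / 2,
                                  sdlog_d))
    names(depths) <- sample_ids
    comm <- stats::rlnorm(n_samp, -spec$sample_log_sd^2 / 2,
                          spec$sample_log_sd)
    counts <- matrix(0L, n_genes, n_samp,
                     dimnames = list(gene_ids, sample_ids))
    for (s in seq_len(n_samp)) {
      eff <- rep(1, n_genes)
      g <- groups[s]
      if (g != "H" && g %in% names(spec$log2_effect)) {
        eff[phyla == spec$effect_phylum] <- 2^spec$log2_effect[[g]]
      }
      mu <- spec$baseline_rel_abundance * w * eff * depths[s] * comm[s]
      cs <- stats::rnbinom(n_genes, mu = mu, size = spec$nb_size)
      if (sum(cs) > depths[s]) {
        cs <- floor(cs * depths[s] / sum(cs))
      }
      counts[, s] <- as.integer(cs)
    }
    list(counts = counts, depths = depths, lineages = lineages,
         metadata = metadata, gene_set = gene_ids)
  })
}

#' Specification of a synthetic bile-acid metabolite table
#'
#' @param ba_names metabolite names; every name must resolve in the
#'   [ba_vocabulary()]. Default: the full shipped vocabulary.
#' @param group_shift named list of named numeric vectors,
#'   class -> (group -> multiplicative effect); classes among primary,
#'   secondary, conjugated_primary. Unlisted combinations default to 1.
#' @param noise_cv coefficient of variation of the log-normal level noise.
#' @param seed integer RNG seed.
#' @return object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(ba_names = NULL, group_shift = list(),
                            noise_cv = 0.4, seed = 1L) {
  vocab <- ba_vocabulary()
  if (is.null(ba_names)) ba_names <- vocab$name
  unknown <- setdiff(tolower(ba_names), vocab$name)
  if (length(unknown) > 0) {
    stop("bile acid name(s) not in vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  bad_class <- setdiff(names(group_shift),
                       c("primary", "secondary", "conjugated_primary"))
  if (length(bad_class) > 0) {
    stop("unknown group_shift class(es): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  structure(list(ba_names = tolower(ba_names), group_shift = group_shift,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "metabolite_spec")
}

#' Generate a synthetic bile-acid level table
#'
#' Strictly positive log-normal levels per metabolite and sample; class-level
#' multiplicative shifts are applied per group (`conjugated_primary` shifts
#' stack multiplicatively on conjugated primary BAs, on top of any `primary`
#' shift).
#'
#' @param spec a [metabolite_spec()].
#' @param metadata sample metadata with columns sample_id and group (groups
#'   within H, CD, UC).
#' @return metabolite x sample numeric matrix of levels.
#' @export
gen_metabolite_table <- function(spec, metadata) {
  stopifnot(inherits(spec, "metabolite_spec"))
  if (!all(metadata$group %in% c("H", "CD", "UC"))) {
    stop("metadata groups must be within H, CD, UC", call. = FALSE)
  }
  vocab <- ba_vocabulary()
  cls <- classify_ba(spec$ba_names)
  with_seed(spec$seed, {
    n_m <- length(spec$ba_names)
    n_s <- nrow(metadata)
    # per-metabolite baselines: secondary BAs dominate a healthy profile
    base <- stats::rlnorm(n_m, log(ifelse(cls$class == "secondary", 40, 10)),
                          0.5)
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    lev <- matrix(0, n_m, n_s,
                  dimnames = list(spec$ba_names, metadata$sample_id))
    shift_for <- function(class, conj, group) {
      s <- 1
      gs <- spec$group_shift
      if (!is.null(gs[[class]]) && group %in% names(gs[[class]])) {
        s <- s * gs[[class]][[group]]
      }
      if (class == "primary" && conj != "unconjugated" &&
          !is.null(gs$conjugated_primary) &&
          group %in% names(gs$conjugated_primary)) {
        s <- s * gs$conjugated_primary[[group]]
      }
      s
    }
    for (j in seq_len(n_s)) {
      g <- metadata$group[j]
      sh <- vapply(seq_len(n_m),
                   function(i) shift_for(cls$class[i], cls$conjugation[i], g),
                   numeric(1))
      lev[, j] <- base * sh * stats::rlnorm(n_m, -sdlog^2 / 2, sdlog)
    }
    lev
  })
}

#' Write a named set of protein sequences as FASTA
#'
#' @param sequences named character vector of protein sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(sequences, path) {
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
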