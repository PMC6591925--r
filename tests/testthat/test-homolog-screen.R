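test_that("calibration recovers perfect separation on separable controls", {
  withr::local_seed(1)
  pos <- make_hits(40, identity = runif(40, 60, 90),
                   evalue_exp = runif(40, -120, -50), coverage = 0.9)
  neg <- make_hits(40, identity = runif(40, 10, 25),
                   evalue_exp = runif(40, -3, 0), coverage = 0.3)
  th <- calibrate_thresholds(pos, neg)
  expect_s3_class(th, "threshold_set")
  expect_equal(th$sensitivity, 1.0)
  expect_equal(th$specificity, 1.0)
})

test_that("calibration ties break toward the most stringent candidate", {
  # positives and negatives identical: J = 0 at every grid point
  h <- make_hits(20, identity = 50, evalue_exp = -30, coverage = 0.9)
  grid <- threshold_grid(identities = c(30, 40), evalues = c(1e-5, 1e-10),
                         coverages = c(0.5, 0.7))
  th <- calibrate_thresholds(h, h, grid)
  expect_equal(th$sensitivity - (1 - th$specificity), 0) # J = 0
  expect_equal(th$min_identity, 40)
  expect_equal(th$max_evalue, 1e-10)
  expect_equal(th$min_query_coverage, 0.7)
})

test_that("single-point grids report directly counted sens/spec", {
  pos <- make_hits(4, identity = c(50, 50, 20, 50), evalue_exp = -30,
                   coverage = 0.9)
  neg <- make_hits(4, identity = c(50, 20, 20, 20), evalue_exp = -30,
                   coverage = 0.9)
  th <- calibrate_thresholds(pos, neg,
                             list(threshold_set(30, 1e-10, 0.7, 0.7)))
  expect_equal(th$sensitivity, 3 / 4)
  expect_equal(th$specificity, 3 / 4)
  expect_error(calibrate_thresholds(pos[0, ], neg), "non-empty")
  expect_error(calibrate_thresholds(pos, neg, list()), "non-empty")
})

test_that("hit filtering honors thresholds with boundary values passing", {
  th <- threshold_set(30, 1e-20, 0.7, 0.7)
  hit <- make_hits(1, identity = 45, evalue_exp = -60, coverage = 0.9)
  hit$target_coverage <- 0.85
  expect_equal(filter_hits(hit, th), "q1")
  low_cov <- hit; low_cov$query_coverage <- 0.5
  expect_equal(filter_hits(low_cov, th), character())
  boundary <- make_hits(1, identity = 30, evalue_exp = -20, coverage = 0.7)
  expect_equal(filter_hits(boundary, th), "q1")
  expect_equal(filter_hits(hit[0, ], th), character())
})

test_that("BSH/PVA discrimination follows e-value semantics by default", {
  expect_equal(classify_bsh_pva(1e-80, 1e-10), "BSH")
  expect_equal(classify_bsh_pva(1e-10, 1e-80), "PVA")
  expect_equal(classify_bsh_pva(1e-20, 1e-20), "ambiguous")
  expect_equal(classify_bsh_pva(NA, 1e-20), "ambiguous")
  # the literal reading is preserved behind a flag, inverted
  expect_equal(classify_bsh_pva(1e-80, 1e-10, mode = "literal_paper_text"),
               "PVA")
  expect_equal(classify_bsh_pva(1e-10, 1e-80, mode = "literal_paper_text"),
               "BSH")
  expect_error(classify_bsh_pva(-1, 1e-10), ">= 0")
})

test_that("domain architectures must match exactly, in order", {
  expect_true(domain_architecture_filter("PF02275", "PF02275"))
  expect_false(domain_architecture_filter(c("PF02275", "PF00106"),
                                          "PF02275"))
  expect_false(domain_architecture_filter(character(), "PF02275"))
  expect_false(domain_architecture_filter(c("PF00106", "PF02275"),
                                          c("PF02275", "PF00106")))
  expect_error(domain_architecture_filter("PF02275", character()),
               "non-empty")
})

test_that("annotation concordance distinguishes strict and relaxed modes", {
  expect_true(annotation_concordance_filter("COG2141", "COG2141"))
  expect_false(annotation_concordance_filter("COG2141", "COG0183"))
  expect_true(annotation_concordance_filter(
    "COG2141", "COG0183", mode = "relaxed",
    candidate_categories = "C", reference_categories = "CI"))
  expect_false(annotation_concordance_filter(
    "COG2141", "COG0183", mode = "relaxed",
    candidate_categories = "K", reference_categories = "CI"))
  expect_error(annotation_concordance_filter("COG2141", ""), "non-empty")
})

# shared synthetic screen: a Bsh family where positives carry the reference
# architecture/annotation and matching HMM scores, decoys none of these
make_screen_inputs <- function(seed = 11, n_pos = 15, n_dec = 15) {
  fam <- gen_protein_family(family_spec(reference_length = 200,
                                        n_true_homologs = n_pos,
                                        n_decoys = n_dec, seed = seed))
  ref <- fam$sequences[[fam$reference_id]]
  cand <- fam$sequences[names(fam$sequences) != fam$reference_id]
  hits <- do.call(rbind, lapply(names(cand), function(a) {
    smith_waterman(cand[[a]], ref, query_id = a, target_id = "REF")
  }))
  truth <- fam$truth[fam$truth$accession != fam$reference_id, ]
  pos <- truth$label == "positive"
  catalog <- enzyme_catalog()
  bsh <- catalog[catalog$name == "Bsh", ]
  records <- data.frame(
    accession = truth$accession,
    lineage = make_lineage(phylum = ifelse(pos, "Firmicutes",
                                           "Proteobacteria"),
                           species = paste0("strain", seq_len(nrow(truth)))),
    category = "Bsh", stringsAsFactors = FALSE)
  list(
    truth = truth, hits = hits, records = records,
    hmm = gen_hmm_scores(stats::setNames(ifelse(pos, "BSH", "PVA"),
                                         truth$accession),
                         separation = 10, seed = seed),
    architectures = stats::setNames(
      ifelse(pos, bsh$reference_architecture, "PF00000"), truth$accession),
    annotations = stats::setNames(
      ifelse(pos, bsh$reference_annotation, "COG0000"), truth$accession))
}

test_that("the composed screen keeps positives and drops decoys", {
  inp <- make_screen_inputs(seed = 11)
  pos_ids <- inp$truth$accession[inp$truth$label == "positive"]
  th <- calibrate_thresholds(inp$hits[inp$hits$query_id %in% pos_ids, ],
                             inp$hits[!inp$hits$query_id %in% pos_ids, ])
  hs <- build_homolog_set(inp$records, inp$hits, inp$hmm,
                          inp$architectures, inp$annotations, th)
  kept <- hs$records$accession[hs$records$pass_all]
  expect_setequal(kept, pos_ids)
  # counts matrix partitions the retained records
  expect_equal(sum(hs$counts), length(kept))
  expect_equal(unname(hs$counts["Firmicutes", "Bsh"]), length(pos_ids))
})

test_that("disabling a filter stage can only grow the homolog set", {
  inp <- make_screen_inputs(seed = 12)
  th <- threshold_set(40, 1e-10, 0.7, 0.7)
  full <- build_homolog_set(inp$records, inp$hits, inp$hmm,
                            inp$architectures, inp$annotations, th)
  no_domain <- build_homolog_set(inp$records, inp$hits, inp$hmm,
                                 inp$architectures, inp$annotations, th,
                                 stages = c("hit", "bsh_pva", "annotation"))
  hit_only <- build_homolog_set(inp$records, inp$hits, inp$hmm,
                                inp$architectures, inp$annotations, th,
                                stages = "hit")
  kept <- function(h) h$records$accession[h$records$pass_all]
  expect_true(all(kept(full) %in% kept(no_domain)))
  expect_true(all(kept(no_domain) %in% kept(hit_only)))
})

test_that("hits referencing unknown accessions are rejected", {
  inp <- make_screen_inputs(seed = 13, n_pos = 3, n_dec = 3)
  bad_hits <- inp$hits
  bad_hits$query_id[1] <- "GHOST001"
  expect_error(build_homolog_set(inp$records, bad_hits, inp$hmm,
                                 inp$architectures, inp$annotations,
                                 threshold_set(30, 1e-5, 0.5, 0.5)),
               "GHOST001")
})

test_that("Bsh candidates without HMM scores are conservatively excluded", {
  inp <- make_screen_inputs(seed = 14, n_pos = 5, n_dec = 0)
  th <- threshold_set(30, 1e-5, 0.5, 0.5)
  hmm_missing <- inp$hmm[-1, ]
  hs <- build_homolog_set(inp$records, inp$hits, hmm_missing,
                          inp$architectures, inp$annotations, th)
  dropped <- inp$hmm$accession[1]
  expect_false(hs$records$pass_all[hs$records$accession == dropped])
  expect_equal(sum(hs$records$pass_all), 4L)
})

test_that("prevalence matrix counts presence per strain and category", {
  strains <- c("s1", "s1", "s1", "s2", "s3")
  cats <- c("BaiA", "BaiB", "Bsh", "BaiA", "HSD")
  records <- data.frame(
    accession = paste0("p", 1:5),
    lineage = make_lineage(phylum = "Firmicutes", species = strains),
    category = cats, stringsAsFactors = FALSE)
  hs <- build_homolog_set(records, make_hits(0, 1, -1, 1)[0, ],
                          thresholds = threshold_set(30, 1e-5, 0.5, 0.5),
                          stages = character())
  mat <- prevalence_matrix(hs)
  expect_equal(unname(rowSums(mat)[c("s1", "s2", "s3")]), c(3, 1, 1))
  expect_equal(unname(mat["s1", "BaiA"]), 1L)
  expect_equal(unname(mat["s2", "Bsh"]), 0L)
  # removing one record changes at most one cell
  hs2 <- build_homolog_set(records[-5, ], make_hits(0, 1, -1, 1)[0, ],
                           thresholds = threshold_set(30, 1e-5, 0.5, 0.5),
                           stages = character())
  mat2 <- prevalence_matrix(hs2)
  common <- intersect(rownames(mat), rownames(mat2))
  expect_lte(sum(mat[common, ] != mat2[common, ]) +
               sum(mat[setdiff(rownames(mat), common), ]), 1)
  # empty set gives an empty matrix
  hs_empty <- build_homolog_set(records[0, ], make_hits(0, 1, -1, 1)[0, ],
                                thresholds = threshold_set(30, 1e-5, 0.5,
                                                           0.5),
                                stages = character())
  expect_equal(nrow(prevalence_matrix(hs_empty)), 0L)
})

test_that("strain selection requires a strict majority of categories", {
  mat <- matrix(0L, 3, 13,
                dimnames = list(c("seven", "six", "all"),
                                enzyme_catalog()$name))
  mat["seven", 1:7] <- 1L
  mat["six", 1:6] <- 1L
  mat["all", ] <- 1L
  sel <- select_prevalent_strains(mat)
  expect_setequal(sel, c("seven", "all"))
  expect_error(select_prevalent_strains(mat, 0), "positive")
})
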