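toy_table <- function() {
  counts <- matrix(c(100, 0, 50, 10,
                     200, 40, 0, 60), nrow = 4,
                   dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  depths <- c(s1 = 1e6, s2 = 2e6)
  lineages <- stats::setNames(
    make_lineage(phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes",
                            ""),
                 family = c("Lachnospiraceae", "Ruminococcaceae",
                            "Bacteroidaceae", ""),
                 genus = c("Coprococcus", "Ruminococcus", "Bacteroides",
                           "")),
    paste0("g", 1:4))
  list(counts = counts, depths = depths, lineages = lineages)
}

test_that("normalization divides by the per-sample total paired reads", {
  toy <- toy_table()
  norm <- normalize_abundance(toy$counts, toy$depths)
  expect_equal(norm["g1", "s1"], 100 / 1e6)
  expect_equal(norm["g2", "s1"], 0)
  expect_equal(unname(colSums(norm)),
               unname(colSums(toy$counts) / toy$depths))
  # idempotence with unit depths
  expect_equal(normalize_abundance(norm, c(s1 = 1, s2 = 1)), norm)
  expect_error(normalize_abundance(toy$counts, c(s1 = 1e6)),
               "missing depth.*s2")
  neg <- toy$counts; neg[1, 1] <- -1
  expect_error(normalize_abundance(neg, toy$depths), "negative")
})

test_that("gene-set totals are additive over disjoint sets", {
  toy <- toy_table()
  norm <- normalize_abundance(toy$counts, toy$depths)
  expect_equal(total_bsbg_abundance(norm, "g1"), norm["g1", ])
  a <- total_bsbg_abundance(norm, c("g1", "g2"))
  b <- total_bsbg_abundance(norm, c("g3", "g4"))
  expect_equal(a + b, total_bsbg_abundance(norm, paste0("g", 1:4)))
  expect_error(total_bsbg_abundance(norm, "gX"), "gX")
})

test_that("taxonomic aggregation matches hand arithmetic and conserves", {
  toy <- toy_table()
  norm <- normalize_abundance(toy$counts, toy$depths)
  phy <- aggregate_by_taxon(norm, toy$lineages, "phylum")
  expect_equal(phy["Firmicutes", "s1"], (100 + 0) / 1e6)
  expect_equal(phy["Bacteroidetes", "s2"], 0 / 2e6)
  # the lineage-less gene lands in the unclassified bucket
  expect_equal(phy["unclassified", "s2"], 60 / 2e6)
  expect_equal(colSums(phy), total_bsbg_abundance(norm, paste0("g", 1:4)),
               tolerance = 1e-12)
  fam <- aggregate_by_taxon(norm, toy$lineages, "family")
  expect_equal(colSums(fam), colSums(phy), tolerance = 1e-12)
  bad <- toy$lineages
  bad["g1"] <- "k__Bacteria;p__Firmicutes"
  expect_error(aggregate_by_taxon(norm, bad, "phylum"), "7 semicolon")
})

test_that("the exact rank test reproduces full-enumeration p-values", {
  md <- function(n1, n2) {
    data.frame(sample_id = paste0("s", seq_len(n1 + n2)),
               group = rep(c("H", "CD"), c(n1, n2)))
  }
  # worked case: complete separation of 3 vs 3
  m <- md(3, 3)
  cmp <- compare_groups(stats::setNames(c(1, 2, 3, 10, 11, 12),
                                        m$sample_id), m)
  expect_equal(cmp$test_name, "mann_whitney")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 0.1)
  # identical multisets: p = 1 under the exact test
  cmp1 <- compare_groups(stats::setNames(c(1, 2, 3, 1, 2, 3),
                                         m$sample_id), m)
  expect_equal(cmp1$p_value, 1)
  # tie-free random cases agree with the independent exact implementation
  withr::local_seed(7)
  for (k in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    m2 <- md(n1, n2)
    v <- stats::setNames(sample(seq_len(50), n1 + n2), m2$sample_id)
    got <- compare_groups(v, m2)
    ref <- stats::wilcox.test(v[1:n1], v[(n1 + 1):(n1 + n2)],
                              exact = TRUE)
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("group comparison dispatches by group count and validates sizes", {
  md3 <- data.frame(sample_id = paste0("s", 1:15),
                    group = rep(c("H", "CD", "UC"), each = 5))
  v <- stats::setNames(rnorm(15), md3$sample_id)
  cmp <- compare_groups(v, md3)
  expect_equal(cmp$test_name, "kruskal_wallis")
  expect_equal(unname(cmp$group_n), c(5L, 5L, 5L))
  expect_true(all(cmp$normality_p > 0 & cmp$normality_p <= 1))
  # large groups take the normal-approximation path and match wilcox.test
  md_big <- data.frame(sample_id = paste0("s", 1:25),
                       group = rep(c("H", "CD"), c(12, 13)))
  vb <- stats::setNames(rnorm(25), md_big$sample_id)
  got <- compare_groups(vb, md_big)
  ref <- stats::wilcox.test(vb[1:12], vb[13:25], exact = FALSE,
                            correct = TRUE)
  expect_equal(got$p_value, ref$p.value)
  expect_error(compare_groups(v[1:6], md3), ">= 2 samples")
})

test_that("significance stars follow the caption cutpoints", {
  expect_equal(significance_stars(c(0.2, 0.05, 0.03, 0.01, 0.0005, 1e-5)),
               c("ns", "*", "*", "**", "***", "****"))
  expect_equal(significance_stars(NA), NA_character_)
})

test_that("the pairwise scan covers every group pair with stars", {
  withr::local_seed(3)
  md3 <- data.frame(sample_id = paste0("s", 1:30),
                    group = rep(c("H", "CD", "UC"), each = 10))
  v <- stats::setNames(rnorm(30) + rep(c(3, 0, 0), each = 10),
                       md3$sample_id)
  scan <- pairwise_group_scan(v, md3)
  expect_equal(nrow(scan), 3L)
  expect_setequal(paste(scan$group1, scan$group2),
                  c("H CD", "H UC", "CD UC"))
  expect_equal(scan$stars, significance_stars(scan$p_value))
  hcd <- scan[scan$group1 == "H" & scan$group2 == "CD", ]
  expect_lt(hcd$p_value, 0.01)
})

test_that("confounder scan flags planted signals and drops constants", {
  withr::local_seed(13)
  md <- data.frame(sample_id = paste0("s", 1:40),
                   group = "H", country = "ES",
                   age = runif(40, 20, 70),
                   bmi = rnorm(40, 24, 3),
                   gender = rep(c("F", "M"), 20))
  v <- stats::setNames(2 * md$age + rnorm(40, 0, 1), md$sample_id)
  scan <- confounder_scan(v, md)
  expect_true(scan$flagged[scan$covariate == "age"])
  expect_equal(nrow(scan), 3L)
  # constant covariate excluded with a warning, not flagged
  md_const <- md; md_const$gender <- "F"
  expect_warning(scan2 <- confounder_scan(v, md_const), "constant")
  expect_false("gender" %in% scan2$covariate)
  expect_error(confounder_scan(v[1:4], md[1:4, ]), "too few samples")
})

test_that("country filtering restricts metadata rows", {
  md <- data.frame(sample_id = c("a", "b", "c"),
                   group = "H", country = c("ES", "US", "ES"))
  expect_equal(filter_country(md, "ES")$sample_id, c("a", "c"))
})
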