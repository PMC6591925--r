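# synthetic hit tables reused across network tests: two tight families with
# a weak inter-family link
two_family_hits <- function() {
  fam1 <- paste0("a", 1:5)
  fam2 <- paste0("b", 1:5)
  intra <- function(ids) {
    p <- utils::combn(ids, 2)
    make_pair_hits(p[1, ], p[2, ], evalue = 1e-100, identity = 80)
  }
  inter <- make_pair_hits(rep(fam1, each = 5), rep(fam2, 5),
                          evalue = 1e-10, identity = 40)
  rbind(intra(fam1), intra(fam2), inter)
}


test_that("all-vs-all produces one hit per unordered pair", {
  fam <- gen_protein_family(family_spec(reference_length = 80,
                                        n_true_homologs = 3, n_decoys = 0,
                                        seed = 4))
  hits <- all_vs_all(fam$sequences)
  expect_equal(nrow(hits), choose(4, 2))
  # pairwise values match single-pair recomputation
  for (k in seq_len(nrow(hits))) {
    redo <- smith_waterman(fam$sequences[[hits$query_id[k]]],
                           fam$sequences[[hits$target_id[k]]])
    expect_equal(hits$score[k], redo$score)
    expect_equal(hits$percent_identity[k], redo$percent_identity)
  }
  dup <- fam$sequences
  names(dup)[2] <- names(dup)[1]
  expect_error(all_vs_all(dup), "duplicate")
  expect_error(all_vs_all(fam$sequences[1]), "at least 2")
  # identical sequences align at 100% identity
  twin <- c(x = "ACDEFGHIKLMNPQRSTVWY", y = "ACDEFGHIKLMNPQRSTVWY")
  expect_equal(all_vs_all(twin)$percent_identity, 100)
})

test_that("threshold sweep separates families at the designed cutoffs", {
  hits <- two_family_hits()
  curve <- threshold_curve(hits, grid = c(1e-5, 1e-50))
  expect_equal(curve$n_components[curve$threshold == 1e-5], 1)
  expect_equal(curve$n_components[curve$threshold == 1e-50], 2)
  expect_error(threshold_curve(hits, grid = numeric()), "non-empty")
  expect_error(threshold_curve(hits, grid = c(1e-50, 1e-5)), "decreasing")
})

test_that("sweep invariants hold on randomized hit tables", {
  withr::local_seed(17)
  for (k in 1:20) {
    n <- sample(5:12, 1)
    p <- utils::combn(paste0("s", 1:n), 2)
    keep <- runif(ncol(p)) < 0.4
    if (!any(keep)) next
    hits <- make_pair_hits(p[1, keep], p[2, keep],
                           evalue = 10^runif(sum(keep), -150, -1),
                           identity = runif(sum(keep), 10, 90))
    curve <- threshold_curve(hits, nodes = paste0("s", 1:n))
    expect_false(is.unsorted(curve$n_components))          # comps grow
    expect_false(is.unsorted(rev(curve$n_edges)))          # edges shrink
  }
})

test_that("degenerate networks sweep correctly", {
  # fully disconnected decoys: every node its own component at all cutoffs
  hits <- make_pair_hits("d1", "d2", evalue = 10, identity = 5)
  curve <- threshold_curve(hits, nodes = paste0("d", 1:5))
  expect_true(all(curve$n_components == 5))
  expect_true(all(curve$n_edges == 0))
})

test_that("the optimal threshold is the stringent end of the longest plateau", {
  # constant curve: single plateau, most stringent grid point wins
  flat <- make_curve(10^-(1:5), rep(3, 5))
  expect_equal(optimal_evalue_threshold(flat), 1e-5)
  # worked plateau case: the 4-long final plateau wins
  curve <- make_curve(10^-(1:9), c(1, 1, 1, 2, 2, 8, 8, 8, 8))
  expect_equal(optimal_evalue_threshold(curve), 1e-9)
  # strictly increasing: all plateaus length 1, stringent tie rule
  inc <- make_curve(10^-(1:4), 1:4)
  expect_equal(optimal_evalue_threshold(inc), 1e-4)
  # longest plateau in the middle
  mid <- make_curve(10^-(1:6), c(1, 4, 4, 4, 7, 8))
  expect_equal(optimal_evalue_threshold(mid), 1e-4)
})

test_that("network edges obey the strict e-value and identity rules", {
  pass <- make_pair_hits("a", "b", evalue = 1e-40, identity = 50)
  expect_equal(nrow(build_network(pass, 1e-20)$edges), 1L)
  low_id <- make_pair_hits("a", "b", evalue = 1e-40, identity = 25)
  expect_equal(nrow(build_network(low_id, 1e-20)$edges), 0L)
  expect_equal(nrow(build_network(low_id, 1e-300)$edges), 0L)
  # boundary: e-value equal to the cutoff is excluded
  at_cut <- make_pair_hits("a", "b", evalue = 1e-20, identity = 50)
  expect_equal(nrow(build_network(at_cut, 1e-20)$edges), 0L)
  expect_error(build_network(pass, 0), "positive")
})

test_that("components equal the transitive-closure oracle on random graphs", {
  withr::local_seed(23)
  for (k in 1:60) {
    n <- sample(2:12, 1)
    edges <- random_graph(n, p_edge = runif(1, 0.05, 0.5))
    nodes <- paste0("n", seq_len(n))
    hits <- if (nrow(edges) > 0) {
      make_pair_hits(edges$from, edges$to, evalue = 1e-50, identity = 90)
    } else make_pair_hits(nodes[1], nodes[2], 10, 5)[0, ]
    net <- build_network(hits, 1e-20, nodes = nodes)
    memb <- connected_components(net)
    oracle <- components_oracle(nodes, edges)
    expect_true(same_partition(memb, oracle))
  }
})

test_that("trivial component structures are labeled correctly", {
  path <- make_pair_hits(c("a", "b"), c("b", "c"), 1e-50, 90)
  net <- build_network(path, 1e-20)
  expect_equal(length(unique(connected_components(net))), 1L)
  lonely <- build_network(path[0, ], 1e-20, nodes = paste0("x", 1:5))
  expect_equal(length(unique(connected_components(lonely))), 5L)
})

test_that("network construction is invariant to input order", {
  hits <- two_family_hits()
  perm <- hits[sample(nrow(hits)), ]
  class(perm) <- class(hits)
  n1 <- build_network(hits, 1e-50)
  n2 <- build_network(perm, 1e-50)
  expect_equal(nrow(n1$edges), nrow(n2$edges))
  c1 <- connected_components(n1)
  c2 <- connected_components(n2)
  expect_true(same_partition(c1, c2[names(c1)]))
})

test_that("phylum mixing metrics match hand counts", {
  hits <- two_family_hits()
  ids <- unique(c(hits$query_id, hits$target_id))
  # all one phylum
  one <- build_network(hits, 1e-50,
                       phyla = stats::setNames(rep("Firmicutes", 10), ids))
  mix1 <- phylum_mixing(one)
  expect_equal(mix1$same_phylum_edge_fraction, 1.0)
  expect_true(all(mix1$component_purity$purity == 1.0))
  # complete bipartite across two phyla: no same-phylum edge
  bip <- make_pair_hits(rep(c("p1", "p2"), each = 3),
                        rep(c("q1", "q2", "q3"), 2), 1e-100, 90)
  net_b <- build_network(bip, 1e-50,
                         phyla = c(p1 = "A", p2 = "A", q1 = "B", q2 = "B",
                                   q3 = "B"))
  expect_equal(phylum_mixing(net_b)$same_phylum_edge_fraction, 0.0)
  # 6-node mixed fixture, hand-enumerated: edges aa, ab, bb -> 2/3 same
  fix <- make_pair_hits(c("x1", "x2", "y1"), c("x2", "y1", "y2"),
                        1e-100, 90)
  net_f <- build_network(fix, 1e-50,
                         phyla = c(x1 = "A", x2 = "A", y1 = "B", y2 = "B",
                                   z1 = "A", z2 = "B"),
                         nodes = c("x1", "x2", "y1", "y2", "z1", "z2"))
  mix_f <- phylum_mixing(net_f)
  expect_equal(mix_f$same_phylum_edge_fraction, 2 / 3)
  # component {x1,x2,y1,y2}: majority 2/4; singletons pure
  expect_setequal(mix_f$component_purity$purity, c(0.5, 1, 1))
  # unlabeled nodes are an error
  expect_error(phylum_mixing(build_network(fix, 1e-50)), "phylum label")
})

test_that("networks and curves write to disk in the documented layouts", {
  hits <- two_family_hits()
  ids <- unique(c(hits$query_id, hits$target_id))
  net <- build_network(hits, 1e-50,
                       phyla = stats::setNames(rep("F", 10), ids))
  edges_path <- withr::local_tempfile(fileext = ".tsv")
  gml_path <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, edges_path, gml_path)
  back <- read.delim(edges_path)
  expect_equal(nrow(back), nrow(net$edges))
  expect_named(back, c("source", "target", "evalue", "identity",
                       "component"))
  expect_true(file.size(gml_path) > 0)
})
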