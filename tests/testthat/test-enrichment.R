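toy_ann <- function() {
  # universe of 10 proteins; term T1 annotates 4 of them
  ann <- rbind(
    data.frame(protein = paste0("P", 1:4), term_id = "T1", term_name = "term one"),
    data.frame(protein = paste0("P", c(1, 5, 6)), term_id = "T2", term_name = "term two"),
    data.frame(protein = paste0("P", 1:10), term_id = "T3", term_name = "everything"))
  annotation_set(ann, universe = paste0("P", 1:10))
}

test_that("hypergeometric p-values match exhaustive enumeration", {
  ann <- toy_ann()
  res <- enrich(paste0("P", 1:5), ann)   # N=10, n=5; T1: K=4, k=4
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$k, 4L)
  expect_equal(t1$p, 6 / 252)
  expect_equal(t1$p, oracle_hyper_p(10, 4, 5, 4), tolerance = 1e-12)

  # a term annotating the whole universe is never enriched
  expect_equal(res$p[res$term_id == "T3"], 1)

  # k = 0 terms are absent
  none <- enrich(paste0("P", 7:10), ann)
  expect_false("T1" %in% none$term_id)

  empty <- annotation_set(data.frame(protein = character(0),
                                     term_id = character(0),
                                     term_name = character(0)),
                          universe = character(0))
  expect_error(enrich("P1", empty), "universe")
})

test_that("enrichment agrees with enumeration across random small universes", {
  set.seed(88)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:N, 1)
    prot <- sprintf("U%02d", 1:N)
    ann <- annotation_set(
      data.frame(protein = prot[1:K], term_id = "T", term_name = "t"),
      universe = prot)
    members <- sample(prot, n)
    res <- enrich(members, ann)
    k <- sum(members %in% prot[1:K])
    if (k == 0) {
      expect_equal(nrow(res), 0L)
    } else {
      expect_equal(res$p, oracle_hyper_p(N, K, n, k), tolerance = 1e-12)
    }
  }
})

test_that("multiple-testing corrections follow the standard formulas", {
  res <- data.frame(term_id = c("a", "b", "c"), p = c(0.01, 0.02, 0.03))
  bh <- adjust_pvalues(res)
  expect_equal(bh$p_adj, c(0.03, 0.03, 0.03))   # step-up by hand

  single <- adjust_pvalues(data.frame(term_id = "a", p = 0.04))
  expect_equal(single$p_adj, 0.04)

  bonf <- adjust_pvalues(data.frame(term_id = c("a", "b"), p = c(0.9, 0.04)),
                         method = "bonferroni")
  expect_equal(bonf$p_adj, c(1.0, 0.08))

  expect_error(adjust_pvalues(res, method = "fdr-ish"))
})

test_that("the functional map connects overlapping terms and applies filters", {
  prot <- sprintf("M%02d", 1:30)
  ann <- annotation_set(rbind(
    data.frame(protein = prot[1:10], term_id = "GO:1", term_name = "alpha"),
    data.frame(protein = prot[1:10], term_id = "GO:2", term_name = "beta"),
    data.frame(protein = prot[21:28], term_id = "GO:3", term_name = "gamma"),
    data.frame(protein = prot[1:7], term_id = "GO:4", term_name = "seven")),
    universe = c(prot, sprintf("X%02d", 1:170)))
  res <- adjust_pvalues(enrich(prot, ann))
  map <- build_functional_map(res, ann, min_proteins = 8, alpha = 0.05)

  # identical memberships -> kappa 1 -> edge; disjoint -> no edge
  expect_true(any(map$edges$term_a == "GO:1" & map$edges$term_b == "GO:2"))
  expect_equal(map$edges$overlap[map$edges$term_a == "GO:1" &
                                 map$edges$term_b == "GO:2"], 1)
  expect_false(any(grepl("GO:3", paste(map$edges$term_a, map$edges$term_b))))

  # k = 7 term excluded by the minimum-protein rule despite significance
  expect_true("GO:4" %in% res$term_id[res$p_adj <= 0.05])
  expect_false("GO:4" %in% map$nodes$term_id)

  # clusters are labelled by their most significant member
  expect_equal(unique(map$nodes$group[map$nodes$term_id %in% c("GO:1", "GO:2")]),
               map$nodes$term_name[which.min(map$nodes$p_adj[1:2])])
})

test_that("the functional map is invariant to the ordering of results", {
  prot <- sprintf("M%02d", 1:30)
  ann <- annotation_set(rbind(
    data.frame(protein = prot[1:12], term_id = "GO:1", term_name = "alpha"),
    data.frame(protein = prot[3:14], term_id = "GO:2", term_name = "beta"),
    data.frame(protein = prot[15:26], term_id = "GO:3", term_name = "gamma")),
    universe = c(prot, sprintf("X%02d", 1:70)))
  res <- adjust_pvalues(enrich(prot, ann))
  shuffled <- res[rev(seq_len(nrow(res))), ]
  attr(shuffled, "member_set") <- attr(res, "member_set")
  m1 <- build_functional_map(res, ann)
  m2 <- build_functional_map(shuffled, ann)
  expect_equal(m1$nodes, m2$nodes)
  expect_equal(m1$edges, m2$edges)
})

test_that("the GAF adapter maps symbol, term, and aspect columns", {
  gaf <- c("!gaf-version: 2.1",
           paste("UniProtKB", "P07900", "HSP90AA1", "", "GO:0006457", "PMID:1",
                 "IDA", "", "P", "", "", "protein", "taxon:9606", "2011", "UniProt",
                 sep = "\t"),
           paste("UniProtKB", "O95433", "AHSA1", "", "GO:0005515", "PMID:2",
                 "IPI", "", "F", "", "", "protein", "taxon:9606", "2011", "UniProt",
                 sep = "\t"))
  f <- withr::local_tempfile(lines = gaf)
  ann <- read_annotations(f, format = "gaf")   # biological_process only
  expect_equal(ann$terms$term_id, "GO:0006457")
  expect_equal(ann$members[["GO:0006457"]], "HSP90AA1")
  both <- read_annotations(f, format = "gaf", namespace = NULL)
  expect_equal(nrow(both$terms), 2L)
})

test_that("the planted term ranks first in nearly all seeded fixtures", {
  wins <- 0L
  for (s in 1:100) {
    b <- generate_fixture(fixture_spec(
      species = c(`9606` = 200), background_edge_p = 0.02, planted_p_in = 0.25,
      query_size = 12, shell_size = 12, human_overlap_fraction = 1,
      n_go_terms = 15, seed = s))
    net <- build_species_network(
      filter_intra_species(filter_physical(b$tables[["9606"]])), 9606)
    members <- extract_query_network(net, b$truth$query)$nodes
    ann <- annotation_set(b$annotations)
    res <- enrich(members, ann)
    if (nrow(res) && res$term_id[1] == b$truth$planted_term) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})
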