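square_diag <- function() {
  # 4-cycle A-B-C-D plus diagonal A-C
  pairs <- rbind(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D"), c("A", "C"))
  df <- data.frame(id_a = pmin(pairs[, 1], pairs[, 2]),
                   id_b = pmax(pairs[, 1], pairs[, 2]),
                   origin = "human", source_dbs = "x", detection_methods = "",
                   pubmed_ids = "", stringsAsFactors = FALSE)
  species_network(9606, nodes = c("A", "B", "C", "D"), edges = df)
}

test_that("measures of the square-plus-diagonal match hand enumeration", {
  m <- compute_measures(square_diag())
  expect_equal(m$n_nodes, 4)
  expect_equal(m$n_edges, 5)
  expect_equal(m$mean_degree, 2.5)
  expect_equal(m$diameter, 2)
  expect_equal(m$index_of_aggregation, 1.0)
  expect_equal(m$connectivity, 5 / 6)
  # local coefficients: A = 2/3, B = 1, C = 2/3, D = 1 -> mean 5/6
  expect_equal(m$clustering_coefficient, 5 / 6)
  expect_equal(m$n_components, 1)

  o <- oracle_measures(c("A", "B", "C", "D"),
                       c("A", "B", "C", "A", "A"), c("B", "C", "D", "D", "C"))
  expect_measures_match(square_diag(), o)
})

test_that("assortativity hits the closed forms and flags degenerate graphs", {
  star <- igraph::make_star(4, mode = "undirected")
  expect_equal(compute_measures(star)$assortativity, -1)

  ring <- igraph::make_ring(4)
  m <- compute_measures(ring)
  expect_true(is.na(m$assortativity))
  expect_false(m$assortativity_defined)
})

test_that("single-node graphs use the degenerate conventions", {
  m <- compute_measures(species_network(9606, nodes = "A"))
  expect_equal(m$diameter, 0)
  expect_equal(m$connectivity, 0)
  expect_false(m$density_defined)
  expect_equal(m$n_components, 1)
})

test_that("degree and clustering histograms bin as documented", {
  tri <- igraph::make_full_graph(3)
  expect_equal(degree_histogram(tri), data.frame(degree = 2L, count = 3L))
  ch <- clustering_histogram(tri)
  expect_equal(ch$count[ch$bin_lo == 0.9], 3L)  # final bin is closed at 1
  expect_equal(sum(ch$count), 3L)

  p3 <- igraph::make_ring(3, circular = FALSE)
  expect_equal(degree_histogram(p3),
               data.frame(degree = c(1L, 2L), count = c(2L, 1L)))
  expect_equal(clustering_histogram(p3)$count[1], 3L)

  empty5 <- species_network(9606, nodes = sprintf("N%d", 1:5))
  expect_equal(degree_histogram(empty5),
               data.frame(degree = 0L, count = 5L))
})

test_that("every measure matches the brute-force oracle on random graphs", {
  set.seed(4002)
  for (i in 1:30) {
    r <- random_small_net()
    o <- oracle_measures(r$nodes, r$ea, r$eb)
    expect_measures_match(r$net, o)
  }
})

test_that("null sampling is deterministic, well-shaped, and exact on complete graphs", {
  base <- igraph::sample_gnp(40, 0.15)
  n1 <- sample_null(base, 5, n_reps = 25, seed = 99)
  n2 <- sample_null(base, 5, n_reps = 25, seed = 99)
  expect_identical(n1, n2)
  expect_false(identical(n1, sample_null(base, 5, n_reps = 25, seed = 100)))
  expect_equal(nrow(n1$samples), 25L)
  expect_equal(vapply(n1$samples, length, integer(1)),
               stats::setNames(rep(25L, 9), names(n1$samples)))

  k20 <- igraph::make_full_graph(20)
  nk <- sample_null(k20, 3, n_reps = 10, seed = 1)
  expect_true(all(nk$samples$index_of_aggregation == 1))
  expect_true(all(nk$samples$connectivity == 1))

  expect_error(sample_null(k20, 25, n_reps = 2, seed = 1), "exceeds")
})

test_that("comparison to the null reports add-one empirical p-values", {
  fake_null <- structure(list(
    n_reps = 300L, query_size = 5L, seed = 1L,
    samples = data.frame(mean_degree = c(rep(4, 150), rep(6, 150)))),
    class = "null_distribution")
  obs_mid <- structure(list(mean_degree = 5), class = "graph_measures")
  obs_out <- structure(list(mean_degree = 50), class = "graph_measures")

  mid <- compare_to_null(obs_mid, fake_null)
  expect_equal(mid$p_empirical, 1)          # everything ties at |x - mu| = 1
  out <- compare_to_null(obs_out, fake_null)
  expect_equal(out$p_empirical, 1 / 301)    # beyond all 300 samples

  small <- structure(list(n_reps = 5L, query_size = 2L, seed = 1L,
                          samples = data.frame(mean_degree = 1:5)),
                     class = "null_distribution")
  expect_warning(compare_to_null(obs_mid, small), "fewer than 20")
})

test_that("a planted dense query machine is detected against the null", {
  spec <- fixture_spec(species = c(`9606` = 500), background_edge_p = 0.005,
                       planted_p_in = 0.5, query_size = 15, shell_size = 15,
                       human_overlap_fraction = 1, seed = 31)
  b <- generate_fixture(spec)
  net <- build_species_network(
    filter_intra_species(filter_physical(b$tables[["9606"]])), 9606)
  ms <- c("mean_degree", "clustering_coefficient")
  obs <- compute_measures(extract_query_network(net, b$truth$query), measures = ms)
  null <- sample_null(net, 15, n_reps = 300, seed = 31, measures = ms)
  cmp <- compare_to_null(obs, null)
  expect_true(all(cmp$observed > cmp$null_mean))
  expect_true(all(cmp$p_empirical <= 0.05))
})
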