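# Independent brute-force oracles and small fixture builders.
# Deliberately written without igraph or any package internals so they can
# arbitrate the production implementations.

# Brute-force graph measures: adjacency matrix, all-pairs BFS for the
# diameter, triple enumeration for clustering, explicit Pearson correlation
# of endpoint degrees for assortativity.
oracle_measures <- function(nodes, ea, eb) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (k in seq_along(ea)) {
    A[ea[k], eb[k]] <- TRUE
    A[eb[k], ea[k]] <- TRUE
  }
  d <- rowSums(A)
  m <- length(ea)

  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    comp[v] <- cid
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(A[u, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  csize <- tabulate(comp)

  big <- which(comp == which.max(csize))
  diam <- 0L
  for (v in big) {
    dist <- rep(NA_integer_, n)
    dist[v] <- 0L
    queue <- v
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(A[u, ] & is.na(dist))
      dist[nb] <- dist[u] + 1L
      queue <- c(queue, nb)
    }
    diam <- max(diam, max(dist[big]))
  }

  cc <- vapply(seq_len(n), function(v) {
    nb <- which(A[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (i in seq_len(k - 1))
      for (j in seq(i + 1, k))
        if (A[nb[i], nb[j]]) links <- links + 1L
    links / choose(k, 2)
  }, numeric(1))

  r <- NA_real_
  if (m > 0) {
    ia <- match(ea, nodes)
    ib <- match(eb, nodes)
    x <- c(d[ia], d[ib])
    y <- c(d[ib], d[ia])
    if (stats::sd(x) > 0) r <- stats::cor(x, y)
  }

  list(n_nodes = n, n_edges = m, mean_degree = 2 * m / n, diameter = diam,
       index_of_aggregation = max(csize) / n,
       connectivity = if (n > 1) 2 * m / (n * (n - 1)) else 0,
       clustering_coefficient = mean(cc), assortativity = r,
       n_components = max(comp))
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# universe of N proteins of which the first K carry the term; count draws
# whose overlap is at least k.
oracle_hyper_p <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(dr) sum(dr <= K) >= k)
  sum(hits) / ncol(draws)
}

# Interaction record builder with sensible defaults.
rec <- function(id_a, id_b, taxid_a = 9606L, taxid_b = taxid_a,
                category = "physical", source_db = "BioGrid",
                detection_method = "", pubmed_ids = "") {
  data.frame(id_a = id_a, id_b = id_b, taxid_a = taxid_a, taxid_b = taxid_b,
             category = category, source_db = source_db,
             detection_method = detection_method, pubmed_ids = pubmed_ids,
             stringsAsFactors = FALSE)
}

# Random simple graph as a species_network plus the raw edge lists the
# oracle consumes.  Node count and density vary with the draw.
random_small_net <- function(max_nodes = 12, taxid = 9606L) {
  n <- sample(2:max_nodes, 1)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < stats::runif(1, 0.15, 0.7)
  ea <- nodes[pairs[1, keep]]
  eb <- nodes[pairs[2, keep]]
  edges <- data.frame(id_a = ea, id_b = eb,
                      origin = rep("human", length(ea)),
                      source_dbs = rep("x", length(ea)),
                      detection_methods = rep("", length(ea)),
                      pubmed_ids = rep("", length(ea)),
                      stringsAsFactors = FALSE)
  net <- species_network(taxid, nodes = nodes, edges = edges)
  list(net = net, nodes = nodes, ea = ea, eb = eb)
}

expect_measures_match <- function(net, oracle, tol = 1e-9) {
  m <- compute_measures(net)
  for (f in c("n_nodes", "n_edges", "mean_degree", "diameter",
              "index_of_aggregation", "connectivity",
              "clustering_coefficient", "n_components")) {
    expect_equal(as.numeric(m[[f]]), as.numeric(oracle[[f]]), tolerance = tol,
                 info = f)
  }
  if (is.na(oracle$assortativity)) {
    expect_false(m$assortativity_defined)
  } else {
    expect_equal(m$assortativity, oracle$assortativity, tolerance = tol,
                 info = "assortativity")
  }
}
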