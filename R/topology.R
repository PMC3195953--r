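MEASURE_NAMES <- c("n_nodes", "n_edges", "mean_degree", "diameter",
                   "index_of_aggregation", "connectivity",
                   "clustering_coefficient", "assortativity", "n_components")

#' Convert a network object to an igraph graph
#' @param net a `species_network`, `merged_network` or `igraph` object
#' @return an undirected simple `igraph` graph with vertex names
#' @export
as_igraph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  if (inherits(net, "species_network")) {
    nodes <- net$nodes
    e <- net$edges
  } else if (inherits(net, "merged_network")) {
    nodes <- net$nodes$id
    e <- net$edges
  } else {
    stop("cannot convert object of class ", paste(class(net), collapse = "/"),
         " to igraph", call. = FALSE)
  }
  igraph::graph_from_data_frame(e[, c("id_a", "id_b")], directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Compute the six topology measures of a network
#'
#' For a loop-free simple graph, reports: node and edge counts, mean degree
#' (2E/V), diameter (longest shortest path within the largest connected
#' component), index of aggregation (largest-component size over V),
#' connectivity (global edge density 2E / V(V-1)), clustering coefficient
#' (mean local clustering, vertices of degree < 2 contributing 0),
#' assortative mixing coefficient (Pearson correlation of endpoint degrees
#' over both orientations of every edge) and number of connected components.
#'
#' Assortativity is undefined — reported as `NA` with
#' `assortativity_defined = FALSE` — when the endpoint degrees have zero
#' variance (e.g. regular graphs).  A single-node graph gets diameter 0 and
#' connectivity 0 by convention (`density_defined = FALSE`).
#'
#' @param net a `species_network`, `merged_network` or `igraph`
#' @param measures optional character vector restricting which measures are
#'   computed (others are `NA`); any of
#'   `r paste(MEASURE_NAMES, collapse = ", ")`
#' @return object of class `graph_measures` (a named list)
#' @export
compute_measures <- function(net, measures = NULL) {
  g <- as_igraph(net)
  want <- if (is.null(measures)) MEASURE_NAMES else match.arg(measures, MEASURE_NAMES,
                                                              several.ok = TRUE)
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  if (nv < 1) stop("compute_measures requires at least one node", call. = FALSE)

  out <- stats::setNames(as.list(rep(NA_real_, length(MEASURE_NAMES))), MEASURE_NAMES)
  out$n_nodes <- nv
  out$n_edges <- ne
  density_defined <- nv > 1
  assortativity_defined <- FALSE

  comp <- NULL
  need_comp <- any(c("diameter", "index_of_aggregation", "n_components") %in% want)
  if (need_comp) comp <- igraph::components(g)

  if ("mean_degree" %in% want) out$mean_degree <- 2 * ne / nv
  if ("connectivity" %in% want)
    out$connectivity <- if (density_defined) 2 * ne / (nv * (nv - 1)) else 0
  if ("n_components" %in% want) out$n_components <- comp$no
  if ("index_of_aggregation" %in% want)
    out$index_of_aggregation <- max(comp$csize) / nv
  if ("diameter" %in% want) {
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    out$diameter <- if (igraph::vcount(sub) == 1) 0
      else igraph::diameter(sub, unconnected = FALSE)
  }
  if ("clustering_coefficient" %in% want)
    out$clustering_coefficient <-
      igraph::transitivity(g, type = "localaverage", isolates = "zero")
  if ("assortativity" %in% want && ne > 0) {
    r <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
    if (is.finite(r)) {
      out$assortativity <- r
      assortativity_defined <- TRUE
    }
  }

  structure(c(out, list(assortativity_defined = assortativity_defined,
                        density_defined = density_defined)),
            class = "graph_measures")
}

#' @export
print.graph_measures <- function(x, ...) {
  cat("<graph_measures>\n")
  for (m in MEASURE_NAMES)
    cat(sprintf("  %-24s %s\n", m,
                if (is.na(x[[m]])) "NA" else format(x[[m]], digits = 6)))
  invisible(x)
}

#' @export
as.data.frame.graph_measures <- function(x, ...) {
  data.frame(measure = MEASURE_NAMES,
             value = vapply(MEASURE_NAMES, function(m) as.numeric(x[[m]]), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Node degree histogram
#' @param net network object or igraph
#' @return data.frame `degree`, `count` over the observed degrees
#' @export
degree_histogram <- function(net) {
  g <- as_igraph(net)
  d <- igraph::degree(g)
  tab <- table(d)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab),
             row.names = NULL)
}

#' Local clustering coefficient histogram
#'
#' Bins the per-node local clustering coefficients (degree < 2 counted as 0)
#' over \[0, 1\] in fixed-width bins, left-closed right-open except the final
#' bin which is closed.
#' @param net network object or igraph
#' @param bin_width bin width (default 0.1)
#' @return data.frame `bin_lo`, `bin_hi`, `count`
#' @export
clustering_histogram <- function(net, bin_width = 0.1) {
  g <- as_igraph(net)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  lo <- seq(0, 1 - bin_width, by = bin_width)
  hi <- lo + bin_width
  idx <- pmin(floor(cc / bin_width) + 1L, length(lo))
  data.frame(bin_lo = lo, bin_hi = hi,
             count = as.integer(tabulate(idx, nbins = length(lo))))
}

#' Sample the random-query null distribution
#'
#' Draws `n_reps` random query sets of size `query_size` uniformly without
#' replacement from the base network's nodes, extracts each query-centred
#' subnetwork (first neighbours, induced subgraph) and computes the graph
#' measures — the null model against which the real query network is judged.
#' Replicate r uses a deterministic RNG stream derived from `(seed, r)`, so
#' the distribution is a pure function of (base network, query_size, n_reps,
#' seed).
#'
#' @param base_net base network (`species_network`, `merged_network` or
#'   igraph)
#' @param query_size number of query nodes per replicate (the real query
#'   list's length in the study design)
#' @param n_reps number of replicates (default 300)
#' @param seed integer seed (mandatory)
#' @param measures optional restriction passed to [compute_measures()]
#' @return object of class `null_distribution`: list with `n_reps`,
#'   `query_size`, `seed`, `samples` (data.frame, one row per replicate),
#'   `means`, `sds` and `n_excluded` (undefined-assortativity replicates)
#' @export
sample_null <- function(base_net, query_size, n_reps = 300, seed, measures = NULL) {
  stopifnot(n_reps >= 1)
  if (missing(seed)) stop("sample_null requires an explicit seed", call. = FALSE)
  g <- as_igraph(base_net)
  nv <- igraph::vcount(g)
  if (query_size > nv)
    stop(sprintf("query_size (%d) exceeds base network size (%d)", query_size, nv),
         call. = FALSE)
  adj <- igraph::as_adj_list(g)

  want <- if (is.null(measures)) MEASURE_NAMES else measures
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, paste0("null-replicate-", r)))
    q <- sample.int(nv, query_size)
    s <- unique(c(q, unlist(adj[q], use.names = FALSE)))
    sub <- igraph::induced_subgraph(g, s)
    m <- compute_measures(sub, measures = measures)
    rows[[r]] <- vapply(MEASURE_NAMES, function(nm) as.numeric(m[[nm]]), numeric(1))
  }
  samples <- as.data.frame(do.call(rbind, rows))
  names(samples) <- MEASURE_NAMES
  samples <- samples[, intersect(MEASURE_NAMES, want), drop = FALSE]

  structure(list(
    n_reps = as.integer(n_reps), query_size = as.integer(query_size),
    seed = as.integer(seed), samples = samples,
    means = vapply(samples, function(x) mean(x, na.rm = TRUE), numeric(1)),
    sds = vapply(samples, function(x) stats::sd(x, na.rm = TRUE), numeric(1)),
    n_excluded = vapply(samples, function(x) sum(is.na(x)), integer(1))
  ), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d replicates, query_size %d, seed %d\n",
              x$n_reps, x$query_size, x$seed))
  print(round(rbind(mean = x$means, sd = x$sds), 4))
  invisible(x)
}

#' Compare observed measures to the random-query null
#'
#' For each measure reports the null mean and standard deviation, the
#' z-score, and an add-one empirical two-sided p-value:
#' p = (1 + #\{replicates at least as far from the null mean as the
#' observation\}) / (n_valid + 1).  Replicates with an undefined measure
#' (assortativity on degree-regular draws) are excluded; their count is
#' reported.
#'
#' @param obs a `graph_measures` object (the real query network)
#' @param null a `null_distribution` from [sample_null()]
#' @return data.frame `measure`, `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_empirical`, `n_excluded`
#' @export
compare_to_null <- function(obs, null) {
  if (null$n_reps < 20)
    warning("fewer than 20 null replicates; empirical p-values are coarse",
            call. = FALSE)
  ms <- names(null$samples)
  rows <- lapply(ms, function(m) {
    x <- null$samples[[m]]
    valid <- x[!is.na(x)]
    o <- as.numeric(obs[[m]])
    mu <- mean(valid)
    s <- stats::sd(valid)
    z <- if (!is.na(o) && !is.na(s) && s > 0) (o - mu) / s else NA_real_
    p <- if (!is.na(o) && length(valid) > 0)
      (1 + sum(abs(valid - mu) >= abs(o - mu))) / (length(valid) + 1)
    else NA_real_
    data.frame(measure = m, observed = o, null_mean = mu, null_sd = s,
               z = z, p_empirical = p, n_excluded = sum(is.na(x)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
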