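#' Construct an annotation set
#'
#' Flat GO annotations: a table of term metadata plus per-term protein
#' membership, together with the background universe used for enrichment.
#' Parent–child propagation is not performed here; supply pre-propagated
#' annotations if the ontology hierarchy should count.
#'
#' @param annotations data.frame with columns `protein`, `term_id`,
#'   `term_name` and optionally `namespace`
#' @param universe background protein set; defaults to all annotated
#'   proteins.  Every annotated protein outside the universe is ignored.
#' @param namespace keep only terms of this GO namespace (`NULL` keeps all);
#'   default `"biological_process"` when a namespace column is present
#' @return object of class `annotation_set`: list with `terms` (data.frame
#'   `term_id`, `term_name`, `namespace`), `members` (named list term_id ->
#'   proteins) and `universe`
#' @export
annotation_set <- function(annotations, universe = NULL,
                           namespace = "biological_process") {
  ann <- annotations
  if (!"namespace" %in% names(ann))
    ann$namespace <- rep("biological_process", nrow(ann))
  if (!is.null(namespace) && "namespace" %in% names(annotations))
    ann <- ann[ann$namespace %in% namespace, , drop = FALSE]
  universe <- sort_c(unique(as.character(universe %||% ann$protein)))
  ann <- ann[ann$protein %in% universe, , drop = FALSE]

  ann <- unique(ann[, c("protein", "term_id", "term_name", "namespace")])
  members <- lapply(split(ann$protein, ann$term_id), function(p) sort_c(unique(p)))
  meta <- unique(ann[, c("term_id", "term_name", "namespace")])
  meta <- meta[!duplicated(meta$term_id), , drop = FALSE]
  meta <- meta[order(meta$term_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(terms = meta, members = members, universe = universe),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d terms over a universe of %d proteins\n",
              nrow(x$terms), length(x$universe)))
  invisible(x)
}

#' Read annotations from a TSV or GAF file
#'
#' The simple dialect is a 3-column tab-separated file `protein`, `term_id`,
#' `term_name` (optional 4th column `namespace`), with or without that
#' header.  The GAF 2.x adapter maps column 3 (DB object symbol), column 5
#' (GO id) and column 9 (aspect: P/F/C, translated to the namespace names);
#' GAF carries no term names, so `term_name` falls back to the term id.
#'
#' @param file path
#' @param format `"tsv"` or `"gaf"`
#' @param universe,namespace passed to [annotation_set()]
#' @return an `annotation_set`
#' @export
read_annotations <- function(file, format = c("tsv", "gaf"), universe = NULL,
                             namespace = "biological_process") {
  format <- match.arg(format)
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^!|^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    if (length(parts) && identical(tolower(parts[[1]][1]), "protein"))
      parts <- parts[-1]
    ann <- data.frame(
      protein = vapply(parts, `[[`, character(1), 1),
      term_id = vapply(parts, `[[`, character(1), 2),
      term_name = vapply(parts, function(p) if (length(p) >= 3) p[[3]] else p[[2]],
                         character(1)),
      namespace = vapply(parts, function(p) if (length(p) >= 4) p[[4]]
                         else "biological_process", character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    aspect_map <- c(P = "biological_process", F = "molecular_function",
                    C = "cellular_component")
    ok <- lengths(parts) >= 9
    parts <- parts[ok]
    ann <- data.frame(
      protein = vapply(parts, `[[`, character(1), 3),
      term_id = vapply(parts, `[[`, character(1), 5),
      term_name = vapply(parts, `[[`, character(1), 5),
      namespace = unname(aspect_map[vapply(parts, `[[`, character(1), 9)]),
      stringsAsFactors = FALSE
    )
    ann <- ann[!is.na(ann$namespace), , drop = FALSE]
  }
  annotation_set(ann, universe = universe, namespace = namespace)
}

#' GO term over-representation by the hypergeometric test
#'
#' For every annotated term with at least one member in `member_set`,
#' computes the upper-tail hypergeometric probability of drawing k or more
#' annotated proteins when n proteins are sampled from a universe of N
#' containing K annotated ones.  Proteins outside the universe are dropped
#' (count in attribute `n_outside_universe`).
#'
#' @param member_set protein symbols (e.g. the merged network's members)
#' @param ann an `annotation_set`
#' @return data.frame of class `enrichment_result` sorted by p ascending:
#'   `term_id`, `term_name`, `k` (overlap), `n` (member-set size in
#'   universe), `K` (annotated in universe), `N` (universe size), `p`;
#'   attribute `member_set` carries the in-universe members
#' @export
enrich <- function(member_set, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  N <- length(ann$universe)
  if (N == 0) stop("annotation universe is empty", call. = FALSE)
  member_set <- unique(as.character(member_set))
  inside <- intersect(member_set, ann$universe)
  n_outside <- length(member_set) - length(inside)
  n <- length(inside)

  term_ids <- names(ann$members) %||% character(0)
  k <- vapply(ann$members, function(m) length(intersect(m, inside)), integer(1))
  K <- lengths(ann$members)
  keep <- which(k >= 1)
  p <- stats::phyper(k[keep] - 1, K[keep], N - K[keep], n, lower.tail = FALSE)

  out <- data.frame(
    term_id = term_ids[keep],
    term_name = ann$terms$term_name[match(term_ids[keep], ann$terms$term_id)],
    k = k[keep], n = rep(n, length(keep)), K = K[keep],
    N = rep(N, length(keep)), p = p,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "member_set") <- sort_c(inside)
  attr(out, "n_outside_universe") <- n_outside
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Adjust enrichment p-values for multiple testing
#' @param results an `enrichment_result` data.frame from [enrich()]
#' @param method `"benjamini-hochberg"` (default) or `"bonferroni"`
#' @return `results` with a `p_adj` column appended
#' @export
adjust_pvalues <- function(results, method = c("benjamini-hochberg", "bonferroni")) {
  method <- match.arg(method)
  results$p_adj <- stats::p.adjust(results$p,
                                   method = c(`benjamini-hochberg` = "BH",
                                              bonferroni = "bonferroni")[[method]])
  results
}

# Cohen's kappa between two binary membership vectors of length N.
# Degenerate agreement (expected agreement 1) maps to 1 for identical
# vectors and 0 otherwise.
membership_kappa <- function(x, y) {
  n <- length(x)
  a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y); d <- sum(!x & !y)
  po <- (a + d) / n
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

membership_jaccard <- function(x, y) {
  u <- sum(x | y)
  if (u == 0) 0 else sum(x & y) / u
}

#' Build the functional map of enriched terms
#'
#' Keeps significantly over-represented terms with a minimum number of
#' contributing proteins from the member set, then connects term pairs whose
#' memberships (binary vectors over the member set) agree beyond
#' `overlap_threshold` under the chosen statistic.  Connected clusters of
#' terms receive a group label: the name of the cluster's most significant
#' term.
#'
#' @param results `enrichment_result` with `p_adj` (see [adjust_pvalues()])
#' @param ann the `annotation_set` used for enrichment
#' @param min_proteins minimum overlap k for a term to enter the map
#'   (default 8)
#' @param alpha adjusted-p cutoff (default 0.05)
#' @param overlap_stat `"kappa"` (Cohen's kappa, default) or `"jaccard"`
#' @param overlap_threshold minimum overlap statistic for a term–term edge
#'   (default 0.4)
#' @return object of class `functional_map`: list with `nodes` (`term_id`,
#'   `term_name`, `k`, `p_adj`, `group`) and `edges` (`term_a`, `term_b`,
#'   `overlap`)
#' @export
build_functional_map <- function(results, ann, min_proteins = 8, alpha = 0.05,
                                 overlap_stat = c("kappa", "jaccard"),
                                 overlap_threshold = 0.4) {
  overlap_stat <- match.arg(overlap_stat)
  if (!"p_adj" %in% names(results))
    stop("results must carry p_adj; run adjust_pvalues() first", call. = FALSE)
  member_set <- attr(results, "member_set")
  if (is.null(member_set))
    stop("results lack the member_set attribute produced by enrich()", call. = FALSE)

  keep <- results[results$p_adj <= alpha & results$k >= min_proteins, , drop = FALSE]
  keep <- keep[order(keep$term_id), , drop = FALSE]
  rownames(keep) <- NULL

  stat_fun <- switch(overlap_stat, kappa = membership_kappa,
                     jaccard = membership_jaccard)
  nt <- nrow(keep)
  memb <- lapply(keep$term_id, function(tid) member_set %in% ann$members[[tid]])
  edges <- if (nt >= 2) {
    pairs <- utils::combn(nt, 2)
    ov <- apply(pairs, 2, function(ij) stat_fun(memb[[ij[1]]], memb[[ij[2]]]))
    hit <- ov >= overlap_threshold
    data.frame(term_a = keep$term_id[pairs[1, hit]],
               term_b = keep$term_id[pairs[2, hit]],
               overlap = ov[hit], stringsAsFactors = FALSE)
  } else {
    data.frame(term_a = character(0), term_b = character(0),
               overlap = numeric(0), stringsAsFactors = FALSE)
  }

  group <- rep(NA_character_, nt)
  if (nt > 0) {
    g <- igraph::graph_from_data_frame(edges[, c("term_a", "term_b")],
                                       directed = FALSE,
                                       vertices = data.frame(name = keep$term_id))
    comp <- igraph::components(g)$membership
    for (cl in unique(comp)) {
      ids <- names(comp)[comp == cl]
      sub <- keep[keep$term_id %in% ids, , drop = FALSE]
      group[keep$term_id %in% ids] <-
        sub$term_name[order(sub$p_adj, sub$term_id)][1]
    }
  }

  structure(list(
    nodes = data.frame(term_id = keep$term_id, term_name = keep$term_name,
                       k = keep$k, p_adj = keep$p_adj, group = group,
                       stringsAsFactors = FALSE),
    edges = edges
  ), class = "functional_map")
}

#' @export
print.functional_map <- function(x, ...) {
  cat(sprintf("<functional_map> %d terms, %d shared-protein edges, %d group(s)\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(stats::na.omit(x$nodes$group)))))
  invisible(x)
}

#' Write a functional map as SIF plus node/edge attribute tables
#' @param map a `functional_map`
#' @param prefix output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`
#' @export
write_functional_map <- function(map, prefix) {
  writeLines(if (nrow(map$edges))
    paste(map$edges$term_a, "shares", map$edges$term_b, sep = "\t")
    else character(0), paste0(prefix, ".sif"))
  utils::write.table(map$nodes, paste0(prefix, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(map$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
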