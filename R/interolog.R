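#' Parse an ortholog-group flat file
#'
#' Reads a HomoloGene-style flat file: six tab-separated columns with no
#' header — group id, taxon id, gene id, gene symbol, protein GI, protein
#' accession.  All genes sharing a group id are orthologs; the group is the
#' join key that lets a non-human interaction be projected onto the human
#' members of the same group.
#'
#' @param file path (or character vector of lines)
#' @return object of class `ortholog_map`: list with `groups` (data.frame
#'   `group_id`, `taxid`, `gene_id`, `symbol`) and derived per-group human
#'   symbol sets
#' @details Malformed rows are skipped with a warning.  A gene (same taxon
#'   and gene id, or same taxon and symbol) assigned to two different groups
#'   violates the one-group-per-gene contract and raises an error.
#' @export
parse_homologene <- function(file) {
  lines <- if (length(file) == 1 && !grepl("\t|\n", file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 4 && !is.na(suppressWarnings(as.integer(p[[1]]))) &&
      !is.na(suppressWarnings(as.integer(p[[2]]))) && nzchar(p[[3]]) && nzchar(p[[4]])
  }, logical(1))
  if (any(!ok))
    warning(sprintf("skipped %d malformed ortholog row(s)", sum(!ok)), call. = FALSE)
  parts <- parts[ok]
  groups <- data.frame(
    group_id = vapply(parts, function(p) as.integer(p[[1]]), integer(1)),
    taxid = vapply(parts, function(p) as.integer(p[[2]]), integer(1)),
    gene_id = vapply(parts, function(p) p[[3]], character(1)),
    symbol = vapply(parts, function(p) p[[4]], character(1)),
    stringsAsFactors = FALSE
  )
  groups <- unique(groups)

  for (keycol in c("gene_id", "symbol")) {
    key <- paste(groups$taxid, groups[[keycol]], sep = "\r")
    ngrp <- tapply(groups$group_id, key, function(g) length(unique(g)))
    if (any(ngrp > 1)) {
      offender <- names(ngrp)[which(ngrp > 1)[1]]
      stop(sprintf("gene (%s) by %s is assigned to %d different ortholog groups",
                   sub("\r", ", ", offender), keycol, max(ngrp)), call. = FALSE)
    }
  }
  ortholog_map(groups)
}

#' Construct an ortholog_map from a group table
#' @param groups data.frame with columns `group_id`, `taxid`, `gene_id`,
#'   `symbol`
#' @return `ortholog_map` object
#' @export
ortholog_map <- function(groups) {
  groups <- unique(groups[, c("group_id", "taxid", "gene_id", "symbol")])
  hum <- groups[groups$taxid == 9606L, , drop = FALSE]
  human_by_group <- split(unique(hum[, c("group_id", "symbol")])$symbol,
                          unique(hum[, c("group_id", "symbol")])$group_id)
  structure(list(groups = groups, human_by_group = human_by_group),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("<ortholog_map> %d genes in %d groups (%d taxa, %d groups with a human member)\n",
              nrow(x$groups), length(unique(x$groups$group_id)),
              length(unique(x$groups$taxid)), length(x$human_by_group)))
  invisible(x)
}

#' Human orthologs of a set of genes
#'
#' @param map an `ortholog_map`
#' @param taxid taxon the query genes belong to
#' @param keys gene identifiers (symbols or gene ids, see `by`)
#' @param by which column anchors the join: `"symbol"` or `"gene_id"`
#' @return list (one element per key) of character vectors of human symbols;
#'   empty when the gene is unmapped or its group has no human member
#' @export
human_of <- function(map, taxid, keys, by = c("symbol", "gene_id")) {
  by <- match.arg(by)
  g <- map$groups[map$groups$taxid == as.integer(taxid), , drop = FALSE]
  grp <- g$group_id[match(keys, g[[by]])]
  out <- lapply(grp, function(gid) {
    if (is.na(gid)) character(0)
    else map$human_by_group[[as.character(gid)]] %||% character(0)
  })
  names(out) <- keys
  out
}

#' Species orthologs of human symbols
#'
#' Inverse direction of [human_of()]: used to translate a human query list
#' into each species' own identifiers before query extraction.
#' @param map an `ortholog_map`
#' @param symbols human gene symbols
#' @param taxid target taxon
#' @param by which species column to return: `"symbol"` or `"gene_id"`
#' @return character vector of species gene identifiers (union over symbols)
#' @export
orthologs_of <- function(map, symbols, taxid, by = c("symbol", "gene_id")) {
  by <- match.arg(by)
  hum <- map$groups[map$groups$taxid == 9606L & map$groups$symbol %in% symbols, , drop = FALSE]
  sp <- map$groups[map$groups$taxid == as.integer(taxid) &
                     map$groups$group_id %in% hum$group_id, , drop = FALSE]
  sort_c(unique(sp[[by]]))
}

#' Project a species network onto human genes (interologs)
#'
#' Every edge (a, b) becomes the cross product of the human orthologs of a
#' and of b; the projected network is a hypothesis set of human interactions
#' supported by conservation.  Edges with an endpoint lacking a human
#' ortholog are dropped (count in attribute `n_dropped_unmapped`); projected
#' pairs that collapse onto a single human gene (two paralogs in one group)
#' are dropped as self-pairs (attribute `n_dropped_self`).  Each retained
#' edge carries the origin tag `interolog:<source taxid>` and inherits the
#' source edge's provenance.
#'
#' @param net a non-human `species_network`
#' @param map an `ortholog_map`
#' @param by join key anchoring the species ids in `map` (`"symbol"` or
#'   `"gene_id"`)
#' @return a `species_network` in the human namespace (taxid 9606), tagged
#'   with the source taxon in attribute `source_taxid`
#' @export
project_interologs <- function(net, map, by = c("symbol", "gene_id")) {
  by <- match.arg(by)
  stopifnot(inherits(net, "species_network"))
  if (net$taxid == 9606L)
    stop("project_interologs expects a non-human network", call. = FALSE)
  tag <- paste0("interolog:", net$taxid)

  e <- net$edges
  hu <- human_of(map, net$taxid, unique(c(e$id_a, e$id_b)), by = by)
  ha <- hu[e$id_a]
  hb <- hu[e$id_b]
  la <- lengths(ha)
  lb <- lengths(hb)
  unmapped <- la == 0 | lb == 0
  n_unmapped <- sum(unmapped)

  keep <- which(!unmapped)
  reps <- la[keep] * lb[keep]
  idx <- rep(keep, reps)
  id_a <- unlist(mapply(function(i, k) rep(ha[[i]], each = k), keep, lb[keep],
                        SIMPLIFY = FALSE), use.names = FALSE)
  id_b <- unlist(mapply(function(i, k) rep(hb[[i]], times = k), keep, la[keep],
                        SIMPLIFY = FALSE), use.names = FALSE)
  self <- id_a == id_b
  n_self <- sum(self)

  raw <- data.frame(
    id_a = id_a[!self], id_b = id_b[!self],
    origin = rep(tag, sum(!self)),
    source_dbs = e$source_dbs[idx][!self],
    detection_methods = e$detection_methods[idx][!self],
    pubmed_ids = e$pubmed_ids[idx][!self],
    stringsAsFactors = FALSE
  )
  edges <- collapse_edges(raw)
  out <- species_network(taxid = 9606L,
                         nodes = sort_c(unique(c(edges$id_a, edges$id_b))),
                         edges = edges)
  attr(out, "source_taxid") <- net$taxid
  attr(out, "n_dropped_unmapped") <- n_unmapped
  attr(out, "n_dropped_self") <- n_self
  out
}

#' Remove interologs already described in human
#'
#' Intersecting the projected network with the experimentally determined
#' human network would double-count known interactions; this keeps only the
#' novel, predicted edges.
#'
#' @param interolog_net projected `species_network` (human namespace)
#' @param human_net the human `species_network` (full cleaned network)
#' @param keep_nodes node identifiers retained even if left without edges
#'   (typically the projected query proteins)
#' @return `species_network` with the known edges removed; the node set is
#'   pruned to edge endpoints plus `keep_nodes`
#' @export
subtract_known <- function(interolog_net, human_net, keep_nodes = character(0)) {
  known <- canonical_pair(human_net$edges$id_a, human_net$edges$id_b)$key
  e <- interolog_net$edges
  key <- canonical_pair(e$id_a, e$id_b)$key
  kept <- e[!(key %in% known), , drop = FALSE]
  rownames(kept) <- NULL
  out <- species_network(
    taxid = interolog_net$taxid,
    nodes = sort_c(unique(c(kept$id_a, kept$id_b, keep_nodes))),
    edges = kept
  )
  attr(out, "source_taxid") <- attr(interolog_net, "source_taxid")
  attr(out, "n_removed_known") <- nrow(e) - nrow(kept)
  out
}
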