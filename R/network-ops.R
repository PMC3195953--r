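#' Extract the query-centred subnetwork
#'
#' Selects the query proteins present in the network together with all of
#' their first neighbours, and returns the subgraph induced on that node set
#' — i.e. first-level (query–neighbour) interactions plus all second-level
#' (neighbour–neighbour) interactions.
#'
#' @param net a `species_network`
#' @param query_ids character vector of query node identifiers; ids absent
#'   from the network are ignored and reported in attribute
#'   `unmatched_queries`
#' @return a `species_network` induced on the query set and its first
#'   neighbours, with attribute `query_ids` (the matched queries)
#' @examples
#' rec <- data.frame(id_a = c("Q", "A", "Q", "C"), id_b = c("A", "B", "C", "D"),
#'                   taxid_a = 9606, taxid_b = 9606, category = "physical",
#'                   source_db = "x", detection_method = "", pubmed_ids = "")
#' net <- build_species_network(rec, 9606)
#' extract_query_network(net, "Q")   # keeps Q, A, C; B and D are 2nd shell
#' @export
extract_query_network <- function(net, query_ids) {
  query_ids <- unique(as.character(query_ids))
  matched <- intersect(query_ids, net$nodes)
  unmatched <- setdiff(query_ids, matched)

  e <- net$edges
  touch_a <- e$id_a %in% matched
  touch_b <- e$id_b %in% matched
  neighbours <- unique(c(e$id_b[touch_a], e$id_a[touch_b]))
  keep_nodes <- unique(c(matched, neighbours))

  in_set_a <- e$id_a %in% keep_nodes
  in_set_b <- e$id_b %in% keep_nodes
  kept <- e[in_set_a & in_set_b, , drop = FALSE]
  rownames(kept) <- NULL

  selfs <- net$self_interactions
  selfs <- selfs[selfs$id %in% keep_nodes, , drop = FALSE]

  out <- species_network(taxid = net$taxid, nodes = sort_c(keep_nodes),
                         edges = kept, self_interactions = selfs)
  attr(out, "query_ids") <- sort_c(matched)
  attr(out, "unmatched_queries") <- sort_c(unmatched)
  out
}

#' Merge query networks into one human-projected interactome
#'
#' Takes the human query network and the projected (and human-subtracted)
#' interolog networks, and unions them: node sets and edge sets merge under
#' the canonical pair key, with origin sets and provenance union-merged.
#' When the same edge arrives with both a `human` and an `interolog:<taxid>`
#' origin, the origins are kept side by side rather than conflicting.
#'
#' @param nets list of `species_network` objects in the human namespace
#' @param query_ids human-namespace query identifiers used to flag query
#'   nodes
#' @return object of class `merged_network`: list with `nodes` (data.frame
#'   `id`, `is_query`) and `edges` (canonical table with `;`-joined `origin`
#'   sets and provenance)
#' @export
merge_networks <- function(nets, query_ids = character(0)) {
  stopifnot(length(nets) >= 1)
  all_edges <- do.call(rbind, lapply(nets, function(n) n$edges))
  edges <- collapse_edges(all_edges)
  node_ids <- sort_c(unique(c(unlist(lapply(nets, function(n) n$nodes),
                                   use.names = FALSE),
                            edges$id_a, edges$id_b)))
  merged_network(
    nodes = data.frame(id = node_ids,
                       is_query = node_ids %in% as.character(query_ids),
                       stringsAsFactors = FALSE),
    edges = edges
  )
}

#' Construct a merged_network object
#' @param nodes data.frame with columns `id`, `is_query`
#' @param edges canonical edge table; every edge must carry a non-empty
#'   origin set
#' @return `merged_network` object
#' @export
merged_network <- function(nodes, edges = empty_edges()) {
  if (nrow(edges) > 0) {
    stopifnot(all(nzchar(edges$origin)),
              all(c(edges$id_a, edges$id_b) %in% nodes$id))
  }
  structure(list(nodes = nodes, edges = edges), class = "merged_network")
}

#' @export
print.merged_network <- function(x, ...) {
  n_int <- sum(grepl("interolog:", x$edges$origin, fixed = TRUE))
  cat(sprintf(
    "<merged_network> %d nodes (%d query), %d edges (%d with interolog support)\n",
    nrow(x$nodes), sum(x$nodes$is_query), nrow(x$edges), n_int))
  invisible(x)
}

# ---- XGMML export / import ---------------------------------------------

#' Write a network as XGMML (Cytoscape-importable)
#'
#' Nodes carry the boolean attribute `is_query`; edges carry `origin`,
#' `source_dbs` and `pubmed_ids`.  Layout coordinates are not written.
#'
#' @param net a `merged_network` (a `species_network` is promoted with all
#'   query flags false)
#' @param file output path
#' @param label graph label attribute
#' @export
write_xgmml <- function(net, file, label = "orthonet") {
  if (inherits(net, "species_network")) {
    net <- merged_network(
      nodes = data.frame(id = net$nodes, is_query = FALSE, stringsAsFactors = FALSE),
      edges = net$edges
    )
  }
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  n <- net$nodes
  e <- net$edges
  node_xml <- sprintf(
    '  <node id="%s" label="%s">\n    <att name="is_query" type="boolean" value="%s"/>\n  </node>',
    esc(n$id), esc(n$id), ifelse(n$is_query, "true", "false"))
  edge_xml <- if (nrow(e)) sprintf(paste0(
    '  <edge source="%s" target="%s" label="%s (pp) %s">\n',
    '    <att name="origin" type="string" value="%s"/>\n',
    '    <att name="source_dbs" type="string" value="%s"/>\n',
    '    <att name="pubmed_ids" type="string" value="%s"/>\n  </edge>'),
    esc(e$id_a), esc(e$id_b), esc(e$id_a), esc(e$id_b),
    esc(e$origin), esc(e$source_dbs), esc(e$pubmed_ids)) else character(0)
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    sprintf('<graph label="%s" directed="0" xmlns="http://www.cs.rpi.edu/XGMML">',
            esc(label)),
    node_xml, edge_xml, "</graph>"), file)
  invisible(file)
}

#' Read an XGMML network file
#'
#' Tolerant reader for Cytoscape-style XGMML: accepts attribute-bearing
#' nodes and edges, resolves node references either by `id` or `label`, and
#' ignores `<graphics>` layout elements and unknown attributes.  Parallel
#' edges collapse onto the canonical undirected pair.
#'
#' @param file path to an XGMML file
#' @return a `merged_network`; missing `is_query`/`origin` attributes
#'   default to `FALSE` / `"human"`
#' @export
read_xgmml <- function(file) {
  doc <- xml2::read_xml(file)
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  node_id <- xml2::xml_attr(nodes, "id")
  node_label <- xml2::xml_attr(nodes, "label")
  name <- ifelse(is.na(node_label) | !nzchar(node_label), node_id, node_label)

  get_att <- function(els, att) {
    vapply(els, function(el) {
      hit <- xml2::xml_find_first(
        el, sprintf(".//*[local-name()='att'][@name='%s']", att))
      if (inherits(hit, "xml_missing")) NA_character_
      else xml2::xml_attr(hit, "value")
    }, character(1))
  }
  is_query <- tolower(get_att(nodes, "is_query")) %in% "true"

  edges <- xml2::xml_find_all(doc, ".//*[local-name()='edge']")
  src <- xml2::xml_attr(edges, "source")
  tgt <- xml2::xml_attr(edges, "target")
  to_name <- function(x) {
    hit <- match(x, node_id)
    ifelse(!is.na(hit), name[hit], x)
  }
  origin <- get_att(edges, "origin")
  src_dbs <- get_att(edges, "source_dbs")
  pmids <- get_att(edges, "pubmed_ids")

  raw <- data.frame(
    id_a = to_name(src), id_b = to_name(tgt),
    origin = ifelse(is.na(origin) | !nzchar(origin), "human", origin),
    source_dbs = ifelse(is.na(src_dbs), "", src_dbs),
    detection_methods = "",
    pubmed_ids = ifelse(is.na(pmids), "", pmids),
    stringsAsFactors = FALSE
  )
  raw <- raw[raw$id_a != raw$id_b, , drop = FALSE]   # loop-free contract
  etab <- collapse_edges(raw)
  node_df <- data.frame(id = name, is_query = is_query, stringsAsFactors = FALSE)
  node_df <- node_df[!duplicated(node_df$id), , drop = FALSE]
  extra <- setdiff(c(etab$id_a, etab$id_b), node_df$id)
  if (length(extra))
    node_df <- rbind(node_df, data.frame(id = extra, is_query = FALSE,
                                         stringsAsFactors = FALSE))
  node_df <- node_df[order(node_df$id), , drop = FALSE]
  rownames(node_df) <- NULL
  merged_network(nodes = node_df, edges = etab)
}

#' Write the merged network's canonical edge table
#' @param net a `merged_network`
#' @param file output path
#' @export
write_merged_edge_table <- function(net, file) {
  utils::write.table(net$edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
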