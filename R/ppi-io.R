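#' Parse a tab-delimited interaction table
#'
#' Reads one database/literature dump into a flat table of interaction
#' records.  The canonical dialect is an 8-column tab-delimited file with a
#' header naming the columns `id_a`, `id_b`, `taxid_a`, `taxid_b`,
#' `category`, `source_db`, `detection_method`, `pubmed_ids`; lines starting
#' with `#` are ignored.  Non-canonical layouts are handled by `column_map`,
#' a named integer vector giving the 1-based position of each canonical
#' column (then no header is assumed unless `header = TRUE`).
#'
#' Malformed rows — missing either identifier, a non-numeric taxon id, or a
#' category other than `physical`/`genetic` — are skipped with a single
#' summary warning; the skip count is attached as attribute `n_skipped`.
#'
#' @param file path to the table (or a character vector of lines)
#' @param column_map optional named integer vector with names among the
#'   canonical column names; required names: `id_a`, `id_b`, `taxid_a`,
#'   `taxid_b`, `category`, `source_db`
#' @param header does the file carry a header row? Defaults to `TRUE` when
#'   `column_map` is `NULL`, otherwise `FALSE`.
#' @return data.frame of interaction records with the 8 canonical columns;
#'   `pubmed_ids` and `detection_method` are `;`-joined strings (empty when
#'   absent).  Attribute `n_skipped` counts malformed rows.
#' @examples
#' tab <- c("id_a\tid_b\ttaxid_a\ttaxid_b\tcategory\tsource_db\tdetection_method\tpubmed_ids",
#'          "HSP90AA1\tAHSA1\t9606\t9606\tphysical\tBioGrid\t\t15937123")
#' parse_interactions(tab)
#' @export
parse_interactions <- function(file, column_map = NULL, header = is.null(column_map)) {
  required <- c("id_a", "id_b", "taxid_a", "taxid_b", "category", "source_db")
  optional <- c("detection_method", "pubmed_ids")
  canon <- c(required, optional)

  lines <- if (length(file) == 1 && !grepl("\t|\n", file)) {
    if (!file.exists(file)) stop("cannot read interaction table: ", file, call. = FALSE)
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]

  if (is.null(column_map)) {
    if (length(lines) == 0) stop("interaction table is empty (no header row)", call. = FALSE)
    hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
    missing_cols <- setdiff(required, hdr)
    if (length(missing_cols))
      stop("interaction table is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    column_map <- stats::setNames(match(canon, hdr), canon)
    lines <- lines[-1]
  } else {
    column_map <- column_map[names(column_map) %in% canon]
    missing_cols <- setdiff(required, names(column_map))
    if (length(missing_cols))
      stop("column_map is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    if (header && length(lines)) lines <- lines[-1]
  }

  if (length(lines) == 0) {
    out <- interaction_records()
    attr(out, "n_skipped") <- 0L
    return(out)
  }

  parts <- strsplit(lines, "\t", fixed = TRUE)
  get_col <- function(i) {
    if (is.na(i)) return(rep("", length(parts)))
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_, character(1))
  }
  cmap <- as.list(column_map)
  cols <- lapply(canon, function(nm) get_col(cmap[[nm]] %||% NA_integer_))
  names(cols) <- canon

  taxid_a <- suppressWarnings(as.integer(cols$taxid_a))
  taxid_b <- suppressWarnings(as.integer(cols$taxid_b))
  category <- tolower(trimws(cols$category))
  bad <- is.na(cols$id_a) | is.na(cols$id_b) |
    !nzchar(trimws(cols$id_a)) | !nzchar(trimws(cols$id_b)) |
    is.na(taxid_a) | is.na(taxid_b) |
    !(category %in% c("physical", "genetic")) |
    is.na(cols$source_db)
  n_skipped <- sum(bad)
  if (n_skipped > 0)
    warning(sprintf("skipped %d malformed interaction row(s)", n_skipped), call. = FALSE)

  keep <- !bad
  out <- data.frame(
    id_a = trimws(cols$id_a[keep]), id_b = trimws(cols$id_b[keep]),
    taxid_a = taxid_a[keep], taxid_b = taxid_b[keep],
    category = category[keep], source_db = trimws(cols$source_db[keep]),
    detection_method = ifelse(is.na(cols$detection_method[keep]), "",
                              trimws(cols$detection_method[keep])),
    pubmed_ids = ifelse(is.na(cols$pubmed_ids[keep]), "",
                        trimws(cols$pubmed_ids[keep])),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Empty interaction record table
#' @return zero-row data.frame with the canonical record columns
#' @export
interaction_records <- function() {
  data.frame(
    id_a = character(0), id_b = character(0),
    taxid_a = integer(0), taxid_b = integer(0),
    category = character(0), source_db = character(0),
    detection_method = character(0), pubmed_ids = character(0),
    stringsAsFactors = FALSE
  )
}

#' Read a PSI-MI TAB 2.5 file into interaction records
#'
#' Convenience adapter for MITAB dumps: maps columns 1, 2 (interactor ids),
#' 10, 11 (taxids), 12 (interaction type), 13 (source database) and 15
#' (publication ids) into the canonical record layout.  Identifier and taxid
#' prefixes (`uniprotkb:`, `taxid:`) are stripped; an interaction type whose
#' free-text name contains "genetic" is classed `genetic`, everything else
#' `physical`.
#'
#' @param file path to a MITAB 2.5 file (no header, or a header line
#'   starting with `#`)
#' @return interaction record data.frame (see [parse_interactions()])
#' @export
read_psimi_tab <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(interaction_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)

  field <- function(p, i) if (length(p) >= i && p[[i]] != "-") p[[i]] else ""
  strip_id <- function(x) sub("^[A-Za-z0-9_.-]+:", "", sub("\\|.*$", "", x))
  strip_tax <- function(x) sub("\\(.*$", "", sub("^taxid:", "", sub("\\|.*$", "", x)))
  first_name <- function(x) {
    m <- regmatches(x, regexpr("\\(([^)]*)\\)", x))
    if (length(m)) gsub("[()]", "", m) else x
  }
  pubmeds <- function(x) {
    if (!nzchar(x)) return("")
    ids <- unlist(strsplit(x, "|", fixed = TRUE))
    ids <- sub("^pubmed:", "", ids[grepl("^pubmed:", ids)])
    paste(ids, collapse = ";")
  }

  rows <- lapply(parts, function(p) {
    itype <- first_name(field(p, 12))
    data.frame(
      id_a = strip_id(field(p, 1)), id_b = strip_id(field(p, 2)),
      taxid_a = suppressWarnings(as.integer(strip_tax(field(p, 10)))),
      taxid_b = suppressWarnings(as.integer(strip_tax(field(p, 11)))),
      category = if (grepl("genetic", itype, ignore.case = TRUE)) "genetic" else "physical",
      source_db = first_name(field(p, 13)),
      detection_method = "",
      pubmed_ids = pubmeds(field(p, 15)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  bad <- !nzchar(out$id_a) | !nzchar(out$id_b) | is.na(out$taxid_a) | is.na(out$taxid_b)
  if (any(bad)) warning(sprintf("skipped %d malformed MITAB row(s)", sum(bad)), call. = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Keep physical interactions only
#'
#' Interactions reported as solely genetic carry no evidence of a physical
#' association and are discarded before network construction.
#' @param records interaction record data.frame
#' @return the subset with `category == "physical"`, input order preserved
#' @export
filter_physical <- function(records) {
  out <- records[records$category == "physical", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep intra-species interactions only
#'
#' @param records interaction record data.frame
#' @return the subset with `taxid_a == taxid_b`, input order preserved
#' @export
filter_intra_species <- function(records) {
  out <- records[records$taxid_a == records$taxid_b, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rewrite interactor identifiers through a conversion map
#'
#' Source databases mix UniProt accessions, systematic names and gene
#' symbols; all identifiers are unified through `id_map` before networks are
#' built.  A one-to-many map entry (one source id listed with several
#' targets, e.g. an isoform-ambiguous chaperone mapped to both paralogs)
#' expands the record to every combination of resolved endpoints.
#'
#' @param records interaction record data.frame
#' @param id_map either a named character vector (`from = to`) or a
#'   two-column data.frame `from`,`to`; may contain repeated `from` entries
#'   (one-to-many)
#' @param policy `"passthrough"` keeps unmapped identifiers unchanged;
#'   `"strict"` drops records with any unmapped identifier (drop count in
#'   attribute `n_dropped`, with a summary warning)
#' @return rewritten (possibly expanded) record data.frame
#' @export
normalize_ids <- function(records, id_map, policy = c("passthrough", "strict")) {
  policy <- match.arg(policy)
  if (is.data.frame(id_map)) {
    lookup <- split(as.character(id_map$to), as.character(id_map$from))
  } else {
    lookup <- split(unname(as.character(id_map)), names(id_map))
  }
  if (nrow(records) == 0) {
    attr(records, "n_dropped") <- 0L
    return(records)
  }

  resolve <- function(ids) {
    hit <- lookup[ids]
    unmapped <- vapply(hit, is.null, logical(1))
    if (policy == "passthrough") hit[unmapped] <- as.list(ids[unmapped])
    list(targets = hit, unmapped = unmapped)
  }
  ra <- resolve(records$id_a)
  rb <- resolve(records$id_b)

  drop <- if (policy == "strict") ra$unmapped | rb$unmapped else rep(FALSE, nrow(records))
  n_dropped <- sum(drop)
  if (n_dropped > 0)
    warning(sprintf("dropped %d record(s) with unresolvable identifier(s)", n_dropped),
            call. = FALSE)

  keep <- which(!drop)
  na <- lengths(ra$targets)[keep]
  nb <- lengths(rb$targets)[keep]
  reps <- na * nb
  idx <- rep(keep, reps)
  out <- records[idx, , drop = FALSE]
  out$id_a <- unlist(mapply(function(i, k) rep(ra$targets[[i]], each = k),
                            keep, nb, SIMPLIFY = FALSE), use.names = FALSE)
  out$id_b <- unlist(mapply(function(i, k) rep(rb$targets[[i]], times = k),
                            keep, na, SIMPLIFY = FALSE), use.names = FALSE)
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build a species interaction network
#'
#' Collapses records for one taxon into a simple undirected graph.  Both
#' orientations of a pair fold into one canonical edge whose provenance
#' (source databases, detection methods, PubMed ids) is the union over all
#' contributing records.  Self-pairs (e.g. chaperone homodimers) are kept in
#' a side table, not as graph edges, so degree-based measures stay loop-free.
#'
#' @param records interaction record data.frame (already physical-only and
#'   intra-species; records of other taxa are ignored)
#' @param taxid NCBI taxon id of the network
#' @return object of class `species_network`: list with `taxid`, `nodes`
#'   (character), `edges` (canonical edge table) and `self_interactions`
#' @examples
#' rec <- data.frame(id_a = c("A", "B", "A"), id_b = c("B", "A", "C"),
#'                   taxid_a = 9606, taxid_b = 9606, category = "physical",
#'                   source_db = "BioGrid", detection_method = "", pubmed_ids = "")
#' build_species_network(rec, 9606)
#' @export
build_species_network <- function(records, taxid) {
  taxid <- as.integer(taxid)
  rec <- records[records$taxid_a == taxid & records$taxid_b == taxid, , drop = FALSE]
  origin <- if (taxid == 9606L) "human" else paste0("native:", taxid)

  self <- rec[rec$id_a == rec$id_b, , drop = FALSE]
  rec <- rec[rec$id_a != rec$id_b, , drop = FALSE]

  raw <- data.frame(
    id_a = rec$id_a, id_b = rec$id_b, origin = rep(origin, nrow(rec)),
    source_dbs = rec$source_db, detection_methods = rec$detection_method,
    pubmed_ids = rec$pubmed_ids, stringsAsFactors = FALSE
  )
  edges <- collapse_edges(raw)

  selfs <- if (nrow(self) > 0) {
    data.frame(
      id = unique(self$id_a),
      source_dbs = merge_set_by(self$source_db, self$id_a),
      pubmed_ids = merge_set_by(self$pubmed_ids, self$id_a),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else {
    data.frame(id = character(0), source_dbs = character(0),
               pubmed_ids = character(0), stringsAsFactors = FALSE)
  }

  species_network(taxid = taxid,
                  nodes = sort_c(unique(c(edges$id_a, edges$id_b, selfs$id))),
                  edges = edges, self_interactions = selfs)
}

#' Construct a species_network object
#' @param taxid NCBI taxon id
#' @param nodes character vector of node identifiers
#' @param edges canonical edge table (`id_a`, `id_b`, `origin`,
#'   `source_dbs`, `detection_methods`, `pubmed_ids`)
#' @param self_interactions side table of self-pairs
#' @return `species_network` object
#' @export
species_network <- function(taxid, nodes = character(0), edges = empty_edges(),
                            self_interactions = NULL) {
  if (nrow(edges) > 0) {
    stopifnot(all(edges$id_a != edges$id_b),
              all(edges$id_a <= edges$id_b),
              all(c(edges$id_a, edges$id_b) %in% nodes))
  }
  structure(
    list(taxid = as.integer(taxid), nodes = as.character(nodes), edges = edges,
         self_interactions = self_interactions %||%
           data.frame(id = character(0), source_dbs = character(0),
                      pubmed_ids = character(0), stringsAsFactors = FALSE)),
    class = "species_network"
  )
}

#' @export
print.species_network <- function(x, ...) {
  cat(sprintf("<species_network> taxid %d: %d nodes, %d edges, %d self-interaction(s)\n",
              x$taxid, length(x$nodes), nrow(x$edges), nrow(x$self_interactions)))
  invisible(x)
}

#' Write a network as a canonical tab-delimited edge table
#'
#' Columns: `id_a`, `id_b`, `taxid`, `origin`, `source_dbs`,
#' `detection_methods`, `pubmed_ids` (set-valued fields `;`-joined).
#' Round-trips through [read_edge_table()].
#' @param net a `species_network`
#' @param file output path
#' @export
write_edge_table <- function(net, file) {
  df <- net$edges
  out <- data.frame(id_a = df$id_a, id_b = df$id_b, taxid = net$taxid,
                    origin = df$origin, source_dbs = df$source_dbs,
                    detection_methods = df$detection_methods,
                    pubmed_ids = df$pubmed_ids, stringsAsFactors = FALSE)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a canonical edge table written by [write_edge_table()]
#' @param file path
#' @return `species_network`
#' @export
read_edge_table <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  taxid <- if ("taxid" %in% names(df) && nrow(df) > 0)
    as.integer(df$taxid[[1]]) else NA_integer_
  edges <- data.frame(id_a = df$id_a, id_b = df$id_b, origin = df$origin,
                      source_dbs = df$source_dbs,
                      detection_methods = df$detection_methods,
                      pubmed_ids = df$pubmed_ids, stringsAsFactors = FALSE)
  species_network(taxid = taxid,
                  nodes = sort_c(unique(c(edges$id_a, edges$id_b))),
                  edges = collapse_edges(edges))
}

#' Export a network in SIF format (`node <tab> pp <tab> node`)
#' @param net a `species_network` or `merged_network`
#' @param file output path
#' @export
write_sif <- function(net, file) {
  e <- net$edges
  writeLines(if (nrow(e)) paste(e$id_a, "pp", e$id_b, sep = "\t") else character(0), file)
  invisible(file)
}
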