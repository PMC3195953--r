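#' Specification for a synthetic multi-species fixture
#'
#' Describes the statistical structure the generator emulates: several
#' species-specific interaction networks sharing a partially conserved
#' ("ancestral") human edge layer, an ortholog map with incomplete coverage,
#' a densely connected planted query machine with a designated neighbour
#' shell, and one GO term enriched in that machine.
#'
#' @param species named integer vector, NCBI taxid -> node count; must
#'   include human (9606).  Defaults to human plus six model organisms.
#' @param background_edge_p Erdős–Rényi edge probability of the ancestral
#'   layer outside the machine
#' @param query_size number of planted query proteins
#' @param shell_size size of the designated neighbour shell; the machine is
#'   query plus shell
#' @param planted_p_in edge probability inside the machine
#'   (>= background_edge_p)
#' @param ortholog_coverage fraction of each non-human species' nodes mapped
#'   to a human gene
#' @param human_overlap_fraction probability that a conserved (projectable)
#'   ancestral edge is also present in the human table — the knob that
#'   exercises the known-human subtraction
#' @param private_noise_p edge probability of species-private noise (pairs
#'   with at least one unmapped gene); default `background_edge_p / 2`
#' @param n_go_terms number of annotation terms
#' @param planted_term_effect fraction of machine nodes annotated to the
#'   planted term
#' @param seed integer seed; the whole bundle is a pure function of the spec
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(species = c(`9606` = 400, `10090` = 350, `7227` = 350,
                                     `6239` = 350, `4932` = 350, `4896` = 300,
                                     `3702` = 300),
                         background_edge_p = 0.01,
                         query_size = 39,
                         shell_size = 40,
                         planted_p_in = 0.25,
                         ortholog_coverage = 0.6,
                         human_overlap_fraction = 0.3,
                         private_noise_p = NULL,
                         n_go_terms = 25,
                         planted_term_effect = 0.75,
                         seed = 1) {
  spec <- list(species = species, background_edge_p = background_edge_p,
               query_size = as.integer(query_size),
               shell_size = as.integer(shell_size),
               planted_p_in = planted_p_in,
               ortholog_coverage = ortholog_coverage,
               human_overlap_fraction = human_overlap_fraction,
               private_noise_p = private_noise_p %||% background_edge_p / 2,
               n_go_terms = as.integer(n_go_terms),
               planted_term_effect = planted_term_effect,
               seed = as.integer(seed))
  if (!"9606" %in% names(spec$species))
    stop("fixture species must include human (9606)", call. = FALSE)
  if (!(spec$background_edge_p > 0 && spec$background_edge_p <= spec$planted_p_in &&
        spec$planted_p_in <= 1))
    stop("need 0 < background_edge_p <= planted_p_in <= 1", call. = FALSE)
  if (spec$ortholog_coverage < 0 || spec$ortholog_coverage > 1)
    stop("ortholog_coverage must be in [0, 1]", call. = FALSE)
  nh <- spec$species[["9606"]]
  if (spec$query_size + spec$shell_size > nh)
    stop("query_size + shell_size exceeds the human node count", call. = FALSE)
  structure(spec, class = "fixture_spec")
}

# All unordered index pairs of 1..n as a 2-row matrix (column-major order;
# vectorised, unlike combn, so ~2e6 pairs stay fast).
all_pairs <- function(n) {
  if (n < 2) return(matrix(integer(0), nrow = 2))
  idx <- which(upper.tri(matrix(FALSE, n, n)))
  rbind(as.integer((idx - 1L) %% n + 1L), as.integer((idx - 1L) %/% n + 1L))
}

#' Generate a synthetic multi-species interaction bundle
#'
#' Emits per-species interaction tables (with duplicate orientations,
#' genetic-category rows, a couple of cross-species rows, self-interactions
#' and identifier aliases sprinkled in to exercise every cleaning stage), a
#' HomoloGene-layout ortholog file, the query list, an identifier map, a GO
#' annotation table, and a ground-truth record holding the exact
#' human-projected merged edge set the pipeline must reproduce.
#'
#' @param spec a [fixture_spec()]
#' @param dir optional output directory; when given, all files (plus a
#'   ready-to-run pipeline `config.yaml`) are written there deterministically
#' @return list with `tables` (per-taxid record data.frames), `homologene`,
#'   `id_map`, `query`, `annotations`, `truth` and `spec`; `truth` holds
#'   `merged_edges` (id_a, id_b, origins), `machine`, `query`,
#'   `planted_term`, and per-species query translations
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  taxids <- as.integer(names(spec$species))
  nh <- spec$species[["9606"]]
  hsym <- sprintf("HS%04d", seq_len(nh))

  query <- sort_c(sample(hsym, spec$query_size))
  shell <- sort_c(sample(setdiff(hsym, query), spec$shell_size))
  machine <- sort_c(c(query, shell))

  # Ancestral conserved edge layer: ER background with a dense machine.
  ij <- all_pairs(nh)
  m_idx <- match(machine, hsym)
  in_machine <- ij[1, ] %in% m_idx & ij[2, ] %in% m_idx
  p_edge <- rep(spec$background_edge_p, ncol(ij))
  p_edge[in_machine] <- spec$planted_p_in
  anc_sel <- stats::runif(ncol(ij)) < p_edge
  anc_a <- hsym[ij[1, anc_sel]]
  anc_b <- hsym[ij[2, anc_sel]]

  # Ortholog structure: per species, a sample of human genes has a 1:1
  # ortholog; remaining species genes are private (unmapped).
  sp_info <- list()
  for (tx in setdiff(taxids, 9606L)) {
    n_s <- spec$species[[as.character(tx)]]
    n_mapped <- min(round(spec$ortholog_coverage * n_s), nh)
    partners <- sort_c(sample(hsym, n_mapped))
    mapped_sym <- if (n_mapped > 0) paste0("T", tx, "_", partners) else character(0)
    private_sym <- if (n_s > n_mapped)
      sprintf("T%d_P%03d", tx, seq_len(n_s - n_mapped)) else character(0)
    sp_info[[as.character(tx)]] <- list(taxid = tx, partners = partners,
                                        mapped_sym = mapped_sym,
                                        private_sym = private_sym)
  }

  # Human table: conserved edges thinned by the overlap fraction, plus
  # human-private noise among never-conserved pairs.
  hof_keep <- stats::runif(length(anc_a)) < spec$human_overlap_fraction
  noise_sel <- !anc_sel & stats::runif(ncol(ij)) < spec$private_noise_p
  human_a <- c(anc_a[hof_keep], hsym[ij[1, noise_sel]])
  human_b <- c(anc_b[hof_keep], hsym[ij[2, noise_sel]])

  edge_sets <- list(`9606` = data.frame(id_a = human_a, id_b = human_b,
                                        stringsAsFactors = FALSE))

  # Species tables: conserved copies through the inverse ortholog map plus
  # private noise touching at least one unmapped gene.
  for (tx in names(sp_info)) {
    info <- sp_info[[tx]]
    to_sp <- stats::setNames(info$mapped_sym, info$partners)
    both <- anc_a %in% info$partners & anc_b %in% info$partners
    cons_a <- unname(to_sp[anc_a[both]])
    cons_b <- unname(to_sp[anc_b[both]])

    genes <- c(info$mapped_sym, info$private_sym)
    gp <- all_pairs(length(genes))
    has_private <- gp[1, ] > length(info$mapped_sym) | gp[2, ] > length(info$mapped_sym)
    nz <- which(has_private)[stats::runif(sum(has_private)) < spec$private_noise_p]
    edge_sets[[tx]] <- data.frame(
      id_a = c(cons_a, genes[gp[1, nz]]),
      id_b = c(cons_b, genes[gp[2, nz]]),
      stringsAsFactors = FALSE
    )
  }

  # Dress edge lists up as realistic interaction records.
  dbs <- c("BioGrid", "IntAct", "MINT", "DIP", "HPRD", "BIND", "curated")
  methods <- c("two hybrid", "affinity chromatography", "coimmunoprecipitation",
               "pull down", "")
  tables <- list()
  for (tx in names(edge_sets)) {
    e <- edge_sets[[tx]]
    txi <- as.integer(tx)
    n <- nrow(e)
    rec <- data.frame(
      id_a = e$id_a, id_b = e$id_b, taxid_a = txi, taxid_b = txi,
      category = "physical",
      source_db = sample(dbs, n, replace = TRUE),
      detection_method = sample(methods, n, replace = TRUE),
      pubmed_ids = as.character(9999999L + sample.int(20000000L, n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    # duplicate ~3% of rows in the reverse orientation from another source
    dup <- which(stats::runif(n) < 0.03)
    if (length(dup)) {
      rdup <- rec[dup, , drop = FALSE]
      rec <- rbind(rec, data.frame(
        id_a = rdup$id_b, id_b = rdup$id_a, taxid_a = txi, taxid_b = txi,
        category = "physical", source_db = sample(dbs, length(dup), replace = TRUE),
        detection_method = rdup$detection_method, pubmed_ids = rdup$pubmed_ids,
        stringsAsFactors = FALSE))
    }
    # purely genetic rows (discarded by the physical filter)
    genes_tx <- unique(c(e$id_a, e$id_b))
    n_gen <- max(2L, round(0.02 * n))
    if (length(genes_tx) >= 2) {
      ga <- sample(genes_tx, n_gen, replace = TRUE)
      gb <- sample(genes_tx, n_gen, replace = TRUE)
      ok <- ga != gb
      rec <- rbind(rec, data.frame(
        id_a = ga[ok], id_b = gb[ok], taxid_a = txi, taxid_b = txi,
        category = "genetic", source_db = "BioGrid",
        detection_method = "synthetic lethality",
        pubmed_ids = as.character(9999999L + sample.int(20000000L, sum(ok), replace = TRUE)),
        stringsAsFactors = FALSE))
    }
    # a couple of cross-species rows (discarded by the intra-species filter)
    other <- setdiff(taxids, txi)[1]
    if (!is.na(other) && length(genes_tx) >= 2) {
      rec <- rbind(rec, data.frame(
        id_a = sample(genes_tx, 2), id_b = sample(genes_tx, 2),
        taxid_a = txi, taxid_b = other, category = "physical",
        source_db = "IntAct", detection_method = "",
        pubmed_ids = "", stringsAsFactors = FALSE))
    }
    # one self-interaction (kept as a record, never a graph edge)
    rec <- rbind(rec, data.frame(
      id_a = genes_tx[1], id_b = genes_tx[1], taxid_a = txi, taxid_b = txi,
      category = "physical", source_db = "curated", detection_method = "",
      pubmed_ids = "", stringsAsFactors = FALSE))
    rec <- rec[sample(nrow(rec)), , drop = FALSE]
    rownames(rec) <- NULL
    tables[[tx]] <- rec
  }

  # Identifier aliases in the human table, restored through the id map.
  alias_of <- sample(hsym, max(3L, round(0.02 * nh)))
  id_map <- data.frame(from = paste0("ALIAS_", alias_of), to = alias_of,
                       stringsAsFactors = FALSE)
  hrec <- tables[["9606"]]
  for (col in c("id_a", "id_b")) {
    hit <- hrec[[col]] %in% alias_of & stats::runif(nrow(hrec)) < 0.5
    hrec[[col]][hit] <- paste0("ALIAS_", hrec[[col]][hit])
  }
  tables[["9606"]] <- hrec

  # HomoloGene-layout group table: one group per human gene.
  hg <- data.frame(group_id = seq_len(nh), taxid = 9606L,
                   gene_id = as.character(100000L + seq_len(nh)),
                   symbol = hsym, stringsAsFactors = FALSE)
  for (tx in names(sp_info)) {
    info <- sp_info[[tx]]
    gid <- match(info$partners, hsym)
    if (length(gid) == 0) next
    hg <- rbind(hg, data.frame(
      group_id = gid, taxid = info$taxid,
      gene_id = as.character(info$taxid * 1000L + seq_along(gid)),
      symbol = info$mapped_sym, stringsAsFactors = FALSE))
  }
  hg <- hg[order(hg$group_id, hg$taxid), , drop = FALSE]
  rownames(hg) <- NULL

  # Annotations: one term enriched in the machine, the rest random.
  terms <- sprintf("GO:%07d", 9000000L + seq_len(spec$n_go_terms))
  planted_term <- terms[1]
  ann_rows <- list()
  planted_members <- sort_c(c(
    sample(machine, round(spec$planted_term_effect * length(machine))),
    sample(setdiff(hsym, machine), max(2L, round(0.02 * nh)))))
  ann_rows[[1]] <- data.frame(protein = planted_members, term_id = planted_term,
                              term_name = "planted_machine_process",
                              namespace = "biological_process",
                              stringsAsFactors = FALSE)
  for (i in seq_len(spec$n_go_terms - 1)) {
    size <- sample(5:40, 1)
    ann_rows[[i + 1]] <- data.frame(
      protein = sort_c(sample(hsym, size)), term_id = terms[i + 1],
      term_name = sprintf("background_process_%02d", i),
      namespace = "biological_process", stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann_rows)

  truth <- fixture_truth(edge_sets, sp_info, query, machine, planted_term)

  bundle <- list(tables = tables, homologene = hg, id_map = id_map,
                 query = query, annotations = annotations, truth = truth,
                 spec = spec)
  if (!is.null(dir)) write_fixture(bundle, dir)
  bundle
}

# Ground truth for the merged human-projected query interactome, computed
# with plain set arithmetic (independent of the pipeline operations).
fixture_truth <- function(edge_sets, sp_info, query, machine, planted_term) {
  canon_key <- function(a, b) {
    lo <- ifelse(a <= b, a, b); hi <- ifelse(a <= b, b, a)
    paste(lo, hi, sep = "\r")
  }
  dedupe <- function(a, b) unique(canon_key(a, b))
  neighbours_of <- function(keys, nodes) {
    ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    unique(c(ab[ab[, 1] %in% nodes, 2], ab[ab[, 2] %in% nodes, 1]))
  }
  induced <- function(keys, nodes) {
    ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    keys[ab[, 1] %in% nodes & ab[, 2] %in% nodes]
  }

  h <- edge_sets[["9606"]]
  h_keys <- dedupe(h$id_a, h$id_b)
  h_nodes <- unique(c(h$id_a, h$id_b))
  q_h <- intersect(query, h_nodes)
  s_h <- unique(c(q_h, neighbours_of(h_keys, q_h)))
  human_query_keys <- induced(h_keys, s_h)

  origin_by_key <- stats::setNames(as.list(rep("human", length(human_query_keys))),
                                   human_query_keys)
  species_queries <- list()
  for (tx in names(sp_info)) {
    info <- sp_info[[tx]]
    to_sp <- stats::setNames(info$mapped_sym, info$partners)
    to_hu <- stats::setNames(info$partners, info$mapped_sym)
    e <- edge_sets[[tx]]
    keys <- dedupe(e$id_a, e$id_b)
    nodes <- unique(c(e$id_a, e$id_b))
    q_s <- intersect(unname(to_sp[intersect(query, info$partners)]), nodes)
    species_queries[[tx]] <- sort_c(q_s)
    s_s <- unique(c(q_s, neighbours_of(keys, q_s)))
    qk <- induced(keys, s_s)
    ab <- do.call(rbind, strsplit(qk, "\r", fixed = TRUE))
    ha <- to_hu[ab[, 1]]
    hb <- to_hu[ab[, 2]]
    ok <- !is.na(ha) & !is.na(hb) & ha != hb
    proj <- unique(canon_key(unname(ha[ok]), unname(hb[ok])))
    novel <- setdiff(proj, h_keys)
    tag <- paste0("interolog:", tx)
    for (k in novel) origin_by_key[[k]] <- sort_c(unique(c(origin_by_key[[k]], tag)))
  }

  keys <- sort_c(names(origin_by_key))
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  merged_edges <- data.frame(
    id_a = ab[, 1], id_b = ab[, 2],
    origins = vapply(origin_by_key[keys], paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  list(merged_edges = merged_edges, machine = machine, query = query,
       species_queries = species_queries, planted_term = planted_term)
}

#' Write a fixture bundle to disk
#'
#' Files: `interactions_<taxid>.tsv`, `homologene.data`, `id_map.tsv`,
#' `query.txt`, `annotations.tsv`, `truth_edges.tsv`, `truth.json` and a
#' pipeline-ready `config.yaml`.  Output is byte-deterministic for a given
#' spec.
#' @param bundle result of [generate_fixture()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  for (tx in names(bundle$tables))
    utils::write.table(bundle$tables[[tx]], p(sprintf("interactions_%s.tsv", tx)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  hg <- bundle$homologene
  writeLines(paste(hg$group_id, hg$taxid, hg$gene_id, hg$symbol,
                   "0", "NP_000000.0", sep = "\t"), p("homologene.data"))
  utils::write.table(bundle$id_map, p("id_map.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(bundle$query, p("query.txt"))
  utils::write.table(bundle$annotations, p("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$merged_edges, p("truth_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(machine = bundle$truth$machine, query = bundle$truth$query,
         planted_term = bundle$truth$planted_term,
         species_queries = bundle$truth$species_queries),
    p("truth.json"), auto_unbox = FALSE, pretty = TRUE)

  cfg <- list(
    target_taxid = 9606L,
    species = lapply(stats::setNames(names(bundle$tables), names(bundle$tables)),
                     function(tx) list(path = sprintf("interactions_%s.tsv", tx),
                                       dialect = "canonical")),
    id_map = list(path = "id_map.tsv", policy = "passthrough"),
    ortholog_file = "homologene.data",
    ortholog_key = "symbol",
    query_file = "query.txt",
    topology = list(reps = 50L, seed = bundle$spec$seed, query_size = NULL),
    enrichment = list(annotation_file = "annotations.tsv", alpha = 0.05,
                      min_proteins = 8L, overlap_threshold = 0.4,
                      correction = "benjamini-hochberg",
                      namespace = "biological_process")
  )
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}
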