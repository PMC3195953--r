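#' Read a pipeline configuration
#'
#' Configurations are YAML (or an equivalent R list) with the entries:
#' `target_taxid` (default 9606), `species` (map taxid -> `path` +
#' `dialect`, `"canonical"` or `"psimi"`), optional `id_map` (`path`,
#' `policy`), `ortholog_file`, `ortholog_key` (`"symbol"` or `"gene_id"`),
#' `query_file`, `topology` (`reps`, `seed`, optional `query_size`) and
#' `enrichment` (`annotation_file`, `alpha`, `min_proteins`,
#' `overlap_threshold`, `correction`, `namespace`).  Relative paths are
#' resolved against the configuration file's directory.
#'
#' @param file path to a YAML config
#' @return config list with absolute paths
#' @export
read_pipeline_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  fix <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  for (tx in names(cfg$species)) cfg$species[[tx]]$path <- fix(cfg$species[[tx]]$path)
  if (!is.null(cfg$id_map)) cfg$id_map$path <- fix(cfg$id_map$path)
  cfg$ortholog_file <- fix(cfg$ortholog_file)
  cfg$query_file <- fix(cfg$query_file)
  if (!is.null(cfg$enrichment))
    cfg$enrichment$annotation_file <- fix(cfg$enrichment$annotation_file)
  cfg
}

#' Run the full interactome-construction pipeline
#'
#' Orchestrates the whole workflow: per-species cleaning (physical-only,
#' intra-species, identifier normalisation), query-centred extraction,
#' interolog projection of the non-human networks, subtraction of known
#' human interactions, the merge into the human-projected interactome,
#' topology measures against the random-query null, and the GO functional
#' map.  Each stage's row/edge counts go into a machine-readable manifest
#' (the construction funnel); any stage error aborts naming the stage.
#'
#' @param config a config list or path to a YAML file (see
#'   [read_pipeline_config()])
#' @param out_dir optional output directory; when given, every stage's
#'   output and `manifest.json` are written there
#' @return list with `species_nets`, `query_nets`, `interolog_nets` (pre and
#'   post subtraction), `merged` (the `merged_network`), `measures`, `null`,
#'   `topology_report`, `enrichment`, `functional_map` and `manifest`
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(fun, name, ...) if (!is.null(out_dir)) fun(..., file.path(out_dir, name))
  target <- as.integer(cfg$target_taxid %||% 9606L)
  manifest <- list(species = list())

  query <- tryCatch(
    suppressWarnings(trimws(readLines(cfg$query_file, warn = FALSE))),
    error = function(e) stop_stage("query-list", conditionMessage(e)))
  query <- query[nzchar(query) & !grepl("^#", query)]

  id_map <- NULL
  if (!is.null(cfg$id_map) && !is.null(cfg$id_map$path)) {
    id_map <- tryCatch(
      suppressWarnings(utils::read.delim(cfg$id_map$path, stringsAsFactors = FALSE,
                                         colClasses = "character")),
      error = function(e) stop_stage("id-map", conditionMessage(e)))
  }

  omap <- NULL
  non_target <- setdiff(names(cfg$species), as.character(target))
  if (length(non_target) > 0) {
    omap <- tryCatch(parse_homologene(cfg$ortholog_file),
                     error = function(e) stop_stage("orthologs", conditionMessage(e)))
  }
  okey <- cfg$ortholog_key %||% "symbol"

  # ---- clean: parse, filter, normalise, build per-species networks ----
  species_nets <- list()
  for (tx in names(cfg$species)) {
    scfg <- cfg$species[[tx]]
    res <- tryCatch({
      rec <- switch(scfg$dialect %||% "canonical",
                    canonical = parse_interactions(scfg$path),
                    psimi = read_psimi_tab(scfg$path),
                    stop("unknown dialect: ", scfg$dialect))
      n_raw <- nrow(rec) + (attr(rec, "n_skipped") %||% 0L)
      rec_p <- filter_physical(rec)
      rec_i <- filter_intra_species(rec_p)
      rec_n <- if (!is.null(id_map))
        normalize_ids(rec_i, id_map, policy = cfg$id_map$policy %||% "passthrough")
      else rec_i
      net <- build_species_network(rec_n, as.integer(tx))
      list(net = net, counts = list(
        rows_raw = n_raw, rows_parsed = nrow(rec), rows_physical = nrow(rec_p),
        rows_intra_species = nrow(rec_i), rows_normalized = nrow(rec_n),
        nodes = length(net$nodes), edges = nrow(net$edges),
        self_interactions = nrow(net$self_interactions)))
    }, error = function(e) stop_stage(paste0("clean:", tx), conditionMessage(e)))
    species_nets[[tx]] <- res$net
    manifest$species[[tx]] <- res$counts
    emit(write_edge_table, sprintf("clean_%s.tsv", tx), res$net)
  }
  if (!as.character(target) %in% names(species_nets))
    stop_stage("clean", sprintf("no input table for the target taxon %d", target))
  human_net <- species_nets[[as.character(target)]]

  manifest$base <- list(
    nodes = sum(vapply(species_nets, function(n) length(n$nodes), numeric(1))),
    edges = sum(vapply(species_nets, function(n) nrow(n$edges), numeric(1))))

  # ---- query extraction per species ----
  query_nets <- list()
  for (tx in names(species_nets)) {
    q_tx <- if (as.integer(tx) == target) query
            else orthologs_of(omap, query, as.integer(tx), by = okey)
    qn <- tryCatch(extract_query_network(species_nets[[tx]], q_tx),
                   error = function(e) stop_stage(paste0("query:", tx),
                                                  conditionMessage(e)))
    query_nets[[tx]] <- qn
    manifest$species[[tx]]$query_translated <- length(q_tx)
    manifest$species[[tx]]$query_matched <- length(attr(qn, "query_ids"))
    manifest$species[[tx]]$query_nodes <- length(qn$nodes)
    manifest$species[[tx]]$query_edges <- nrow(qn$edges)
    emit(write_edge_table, sprintf("query_%s.tsv", tx), qn)
  }
  manifest$queried <- list(
    nodes = sum(vapply(query_nets, function(n) length(n$nodes), numeric(1))),
    edges = sum(vapply(query_nets, function(n) nrow(n$edges), numeric(1))))

  # ---- interolog projection and known-human subtraction ----
  interolog_nets <- list()
  for (tx in non_target) {
    res <- tryCatch({
      proj <- project_interologs(query_nets[[tx]], omap, by = okey)
      q_tx <- attr(query_nets[[tx]], "query_ids")
      keep <- unique(unlist(human_of(omap, as.integer(tx), q_tx, by = okey),
                            use.names = FALSE))
      novel <- subtract_known(proj, human_net, keep_nodes = keep)
      list(proj = proj, novel = novel)
    }, error = function(e) stop_stage(paste0("project:", tx), conditionMessage(e)))
    interolog_nets[[tx]] <- res
    manifest$species[[tx]]$interolog_edges <- nrow(res$proj$edges)
    manifest$species[[tx]]$interolog_dropped_unmapped <-
      attr(res$proj, "n_dropped_unmapped")
    manifest$species[[tx]]$interolog_removed_known <-
      attr(res$novel, "n_removed_known")
    manifest$species[[tx]]$interolog_novel_edges <- nrow(res$novel$edges)
    emit(write_edge_table, sprintf("interolog_%s_raw.tsv", tx), res$proj)
    emit(write_edge_table, sprintf("interolog_%s_novel.tsv", tx), res$novel)
  }

  # ---- merge ----
  merged <- tryCatch(
    merge_networks(c(list(query_nets[[as.character(target)]]),
                     lapply(interolog_nets, `[[`, "novel")),
                   query_ids = query),
    error = function(e) stop_stage("merge", conditionMessage(e)))
  manifest$merged <- list(nodes = nrow(merged$nodes), edges = nrow(merged$edges),
                          query_nodes = sum(merged$nodes$is_query))
  if (!is.null(out_dir)) {
    write_xgmml(merged, file.path(out_dir, "merged.xgmml"), label = "merged_interactome")
    write_merged_edge_table(merged, file.path(out_dir, "merged_edges.tsv"))
    write_sif(merged, file.path(out_dir, "merged.sif"))
  }

  # ---- topology vs random-query null ----
  measures <- null <- topo <- NULL
  tcfg <- cfg$topology
  if (!is.null(tcfg)) {
    if (is.null(tcfg$seed))
      stop_stage("topology", "the configuration must provide topology$seed")
    res <- tryCatch({
      measures <- compute_measures(merged)
      base <- merge_networks(species_nets, query_ids = character(0))
      qsize <- tcfg$query_size %||% length(query)
      null <- sample_null(base, query_size = qsize,
                          n_reps = tcfg$reps %||% 300,
                          seed = derive_seed(tcfg$seed, "topology"))
      list(measures = measures, null = null,
           report = compare_to_null(measures, null))
    }, error = function(e) stop_stage("topology", conditionMessage(e)))
    measures <- res$measures; null <- res$null; topo <- res$report
    if (!is.null(out_dir)) {
      utils::write.table(format(topo, digits = 10), file.path(out_dir, "topology_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(format(null$samples, digits = 10),
                         file.path(out_dir, "null_distribution.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(degree_histogram(merged),
                         file.path(out_dir, "degree_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(clustering_histogram(merged),
                         file.path(out_dir, "clustering_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # ---- GO over-representation and functional map ----
  enr <- fmap <- NULL
  ecfg <- cfg$enrichment
  if (!is.null(ecfg) && !is.null(ecfg$annotation_file)) {
    res <- tryCatch({
      universe <- unique(c(
        human_net$nodes,
        unlist(lapply(non_target, function(tx)
          unlist(human_of(omap, as.integer(tx), species_nets[[tx]]$nodes, by = okey),
                 use.names = FALSE)), use.names = FALSE)))
      ann <- read_annotations(ecfg$annotation_file, universe = universe,
                              namespace = ecfg$namespace %||% "biological_process")
      enr <- adjust_pvalues(enrich(merged$nodes$id, ann),
                            method = ecfg$correction %||% "benjamini-hochberg")
      fmap <- build_functional_map(
        enr, ann,
        min_proteins = ecfg$min_proteins %||% 8,
        alpha = ecfg$alpha %||% 0.05,
        overlap_threshold = ecfg$overlap_threshold %||% 0.4)
      list(enr = enr, fmap = fmap)
    }, error = function(e) stop_stage("enrichment", conditionMessage(e)))
    enr <- res$enr; fmap <- res$fmap
    manifest$enrichment <- list(terms_tested = nrow(enr),
                                terms_in_map = nrow(fmap$nodes),
                                map_edges = nrow(fmap$edges))
    if (!is.null(out_dir)) {
      utils::write.table(format(enr, digits = 10), file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_functional_map(fmap, file.path(out_dir, "functional_map"))
    }
  }

  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

  list(species_nets = species_nets, query_nets = query_nets,
       interolog_nets = interolog_nets, merged = merged,
       measures = measures, null = null, topology_report = topo,
       enrichment = enr, functional_map = fmap, manifest = manifest)
}
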