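hdr <- "id_a\tid_b\ttaxid_a\ttaxid_b\tcategory\tsource_db\tdetection_method\tpubmed_ids"

test_that("parse_interactions reads canonical rows and captures provenance", {
  tab <- c(hdr, "HSP90AA1\tAHSA1\t9606\t9606\tphysical\tBioGrid\t\t15937123")
  out <- parse_interactions(tab)
  expect_equal(nrow(out), 1L)
  expect_equal(out$id_a, "HSP90AA1")
  expect_equal(out$pubmed_ids, "15937123")
  expect_equal(attr(out, "n_skipped"), 0L)
})

test_that("parse_interactions handles degenerate and malformed input", {
  expect_equal(nrow(parse_interactions(hdr)), 0L)

  tab <- c(hdr,
           "A\tB\t9606\t9606\tphysical\tDIP\t\t",
           "A\t\t9606\t9606\tphysical\tDIP\t\t",
           "C\tD\t9606\t9606\tphysical\tDIP\t\t")
  expect_warning(out <- parse_interactions(tab), "malformed")
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_skipped"), 1L)

  bad_hdr <- "id_a\tid_b\ttaxid_a\ttaxid_b\tsource_db"
  expect_error(parse_interactions(c(bad_hdr, "A\tB\t9606\t9606\tDIP")),
               "category")
})

test_that("parse_interactions accepts positional column maps and comments", {
  tab <- c("# a comment", "B\tA\tDIP\t9606\t9606\tphysical")
  out <- parse_interactions(tab, column_map = c(id_a = 1L, id_b = 2L,
                                                source_db = 3L, taxid_a = 4L,
                                                taxid_b = 5L, category = 6L))
  expect_equal(out$source_db, "DIP")
  expect_equal(out$taxid_a, 9606L)
})

test_that("category and species filters match their definitions and are idempotent", {
  recs <- rbind(rec("A", "B"), rec("C", "D", category = "genetic"), rec("E", "F"))
  phys <- filter_physical(recs)
  expect_equal(phys$id_a, c("A", "E"))
  expect_equal(filter_physical(phys), phys)
  expect_equal(nrow(filter_physical(rec("A", "B", category = "genetic"))), 0L)
  expect_equal(nrow(filter_physical(interaction_records())), 0L)

  recs2 <- rbind(rec("A", "B", 9606L, 10090L), rec("C", "D", 4932L),
                 rec("E", "F"), rec("G", "H", 7227L))
  intra <- filter_intra_species(recs2)
  expect_equal(nrow(intra), 3L)
  expect_false("A" %in% intra$id_a)
  expect_equal(filter_intra_species(intra), intra)
})

test_that("normalize_ids rewrites, drops under strict policy, and expands one-to-many", {
  r <- rec("P07900", "AHSA1")
  out <- normalize_ids(r, c(P07900 = "HSP90AA1"))
  expect_equal(out$id_a, "HSP90AA1")
  expect_equal(out$id_b, "AHSA1")    # passthrough for unmapped

  expect_warning(strict <- normalize_ids(r, c(P07900 = "HSP90AA1"),
                                         policy = "strict"), "dropped")
  expect_equal(nrow(strict), 0L)
  expect_equal(attr(strict, "n_dropped"), 1L)

  # isoform-ambiguous id duplicated to both paralogs via a one-to-many entry
  iso_map <- data.frame(from = c("HSP90", "HSP90"),
                        to = c("HSP90AA1", "HSP90AB1"))
  dup <- normalize_ids(rec("HSP90", "AHSA1"), iso_map)
  expect_equal(sort(dup$id_a), c("HSP90AA1", "HSP90AB1"))
  expect_equal(dup$id_b, c("AHSA1", "AHSA1"))
})

test_that("build_species_network canonicalizes pairs and unions provenance", {
  recs <- rbind(rec("A", "B", source_db = "BioGrid", pubmed_ids = "111"),
                rec("B", "A", source_db = "IntAct", pubmed_ids = "222"),
                rec("A", "C"))
  net <- build_species_network(recs, 9606)
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  ab <- net$edges[net$edges$id_a == "A" & net$edges$id_b == "B", ]
  expect_equal(ab$source_dbs, "BioGrid;IntAct")
  expect_equal(ab$pubmed_ids, "111;222")

  selfed <- build_species_network(rec("A", "A"), 9606)
  expect_equal(nrow(selfed$edges), 0L)
  expect_equal(selfed$self_interactions$id, "A")
  expect_true("A" %in% selfed$nodes)
})

test_that("edge count never exceeds record count and foreign taxa are ignored", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    ids <- sample(LETTERS[1:6], 2 * n, replace = TRUE)
    recs <- rec(ids[seq_len(n)], ids[n + seq_len(n)])
    recs <- recs[recs$id_a != recs$id_b, , drop = FALSE]
    net <- build_species_network(recs, 9606)
    expect_lte(nrow(net$edges), nrow(recs))
  }
  expect_equal(nrow(build_species_network(rec("A", "B", 4932L), 9606)$edges), 0L)
})

test_that("edge tables round-trip through write and re-parse", {
  set.seed(7)
  net <- random_small_net()$net
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(net, f)
  back <- read_edge_table(f)
  expect_equal(back$taxid, net$taxid)
  expect_setequal(back$nodes, sort(unique(c(net$edges$id_a, net$edges$id_b))))
  expect_equal(back$edges, net$edges)
})

test_that("the PSI-MI TAB adapter strips prefixes and classes interaction types", {
  mitab <- paste(
    "uniprotkb:P07900", "uniprotkb:O95433", "-", "-", "-", "-", "-", "-", "-",
    "taxid:9606(human)", "taxid:9606(human)",
    'psi-mi:"MI:0915"(physical association)', 'psi-mi:"MI:0463"(biogrid)',
    "-", "pubmed:15937123|pubmed:16000000", sep = "\t")
  genetic <- paste(
    "g1", "g2", "-", "-", "-", "-", "-", "-", "-",
    "taxid:4932", "taxid:4932",
    'psi-mi:"MI:0208"(genetic interaction)', 'psi-mi:"MI:0463"(biogrid)',
    "-", "-", sep = "\t")
  f <- withr::local_tempfile(lines = c(mitab, genetic))
  out <- read_psimi_tab(f)
  expect_equal(out$id_a, c("P07900", "g1"))
  expect_equal(out$taxid_a, c(9606L, 4932L))
  expect_equal(out$category, c("physical", "genetic"))
  expect_equal(out$pubmed_ids[1], "15937123;16000000")
  expect_equal(out$source_db[1], "biogrid")
})
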