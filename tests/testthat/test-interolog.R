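hg_lines <- c(
  "1\t9606\t3320\tHSP90AA1\t0\tNP_1",
  "1\t4932\t851376\tHSP82\t0\tNP_2",
  "2\t9606\t10598\tAHSA1\t0\tNP_3",
  "2\t4932\t853225\tAHA1\t0\tNP_4",
  "3\t4932\t850000\tYST1\t0\tNP_5"   # yeast-only group, no human member
)

yeast_net <- function(edges_df) {
  recs <- do.call(rbind, lapply(seq_len(nrow(edges_df)), function(i)
    rec(edges_df$a[i], edges_df$b[i], 4932L)))
  build_species_network(recs, 4932)
}

test_that("parse_homologene builds group lookups in both directions", {
  map <- parse_homologene(hg_lines)
  expect_equal(human_of(map, 4932, "HSP82")[["HSP82"]], "HSP90AA1")
  expect_equal(human_of(map, 4932, "YST1")[["YST1"]], character(0))
  expect_equal(human_of(map, 4932, "unknown")[["unknown"]], character(0))
  expect_equal(orthologs_of(map, c("HSP90AA1", "AHSA1"), 4932),
               c("AHA1", "HSP82"))
})

test_that("parse_homologene rejects conflicting group membership and skips junk", {
  conflict <- c(hg_lines, "2\t4932\t851376\tHSP82\t0\tNP_9")
  expect_error(parse_homologene(conflict), "different ortholog groups")
  expect_warning(map <- parse_homologene(c(hg_lines, "not a real row")),
                 "malformed")
  expect_equal(length(unique(map$groups$group_id)), 3L)
})

test_that("projection maps edges through ortholog groups with origin tags", {
  map <- parse_homologene(hg_lines)
  net <- yeast_net(data.frame(a = c("HSP82", "HSP82"), b = c("AHA1", "YST1")))
  proj <- project_interologs(net, map)
  expect_equal(nrow(proj$edges), 1L)
  expect_equal(proj$edges$id_a, "AHSA1")
  expect_equal(proj$edges$id_b, "HSP90AA1")
  expect_equal(proj$edges$origin, "interolog:4932")
  expect_equal(attr(proj, "n_dropped_unmapped"), 1L)
  expect_equal(attr(proj, "source_taxid"), 4932L)
})

test_that("one-to-many orthology expands to the cross product", {
  # HSP82 maps to both human cytosolic isoforms -> 2 projected edges
  two_iso <- c("1\t9606\t3320\tHSP90AA1\t0\tNP_1",
               "1\t9606\t3326\tHSP90AB1\t0\tNP_1b",
               "1\t4932\t851376\tHSP82\t0\tNP_2",
               "2\t9606\t10598\tAHSA1\t0\tNP_3",
               "2\t4932\t853225\tAHA1\t0\tNP_4")
  map <- parse_homologene(two_iso)
  proj <- project_interologs(yeast_net(data.frame(a = "HSP82", b = "AHA1")), map)
  expect_equal(nrow(proj$edges), 2L)
  expect_setequal(proj$edges$id_b, c("HSP90AA1", "HSP90AB1"))
  expect_equal(proj$edges$id_a, c("AHSA1", "AHSA1"))
})

test_that("paralog pairs collapsing to one human gene are dropped as self-pairs", {
  paralogs <- c("1\t9606\t3320\tHSP90AA1\t0\tNP_1",
                "1\t4932\t851376\tHSP82\t0\tNP_2",
                "1\t4932\t855836\tHSC82\t0\tNP_6")
  map <- parse_homologene(paralogs)
  proj <- project_interologs(yeast_net(data.frame(a = "HSC82", b = "HSP82")), map)
  expect_equal(nrow(proj$edges), 0L)
  expect_equal(attr(proj, "n_dropped_self"), 1L)
})

test_that("projected endpoints are always human symbols and projection is monotone", {
  set.seed(101)
  b <- generate_fixture(fixture_spec(species = c(`9606` = 60, `4932` = 50),
                                     query_size = 6, shell_size = 6, seed = 5))
  map <- ortholog_map(b$homologene)
  net <- build_species_network(
    filter_intra_species(filter_physical(b$tables[["4932"]])), 4932)
  proj <- project_interologs(net, map)
  human_symbols <- map$groups$symbol[map$groups$taxid == 9606]
  expect_true(all(c(proj$edges$id_a, proj$edges$id_b) %in% human_symbols))

  # removing edges from the source can only remove projected edges
  sub <- net
  sub$edges <- sub$edges[seq_len(floor(nrow(sub$edges) / 2)), , drop = FALSE]
  sub <- species_network(4932, nodes = net$nodes, edges = sub$edges)
  proj_sub <- project_interologs(sub, map)
  key <- function(e) paste(e$id_a, e$id_b)
  expect_true(all(key(proj_sub$edges) %in% key(proj$edges)))
})

test_that("subtract_known removes exactly the edges present in the human network", {
  mk <- function(pairs) {
    df <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                     origin = "interolog:4932", source_dbs = "x",
                     detection_methods = "", pubmed_ids = "",
                     stringsAsFactors = FALSE)
    species_network(9606, nodes = sort(unique(c(df$id_a, df$id_b))), edges = df)
  }
  inter <- mk(rbind(c("H1", "H2"), c("H2", "H3")))
  human <- mk(rbind(c("H2", "H3")))

  out <- subtract_known(inter, human)
  expect_equal(nrow(out$edges), 1L)
  expect_equal(out$edges$id_a, "H1")
  expect_equal(attr(out, "n_removed_known"), 1L)

  disjoint <- subtract_known(inter, mk(rbind(c("H8", "H9"))))
  expect_equal(disjoint$edges, inter$edges)

  none <- subtract_known(inter, inter)
  expect_equal(nrow(none$edges), 0L)

  # post-condition: no surviving edge may appear in the human network
  key <- function(e) paste(e$id_a, e$id_b)
  expect_length(intersect(key(out$edges), key(human$edges)), 0)
})
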