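test_that("Newick parsing builds a labelled rooted tree and round-trips", {
  tr <- parse_species_tree("((A,B)AB,C)ROOT;")
  expect_s3_class(tr, "species_tree")
  expect_setequal(clade_leaves(tr, "ROOT"), c("A", "B", "C"))
  expect_setequal(clade_leaves(tr, "AB"), c("A", "B"))
  expect_equal(tree_lca(tr, c("A", "B")), "AB")
  expect_equal(tree_lca(tr, c("A", "C")), "ROOT")
  # round trip preserves topology and labels
  expect_equal(serialize_species_tree(parse_species_tree(
    serialize_species_tree(tr))), "((A,B)AB,C)ROOT;")
  # unlabelled internal nodes are auto-named in preorder
  tr2 <- parse_species_tree("((A,B),C);")
  expect_setequal(internal_levels(tr2), c("N1", "N2"))
})

test_that("degenerate or malformed Newick is rejected with a location", {
  expect_error(parse_species_tree("(A);"), ">= 2 children")
  expect_error(parse_species_tree("((A,B)AB,C"), "offset")
  expect_error(parse_species_tree("((A,B))AB,C);"), "offset")
  expect_error(parse_species_tree("((A,B)X,(C,D)X)R;"), "duplicate")
})

test_that("OrthoXML parsing assigns levels, ids and the gene partition", {
  fx <- fixture_forest()
  forest <- fx$forest
  expect_length(forest$roots, 4)
  # partition: every gene in exactly one root tree
  expect_equal(sort(forest$genes$gene_id),
               sort(c(paste0("a", 1:4), paste0("b", 1:4), paste0("c", 1:3))))
  expect_false(anyDuplicated(forest$genes$gene_id) > 0)
  # duplication children extend the parent id with letter suffixes
  f2 <- forest$roots[[2]]
  expect_equal(f2$hog_id, "HOG:F002")
  par <- f2$children[[1]]
  expect_equal(par$kind, "paralog")
  expect_setequal(vapply(par$children, `[[`, character(1), "hog_id"),
                  c("HOG:F002.1a", "HOG:F002.1b"))
})

test_that("group levels fall back to the member LCA without TaxRange", {
  fx <- fixture_forest(taxranges = FALSE)
  lv <- vapply(fx$forest$roots, `[[`, character(1), "level")
  expect_equal(lv, c("R", "R", "C", "AB"))
  nested_ab <- fx$forest$roots[[1]]$children[[1]]
  expect_equal(nested_ab$level, "AB")
})

test_that("invalid OrthoXML groups are rejected", {
  tree <- parse_species_tree(fixture_newick())
  empty <- paste0(
    '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3">',
    '<species name="A"><database name="t"><genes><gene id="1" protId="a1"/>',
    '</genes></database></species>',
    '<groups><orthologGroup></orthologGroup></groups></orthoXML>')
  expect_error(parse_hogs(empty, tree), "empty")
  missing_gene <- paste0(
    '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3">',
    '<species name="A"><database name="t"><genes><gene id="1" protId="a1"/>',
    '</genes></database></species>',
    '<groups><orthologGroup><geneRef id="1"/><geneRef id="99"/>',
    '</orthologGroup></groups></orthoXML>')
  expect_error(parse_hogs(missing_gene, tree), "99")
})

test_that("OrthoXML serialization round-trips through the parser", {
  fx <- fixture_forest()
  xml <- write_orthoxml(fx$forest)
  re <- parse_hogs(xml, fx$tree)
  expect_equal(length(re$roots), length(fx$forest$roots))
  expect_equal(re$genes[order(re$genes$gene_id), ],
               fx$forest$genes[order(fx$forest$genes$gene_id), ],
               ignore_attr = TRUE)
  expect_equal(vapply(re$roots, `[[`, character(1), "level"),
               vapply(fx$forest$roots, `[[`, character(1), "level"))
})

test_that("gene orders: GFF3 coordinates convert and ranks follow start", {
  gff <- paste(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t51\t90\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=m1",
    "chr2\tsrc\tgene\t1\t50\t.\t+\t.\tID=g3",
    sep = "\n")
  gs <- parse_gene_orders(gff, format = "gff3", species = "A")
  g <- gs[["A"]]$genes
  expect_equal(g$start[g$gene_id == "g1"], 100L)  # 1-based -> 0-based
  expect_equal(g$rank[g$gene_id == "g2"], 0L)     # sorted by start
  expect_equal(g$rank[g$gene_id == "g1"], 1L)
  expect_equal(g$rank[g$gene_id == "g3"], 0L)     # per-contig ranks
  expect_equal(nrow(g), 3L)                       # mRNA row ignored
})

test_that("gene orders: TSV dialect round-trips and rejects duplicates", {
  tsv <- "species\tcontig\tstart\tgene_id\nA\tc1\t100\tg1\nA\tc1\t50\tg2\n"
  gs <- parse_gene_orders(tsv, format = "tsv")
  expect_equal(gs[["A"]]$contigs$c1, c("g2", "g1"))
  out <- write_gene_orders(gs)
  expect_equal(parse_gene_orders(out, format = "tsv")[["A"]]$genes,
               gs[["A"]]$genes)
  dup <- "species\tcontig\tstart\tgene_id\nA\tc1\t1\tg1\nA\tc2\t2\tg1\n"
  expect_error(parse_gene_orders(dup, format = "tsv"), "duplicate")
})

test_that("OBO parsing: aliases, obsoletes, part_of and cycle detection", {
  onto <- parse_ontology(fixture_obo())
  expect_equal(resolve_term(onto, "GO:0000777"), "GO:0000002")
  expect_true(onto$terms["GO:0000004", "obsolete"])
  expect_equal(onto$parents[["GO:0000006"]], "GO:0000005")  # part_of
  cyc <- paste("[Term]", "id: GO:1", "name: a", "is_a: GO:2", "",
               "[Term]", "id: GO:2", "name: b", "is_a: GO:1", sep = "\n")
  expect_error(parse_ontology(cyc), "cyclic")
})

test_that("GAF loading filters ND/NOT, maps alt ids, stays non-redundant", {
  onto <- parse_ontology(fixture_obo())
  gaf <- paste(
    "!gaf-version: 2.2",
    "db\tg1\tg1\t\tGO:0000003\tref\tIEA\t\tP\t\t\tprotein\ttaxon:1\t20230101\tdb",
    "db\tg1\tg1\t\tGO:0000002\tref\tIEA\t\tP\t\t\tprotein\ttaxon:1\t20230101\tdb",
    "db\tg2\tg2\t\tGO:0000777\tref\tIEA\t\tP\t\t\tprotein\ttaxon:1\t20230101\tdb",
    "db\tg3\tg3\tNOT\tGO:0000002\tref\tIEA\t\tP\t\t\tprotein\ttaxon:1\t20230101\tdb",
    "db\tg4\tg4\t\tGO:0000002\tref\tND\t\tP\t\t\tprotein\ttaxon:1\t20230101\tdb",
    sep = "\n")
  ann <- parse_gaf(gaf, onto)
  # ancestor row of g1 removed; alt id of g2 resolved; g3 (NOT) and g4 (ND) gone
  expect_equal(ann$subject_id, c("g1", "g2"))
  expect_equal(ann$term_id, c("GO:0000003", "GO:0000002"))
  expect_warning(
    parse_gaf(paste(
      "db\tg1\tg1\t\tGO:9999999\tref\tIEA\t\tP\t\t\tprotein\ttaxon:1\t20230101\tdb",
      "db\tg1\tg1\t\tGO:0000002\tref\tIEA\t\tP\t\t\tprotein\ttaxon:1\t20230101\tdb",
      sep = "\n"), onto),
    "1 GAF row")
})
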