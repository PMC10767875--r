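test_that("projection maps genes to level HOGs and closes gaps", {
  fx <- fixture_forest()
  # A's order: a1 a2 a3 a4; c3 is F003 (no HOG at AB)
  tsv <- paste("species\tcontig\tstart\tgene_id",
               "A\tc1\t0\ta1", "A\tc1\t10\ta2", "A\tc1\t20\ta3",
               "A\tc1\t30\ta4",
               "C\tc1\t0\tc1", "C\tc1\t10\tc3", "C\tc1\t20\tc2",
               sep = "\n")
  genomes <- parse_gene_orders(tsv, format = "tsv")
  proj_ab <- project_genomes(genomes, fx$forest, fx$tree, "AB")
  expect_length(proj_ab, 1)  # C is outside the clade of AB
  expect_equal(proj_ab[[1]]$contigs$c1,
               c("HOG:F001", "HOG:F002.1a", "HOG:F002.1b", "HOG:F004"))
  # at R, c3 maps to F003; gap-closing removes nothing here
  proj_r <- project_genomes(genomes, fx$forest, fx$tree, "R")
  cproj <- proj_r[[which(vapply(proj_r, `[[`, character(1), "species") == "C")]]
  expect_equal(cproj$contigs$c1, c("HOG:F001", "HOG:F003", "HOG:F002"))
  # unmapped genes close the gap: drop F003's gene from the ontology view
  lg <- hogs_at_level(fx$forest, "R", fx$tree)
  lg <- lg[lg$hog_id != "HOG:F003", ]
  proj2 <- project_genomes(genomes, fx$forest, fx$tree, "R", level_genes = lg)
  cproj2 <- proj2[[which(vapply(proj2, `[[`, character(1), "species") == "C")]]
  expect_equal(cproj2$contigs$c1, c("HOG:F001", "HOG:F002"))
})

test_that("adjacency weights count supporting contexts, skip tandems, ignore order", {
  mk <- function(...) lapply(list(...), function(ctg)
    list(species = "s", contigs = list(ctg)))
  lg <- data.frame(hog_id = c("H1", "H2", "H3"), completeness = 1,
                   n_members = 1)
  g <- build_adjacency_graph(mk(c("H1", "H2", "H3"), c("H1", "H2", "H3")), lg)
  expect_equal(g$edges$weight, c(2, 2))
  g2 <- build_adjacency_graph(mk(c("H1", "H1", "H2")), lg)
  expect_equal(g2$edges[, c("hog_u", "hog_v")],
               data.frame(hog_u = "H1", hog_v = "H2"))
  expect_equal(g2$edges$weight, 1)
  g3 <- build_adjacency_graph(mk(c("H1", "H2"), c("H2", "H1")), lg)
  expect_equal(g3$edges$weight, 2)
})

test_that("total edge weight equals adjacent pairs minus tandem skips", {
  sim <- simulate_clade(simulation_config(
    n_species = 6, n_ancestral_genes = 30, gain_rate = 2, loss_rate = 2,
    dup_rate = 2, n_inversions = 1, seed = 9))
  tree <- parse_species_tree(sim$newick)
  forest <- parse_hogs(sim$orthoxml, tree)
  genomes <- parse_gene_orders(sim$gene_orders, format = "tsv")
  lv <- internal_levels(tree)[1]
  lg <- hogs_at_level(forest, lv, tree)
  proj <- project_genomes(genomes, forest, tree, lv, level_genes = lg)
  graph <- build_adjacency_graph(proj, lg, lv)
  expected <- sum(vapply(proj, function(p) {
    sum(vapply(p$contigs, function(ctg) {
      if (length(ctg) < 2) return(0L)
      sum(ctg[-length(ctg)] != ctg[-1])
    }, integer(1)))
  }, numeric(1)))
  expect_equal(sum(graph$edges$weight), expected)
})

test_that("linearize handles paths, stars, cycles with the stated tie rule", {
  path <- make_graph(data.frame(hog_u = c("H1", "H2"), hog_v = c("H2", "H3"),
                                weight = c(5, 4)))
  expect_equal(linearize(path)[[1]], c("H1", "H2", "H3"))
  star <- make_graph(data.frame(hog_u = c("H0", "H0", "H0"),
                                hog_v = c("H1", "H2", "H3"),
                                weight = c(3, 2, 1)))
  lin <- linearize(star)
  expect_equal(lin[[1]], c("H1", "H0", "H2"))
  expect_equal(lin[[2]], "H3")
  tri <- make_graph(data.frame(hog_u = c("H1", "H1", "H2"),
                               hog_v = c("H2", "H3", "H3"),
                               weight = c(1, 1, 1)))
  lt <- linearize(tri)
  expect_length(lt, 1)
  # tie rule accepts (H1,H2) then (H1,H3): the path is H2-H1-H3
  expect_equal(lt[[1]], c("H2", "H1", "H3"))
  # min_weight threshold drops weak evidence
  expect_equal(lengths(linearize(path, min_weight = 5)), c(2L, 1L))
})

test_that("linearize output is a linear forest with each HOG placed once", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(3:9, 1)
    nodes <- sprintf("H%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.45
    if (!any(keep)) next
    edges <- data.frame(hog_u = pairs[keep, 1], hog_v = pairs[keep, 2],
                        weight = sample(1:9, sum(keep), replace = TRUE),
                        stringsAsFactors = FALSE)
    contigs <- linearize(make_graph(edges, nodes))
    placed <- unlist(contigs)
    expect_setequal(placed, nodes)
    expect_false(anyDuplicated(placed) > 0)
    expect_true(all(diff(-lengths(contigs)) >= -1e-9))  # sorted by length
  }
})

test_that("zero-inversion simulations recover the planted root order exactly", {
  sim <- simulate_clade(simulation_config(
    n_species = 8, n_ancestral_genes = 40, gain_rate = 4, loss_rate = 0,
    dup_rate = 3, n_inversions = 0, seed = 13))
  tree <- parse_species_tree(sim$newick)
  forest <- parse_hogs(sim$orthoxml, tree)
  genomes <- parse_gene_orders(sim$gene_orders, format = "tsv")
  root <- internal_levels(tree)[1]
  contigs <- ancestral_gene_order(genomes, forest, tree, root)$contigs
  planted <- paste0("HOG:",
                    unname(sim$truth$family_of[sim$truth$content[[root]]]))
  expect_length(contigs, 1)
  expect_true(identical(contigs[[1]], planted) ||
                identical(contigs[[1]], rev(planted)))
})

test_that("few inversions leave a small breakpoint distance to the truth", {
  for (seed in 1:5) {
    sim <- simulate_clade(simulation_config(
      n_species = 6, n_ancestral_genes = 30, gain_rate = 0, loss_rate = 0,
      dup_rate = 0, n_inversions = 1, seed = seed))
    tree <- parse_species_tree(sim$newick)
    forest <- parse_hogs(sim$orthoxml, tree)
    genomes <- parse_gene_orders(sim$gene_orders, format = "tsv")
    root <- internal_levels(tree)[1]
    contigs <- ancestral_gene_order(genomes, forest, tree, root)$contigs
    planted <- paste0("HOG:",
                      unname(sim$truth$family_of[sim$truth$content[[root]]]))
    k <- sum(vapply(sim$truth$branch_counts, `[`, numeric(1), "inversions"))
    expect_lte(breakpoint_distance(planted, contigs), 2 * k)
  }
})
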