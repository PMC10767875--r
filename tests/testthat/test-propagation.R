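test_that("term closure implements the true-path rule and is idempotent", {
  onto <- parse_ontology(fixture_obo())
  expect_equal(term_closure("GO:0000001", onto), "GO:0000001")  # root
  expect_equal(term_closure("GO:0000003", onto),
               c("GO:0000001", "GO:0000002", "GO:0000003"))
  cl <- term_closure(c("GO:0000003", "GO:0000006"), onto)
  expect_equal(term_closure(cl, onto), cl)
  expect_error(term_closure("GO:9999999", onto), "unknown")
  expect_error(term_closure("GO:0000004", onto), "obsolete")
})

# a balanced 4-leaf family over ((A,B)AB,(C,D)CD)R: the root node has two
# children (the AB and CD subfamilies), each with two leaf genes
balanced_family <- function() {
  xml <- paste0(
    '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3">',
    '<species name="A"><database name="t"><genes>',
    '<gene id="1" protId="l1"/></genes></database></species>',
    '<species name="B"><database name="t"><genes>',
    '<gene id="2" protId="l2"/></genes></database></species>',
    '<species name="C"><database name="t"><genes>',
    '<gene id="3" protId="l3"/></genes></database></species>',
    '<species name="D"><database name="t"><genes>',
    '<gene id="4" protId="l4"/></genes></database></species>',
    '<groups><orthologGroup id="HOG:F1">',
    '<orthologGroup><geneRef id="1"/><geneRef id="2"/></orthologGroup>',
    '<orthologGroup><geneRef id="3"/><geneRef id="4"/></orthologGroup>',
    '</orthologGroup></groups></orthoXML>')
  tree <- parse_species_tree("((A,B)AB,(C,D)CD)R;")
  list(tree = tree, forest = parse_hogs(xml, tree),
       onto = parse_ontology(fixture_obo()))
}

test_that("child-fraction propagation follows unanimity and the tau threshold", {
  bf <- balanced_family()
  ann_all <- annotation_table(data.frame(
    subject_id = c("l1", "l2", "l3", "l4"), term_id = "GO:0000003"))
  prop <- propagate_to_hogs(ann_all, bf$forest, bf$onto)
  # unanimous term reaches the family root with support 1
  root_key <- bf$forest$roots[[1]]$node_key
  at_root <- prop[prop$node_key == root_key, ]
  expect_equal(at_root$term_id, "GO:0000003")
  expect_equal(at_root$support, 1)

  # term in the AB subtree only: root support 1/2, kept at tau 0.5,
  # dropped at tau 0.6
  ann_half <- annotation_table(data.frame(
    subject_id = c("l1", "l2"), term_id = "GO:0000003"))
  p5 <- propagate_to_hogs(ann_half, bf$forest, bf$onto, tau = 0.5)
  expect_equal(p5$support[p5$node_key == root_key], 0.5)
  p6 <- propagate_to_hogs(ann_half, bf$forest, bf$onto, tau = 0.6)
  expect_false(root_key %in% p6$node_key)
})

test_that("a single-leaf term never passes a >= 2-child node at tau > 0.5", {
  bf <- balanced_family()
  ann <- annotation_table(data.frame(subject_id = "l1",
                                     term_id = "GO:0000003"))
  prop <- propagate_to_hogs(ann, bf$forest, bf$onto, tau = 0.51)
  multi <- function(node) length(node$children) >= 2
  # collect node keys of nodes with >= 2 children
  keys <- character(0)
  walk <- function(n) {
    if (multi(n)) keys <<- c(keys, n$node_key)
    lapply(n$children, walk)
  }
  walk(bf$forest$roots[[1]])
  expect_false(any(prop$node_key %in% keys))
})

test_that("emitted rows are minimal: implied ancestors are suppressed", {
  bf <- balanced_family()
  # the specific term everywhere implies its parent; only the specific
  # term must be reported at the root
  ann <- annotation_table(data.frame(
    subject_id = c("l1", "l2", "l3", "l4"), term_id = "GO:0000003"))
  prop <- propagate_to_hogs(ann, bf$forest, bf$onto)
  root_terms <- prop$term_id[prop$node_key == bf$forest$roots[[1]]$node_key]
  expect_false("GO:0000002" %in% root_terms)
  expect_false("GO:0000001" %in% root_terms)
})

test_that("term_stats: probabilities, information content, monotonicity", {
  onto <- parse_ontology(fixture_obo())
  subjects <- sprintf("s%03d", 1:100)
  corpus <- lapply(subjects, function(s) "GO:0000001")
  corpus[[1]] <- c("GO:0000001", "GO:0000002", "GO:0000003")
  names(corpus) <- subjects
  st <- term_stats(corpus, onto)
  expect_equal(st["GO:0000001", "probability"], 1)
  expect_equal(st["GO:0000001", "ic"], 0)
  expect_equal(st["GO:0000003", "probability"], 0.01)
  expect_equal(st["GO:0000003", "ic"], -log(0.01), tolerance = 1e-12)
  # IC monotone along every parent edge
  for (t in st$term_id) {
    for (p in onto$parents[[t]]) {
      if (p %in% st$term_id) expect_gte(st[t, "ic"], st[p, "ic"])
    }
  }
  expect_error(term_stats(list(), onto), "empty")
})

test_that("fully annotated simulations give full coverage at every level", {
  sim <- simulate_clade(simulation_config(
    n_species = 6, n_ancestral_genes = 20, gain_rate = 1, loss_rate = 1,
    dup_rate = 1, n_inversions = 0, annotation_noise = 0, seed = 3))
  tree <- parse_species_tree(sim$newick)
  forest <- parse_hogs(sim$orthoxml, tree)
  onto <- parse_ontology(sim$obo)
  ann <- parse_gaf(sim$gaf, onto)
  prop <- propagate_to_hogs(ann, forest, onto, tau = 0.5)
  cov <- annotation_coverage(forest, tree, prop)
  expect_true(all(cov$percent == 100))
  expect_equal(cov$level, internal_levels(tree))
})
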