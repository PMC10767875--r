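# Shared fixtures: a 3-species clade with one family per scenario
# (retained, duplicated, clade-specific loss, clade-specific gain), plus
# small ontologies, all built in code.

fixture_newick <- function() "((A,B)AB,C)R;"

# genes: a1..a4 in A, b1..b4 in B, c1..c3 in C
fixture_orthoxml <- function(taxranges = TRUE) {
  tr <- function(lv) if (taxranges)
    sprintf('<property name="TaxRange" value="%s"/>', lv) else ""
  paste0(
    '<?xml version="1.0"?>\n',
    '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="t" originVersion="0">\n',
    '<species name="A" NCBITaxId="0"><database name="t" version="0"><genes>\n',
    '<gene id="1" protId="a1"/><gene id="2" protId="a2"/>\n',
    '<gene id="3" protId="a3"/><gene id="4" protId="a4"/>\n',
    '</genes></database></species>\n',
    '<species name="B" NCBITaxId="0"><database name="t" version="0"><genes>\n',
    '<gene id="11" protId="b1"/><gene id="12" protId="b2"/>\n',
    '<gene id="13" protId="b3"/><gene id="14" protId="b4"/>\n',
    '</genes></database></species>\n',
    '<species name="C" NCBITaxId="0"><database name="t" version="0"><genes>\n',
    '<gene id="21" protId="c1"/><gene id="22" protId="c2"/>\n',
    '<gene id="23" protId="c3"/>\n',
    '</genes></database></species>\n',
    '<groups>\n',
    # F001: retained single copy everywhere
    '<orthologGroup id="HOG:F001">', tr("R"),
    '<orthologGroup>', tr("AB"),
    '<geneRef id="1"/><geneRef id="11"/></orthologGroup>',
    '<geneRef id="21"/></orthologGroup>\n',
    # F002: duplication on the branch R -> AB
    '<orthologGroup id="HOG:F002">', tr("R"),
    '<paralogGroup>',
    '<orthologGroup>', tr("AB"), '<geneRef id="2"/><geneRef id="12"/></orthologGroup>',
    '<orthologGroup>', tr("AB"), '<geneRef id="3"/><geneRef id="13"/></orthologGroup>',
    '</paralogGroup>',
    '<geneRef id="22"/></orthologGroup>\n',
    # F003: present at R, lost in the AB clade (members only in C)
    '<orthologGroup id="HOG:F003">', tr("R"),
    '<geneRef id="23"/></orthologGroup>\n',
    # F004: gained on the branch R -> AB (root HOG at AB)
    '<orthologGroup id="HOG:F004">', tr("AB"),
    '<geneRef id="4"/><geneRef id="14"/></orthologGroup>\n',
    '</groups></orthoXML>\n')
}

fixture_forest <- function(taxranges = TRUE) {
  tree <- parse_species_tree(fixture_newick())
  list(tree = tree, forest = parse_hogs(fixture_orthoxml(taxranges), tree))
}

# linear ontology: root -> t1 -> t2 (BP), with an alt_id and an obsolete term
fixture_obo <- function() {
  paste(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: t1", "namespace: biological_process",
    "alt_id: GO:0000777", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: t2", "namespace: biological_process",
    "is_a: GO:0000002 ! t1", "",
    "[Term]", "id: GO:0000004", "name: old", "namespace: biological_process",
    "is_a: GO:0000001", "is_obsolete: true", "",
    "[Term]", "id: GO:0000005", "name: molecular_function",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000006", "name: m1", "namespace: molecular_function",
    "relationship: part_of GO:0000005 ! root",
    sep = "\n")
}

# six-term BP DAG with hand-set probabilities for simRel checks:
#        root(p=1)
#        /      \
#      t1(.5)  t2(.4)
#      /   \   /
#   t3(.2) t4(.1)
#             |
#           t5(.05)
fixture_dag <- function() {
  obo <- paste(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000100", "name: biological_process",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000101", "name: t1", "namespace: biological_process",
    "is_a: GO:0000100", "",
    "[Term]", "id: GO:0000102", "name: t2", "namespace: biological_process",
    "is_a: GO:0000100", "",
    "[Term]", "id: GO:0000103", "name: t3", "namespace: biological_process",
    "is_a: GO:0000101", "",
    "[Term]", "id: GO:0000104", "name: t4", "namespace: biological_process",
    "is_a: GO:0000101", "is_a: GO:0000102", "",
    "[Term]", "id: GO:0000105", "name: t5", "namespace: biological_process",
    "is_a: GO:0000104",
    sep = "\n")
  onto <- parse_ontology(obo)
  probs <- c("GO:0000100" = 1, "GO:0000101" = 0.5, "GO:0000102" = 0.4,
             "GO:0000103" = 0.2, "GO:0000104" = 0.1, "GO:0000105" = 0.05)
  stats <- data.frame(term_id = names(probs), namespace = "BP",
                      count = as.integer(probs * 100), probability = probs,
                      ic = -log(probs), stringsAsFactors = FALSE)
  rownames(stats) <- stats$term_id
  class(stats) <- c("term_stats", "data.frame")
  list(ontology = onto, stats = stats)
}

make_graph <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$hog_u, edges$hog_v)))
  structure(list(
    level = "X",
    nodes = data.frame(hog_id = nodes, completeness = 1, n_members = 1,
                       stringsAsFactors = FALSE),
    edges = edges), class = "adjacency_graph")
}
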