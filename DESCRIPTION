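Package: paleohog
Title: Ancestral Gene Content, Gene Order and Function from Hierarchical
    Orthologous Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs ancestral genomes from hierarchical orthologous
    groups (HOGs). Parses species trees (Newick), nested ortholog/paralog
    groups (OrthoXML), extant gene orders (GFF3 or TSV) and Gene Ontology
    data (OBO, GAF). Treats the HOGs defined at an internal node of the
    species tree as that ancestor's gene content, scores them with a
    completeness score, classifies per-branch evolutionary events
    (retained, duplicated, gained, lost), infers ancestral gene order by
    adjacency parsimony over extant gene neighbourhoods, propagates GO
    annotations from extant genes up to ancestral genes, and runs extant
    or ancestral GO enrichment (Fisher's exact test with Bonferroni and
    Benjamini-Hochberg correction) summarised as simRel/MDS semantic maps.
    Ships a synthetic clade simulator with planted ground truth so the
    whole pipeline is testable without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    xml2,
    jsonlite,
    yaml,
    optparse,
    rtracklayer,
    ggplot2,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
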