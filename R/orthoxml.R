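#' Parse hierarchical orthologous groups from OrthoXML
#'
#' Reads nested \code{orthologGroup}/\code{paralogGroup} elements into a
#' HOG forest. Every ortholog group is attached to a taxonomic level: an
#' explicit \code{TaxRange} property when present, otherwise the last
#' common ancestor (in \code{tree}) of the member species. HOG identifiers
#' follow the grammar \code{HOG:<RootId>(.<subId>)*}: root identifiers are
#' taken from the input when present (else \code{HOG:R<k>} by root index),
#' and the children of the d-th duplication under a group get suffixes
#' \code{.<d>a}, \code{.<d>b}, ... in document order.
#'
#' @param orthoxml_text OrthoXML document as a string (or an \code{xml_document}).
#' @param tree The \code{species_tree} naming all member species.
#' @return An object of class \code{hog_forest} with elements
#'   \code{roots} (list of nested HOG nodes), \code{genes} (data.frame
#'   gene_id / species / root_hog_id) and \code{n_nodes}.
#' @export
parse_hogs <- function(orthoxml_text, tree) {
  doc <- if (inherits(orthoxml_text, "xml_document")) orthoxml_text
         else xml2::read_xml(orthoxml_text)
  xml2::xml_ns_strip(doc)

  # internal numeric gene ids -> external gene ids + species
  gene_map <- list()
  for (sp in xml2::xml_find_all(doc, ".//species")) {
    sp_name <- xml2::xml_attr(sp, "name")
    for (g in xml2::xml_find_all(sp, ".//gene")) {
      gid <- xml2::xml_attr(g, "id")
      ext <- xml2::xml_attr(g, "protId")
      if (is.na(ext)) ext <- xml2::xml_attr(g, "geneId")
      if (is.na(ext)) ext <- gid
      gene_map[[gid]] <- c(ext, sp_name)
    }
  }
  unknown_sp <- setdiff(unique(vapply(gene_map, `[`, character(1), 2)),
                        tree$labels[seq_len(tree$n_tips)])
  if (length(unknown_sp)) {
    stop("OrthoXML references species absent from the tree: ",
         paste(unknown_sp, collapse = ", "), call. = FALSE)
  }

  groups <- xml2::xml_find_all(doc, "./groups/*")
  groups <- groups[xml2::xml_name(groups) %in% c("orthologGroup", "paralogGroup")]
  if (!length(groups)) stop("OrthoXML contains no groups", call. = FALSE)

  state <- new.env(parent = emptyenv())
  state$key <- 0L
  state$missing_genes <- character(0)

  roots <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    el <- groups[[k]]
    root_id <- xml2::xml_attr(el, "id")
    if (is.na(root_id) || root_id == "") root_id <- paste0("HOG:R", k)
    if (!startsWith(root_id, "HOG:")) root_id <- paste0("HOG:", root_id)
    roots[[k]] <- .parse_group(el, root_id, gene_map, tree, state)
  }
  if (length(state$missing_genes)) {
    stop("OrthoXML geneRef(s) not declared in any genome: ",
         paste(unique(state$missing_genes), collapse = ", "), call. = FALSE)
  }

  genes <- do.call(rbind, lapply(roots, function(r) {
    data.frame(gene_id = r$members, species = r$member_species_by_gene,
               root_hog_id = r$hog_id, stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  if (anyDuplicated(genes$gene_id)) {
    stop("gene(s) appear in more than one root HOG: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(roots = roots, genes = genes, n_nodes = state$key),
            class = "hog_forest")
}

# Recursively parse one group element into a hog node.
.parse_group <- function(el, hog_id, gene_map, tree, state) {
  nm <- xml2::xml_name(el)
  state$key <- state$key + 1L
  key <- paste0("h", state$key)

  if (nm == "geneRef") {
    ref <- xml2::xml_attr(el, "id")
    info <- gene_map[[ref]]
    if (is.null(info)) {
      state$missing_genes <- c(state$missing_genes, ref)
      info <- c(ref, NA_character_)
    }
    return(list(node_key = key, hog_id = hog_id, level = info[2],
                kind = "gene", gene_id = info[1], species = info[2],
                children = list(),
                members = info[1], member_species = info[2],
                member_species_by_gene = info[2]))
  }

  kids_el <- xml2::xml_children(el)
  kids_nm <- xml2::xml_name(kids_el)
  keep <- kids_nm %in% c("orthologGroup", "paralogGroup", "geneRef")
  kids_el <- kids_el[keep]; kids_nm <- kids_nm[keep]
  if (!length(kids_el)) {
    stop("empty ", nm, " (", hog_id, ") in OrthoXML", call. = FALSE)
  }

  children <- vector("list", length(kids_el))
  dup_counter <- 0L
  for (i in seq_along(kids_el)) {
    if (kids_nm[i] == "paralogGroup") {
      dup_counter <- dup_counter + 1L
      children[[i]] <- .parse_paralog(kids_el[[i]], hog_id, dup_counter,
                                      gene_map, tree, state)
    } else {
      children[[i]] <- .parse_group(kids_el[[i]], hog_id, gene_map, tree, state)
    }
  }

  members <- unlist(lapply(children, `[[`, "members"), use.names = FALSE)
  mem_sp <- unlist(lapply(children, `[[`, "member_species_by_gene"),
                   use.names = FALSE)
  ok_sp <- mem_sp[!is.na(mem_sp)]

  level <- .tax_range(el)
  if (is.na(level)) {
    level <- if (length(unique(ok_sp)) >= 1L) tree_lca(tree, ok_sp)
             else NA_character_
  } else if (!level %in% tree$labels) {
    stop("TaxRange '", level, "' not a taxon of the species tree", call. = FALSE)
  }

  list(node_key = key, hog_id = hog_id, level = level,
       kind = if (nm == "paralogGroup") "paralog" else "ortholog",
       children = children,
       members = members, member_species = unique(ok_sp),
       member_species_by_gene = mem_sp)
}

# A duplication: its k non-geneRef children continue as sub-HOGs with
# letter suffixes; the paralog node itself sits at the LCA of its members.
.parse_paralog <- function(el, parent_id, dup_index, gene_map, tree, state) {
  state$key <- state$key + 1L
  key <- paste0("h", state$key)
  kids_el <- xml2::xml_children(el)
  kids_nm <- xml2::xml_name(kids_el)
  keep <- kids_nm %in% c("orthologGroup", "paralogGroup", "geneRef")
  kids_el <- kids_el[keep]; kids_nm <- kids_nm[keep]
  if (length(kids_el) < 2L) {
    stop("paralogGroup under ", parent_id, " needs >= 2 children", call. = FALSE)
  }
  children <- vector("list", length(kids_el))
  for (i in seq_along(kids_el)) {
    suffix <- paste0(".", dup_index, letters[i])
    child_id <- paste0(parent_id, suffix)
    if (kids_nm[i] == "paralogGroup") {
      children[[i]] <- .parse_paralog(kids_el[[i]], child_id, 1L,
                                      gene_map, tree, state)
    } else {
      children[[i]] <- .parse_group(kids_el[[i]], child_id, gene_map, tree, state)
    }
  }
  members <- unlist(lapply(children, `[[`, "members"), use.names = FALSE)
  mem_sp <- unlist(lapply(children, `[[`, "member_species_by_gene"),
                   use.names = FALSE)
  ok_sp <- mem_sp[!is.na(mem_sp)]
  level <- if (length(ok_sp)) tree_lca(tree, ok_sp) else NA_character_
  list(node_key = key, hog_id = parent_id, level = level,
       kind = "paralog", children = children,
       members = members, member_species = unique(ok_sp),
       member_species_by_gene = mem_sp)
}

.tax_range <- function(el) {
  props <- xml2::xml_find_all(el, "./property")
  for (p in props) {
    if (identical(xml2::xml_attr(p, "name"), "TaxRange")) {
      return(xml2::xml_attr(p, "value"))
    }
  }
  NA_character_
}

#' @export
print.hog_forest <- function(x, ...) {
  cat(sprintf("<hog_forest> %d root HOGs, %d genes, %d nodes\n",
              length(x$roots), nrow(x$genes), x$n_nodes))
  invisible(x)
}

#' Serialize a HOG forest to OrthoXML
#'
#' Writes nested ortholog/paralog groups with explicit \code{TaxRange}
#' properties, in the layout produced by the clade simulator. Scores are
#' not written.
#'
#' @param forest A \code{hog_forest}.
#' @param origin Value for the document's \code{origin} attribute.
#' @return A single string containing the OrthoXML document.
#' @export
write_orthoxml <- function(forest, origin = "paleohog") {
  genes <- forest$genes
  if (!nrow(genes)) {
    return(paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
                  '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="',
                  origin, '" originVersion="0.1">\n <groups>\n </groups>\n',
                  '</orthoXML>\n'))
  }
  gid_num <- seq_len(nrow(genes))
  names(gid_num) <- genes$gene_id
  sp_blocks <- vapply(split(seq_len(nrow(genes)), genes$species),
    function(rows) {
      gl <- paste0(sprintf('      <gene id="%d" protId="%s"/>',
                           gid_num[rows], genes$gene_id[rows]), collapse = "\n")
      paste0('  <species name="', genes$species[rows[1]],
             '" NCBITaxId="0">\n   <database name="', origin,
             '" version="0"><genes>\n', gl,
             "\n   </genes></database>\n  </species>")
    }, character(1))

  emit <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (node$kind == "gene") {
      return(sprintf('%s<geneRef id="%d"/>', pad, gid_num[node$gene_id]))
    }
    tag <- if (node$kind == "paralog") "paralogGroup" else "orthologGroup"
    attr <- if (node$kind == "ortholog" && !is.null(node$root_attr_id))
      sprintf(' id="%s"', node$root_attr_id) else ""
    prop <- if (node$kind == "ortholog" && !is.na(node$level))
      sprintf('\n%s <property name="TaxRange" value="%s"/>', pad, node$level)
      else ""
    body <- paste(vapply(node$children, emit, character(1), indent + 2L),
                  collapse = "\n")
    sprintf("%s<%s%s>%s\n%s\n%s</%s>", pad, tag, attr, prop, body, pad, tag)
  }
  roots <- lapply(forest$roots, function(r) { r$root_attr_id <- r$hog_id; r })
  grp <- paste(vapply(roots, emit, character(1), 3L), collapse = "\n")
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<orthoXML xmlns="http://orthoXML.org/2011/" version="0.3" origin="',
         origin, '" originVersion="0.1">\n',
         paste(sp_blocks, collapse = "\n"), "\n <groups>\n", grp,
         "\n </groups>\n</orthoXML>\n")
}
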