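#' Phylogeny-aware local synteny window
#'
#' Builds the data behind a local synteny view: the focal HOG's inferred
#' ancestral neighbourhood at \code{level} (the central HOG plus up to
#' \code{window} flanking HOGs in both directions), one row per extant
#' member gene showing its genomic neighbourhood, and, for every collapsed
#' internal node, the inferred neighbourhood of the focal gene's ancestor
#' at that node. Entries are coloured by the level HOG their own family
#' maps to; neighbours with no inferred homology to the reference
#' neighbourhood are classed \code{"unrelated"} (rendered grey).
#'
#' @param focal A HOG id at \code{level}, or an extant gene id.
#' @param level Internal taxon label of the reference row.
#' @param forest A \code{hog_forest}.
#' @param tree The \code{species_tree}.
#' @param genomes List of \code{extant_genome} objects.
#' @param window Maximum flanking genes per side (default 5).
#' @param collapse Character vector of internal nodes whose extant leaves
#'   are replaced by the ancestral neighbourhood at that node.
#' @param min_weight Adjacency weight threshold passed to [linearize()].
#' @return A \code{synteny_view}: list with the focal id, level, window
#'   and \code{rows}; each row has \code{node}, \code{type}
#'   ("ancestral"/"extant") and an \code{entries} data.frame with columns
#'   slot (offset from focal), id, color_class, is_focal.
#' @export
synteny_window <- function(focal, level, forest, tree, genomes,
                           window = 5, collapse = character(0),
                           min_weight = 1) {
  lg <- hogs_at_level(forest, level, tree)
  gene2hog <- rep(lg$hog_id, lengths(lg$members))
  names(gene2hog) <- unlist(lg$members, use.names = FALSE)

  if (focal %in% names(gene2hog)) {
    focal_hog <- unname(gene2hog[focal])
  } else if (focal %in% lg$hog_id) {
    focal_hog <- focal
  } else {
    stop("focal '", focal, "' is neither a HOG at level ", level,
         " nor a member gene of one", call. = FALSE)
  }
  focal_node <- .find_node_by_key(forest, lg$node_key[lg$hog_id == focal_hog])

  color_of <- function(gene_ids) {
    cls <- unname(gene2hog[gene_ids])
    cls[is.na(cls)] <- "unrelated"
    cls
  }

  rows <- list()
  # reference ancestral row at `level`
  ord <- ancestral_gene_order(genomes, forest, tree, level,
                              min_weight = min_weight)
  top <- .ancestral_row(focal_hog, ord$contigs, window, level,
                        function(hogs) {
                          cls <- hogs  # a level HOG is its own colour class
                          cls[!(hogs %in% lg$hog_id)] <- "unrelated"
                          cls
                        })
  warn_flag <- is.null(top)
  if (warn_flag) {
    top <- list(node = level, type = "ancestral",
                entries = data.frame(slot = 0L, id = focal_hog,
                                     color_class = focal_hog,
                                     is_focal = TRUE))
  }
  rows[[1]] <- top

  clade <- clade_leaves(tree, level)
  bad <- collapse[!vapply(collapse, function(n)
    n %in% tree$labels && is_ancestor(tree, level, n) && n != level,
    logical(1))]
  if (length(bad)) {
    stop("collapse node(s) not strictly inside the clade of ", level, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  hidden <- unique(unlist(lapply(collapse, clade_leaves, tree = tree)))

  # collapsed ancestral rows
  for (node in collapse) {
    sub_lg <- hogs_at_level(forest, node, tree)
    desc <- .deepest_at_level(focal_node, node, clade_leaves(tree, node), tree)
    if (!length(desc)) next  # focal family absent at this ancestor
    sub_ord <- ancestral_gene_order(genomes, forest, tree, node,
                                    min_weight = min_weight)
    sub_map <- rep(sub_lg$hog_id, lengths(sub_lg$members))
    names(sub_map) <- unlist(sub_lg$members, use.names = FALSE)
    color_sub <- function(hogs) {
      # colour a node-level HOG by the level HOG of one of its members
      vapply(hogs, function(h) {
        mem <- sub_lg$members[[match(h, sub_lg$hog_id)]]
        cls <- unname(gene2hog[mem[1]])
        if (is.na(cls)) "unrelated" else cls
      }, character(1))
    }
    for (d in desc) {
      r <- .ancestral_row(d$hog_id, sub_ord$contigs, window, node, color_sub)
      if (!is.null(r)) rows[[length(rows) + 1L]] <- r
    }
  }

  # extant rows for uncollapsed leaves, in tree order
  focal_members <- lg$members[[match(focal_hog, lg$hog_id)]]
  by_gene <- structure(forest$genes$species, names = forest$genes$gene_id)
  for (sp in clade[!(clade %in% hidden)]) {
    sp_genes <- focal_members[by_gene[focal_members] == sp]
    gm <- Filter(function(g) g$species == sp, genomes)
    if (!length(gm)) next
    gm <- gm[[1]]
    for (g in sp_genes) {
      gi <- match(g, gm$genes$gene_id)
      if (is.na(gi)) next
      contig <- gm$contigs[[gm$genes$contig[gi]]]
      pos <- match(g, contig)
      lo <- max(1L, pos - window); hi <- min(length(contig), pos + window)
      ids <- contig[lo:hi]
      rows[[length(rows) + 1L]] <- list(
        node = sp, type = "extant",
        entries = data.frame(slot = (lo:hi) - pos, id = ids,
                             color_class = color_of(ids),
                             is_focal = ids == g,
                             stringsAsFactors = FALSE))
    }
  }

  structure(list(focal = focal, focal_hog = focal_hog, level = level,
                 window = window, unplaced = warn_flag, rows = rows),
            class = "synteny_view")
}

.ancestral_row <- function(hog, contigs, window, node, color_fun) {
  for (contig in contigs) {
    pos <- match(hog, contig)
    if (!is.na(pos)) {
      lo <- max(1L, pos - window); hi <- min(length(contig), pos + window)
      ids <- contig[lo:hi]
      return(list(node = node, type = "ancestral",
                  entries = data.frame(slot = (lo:hi) - pos, id = ids,
                                       color_class = color_fun(ids),
                                       is_focal = ids == hog,
                                       stringsAsFactors = FALSE)))
    }
  }
  NULL
}

.find_node_by_key <- function(forest, key) {
  rec <- function(node) {
    if (identical(node$node_key, key)) return(node)
    for (k in node$children) {
      r <- rec(k)
      if (!is.null(r)) return(r)
    }
    NULL
  }
  for (root in forest$roots) {
    r <- rec(root)
    if (!is.null(r)) return(r)
  }
  stop("internal error: HOG node ", key, " not found", call. = FALSE)
}

#' @export
print.synteny_view <- function(x, ...) {
  cat(sprintf("<synteny_view> focal %s at %s: %d row(s), window %d\n",
              x$focal_hog, x$level, length(x$rows), x$window))
  invisible(x)
}

#' Serialize a synteny view to JSON
#'
#' @param view A \code{synteny_view}.
#' @param path Optional output file.
#' @return The JSON string (invisibly when written to a file).
#' @export
write_synteny_json <- function(view, path = NULL) {
  payload <- list(
    focal = view$focal, focal_hog = view$focal_hog, level = view$level,
    window = view$window, unplaced = view$unplaced,
    rows = lapply(view$rows, function(r)
      list(node = r$node, type = r$type, entries = r$entries)))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
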