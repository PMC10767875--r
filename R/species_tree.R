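#' Parse a rooted species tree from Newick text
#'
#' Builds the taxonomy backbone used throughout the package: leaves are
#' extant species, internal nodes are the ancestral taxonomic levels at
#' which HOGs (and hence ancestral genomes) are defined. Unary chains are
#' collapsed and unlabeled internal nodes are auto-named \code{N1, N2, ...}
#' in preorder so that every level is addressable.
#'
#' @param newick_text A single Newick string (one tree, terminated by ";").
#' @return An object of class \code{species_tree}: a rooted node table with
#'   unique labels, parent/child pointers and a label index.
#' @examples
#' tr <- parse_species_tree("((A,B)AB,C)ROOT;")
#' clade_leaves(tr, "AB")
#' @export
parse_species_tree <- function(newick_text) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  .check_newick_syntax(newick_text)
  ph <- tryCatch(
    ape::read.tree(text = newick_text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(ph)) {
    stop("malformed Newick: could not be parsed", call. = FALSE)
  }
  if (length(ph$tip.label) < 2L) {
    stop("invalid species tree: internal nodes need >= 2 children",
         call. = FALSE)
  }
  ph <- ape::collapse.singles(ph)
  .species_tree_from_phylo(ph)
}

# cheap syntactic pre-check so parse errors can carry a character offset
.check_newick_syntax <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unbalanced ')' at character offset %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf(
      "malformed Newick: %d unclosed '(' at end of input (offset %d)",
      depth, length(chars)), call. = FALSE)
  }
  if (!grepl(";", s, fixed = TRUE)) {
    stop(sprintf("malformed Newick: missing terminating ';' (offset %d)",
                 length(chars)), call. = FALSE)
  }
  invisible(TRUE)
}

.species_tree_from_phylo <- function(ph) {
  ntip <- length(ph$tip.label)
  nnode <- ph$Nnode
  if (ntip < 2L || nnode < 1L) {
    stop("invalid species tree: internal nodes need >= 2 children",
         call. = FALSE)
  }
  n <- ntip + nnode
  parent <- rep(NA_integer_, n)
  children <- vector("list", n)
  for (i in seq_len(nrow(ph$edge))) {
    p <- ph$edge[i, 1]; c <- ph$edge[i, 2]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  root <- ntip + 1L
  if (any(lengths(children[(ntip + 1L):n]) < 2L)) {
    stop("invalid species tree: internal nodes need >= 2 children",
         call. = FALSE)
  }
  labels <- character(n)
  labels[seq_len(ntip)] <- ph$tip.label
  nl <- ph$node.label
  if (!is.null(nl)) labels[(ntip + 1L):n] <- nl
  # auto-label unnamed internal nodes in preorder
  counter <- 0L
  order_pre <- .preorder_ids(root, children)
  for (id in order_pre) {
    if (id > ntip && (is.na(labels[id]) || labels[id] == "")) {
      repeat {
        counter <- counter + 1L
        cand <- paste0("N", counter)
        if (!cand %in% labels) break
      }
      labels[id] <- cand
    }
  }
  if (anyDuplicated(labels)) {
    stop("duplicate taxon labels in species tree: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  idx <- seq_len(n)
  names(idx) <- labels
  structure(list(
    labels = labels,
    parent = parent,
    children = children,
    root = root,
    n_tips = ntip,
    index = idx
  ), class = "species_tree")
}

.preorder_ids <- function(root, children) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    id <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, id)
    kids <- children[[id]]
    if (length(kids)) stack <- c(kids, stack)
  }
  out
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("<species_tree> %d species, %d ancestral levels; root = %s\n",
              x$n_tips, length(x$labels) - x$n_tips, x$labels[x$root]))
  invisible(x)
}

.node_id <- function(tree, label) {
  id <- tree$index[label]
  if (any(is.na(id))) {
    stop("unknown taxon label(s): ",
         paste(label[is.na(id)], collapse = ", "), call. = FALSE)
  }
  unname(id)
}

#' Species tree accessors
#'
#' `clade_leaves()` lists the extant species under a taxon, `tree_lca()`
#' gives the label of the last common ancestor of a set of taxa,
#' `is_ancestor()` tests ancestor-or-equal relationships, and
#' `internal_levels()` lists all ancestral (internal) taxa in preorder.
#'
#' @param tree A \code{species_tree}.
#' @param label,labels Taxon label(s).
#' @name species-tree-accessors
NULL

#' @rdname species-tree-accessors
#' @export
clade_leaves <- function(tree, label) {
  id <- .node_id(tree, label)
  if (id <= tree$n_tips) return(tree$labels[id])
  out <- integer(0)
  stack <- id
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (cur <= tree$n_tips) out <- c(out, cur)
    else stack <- c(tree$children[[cur]], stack)
  }
  tree$labels[out]
}

.ancestor_ids <- function(tree, id) {
  out <- id
  while (!is.na(tree$parent[id])) {
    id <- tree$parent[id]
    out <- c(out, id)
  }
  out
}

#' @rdname species-tree-accessors
#' @export
tree_lca <- function(tree, labels) {
  ids <- .node_id(tree, unique(labels))
  anc <- .ancestor_ids(tree, ids[1])
  for (id in ids[-1]) {
    anc <- anc[anc %in% .ancestor_ids(tree, id)]
  }
  tree$labels[anc[1]]
}

#' @rdname species-tree-accessors
#' @param ancestor,descendant Taxon labels; `is_ancestor()` is TRUE when
#'   `ancestor` equals `descendant` or lies on its path to the root.
#' @export
is_ancestor <- function(tree, ancestor, descendant) {
  a <- .node_id(tree, ancestor)
  d <- .node_id(tree, descendant)
  a %in% .ancestor_ids(tree, d)
}

#' @rdname species-tree-accessors
#' @export
internal_levels <- function(tree) {
  pre <- .preorder_ids(tree$root, tree$children)
  tree$labels[pre[pre > tree$n_tips]]
}

#' @rdname species-tree-accessors
#' @export
parent_level <- function(tree, label) {
  id <- .node_id(tree, label)
  p <- tree$parent[id]
  if (is.na(p)) NA_character_ else tree$labels[p]
}

#' Serialize a species tree back to Newick
#'
#' @param tree A \code{species_tree}.
#' @return A Newick string with all internal labels.
#' @export
serialize_species_tree <- function(tree) {
  rec <- function(id) {
    if (id <= tree$n_tips) return(tree$labels[id])
    paste0("(", paste(vapply(tree$children[[id]], rec, character(1)),
                      collapse = ","), ")", tree$labels[id])
  }
  paste0(rec(tree$root), ";")
}
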