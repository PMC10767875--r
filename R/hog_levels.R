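# Level-specific ancestral gene extraction.
#
# A node of a HOG tree "qualifies" for a query level L when its own level
# is an ancestor of (or equal to) L and at least one of its member genes
# belongs to a species inside the clade of L. The HOGs *at* L are the
# deepest qualifying nodes: following qualifying children refines the
# family into the sub-HOGs created by duplications at or above L.

.qualifies <- function(node, level, clade, tree) {
  if (is.na(node$level)) return(FALSE)
  if (node$kind == "gene") return(identical(node$level, level))
  is_ancestor(tree, node$level, level) && any(node$member_species %in% clade)
}

.deepest_at_level <- function(node, level, clade, tree) {
  if (!.qualifies(node, level, clade, tree)) return(list())
  qual_kids <- Filter(function(k) .qualifies(k, level, clade, tree),
                      node$children)
  if (!length(qual_kids)) return(list(node))
  unlist(lapply(qual_kids, .deepest_at_level, level = level, clade = clade,
                tree = tree), recursive = FALSE)
}

#' Ancestral genes at a taxonomic level
#'
#' Returns one row per HOG defined at the internal taxon \code{level}: the
#' deepest node of each family whose own level is ancestral to (or equal
#' to) the query and that has extant members inside the clade. Members are
#' restricted to the clade, and the completeness score is the fraction of
#' the clade's species represented in the HOG.
#'
#' @param forest A \code{hog_forest}.
#' @param level An internal taxon label of \code{tree}.
#' @param tree The \code{species_tree}.
#' @param min_completeness Keep HOGs with completeness >= this threshold
#'   (default 0, i.e. no filtering; the browser-style quality filter uses
#'   0.3 — see [filter_completeness()]).
#' @return data.frame with columns hog_id, root_hog_id, hog_level (the
#'   node's own level), node_key, n_members, n_species_present,
#'   completeness, and a list-column \code{members} of clade-restricted
#'   gene ids; rows ordered by hog_id.
#' @export
hogs_at_level <- function(forest, level, tree, min_completeness = 0) {
  id <- .node_id(tree, level)
  if (id <= tree$n_tips) {
    stop("'", level, "' is an extant species; list its genes from the ",
         "extant genome instead", call. = FALSE)
  }
  clade <- clade_leaves(tree, level)
  rows <- list()
  for (root in forest$roots) {
    for (node in .deepest_at_level(root, level, clade, tree)) {
      in_clade <- node$member_species_by_gene %in% clade
      members <- node$members[in_clade]
      spp <- unique(node$member_species_by_gene[in_clade])
      rows[[length(rows) + 1L]] <- list(
        hog_id = node$hog_id, root_hog_id = root$hog_id,
        hog_level = node$level, node_key = node$node_key,
        n_members = length(members), n_species_present = length(spp),
        completeness = length(spp) / length(clade),
        members = list(members))
    }
  }
  if (!length(rows)) {
    out <- data.frame(hog_id = character(0), root_hog_id = character(0),
                      hog_level = character(0), node_key = character(0),
                      n_members = integer(0), n_species_present = integer(0),
                      completeness = numeric(0))
    out$members <- list()
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[setdiff(names(r), "members")], stringsAsFactors = FALSE)))
  out$members <- lapply(rows, function(r) r$members[[1]])
  out <- out[order(out$hog_id), , drop = FALSE]
  rownames(out) <- NULL
  out[out$completeness >= min_completeness, , drop = FALSE]
}

#' Completeness score of an ancestral gene
#'
#' Number of species included in the HOG divided by the total number of
#' species in the clade of its level; ranges over (0, 1] for any HOG
#' returned by [hogs_at_level()].
#'
#' @param gene One row of the [hogs_at_level()] table (or any list with
#'   \code{n_species_present}).
#' @param tree The \code{species_tree}.
#' @param level The taxonomic level the gene was extracted at.
#' @export
completeness_score <- function(gene, tree, level) {
  gene$n_species_present / length(clade_leaves(tree, level))
}

#' Filter ancestral genes by completeness
#'
#' @param genes A [hogs_at_level()] table.
#' @param threshold Minimum completeness score; the default quality filter
#'   keeps HOGs covering at least 30% of the clade's species.
#' @export
filter_completeness <- function(genes, threshold = 0.3) {
  genes[genes$completeness >= threshold, , drop = FALSE]
}

#' Classify per-branch evolutionary events of ancestral genes
#'
#' Compares the ancestral genome at \code{level} with the one at
#' \code{parent_level} (its most recent parental genome) and labels each
#' level HOG: \code{retained} when it is the single descendant of a
#' parent-level HOG, \code{duplicated} when two or more level HOGs descend
#' from one parent-level HOG (all siblings are labelled), and
#' \code{gained} when the family has no counterpart at the parent level
#' (it originated on the branch, i.e. a root HOG at or below
#' \code{level}). Parent-level HOGs with no descendant at \code{level} and
#' no extant member inside the clade are reported as \code{lost}.
#'
#' @param forest A \code{hog_forest}.
#' @param level,parent_level Internal taxon labels; \code{parent_level}
#'   must be an ancestor of \code{level}.
#' @param tree The \code{species_tree}.
#' @return list with \code{events} (named character vector, level hog_id
#'   -> event) and \code{lost} (character vector of parent-level hog_ids).
#' @export
classify_events <- function(forest, level, parent_level, tree) {
  if (identical(level, parent_level) ||
      !is_ancestor(tree, parent_level, level)) {
    stop("'", parent_level, "' is not an ancestor of '", level, "'",
         call. = FALSE)
  }
  clade <- clade_leaves(tree, level)
  parent_genes <- hogs_at_level(forest, parent_level, tree)

  # locate the actual parent-level nodes to recurse below them
  events <- character(0)
  lost <- character(0)
  covered_keys <- character(0)
  by_parent <- list()
  for (root in forest$roots) {
    pnodes <- .deepest_at_level(root, parent_level,
                                clade_leaves(tree, parent_level), tree)
    for (pn in pnodes) {
      desc <- .deepest_at_level(pn, level, clade, tree)
      if (!length(desc)) {
        lost <- c(lost, pn$hog_id)
        by_parent[[pn$hog_id]] <- character(0)
      } else {
        lab <- if (length(desc) >= 2L) "duplicated" else "retained"
        for (d in desc) {
          events[d$hog_id] <- lab
          covered_keys <- c(covered_keys, d$node_key)
        }
        by_parent[[pn$hog_id]] <- vapply(desc, `[[`, character(1), "hog_id")
      }
    }
  }
  level_genes <- hogs_at_level(forest, level, tree)
  gained <- setdiff(level_genes$node_key, covered_keys)
  events[level_genes$hog_id[level_genes$node_key %in% gained]] <- "gained"
  list(events = events[sort(names(events))], lost = sort(lost),
       by_parent = by_parent)
}

#' Assemble an ancestral genome at one taxonomic level
#'
#' Convenience wrapper combining [hogs_at_level()], the completeness
#' filter and [classify_events()] against the most recent parental genome
#' (the parent node in the species tree, unless overridden).
#'
#' @inheritParams hogs_at_level
#' @param parent Parental level for event classification; defaults to the
#'   tree parent of \code{level}. NA at the root (events are then all
#'   \code{gained} by definition and reported as NA).
#' @export
ancestral_genome <- function(forest, level, tree, parent = NULL,
                             min_completeness = 0) {
  genes <- hogs_at_level(forest, level, tree, min_completeness)
  if (is.null(parent)) parent <- parent_level(tree, level)
  lost <- character(0)
  if (!is.na(parent)) {
    ev <- classify_events(forest, level, parent, tree)
    genes$event <- unname(ev$events[genes$hog_id])
    lost <- ev$lost
  } else {
    genes$event <- NA_character_
  }
  structure(list(level = level, parent_level = parent, genes = genes,
                 lost = lost),
            class = "ancestral_genome")
}

#' @export
print.ancestral_genome <- function(x, ...) {
  cat(sprintf("<ancestral_genome> %s: %d ancestral genes", x$level,
              nrow(x$genes)))
  if (!is.na(x$parent_level)) {
    tab <- table(x$genes$event)
    cat(sprintf(" (vs %s: %s; %d lost)", x$parent_level,
                paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
                length(x$lost)))
  }
  cat("\n")
  invisible(x)
}
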