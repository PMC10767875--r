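# Parsimony-style upward propagation of GO annotations through the HOG
# hierarchy: a leaf gene carries the closure of its annotations; an
# internal node is annotated with a term when the fraction of its children
# whose (already propagated) term set contains it reaches the threshold
# tau. Children count once each regardless of subtree size unless
# weight_by_size is requested.

#' Propagate GO annotations from extant genes to ancestral genes
#'
#' @param annotations An \code{annotation_table} over extant gene ids.
#' @param forest A \code{hog_forest}.
#' @param ontology A \code{gene_ontology}.
#' @param tau Child-support threshold in (0, 1]; a term is kept at a node
#'   when at least this fraction of its children carry it (default 0.5,
#'   a majority-of-children parsimony rule).
#' @param weight_by_size Weight children by the number of extant genes
#'   under them instead of equally (default FALSE).
#' @return An \code{ancestral_annotation_set}: data.frame with columns
#'   hog_id, level, node_key, term_id, support. Per node only the most
#'   specific terms are emitted (no term that is an ancestor of another
#'   emitted term with at least equal support).
#' @export
propagate_to_hogs <- function(annotations, forest, ontology, tau = 0.5,
                              weight_by_size = FALSE) {
  stopifnot(tau > 0, tau <= 1)
  leaf_sets <- .subject_closures(annotations, ontology)
  rows <- list()

  emit <- function(node, support) {
    terms <- names(support)
    if (!length(terms)) return(invisible())
    # drop t when a more specific emitted term implies it at >= its support
    redundant <- vapply(terms, function(t) {
      desc <- terms[vapply(terms, function(s)
        t %in% ontology$ancestors[[s]], logical(1))]
      any(support[desc] >= support[[t]])
    }, logical(1))
    keep <- terms[!redundant]
    rows[[length(rows) + 1L]] <<- data.frame(
      hog_id = node$hog_id, level = node$level, node_key = node$node_key,
      term_id = keep, support = unname(support[keep]),
      stringsAsFactors = FALSE)
  }

  walk <- function(node) {
    if (node$kind == "gene") {
      ts <- leaf_sets[[node$gene_id]]
      if (is.null(ts)) ts <- character(0)
      sup <- rep(1, length(ts)); names(sup) <- ts
      return(sup)
    }
    kid_sets <- lapply(node$children, walk)
    wts <- if (weight_by_size)
      vapply(node$children, function(k) length(k$members), numeric(1))
      else rep(1, length(kid_sets))
    wts <- wts / sum(wts)
    all_terms <- unique(unlist(lapply(kid_sets, names), use.names = FALSE))
    sup <- vapply(all_terms, function(t)
      sum(wts[vapply(kid_sets, function(s) t %in% names(s), logical(1))]),
      numeric(1))
    names(sup) <- all_terms
    sup <- sup[sup >= tau - 1e-12]
    emit(node, sup)
    sup
  }

  for (root in forest$roots) walk(root)
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(hog_id = character(0), level = character(0),
                         node_key = character(0), term_id = character(0),
                         support = numeric(0))
  out <- out[order(out$hog_id, out$level, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ancestral_annotation_set", "data.frame")
  out
}

#' Annotations of the ancestral genes at one taxonomic level
#'
#' Restricts a propagated annotation set to the HOGs defined at
#' \code{level} (matching by HOG node, since the node that represents a
#' HOG at a level may itself be labelled with an older level) and returns
#' them as an \code{annotation_table} keyed by the level hog_id, ready for
#' ancestral enrichment.
#'
#' @param propagated An \code{ancestral_annotation_set} from
#'   [propagate_to_hogs()].
#' @param level_genes The [hogs_at_level()] table of the level.
#' @return An \code{annotation_table} (subject_id = hog_id at the level,
#'   term_id, evidence_code) with a \code{support} column retained.
#' @export
level_annotations <- function(propagated, level_genes) {
  rows <- propagated[propagated$node_key %in% level_genes$node_key, ,
                     drop = FALSE]
  hid <- level_genes$hog_id[match(rows$node_key, level_genes$node_key)]
  out <- data.frame(subject_id = hid, term_id = rows$term_id,
                    evidence_code = "IEA", support = rows$support,
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' GO annotation coverage of ancestral genomes
#'
#' For each requested level, the number and fraction of HOGs annotated
#' with at least one propagated GO term — the per-level coverage summary
#' of an annotated clade.
#'
#' @param forest A \code{hog_forest}.
#' @param tree The \code{species_tree}.
#' @param propagated An \code{ancestral_annotation_set}.
#' @param levels Internal taxa to report (default: all, preorder).
#' @return data.frame with columns level, n_annotated, n_total, percent.
#' @export
annotation_coverage <- function(forest, tree, propagated,
                                levels = internal_levels(tree)) {
  do.call(rbind, lapply(levels, function(lv) {
    genes <- hogs_at_level(forest, lv, tree)
    ann <- genes$node_key %in% propagated$node_key
    data.frame(level = lv, n_annotated = sum(ann), n_total = nrow(genes),
               percent = if (nrow(genes)) 100 * sum(ann) / nrow(genes)
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Annotation-frequency statistics of GO terms over a corpus
#'
#' Counts, for every term, the number of subjects in the corpus whose
#' closure contains it; the term probability is that count divided by the
#' count of the namespace root, and the information content is its
#' negative natural logarithm. These statistics feed the simRel semantic
#' similarity and the bubble sizes of the semantic maps.
#'
#' @param corpus Either an \code{annotation_table} or a named list of
#'   subject -> closure-expanded term vectors.
#' @param ontology A \code{gene_ontology}.
#' @return A \code{term_stats} data.frame: term_id, namespace, count,
#'   probability, ic. Terms never annotated in the corpus are absent.
#' @export
term_stats <- function(corpus, ontology) {
  closures <- if (is.data.frame(corpus)) .subject_closures(corpus, ontology)
              else corpus
  if (!length(closures)) stop("empty annotation corpus", call. = FALSE)
  counts <- table(unlist(closures, use.names = FALSE))
  ids <- names(counts)
  ns <- ontology$terms[ids, "namespace"]
  roots <- ids[!vapply(ontology$parents[ids], length, integer(1))]
  root_count <- vapply(split(as.numeric(counts), ns)[unique(ns)], max,
                       numeric(1))
  # the namespace root's count is the maximum by the closure property;
  # use the explicit root when present
  for (r in roots) root_count[ontology$terms[r, "namespace"]] <- counts[[r]]
  p <- as.numeric(counts) / unname(root_count[ns])
  out <- data.frame(term_id = ids, namespace = ns,
                    count = as.integer(counts), probability = p,
                    ic = -log(p), stringsAsFactors = FALSE)
  rownames(out) <- out$term_id
  class(out) <- c("term_stats", "data.frame")
  out
}
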