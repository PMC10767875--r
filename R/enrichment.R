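#' One-sided Fisher's exact test for over-representation
#'
#' Upper hypergeometric tail probability P[X >= n_study] with
#' X ~ Hypergeom(N_pop, n_pop, N_study): the probability of drawing at
#' least \code{n_study} annotated subjects when sampling \code{N_study}
#' subjects without replacement from a population of \code{N_pop} of
#' which \code{n_pop} are annotated.
#'
#' @param n_study Annotated subjects in the study set.
#' @param N_study Size of the study set.
#' @param n_pop Annotated subjects in the population.
#' @param N_pop Size of the population.
#' @return The one-sided p-value (vectorised over its arguments).
#' @export
fisher_overrep <- function(n_study, N_study, n_pop, N_pop) {
  ok <- n_study >= 0 & n_study <= pmin(N_study, n_pop) &
    N_study <= N_pop & n_pop <= N_pop
  if (any(!ok)) {
    stop("invalid 2x2 table: need 0 <= n_study <= min(N_study, n_pop) ",
         "and N_study, n_pop <= N_pop", call. = FALSE)
  }
  stats::phyper(n_study - 1, n_pop, N_pop - n_pop, N_study,
                lower.tail = FALSE)
}

#' Multiple-testing corrections
#'
#' \code{correct_bonferroni()} is \code{min(1, p * m)} with \code{m} the
#' number of tested terms; \code{correct_bh()} is the Benjamini-Hochberg
#' step-up procedure, reported in input order.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @param m Number of tests (defaults to \code{length(pvals)}).
#' @return Adjusted p-values, same order as the input.
#' @export
correct_bonferroni <- function(pvals, m = length(pvals)) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  pmin(1, pvals * m)
}

#' @rdname correct_bonferroni
#' @export
correct_bh <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Parse a whitespace/comma separated identifier list
#'
#' Splits on any mix of spaces, tabs, commas and newlines, drops empty
#' tokens and removes duplicates (warning with the duplicate count).
#'
#' @param text A single string.
#' @return Character vector of unique ids, in first-seen order.
#' @export
parse_id_list <- function(text) {
  toks <- strsplit(paste(text, collapse = "\n"), "[ \t,\r\n]+")[[1]]
  toks <- toks[nzchar(toks)]
  dup <- sum(duplicated(toks))
  if (dup > 0) {
    warning(dup, " duplicate identifier(s) removed from the input list",
            call. = FALSE)
  }
  unique(toks)
}

#' GO over-representation analysis of extant genes or ancestral genes
#'
#' Tests every GO term present in at least one study subject's closure
#' (the default test universe) for over-representation of the study set
#' against the population, using the one-sided Fisher's exact test, and
#' corrects for multiple testing with both Bonferroni and the
#' Benjamini-Hochberg procedure. In ancestral mode, subjects are HOG ids
#' at one stated taxonomic level; in extant mode, subjects are gene ids
#' and the taxonomic level implied by the study species (their last
#' common ancestor) is reported when the forest and tree are supplied.
#'
#' @param study Character vector of subject ids; must be a subset of
#'   \code{population}.
#' @param population Character vector of subject ids: all genes of the
#'   genome of interest (extant mode) or all HOGs at the stated level
#'   (ancestral mode), annotated or not.
#' @param annotations Subject annotations: an \code{annotation_table}, an
#'   \code{ancestral_annotation_set}, or a named list of subject ->
#'   closure-expanded term vectors.
#' @param ontology A \code{gene_ontology}.
#' @param mode \code{"extant"} or \code{"ancestral"}.
#' @param level Taxonomic level of the subjects (required in ancestral
#'   mode).
#' @param alpha Significance threshold on the corrected p-value
#'   (default 0.05).
#' @param method Correction used for the report filter: \code{"bh"}
#'   (default) or \code{"bonferroni"}.
#' @param test_universe \code{"study"} (default: every term hit by the
#'   study) or \code{"population"} (every term annotated in the
#'   population).
#' @param forest,tree Optional, extant mode only: used to report the
#'   taxonomic level implied by the study species.
#' @return An \code{enrichment_result}: data.frame with one row per
#'   reported term (term_id, name, namespace, p_uncorrected,
#'   p_bonferroni, p_bh, n_study, N_study, n_pop, N_pop, ratio_study,
#'   ratio_pop, fold_change and a list-column study_hits), sorted by
#'   p_uncorrected then term_id. Attributes: \code{m} (number of tested
#'   terms), \code{level}, \code{mode}, \code{alpha}, \code{method},
#'   \code{study}, \code{population}.
#' @export
run_enrichment <- function(study, population, annotations, ontology,
                           mode = c("extant", "ancestral"), level = NULL,
                           alpha = 0.05, method = c("bh", "bonferroni"),
                           test_universe = c("study", "population"),
                           forest = NULL, tree = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  test_universe <- match.arg(test_universe)
  study <- unique(study); population <- unique(population)
  if (!all(study %in% population)) {
    stop("study set is not a subset of the population; offending ids: ",
         paste(utils::head(setdiff(study, population), 5), collapse = ", "),
         call. = FALSE)
  }

  closures <- .enrichment_closures(annotations, ontology, mode, level)
  unknown <- setdiff(names(closures), population)
  closures <- closures[names(closures) %in% population]

  if (mode == "ancestral" && is.null(level)) {
    stop("ancestral enrichment requires the taxonomic level of the HOG ids",
         call. = FALSE)
  }
  if (mode == "extant" && !is.null(forest) && !is.null(tree)) {
    spp <- forest$genes$species[match(study, forest$genes$gene_id)]
    spp <- spp[!is.na(spp)]
    if (length(spp)) level <- tree_lca(tree, spp)
  }

  study_cl <- closures[names(closures) %in% study]
  universe <- if (test_universe == "study")
    sort(unique(unlist(study_cl, use.names = FALSE)))
  else sort(unique(unlist(closures, use.names = FALSE)))
  m <- length(universe)

  if (m == 0L) {
    out <- .empty_enrichment()
    attr(out, "m") <- 0L
    attr(out, "level") <- level
    attr(out, "mode") <- mode
    return(out)
  }

  N_study <- length(study); N_pop <- length(population)
  long_subj <- rep(names(closures), lengths(closures))
  long_term <- unlist(closures, use.names = FALSE)
  keep <- long_term %in% universe
  long_subj <- long_subj[keep]; long_term <- long_term[keep]
  n_pop <- as.integer(table(factor(long_term, levels = universe)))
  in_study <- long_subj %in% study
  hits_study <- split(long_subj[in_study],
                      factor(long_term[in_study], levels = universe))
  hits_study <- lapply(hits_study, as.character)
  n_study <- lengths(hits_study)

  p <- fisher_overrep(n_study, N_study, n_pop, N_pop)
  out <- data.frame(
    term_id = universe,
    name = ontology$terms[universe, "name"],
    namespace = ontology$terms[universe, "namespace"],
    p_uncorrected = p,
    p_bonferroni = correct_bonferroni(p, m),
    p_bh = correct_bh(p),
    n_study = as.integer(n_study), N_study = N_study,
    n_pop = as.integer(n_pop), N_pop = N_pop,
    ratio_study = n_study / N_study,
    ratio_pop = n_pop / N_pop,
    stringsAsFactors = FALSE)
  out$fold_change <- out$ratio_study / out$ratio_pop
  out$study_hits <- hits_study
  p_filter <- if (method == "bh") out$p_bh else out$p_bonferroni
  out <- out[p_filter <= alpha, , drop = FALSE]
  out <- out[order(out$p_uncorrected, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "m") <- m
  attr(out, "level") <- level
  attr(out, "mode") <- mode
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  attr(out, "study") <- study
  attr(out, "population") <- population
  if (length(unknown)) attr(out, "unknown_subjects") <- unknown
  out
}

.enrichment_closures <- function(annotations, ontology, mode, level) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    return(annotations)
  }
  if (inherits(annotations, "ancestral_annotation_set")) {
    stop("pass the per-node propagated set through level_annotations() ",
         "to restrict it to the HOGs of one taxonomic level first",
         call. = FALSE)
  }
  .subject_closures(annotations, ontology)
}

.empty_enrichment <- function() {
  out <- data.frame(term_id = character(0), name = character(0),
                    namespace = character(0), p_uncorrected = numeric(0),
                    p_bonferroni = numeric(0), p_bh = numeric(0),
                    n_study = integer(0), N_study = integer(0),
                    n_pop = integer(0), N_pop = integer(0),
                    ratio_study = numeric(0), ratio_pop = numeric(0),
                    fold_change = numeric(0), stringsAsFactors = FALSE)
  out$study_hits <- list()
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d significant term(s) of %s tested",
              nrow(x), attr(x, "m") %||% "?"))
  if (!is.null(attr(x, "level"))) cat(" at level ", attr(x, "level"), sep = "")
  cat("\n")
  if (nrow(x)) {
    print.data.frame(utils::head(
      x[, c("term_id", "namespace", "p_uncorrected", "p_bh", "n_study",
            "n_pop", "fold_change")], 10))
  }
  invisible(x)
}

#' Build a phylostratigraphy study set from branch events
#'
#' Selects the HOG ids at a level whose evolutionary event (relative to
#' the parental genome) matches one of the requested categories, e.g. all
#' genes gained on the branch — the study sets used for phylostratigraphic
#' enrichment.
#'
#' @param forest A \code{hog_forest}.
#' @param tree The \code{species_tree}.
#' @param level,parent Taxon labels passed to [classify_events()].
#' @param events Subset of \code{c("retained", "duplicated", "gained",
#'   "lost")}. \code{"lost"} returns parent-level hog ids.
#' @return Character vector of hog ids.
#' @export
study_from_events <- function(forest, tree, level, parent,
                              events = "gained") {
  events <- match.arg(events, c("retained", "duplicated", "gained", "lost"),
                      several.ok = TRUE)
  cls <- classify_events(forest, level, parent, tree)
  out <- character(0)
  if (any(events %in% c("retained", "duplicated", "gained"))) {
    keep <- cls$events[cls$events %in% setdiff(events, "lost")]
    out <- c(out, names(keep))
  }
  if ("lost" %in% events) out <- c(out, cls$lost)
  sort(unique(out))
}
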