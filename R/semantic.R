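# simRel semantic similarity and the 2-D semantic maps that summarise an
# enrichment result per GO namespace.

#' simRel semantic similarity between two GO terms
#'
#' Over the common ancestors a of t1 and t2 (both terms included in their
#' own closure), simRel is the maximum of
#' \deqn{\frac{2 \ln p(a)}{\ln p(t_1) + \ln p(t_2)} (1 - p(a))}
#' i.e. Lin-style normalisation by the terms' information content times
#' the relevance (1 - p) of the common ancestor. It is 0 when the only
#' common ancestor is the namespace root (p = 1), and for a term with
#' itself it collapses to 1 - p(t).
#'
#' @param t1,t2 Term ids from the same namespace.
#' @param stats A \code{term_stats} table computed over the enrichment
#'   population corpus.
#' @param ontology A \code{gene_ontology}.
#' @return Similarity in [0, 1].
#' @export
simrel <- function(t1, t2, stats, ontology) {
  if (!identical(ontology$terms[t1, "namespace"],
                 ontology$terms[t2, "namespace"])) {
    stop("simRel is defined within one namespace; got ",
         ontology$terms[t1, "namespace"], " vs ",
         ontology$terms[t2, "namespace"], call. = FALSE)
  }
  p <- function(t) stats[t, "probability"]
  common <- intersect(term_closure(t1, ontology), term_closure(t2, ontology))
  common <- common[common %in% stats$term_id]
  if (!length(common)) return(0)
  denom <- log(p(t1)) + log(p(t2))
  if (denom == 0) return(0)  # both terms are roots
  best <- 0
  for (a in common) {
    pa <- p(a)
    if (is.na(pa) || pa >= 1) next  # the root contributes 0
    val <- (2 * log(pa) / denom) * (1 - pa)
    if (val > best) best <- val
  }
  best
}

#' Pairwise simRel matrix of a term set
#'
#' @param terms Term ids (one namespace).
#' @inheritParams simrel
#' @return Symmetric matrix of simRel values with the terms as dimnames.
#' @export
simrel_matrix <- function(terms, stats, ontology) {
  n <- length(terms)
  S <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    for (j in i:n) {
      S[i, j] <- S[j, i] <- simrel(terms[i], terms[j], stats, ontology)
    }
  }
  S
}

#' Classical metric MDS embedding of a similarity matrix
#'
#' Torgerson double-centering on the distance d = 1 - sim, after
#' normalising self-similarities to 1 so identical terms coincide. The
#' embedding is deterministic; the sign of each axis is fixed by forcing
#' its largest-magnitude coordinate positive.
#'
#' @param similarities Symmetric similarity matrix in [0, 1].
#' @return n x 2 coordinate matrix. A single point (or an empty matrix)
#'   embeds at the origin, flagged with attribute \code{degenerate}.
#' @export
mds_embed <- function(similarities) {
  S <- as.matrix(similarities)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-9) {
    stop("similarity matrix must be square and symmetric", call. = FALSE)
  }
  n <- nrow(S)
  if (n < 2L) {
    out <- matrix(0, n, 2, dimnames = list(rownames(S), NULL))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  diag(S) <- 1
  d <- stats::as.dist(1 - S)
  fit <- stats::cmdscale(d, k = min(2L, n - 1L))
  if (ncol(fit) < 2L) {
    fit <- cbind(fit, matrix(0, n, 2L - ncol(fit)))
  }
  for (ax in 1:2) {
    i <- which.max(abs(fit[, ax]))
    if (fit[i, ax] < 0) fit[, ax] <- -fit[, ax]
  }
  dimnames(fit) <- list(rownames(S), NULL)
  fit
}

#' Semantic maps of an enrichment result
#'
#' For each namespace (MF, BP, CC) with at least one significant term,
#' embeds the significant terms in a 2-D semantic space by classical MDS
#' of pairwise simRel similarities. Each point carries the term name, the
#' corrected p-value and the information content (the bubble size in the
#' standard rendering).
#'
#' @param rows An \code{enrichment_result}.
#' @param stats A \code{term_stats} table over the population corpus.
#' @param ontology A \code{gene_ontology}.
#' @param alpha,method Significance filter; default to the values stored
#'   on \code{rows}.
#' @return Named list of \code{semantic_map} data.frames (term_id, name,
#'   x, y, corrected_p, information_content), one per namespace with
#'   significant terms ("up to three maps").
#' @export
export_map <- function(rows, stats, ontology, alpha = NULL, method = NULL) {
  alpha <- alpha %||% attr(rows, "alpha") %||% 0.05
  method <- method %||% attr(rows, "method") %||% "bh"
  pcol <- if (method == "bh") "p_bh" else "p_bonferroni"
  sig <- rows[rows[[pcol]] <= alpha, , drop = FALSE]
  maps <- list()
  for (ns in c("MF", "BP", "CC")) {
    sub <- sig[sig$namespace == ns, , drop = FALSE]
    if (!nrow(sub)) next
    terms <- sub$term_id
    xy <- mds_embed(simrel_matrix(terms, stats, ontology))
    ic <- stats[terms, "ic"]
    ic[is.na(ic)] <- 0
    map <- data.frame(term_id = terms, name = sub$name,
                      x = xy[, 1], y = xy[, 2],
                      corrected_p = sub[[pcol]],
                      information_content = ic,
                      stringsAsFactors = FALSE)
    rownames(map) <- NULL
    class(map) <- c("semantic_map", "data.frame")
    attr(map, "namespace") <- ns
    maps[[ns]] <- map
  }
  maps
}

#' Write semantic maps as JSON and PNG bubble plots
#'
#' One \code{<namespace>.json} (schema: term, name, x, y, p_corrected,
#' ic) and one \code{<namespace>.png} per map.
#'
#' @param maps Output of [export_map()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_semantic_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ns in names(maps)) {
    map <- maps[[ns]]
    js <- jsonlite::toJSON(data.frame(
      term = map$term_id, name = map$name, x = map$x, y = map$y,
      p_corrected = map$corrected_p, ic = map$information_content,
      stringsAsFactors = FALSE), auto_unbox = TRUE, digits = NA)
    jp <- file.path(dir, paste0(ns, ".json"))
    writeLines(js, jp)
    pp <- file.path(dir, paste0(ns, ".png"))
    g <- ggplot2::ggplot(map, ggplot2::aes(
      x = .data$x, y = .data$y, size = .data$information_content,
      colour = -log10(.data$corrected_p))) +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::scale_colour_viridis_c(name = "-log10 corrected p") +
      ggplot2::scale_size_continuous(name = "information content") +
      ggplot2::labs(title = paste0(ns, " semantic map"),
                    x = "semantic dimension 1", y = "semantic dimension 2") +
      ggplot2::theme_minimal()
    grDevices::png(pp, width = 900, height = 700, res = 120)
    print(g)
    grDevices::dev.off()
    paths <- c(paths, jp, pp)
  }
  invisible(paths)
}
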