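#' Parse a Gene Ontology from OBO text
#'
#' Supports the OBO 1.2/1.4 \code{[Term]} stanzas used by the Gene
#' Ontology: \code{id}, \code{name}, \code{namespace}, \code{alt_id},
#' \code{is_a}, \code{relationship: part_of} and \code{is_obsolete}.
#' Both \code{is_a} and \code{part_of} become parent edges; alternative
#' identifiers resolve to their primary term. The parent graph must be a
#' DAG.
#'
#' @param obo_text OBO document as a single string, a character vector of
#'   lines, or a path to an .obo file.
#' @return A \code{gene_ontology}: term table, parent lists, precomputed
#'   ancestor closures and an alt_id map.
#' @export
parse_ontology <- function(obo_text) {
  lines <- .as_lines(obo_text)
  terms <- list(); cur <- NULL; in_term <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms); cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) cur <- list(parents = character(0), alt = character(0),
                               obsolete = FALSE)
      next
    }
    if (!in_term) next
    kv <- regmatches(ln, regexec("^([a-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) next
    key <- kv[2]; val <- kv[3]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "alt_id") cur$alt <- c(cur$alt, val)
    else if (key == "is_a") cur$parents <- c(cur$parents, trimws(val))
    else if (key == "relationship") {
      rel <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(rel) >= 2L && rel[1] == "part_of") {
        cur$parents <- c(cur$parents, rel[2])
      }
    }
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found in OBO input", call. = FALSE)

  ids <- names(terms)
  tab <- data.frame(
    term_id = ids,
    name = vapply(terms, function(t) t$name %||% t$id, character(1)),
    namespace = .aspect_code(vapply(terms, function(t)
      t$namespace %||% NA_character_, character(1))),
    obsolete = vapply(terms, `[[`, logical(1), "obsolete"),
    stringsAsFactors = FALSE)
  rownames(tab) <- ids
  parents <- lapply(terms, function(t) unique(intersect(t$parents, ids)))
  alt <- character(0)
  for (t in terms) if (length(t$alt)) {
    alt[t$alt] <- t$id
  }
  onto <- structure(list(terms = tab, parents = parents, alt = alt),
                    class = "gene_ontology")
  onto$ancestors <- .build_ancestors(onto)
  onto
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.aspect_code <- function(ns) {
  map <- c(biological_process = "BP", molecular_function = "MF",
           cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC")
  out <- unname(map[ns])
  out[is.na(out)] <- ns[is.na(out)]
  out
}

# Full ancestor closure per term (excluding the term itself), memoised in
# topological order; detects cycles.
.build_ancestors <- function(onto) {
  ids <- onto$terms$term_id
  anc <- vector("list", length(ids)); names(anc) <- ids
  state <- integer(length(ids)); names(state) <- ids  # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 2L) return(anc[[id]])
    if (state[[id]] == 1L) stop("cyclic ontology at term ", id, call. = FALSE)
    state[[id]] <<- 1L
    ps <- onto$parents[[id]]
    res <- ps
    for (p in ps) res <- union(res, visit(p))
    anc[[id]] <<- res
    state[[id]] <<- 2L
    res
  }
  for (id in ids) visit(id)
  anc
}

#' @export
print.gene_ontology <- function(x, ...) {
  cat(sprintf("<gene_ontology> %d terms (%s)\n", nrow(x$terms),
              paste(sprintf("%s: %d", names(table(x$terms$namespace)),
                            table(x$terms$namespace)), collapse = ", ")))
  invisible(x)
}

#' Resolve a term id, following alt_id aliases
#' @param ontology A \code{gene_ontology}.
#' @param term_id Character vector of GO ids (primary or alternative).
#' @return Primary ids; NA for unknown ids.
#' @export
resolve_term <- function(ontology, term_id) {
  out <- term_id
  is_alt <- !(out %in% ontology$terms$term_id) & out %in% names(ontology$alt)
  out[is_alt] <- ontology$alt[out[is_alt]]
  out[!(out %in% ontology$terms$term_id)] <- NA_character_
  out
}

#' Term closure under the true-path rule
#'
#' A GO annotation implies all ancestors of the term through is_a/part_of;
#' the closure of a set of terms is the union of the terms and all their
#' ancestors. Obsolete terms are rejected.
#'
#' @param terms Character vector of term ids.
#' @param ontology A \code{gene_ontology}.
#' @return Character vector (sorted, unique).
#' @export
term_closure <- function(terms, ontology) {
  terms <- resolve_term(ontology, terms)
  if (anyNA(terms)) stop("unknown GO term(s) in closure request", call. = FALSE)
  if (any(ontology$terms[terms, "obsolete"])) {
    stop("obsolete term(s) cannot be used in closure: ",
         paste(terms[ontology$terms[terms, "obsolete"]], collapse = ", "),
         call. = FALSE)
  }
  sort(unique(c(terms, unlist(ontology$ancestors[terms], use.names = FALSE))))
}

# Remove rows whose term is an ancestor of another term annotated to the
# same subject (keeps the most specific terms only).
.minimal_terms <- function(terms, ontology) {
  terms <- unique(terms)
  if (length(terms) < 2L) return(terms)
  implied <- unique(unlist(ontology$ancestors[terms], use.names = FALSE))
  setdiff(terms, implied)
}

#' Parse gene annotations from a GAF 2.x file
#'
#' Keeps all evidence codes except \code{ND}; rows with a NOT qualifier
#' are dropped, alternative term ids are mapped to their primary id, rows
#' citing unknown terms are skipped (with a warning giving the count), and
#' the resulting table is made non-redundant per subject: no annotation
#' whose term is an ancestor of another annotation of the same subject.
#'
#' @param gaf_text GAF document (string, lines, or path).
#' @param ontology A \code{gene_ontology}.
#' @return An \code{annotation_table} data.frame with columns
#'   \code{subject_id}, \code{term_id}, \code{evidence_code}.
#' @export
parse_gaf <- function(gaf_text, ontology) {
  lines <- .as_lines(gaf_text)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) {
    return(annotation_table(data.frame(subject_id = character(0),
                                       term_id = character(0),
                                       evidence_code = character(0))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  getf <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1))
  df <- data.frame(subject_id = getf(2), qualifier = getf(4),
                   term_id = getf(5), evidence_code = getf(7),
                   stringsAsFactors = FALSE)
  df <- df[!grepl("NOT", df$qualifier, fixed = TRUE), , drop = FALSE]
  df <- df[df$evidence_code != "ND", , drop = FALSE]
  resolved <- resolve_term(ontology, df$term_id)
  n_skip <- sum(is.na(resolved))
  if (n_skip > 0) {
    warning(n_skip, " GAF row(s) cite GO ids absent from the ontology; skipped",
            call. = FALSE)
  }
  df$term_id <- resolved
  df <- df[!is.na(df$term_id), , drop = FALSE]
  df <- df[!ontology$terms[df$term_id, "obsolete"], , drop = FALSE]
  df$qualifier <- NULL
  annotation_table(df, ontology)
}

#' Construct a non-redundant annotation table
#'
#' @param df data.frame with subject_id, term_id and optionally
#'   evidence_code columns.
#' @param ontology Optional \code{gene_ontology}; when given, redundant
#'   rows (terms that are ancestors of another term of the same subject)
#'   are removed.
#' @export
annotation_table <- function(df, ontology = NULL) {
  if (is.null(df$evidence_code)) df$evidence_code <- "IEA"
  df <- unique(df[, c("subject_id", "term_id", "evidence_code")])
  if (!is.null(ontology) && nrow(df)) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$subject_id), function(i) {
      i[df$term_id[i] %in% .minimal_terms(df$term_id[i], ontology)]
    }), use.names = FALSE)
    df <- df[sort(keep), , drop = FALSE]
  }
  df <- df[order(df$subject_id, df$term_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

# subject -> closure-expanded term sets
.subject_closures <- function(annotations, ontology) {
  lapply(split(annotations$term_id, annotations$subject_id),
         term_closure, ontology = ontology)
}

.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) strsplit(x, "\n", fixed = TRUE)[[1]] else x
}
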