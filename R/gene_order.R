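# Ancestral gene order by adjacency parsimony: extant gene orders are
# projected onto the HOGs of a target level, consecutive HOG pairs are
# counted as supporting contexts, and the resulting weighted graph is
# linearized into ancestral contigs.

#' Project extant gene orders onto the HOGs of a level
#'
#' Every gene is replaced by the identifier of the level HOG it belongs
#' to; genes belonging to no HOG at the level are removed and the gap is
#' closed, so their neighbours become adjacent. Only genomes of species
#' inside the clade of \code{level} are projected.
#'
#' @param genomes List of \code{extant_genome} objects.
#' @param forest A \code{hog_forest}.
#' @param tree The \code{species_tree}.
#' @param level Internal taxon label.
#' @param level_genes Optional precomputed [hogs_at_level()] table.
#' @return List of projections, one per genome: \code{species} plus
#'   \code{contigs}, a list of character vectors of hog_ids.
#' @export
project_genomes <- function(genomes, forest, tree, level, level_genes = NULL) {
  if (is.null(level_genes)) level_genes <- hogs_at_level(forest, level, tree)
  gene2hog <- rep(level_genes$hog_id, lengths(level_genes$members))
  names(gene2hog) <- unlist(level_genes$members, use.names = FALSE)
  clade <- clade_leaves(tree, level)
  genomes <- Filter(function(g) g$species %in% clade, genomes)
  lapply(genomes, function(g) {
    contigs <- lapply(g$contigs, function(genes) {
      h <- unname(gene2hog[genes])
      h[!is.na(h)]
    })
    list(species = g$species, contigs = contigs[lengths(contigs) > 0])
  })
}

#' Build the ancestral adjacency graph of a level
#'
#' Nodes are the HOGs at the level; an edge links two HOGs observed
#' consecutively in a projected extant contig, with weight equal to the
#' number of supporting contexts (one per consecutive occurrence per
#' extant contig; edges are unordered). Tandem pairs (the same HOG twice
#' in a row) are skipped, so the graph has no self-edges.
#'
#' @param projected Output of [project_genomes()].
#' @param level_genes The [hogs_at_level()] table (provides node
#'   completeness and size).
#' @param level Taxon label stored on the graph.
#' @return An \code{adjacency_graph}: \code{nodes} data.frame (hog_id,
#'   completeness, n_members) and \code{edges} data.frame (hog_u, hog_v,
#'   weight) with hog_u < hog_v.
#' @export
build_adjacency_graph <- function(projected, level_genes, level = NA) {
  counts <- new.env(parent = emptyenv())
  for (pg in projected) {
    for (contig in pg$contigs) {
      n <- length(contig)
      if (n < 2L) next
      for (i in seq_len(n - 1L)) {
        a <- contig[i]; b <- contig[i + 1L]
        if (a == b) next  # tandem duplication context
        key <- if (a < b) paste(a, b, sep = "\t") else paste(b, a, sep = "\t")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  keys <- ls(counts)
  if (length(keys)) {
    uv <- do.call(rbind, strsplit(keys, "\t", fixed = TRUE))
    edges <- data.frame(hog_u = uv[, 1], hog_v = uv[, 2],
                        weight = vapply(keys, function(k) counts[[k]],
                                        numeric(1)),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$hog_u, edges$hog_v), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(hog_u = character(0), hog_v = character(0),
                        weight = numeric(0))
  }
  nodes <- level_genes[, c("hog_id", "completeness", "n_members")]
  rownames(nodes) <- NULL
  structure(list(level = level, nodes = nodes, edges = edges),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph> level %s: %d HOGs, %d adjacencies\n",
              x$level, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# ---- linearization ---------------------------------------------------------

# union-find with path compression
.uf_new <- function(n) seq_len(n)
.uf_find <- function(uf, i) {
  while (uf[i] != i) {
    uf[i] <- uf[uf[i]]
    i <- uf[i]
  }
  i
}

# Greedy maximum-weight linear forest: edges by descending weight (ties:
# lexicographically smaller pair first), accepted iff both endpoints keep
# degree <= 2 and no cycle forms. Returns logical acceptance vector over
# the rows of `edges` (assumed pre-sorted).
.linear_forest_greedy <- function(edges, node_ids) {
  deg <- integer(length(node_ids)); names(deg) <- node_ids
  uf <- .uf_new(length(node_ids))
  idx <- match(edges$hog_u, node_ids)
  jdx <- match(edges$hog_v, node_ids)
  accept <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- idx[e]; j <- jdx[e]
    if (deg[i] >= 2L || deg[j] >= 2L) next
    ri <- .uf_find(uf, i); rj <- .uf_find(uf, j)
    if (ri == rj) next
    uf[ri] <- rj
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    accept[e] <- TRUE
  }
  accept
}

# Exact maximum-weight linear forest on one small component by bitmask
# dynamic programming over vertex subsets (path partition DP). `w` is the
# symmetric weight matrix with NA for absent edges. Returns list of paths
# as integer index vectors.
.linear_forest_exact <- function(w) {
  m <- nrow(w)
  full <- bitwShiftL(1L, m) - 1L
  # best path spanning subset S ending at u
  ham <- matrix(-Inf, nrow = full + 1L, ncol = m)
  prev <- matrix(0L, nrow = full + 1L, ncol = m)
  for (v in seq_len(m)) ham[bitwShiftL(1L, v - 1L) + 1L, v] <- 0
  for (S in seq_len(full)) {
    for (u in seq_len(m)) {
      hu <- ham[S + 1L, u]
      if (hu == -Inf) next
      for (v in seq_len(m)) {
        bit <- bitwShiftL(1L, v - 1L)
        if (bitwAnd(S, bit) != 0L || is.na(w[u, v])) next
        S2 <- bitwOr(S, bit)
        cand <- hu + w[u, v]
        if (cand > ham[S2 + 1L, v]) {
          ham[S2 + 1L, v] <- cand
          prev[S2 + 1L, v] <- u
        }
      }
    }
  }
  bestpath <- apply(ham, 1, max)          # -Inf when S spans no single path
  bestend <- apply(ham, 1, which.max)
  # optimal partition of S into vertex-disjoint paths
  f <- rep(0, full + 1L)
  choice <- rep(0L, full + 1L)            # chosen path-subset T (0 = singleton)
  for (S in seq_len(full)) {
    v <- bitwAnd(S, -S)                   # lowest set bit: its node is covered
    best <- f[bitwAnd(S, bitwNot(v)) + 1L]  # as a singleton path
    pick <- 0L
    T <- S
    repeat {
      if (bitwAnd(T, v) != 0L && bestpath[T + 1L] > -Inf) {
        cand <- bestpath[T + 1L] + f[bitwAnd(S, bitwNot(T)) + 1L]
        if (cand > best) { best <- cand; pick <- T }
      }
      if (T == 0L) break
      T <- bitwAnd(T - 1L, S)
    }
    f[S + 1L] <- best
    choice[S + 1L] <- pick
  }
  # reconstruct paths
  paths <- list()
  S <- full
  while (S != 0L) {
    T <- choice[S + 1L]
    if (T == 0L) {
      v <- bitwAnd(S, -S)
      paths[[length(paths) + 1L]] <- as.integer(log2(v)) + 1L
      S <- bitwAnd(S, bitwNot(v))
    } else {
      u <- bestend[T + 1L]
      path <- u
      Sp <- T
      while (prev[Sp + 1L, u] != 0L) {
        nu <- prev[Sp + 1L, u]
        Sp <- bitwAnd(Sp, bitwNot(bitwShiftL(1L, u - 1L)))
        u <- nu
        path <- c(u, path)
      }
      paths[[length(paths) + 1L]] <- path
      S <- bitwAnd(S, bitwNot(T))
    }
  }
  attr(paths, "weight") <- f[full + 1L]
  paths
}

#' Linearize an adjacency graph into ancestral contigs
#'
#' Selects a maximum-weight linear subgraph (every node of degree at most
#' two, no cycles) of the adjacency graph after dropping edges below
#' \code{min_weight}; its connected components are the ancestral contigs,
#' reported in decreasing length. Small connected components (at most
#' \code{max_exact_nodes} nodes) are solved exactly by dynamic
#' programming; larger components fall back to a deterministic greedy
#' sweep over edges by decreasing weight (ties broken towards the
#' lexicographically smaller HOG pair). When the exact optimum does not
#' beat the greedy selection, the greedy (tie-rule) solution is kept, so
#' tie-breaking is identical in both regimes.
#'
#' @param graph An \code{adjacency_graph}.
#' @param min_weight Drop edges with fewer supporting contexts (default 1:
#'   keep all evidence).
#' @param max_exact_nodes Component size limit for the exact solver.
#' @return List of character vectors (hog_id paths), class
#'   \code{ancestral_contigs}, sorted by decreasing length (ties by
#'   smallest hog_id). Singleton HOGs become length-1 contigs.
#' @export
linearize <- function(graph, min_weight = 1, max_exact_nodes = 10) {
  edges <- graph$edges[graph$edges$weight >= min_weight, , drop = FALSE]
  edges <- edges[order(-edges$weight, edges$hog_u, edges$hog_v), , drop = FALSE]
  node_ids <- sort(unique(c(graph$nodes$hog_id, edges$hog_u, edges$hog_v)))

  accept <- .linear_forest_greedy(edges, node_ids)
  acc <- edges[accept, , drop = FALSE]

  # refine each connected component of the *kept* graph exactly when small
  comp <- .components(node_ids, edges)
  final_edges <- list()
  for (nodes_c in comp) {
    in_c <- edges$hog_u %in% nodes_c
    ec <- edges[in_c, , drop = FALSE]
    gc <- acc[acc$hog_u %in% nodes_c, , drop = FALSE]
    if (length(nodes_c) <= max_exact_nodes && nrow(ec)) {
      w <- matrix(NA_real_, length(nodes_c), length(nodes_c))
      iu <- match(ec$hog_u, nodes_c); iv <- match(ec$hog_v, nodes_c)
      for (k in seq_len(nrow(ec))) {
        w[iu[k], iv[k]] <- ec$weight[k]
        w[iv[k], iu[k]] <- ec$weight[k]
      }
      paths <- .linear_forest_exact(w)
      if (attr(paths, "weight") > sum(gc$weight) + 1e-9) {
        for (p in paths) {
          if (length(p) < 2L) next
          final_edges[[length(final_edges) + 1L]] <- data.frame(
            hog_u = nodes_c[p[-length(p)]], hog_v = nodes_c[p[-1]],
            weight = w[cbind(p[-length(p)], p[-1])],
            stringsAsFactors = FALSE)
        }
        next
      }
    }
    if (nrow(gc)) final_edges[[length(final_edges) + 1L]] <- gc
  }
  acc <- if (length(final_edges)) do.call(rbind, final_edges)
         else edges[0, , drop = FALSE]

  contigs <- .paths_from_edges(node_ids, acc)
  ord <- order(-lengths(contigs),
               vapply(contigs, function(p) min(p), character(1)))
  structure(contigs[ord], class = "ancestral_contigs", level = graph$level,
            weight = sum(acc$weight))
}

# connected components of (node_ids, edges); returns list of node-id sets
.components <- function(node_ids, edges) {
  uf <- .uf_new(length(node_ids))
  iu <- match(edges$hog_u, node_ids); iv <- match(edges$hog_v, node_ids)
  for (k in seq_along(iu)) {
    ri <- .uf_find(uf, iu[k]); rj <- .uf_find(uf, iv[k])
    if (ri != rj) uf[ri] <- rj
  }
  roots <- vapply(seq_along(node_ids), function(i) .uf_find(uf, i), integer(1))
  unname(split(node_ids, roots))
}

# walk each path component; orientation starts at the endpoint with the
# smaller hog_id. Unplaced nodes become singleton contigs.
.paths_from_edges <- function(node_ids, acc) {
  adj <- vector("list", length(node_ids)); names(adj) <- node_ids
  for (k in seq_len(nrow(acc))) {
    adj[[acc$hog_u[k]]] <- c(adj[[acc$hog_u[k]]], acc$hog_v[k])
    adj[[acc$hog_v[k]]] <- c(adj[[acc$hog_v[k]]], acc$hog_u[k])
  }
  seen <- character(0)
  contigs <- list()
  deg <- lengths(adj)
  endpoints <- node_ids[deg <= 1L]
  for (start in sort(endpoints)) {
    if (start %in% seen) next
    path <- start
    prev <- NA_character_
    cur <- start
    repeat {
      nxt <- setdiff(adj[[cur]], prev)
      if (!length(nxt)) break
      prev <- cur; cur <- nxt[1]
      path <- c(path, cur)
    }
    # orient towards the smaller endpoint
    if (path[length(path)] < path[1]) path <- rev(path)
    contigs[[length(contigs) + 1L]] <- path
    seen <- c(seen, path)
  }
  contigs
}

#' @export
print.ancestral_contigs <- function(x, ...) {
  cat(sprintf("<ancestral_contigs> level %s: %d contig(s), lengths %s\n",
              attr(x, "level"), length(x),
              paste(utils::head(lengths(x), 10), collapse = ",")))
  invisible(x)
}

#' Full ancestral gene-order reconstruction at a level
#'
#' Projection, adjacency counting and linearization in one call.
#'
#' @inheritParams project_genomes
#' @inheritParams linearize
#' @return list with \code{graph} (adjacency_graph) and \code{contigs}
#'   (ancestral_contigs).
#' @export
ancestral_gene_order <- function(genomes, forest, tree, level,
                                 min_weight = 1, min_completeness = 0) {
  lg <- hogs_at_level(forest, level, tree, min_completeness)
  proj <- project_genomes(genomes, forest, tree, level, level_genes = lg)
  graph <- build_adjacency_graph(proj, lg, level)
  list(graph = graph, contigs = linearize(graph, min_weight = min_weight))
}
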