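# Synthetic clade simulator with planted ground truth.
#
# A root genome of single-copy genes evolves down a species tree; on each
# branch duplications, gains, losses and inversions are applied (in that
# order). The simulator emits exactly the four standard inputs the parsers
# read — Newick, OrthoXML, gene-order TSV, OBO + GAF — plus the planted
# truth (per-node gene content and order, per-branch events, ancestral
# term sets), so reconstruction can be checked end to end.

#' Simulation configuration
#'
#' Event counts per branch are Poisson with the given expectations; event
#' positions are uniform. Duplicate copies are inserted adjacent to their
#' template so zero-inversion simulations stay collinear.
#'
#' @param n_species Number of extant species.
#' @param tree_shape "balanced", "caterpillar" or "random".
#' @param n_ancestral_genes Genes in the root genome (one contig).
#' @param gain_rate,loss_rate,dup_rate Expected events per branch.
#' @param n_inversions Expected inversions per branch (Poisson).
#' @param ontology_size Total number of GO terms across the three
#'   namespaces (minimum 9).
#' @param terms_per_gene Specific (leaf) terms planted on each gene family.
#' @param annotation_noise Probability that an extant gene receives one
#'   additional random (spurious) leaf-term annotation.
#' @param seed Integer seed fixing every draw.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_species = 10, tree_shape = "balanced",
                              n_ancestral_genes = 100,
                              gain_rate = 5, loss_rate = 5, dup_rate = 3,
                              n_inversions = 1,
                              ontology_size = 150, terms_per_gene = 3,
                              annotation_noise = 0.05, seed = 1) {
  stopifnot(n_species >= 2, n_ancestral_genes >= 1,
            gain_rate >= 0, loss_rate >= 0, dup_rate >= 0,
            n_inversions >= 0, ontology_size >= 9,
            annotation_noise >= 0, annotation_noise <= 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a clade with planted ground truth
#'
#' @param config A [simulation_config()].
#' @return A \code{clade_simulation} list: \code{newick},
#'   \code{orthoxml}, \code{gene_orders} (TSV text), \code{obo},
#'   \code{gaf} (input texts) and \code{truth} (planted ground truth: per
#'   internal node \code{content} — ordered copy ids —, \code{family_of}
#'   copy -> family map, per-branch \code{events}, \code{term_sets} per
#'   family, and the tree).
#' @export
simulate_clade <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  tree <- .sim_tree(config$n_species, config$tree_shape)
  depth_warning <- config$loss_rate *
    max(lengths(lapply(seq_len(tree$n_tips), .ancestor_ids, tree = tree))) >=
    config$n_ancestral_genes
  if (depth_warning) {
    warning("loss rate x tree depth reaches the root genome size: ",
            "genomes may go extinct", call. = FALSE)
  }

  sim <- new.env(parent = emptyenv())
  sim$next_uid <- 0L
  sim$next_family <- 0L
  sim$copies <- list()     # uid -> list(family, parent_uid, node)
  sim$content <- list()    # node label -> ordered uid vector
  sim$events <- list()     # child label -> data.frame(family, event)
  sim$copy_events <- list()
  sim$branch_counts <- list()
  sim$family_origin <- character(0)  # family -> node label of origin

  new_copy <- function(family, parent_uid, node_label) {
    sim$next_uid <- sim$next_uid + 1L
    uid <- paste0("g", sprintf("%05d", sim$next_uid))
    sim$copies[[uid]] <- list(family = family, parent_uid = parent_uid,
                              node = node_label)
    uid
  }
  new_family <- function(origin_label) {
    sim$next_family <- sim$next_family + 1L
    fam <- paste0("F", sprintf("%04d", sim$next_family))
    sim$family_origin[fam] <- origin_label
    fam
  }

  root_label <- tree$labels[tree$root]
  root_genome <- vapply(seq_len(config$n_ancestral_genes), function(i)
    new_copy(new_family(root_label), NA_character_, root_label),
    character(1))
  sim$content[[root_label]] <- root_genome

  evolve <- function(node_id) {
    label <- tree$labels[node_id]
    genome <- sim$content[[label]]
    for (child_id in tree$children[[node_id]]) {
      child <- tree$labels[child_id]
      fam_of <- vapply(genome, function(u) sim$copies[[u]]$family,
                       character(1))
      # descend every surviving copy into the child
      g <- unname(vapply(genome, function(u)
        new_copy(sim$copies[[u]]$family, u, child), character(1)))
      parent_fams <- unique(fam_of)
      ev <- character(0)

      n_dup <- min(stats::rpois(1, config$dup_rate), length(g))
      for (k in seq_len(n_dup)) {
        i <- sample.int(length(g), 1)
        tmpl <- g[i]
        extra <- new_copy(sim$copies[[tmpl]]$family,
                          sim$copies[[tmpl]]$parent_uid, child)
        g <- append(g, extra, after = i)  # adjacent to the template
        ev[sim$copies[[tmpl]]$family] <- "duplicated"
      }
      n_gain <- stats::rpois(1, config$gain_rate)
      gained_fams <- character(0)
      for (k in seq_len(n_gain)) {
        fam <- new_family(child)
        gained_fams <- c(gained_fams, fam)
        u <- new_copy(fam, NA_character_, child)
        g <- append(g, u, after = sample.int(length(g) + 1L, 1) - 1L)
      }
      n_loss <- min(stats::rpois(1, config$loss_rate), length(g))
      if (n_loss > 0 && length(g)) {
        drop <- sample.int(length(g), n_loss)
        g <- g[-drop]
      }
      n_inv <- stats::rpois(1, config$n_inversions)
      inv_applied <- 0L
      for (k in seq_len(n_inv)) {
        if (length(g) < 2L) break
        ij <- sort(sample.int(length(g), 2))
        g[ij[1]:ij[2]] <- rev(g[ij[1]:ij[2]])
        inv_applied <- inv_applied + 1L
      }

      child_fams <- unique(vapply(g, function(u) sim$copies[[u]]$family,
                                  character(1)))
      lost_fams <- setdiff(parent_fams, child_fams)
      ev[lost_fams] <- "lost"
      retained <- setdiff(parent_fams, c(lost_fams, names(ev)))
      ev[retained] <- "retained"
      ev[intersect(gained_fams, child_fams)] <- "gained"
      sim$events[[child]] <- data.frame(family = names(ev),
                                        event = unname(ev),
                                        stringsAsFactors = FALSE)
      # copy-resolution truth: surviving children per parent copy
      surv_parent <- vapply(g, function(u) {
        p <- sim$copies[[u]]$parent_uid
        if (is.na(p)) NA_character_ else p
      }, character(1))
      sim$copy_events[[child]] <- data.frame(
        parent_uid = genome, family = fam_of,
        n_children = vapply(genome, function(p)
          sum(surv_parent == p, na.rm = TRUE), integer(1)),
        stringsAsFactors = FALSE)
      sim$branch_counts[[child]] <- c(parent = length(genome),
                                      duplications = n_dup, gains = n_gain,
                                      losses = n_loss,
                                      inversions = inv_applied,
                                      child = length(g))
      sim$content[[child]] <- g
      if (child_id > tree$n_tips) evolve(child_id)
    }
  }
  evolve(tree$root)

  ontology <- .sim_ontology(config$ontology_size)
  planted_terms <- .sim_family_terms(names(sim$family_origin), ontology,
                                     config$terms_per_gene)
  gaf <- .sim_gaf(sim, tree, planted_terms, ontology,
                  config$annotation_noise)

  forest <- .sim_forest(sim, tree)
  orders <- .sim_orders(sim, tree)

  copies_df <- data.frame(
    uid = names(sim$copies),
    family = vapply(sim$copies, `[[`, character(1), "family"),
    parent_uid = vapply(sim$copies, `[[`, character(1), "parent_uid"),
    node = vapply(sim$copies, `[[`, character(1), "node"),
    row.names = NULL, stringsAsFactors = FALSE)
  truth <- list(
    tree = tree,
    copies = copies_df,
    content = sim$content,
    family_of = vapply(sim$copies, `[[`, character(1), "family"),
    family_origin = sim$family_origin,
    events = sim$events,
    copy_events = sim$copy_events,
    branch_counts = sim$branch_counts,
    term_sets = planted_terms$family_terms,
    forest = forest)

  structure(list(
    config = config,
    newick = serialize_species_tree(tree),
    orthoxml = write_orthoxml(forest, origin = "paleohog-sim"),
    gene_orders = orders,
    obo = planted_terms$obo,
    gaf = gaf,
    truth = truth), class = "clade_simulation")
}

#' @export
print.clade_simulation <- function(x, ...) {
  cat(sprintf(paste0("<clade_simulation> seed %d: %d species, ",
                     "%d root genes, %d families\n"),
              x$config$seed, x$config$n_species,
              x$config$n_ancestral_genes, length(x$truth$family_origin)))
  invisible(x)
}

# ---- tree shapes -----------------------------------------------------------

.sim_tree <- function(n, shape) {
  leaf <- function(i) sprintf("S%02d", i)
  build_balanced <- function(lo, hi) {
    if (lo == hi) return(leaf(lo))
    mid <- lo + (hi - lo) %/% 2
    paste0("(", build_balanced(lo, mid), ",",
           build_balanced(mid + 1, hi), ")")
  }
  nwk <- switch(shape,
    balanced = paste0(build_balanced(1, n), ";"),
    caterpillar = {
      s <- leaf(1)
      for (i in 2:n) s <- paste0("(", s, ",", leaf(i), ")")
      paste0(s, ";")
    },
    random = {
      parts <- vapply(seq_len(n), leaf, character(1))
      while (length(parts) > 1L) {
        ij <- sample.int(length(parts), 2)
        merged <- paste0("(", parts[ij[1]], ",", parts[ij[2]], ")")
        parts <- c(parts[-ij], merged)
      }
      paste0(parts, ";")
    },
    stop("unknown tree_shape: ", shape, call. = FALSE))
  parse_species_tree(nwk)
}

# ---- OrthoXML assembly from the copy genealogy -----------------------------

# Family trees: for each family, nested groups follow the species tree
# from the origin node of the founder copy; >= 2 copies descending from
# one parent copy on a branch form a paralogGroup.
.sim_forest <- function(sim, tree) {
  copies <- sim$copies
  uids <- names(copies)
  fam_of <- vapply(copies, `[[`, character(1), "family")
  node_of <- vapply(copies, `[[`, character(1), "node")
  parent_of <- vapply(copies, `[[`, character(1), "parent_uid")
  kids_of <- split(uids, factor(parent_of, levels = uids))

  # copies present in a node's genome (survivors only)
  surviving <- new.env(parent = emptyenv())
  for (lbl in names(sim$content)) {
    for (u in sim$content[[lbl]]) surviving[[u]] <- TRUE
  }
  alive <- function(u) isTRUE(surviving[[u]])

  # does copy u (alive at `node`) have extant descendants?
  has_extant <- function(u, node_id) {
    if (node_id <= tree$n_tips) return(alive(u))
    any(vapply(kids_of[[u]], function(k) {
      kid_node <- .node_id(tree, copies[[k]]$node)
      alive(k) && has_extant(k, kid_node)
    }, logical(1)))
  }

  key_env <- new.env(parent = emptyenv()); key_env$n <- 0L
  next_key <- function() {
    key_env$n <- key_env$n + 1L
    paste0("h", key_env$n)
  }

  build <- function(u, node_id, hog_id) {
    label <- tree$labels[node_id]
    if (node_id <= tree$n_tips) {
      return(list(node_key = next_key(), hog_id = hog_id, level = label,
                  kind = "gene", gene_id = u, species = label,
                  children = list(), members = u, member_species = label,
                  member_species_by_gene = label))
    }
    children <- list()
    dup_counter <- 0L
    for (child_id in tree$children[[node_id]]) {
      child_label <- tree$labels[child_id]
      ks <- kids_of[[u]]
      ks <- ks[vapply(ks, function(k)
        copies[[k]]$node == child_label && alive(k) &&
          has_extant(k, child_id), logical(1))]
      if (!length(ks)) next
      if (length(ks) == 1L) {
        children[[length(children) + 1L]] <- build(ks, child_id, hog_id)
      } else {
        dup_counter <- dup_counter + 1L
        sub <- lapply(seq_along(ks), function(i)
          build(ks[i], child_id,
                paste0(hog_id, ".", dup_counter, letters[i])))
        mem <- unlist(lapply(sub, `[[`, "members"), use.names = FALSE)
        msp <- unlist(lapply(sub, `[[`, "member_species_by_gene"),
                      use.names = FALSE)
        children[[length(children) + 1L]] <- list(
          node_key = next_key(), hog_id = hog_id,
          level = tree_lca(tree, msp), kind = "paralog", children = sub,
          members = mem, member_species = unique(msp),
          member_species_by_gene = msp)
      }
    }
    mem <- unlist(lapply(children, `[[`, "members"), use.names = FALSE)
    msp <- unlist(lapply(children, `[[`, "member_species_by_gene"),
                  use.names = FALSE)
    list(node_key = next_key(), hog_id = hog_id, level = label,
         kind = "ortholog", children = children, members = mem,
         member_species = unique(msp), member_species_by_gene = msp)
  }

  founders <- uids[is.na(parent_of)]
  founders <- founders[vapply(founders, function(u)
    alive(u) && has_extant(u, .node_id(tree, copies[[u]]$node)),
    logical(1))]
  # stable family order
  founders <- founders[order(fam_of[founders])]
  roots <- lapply(founders, function(u) {
    r <- build(u, .node_id(tree, copies[[u]]$node),
               paste0("HOG:", fam_of[[u]]))
    if (r$kind == "gene") {
      # terminal-branch gain: wrap the single gene in an ortholog group
      key_env$n <- key_env$n + 1L
      r <- list(node_key = paste0("h", key_env$n), hog_id = r$hog_id,
                level = r$species, kind = "ortholog", children = list(r),
                members = r$members, member_species = r$member_species,
                member_species_by_gene = r$member_species_by_gene)
    }
    r
  })
  genes <- if (length(roots)) {
    do.call(rbind, lapply(roots, function(r)
      data.frame(gene_id = r$members, species = r$member_species_by_gene,
                 root_hog_id = r$hog_id, stringsAsFactors = FALSE)))
  } else {
    data.frame(gene_id = character(0), species = character(0),
               root_hog_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(genes) <- NULL
  structure(list(roots = roots, genes = genes, n_nodes = key_env$n),
            class = "hog_forest")
}

# ---- extant gene orders ----------------------------------------------------

.sim_orders <- function(sim, tree) {
  sp <- tree$labels[seq_len(tree$n_tips)]
  lines <- c("species\tcontig\tstart\tgene_id")
  for (s in sp) {
    g <- sim$content[[s]]
    if (!length(g)) next
    lines <- c(lines, sprintf("%s\tc1\t%d\t%s", s,
                              (seq_along(g) - 1L) * 100L, g))
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

# ---- ontology and annotations ----------------------------------------------

# Random layered DAG under three namespace roots.
.sim_ontology <- function(size) {
  ns <- c("biological_process", "molecular_function", "cellular_component")
  per <- diff(round(seq(0, size, length.out = 4)))
  term_id <- function(k) sprintf("GO:%07d", k)
  k <- 0L
  stanzas <- character(0)
  for (i in seq_along(ns)) {
    k <- k + 1L
    root <- term_id(k)
    stanzas <- c(stanzas, sprintf(
      "[Term]\nid: %s\nname: %s\nnamespace: %s\n", root, ns[i], ns[i]))
    n_terms <- max(per[i] - 1L, 2L)
    layers <- list(root)
    for (t in seq_len(n_terms)) {
      k <- k + 1L
      id <- term_id(k)
      depth <- min(1L + (t - 1L) %/% 5L, length(layers))
      pool <- layers[[depth]]
      n_par <- min(length(pool), sample.int(2L, 1))
      parents <- sample(pool, n_par)
      rel <- c(sprintf("is_a: %s ! parent", parents[1]),
               if (n_par > 1L)
                 sprintf("relationship: part_of %s ! parent", parents[2]))
      stanzas <- c(stanzas, sprintf(
        "[Term]\nid: %s\nname: synthetic term %d\nnamespace: %s\n%s\n",
        id, k, ns[i], paste(rel, collapse = "\n")))
      if (depth + 1L > length(layers)) layers[[depth + 1L]] <- character(0)
      layers[[depth + 1L]] <- c(layers[[depth + 1L]], id)
    }
  }
  obo <- paste0("format-version: 1.2\nontology: synthetic-go\n\n",
                paste(stanzas, collapse = "\n"))
  onto <- parse_ontology(obo)
  leaf_terms <- onto$terms$term_id[
    !onto$terms$term_id %in%
      unique(unlist(onto$parents, use.names = FALSE))]
  list(obo = obo, ontology = onto, leaf_terms = leaf_terms)
}

.sim_family_terms <- function(families, onto, terms_per_gene) {
  leaf_terms <- onto$leaf_terms
  fam_terms <- lapply(families, function(f)
    sample(leaf_terms, min(terms_per_gene, length(leaf_terms))))
  names(fam_terms) <- families
  list(obo = onto$obo, ontology = onto$ontology,
       family_terms = fam_terms, leaf_terms = leaf_terms)
}

.sim_gaf <- function(sim, tree, planted, onto, noise) {
  sp <- tree$labels[seq_len(tree$n_tips)]
  rows <- character(0)
  aspect <- c(BP = "P", MF = "F", CC = "C")
  onto_tab <- planted$ontology$terms
  for (s in sp) {
    for (u in sim$content[[s]]) {
      fam <- sim$copies[[u]]$family
      terms <- planted$family_terms[[fam]]
      if (noise > 0 && stats::runif(1) < noise) {
        terms <- unique(c(terms, sample(planted$leaf_terms, 1)))
      }
      for (t in terms) {
        rows <- c(rows, paste(
          "paleosim", u, u, "", t, "SYN:0000001", "IEA", "",
          aspect[[onto_tab[t, "namespace"]]], "", "", "protein",
          "taxon:1", "20230101", "paleosim", "", "", sep = "\t"))
      }
    }
  }
  paste0("!gaf-version: 2.2\n", paste(rows, collapse = "\n"), "\n")
}

#' Write all simulated inputs to a directory
#'
#' @param sim A \code{clade_simulation}.
#' @param dir Output directory.
#' @return Invisibly, the file paths (tree.nwk, hogs.orthoxml,
#'   gene_orders.tsv, go.obo, annotations.gaf, truth.json).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             hogs = file.path(dir, "hogs.orthoxml"),
             orders = file.path(dir, "gene_orders.tsv"),
             obo = file.path(dir, "go.obo"),
             gaf = file.path(dir, "annotations.gaf"),
             truth = file.path(dir, "truth.json"))
  writeLines(sim$newick, paths["tree"])
  writeLines(sub("\n$", "", sim$orthoxml), paths["hogs"])
  writeLines(sub("\n$", "", sim$gene_orders), paths["orders"])
  writeLines(sim$obo, paths["obo"])
  writeLines(sub("\n$", "", sim$gaf), paths["gaf"])
  truth <- list(
    content = sim$truth$content,
    family_of = as.list(sim$truth$family_of),
    family_origin = as.list(sim$truth$family_origin),
    events = sim$truth$events,
    term_sets = sim$truth$term_sets)
  writeLines(jsonlite::toJSON(truth, auto_unbox = FALSE, digits = NA),
             paths["truth"])
  invisible(paths)
}
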