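#' Read extant gene orders
#'
#' Accepts either GFF3 (rows of type \code{gene}; 1-based inclusive
#' coordinates, converted internally to 0-based half-open) or a simple TSV
#' dialect with columns \code{species}, \code{contig}, \code{start},
#' \code{gene_id} (start already 0-based). Genes are ranked by ascending
#' start within each contig; strand is recorded from GFF3 for display but
#' never used downstream (adjacencies are unordered).
#'
#' @param path_or_text File path, or the file content as a string.
#' @param format \code{"gff3"} or \code{"tsv"}.
#' @param species Species label; required for GFF3 (which carries none).
#' @return A list of \code{extant_genome} objects, each with a
#'   \code{genes} data.frame (gene_id, contig, start, rank, strand) sorted
#'   by contig and rank.
#' @export
parse_gene_orders <- function(path_or_text, format = c("tsv", "gff3"),
                              species = NULL) {
  format <- match.arg(format)
  if (format == "gff3") {
    if (is.null(species)) stop("GFF3 input needs an explicit `species`",
                               call. = FALSE)
    path <- .as_path(path_or_text, ".gff3")
    gff <- rtracklayer::readGFF(path, filter = list(type = "gene"))
    gid <- if (!is.null(gff$ID)) as.character(gff$ID) else as.character(gff$Name)
    df <- data.frame(species = species,
                     contig = as.character(gff$seqid),
                     start = as.integer(gff$start) - 1L,  # 1-based -> 0-based
                     gene_id = gid,
                     strand = as.character(gff$strand),
                     stringsAsFactors = FALSE)
  } else {
    path <- .as_path(path_or_text, ".tsv")
    df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
    need <- c("species", "contig", "start", "gene_id")
    if (!all(need %in% names(df))) {
      stop("gene-order TSV needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    df$start <- as.integer(df$start)
    df$strand <- if ("strand" %in% names(df)) as.character(df$strand) else "+"
  }
  lapply(split(df, df$species), .make_extant_genome)
}

.make_extant_genome <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id within species '", df$species[1], "': ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$contig, df$start, df$gene_id), , drop = FALSE]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$contig)[unique(df$contig)],
                           function(i) seq_along(i) - 1L), use.names = FALSE)
  rownames(df) <- NULL
  structure(list(species = df$species[1],
                 genes = df[, c("gene_id", "contig", "start", "rank", "strand")],
                 contigs = split(df$gene_id, df$contig)),
            class = "extant_genome")
}

#' @export
print.extant_genome <- function(x, ...) {
  cat(sprintf("<extant_genome> %s: %d genes on %d contig(s)\n",
              x$species, nrow(x$genes), length(x$contigs)))
  invisible(x)
}

#' Serialize extant genomes to the gene-order TSV dialect
#'
#' @param genomes List of \code{extant_genome} objects.
#' @param path Optional output file; when NULL the TSV is returned as a string.
#' @export
write_gene_orders <- function(genomes, path = NULL) {
  df <- do.call(rbind, lapply(genomes, function(g) {
    cbind(species = g$species,
          g$genes[, c("contig", "start", "gene_id")])
  }))
  rownames(df) <- NULL
  txt <- paste0("species\tcontig\tstart\tgene_id\n",
                paste(df$species, df$contig, df$start, df$gene_id,
                      sep = "\t", collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}

# Accept either an existing path or raw text (written to a temp file).
.as_path <- function(x, ext) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(x)
  }
  tf <- tempfile(fileext = ext)
  writeLines(x, tf)
  tf
}
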