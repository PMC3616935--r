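# Input parsing and validation: codon alignments (FASTA), trees (Newick with
# optional #1 foreground tags), pathway edge lists and annotation tables (TSV).

#' Construct a codon alignment
#'
#' @param gene_id Gene identifier.
#' @param taxa Ordered taxon labels.
#' @param sites Integer matrix (taxa x codon sites) of 1-based sense-codon
#'   indices; `NA` marks missing codons (gaps/ambiguity).
#' @return Object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene_id, taxa, sites) {
  if (length(taxa) < 2) stop("an alignment needs at least 2 taxa")
  if (!is.matrix(sites) || nrow(sites) != length(taxa)) {
    stop("sites must be a matrix with one row per taxon")
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon labels")
  storage.mode(sites) <- "integer"
  rownames(sites) <- taxa
  structure(list(gene_id = gene_id, taxa = taxa, sites = sites),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment", x$gene_id %||% "", ":", length(x$taxa), "taxa x",
      ncol(x$sites), "codon sites,", sum(is.na(x$sites)), "missing cells\n")
  invisible(x)
}

#' Read a codon-aligned FASTA file
#'
#' Records must share one length divisible by 3.  Codons containing gaps
#' (`-`) or ambiguity characters become missing cells; stop codons are
#' rejected with the offending taxon and site.
#'
#' @param path FASTA file of aligned coding sequences.
#' @param code A `genetic_code`.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path, code = universal_code(),
                                 gene_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2) stop("alignment needs at least 2 records")
  strs <- toupper(as.character(seqs))
  names(strs) <- sub("\\s.*$", "", names(seqs))
  codon_alignment_from_strings(strs, code,
                               gene_id %||% tools::file_path_sans_ext(basename(path)))
}

# shared by the FASTA reader and the simulator round-trip
codon_alignment_from_strings <- function(strs, code = universal_code(),
                                         gene_id = NULL) {
  lens <- nchar(strs)
  if (length(unique(lens)) != 1) {
    bad <- names(strs)[lens != lens[1]][1]
    stop("alignment length mismatch at record '", bad, "' (",
         lens[names(strs) == bad][1], " vs ", lens[1], " nt)")
  }
  if (lens[1] %% 3 != 0) {
    stop("alignment length ", lens[1], " is not divisible by 3")
  }
  n_site <- lens[1] %/% 3
  idx <- code$codon_index
  sites <- matrix(NA_integer_, length(strs), n_site)
  for (i in seq_along(strs)) {
    codons <- substring(strs[i], 3 * seq_len(n_site) - 2, 3 * seq_len(n_site))
    stop_hit <- codons %in% code$stop_codons
    if (any(stop_hit)) {
      stop("stop codon ", codons[which(stop_hit)[1]], " in record '",
           names(strs)[i], "' at codon site ", which(stop_hit)[1])
    }
    sites[i, ] <- unname(idx[codons])   # unknown/gapped codons -> NA
  }
  codon_alignment(gene_id, names(strs), sites)
}

#' Write a codon alignment as FASTA
#'
#' Missing cells are written as `---`.
#'
#' @param alignment A `codon_alignment`.
#' @param path Output file.
#' @param code Genetic code.
#' @export
write_codon_alignment <- function(alignment, path, code = universal_code()) {
  sense <- code$sense_codons
  lines <- character(2 * length(alignment$taxa))
  for (i in seq_along(alignment$taxa)) {
    s <- alignment$sites[i, ]
    codons <- ifelse(is.na(s), "---", sense[s])
    lines[2 * i - 1] <- paste0(">", alignment$taxa[i])
    lines[2 * i] <- paste(codons, collapse = "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Newick tree, honoring codeml-style foreground tags
#'
#' A `#1` suffix on a tip or internal-node label marks the branch above that
#' node as foreground for branch-site models; the tag is stripped from the
#' label and recorded on the tree (see [foreground_nodes()]).  Trees without
#' branch lengths get a configurable default.
#'
#' @param path Newick file, or a literal Newick string via `text`.
#' @param text Optional Newick string (overrides `path`).
#' @param default_bl Branch length to assign when the tree carries none.
#' @return A `phylo` with a foreground attribute.
#' @export
read_tree <- function(path = NULL, text = NULL, default_bl = 0.1) {
  tree <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else {
      if (!file.exists(path)) stop("no such file: ", path)
      ape::read.tree(path)
    },
    error = function(e) stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned nothing")
  fg <- integer(0)
  strip <- function(labels, offset) {
    tagged <- grepl("#1$", labels)
    if (any(tagged)) {
      fg <<- c(fg, which(tagged) + offset)
      labels[tagged] <- sub("\\s*#1$", "", labels[tagged])
    }
    labels
  }
  tree$tip.label <- strip(tree$tip.label, 0L)
  if (!is.null(tree$node.label)) {
    tree$node.label <- strip(tree$node.label, length(tree$tip.label))
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(default_bl, nrow(tree$edge))
  }
  attr(tree, "foreground") <- fg
  tree
}

#' Write a tree to Newick, re-adding foreground tags
#'
#' @param tree A `phylo` (with optional foreground attribute).
#' @param path Output file; if `NULL` the Newick string is returned.
#' @export
write_tree <- function(tree, path = NULL) {
  fg <- foreground_nodes(tree)
  ntip <- length(tree$tip.label)
  if (length(fg) > 0) {
    tips <- fg[fg <= ntip]
    tree$tip.label[tips] <- paste0(tree$tip.label[tips], "#1")
    ints <- fg[fg > ntip]
    if (length(ints) > 0) {
      if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
      tree$node.label[ints - ntip] <- paste0(tree$node.label[ints - ntip], "#1")
    }
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a pathway interaction network from a two-column TSV edge list
#'
#' Lines starting with `#` are comments; no header row.  The graph is
#' undirected and simple: duplicate edges are collapsed and self-loops are
#' dropped with a warning.
#'
#' @param path TSV file with two gene-ID columns.
#' @return A `pathway_network` (see [pathway_network()]).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty edge list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad) > 0) {
    stop("edge list line ", which(keep)[bad[1]],
         " does not have two tab-separated columns")
  }
  edges <- do.call(rbind, lapply(parts, function(p) trimws(p[1:2])))
  pathway_network(edges)
}

#' Construct a pathway network from an edge matrix
#'
#' @param edges Two-column character matrix of gene-ID pairs.
#' @param nodes Optional node set (defaults to all edge endpoints); extra
#'   isolated nodes are allowed.
#' @return Object of class `pathway_network`: list with the `igraph` graph,
#'   `nodes`, and the deduplicated `edges`.
#' @export
pathway_network <- function(edges, nodes = NULL) {
  stopifnot(is.matrix(edges), ncol(edges) == 2)
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from the edge list")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(nodes)) {
    missing_nodes <- setdiff(nodes, igraph::V(g)$name)
    g <- igraph::add_vertices(g, length(missing_nodes), name = missing_nodes)
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  el <- igraph::as_edgelist(g)
  structure(list(graph = g, nodes = igraph::V(g)$name, edges = el),
            class = "pathway_network")
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("Pathway network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Write a pathway network as a TSV edge list
#'
#' @param network A `pathway_network`.
#' @param path Output file.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

CELL_TYPES <- c("rod", "cone", "shared")
PROCESSES <- c("development", "phototransduction", "retinoid_cycle")
FUNCTIONS <- c("enzyme", "chaperone", "opsin", "g_protein",
               "phosphodiesterase", "signal_regulator",
               "ion_channel_exchanger", "guanylate_cyclase", "miscellaneous")

#' Read a gene annotation table
#'
#' Tab-separated with a header row; columns `gene_id`, `cell_type`,
#' `process`, `fun`, `protein_length`.  `cell_type` must be one of rod, cone,
#' shared; `process` one of development, phototransduction, retinoid_cycle;
#' `fun` one of the nine functional classes (enzyme, chaperone, opsin,
#' g_protein, phosphodiesterase, signal_regulator, ion_channel_exchanger,
#' guanylate_cyclase, miscellaneous).
#'
#' @param path TSV file.
#' @return Data frame with validated factor columns.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "")
  validate_annotations(df)
}

validate_annotations <- function(df) {
  need <- c("gene_id", "cell_type", "process", "fun", "protein_length")
  if (!all(need %in% names(df))) {
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  }
  chk <- function(col, levels) {
    bad <- setdiff(unique(df[[col]]), levels)
    if (length(bad) > 0) {
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "))
    }
    factor(df[[col]], levels = levels)
  }
  df$cell_type <- chk("cell_type", CELL_TYPES)
  df$process <- chk("process", PROCESSES)
  df$fun <- chk("fun", FUNCTIONS)
  if (any(!is.finite(df$protein_length)) || any(df$protein_length <= 0)) {
    stop("protein_length must be positive")
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotations")
  df
}

#' Write annotations to TSV
#' @param annotations Data frame as from [read_annotations()].
#' @param path Output file.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
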