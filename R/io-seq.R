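AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

parse_species_tag <- function(labels, what = "sequence") {
  parts <- regmatches(labels, regexec("^([^|]+)\\|(.+)$", labels))
  bad <- labels[vapply(parts, length, integer(1)) != 3L]
  if (length(bad))
    stop("validation error: ", what, " name(s) without '<Species>|<gene>' tag: ",
         paste(bad, collapse = ", "))
  list(species = vapply(parts, `[`, character(1), 2L),
       gene_id = vapply(parts, `[`, character(1), 3L))
}

#' Construct a protein multiple sequence alignment
#'
#' Sequences are stored as a character matrix over the 20 amino-acid letters
#' plus the gap character `-`; columns are 1-based.  Every record carries a
#' species tag parsed from `<Species>|<gene_id>` identifiers.
#'
#' @param seqs Named character vector of aligned sequences (equal length),
#'   names of the form `<Species>|<gene_id>`.
#' @return Object of class `protein_msa` with elements `seq` (character
#'   matrix, one row per record), `seq_id`, `species`, `gene_id`, `length`.
#' @export
protein_msa <- function(seqs) {
  if (!length(seqs)) stop("empty alignment")
  if (anyDuplicated(names(seqs))) stop("validation error: duplicate seq_id")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("validation error: ragged alignment (unequal sequence lengths)")
  tags <- parse_species_tag(names(seqs))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  bad <- setdiff(unique(as.vector(mat)), c(AA_LETTERS, "-", "X"))
  if (length(bad))
    stop("validation error: non amino-acid character(s): ",
         paste(bad, collapse = ", "))
  structure(list(seq = mat, seq_id = names(seqs), species = tags$species,
                 gene_id = tags$gene_id, length = unname(lens[1L])),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa> %d sequences x %d columns (%d species)\n",
              nrow(x$seq), x$length, length(unique(x$species))))
  invisible(x)
}

#' Read a protein alignment from FASTA
#'
#' FASTA headers must encode the species as `<Species>|<gene_id>`.
#'
#' @param path FASTA file.
#' @return A [protein_msa()].
#' @export
read_alignment_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  protein_msa(stats::setNames(as.character(ss), names(ss)))
}

#' Write a protein alignment to FASTA
#' @param msa A [protein_msa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "protein_msa"))
  seqs <- apply(msa$seq, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Construct a species-labelled gene tree
#'
#' @param phy An `ape::phylo` tree whose tip labels are
#'   `<Species>|<gene_id>`.
#' @return Object of class `gene_tree` wrapping the `phylo` plus parsed
#'   `species` and `gene_id` vectors (in tip order).
#' @export
gene_tree <- function(phy) {
  stopifnot(inherits(phy, "phylo"))
  if (length(phy$tip.label) < 2L) stop("a gene tree needs >= 2 leaves")
  tags <- parse_species_tag(phy$tip.label, what = "leaf")
  if (anyDuplicated(tags$gene_id))
    stop("validation error: duplicate leaf gene_id")
  structure(list(phylo = phy, species = tags$species, gene_id = tags$gene_id),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %d leaves, %d species, %s\n",
              length(x$phylo$tip.label), length(unique(x$species)),
              if (ape::is.rooted(x$phylo)) "rooted" else "unrooted"))
  invisible(x)
}

#' Read a species-labelled gene tree from Newick
#'
#' Leaf names must encode the species as `<Species>|<gene_id>`.
#'
#' @param path Newick file.
#' @return A [gene_tree()].
#' @export
read_tree_newick <- function(path) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("format error: could not parse Newick file ", path)
  gene_tree(phy)
}

#' Write a gene tree to Newick
#' @param tree A [gene_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "gene_tree"))
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

#' Construct a gene-gene similarity graph
#'
#' An undirected weighted graph whose edge weights derive from BLASTp-style
#' E-values.  Self-loops are rejected on input (Markov clustering adds its own
#' internally); duplicate undirected edges keep the smaller E-value.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `evalue`.
#' @param nodes Optional character vector of node ids (defaults to the genes
#'   appearing in `edges`); extra ids become isolated nodes.
#' @return Object of class `similarity_graph`.
#' @export
similarity_graph <- function(edges, nodes = NULL) {
  need <- c("gene_a", "gene_b", "evalue")
  if (!all(need %in% names(edges)))
    stop("format error: edge list needs columns ", paste(need, collapse = ", "))
  edges$evalue <- as.numeric(edges$evalue)
  if (anyNA(edges$evalue) || any(edges$evalue < 0))
    stop("validation error: E-values must be numeric and >= 0")
  if (any(edges$gene_a == edges$gene_b))
    stop("validation error: self-loop in similarity graph")
  if (nrow(edges)) {
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    key <- paste(a, b, sep = "\r")
    ev <- tapply(edges$evalue, key, min)
    uk <- strsplit(names(ev), "\r", fixed = TRUE)
    edges <- data.frame(gene_a = vapply(uk, `[`, character(1), 1L),
                        gene_b = vapply(uk, `[`, character(1), 2L),
                        evalue = as.numeric(ev), stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  all_nodes <- sort(unique(c(edges$gene_a, edges$gene_b, nodes)))
  structure(list(edges = edges, nodes = all_nodes),
            class = "similarity_graph")
}

#' Read a similarity graph edge list
#'
#' TSV with columns `gene_a`, `gene_b`, `evalue`.
#'
#' @param path File path.
#' @return A [similarity_graph()].
#' @export
read_similarity_graph <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "numeric"))
  similarity_graph(df)
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Preset species roles for the three-lineage CAM comparison
#'
#' Photosynthetic-pathway roles for the default synthetic species set: one
#' eudicot CAM lineage (`Kf`), two monocot CAM lineages (`Ac` pineapple-like,
#' `Pe` orchid-like), C3 references (`At`, `Vv`, `Os`) and C4 references
#' (`Sb`, `Zm`).  Tags are free strings; supply your own named vector to use
#' other species.
#'
#' @return Named character vector, species tag -> role in
#'   `{CAM_dicot, CAM_monocot, C3, C4, other}`.
#' @export
cam_species_roles <- function() {
  c(Kf = "CAM_dicot", Ac = "CAM_monocot", Pe = "CAM_monocot",
    At = "C3", Vv = "C3", Os = "C3", Sb = "C4", Zm = "C4")
}

#' Read a species-role table
#' @param path TSV with columns `species_tag`, `role`.
#' @return Named character vector, tag -> role.
#' @export
read_species_roles <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (!all(c("species_tag", "role") %in% names(df)))
    stop("format error: roles table needs columns species_tag, role")
  ok <- c("CAM_dicot", "CAM_monocot", "C3", "C4", "other")
  if (!all(df$role %in% ok))
    stop("validation error: unknown role(s): ",
         paste(setdiff(df$role, ok), collapse = ", "))
  stats::setNames(df$role, df$species_tag)
}
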