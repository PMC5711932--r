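#' Fitch parsimony ancestral states for one alignment column
#'
#' Bottom-up/top-down Fitch parsimony on a rooted tree for a discrete
#' character (amino-acid letters).  Gaps/unknowns (`-`, `X`, `NA`) are
#' missing data: they do not constrain the reconstruction and their leaves
#' inherit the parental state.  One minimum-change labelling is returned.
#' Ties at an internal node are resolved toward the parent's state, then
#' alphabetically; ties at the root are resolved toward the state most
#' frequent among the column's non-missing leaves, then alphabetically (a
#' frequency-guided choice that avoids spuriously attributing a rare derived
#' residue to deep ancestors when the two resolutions are equally
#' parsimonious).
#'
#' @param tree A rooted [gene_tree()] (or `phylo`).
#' @param states Character vector of leaf states, named by tip label, or
#'   unnamed in tip order.
#' @return List: `states` (length tips + internal nodes; `NA` where
#'   unresolvable from all-missing subtrees), `score` (minimum number of
#'   changes), `sets` (the bottom-up state sets).
#' @export
fitch_ancestral <- function(tree, states) {
  phy <- if (inherits(tree, "gene_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("fitch_ancestral needs a rooted tree")
  ntip <- length(phy$tip.label)
  if (!is.null(names(states))) {
    miss <- setdiff(phy$tip.label, names(states))
    if (length(miss)) stop("no state for tip(s): ", paste(miss, collapse = ", "))
    states <- states[phy$tip.label]
  } else stopifnot(length(states) == ntip)
  states <- toupper(as.character(states))
  states[states %in% c("-", "X", "")] <- NA_character_
  nn <- ntip + phy$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip))
    sets[[i]] <- if (is.na(states[i])) character(0) else states[i]
  if (all(lengths(sets[seq_len(ntip)]) == 0L))
    return(list(states = rep(NA_character_, nn), score = 0L, sets = sets))
  po <- ape::reorder.phylo(phy, "postorder")
  parent <- integer(nn)
  children <- split(po$edge[, 2L], po$edge[, 1L])
  score <- 0L
  for (e in seq_len(nrow(po$edge))) parent[po$edge[e, 2L]] <- po$edge[e, 1L]
  node_order <- unique(po$edge[, 1L])   # postorder guarantees children first
  for (p in node_order) {
    acc <- NULL
    for (ch in children[[as.character(p)]]) {
      s <- sets[[ch]]
      if (!length(s)) next                       # missing subtree
      if (is.null(acc)) { acc <- s; next }
      inter <- intersect(acc, s)
      if (length(inter)) acc <- inter
      else { acc <- union(acc, s); score <- score + 1L }
    }
    sets[[p]] <- if (is.null(acc)) character(0) else acc
  }
  # top-down assignment
  assigned <- rep(NA_character_, nn)
  root <- ntip + 1L
  counts <- table(states[!is.na(states)])
  pick_major <- function(set) {
    k <- counts[set]; k[is.na(k)] <- 0L
    set <- set[order(-as.integer(k), set)]
    set[1L]
  }
  rs <- sets[[root]]
  assigned[root] <- if (length(rs)) pick_major(sort(rs)) else NA_character_
  preorder <- rev(seq_len(nrow(po$edge)))
  for (e in preorder) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    s <- sets[[ch]]
    assigned[ch] <-
      if (!length(s)) assigned[p]                       # missing: inherit
      else if (!is.na(assigned[p]) && assigned[p] %in% s) assigned[p]
      else sort(s)[1L]
  }
  list(states = assigned, score = score, sets = sets)
}
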