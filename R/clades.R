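#' Midpoint-root a gene tree
#' @param tree A [gene_tree()].
#' @return A rooted [gene_tree()].
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  gene_tree(phangorn::midpoint(tree$phylo))
}

tip_roles <- function(tree, roles) {
  r <- roles[tree$species]
  if (anyNA(r))
    stop("species without declared role: ",
         paste(unique(tree$species[is.na(r)]), collapse = ", "))
  r
}

#' Find maximal CAM-convergence clades in a gene tree
#'
#' A CAM-convergence clade contains at least one CAM-dicot leaf and at least
#' one CAM-monocot leaf but no C3 or C4 leaf; leaves of role `other` are
#' permitted inside.  Only *maximal* such clades are returned (the parent
#' clade violates the rule).  The tree must be rooted; use [midpoint_root()]
#' first if it is not.
#'
#' @param tree A rooted [gene_tree()].
#' @param roles Named character vector, species tag -> role (see
#'   [cam_species_roles()]).
#' @return List of `cam_clade_call` objects: `node` (internal node id),
#'   `leaves` (tip labels), `contains_kf`, `monocot_cam_species`, `verdict`.
#' @export
find_cam_clades <- function(tree, roles = cam_species_roles()) {
  stopifnot(inherits(tree, "gene_tree"))
  phy <- tree$phylo
  if (!ape::is.rooted(phy))
    stop("tree is unrooted: root it first (e.g. midpoint_root())")
  r <- tip_roles(tree, roles)
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  cnt <- matrix(0L, nn, 3L)  # columns: CAM_dicot, CAM_monocot, C3/C4
  cnt[seq_len(ntip), 1L] <- as.integer(r == "CAM_dicot")
  cnt[seq_len(ntip), 2L] <- as.integer(r == "CAM_monocot")
  cnt[seq_len(ntip), 3L] <- as.integer(r %in% c("C3", "C4"))
  tipsets <- c(as.list(seq_len(ntip)), vector("list", phy$Nnode))
  po <- ape::reorder.phylo(phy, "postorder")
  parent <- integer(nn)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    cnt[p, ] <- cnt[p, ] + cnt[ch, ]
    tipsets[[p]] <- c(tipsets[[p]], tipsets[[ch]])
    parent[ch] <- p
  }
  qual <- cnt[, 1L] > 0L & cnt[, 2L] > 0L & cnt[, 3L] == 0L
  root <- ntip + 1L
  maximal <- which(qual & (seq_len(nn) == root | !qual[pmax(parent, 1L)]))
  lapply(maximal, function(node) {
    tips <- sort(tipsets[[node]])
    structure(list(
      node = node,
      leaves = phy$tip.label[tips],
      contains_kf = any(r[tips] == "CAM_dicot"),
      monocot_cam_species = sort(unique(tree$species[tips][r[tips] == "CAM_monocot"])),
      verdict = TRUE), class = "cam_clade_call")
  })
}

#' @export
print.cam_clade_call <- function(x, ...) {
  cat(sprintf("<cam_clade_call> node %d: {%s}\n", x$node,
              paste(x$leaves, collapse = ", ")))
  invisible(x)
}
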