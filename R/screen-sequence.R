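#' Default species tree for the synthetic eight-species comparison
#'
#' Rooted topology with rough branch lengths (expected substitutions/site)
#' for the preset of [cam_species_roles()]: a eudicot clade (Kf CAM; At, Vv
#' C3) and a monocot clade (Pe orchid-like CAM; Ac pineapple-like CAM; Os C3;
#' Sb, Zm C4 grasses).
#'
#' @return An `ape::phylo` with species tags as tip labels.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = paste0(
    "((Kf:0.10,(At:0.08,Vv:0.07):0.03):0.05,",
    "(Pe:0.10,(Ac:0.08,(Os:0.06,(Sb:0.03,Zm:0.03):0.03):0.03):0.03):0.05);"))
}

# Newick for a left-ladder of labels: (((a,b),c),d)
ladder_newick <- function(labels) {
  out <- labels[1L]
  for (l in labels[-1L]) out <- sprintf("(%s,%s)", out, l)
  out
}

#' Attach tribe genes to a species topology
#'
#' Builds the reference topology on which independent substitutions are
#' identifiable: every gene is placed at its own species' position in the
#' declared species tree (multiple genes of one species become a ladder at
#' that tip); species absent from the tribe are pruned.  Branch lengths are
#' dropped (parsimony uses topology only).
#'
#' @param species_tree `phylo` with species tags as tip labels.
#' @param seq_ids Gene sequence ids of the form `<Species>|<gene>`.
#' @return A rooted [gene_tree()] over `seq_ids`.
#' @export
reference_topology <- function(species_tree, seq_ids) {
  tags <- parse_species_tag(seq_ids)
  by_sp <- split(seq_ids, tags$species)
  absent <- setdiff(species_tree$tip.label, names(by_sp))
  unknown <- setdiff(names(by_sp), species_tree$tip.label)
  if (length(unknown))
    stop("species not in species tree: ", paste(unknown, collapse = ", "))
  phy <- species_tree
  if (length(absent)) {
    if (length(setdiff(phy$tip.label, absent)) < 2L)
      stop("fewer than 2 species shared with the species tree")
    phy <- ape::drop.tip(phy, absent)
  }
  build <- function(node) {
    ntip <- length(phy$tip.label)
    if (node <= ntip) return(ladder_newick(sort(by_sp[[phy$tip.label[node]]])))
    ch <- phy$edge[phy$edge[, 1L] == node, 2L]
    sprintf("(%s)", paste(vapply(ch, build, character(1)), collapse = ","))
  }
  nwk <- paste0(build(length(phy$tip.label) + 1L), ";")
  gene_tree(ape::read.tree(text = nwk))
}

#' Neighbor-joining gene tree from alignment p-distances
#'
#' Convenience helper for synthetic tests; tree inference fidelity is out of
#' scope for the screens, which consume pre-built trees.
#'
#' @param msa A [protein_msa()].
#' @return A midpoint-rooted [gene_tree()].
#' @export
build_nj_tree <- function(msa) {
  stopifnot(inherits(msa, "protein_msa"))
  n <- nrow(msa$seq)
  d <- matrix(0, n, n, dimnames = list(msa$seq_id, msa$seq_id))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- msa$seq[i, ]; b <- msa$seq[j, ]
    ok <- !(a %in% c("-", "X")) & !(b %in% c("-", "X"))
    d[i, j] <- d[j, i] <- if (any(ok)) mean(a[ok] != b[ok]) else 0
  }
  midpoint_root(gene_tree(ape::nj(stats::as.dist(d))))
}

#' Screen tribes for protein-sequence convergence
#'
#' For each tribe (gene tree + alignment) this applies the three-part
#' sequence-convergence rule to every CAM-dicot gene:
#' \enumerate{
#'   \item it sits in a CAM-convergence clade of the tribe tree
#'     ([find_cam_clades()]);
#'   \item on the species-role reference topology ([reference_topology()]),
#'     counting substitutions under Fitch parsimony between the gene's
#'     terminal branch and a clade CAM-monocot gene's terminal branch yields
#'     at least one convergent substitution;
#'   \item the clade shares at least one derived residue against the C3/C4
#'     background ([shared_substitution_sites()]).
#' }
#' Tribes lacking the required species coverage are skipped with a log note;
#' unrooted tribe trees are midpoint-rooted with a warning.
#'
#' @param tribes List of tribes, each a list with elements `id`, `tree`
#'   (a [gene_tree()]) and `msa` (a [protein_msa()]).
#' @param roles Species-role vector (see [cam_species_roles()]).
#' @param config A [cam_config()].
#' @param species_tree Species topology for the reference attachment
#'   (default [default_species_tree()]).
#' @param required_species Species tags every screened tribe must contain
#'   (default: all species named in `roles`).
#' @return Object of class `seq_screen`: `calls` data frame (one row per
#'   CAM-dicot gene), `sites` (per-gene site tables), `skipped`, `summary`.
#' @export
screen_sequence_convergence <- function(tribes, roles = cam_species_roles(),
                                        config = cam_config(),
                                        species_tree = default_species_tree(),
                                        required_species = names(roles)) {
  calls <- list(); sites <- list(); skipped <- character(0)
  for (tb in tribes) {
    id <- tb$id
    tree <- tb$tree; msa <- tb$msa
    if (!setequal(intersect(required_species, unique(msa$species)),
                  required_species)) {
      skipped <- c(skipped, sprintf("%s: species coverage below requirement", id))
      next
    }
    if (length(setdiff(tree$gene_id, msa$gene_id)) ||
        length(setdiff(msa$gene_id, tree$gene_id))) {
      skipped <- c(skipped, sprintf("%s: tree/alignment leaf-set mismatch", id))
      next
    }
    if (!ape::is.rooted(tree$phylo)) {
      warning("tribe ", id, ": unrooted tree midpoint-rooted")
      tree <- midpoint_root(tree)
    }
    clades <- find_cam_clades(tree, roles)
    kf_ids <- tree$phylo$tip.label[roles[tree$species] == "CAM_dicot"]
    background <- msa$seq_id[roles[msa$species] %in% c("C3", "C4")]
    ref <- reference_topology(species_tree, msa$seq_id)
    for (kf in kf_ids) {
      in_clade <- vapply(clades, function(cl) kf %in% cl$leaves, logical(1))
      if (!any(in_clade)) {
        calls[[length(calls) + 1L]] <- data.frame(
          tribe = id, kf_gene = kf, in_cam_clade = FALSE,
          clade_size = NA_integer_, n_convergent_sub = NA_integer_,
          n_divergent_sub = NA_integer_, n_shared_sites = NA_integer_,
          convergent = FALSE, stringsAsFactors = FALSE)
        next
      }
      cl <- clades[[which(in_clade)[1L]]]
      mono <- cl$leaves[roles[parse_species_tag(cl$leaves)$species] ==
                          "CAM_monocot"]
      cd_best <- NULL
      for (m in mono) {
        cd <- tryCatch(count_conv_div(ref, msa, kf, m), error = function(e) NULL)
        if (is.null(cd)) next
        if (is.null(cd_best) || cd$n_convergent > cd_best$n_convergent)
          cd_best <- cd
      }
      st <- shared_substitution_sites(msa, foreground = cl$leaves,
                                      background = background,
                                      min_bg_coverage = config$min_bg_coverage)
      crit2 <- !is.null(cd_best) && cd_best$n_convergent >= 1L
      crit3 <- nrow(st) >= 1L
      calls[[length(calls) + 1L]] <- data.frame(
        tribe = id, kf_gene = kf, in_cam_clade = TRUE,
        clade_size = length(cl$leaves),
        n_convergent_sub = if (is.null(cd_best)) NA_integer_ else cd_best$n_convergent,
        n_divergent_sub = if (is.null(cd_best)) NA_integer_ else cd_best$n_divergent,
        n_shared_sites = nrow(st),
        convergent = crit2 && crit3, stringsAsFactors = FALSE)
      if (crit2 && crit3) sites[[paste(id, kf, sep = ":")]] <- st
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls)
           else data.frame(tribe = character(0), kf_gene = character(0),
                           in_cam_clade = logical(0), clade_size = integer(0),
                           n_convergent_sub = integer(0),
                           n_divergent_sub = integer(0),
                           n_shared_sites = integer(0), convergent = logical(0))
  rownames(calls) <- NULL
  structure(list(calls = calls, sites = sites, skipped = skipped,
                 summary = list(
                   n_tribes = length(tribes),
                   n_screened = length(tribes) - length(skipped),
                   n_kf_genes = nrow(calls),
                   n_in_clade = sum(calls$in_cam_clade),
                   n_convergent = sum(calls$convergent))),
            class = "seq_screen")
}

#' @export
print.seq_screen <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<seq_screen> %d tribes (%d screened, %d skipped); ",
                     "%d CAM-dicot genes, %d in CAM-convergence clades, ",
                     "%d called convergent\n"),
              s$n_tribes, s$n_screened, length(x$skipped), s$n_kf_genes,
              s$n_in_clade, s$n_convergent))
  invisible(x)
}
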