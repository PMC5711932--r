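#' Shared derived residues of a foreground clade against a background
#'
#' Scans alignment columns for the signature of a shared amino-acid change:
#' all foreground sequences (the members of a CAM-convergence clade) carry
#' one identical, non-gap residue that no background (C3/C4) sequence
#' carries, with at least `min_bg_coverage` of the background non-gap at the
#' column.  Background residues may differ among themselves (e.g. a
#' foreground aspartate against an R/K/H background).  Columns are reported
#' 1-based.
#'
#' @param msa A [protein_msa()].
#' @param foreground Character vector of foreground seq_ids.
#' @param background Character vector of background seq_ids.
#' @param max_fg_gap Maximum foreground gaps tolerated (default 0: unanimity).
#' @param min_bg_coverage Minimum fraction of background sequences non-gap.
#' @return Data frame: `column`, `cam_residue`, `background_residues`
#'   (comma-collapsed set), `n_gaps`.
#' @export
shared_substitution_sites <- function(msa, foreground, background,
                                      max_fg_gap = 0, min_bg_coverage = 0.8) {
  stopifnot(inherits(msa, "protein_msa"))
  if (!length(foreground)) stop("foreground set is empty")
  miss <- setdiff(c(foreground, background), msa$seq_id)
  if (length(miss)) stop("seq_id(s) not in alignment: ",
                         paste(miss, collapse = ", "))
  fg <- msa$seq[foreground, , drop = FALSE]
  bg <- msa$seq[background, , drop = FALSE]
  out <- list()
  for (j in seq_len(msa$length)) {
    f <- fg[, j]
    gaps <- sum(f %in% c("-", "X"))
    if (gaps > max_fg_gap) next
    f <- f[!f %in% c("-", "X")]
    if (!length(f) || length(unique(f)) != 1L) next
    res <- f[1L]
    b <- bg[, j]
    bok <- !b %in% c("-", "X")
    if (length(b) && mean(bok) < min_bg_coverage) next
    bres <- unique(b[bok])
    if (res %in% bres) next
    out[[length(out) + 1L]] <- data.frame(
      column = j, cam_residue = res,
      background_residues = paste(sort(bres), collapse = ","),
      n_gaps = sum(!bok) + gaps, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(column = integer(0), cam_residue = character(0),
                      background_residues = character(0), n_gaps = integer(0)))
  do.call(rbind, out)
}

# resolve a branch given as tip label or node number to its child-end node
resolve_branch <- function(phy, branch) {
  node <- if (is.character(branch)) match(branch, phy$tip.label)
          else as.integer(branch)
  if (is.na(node) || node < 1L || node > length(phy$tip.label) + phy$Nnode)
    stop("unknown branch: ", branch)
  if (node == length(phy$tip.label) + 1L)
    stop("the root has no parent branch")
  node
}

#' Count convergent and divergent substitutions between two branches
#'
#' For every alignment column, ancestral states are reconstructed by
#' [fitch_ancestral()]; a branch "substitutes" at a column when its parent
#' and child states differ (both resolved).  A column is *convergent* when
#' both branches substitute and arrive at the same residue, *divergent* when
#' both substitute to different residues.  The two branches must not share a
#' node, otherwise the two events would not be independent.  The alignment's
#' frequency-based null fraction (see [convergence_null_fraction()]) is
#' reported alongside the counts.
#'
#' @param tree A rooted [gene_tree()] whose tip labels match `msa` seq_ids.
#' @param msa A [protein_msa()].
#' @param branch_a,branch_b Tip labels (terminal branches) or node numbers
#'   identifying the child end of each branch.
#' @return Object of class `conv_div_count`: `n_convergent`, `n_divergent`,
#'   `null_expected_convergent_fraction`, `columns` (per-column detail for
#'   the counted events).
#' @export
count_conv_div <- function(tree, msa, branch_a, branch_b) {
  stopifnot(inherits(tree, "gene_tree"), inherits(msa, "protein_msa"))
  phy <- tree$phylo
  if (!ape::is.rooted(phy)) stop("count_conv_div needs a rooted tree")
  a <- resolve_branch(phy, branch_a)
  b <- resolve_branch(phy, branch_b)
  parent <- integer(length(phy$tip.label) + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  if (length(intersect(c(a, parent[a]), c(b, parent[b]))))
    stop("branches are adjacent: convergent/divergent comparison undefined")
  miss <- setdiff(phy$tip.label, msa$seq_id)
  if (length(miss)) stop("tip(s) missing from alignment: ",
                         paste(miss, collapse = ", "))
  seqm <- msa$seq[phy$tip.label, , drop = FALSE]
  n_conv <- 0L; n_div <- 0L
  cols <- list()
  for (j in seq_len(msa$length)) {
    st <- seqm[, j]
    if (all(st %in% c("-", "X"))) next
    fit <- fitch_ancestral(phy, stats::setNames(st, phy$tip.label))
    s <- fit$states
    sub_a <- !is.na(s[a]) && !is.na(s[parent[a]]) && s[a] != s[parent[a]]
    sub_b <- !is.na(s[b]) && !is.na(s[parent[b]]) && s[b] != s[parent[b]]
    if (sub_a && sub_b) {
      if (s[a] == s[b]) {
        n_conv <- n_conv + 1L
        cols[[length(cols) + 1L]] <- data.frame(column = j, type = "convergent",
                                                state_a = s[a], state_b = s[b])
      } else {
        n_div <- n_div + 1L
        cols[[length(cols) + 1L]] <- data.frame(column = j, type = "divergent",
                                                state_a = s[a], state_b = s[b])
      }
    }
  }
  structure(list(
    branch_a = branch_a, branch_b = branch_b,
    n_convergent = n_conv, n_divergent = n_div,
    null_expected_convergent_fraction = convergence_null_fraction(msa),
    columns = if (length(cols)) do.call(rbind, cols)
              else data.frame(column = integer(0), type = character(0),
                              state_a = character(0), state_b = character(0))),
    class = "conv_div_count")
}

#' @export
print.conv_div_count <- function(x, ...) {
  cat(sprintf(
    "<conv_div_count> %s vs %s: %d convergent, %d divergent (null fraction %.4f)\n",
    format(x$branch_a), format(x$branch_b), x$n_convergent, x$n_divergent,
    x$null_expected_convergent_fraction))
  invisible(x)
}

#' Frequency-based null fraction of convergent double substitutions
#'
#' The probability that two independent substitutions drawn from the
#' alignment's amino-acid frequency vector `pi` land on the same residue,
#' `sum(pi^2)`.  Reported alongside convergent/divergent counts as the
#' expected convergent fraction among double-substitution columns under a
#' no-convergence null; it is an interpretive yardstick, not a test.
#'
#' @param msa A [protein_msa()].
#' @return Probability in `[0, 1]`.
#' @export
convergence_null_fraction <- function(msa) {
  stopifnot(inherits(msa, "protein_msa"))
  res <- as.vector(msa$seq)
  res <- res[res %in% AA_LETTERS]
  if (!length(res)) return(0)
  pi <- table(res) / length(res)
  sum(pi^2)
}
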