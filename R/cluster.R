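#' Hierarchical clustering of diel profiles by rank correlation
#'
#' Average-linkage hierarchical clustering with distance `1 - Spearman rho`
#' between replicate-mean time courses.  Profiles are ordered by gene_id
#' before clustering so the result is deterministic regardless of input
#' order; degenerate (zero-variance) profiles are rejected.
#'
#' @param profiles List of [diel_profile()] objects on one common grid.
#' @param k Number of clusters to cut into (optional).
#' @param h Cut height in `1 - rho` units (optional; one of `k`/`h` required).
#' @return Named integer vector of cluster labels (names = gene_id), with the
#'   `hclust` object as attribute `hclust`.
#' @export
cluster_profiles <- function(profiles, k = NULL, h = NULL) {
  if (length(profiles) < 2L) stop("need >= 2 profiles to cluster")
  ids <- vapply(profiles, function(p) p$gene_id, character(1))
  profiles <- profiles[order(ids)]
  ids <- sort(ids)
  if (!is.null(k) && k > length(profiles))
    stop("k cannot exceed the number of profiles")
  if (is.null(k) && is.null(h)) stop("supply k or h")
  mm <- vapply(profiles, replicate_mean, numeric(length(profiles[[1]]$times)))
  if (any(apply(mm, 2L, stats::sd) == 0))
    stop("degenerate (zero-variance) profile cannot be clustered")
  d <- stats::as.dist(1 - stats::cor(mm, method = "spearman"))
  attr(d, "Labels") <- ids
  hc <- stats::hclust(d, method = "average")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else stats::cutree(hc, h = h)
  names(labels) <- ids
  attr(labels, "hclust") <- hc
  labels
}
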