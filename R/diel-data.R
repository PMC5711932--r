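#' Canonical diel sampling grid
#'
#' Twelve time points at 2-h intervals over a 12 h light / 12 h dark cycle,
#' expressed as hours after the beginning of the light period on the circular
#' interval (0, 24] (hour 24 is equivalent to hour 0).
#'
#' @return Numeric vector `c(2, 4, ..., 24)`.
#' @export
canonical_grid <- function() seq(2, 24, by = 2)

#' Diel time windows and their opposites
#'
#' The 24-h cycle is partitioned into four labelled windows of three canonical
#' time points each: dawn {22, 24, 2}, midday {4, 6, 8}, dusk {10, 12, 14} and
#' midnight {16, 18, 20} hours after light onset.  Dawn/dusk and
#' midday/midnight are "opposite" windows; abundance contrasts are tested
#' between opposite windows.
#'
#' @return Object of class `time_window_scheme` with elements `windows` (named
#'   list of time-point vectors) and `opposite` (named character vector).
#' @export
time_window_scheme <- function() {
  scheme <- list(
    windows = list(
      dawn     = c(22, 24, 2),
      midday   = c(4, 6, 8),
      dusk     = c(10, 12, 14),
      midnight = c(16, 18, 20)
    ),
    opposite = c(dawn = "dusk", dusk = "dawn",
                 midday = "midnight", midnight = "midday")
  )
  pts <- sort(unlist(scheme$windows, use.names = FALSE))
  stopifnot(identical(pts, canonical_grid()))
  structure(scheme, class = "time_window_scheme")
}

#' Construct a single-gene diel expression profile
#'
#' @param gene_id Gene identifier.
#' @param species Species tag.
#' @param times Strictly increasing sampling times in hours after light onset,
#'   each in (0, 24].
#' @param values Abundance matrix (FPKM), `length(times)` rows x replicates
#'   columns; a vector is taken as a single replicate.
#' @return Object of class `diel_profile`.
#' @export
diel_profile <- function(gene_id, species, times, values) {
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  times <- as.numeric(times)
  if (length(gene_id) != 1L || !nzchar(gene_id))
    stop("gene_id must be a single non-empty string")
  if (any(!is.finite(times)) || any(times <= 0) || any(times > 24))
    stop("times must be finite and in (0, 24]")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (nrow(values) != length(times))
    stop("values must have one row per time point")
  if (ncol(values) < 1L)
    stop("at least one replicate is required")
  if (any(!is.finite(values)) || any(values < 0))
    stop("abundance values must be finite and >= 0")
  structure(
    list(gene_id = as.character(gene_id), species = as.character(species),
         times = times, values = values),
    class = "diel_profile"
  )
}

#' @export
print.diel_profile <- function(x, ...) {
  cat(sprintf("<diel_profile> %s [%s]: %d time points x %d replicate(s)\n",
              x$gene_id, x$species, length(x$times), ncol(x$values)))
  invisible(x)
}

#' Construct a per-species collection of diel profiles on one grid
#'
#' @param species Species tag shared by all profiles.
#' @param profiles List of [diel_profile()] objects with identical `times`.
#' @param photoperiod Light/dark hours (default 12/12).
#' @return Object of class `diel_matrix`: the profiles stacked into a
#'   3-d array `genes x times x replicates`.
#' @export
diel_matrix <- function(species, profiles,
                        photoperiod = c(light = 12, dark = 12)) {
  if (length(profiles) == 0L) {
    arr <- array(numeric(0), dim = c(0L, 12L, 0L),
                 dimnames = list(NULL, paste0("t", canonical_grid()), NULL))
    return(structure(list(species = species, times = canonical_grid(),
                          values = arr, photoperiod = photoperiod),
                     class = "diel_matrix"))
  }
  ids <- vapply(profiles, function(p) p$gene_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate gene_id in diel_matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  times <- profiles[[1L]]$times
  nrep <- ncol(profiles[[1L]]$values)
  for (p in profiles) {
    if (!identical(p$times, times))
      stop("all profiles in a diel_matrix must share one sampling grid")
    if (ncol(p$values) != nrep)
      stop("all profiles in a diel_matrix must share the replicate count")
    if (!identical(p$species, species))
      stop("profile species does not match matrix species")
  }
  arr <- array(NA_real_, dim = c(length(ids), length(times), nrep),
               dimnames = list(ids, paste0("t", times), paste0("r", seq_len(nrep))))
  for (i in seq_along(profiles)) arr[i, , ] <- profiles[[i]]$values
  structure(list(species = species, times = times, values = arr,
                 photoperiod = photoperiod),
            class = "diel_matrix")
}

#' @export
print.diel_matrix <- function(x, ...) {
  cat(sprintf("<diel_matrix> %s: %d genes x %d time points x %d replicate(s)\n",
              x$species, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

#' Gene identifiers of a diel matrix
#' @param x A `diel_matrix`.
#' @return Character vector of gene ids.
#' @export
genes <- function(x) {
  stopifnot(inherits(x, "diel_matrix"))
  dimnames(x$values)[[1L]]
}

#' Extract one gene's profile from a diel matrix
#' @param x A `diel_matrix`.
#' @param gene_id Gene identifier present in `x`.
#' @return A [diel_profile()].
#' @export
get_profile <- function(x, gene_id) {
  stopifnot(inherits(x, "diel_matrix"))
  if (!gene_id %in% genes(x)) stop("unknown gene_id: ", gene_id)
  vals <- x$values[gene_id, , , drop = TRUE]
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = dim(x$values)[3])
  diel_profile(gene_id, x$species, x$times, vals)
}

#' Replicate-mean time course of a profile
#' @param profile A `diel_profile`.
#' @return Numeric vector, one mean abundance per time point.
#' @export
replicate_mean <- function(profile) {
  stopifnot(inherits(profile, "diel_profile"))
  rowMeans(profile$values)
}

#' Does a profile sit on the canonical 2-h grid?
#' @param profile A `diel_profile`.
#' @return Logical.
#' @export
on_canonical_grid <- function(profile) {
  identical(profile$times, canonical_grid())
}

#' Construct an ortholog group
#'
#' @param group_id Group identifier.
#' @param members Named list, species tag -> character vector of gene ids.
#' @return Object of class `ortholog_group`.
#' @export
ortholog_group <- function(group_id, members) {
  if (!length(members) || !any(lengths(members) > 0))
    stop("an ortholog group needs at least one member")
  all_ids <- unlist(members, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("gene_ids must be unique within an ortholog group")
  structure(list(group_id = as.character(group_id), members = members),
            class = "ortholog_group")
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat(sprintf("<ortholog_group> %s: %s\n", x$group_id,
              paste(sprintf("%s(%d)", names(x$members), lengths(x$members)),
                    collapse = " ")))
  invisible(x)
}
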