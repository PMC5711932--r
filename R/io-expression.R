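#' Read a diel expression table
#'
#' Expects a TSV whose first column is `gene_id` and whose remaining columns
#' are named `t<hour>_r<replicate>` (e.g. `t2_r1`, ..., `t24_r3`).  Hours are
#' hours after light onset in (0, 24]; every time point must carry the same
#' set of replicates.  Missing time points relative to the canonical 2-h grid
#' are allowed (e.g. 4-h resolution C3 reference data) and flagged via the
#' `missing_canonical` attribute; downstream comparisons require
#' [interpolate_to_grid()] first.
#'
#' @param path File path.
#' @param species Species tag to attach to the matrix.
#' @return A [diel_matrix()].
#' @export
read_expression_table <- function(path, species) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L || names(df)[1L] != "gene_id")
    stop("format error: expected header starting with 'gene_id' then t<hour>_r<rep> columns")
  vcols <- names(df)[-1L]
  m <- regmatches(vcols, regexec("^t([0-9]+(?:\\.[0-9]+)?)_r([0-9]+)$", vcols))
  bad <- vcols[vapply(m, length, integer(1)) == 0L]
  if (length(bad))
    stop("format error: unparseable column name(s): ", paste(bad, collapse = ", "))
  hours <- as.numeric(vapply(m, `[`, character(1), 2L))
  reps <- as.integer(vapply(m, `[`, character(1), 3L))
  times <- sort(unique(hours))
  rep_ids <- sort(unique(reps))
  if (!all(table(hours) == length(rep_ids)))
    stop("format error: every time point must have the same replicates")
  if (anyDuplicated(df$gene_id))
    stop("validation error: duplicate gene_id in expression table")
  num <- suppressWarnings(vapply(df[-1L], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, vcols))
  if (any(is.na(num) & !is.na(as.matrix(df[-1L]))) || anyNA(num))
    stop("format error: unparseable numeric value in expression table")
  if (any(num < 0))
    stop("validation error: negative FPKM value")
  profiles <- lapply(seq_len(nrow(df)), function(i) {
    vals <- matrix(NA_real_, length(times), length(rep_ids))
    for (j in seq_along(vcols))
      vals[match(hours[j], times), match(reps[j], rep_ids)] <- num[i, j]
    diel_profile(df$gene_id[i], species, times, vals)
  })
  out <- diel_matrix(species, profiles)
  attr(out, "missing_canonical") <- setdiff(canonical_grid(), times)
  out
}

#' Write a diel expression table
#'
#' Inverse of [read_expression_table()]: columns `gene_id`, then
#' `t<hour>_r<rep>` in time-major order.
#'
#' @param x A [diel_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "diel_matrix"))
  nrep <- dim(x$values)[3]
  cols <- list(gene_id = genes(x))
  for (ti in seq_along(x$times))
    for (r in seq_len(nrep))
      cols[[sprintf("t%s_r%d", format(x$times[ti]), r)]] <- x$values[, ti, r]
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read ortholog-group membership
#'
#' TSV with columns `group_id`, `species`, `gene_id`, one row per member gene.
#' Groups are assembled in order of first appearance; a gene listed in two
#' groups is a validation error.
#'
#' @param path File path.
#' @return List of [ortholog_group()] objects.
#' @export
read_orthogroups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("group_id", "species", "gene_id")
  if (!all(need %in% names(df)))
    stop("format error: orthogroup table needs columns ",
         paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  if (anyDuplicated(df$gene_id))
    stop("validation error: gene assigned to more than one ortholog group: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  gorder <- unique(df$group_id)
  lapply(gorder, function(g) {
    sub <- df[df$group_id == g, , drop = FALSE]
    ortholog_group(g, split(sub$gene_id, sub$species))
  })
}

#' Write ortholog-group membership
#' @param groups List of [ortholog_group()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(groups, path) {
  rows <- do.call(rbind, c(list(data.frame(group_id = character(0),
                                           species = character(0),
                                           gene_id = character(0))),
    lapply(groups, function(g) {
      data.frame(group_id = g$group_id,
                 species = rep(names(g$members), lengths(g$members)),
                 gene_id = unlist(g$members, use.names = FALSE))
    })))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
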