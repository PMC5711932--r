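#' Expression filter: detectably expressed genes
#'
#' Keeps genes whose replicate-mean abundance strictly exceeds `min_fpkm`
#' at `min_timepoints` or more of the 12 canonical time points.
#'
#' @param matrix A [diel_matrix()] on the canonical grid.
#' @param min_fpkm Threshold (strict >; default 0.01 FPKM).
#' @param min_timepoints Minimum qualifying time points (default 6).
#' @return Character vector of retained gene ids.
#' @export
expression_filter <- function(matrix, min_fpkm = 0.01, min_timepoints = 6) {
  stopifnot(inherits(matrix, "diel_matrix"))
  if (!identical(matrix$times, canonical_grid()))
    stop("expression_filter requires the canonical 2-h grid")
  if (dim(matrix$values)[1] == 0L) return(character(0))
  means <- apply(matrix$values, c(1, 2), mean)
  keep <- rowSums(means > min_fpkm) >= min_timepoints
  genes(matrix)[keep]
}

# r against every ortholog of one species; returns best id, best r, all r.
best_ortholog_cor <- function(kf_prof, mat, ids) {
  rs <- rep(NA_real_, length(ids)); names(rs) <- ids
  for (id in ids) {
    p <- get_profile(mat, id)
    if (stats::sd(replicate_mean(p)) == 0) next  # degenerate: excluded
    rs[id] <- diel_spearman(kf_prof, p)
  }
  ok <- !is.na(rs)
  if (!any(ok)) return(list(best = NA_character_, r = NA_real_, all = rs))
  best <- names(rs)[ok][which.max(rs[ok])]
  list(best = best, r = rs[[best]], all = rs)
}

#' Classify one ortholog group for convergent diel expression
#'
#' Applies the three-criterion convergent-expression rule to each CAM-dicot
#' gene of an ortholog group:
#' \enumerate{
#'   \item its diel pattern correlates with at least one CAM-monocot ortholog
#'     at Spearman rho above `r_high`, and with no C3 ortholog at rho of
#'     `r_low` or more;
#'   \item it shows a significant opposite-window abundance contrast
#'     (genome-wide BH `q < fdr`);
#'   \item its time shift to the best CAM-monocot ortholog is at most
#'     `max_cam_shift` hours while both CAM orthologs are shifted by at least
#'     `min_c3_shift` hours against the best-matched C3 ortholog.
#' }
#' "Best-matched" means highest Spearman correlation with the CAM-dicot gene.
#' Degenerate (zero-variance) profiles are excluded and can never support a
#' convergent call.
#'
#' @param group An [ortholog_group()].
#' @param matrices Named list of filtered [diel_matrix()] objects on the
#'   canonical grid, keyed by species tag.
#' @param enrichment Named list (by species tag) of data frames from
#'   [assign_enrichment()].
#' @param config A [cam_config()].
#' @return Data frame with one row per CAM-dicot gene: correlations, shifts,
#'   enrichment, the three criterion booleans, `convergent`, `evaluable`.
#' @export
classify_convergent_expression <- function(group, matrices, enrichment,
                                           config = cam_config()) {
  sp <- config$species
  empty_call <- function(kf_gene, evaluable = FALSE) {
    data.frame(group_id = group$group_id, kf_gene = kf_gene,
               best_ac_gene = NA_character_, best_at_gene = NA_character_,
               r_kf_ac = NA_real_, r_kf_at_max = NA_real_,
               shift_kf_ac = NA_real_, shift_kf_at = NA_real_,
               shift_ac_at = NA_real_,
               kf_enriched_window = NA_character_,
               criterion1 = FALSE, criterion2 = FALSE, criterion3 = FALSE,
               convergent = FALSE, evaluable = evaluable,
               stringsAsFactors = FALSE)
  }
  kf_ids <- intersect(group$members[[sp[["cam_dicot"]]]],
                      genes(matrices[[sp[["cam_dicot"]]]]))
  ac_ids <- intersect(group$members[[sp[["cam_monocot"]]]],
                      genes(matrices[[sp[["cam_monocot"]]]]))
  at_ids <- intersect(group$members[[sp[["c3"]]]],
                      genes(matrices[[sp[["c3"]]]]))
  if (!length(kf_ids) || !length(ac_ids) || !length(at_ids)) {
    missing_kf <- setdiff(group$members[[sp[["cam_dicot"]]]], character(0))
    return(empty_call(if (length(missing_kf)) missing_kf[1] else NA_character_))
  }
  enr_kf <- enrichment[[sp[["cam_dicot"]]]]
  calls <- lapply(kf_ids, function(kf_gene) {
    kf_prof <- get_profile(matrices[[sp[["cam_dicot"]]]], kf_gene)
    if (stats::sd(replicate_mean(kf_prof)) == 0)
      return(empty_call(kf_gene))
    ac <- best_ortholog_cor(kf_prof, matrices[[sp[["cam_monocot"]]]], ac_ids)
    at <- best_ortholog_cor(kf_prof, matrices[[sp[["c3"]]]], at_ids)
    if (is.na(ac$best) || is.na(at$best))
      return(empty_call(kf_gene))
    crit1 <- (ac$r > config$r_high) &&
      all(at$all[!is.na(at$all)] < config$r_low)
    win <- enr_kf$enriched_window[match(kf_gene, enr_kf$gene_id)]
    crit2 <- !is.na(win)
    ac_prof <- get_profile(matrices[[sp[["cam_monocot"]]]], ac$best)
    at_prof <- get_profile(matrices[[sp[["c3"]]]], at$best)
    s_kf_ac <- estimate_time_shift(kf_prof, ac_prof, config$shift_grid)$shift
    s_kf_at <- estimate_time_shift(kf_prof, at_prof, config$shift_grid)$shift
    s_ac_at <- estimate_time_shift(ac_prof, at_prof, config$shift_grid)$shift
    crit3 <- abs(s_kf_ac) <= config$max_cam_shift &&
      abs(s_kf_at) >= config$min_c3_shift &&
      abs(s_ac_at) >= config$min_c3_shift
    data.frame(group_id = group$group_id, kf_gene = kf_gene,
               best_ac_gene = ac$best, best_at_gene = at$best,
               r_kf_ac = ac$r, r_kf_at_max = at$r,
               shift_kf_ac = s_kf_ac, shift_kf_at = s_kf_at,
               shift_ac_at = s_ac_at,
               kf_enriched_window = if (crit2) win else NA_character_,
               criterion1 = crit1, criterion2 = crit2, criterion3 = crit3,
               convergent = crit1 && crit2 && crit3, evaluable = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Enrichment triangle network
#'
#' Emits one triangle motif (CAM-dicot, CAM-monocot, C3 ortholog edges) per
#' call in which both CAM genes have significantly enriched expression in the
#' *same* time window while the C3 ortholog is enriched in the *opposite*
#' window; edges carry the pairwise time-shift estimates.
#'
#' @param calls Data frame from [classify_convergent_expression()] /
#'   [run_expression_screen()].
#' @param enrichment Named list (species tag -> [assign_enrichment()] table).
#' @param config A [cam_config()].
#' @param scheme A [time_window_scheme()].
#' @return Data frame: one row per emitted triangle with the shared CAM
#'   window, the C3 window and the three edge shifts.
#' @export
build_triangle_network <- function(calls, enrichment, config = cam_config(),
                                   scheme = time_window_scheme()) {
  sp <- config$species
  empty <- data.frame(group_id = character(0), kf_gene = character(0),
                      ac_gene = character(0), at_gene = character(0),
                      cam_window = character(0), c3_window = character(0),
                      shift_kf_ac = numeric(0), shift_kf_at = numeric(0),
                      shift_ac_at = numeric(0))
  if (!nrow(calls)) return(empty)
  win_of <- function(species_tag, gene) {
    tab <- enrichment[[species_tag]]
    tab$enriched_window[match(gene, tab$gene_id)]
  }
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    cl <- calls[i, ]
    if (!isTRUE(cl$evaluable) || is.na(cl$best_ac_gene) ||
        is.na(cl$best_at_gene)) return(NULL)
    w_kf <- win_of(sp[["cam_dicot"]], cl$kf_gene)
    w_ac <- win_of(sp[["cam_monocot"]], cl$best_ac_gene)
    w_at <- win_of(sp[["c3"]], cl$best_at_gene)
    if (is.na(w_kf) || is.na(w_ac) || is.na(w_at)) return(NULL)
    if (w_kf != w_ac) return(NULL)
    if (w_at != scheme$opposite[[w_kf]]) return(NULL)
    data.frame(group_id = cl$group_id, kf_gene = cl$kf_gene,
               ac_gene = cl$best_ac_gene, at_gene = cl$best_at_gene,
               cam_window = w_kf, c3_window = w_at,
               shift_kf_ac = cl$shift_kf_ac, shift_kf_at = cl$shift_kf_at,
               shift_ac_at = cl$shift_ac_at, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
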