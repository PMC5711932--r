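#' Test opposite-time-window abundance contrasts for one gene
#'
#' For each of the two opposite-window contrasts (midday vs midnight, dawn vs
#' dusk) the replicate-resolved abundances of the three time points in one
#' window are pooled (3 time points x n replicates observations) and compared
#' to the opposite window by a two-sided Welch t-test.  The window means and
#' both p-values are recorded; which side is "enriched" is decided later,
#' after genome-wide FDR adjustment, by [assign_enrichment()].
#'
#' @param profile Replicate-resolved [diel_profile()] on the canonical grid.
#' @param scheme A [time_window_scheme()].
#' @return Object of class `window_enrichment`: list with `means` (named,
#'   all four windows), `contrasts` (data frame: contrast, p, larger_window).
#' @export
window_enrichment_test <- function(profile, scheme = time_window_scheme()) {
  stopifnot(inherits(profile, "diel_profile"))
  if (!on_canonical_grid(profile))
    stop("window tests require the canonical 2-h grid")
  pool <- function(w) {
    as.vector(profile$values[match(scheme$windows[[w]], profile$times), ,
                             drop = FALSE])
  }
  obs <- lapply(stats::setNames(nm = names(scheme$windows)), pool)
  if (any(lengths(obs) < 2L))
    stop("need >= 2 observations per window")
  means <- vapply(obs, mean, numeric(1))
  one <- function(w1, w2) {
    p <- if (stats::sd(c(obs[[w1]], obs[[w2]])) == 0) 1
         else stats::t.test(obs[[w1]], obs[[w2]])$p.value
    data.frame(contrast = paste0(w1, "_vs_", w2), p = p,
               larger_window = if (means[[w1]] >= means[[w2]]) w1 else w2,
               stringsAsFactors = FALSE)
  }
  contrasts <- rbind(one("midday", "midnight"), one("dawn", "dusk"))
  structure(list(gene_id = profile$gene_id, species = profile$species,
                 means = means, contrasts = contrasts),
            class = "window_enrichment")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Standard BH false-discovery-rate adjustment: monotone in rank and never
#' smaller than the raw p-value.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(is.finite(pvalues)), all(pvalues >= 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Attach q-values and the enriched-window verdict
#'
#' Given the per-gene window tests of one species, applies [bh_fdr()] across
#' all contrast p-values genome-wide and labels each gene's enriched window:
#' the larger-mean window of its most significant contrast, provided that
#' contrast has `q < fdr`; otherwise none.
#'
#' @param enrichments List of `window_enrichment` objects (one species).
#' @param fdr FDR threshold (default 0.01).
#' @return Data frame: gene_id, contrast, p, q, larger_window, plus per gene
#'   the attribute-free columns `enriched_window` (NA when not significant)
#'   repeated on its rows.
#' @export
assign_enrichment <- function(enrichments, fdr = 0.01) {
  if (!length(enrichments))
    return(data.frame(gene_id = character(0), contrast = character(0),
                      p = numeric(0), q = numeric(0),
                      larger_window = character(0),
                      enriched_window = character(0)))
  tab <- do.call(rbind, lapply(enrichments, function(e) {
    cbind(data.frame(gene_id = e$gene_id, stringsAsFactors = FALSE),
          e$contrasts)
  }))
  tab$q <- bh_fdr(tab$p)
  enr <- vapply(split(tab, tab$gene_id), function(sub) {
    i <- which.min(sub$q)
    if (sub$q[i] < fdr) sub$larger_window[i] else NA_character_
  }, character(1))
  tab$enriched_window <- enr[tab$gene_id]
  rownames(tab) <- NULL
  tab
}

#' Flat-line test for time-structured expression
#'
#' Fits a polynomial of degree `degree` in time to `log2(x + 1)`-transformed
#' replicate-resolved abundances and compares it against an intercept-only
#' flat line by a nested-model F-test.  Genes with `p < 0.05` are considered
#' time-structured.  A constant, noise-free series has an undefined F and is
#' reported as `p = 1` (not time-structured).
#'
#' @param profile Replicate-resolved [diel_profile()] (>= 3 time points).
#' @param degree Polynomial degree (default 3).
#' @return The F-test p-value.
#' @export
flatline_test <- function(profile, degree = 3) {
  stopifnot(inherits(profile, "diel_profile"))
  if (length(profile$times) < 3L) stop("need >= 3 time points")
  if (length(profile$times) <= degree)
    stop("polynomial degree must be below the number of time points")
  t <- rep(profile$times, times = ncol(profile$values))
  y <- log2(as.vector(profile$values) + 1)
  if (stats::sd(y) == 0) return(1)
  fit0 <- stats::lm(y ~ 1)
  fit1 <- stats::lm(y ~ stats::poly(t, degree))
  p <- stats::anova(fit0, fit1)[2, "Pr(>F)"]
  if (!is.finite(p)) 1 else p
}
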