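#' Evaluate a periodic cubic spline through diel samples
#'
#' Fits a periodic (circular) cubic spline through `(times, values)` treated
#' as one 24-h cycle, and evaluates it at `at` (hours, interpreted modulo 24).
#' The periodic boundary is the physically correct choice for a diel cycle:
#' the curve and its first two derivatives match across the midnight/dawn
#' seam instead of flattening at artificial endpoints.
#'
#' @param times Sample times in (0, 24], strictly increasing.
#' @param values One value per time.
#' @param at Query times (any real hours; wrapped into the cycle).
#' @return Numeric vector of interpolated values.
#' @export
periodic_spline <- function(times, values, at) {
  stopifnot(length(times) == length(values), length(times) >= 3L)
  x <- c(times, times[1L] + 24)
  y <- c(values, values[1L])
  atw <- ((at - times[1L]) %% 24) + times[1L]
  stats::spline(x, y, method = "periodic", xout = atw)$y
}

#' Interpolate a diel profile onto a regular grid
#'
#' Replicate means are interpolated by a periodic cubic spline onto the grid
#' `{step, 2*step, ..., 24}` (the canonical grid for `step = 2`).  Used to
#' bring 4-h-resolution reference data onto the 2-h comparison grid, and to
#' upsample profiles before phase-shift estimation.  Values are clipped at 0
#' since FPKM cannot be negative.
#'
#' @param profile A [diel_profile()].
#' @param target_step Grid step in hours; must divide 24.
#' @return A [diel_profile()] with a single replicate (the interpolated mean).
#' @export
interpolate_to_grid <- function(profile, target_step = 2) {
  stopifnot(inherits(profile, "diel_profile"))
  if (length(profile$times) < 4L)
    stop("insufficient data: need >= 4 distinct time points to interpolate")
  if (24 %% target_step != 0)
    stop("target_step must divide 24")
  grid <- seq(target_step, 24, by = target_step)
  m <- replicate_mean(profile)
  if (identical(profile$times, grid))
    return(diel_profile(profile$gene_id, profile$species, grid, m))
  vals <- pmax(periodic_spline(profile$times, m, grid), 0)
  diel_profile(profile$gene_id, profile$species, grid, vals)
}

#' Z-score normalize a diel profile
#'
#' Transforms the replicate-mean series to mean 0, sd 1.  A zero-variance
#' series cannot be normalized and is returned flagged as degenerate
#' (attribute `degenerate`); degenerate profiles are excluded from
#' correlation and shift estimation and can never be called convergent.
#'
#' @param profile A [diel_profile()].
#' @return A single-replicate `diel_profile` of z-scores, with logical
#'   attribute `degenerate`.
#' @export
zscore <- function(profile) {
  stopifnot(inherits(profile, "diel_profile"))
  m <- replicate_mean(profile)
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) {
    out <- diel_profile(profile$gene_id, profile$species, profile$times,
                        rep(0, length(m)))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (m - mean(m)) / s
  # built directly: z-scores are negative, unlike raw FPKM
  out <- structure(list(gene_id = profile$gene_id, species = profile$species,
                        times = profile$times, values = matrix(z, ncol = 1L)),
                   class = "diel_profile")
  attr(out, "degenerate") <- FALSE
  out
}

#' Is a (z-scored) profile degenerate?
#' @param profile A profile returned by [zscore()].
#' @return Logical.
#' @export
is_degenerate <- function(profile) isTRUE(attr(profile, "degenerate"))
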