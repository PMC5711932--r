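#' Screen configuration
#'
#' Collects every tunable threshold of the two screens with its default.
#' Expression-arm defaults: Spearman `r_high` 0.8 (CAM-CAM) and `r_low` 0.5
#' (CAM-C3), window-contrast FDR 0.01, CAM-CAM shift at most 3 h, CAM-C3
#' shift at least 6 h, expression filter > 0.01 FPKM at >= 6 of 12 time
#' points, 0.5-h shift grid, flat-line polynomial degree 3.  Sequence-arm
#' defaults: MCL inflation 5.0, E-value cutoff 1e-5, background non-gap
#' coverage 0.8.
#'
#' @param r_high Minimum (strict) CAM-CAM Spearman correlation.
#' @param r_low Maximum (strict) CAM-C3 Spearman correlation.
#' @param fdr Window-contrast FDR threshold.
#' @param max_cam_shift Maximum |shift| in hours between the CAM orthologs.
#' @param min_c3_shift Minimum |shift| in hours between each CAM ortholog and
#'   the best-matched C3 ortholog.
#' @param min_fpkm Expression filter threshold (strict >).
#' @param min_timepoints Minimum number of time points above `min_fpkm`.
#' @param shift_grid Lag resolution in hours for shift estimation.
#' @param poly_degree Flat-line test polynomial degree.
#' @param inflation MCL inflation.
#' @param evalue_cutoff MCL E-value cutoff.
#' @param min_bg_coverage Minimum background non-gap fraction for site calls.
#' @param species Named character vector mapping the comparison slots
#'   `cam_dicot`, `cam_monocot`, `c3` to species tags of the expression
#'   matrices.
#' @param roles Species-role vector as from [cam_species_roles()].
#' @param seed Integer seed recorded for provenance of stochastic steps.
#' @return Object of class `cam_config`.
#' @export
cam_config <- function(r_high = 0.8, r_low = 0.5, fdr = 0.01,
                       max_cam_shift = 3, min_c3_shift = 6,
                       min_fpkm = 0.01, min_timepoints = 6,
                       shift_grid = 0.5, poly_degree = 3,
                       inflation = 5.0, evalue_cutoff = 1e-5,
                       min_bg_coverage = 0.8,
                       species = c(cam_dicot = "Kf", cam_monocot = "Ac",
                                   c3 = "At"),
                       roles = cam_species_roles(),
                       seed = NULL) {
  stopifnot(r_high > r_low, fdr > 0, fdr < 1, max_cam_shift >= 0,
            min_c3_shift >= 0, min_fpkm >= 0,
            min_timepoints >= 1, min_timepoints <= 12,
            shift_grid > 0, 24 %% shift_grid == 0,
            inflation > 1, evalue_cutoff > 0,
            min_bg_coverage >= 0, min_bg_coverage <= 1,
            all(c("cam_dicot", "cam_monocot", "c3") %in% names(species)))
  structure(list(r_high = r_high, r_low = r_low, fdr = fdr,
                 max_cam_shift = max_cam_shift, min_c3_shift = min_c3_shift,
                 min_fpkm = min_fpkm, min_timepoints = min_timepoints,
                 shift_grid = shift_grid, poly_degree = poly_degree,
                 inflation = inflation, evalue_cutoff = evalue_cutoff,
                 min_bg_coverage = min_bg_coverage,
                 species = species, roles = roles, seed = seed),
            class = "cam_config")
}

#' @export
print.cam_config <- function(x, ...) {
  cat("<cam_config>\n")
  for (nm in setdiff(names(x), c("species", "roles")))
    cat(sprintf("  %-16s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  cat(sprintf("  species          %s\n",
              paste(names(x$species), x$species, sep = "=", collapse = " ")))
  cat(sprintf("  roles            %s\n",
              paste(names(x$roles), x$roles, sep = "=", collapse = " ")))
  invisible(x)
}

#' Write a configuration to YAML
#' @param config A [cam_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cam_config"))
  vals <- unclass(config)
  vals$species <- as.list(vals$species)   # keep names as a yaml map
  vals$roles <- as.list(vals$roles)
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#'
#' @param path YAML file.
#' @return A [cam_config()].
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cam_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(vals$species)) vals$species <- unlist(vals$species)
  if (!is.null(vals$roles)) vals$roles <- unlist(vals$roles)
  do.call(cam_config, vals)
}
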