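#' Scan the sensitivity of dry mass production to one architectural trait
#'
#' Re-runs the simulation with a single trait scaled
#' ([apply_trait_scaling()]) while everything else — climate, salinity,
#' stressed light-use efficiency `k_T,x * eps`, seed — stays fixed, and
#' normalises shoot dry mass and total leaf area to the unscaled reference
#' run. Scanned levels follow the literature-derived grids: leaf-number
#' and internode-length retention factors from per-10-mM reduction rates
#' (see [retention_factor()]), 50-150% of the leaf-elongation salinity
#' sensitivity, and 70-130% of the leaf-angle profile.
#'
#' @param trait One of `"leaf_number"`, `"c_el_max"`, `"internode_length"`,
#'   `"leaf_angle"`.
#' @param levels Scaling factors (1 = reference).
#' @param scenario A [treatment()] (salinity 40 or 80 mM typically).
#' @param params A [growth_params()] object.
#' @param climate Climate table for the scenario's regime.
#' @param lue A [lue_function()].
#' @param k_stress A [k_schedule()] with the stressed `k_T,x`.
#' @param seed Shared seed across all runs of the scan.
#' @param n_rays Rays per daily trace.
#' @param ... Passed on to [simulate_canopy()].
#' @return A data frame of class `sensitivity_results`: `trait`, `level`,
#'   `regime`, `salinity`, `w_sh_rel` and `a_s_rel` (% of the reference
#'   run), `transmittance_pct` (final-day Q_T/Q_0, %), `w_sh` (g), `a_s`
#'   (cm^2) and `interception_J` (season total light absorbed by the
#'   foliage). The reference run is the `level = 1` row (always included).
#' @export
scan_trait <- function(trait, levels, scenario, params, climate,
                       lue = lue_function(), k_stress = NULL, seed = 1,
                       n_rays = 4000, ...) {
  if (!trait %in% c("leaf_number", "c_el_max", "internode_length",
                    "leaf_angle"))
    stop("unknown trait: ", trait)
  levels <- sort(unique(c(1, levels)))
  rows <- list()
  runs <- list()
  for (lv in levels) {
    p_lv <- apply_trait_scaling(params, trait, lv)
    runs[[as.character(lv)]] <-
      simulate_canopy(p_lv, climate, scenario, lue, k_stress,
                      n_rays = n_rays, seed = seed, ...)
  }
  ref <- runs[["1"]]
  last <- nrow(ref)
  ref_w <- ref$w_sh[last]
  ref_a <- ref$leaf_area_cm2[last]
  for (lv in levels) {
    tr <- runs[[as.character(lv)]]
    rows[[as.character(lv)]] <- data.frame(
      trait = trait, level = lv, regime = scenario$regime,
      salinity = scenario$salinity_x,
      w_sh_rel = 100 * tr$w_sh[last] / ref_w,
      a_s_rel = 100 * tr$leaf_area_cm2[last] / ref_a,
      transmittance_pct = 100 * tr$transmittance[last],
      w_sh = tr$w_sh[last], a_s = tr$leaf_area_cm2[last],
      interception_J = sum(tr$intercepted_frac * climate$par * 1e6))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_results", "data.frame")
  out
}

#' Regress the dry-mass response on the light-interception response
#'
#' Across the points of a sensitivity scan, ordinary least squares of the
#' change in shoot dry mass (relative to the reference run, %) on the
#' change in season-total canopy light interception (%). The coefficient
#' of determination measures how much of the dry-mass response is
#' explained by light interception alone.
#'
#' @param results A `sensitivity_results` data frame (>= 5 points,
#'   reference included).
#' @return List with `slope`, `intercept`, `r2`, `n`.
#' @export
interception_regression <- function(results) {
  if (nrow(results) < 5) stop("need at least 5 scan points")
  ref <- results[results$level == 1, ]
  if (nrow(ref) != 1) stop("scan must contain exactly one reference row")
  dw <- results$w_sh_rel - 100
  di <- 100 * (results$interception_J / ref$interception_J - 1)
  if (stats::sd(di) < 1e-12) stop("undefined fit: no interception variance")
  fit <- stats::lm(dw ~ di)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = suppressWarnings(summary(fit))$r.squared, n = nrow(results))
}

#' Write sensitivity results as CSV
#' @param results A `sensitivity_results` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sensitivity_csv <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
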