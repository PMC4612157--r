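#' Growth parameters for the virtual tomato canopy
#'
#' Bundles every architectural and physiological parameter of the growth
#' model: phyllochron, potential organ sizes and elongation rates, the
#' salinity sensitivity of leaf elongation, leaf inclination and curvature,
#' leaflet shape, and phyllotaxis. Defaults are calibrated so that an
#' unstressed canopy at 22/18 degC reaches roughly 30 leaves and a final
#' leaf length near 40 cm after 80 days.
#'
#' @param phyllochron_dd Thermal time between successive leaf appearances
#'   (degC d, base 10 degC).
#' @param l_max Potential final leaf (rachis) length, cm.
#' @param ler_max Potential leaf elongation rate at the peak of the
#'   expansion window under optimal conditions, cm d^-1.
#' @param leaf_dur_dd Thermal duration of leaf expansion, degC d.
#' @param c_el_max Salinity sensitivity of leaf elongation
#'   (mM^-1 kPa^-1, non-positive). The stress factor is
#'   `max(0, 1 + c_el_max * x * vpd)` for x mM NaCl.
#' @param i_max Potential final internode length, cm.
#' @param ier_max Potential internode elongation rate, cm d^-1.
#' @param int_dur_dd Thermal duration of internode elongation, degC d.
#' @param theta_base_deg Rachis inclination below the horizontal at the leaf
#'   base, degrees.
#' @param curvature_deg Additional droop of the rachis from base to tip
#'   (progressive midrib curvature), degrees.
#' @param leaflet_aspect Width/length ratio of the rhombus leaflets.
#' @param blade_area_coef Blade area per squared leaf length
#'   (area = `blade_area_coef * length^2`); the default 0.4375 makes a
#'   40 cm leaf carry 700 cm^2.
#' @param phyllotaxis_deg Azimuthal rotation between successive leaves.
#' @param phyllotaxis_jitter_deg Half-width of the uniform jitter added to
#'   the phyllotaxis angle, degrees.
#' @param sla Specific leaf area, cm^2 g^-1 (geometry/area bookkeeping only).
#' @param t_base Base temperature for thermal time, degC.
#' @param t_opt Optimum temperature of the growth response, degC.
#' @param t_width Width (degC) of the Gaussian temperature response.
#' @param tt_cap Maximum thermal time accumulated per day, degC d.
#' @param vpd_thresh VPD (kPa) above which elongation declines.
#' @param vpd_slope Fractional decline of elongation per kPa above
#'   `vpd_thresh`.
#' @param g_v_floor Floor of the VPD response factor.
#' @param initial_mass Plant dry mass at day 0, g.
#'
#' @return An object of class `growth_params` (a named list).
#' @export
growth_params <- function(phyllochron_dd = 26,
                          l_max = 40,
                          ler_max = 3.2,
                          leaf_dur_dd = 350,
                          c_el_max = -6e-4,
                          i_max = 6,
                          ier_max = 0.55,
                          int_dur_dd = 250,
                          theta_base_deg = 25,
                          curvature_deg = 30,
                          leaflet_aspect = 0.7,
                          blade_area_coef = 0.4375,
                          phyllotaxis_deg = 144,
                          phyllotaxis_jitter_deg = 10,
                          sla = 250,
                          t_base = 10,
                          t_opt = 25,
                          t_width = 12,
                          tt_cap = 15,
                          vpd_thresh = 1,
                          vpd_slope = 0.15,
                          g_v_floor = 0.5,
                          initial_mass = 0.2) {
  p <- as.list(environment())
  if (p$l_max <= 0) stop("l_max must be positive")
  if (p$i_max < 0) stop("i_max must be non-negative")
  if (p$leaflet_aspect <= 0 || p$leaflet_aspect >= 2)
    stop("leaflet_aspect must be in (0, 2)")
  if (p$c_el_max > 0) stop("c_el_max must be <= 0")
  if (p$phyllochron_dd <= 0) stop("phyllochron_dd must be positive")
  class(p) <- "growth_params"
  p
}

#' Temperature response of organ elongation
#'
#' Gaussian optimum curve peaking at `t_opt` (default 25 degC), value 1 at
#' the optimum.
#'
#' @param t_day Daytime temperature, degC.
#' @param params A [growth_params()] object.
#' @return Dimensionless factor in (0, 1].
#' @export
g_temperature <- function(t_day, params) {
  exp(-((t_day - params$t_opt) / params$t_width)^2)
}

#' VPD response of organ elongation
#'
#' Equal to 1 up to `vpd_thresh` kPa, then declines linearly with slope
#' `vpd_slope` per kPa, floored at `g_v_floor`.
#'
#' @param vpd Daytime mean vapour pressure deficit, kPa.
#' @param params A [growth_params()] object.
#' @return Dimensionless factor in `[g_v_floor, 1]`.
#' @export
g_vpd <- function(vpd, params) {
  pmax(params$g_v_floor, 1 - params$vpd_slope * pmax(0, vpd - params$vpd_thresh))
}

#' Salinity response of organ elongation
#'
#' For leaves, `max(0, 1 + c_el_max * x * vpd)`: the suppression grows with
#' both the NaCl concentration and the evaporative demand. Internode
#' elongation is insensitive to salinity (factor identically 1), matching
#' the empirical finding that salinity does not change internode length.
#'
#' @param salinity_x NaCl concentration in the nutrient solution, mM.
#' @param vpd Daytime mean VPD, kPa.
#' @param params A [growth_params()] object.
#' @param organ `"leaf"` or `"internode"`.
#' @return Dimensionless factor in `[0, 1]`.
#' @export
g_salinity <- function(salinity_x, vpd, params, organ = c("leaf", "internode")) {
  organ <- match.arg(organ)
  if (any(salinity_x < 0)) stop("salinity_x must be non-negative")
  if (organ == "internode") return(rep(1, length(salinity_x)))
  pmax(0, 1 + params$c_el_max * salinity_x * vpd)
}

# Beta-shaped potential elongation profile over the thermal expansion
# window: peak rate at mid-expansion, zero outside [0, dur].
beta_shape <- function(age_dd, dur_dd) {
  u <- age_dd / dur_dd
  ifelse(u < 0 | u > 1, 0, 4 * u * (1 - u))
}

#' Daily elongation rate of a leaf or internode
#'
#' Rate = potential rate (beta function of thermal age) x temperature
#' response x VPD response x salinity response, scaled by the day's thermal
#' drive. Organ length saturates at its potential maximum in [step_day()].
#'
#' @param organ_kind `"leaf"` or `"internode"`.
#' @param age_dd Thermal age of the organ, degC d (vectorised).
#' @param climate A single-row climate record (see [generate_climate()]).
#' @param salinity_x NaCl concentration, mM.
#' @param params A [growth_params()] object.
#' @return Elongation rate, cm d^-1.
#' @export
organ_elongation <- function(organ_kind = c("leaf", "internode"),
                             age_dd, climate, salinity_x, params) {
  organ_kind <- match.arg(organ_kind)
  if (any(age_dd < 0)) stop("age_dd must be non-negative")
  if (any(salinity_x < 0)) stop("salinity_x must be non-negative")
  rmax <- if (organ_kind == "leaf") params$ler_max else params$ier_max
  dur <- if (organ_kind == "leaf") params$leaf_dur_dd else params$int_dur_dd
  drive <- daily_thermal_time(climate, params) / params$tt_cap
  rmax * beta_shape(age_dd, dur) * drive *
    g_temperature(climate$t_day, params) *
    g_vpd(climate$vpd, params) *
    g_salinity(salinity_x, climate$vpd, params, organ_kind)
}

# Thermal time accumulated in one day from the day/night mean, base
# t_base, capped at tt_cap (development saturates above the optimum).
daily_thermal_time <- function(climate, params) {
  tmean <- (climate$t_day + climate$t_night) / 2
  min(max(tmean - params$t_base, 0), params$tt_cap)
}

#' Scale one architectural trait, leaving all others untouched
#'
#' Implements the single-trait perturbations of the sensitivity scan:
#' * `leaf_number`: a retention factor f acts on the phyllochron
#'   (`phyllochron_dd / f`), so a factor 0.88 yields ~88% of the reference
#'   final leaf count;
#' * `c_el_max`: multiplies the salinity sensitivity of leaf elongation;
#' * `internode_length`: multiplies the potential internode length `i_max`;
#' * `leaf_angle`: multiplies the leaf inclination profile
#'   (`theta_base_deg` and `curvature_deg`), larger factors giving steeper
#'   (more drooping) leaves.
#'
#' @param params A [growth_params()] object.
#' @param trait One of `"leaf_number"`, `"c_el_max"`, `"internode_length"`,
#'   `"leaf_angle"`.
#' @param factor Positive scaling factor (1 = reference).
#' @return A modified copy of `params`.
#' @export
apply_trait_scaling <- function(params, trait, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0)
    stop("factor must be a positive scalar")
  switch(trait,
    leaf_number = {
      params$phyllochron_dd <- params$phyllochron_dd / factor
    },
    c_el_max = {
      params$c_el_max <- params$c_el_max * factor
    },
    internode_length = {
      params$i_max <- params$i_max * factor
    },
    leaf_angle = {
      params$theta_base_deg <- params$theta_base_deg * factor
      params$curvature_deg <- params$curvature_deg * factor
    },
    stop("unknown trait: ", trait)
  )
  params
}

#' Convert a per-10-mM trait reduction rate to an overall retention factor
#'
#' A reduction of r% per 10 mM NaCl at x mM gives a retention of
#' `1 - r/100 * x/10` (linear in salinity), e.g. 3%/10 mM at 40 mM -> 0.88.
#'
#' @param rate_pct_per_10mM Reduction rate, percent per 10 mM NaCl.
#' @param salinity_x NaCl concentration, mM.
#' @return Retention factor in `[0, 1]`.
#' @export
retention_factor <- function(rate_pct_per_10mM, salinity_x) {
  pmax(0, 1 - rate_pct_per_10mM / 100 * salinity_x / 10)
}
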