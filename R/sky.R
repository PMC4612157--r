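#' Leaf and ground optical properties
#'
#' Defaults: adaxial/abaxial reflectance 7.3% / 12.7%, transmittance
#' 2.4% / 2.5%; the ground reflects 80% of incident light without
#' transmittance.
#'
#' @param adaxial_reflect,abaxial_reflect Reflectance of the upper/lower
#'   leaf surface.
#' @param adaxial_transmit,abaxial_transmit Transmittance of the upper/
#'   lower leaf surface.
#' @param ground_reflect,ground_transmit Ground reflectance/transmittance.
#' @return An object of class `optical_props`.
#' @export
optical_props <- function(adaxial_reflect = 0.073, abaxial_reflect = 0.127,
                          adaxial_transmit = 0.024, abaxial_transmit = 0.025,
                          ground_reflect = 0.80, ground_transmit = 0.0) {
  p <- as.list(environment())
  vals <- unlist(p)
  if (any(vals < 0 | vals > 1)) stop("optical coefficients must be in [0, 1]")
  if (p$adaxial_reflect + p$adaxial_transmit > 1 ||
      p$abaxial_reflect + p$abaxial_transmit > 1 ||
      p$ground_reflect + p$ground_transmit > 1)
    stop("reflectance + transmittance must be <= 1 per surface")
  class(p) <- "optical_props"
  p
}

# Ring layout of the 46-patch dome: 7 elevation bands of 12 deg plus a
# zenith cap, patch counts per ring chosen to keep solid angles comparable.
dome_layout <- function() {
  list(edges = seq(0, 72, by = 12), counts = c(12, 12, 8, 6, 4, 2, 1),
       cap_edge = 84)
}

# Closed-form flux weight of an elevation band under the standard overcast
# sky, L(e) proportional to (1 + 2 sin e) / 3: integrate L sin(e) cos(e) de.
soc_band_weight <- function(e1, e2) {
  f <- function(e) sin(e)^2 / 2 + (2 / 3) * sin(e)^3
  (f(e2 * pi / 180) - f(e1 * pi / 180)) / 3
}

solar_declination <- function(day_of_year) {
  23.45 * sin(2 * pi * (284 + day_of_year) / 365)
}

solar_elevation <- function(latitude, day_of_year, hour) {
  d <- solar_declination(day_of_year) * pi / 180
  phi <- latitude * pi / 180
  h <- (hour - 12) * 15 * pi / 180
  asin(sin(phi) * sin(d) + cos(phi) * cos(d) * cos(h)) * 180 / pi
}

solar_azimuth <- function(latitude, day_of_year, hour) {
  d <- solar_declination(day_of_year) * pi / 180
  phi <- latitude * pi / 180
  h <- (hour - 12) * 15 * pi / 180
  el <- solar_elevation(latitude, day_of_year, hour) * pi / 180
  saz <- atan2(sin(h), cos(h) * sin(phi) - tan(d) * cos(phi))
  (saz * 180 / pi + 180) %% 360
}

#' Construct a discretised sky dome
#'
#' Builds a hemispherical dome (46 patches by default: 7 elevation rings
#' plus a zenith cap) whose weights combine a diffuse component (standard
#' overcast sky) and a direct component obtained by tracking the solar
#' position over the day for the given latitude and date; the direct flux
#' is binned into the nearest patch with a weight proportional to the sine
#' of the solar elevation. Weights are normalised to sum to 1 and all
#' directions point downward.
#'
#' @param latitude,longitude Site coordinates, degrees (Hannover:
#'   52.38 N, 9.62 E).
#' @param day_of_year Calendar day, 1..366.
#' @param diffuse_fraction Fraction of daily flux that is diffuse.
#' @param flux Total daily PAR above the canopy, J m^-2 d^-1 (set per day
#'   by the simulation loop; default 1).
#' @return An object of class `sky_dome`: data frame of `dx,dy,dz,weight`
#'   with attributes `flux` and `max_solar_elevation`.
#' @export
build_sky <- function(latitude = 52.38, longitude = 9.62, day_of_year = 120,
                      diffuse_fraction = 0.5, flux = 1) {
  if (abs(latitude) > 90) stop("latitude must be within [-90, 90]")
  if (day_of_year < 1 || day_of_year > 366) stop("invalid day of year")
  lay <- dome_layout()
  ec <- (lay$edges + 6)           # ring centre elevations
  dirs <- list(); w_soc <- list()
  for (i in seq_along(lay$counts)) {
    k <- lay$counts[i]
    az <- (seq_len(k) - 0.5) / k * 2 * pi
    el <- ec[i] * pi / 180
    dirs[[i]] <- cbind(-cos(el) * sin(az), -cos(el) * cos(az),
                       rep(-sin(el), k))
    w_soc[[i]] <- rep(soc_band_weight(lay$edges[i], lay$edges[i] + 12) / k, k)
  }
  dirs[[length(dirs) + 1]] <- matrix(c(0, 0, -1), 1, 3)  # zenith cap
  w_soc[[length(w_soc) + 1]] <- soc_band_weight(lay$cap_edge, 90)
  dirs <- do.call(rbind, dirs)
  w_soc <- unlist(w_soc)
  w_soc <- w_soc / sum(w_soc)

  # direct beam: hourly solar track, horizontal-flux weighting
  w_dir <- numeric(nrow(dirs))
  hours <- seq(0.25, 23.75, by = 0.5)
  el <- solar_elevation(latitude, day_of_year, hours)
  keep <- el > 0
  max_el <- if (any(keep)) max(el[keep]) else 0
  if (any(keep)) {
    az <- solar_azimuth(latitude, day_of_year, hours[keep])
    elr <- el[keep] * pi / 180
    azr <- az * pi / 180
    sun <- cbind(-cos(elr) * sin(azr), -cos(elr) * cos(azr), -sin(elr))
    wt <- sin(elr)
    for (j in seq_along(wt)) {
      dots <- dirs %*% sun[j, ]
      w_dir[which.max(dots)] <- w_dir[which.max(dots)] + wt[j]
    }
    w_dir <- w_dir / sum(w_dir)
  } else {
    diffuse_fraction <- 1
  }
  w <- diffuse_fraction * w_soc + (1 - diffuse_fraction) * w_dir
  out <- data.frame(dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
                    weight = w / sum(w))
  attr(out, "flux") <- flux
  attr(out, "max_solar_elevation") <- max_el
  attr(out, "latitude") <- latitude
  attr(out, "longitude") <- longitude
  attr(out, "day_of_year") <- day_of_year
  class(out) <- c("sky_dome", "data.frame")
  out
}

#' Assemble a sky dome from explicit directions and weights
#'
#' Mainly used for controlled scenes in tests (e.g. a single vertical
#' beam).
#'
#' @param directions n x 3 matrix of (not necessarily unit) direction
#'   vectors with negative z (pointing down).
#' @param weights Non-negative weights, normalised to sum to 1.
#' @param flux Total daily flux, J m^-2 d^-1.
#' @return A `sky_dome` object.
#' @export
sky_dome <- function(directions, weights = rep(1, nrow(directions)),
                     flux = 1) {
  directions <- matrix(as.numeric(directions), ncol = 3)
  if (any(directions[, 3] >= 0)) stop("sky directions must point downward")
  nrm <- sqrt(rowSums(directions^2))
  directions <- directions / nrm
  if (any(weights < 0)) stop("weights must be non-negative")
  out <- data.frame(dx = directions[, 1], dy = directions[, 2],
                    dz = directions[, 3], weight = weights / sum(weights))
  attr(out, "flux") <- flux
  class(out) <- c("sky_dome", "data.frame")
  out
}
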