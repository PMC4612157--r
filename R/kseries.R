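#' Construct the measured shoot-mass series at harvest days
#'
#' Three constructions are exposed because a harvest carries two
#' measurements of plant size: the destructive shoot mass, and the leaf
#' area which maps to mass through the allometric relationship.
#' `mode = "mass"` uses the replicate-mean measured shoot mass directly;
#' `mode = "allometry"` passes the replicate-mean measured leaf area
#' through the fitted allometry; `mode = "combined"` (default) merges the
#' two on the log scale by inverse-variance weighting (equal measurement
#' CVs on mass and area give the area-derived log mass a variance larger
#' by `1/p^2`, hence weight `p^2`). All modes coincide exactly in the
#' noise-free limit.
#'
#' @param records Harvest records for a single treatment (one regime and
#'   one salinity level).
#' @param fit An `allometry_fit` for the record's group (required for
#'   modes `"allometry"` and `"combined"`).
#' @param mode `"combined"`, `"allometry"` or `"mass"`.
#' @return Data frame `dafla`, `w_sh` (g).
#' @export
measured_mass_series <- function(records, fit = NULL,
                                 mode = c("combined", "allometry", "mass")) {
  mode <- match.arg(mode)
  if (length(unique(records$regime)) > 1 ||
      length(unique(records$salinity)) > 1)
    stop("records must belong to a single treatment")
  days <- sort(unique(records$dafla))
  w_mass <- vapply(days, function(d)
    mean(records$shoot_mass[records$dafla == d]), numeric(1))
  if (mode == "mass") {
    w <- w_mass
  } else {
    if (is.null(fit)) stop("mode '", mode, "' needs an allometry fit")
    a <- vapply(days, function(d)
      mean(records$leaf_area[records$dafla == d]), numeric(1))
    w_area <- mass_from_area(a, fit)
    w <- if (mode == "allometry") w_area else {
      wt <- fit$p^2
      exp((log(w_mass) + wt * log(w_area)) / (1 + wt))
    }
  }
  data.frame(dafla = days, w_sh = w)
}

#' Estimate the interval-wise relative canopy light-use efficiency
#'
#' For each harvest interval (t, t+1), k is the ratio of the measured
#' shoot-mass increment to the increment of the reference simulation run
#' with the reference light-use efficiency:
#' `k = (W_m(t+1) - W_m(t)) / (W_r(t+1) - W_r(t))`.
#'
#' @param measured Data frame `dafla`, `w_sh`: measured shoot-mass series
#'   at the harvest days (see [measured_mass_series()]).
#' @param reference A reference `canopy_trajectory` (k = 1 run) covering
#'   the harvest days.
#' @param harvest_days Harvest days (DAFLA).
#' @return A [k_schedule()] with one k per inter-harvest interval.
#' @export
estimate_k <- function(measured, reference,
                       harvest_days = default_harvest_days()) {
  if (!all(harvest_days %in% measured$dafla))
    stop("measured series does not cover all harvest days")
  if (!all(harvest_days %in% reference$dafla))
    stop("reference trajectory does not cover all harvest days")
  w_m <- measured$w_sh[match(harvest_days, measured$dafla)]
  w_r <- reference$w_sh[match(harvest_days, reference$dafla)]
  d_m <- diff(w_m)
  d_r <- diff(w_r)
  if (any(d_r <= 0)) {
    i <- which(d_r <= 0)[1]
    stop("degenerate interval ", harvest_days[i], "-", harvest_days[i + 1],
         ": non-positive reference increment")
  }
  k_hat <- d_m / d_r
  if (any(k_hat <= 0))
    warning("non-positive k estimate in interval(s) ",
            paste(which(k_hat <= 0), collapse = ", "),
            " (measured series not increasing there)")
  k_schedule(k_hat,
             intervals = data.frame(from = utils::head(harvest_days, -1) + 1,
                                    to = utils::tail(harvest_days, -1)),
             strict = FALSE)
}

#' Dissect relative light-use efficiency into temperature and salinity
#' factors
#'
#' Factors the raw interval-wise k as `k_T,x = k_LT,0 * k_HT * k_x`, where
#' `k_LT,0` is the value under the low-temperature control, `k_HT` is the
#' high-temperature effect (`k_HT,0 / k_LT,0`; 1 under LT) and `k_x` the
#' salinity effect (`k_T,x / k_T,0`; 1 at 0 mM). The recomposition
#' reproduces every raw k to floating-point precision.
#'
#' @param k_table Data frame with columns `regime`, `salinity`, `from`,
#'   `to`, `k` holding the raw k for every regime x salinity x interval;
#'   the 0 mM column must be present for both regimes.
#' @return A data frame of class `k_dissection`: the input plus columns
#'   `k_lt0`, `k_ht`, `k_x`.
#' @export
dissect_k <- function(k_table) {
  need <- c("regime", "salinity", "from", "to", "k")
  if (!all(need %in% names(k_table))) stop("missing k table columns")
  key <- function(r, x, f) paste(r, x, f, sep = "|")
  idx <- stats::setNames(k_table$k,
                         key(k_table$regime, k_table$salinity, k_table$from))
  get_k <- function(r, x, f) {
    v <- idx[key(r, x, f)]
    if (is.na(v)) stop("incomplete k table: missing ", r, " ", x,
                       " mM control entry for interval starting ", f)
    unname(v)
  }
  out <- k_table
  out$k_lt0 <- mapply(function(f) get_k("LT", 0, f), k_table$from)
  out$k_ht <- ifelse(k_table$regime == "LT", 1,
                     mapply(function(f) get_k("HT", 0, f) / get_k("LT", 0, f),
                            k_table$from))
  out$k_x <- mapply(function(r, x, f)
    if (x == 0) 1 else get_k(r, x, f) / get_k(r, 0, f),
    k_table$regime, k_table$salinity, k_table$from)
  class(out) <- c("k_dissection", "data.frame")
  out
}

#' Round half away from zero
#'
#' Reporting convention for the dissected k tables (2 decimals, half-up),
#' unlike base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Closure check: re-simulate with the estimated k and compare allometry
#'
#' Runs the simulation again with `k_hat * eps` and reports the
#' discrepancy between the re-simulated series and the measured series:
#' the maximum relative shoot-mass error over the harvest days, and the
#' slope/intercept deltas between the allometric fit of the re-simulated
#' (area, mass) pairs and the measured-group fit.
#'
#' @param k_hat A [k_schedule()] (the estimate under scrutiny).
#' @param reference The reference `canopy_trajectory` used for the
#'   estimate (k = 1 run, same architecture scenario).
#' @param measured Data frame `dafla`, `w_sh` of measured masses.
#' @param measured_fit The measured-group `allometry_fit` (optional; slope
#'   and intercept deltas are `NA` without it).
#' @param harvest_days Harvest days (DAFLA).
#' @return List: `max_rel_mass_error`, `slope_delta`, `intercept_delta`,
#'   `resimulated` (data frame `dafla`, `w_sh`, `leaf_area_cm2`).
#' @export
closure_run <- function(k_hat, reference, measured, measured_fit = NULL,
                        harvest_days = default_harvest_days()) {
  resim <- rescale_trajectory(reference, k_hat)
  i <- match(harvest_days, resim$dafla)
  w_s <- resim$w_sh[i]
  a_s <- resim$leaf_area_cm2[i]
  w_m <- measured$w_sh[match(harvest_days, measured$dafla)]
  max_err <- max(abs(w_s - w_m) / w_m)
  slope_delta <- intercept_delta <- NA_real_
  if (!is.null(measured_fit)) {
    fit_sim <- stats::lm(log(a_s) ~ log(w_s))
    slope_delta <- unname(stats::coef(fit_sim)[2]) - measured_fit$p
    intercept_delta <- unname(stats::coef(fit_sim)[1]) - measured_fit$q
  }
  list(max_rel_mass_error = max_err, slope_delta = slope_delta,
       intercept_delta = intercept_delta,
       resimulated = data.frame(dafla = harvest_days, w_sh = w_s,
                                leaf_area_cm2 = a_s))
}

#' Write a k table (raw and dissected blocks) as CSV
#'
#' Mirrors the two-block layout of the reference table: the upper block
#' holds the raw interval-wise k per regime and salinity, the lower block
#' the dissected factors `k_ht` and `k_x`, rounded half-up to 2 decimals.
#'
#' @param dissection A `k_dissection` from [dissect_k()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_k_table_csv <- function(dissection, path) {
  d <- as.data.frame(dissection)
  d$k <- round_half_up(d$k, 2)
  d$k_ht <- round_half_up(d$k_ht, 2)
  d$k_x <- round_half_up(d$k_x, 2)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
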