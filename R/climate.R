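#' Define a salinity x temperature treatment
#'
#' @param regime `"LT"` (22/18 degC day/night) or `"HT"` (32/28 degC).
#' @param salinity_x NaCl concentration in the nutrient solution, mM
#'   (0, 40, 60, 80 in the evaluation experiment; any non-negative value is
#'   accepted).
#' @param salinity_start Day after first leaf appearance (DAFLA) on which
#'   the salinity treatment is applied (default 21).
#' @return An object of class `treatment`.
#' @export
treatment <- function(regime = c("LT", "HT"), salinity_x = 0,
                      salinity_start = 21) {
  regime <- match.arg(regime)
  if (salinity_x < 0) stop("salinity_x must be non-negative")
  structure(list(regime = regime, salinity_x = salinity_x,
                 salinity_start = salinity_start),
            class = "treatment")
}

regime_targets <- function(regime) {
  switch(regime,
    LT = list(t_day = 22, t_night = 18, vpd_mean = 1.0),
    HT = list(t_day = 32, t_night = 28, vpd_mean = 2.2),
    stop("unknown regime: ", regime)
  )
}

#' Generate a synthetic daily greenhouse climate
#'
#' Emulates the statistical structure of the greenhouse climate records:
#' day temperatures fluctuate around the regime set-point; daytime VPD is a
#' linear function of day temperature plus noise, tuned to a
#' temperature-VPD coefficient of determination near 0.71; daily incident
#' PAR follows a seasonal sinusoid with multiplicative log-normal
#' day-to-day variation (cloudiness). All values are non-negative.
#'
#' @param n_days Number of days (DAFLA 1..n_days).
#' @param regime `"LT"` or `"HT"`.
#' @param seed Integer seed (bit-reproducible output).
#' @param t_sd Standard deviation of day temperature around the set-point,
#'   degC.
#' @param vpd_slope Increase of VPD per degC of day temperature, kPa.
#' @param vpd_r Target Pearson correlation between day temperature and VPD.
#' @param par_mean Mean daily PAR, MJ m^-2 d^-1.
#' @param par_amp Relative amplitude of the seasonal PAR sinusoid.
#' @param par_cv Log-scale SD of the day-to-day PAR variation.
#' @param doy_start Day of year corresponding to DAFLA 1 (spring default).
#' @return A data frame of class `climate` with columns `dafla`, `t_day`,
#'   `t_night`, `vpd`, `par`.
#' @export
generate_climate <- function(n_days, regime = c("LT", "HT"), seed = 1,
                             t_sd = 1, vpd_slope = 0.25, vpd_r = 0.84,
                             par_mean = 8, par_amp = 0.4, par_cv = 0.25,
                             doy_start = 90) {
  regime <- match.arg(regime)
  if (!is.numeric(n_days) || n_days < 1) stop("n_days must be >= 1")
  n_days <- as.integer(n_days)
  tg <- regime_targets(regime)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  t_day <- tg$t_day + stats::rnorm(n_days, 0, t_sd)
  t_night <- tg$t_night + stats::rnorm(n_days, 0, t_sd / 2)
  # vpd = a + b*t_day + eps; noise SD chosen so cor(t_day, vpd) ~= vpd_r
  sd_signal <- vpd_slope * t_sd
  sd_noise <- sd_signal * sqrt(1 / vpd_r^2 - 1)
  a <- tg$vpd_mean - vpd_slope * tg$t_day
  vpd <- pmax(0.05, a + vpd_slope * t_day + stats::rnorm(n_days, 0, sd_noise))
  doy <- doy_start + seq_len(n_days) - 1
  par_season <- par_mean * (1 + par_amp * sin(2 * pi * (doy - 80) / 365))
  par <- par_season * exp(stats::rnorm(n_days, -par_cv^2 / 2, par_cv))

  out <- data.frame(dafla = seq_len(n_days), t_day = t_day,
                    t_night = t_night, vpd = vpd, par = par)
  attr(out, "regime") <- regime
  attr(out, "doy_start") <- doy_start
  class(out) <- c("climate", "data.frame")
  out
}

#' Write / read a daily climate table as CSV
#'
#' Columns: `dafla,t_day,t_night,vpd,par`.
#'
#' @param climate A climate data frame.
#' @param path File path.
#' @return `read_climate_csv` returns a `climate` data frame;
#'   `write_climate_csv` returns `path` invisibly.
#' @export
write_climate_csv <- function(climate, path) {
  utils::write.csv(as.data.frame(climate)[, c("dafla", "t_day", "t_night",
                                              "vpd", "par")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  out <- utils::read.csv(path)
  req <- c("dafla", "t_day", "t_night", "vpd", "par")
  if (!all(req %in% names(out))) stop("missing climate columns")
  class(out) <- c("climate", "data.frame")
  out
}
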