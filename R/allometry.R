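#' Fit log-log allometric relationships between leaf area and shoot mass
#'
#' Ordinary least squares of `ln(leaf area)` on `ln(shoot mass)`,
#' `ln(A) = p * ln(W_sh) + q`, fitted separately for the two temperature
#' regimes and, within each regime, for non-stressed records (salinity 0)
#' and for all salinity levels pooled — four groups in total. The
#' regression direction follows the relationship exactly as written (not
#' reduced major axis); the slope p-value is the two-sided t-test.
#'
#' @param records Harvest data frame with columns `regime`, `salinity`,
#'   `leaf_area` (cm^2) and `shoot_mass` (g).
#' @return A list of `allometry_fit` objects keyed
#'   `"LT.nonstress"`, `"LT.salinity"`, `"HT.nonstress"`, `"HT.salinity"`
#'   (groups with fewer than 3 records are skipped). Each holds `p`, `q`,
#'   `r2`, `p_value`, `n`, `group` and the underlying `lm` fit.
#' @export
fit_allometry <- function(records) {
  bad <- which(records$leaf_area <= 0 | records$shoot_mass <= 0)
  if (length(bad))
    stop("non-positive leaf area or shoot mass in record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  groups <- list(
    LT.nonstress = records$regime == "LT" & records$salinity == 0,
    LT.salinity = records$regime == "LT" & records$salinity > 0,
    HT.nonstress = records$regime == "HT" & records$salinity == 0,
    HT.salinity = records$regime == "HT" & records$salinity > 0)
  fits <- list()
  for (g in names(groups)) {
    sub <- records[groups[[g]], ]
    if (nrow(sub) < 3) next
    fits[[g]] <- fit_allometry_group(sub, g)
  }
  fits
}

fit_allometry_group <- function(records, group = "all") {
  if (nrow(records) < 3) stop("need at least 3 records to fit")
  fit <- stats::lm(log(leaf_area) ~ log(shoot_mass), data = records)
  sm <- suppressWarnings(summary(fit))  # exact fits trip summary.lm
  structure(list(
    p = unname(stats::coef(fit)[2]),
    q = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n = nrow(records),
    group = group,
    fit = fit,
    p_se = sm$coefficients[2, 2],
    q_se = sm$coefficients[1, 2]
  ), class = "allometry_fit")
}

#' Invert / apply an allometric fit
#'
#' `area_from_mass` evaluates `A = exp(p ln W + q)`; `mass_from_area` is
#' the exact algebraic inversion `W = exp((ln A - q) / p)`. The round trip
#' is the identity to floating-point precision.
#'
#' @param A Leaf area, cm^2 (positive).
#' @param W Shoot dry mass, g (positive).
#' @param fit An `allometry_fit`, or any list with elements `p` and `q`.
#' @return Mass in g, or area in cm^2.
#' @export
mass_from_area <- function(A, fit) {
  if (any(A <= 0)) stop("leaf area must be positive")
  exp((log(A) - fit$q) / fit$p)
}

#' @rdname mass_from_area
#' @export
area_from_mass <- function(W, fit) {
  if (any(W <= 0)) stop("shoot mass must be positive")
  exp(fit$p * log(W) + fit$q)
}

#' Serialise allometric fits to JSON
#' @param fits A list of `allometry_fit` objects (or a single one).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_allometry_json <- function(fits, path) {
  if (inherits(fits, "allometry_fit")) fits <- list(fits)
  out <- lapply(fits, function(f)
    list(p = f$p, q = f$q, r2 = f$r2, p_value = f$p_value, n = f$n,
         group = f$group))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
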