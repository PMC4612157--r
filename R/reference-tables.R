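#' Reference relative canopy light-use efficiency table
#'
#' Interval-wise relative canopy light-use efficiency (k) estimates for
#' tomato grown under two day/night temperature regimes (LT = 22/18 degC,
#' HT = 32/28 degC) and four NaCl levels in a greenhouse evaluation
#' experiment. Shipped as a worked-example input for [dissect_k()] and as
#' the default ground-truth schedule of the synthetic-data generator.
#'
#' @return Data frame with columns `regime`, `salinity` (mM NaCl), `from`,
#'   `to` (DAFLA interval) and `k`.
#' @export
reference_k_table <- function() {
  iv <- default_intervals()
  k <- list(
    LT.0  = c(1.38, 1.60, 1.02, 1.16, 0.70, 1.18, 0.86),
    HT.0  = c(1.33, 1.59, 0.91, 0.88, 0.49, 0.76, 0.71),
    LT.40 = c(1.61, 1.76, 1.07, 1.24, 0.68, 1.24, 0.80),
    HT.40 = c(1.42, 1.69, 0.93, 0.90, 0.46, 0.80, 0.68),
    LT.60 = c(1.32, 1.41, 0.87, 1.00, 0.55, 0.86, 0.65),
    HT.60 = c(1.24, 1.45, 0.78, 0.75, 0.39, 0.68, 0.59),
    LT.80 = c(1.10, 1.10, 0.69, 0.77, 0.45, 0.78, 0.52),
    HT.80 = c(1.08, 1.24, 0.66, 0.63, 0.33, 0.57, 0.50))
  rows <- lapply(names(k), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(regime = parts[1], salinity = as.numeric(parts[2]),
               from = iv$from, to = iv$to, k = k[[nm]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference architectural / non-architectural effect table
#'
#' Interval-wise and whole-period architectural (`r_a`, %) and
#' non-architectural (`r_n`, %) effects of salinity on shoot dry mass for
#' the same greenhouse evaluation experiment; the whole-period rows span
#' DAFLA 29-77. Shipped as a worked-example input for [total_effect()].
#'
#' @return Data frame with columns `from`, `to`, `regime`, `salinity`,
#'   `r_a`, `r_n`.
#' @export
reference_effect_table <- function() {
  iv <- rbind(default_intervals(), data.frame(from = 29, to = 77))
  r_a <- list(
    LT.40 = c(23.2, 11.7, 12.1, 13.2, 4.3, 11.3, 0.9, 8.8),
    HT.40 = c(21.2, 13.7, 8.9, 9.0, 1.1, 13.0, 5.7, 10.4),
    LT.60 = c(24.9, 16.4, 12.5, 12.3, 4.2, 9.4, 0.4, 8.9),
    HT.60 = c(27.8, 18.3, 13.3, 12.7, 6.5, 17.4, 13.2, 15.8),
    LT.80 = c(27.5, 15.6, 12.7, 12.4, 5.5, 8.4, 0.8, 9.7),
    HT.80 = c(34.4, 24.0, 18.7, 17.8, 12.8, 22.8, 20.3, 21.9))
  r_n <- list(
    LT.40 = c(-11.1, -8.5, -4.6, -5.9, 1.5, -3.7, 4.2, -2.7),
    HT.40 = c(-4.9, -5.2, -2.0, -1.7, 5.3, -3.1, -2.1, 1.2),
    LT.60 = c(2.6, 9.8, 13.0, 12.4, 19.9, 24.0, 25.6, 16.8),
    HT.60 = c(4.4, 7.3, 11.8, 12.9, 18.7, 10.1, 13.7, 10.5),
    LT.80 = c(12.8, 25.7, 27.9, 29.5, 33.8, 31.3, 37.6, 29.0),
    HT.80 = c(11.0, 16.6, 21.7, 22.8, 28.0, 20.0, 22.5, 19.0))
  rows <- lapply(names(r_a), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(from = iv$from, to = iv$to, regime = parts[1],
               salinity = as.numeric(parts[2]),
               r_a = r_a[[nm]], r_n = r_n[[nm]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
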