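#' Ground truth for the synthetic evaluation experiment
#'
#' Bundles the known quantities the generator uses so that the estimation
#' pipeline can be tested for parameter recovery: the true interval-wise
#' relative light-use efficiency per treatment, the log-log allometry
#' coefficients per regime, and the measurement noise level.
#'
#' @param k_table Data frame with columns `regime`, `salinity`, `from`,
#'   `to`, `k`: the true relative canopy light-use efficiency per harvest
#'   interval and treatment.
#' @param allometry Named list (`LT`, `HT`) of lists with elements `p` and
#'   `q` of the ground-truth allometry `ln(A) = p ln(W) + q`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise on both mass and area (default 0.08).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(k_table = default_k_truth(),
                         allometry = default_allometry_truth(),
                         noise_cv = 0.08) {
  if (any(k_table$k <= 0)) stop("all true k must be positive")
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  structure(list(k_table = k_table, allometry = allometry,
                 noise_cv = noise_cv),
            class = "ground_truth")
}

#' Default ground-truth k schedule of the synthetic experiment
#'
#' The reference greenhouse estimates ([reference_k_table()]): k above one
#' in the young canopy and declining with age, reduced under the high
#' temperature regime, and progressively reduced by salinity (more so with
#' time and concentration).
#'
#' @return Data frame `regime`, `salinity`, `from`, `to`, `k`.
#' @export
default_k_truth <- function() reference_k_table()

#' Default ground-truth allometry coefficients
#' @return Named list (`LT`, `HT`) of `p`, `q`.
#' @export
default_allometry_truth <- function() {
  list(LT = list(p = 0.62, q = 6.15), HT = list(p = 0.66, q = 5.75))
}

truth_schedule <- function(gt, regime, salinity) {
  sub <- gt$k_table[gt$k_table$regime == regime &
                      gt$k_table$salinity == salinity, ]
  if (nrow(sub) == 0)
    stop("no ground-truth k for ", regime, " / ", salinity, " mM")
  k_schedule(sub$k, intervals = sub[, c("from", "to")])
}

#' Generate synthetic harvest records
#'
#' Emulates the destructive harvests of the evaluation experiment: at each
#' harvest day the true shoot mass equals the forward simulation run with
#' `k_true * eps` instead of `eps` (obtained exactly from the reference
#' trajectory by linearity of the dry-mass equation in k), each replicate
#' is an independent mean-unbiased multiplicative log-normal draw around
#' it, and the leaf area is derived from the true mass through the
#' ground-truth allometry, with its own noise draw.
#'
#' @param gt A [ground_truth()] object.
#' @param treatments List of [treatment()] objects.
#' @param reference Named list of reference trajectories (k = 1 runs from
#'   [simulate_canopy()]), keyed by regime (`"LT"`, `"HT"`) or by
#'   `"regime.salinity"` (e.g. `"LT.40"`) when architecture differs by
#'   salinity.
#' @param harvest_days Harvest days (DAFLA), all within the simulated
#'   horizon.
#' @param n_reps Replicates per treatment and harvest day.
#' @param seed Integer seed (bit-reproducible output).
#' @return Data frame of class `harvest_records`: `dafla`, `replicate`,
#'   `regime`, `salinity`, `leaf_area` (cm^2), `shoot_mass` (g); the true
#'   (noise-free) values are attached as attribute `truth`.
#' @export
generate_harvests <- function(gt, treatments, reference,
                              harvest_days = default_harvest_days(),
                              n_reps = 4, seed = 1) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sdlog <- sqrt(log(1 + gt$noise_cv^2))
  rows <- list()
  truth_rows <- list()
  for (tr in treatments) {
    key <- paste(tr$regime, tr$salinity_x, sep = ".")
    traj <- reference[[key]] %||% reference[[tr$regime]]
    if (is.null(traj)) stop("no reference trajectory for ", key)
    if (!all(harvest_days %in% traj$dafla))
      stop("harvest day outside the simulated horizon")
    sched <- truth_schedule(gt, tr$regime, tr$salinity_x)
    scaled <- rescale_trajectory(traj, sched)
    w_true <- scaled$w_sh[match(harvest_days, scaled$dafla)]
    al <- gt$allometry[[tr$regime]]
    a_true <- exp(al$p * log(w_true) + al$q)
    for (i in seq_along(harvest_days)) {
      em <- exp(stats::rnorm(n_reps, -sdlog^2 / 2, sdlog))
      ea <- exp(stats::rnorm(n_reps, -sdlog^2 / 2, sdlog))
      rows[[length(rows) + 1]] <- data.frame(
        dafla = harvest_days[i], replicate = seq_len(n_reps),
        regime = tr$regime, salinity = tr$salinity_x,
        leaf_area = a_true[i] * ea, shoot_mass = w_true[i] * em)
    }
    truth_rows[[key]] <- data.frame(dafla = harvest_days,
                                    regime = tr$regime,
                                    salinity = tr$salinity_x,
                                    leaf_area = a_true, shoot_mass = w_true)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth_rows)
  class(out) <- c("harvest_records", "data.frame")
  out
}

#' Write / read harvest records as CSV
#'
#' Columns: `dafla,replicate,regime,salinity,leaf_area_cm2,shoot_mass_g`.
#'
#' @param records A `harvest_records` data frame.
#' @param path File path.
#' @return `read_harvest_csv` returns a `harvest_records` data frame;
#'   `write_harvest_csv` returns `path` invisibly.
#' @export
write_harvest_csv <- function(records, path) {
  df <- data.frame(dafla = records$dafla, replicate = records$replicate,
                   regime = records$regime, salinity = records$salinity,
                   leaf_area_cm2 = records$leaf_area,
                   shoot_mass_g = records$shoot_mass)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_harvest_csv
#' @export
read_harvest_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(dafla = df$dafla, replicate = df$replicate,
                    regime = df$regime, salinity = df$salinity,
                    leaf_area = df$leaf_area_cm2,
                    shoot_mass = df$shoot_mass_g)
  class(out) <- c("harvest_records", "data.frame")
  out
}

#' Serialise a ground truth to JSON
#' @param gt A [ground_truth()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(list(k_table = gt$k_table,
                            allometry = gt$allometry,
                            noise_cv = gt$noise_cv),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
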