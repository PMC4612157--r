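#' Assemble a run configuration
#'
#' A single document capturing every parameter and seed of a pipeline run
#' so that runs are reproducible and diff-able. Round-trips through YAML
#' identically.
#'
#' @param params A [growth_params()] object.
#' @param optics An [optical_props()] object.
#' @param lue_pars List with `eps_max`, `i_half` of the reference
#'   light-use efficiency.
#' @param mu Shoot partitioning fraction.
#' @param n_rays Rays per daily trace.
#' @param seed Master seed.
#' @param scenarios Data frame (`regime`, `salinity`) of the scenario
#'   grid.
#' @param intervals Harvest-interval table.
#' @param extra Optional named list merged into the document.
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(params = growth_params(), optics = optical_props(),
                       lue_pars = list(eps_max = 7e-6, i_half = 5e6),
                       mu = 0.87, n_rays = 4000, seed = 1,
                       scenarios = expand.grid(regime = c("LT", "HT"),
                                               salinity = c(0, 40, 60, 80),
                                               stringsAsFactors = FALSE),
                       intervals = default_intervals(), extra = list()) {
  scenarios <- as.data.frame(scenarios)
  attr(scenarios, "out.attrs") <- NULL
  cfg <- list(params = unclass(params), optics = unclass(optics),
              lue = lue_pars, mu = mu, n_rays = n_rays, seed = seed,
              scenarios = scenarios,
              intervals = intervals)
  cfg <- utils::modifyList(cfg, extra)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (YAML)
#'
#' `read_run_config(write_run_config(cfg, path))` reproduces `cfg`
#' exactly.
#'
#' @param cfg A [run_config()] object.
#' @param path File path.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(cfg, path) {
  doc <- unclass(cfg)
  doc$scenarios <- as.list(doc$scenarios)
  doc$intervals <- as.list(doc$intervals)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  doc$scenarios <- as.data.frame(doc$scenarios,
                                 stringsAsFactors = FALSE)
  doc$intervals <- as.data.frame(doc$intervals)
  class(doc) <- "run_config"
  doc
}
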