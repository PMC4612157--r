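#' Compare simulated and observed series
#'
#' Root mean square deviation `rmsd = sqrt(mean((sim - obs)^2))`, bias
#' `mean(sim - obs)` and accuracy `100 * (1 - rmsd / mean(obs))`, floored
#' at 0. Accuracy is undefined (flagged `NA` with a warning) when the
#' observed mean is zero.
#'
#' @param sim,obs Numeric series aligned on the same time points.
#' @return An object of class `eval_stats`: list with `rmsd`, `bias`,
#'   `accuracy` (%), `n`.
#' @export
evaluate_series <- function(sim, obs) {
  if (length(sim) != length(obs))
    stop("alignment error: series lengths differ (", length(sim), " vs ",
         length(obs), ")")
  if (length(sim) < 1) stop("need at least one point")
  d <- sim - obs
  rmsd <- sqrt(mean(d^2))
  bias <- mean(d)
  m <- mean(obs)
  accuracy <- if (m == 0) {
    warning("accuracy undefined: observed mean is zero")
    NA_real_
  } else {
    max(0, 100 * (1 - rmsd / m))
  }
  structure(list(rmsd = rmsd, bias = bias, accuracy = accuracy,
                 n = length(sim)),
            class = "eval_stats")
}

#' @export
print.eval_stats <- function(x, ...) {
  cat(sprintf("RMSD %.4g | bias %.4g | accuracy %s%% | n = %d\n",
              x$rmsd, x$bias,
              if (is.na(x$accuracy)) "NA" else sprintf("%.1f", x$accuracy),
              x$n))
  invisible(x)
}
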