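#' Fit a smoothing spline to replicate time-series measurements
#'
#' Pools all replicates (each replicate contributes an observation at its
#' sampling time) and fits a cubic smoothing spline.  The smoothing level
#' is chosen by generalized cross-validation unless an equivalent degrees
#' of freedom is given; `smoothing = "interpolate"` forces the
#' interpolation limit (degrees of freedom equal to the number of distinct
#' times).
#'
#' @param times Sampling times, minutes (replicated times allowed).
#' @param values Positive measurements, same length as `times`.
#' @param smoothing `"gcv"` (default), `"interpolate"`, or a numeric
#'   equivalent degrees of freedom.
#' @return A `spline_fit` object: list with the fitted `fun(t)`, the
#'   underlying [stats::smooth.spline] fit (or constant), and the inputs.
#' @export
#' @examples
#' f <- fit_smoothing_spline(rep(seq(0, 30, 5), 2), rnorm(14, 10, 0.1))
#' f$fun(12.5)
fit_smoothing_spline <- function(times, values, smoothing = "gcv") {
  if (length(times) != length(values)) {
    abort("`times` and `values` must have the same length")
  }
  ux <- unique(times)
  if (length(ux) < 4) abort("need at least 4 distinct time points")
  if (any(values <= 0)) abort("`values` must be positive")

  if (sd(values) < 1e-12 * max(abs(values))) {
    ## constant data: the spline is the constant (smooth.spline degenerates)
    const <- mean(values)
    return(structure(list(fun = function(t) rep(const, length(t)),
                          fit = NULL, constant = const,
                          times = times, values = values,
                          smoothing = smoothing),
                     class = "spline_fit"))
  }
  fit <- if (identical(smoothing, "gcv")) {
    smooth.spline(times, values, cv = FALSE)
  } else if (identical(smoothing, "interpolate")) {
    smooth.spline(times, values, df = length(ux), cv = FALSE)
  } else if (is.numeric(smoothing)) {
    smooth.spline(times, values, df = smoothing, cv = FALSE)
  } else {
    abort("`smoothing` must be \"gcv\", \"interpolate\" or a numeric df")
  }
  structure(list(fun = function(t) predict(fit, t)$y, fit = fit,
                 constant = NULL, times = times, values = values,
                 smoothing = smoothing),
            class = "spline_fit")
}

#' Resample a spline fit on the per-minute grid
#'
#' Evaluates the fitted smooth at integer minutes `0..t_max` and forms the
#' discrete slope `X(t) - X(t-1)` used by the flux estimator.  Negative
#' spline values (smoothing artifacts: concentrations are positive) are
#' floored at a small positive epsilon with a warning.
#'
#' @param fit A [fit_smoothing_spline()] result.
#' @param t_max Last minute of the grid (default 30).
#' @param floor_eps Floor for negative values; defaults to `1e-9` times the
#'   mean observed value.
#' @return Tibble with `t_max + 1` rows: `time_min`, `value`, `diff`
#'   (`NA` at minute 0).
#' @export
resample_per_minute <- function(fit, t_max = 30, floor_eps = NULL) {
  grid <- 0:t_max
  vals <- fit$fun(grid)
  eps <- floor_eps %||% (1e-9 * mean(fit$values))
  if (any(vals < eps)) {
    warn(sprintf("flooring %d non-positive spline value(s) at %.3g",
                 sum(vals < eps), eps))
    vals <- pmax(vals, eps)
  }
  tibble::tibble(time_min = grid, value = vals,
                 diff = c(NA_real_, base::diff(vals)))
}

#' Preprocess an observed dataset to the per-minute grid
#'
#' Applies [fit_smoothing_spline()] and [resample_per_minute()] to every
#' pool of a tidy observation table.
#'
#' @param observations Tibble with columns `time_min`, `replicate`, `pool`
#'   (and optionally `pool_id`), `value` — the schema written by
#'   [write_dataset()], which real data can adopt as well.
#' @param smoothing Passed to [fit_smoothing_spline()].
#' @param t_max Last minute of the resampling grid.
#' @return Tibble with columns `pool` (and `pool_id` if present in the
#'   input), `time_min`, `value`, `diff`.
#' @export
#' @examples
#' net <- ceramide_network()
#' ds <- generate_dataset(net, seed = 1)
#' pm <- preprocess_timeseries(ds$observations)
preprocess_timeseries <- function(observations, smoothing = "gcv",
                                  t_max = 30) {
  keys <- intersect(c("pool_id", "pool"), names(observations))
  if (!"pool" %in% keys) abort("`observations` needs a `pool` column")
  observations |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      fit <- fit_smoothing_spline(d$time_min, d$value, smoothing)
      resample_per_minute(fit, t_max)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(keys[1], "time_min"))))
}
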