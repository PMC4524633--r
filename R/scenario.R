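#' Parametric activity shapes
#'
#' Unit-baseline multipliers used by the scenario generator to emulate the
#' qualitative enzyme-activity responses seen under heat stress: an
#' immediate spike that decays (`spike_decay`), a slower bump peaking later
#' (`delayed_peak`), a spike followed by a dip below baseline that recovers
#' (`undershoot_recover`), a sustained step change (`step`), and no change
#' (`flat`).  Every shape evaluates to exactly 1 at `t = 0` and is floored
#' at 0.
#'
#' @param t Time in minutes (vectorized).
#' @param shape One of `"flat"`, `"spike_decay"`, `"delayed_peak"`,
#'   `"undershoot_recover"`, `"step"`.
#' @param peak Peak fold change (for the bump shapes).
#' @param t_peak Time of the peak, minutes.
#' @param depth Depth of the undershoot below baseline (fraction, < 1).
#' @param t_under Time of the deepest undershoot, minutes.
#' @param step_fold,step_time Fold level after, and time of, the step.
#' @return Numeric multiplier vector, same length as `t`.
#' @export
#' @examples
#' activity_shape(0:30, "spike_decay", peak = 5, t_peak = 2)
activity_shape <- function(t, shape, peak = 2, t_peak = 2,
                           depth = 0.5, t_under = 10,
                           step_fold = 2, step_time = 9) {
  bump1 <- function(t, tp) (t / tp) * exp(1 - t / tp)
  bump3 <- function(t, tp) (t / tp)^3 * exp(3 * (1 - t / tp))
  val <- switch(shape,
    flat = rep(1, length(t)),
    spike_decay = 1 + (peak - 1) * bump1(t, t_peak),
    delayed_peak = 1 + (peak - 1) * bump3(t, t_peak),
    undershoot_recover =
      1 + (peak - 1) * bump1(t, t_peak) - depth * bump3(t, t_under),
    step = ifelse(t >= step_time, step_fold, 1),
    abort(sprintf("unknown activity shape '%s'", shape))
  )
  pmax(val, 0)
}

#' Build a ground-truth activity scenario
#'
#' Assigns a parametric activity shape to every flux of the network, by
#' enzyme class and/or by individual flux id.  The result is the synthetic
#' ground truth handed to the simulator: the multiplier of each flux's
#' baseline activity over the 30-minute heat-stress window.
#'
#' @param net A [ceramide_network()].
#' @param assignments A list whose names are enzyme classes (e.g.
#'   `ceramide_synthase`) or flux ids (`"V21"`), and whose elements are
#'   lists with a `shape` and its parameters (see [activity_shape()]).
#'   Unassigned fluxes are `flat`.  Alternatively a preset name from
#'   [scenario_presets()].
#' @param seed Integer; stored in the scenario and used for the optional
#'   parameter `jitter`.
#' @param jitter Relative log-normal jitter applied to `peak` and `t_peak`
#'   per flux (default 0, i.e. fully deterministic parameters).
#' @return An `activity_scenario` object: a tibble of per-flux shape
#'   parameters with the seed attached.
#' @export
#' @examples
#' net <- ceramide_network()
#' sc <- make_scenario(net, "heat_stress", seed = 1)
make_scenario <- function(net, assignments = list(), seed = 1L, jitter = 0) {
  if (is.character(assignments) && length(assignments) == 1L) {
    presets <- scenario_presets()
    if (!assignments %in% names(presets)) {
      abort(sprintf("unknown scenario preset '%s'", assignments))
    }
    assignments <- presets[[assignments]]
  }
  sc <- tibble::tibble(
    flux_id = net$fluxes$id,
    flux = paste0("V", net$fluxes$id),
    enzyme_class = net$fluxes$enzyme_class,
    shape = "flat", peak = 1, t_peak = 2, depth = 0,
    t_under = 10, step_fold = 1, step_time = 9
  )
  apply_one <- function(sc, rows, spec) {
    for (fld in names(spec)) {
      if (!fld %in% names(sc)) abort(sprintf("unknown shape field '%s'", fld))
      sc[rows, fld] <- spec[[fld]]
    }
    sc
  }
  ## class-level assignments first, then per-flux overrides
  for (nm in names(assignments)) {
    if (nm %in% ENZYME_CLASSES) {
      sc <- apply_one(sc, sc$enzyme_class == nm, assignments[[nm]])
    }
  }
  for (nm in names(assignments)) {
    if (grepl("^V[0-9]+$", nm)) {
      if (!nm %in% sc$flux) abort(sprintf("unknown flux '%s'", nm))
      sc <- apply_one(sc, sc$flux == nm, assignments[[nm]])
    } else if (!nm %in% ENZYME_CLASSES) {
      abort(sprintf("'%s' is neither an enzyme class nor a flux id", nm))
    }
  }
  bad <- sc$flux[sc$peak < 0.1 & sc$shape != "flat" |
                 sc$peak > 20 | sc$t_peak < 0 | sc$t_peak > 30]
  if (length(bad)) {
    abort(sprintf("shape parameters out of range for: %s",
                  paste(bad, collapse = ", ")))
  }
  if (jitter > 0) {
    n <- nrow(sc)
    fac <- with_seed(seed, matrix(exp(rnorm(2 * n, 0, jitter)), n, 2))
    sc$peak <- 1 + (sc$peak - 1) * fac[, 1]
    sc$t_peak <- pmin(pmax(sc$t_peak * fac[, 2], 0.5), 30)
  }
  structure(sc, seed = seed, class = c("activity_scenario", class(sc)))
}

#' Bundled scenario presets
#'
#' Named shape assignments that mimic the qualitative heat-stress findings
#' for the ceramide pathway (immediate synthase spike, delayed IPCase peak,
#' very-long-chain synthase undershoot, ...).  All magnitudes are synthetic
#' choices; only the shapes carry meaning.
#'
#' @return Named list of assignment lists for [make_scenario()].
#' @export
scenario_presets <- function() {
  list(
    flat = list(),
    heat_stress = list(
      ceramide_synthase = list(shape = "spike_decay", peak = 4, t_peak = 2),
      dihydroceramidase = list(shape = "spike_decay", peak = 3, t_peak = 3),
      phytoceramidase   = list(shape = "delayed_peak", peak = 2.5, t_peak = 5),
      IPC_synthase      = list(shape = "spike_decay", peak = 2, t_peak = 3),
      IPCase            = list(shape = "delayed_peak", peak = 3, t_peak = 10),
      DHC_hydroxylase   = list(shape = "spike_decay", peak = 2, t_peak = 2),
      ## very-long-chain synthase: brief strong flare then undershoot
      V21 = list(shape = "undershoot_recover", peak = 5, t_peak = 1,
                 depth = 0.6, t_under = 10),
      V42 = list(shape = "spike_decay", peak = 4.5, t_peak = 1.5)
    ),
    synthase_C26_spike = list(
      V21 = list(shape = "undershoot_recover", peak = 5, t_peak = 1,
                 depth = 0.6, t_under = 10),
      V42 = list(shape = "spike_decay", peak = 4.5, t_peak = 1.5)
    ),
    ipcase_midpeak = list(
      IPCase = list(shape = "delayed_peak", peak = 3, t_peak = 10)
    ),
    ipcase_step = list(
      IPCase = list(shape = "step", step_fold = 2, step_time = 9)
    )
  )
}

#' Evaluate a scenario's activity multipliers
#'
#' @param scenario An [make_scenario()] object.
#' @param t A single time point, minutes.
#' @return Numeric vector of per-flux multipliers (baseline fold).
#' @export
scenario_multipliers <- function(scenario, t) {
  vapply(seq_len(nrow(scenario)), function(i) {
    activity_shape(t, scenario$shape[i], scenario$peak[i], scenario$t_peak[i],
                   scenario$depth[i], scenario$t_under[i],
                   scenario$step_fold[i], scenario$step_time[i])
  }, numeric(1))
}

## activity function t -> 53-vector for a scenario on top of baseline
scenario_activity_fn <- function(scenario, baseline_activities) {
  ## precompute per-shape closures once; evaluated per ODE step
  n <- nrow(scenario)
  force(baseline_activities)
  function(t) baseline_activities * scenario_multipliers(scenario, t)
}
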