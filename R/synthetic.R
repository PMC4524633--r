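#' Generate a synthetic heat-stress ceramide dataset
#'
#' Simulates the network from its pre-stress steady state under a
#' ground-truth activity scenario, then emulates the experimental design:
#' the ten ceramide pools (DHC and PHC species; fatty-acyl-CoA pools are
#' unobserved) are sampled every 5 minutes from 0 to 30 minutes in
#' duplicate, and every observation is perturbed by an independent
#' multiplicative factor drawn from `U(noise[1], noise[2])` (default
#' `U(1/1.5, 1.5)`).  The per-minute ground truth (concentrations, fluxes
#' and activities) is retained so every downstream estimate can be scored.
#'
#' @param net A [ceramide_network()].
#' @param scenario An [make_scenario()] scenario (default flat).
#' @param baseline Output of [baseline_state()]: the steady-state operating
#'   point from which the simulation starts.
#' @param noise Multiplicative noise bounds `c(a, b)` with
#'   `0 < a <= 1 <= b`; use `c(1, 1)` for noise-free data.
#' @param noise_model `"uniform"` (default) or `"lognormal"` (matched so
#'   that `log(b)` is the log-sd).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @param sample_times Observation times, minutes.
#' @param n_replicates Number of replicate series.
#' @return A `ceramide_dataset`: list with `observations` (tibble
#'   `time_min, replicate, pool_id, pool, value`), `truth` (per-minute
#'   tibbles `concentrations`, `fluxes`, `activities`), `scenario`,
#'   `baseline`, `noise`, `seed` and the network.
#' @export
#' @examples
#' net <- ceramide_network()
#' ds <- generate_dataset(net, seed = 1, noise = c(1, 1))
generate_dataset <- function(net, scenario = make_scenario(net),
                             baseline = baseline_state(net),
                             noise = c(1 / 1.5, 1.5),
                             noise_model = c("uniform", "lognormal"),
                             seed = 1L,
                             sample_times = seq(0, 30, by = 5),
                             n_replicates = 2L) {
  noise_model <- match.arg(noise_model)
  if (!(noise[1] > 0 && noise[1] <= 1 && noise[2] >= 1)) {
    abort("`noise` must satisfy 0 < a <= 1 <= b")
  }
  act_fn <- scenario_activity_fn(scenario, baseline$activities)
  grid <- 0:30
  traj <- simulate_network(net, act_fn, baseline$x0, grid)
  conc <- tidyr::pivot_wider(traj, names_from = "pool", values_from = "value",
                             id_cols = "time_min")
  conc_mat <- as.matrix(conc[, net$pools$name])

  dvals_at <- function(t) vapply(net$drivers, function(f) f(t), numeric(1))
  act_mat <- t(vapply(grid, act_fn, numeric(nrow(net$fluxes))))
  flux_mat <- t(vapply(seq_along(grid), function(i) {
    rates_fast(net, conc_mat[i, ], act_mat[i, ], dvals_at(grid[i]))
  }, numeric(nrow(net$fluxes))))

  measured <- net$pools$id[net$pools$role != "FattyAcylCoA"]
  obs_grid <- tidyr::expand_grid(
    time_min = sample_times,
    replicate = seq_len(n_replicates),
    pool_id = measured
  )
  truth_vals <- conc_mat[cbind(match(obs_grid$time_min, grid),
                               obs_grid$pool_id)]
  n_obs <- nrow(obs_grid)
  factors <- with_seed(seed, switch(noise_model,
    uniform = runif(n_obs, noise[1], noise[2]),
    lognormal = exp(rnorm(n_obs, 0, log(noise[2])))
  ))

  flux_names <- colnames(net$S)
  truth_fluxes <- tibble::tibble(
    time_min = rep(grid, times = ncol(flux_mat)),
    flux_id = rep(net$fluxes$id, each = length(grid)),
    flux = rep(flux_names, each = length(grid)),
    enzyme_class = rep(net$fluxes$enzyme_class, each = length(grid)),
    value = as.vector(flux_mat)
  )
  truth_acts <- truth_fluxes
  truth_acts$value <- as.vector(act_mat)

  structure(list(
    observations = dplyr::mutate(
      obs_grid,
      pool = net$pools$name[.data$pool_id],
      truth = truth_vals,
      noise_factor = factors,
      value = truth_vals * factors
    ),
    truth = list(
      concentrations = traj,
      fluxes = truth_fluxes,
      activities = truth_acts
    ),
    scenario = scenario,
    baseline = baseline,
    network = net,
    noise = noise,
    noise_model = noise_model,
    seed = seed
  ), class = "ceramide_dataset")
}

#' @export
print.ceramide_dataset <- function(x, ...) {
  cat(sprintf(
    "<ceramide_dataset> %d observations (%d pools x %d times x %d replicates), noise U(%.3g, %.3g), seed %d\n",
    nrow(x$observations), length(unique(x$observations$pool_id)),
    length(unique(x$observations$time_min)),
    max(x$observations$replicate), x$noise[1], x$noise[2], x$seed))
  invisible(x)
}

#' Boundary-flux constraint table of a synthetic dataset
#'
#' Sums the true per-minute fluxes over each boundary group: exactly the
#' grouped flux time courses that, for real data, would be exported from
#' the prior whole-pathway model and handed to the flux estimator as
#' constraints.
#'
#' @param dataset A [generate_dataset()] result.
#' @param groups Optional alternative grouping (named list of flux ids);
#'   defaults to the network's boundary groups.  Fluxes covered by no group
#'   trigger a coverage warning.
#' @return Tibble with columns `time_min`, `group`, `value`.
#' @export
export_boundary_table <- function(dataset, groups = NULL) {
  net <- dataset$network
  if (is.null(groups)) {
    groups <- net$boundary_groups
  }
  covered <- sort(unique(unlist(groups)))
  missing <- setdiff(net$fluxes$id, covered)
  if (length(missing)) {
    warn(sprintf("flux(es) not covered by any boundary group: %s",
                 paste(missing, collapse = ", ")))
  }
  fl <- dataset$truth$fluxes
  purrr::imap_dfr(groups, function(ids, nm) {
    fl |>
      dplyr::filter(.data$flux_id %in% ids) |>
      dplyr::group_by(.data$time_min) |>
      dplyr::summarise(value = sum(.data$value), .groups = "drop") |>
      dplyr::mutate(group = nm, .after = "time_min")
  })
}

#' Ground-truth per-minute table of a synthetic dataset
#'
#' Formats the dataset's true per-minute concentrations in the schema
#' produced by [preprocess_timeseries()] (`pool_id`, `pool`, `time_min`,
#' `value`, `diff`), so downstream stages can be scored against an input
#' free of sampling and smoothing error.
#'
#' @param dataset A [generate_dataset()] result.
#' @param pools `"measured"` (default): the ten observed ceramide pools;
#'   `"all"`: the full state including the fatty-acyl-CoA pools.
#' @return Tibble with one row per pool and minute.
#' @export
truth_minute_table <- function(dataset, pools = c("measured", "all")) {
  pools <- match.arg(pools)
  net <- dataset$network
  keep <- if (pools == "measured") {
    net$pools$id[net$pools$role != "FattyAcylCoA"]
  } else {
    net$pools$id
  }
  dataset$truth$concentrations |>
    dplyr::filter(.data$pool_id %in% keep) |>
    dplyr::group_by(.data$pool_id, .data$pool) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::mutate(diff = c(NA_real_, base::diff(.data$value))) |>
    dplyr::ungroup()
}

#' Write a dataset's tidy CSV and manifest files
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    observations = file.path(dir, "observations.csv"),
    truth_concentrations = file.path(dir, "truth_concentrations.csv"),
    truth_fluxes = file.path(dir, "truth_fluxes.csv"),
    truth_activities = file.path(dir, "truth_activities.csv"),
    boundary_table = file.path(dir, "boundary_table.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  utils::write.csv(
    dataset$observations[, c("time_min", "replicate", "pool", "value")],
    paths["observations"], row.names = FALSE)
  utils::write.csv(dataset$truth$concentrations,
                   paths["truth_concentrations"], row.names = FALSE)
  utils::write.csv(dataset$truth$fluxes, paths["truth_fluxes"],
                   row.names = FALSE)
  utils::write.csv(dataset$truth$activities, paths["truth_activities"],
                   row.names = FALSE)
  utils::write.csv(export_boundary_table(dataset), paths["boundary_table"],
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = dataset$seed, noise = dataset$noise,
         noise_model = dataset$noise_model,
         scenario = as.data.frame(dataset$scenario)),
    paths["manifest"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
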