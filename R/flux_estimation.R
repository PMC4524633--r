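#' Assemble a single-minute flux estimation problem
#'
#' The estimation objective at one minute combines three quadratic terms:
#' the stoichiometric slope fit `w_slope * ||S v - slope||^2`, the
#' boundary-group constraint `w_boundary * ||A v - b||^2` (the grouped flux
#' totals known from the prior whole-pathway model), and a smoothness pull
#' toward the previous minute's flux vector
#' `w_smooth * ||v - v_prev||^2`, all subject to per-flux bounds
#' `0 <= v <= upper`.  The result is a bound-constrained convex quadratic
#' program; its quadratic form is precomputed here.
#'
#' @param net A [ceramide_network()].
#' @param slopes Numeric vector, one discrete slope `X(t) - X(t-1)` per
#'   pool (unmeasured pools are assumed at steady state, i.e. slope 0).
#' @param boundary_targets Named vector of group flux totals at this
#'   minute.
#' @param v_prev Previous-minute flux vector for the smoothness term, or
#'   `NULL` to drop the term.
#' @param bounds List with `lower` and `upper` per-flux bound vectors.
#' @param weights Named vector `c(slope =, boundary =, smooth =)`.
#' @return A `flux_problem` list with the precomputed quadratic form.
#' @export
flux_problem <- function(net, slopes, boundary_targets, v_prev = NULL,
                         bounds = NULL,
                         weights = c(slope = 1, boundary = 1, smooth = 0.1)) {
  n <- nrow(net$fluxes)
  if (length(slopes) != nrow(net$pools)) {
    abort("`slopes` must have one entry per pool")
  }
  A <- group_matrix(net)
  gnames <- rownames(A)
  if (!all(gnames %in% names(boundary_targets))) {
    abort("`boundary_targets` must cover every boundary group")
  }
  b <- boundary_targets[gnames]
  if (is.null(bounds)) bounds <- list(lower = rep(0, n), upper = rep(Inf, n))
  if (any(bounds$lower < 0)) abort("lower flux bounds must be >= 0")
  w <- weights
  ws <- w[["slope"]]; wb <- w[["boundary"]]
  wm <- if (is.null(v_prev)) 0 else w[["smooth"]]
  if (is.null(v_prev)) v_prev <- rep(0, n)

  Q <- ws * crossprod(net$S) + wb * crossprod(A) + wm * diag(n)
  cvec <- ws * drop(crossprod(net$S, slopes)) +
    wb * drop(crossprod(A, b)) + wm * v_prev
  const <- ws * sum(slopes^2) + wb * sum(b^2) + wm * sum(v_prev^2)

  structure(list(net = net, slopes = slopes, boundary_targets = b,
                 v_prev = v_prev, bounds = bounds, weights = w,
                 Q = Q, cvec = cvec, const = const, n = n),
            class = "flux_problem")
}

## objective and gradient of the quadratic program
qp_objective <- function(problem, v) {
  drop(v %*% problem$Q %*% v) - 2 * sum(problem$cvec * v) + problem$const
}

#' Solve one random restart of a flux estimation problem
#'
#' Runs a bound-constrained quasi-Newton solve (`L-BFGS-B`) of the
#' quadratic objective from the given initial flux vector.  The returned
#' objective is never worse than the objective at the initial point.
#'
#' @param problem A [flux_problem()].
#' @param init Initial flux vector (clipped into the bounds).
#' @param tol Convergence control: the solve is flagged converged when the
#'   optimizer reports success at `factr = tol / .Machine$double.eps`.
#' @return List with `solution`, `objective`, `converged`.
#' @export
solve_flux_restart <- function(problem, init, tol = 1e-12) {
  lo <- problem$bounds$lower
  hi <- problem$bounds$upper
  init <- pmin(pmax(init, lo), hi)
  Q <- problem$Q; cvec <- problem$cvec
  fn <- function(v) drop(v %*% Q %*% v) - 2 * sum(cvec * v) + problem$const
  gr <- function(v) drop(2 * (Q %*% v) - 2 * cvec)
  fit <- optim(init, fn, gr, method = "L-BFGS-B", lower = lo, upper = hi,
               control = list(maxit = 2000L,
                              factr = tol / .Machine$double.eps))
  conv <- fit$convergence == 0L
  if (!conv) {
    ## line searches can terminate abnormally near the solution on
    ## ill-conditioned problems; polish from the endpoint and accept the
    ## point when the first-order condition holds or progress has stalled
    refit <- optim(fit$par, fn, gr, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = 2000L,
                                  factr = tol / .Machine$double.eps))
    gain <- fit$value - refit$value
    if (refit$value <= fit$value) fit <- refit
    g <- gr(fit$par)
    at_lo <- fit$par <= lo + 1e-12 & g > 0
    at_hi <- fit$par >= hi - 1e-12 & g < 0
    conv <- refit$convergence == 0L ||
      max(abs(g[!(at_lo | at_hi)]), 0) <= 1e-8 ||
      gain < 1e-12 * max(1, abs(fit$value))
  }
  obj <- max(fit$value, 0)   # guard tiny negative round-off
  list(solution = fit$par, objective = obj, converged = conv)
}

#' Ensemble dynamic flux estimation over the 30-minute grid
#'
#' For every minute `t = 1..30`, solves the flux estimation problem from
#' `n_restart` random initial flux vectors drawn i.i.d. from
#' `U(init[1], init[2])` (defaults `U(0.01, 100)`), and aggregates the
#' converged solutions (mean, median, 20th/80th percentiles per flux).
#' The minute-0 anchor — also used as the previous-minute vector of the
#' first solve — is the minimum-norm steady-state flux vector implied by
#' the minute-0 state and boundary targets; subsequent minutes are pulled
#' toward the previous minute's ensemble mean.
#'
#' @param minute_tbl Per-minute values and diffs from
#'   [preprocess_timeseries()].
#' @param boundary_tbl Boundary-group time courses (`time_min`, `group`,
#'   `value`), e.g. from [export_boundary_table()]; interpolated linearly
#'   to the estimation minutes.
#' @param net A [ceramide_network()].
#' @param n_restart Number of random restarts per minute.
#' @param init Lower and upper limit of the uniform restart distribution.
#' @param weights Objective weights, see [flux_problem()].
#' @param bounds Optional bounds list; default `[0, 100 x baseline flux]`
#'   per flux (baseline floored at 1% of the mean baseline flux so that
#'   fluxes with a tiny minimum-norm baseline are not frozen).
#' @param unobserved_state Named concentrations for pools absent from
#'   `minute_tbl` (default: the reference baseline); their slopes are
#'   taken as 0 (assumed near steady state, as for the unmeasured
#'   fatty-acyl-CoA pools).
#' @param seed Integer seed; ensembles are byte-identical given the seed.
#' @return A `flux_ensemble` object (solutions per minute, aggregates,
#'   problem record).  Use [tidy()] for the aggregate table.
#' @export
#' @examples
#' \donttest{
#' net <- ceramide_network()
#' ds <- generate_dataset(net, seed = 1, noise = c(1, 1))
#' pm <- preprocess_timeseries(ds$observations)
#' bt <- export_boundary_table(ds)
#' ens <- estimate_flux_ensemble(pm, bt, net, n_restart = 10, seed = 1)
#' }
estimate_flux_ensemble <- function(minute_tbl, boundary_tbl, net,
                                   n_restart = 100L,
                                   init = c(0.01, 100),
                                   weights = c(slope = 1, boundary = 1,
                                               smooth = 0.1),
                                   bounds = NULL,
                                   unobserved_state = NULL,
                                   seed = 1L) {
  if (n_restart < 1L) abort("`n_restart` must be >= 1")
  if (!(init[1] > 0 && init[1] < init[2])) {
    abort("`init` must satisfy 0 < low < high")
  }
  pools <- net$pools
  measured <- intersect(pools$name, unique(minute_tbl$pool))
  if (!length(measured)) abort("no pool of `minute_tbl` matches the network")
  unmeasured <- setdiff(pools$name, measured)
  if (is.null(unobserved_state)) {
    unobserved_state <- baseline_state(net)$x0[unmeasured]
  }
  t_grid <- sort(unique(minute_tbl$time_min))
  minutes <- t_grid[t_grid >= 1]

  wide_val <- tidyr::pivot_wider(minute_tbl, id_cols = "time_min",
                                 names_from = "pool", values_from = "value")
  wide_dif <- tidyr::pivot_wider(minute_tbl, id_cols = "time_min",
                                 names_from = "pool", values_from = "diff")
  state_at <- function(t) {
    x <- setNames(rep(NA_real_, nrow(pools)), pools$name)
    row <- which(wide_val$time_min == t)
    x[measured] <- unlist(wide_val[row, measured])
    x[unmeasured] <- unobserved_state[unmeasured]
    x
  }
  slope_at <- function(t) {
    s <- setNames(rep(0, nrow(pools)), pools$name)
    row <- which(wide_dif$time_min == t)
    s[measured] <- unlist(wide_dif[row, measured])
    s
  }

  gnames <- names(net$boundary_groups)
  target_fns <- lapply(gnames, function(g) {
    d <- boundary_tbl[boundary_tbl$group == g, ]
    if (!nrow(d)) abort(sprintf("boundary table has no rows for group '%s'", g))
    approxfun(d$time_min, d$value, rule = 2)
  })
  names(target_fns) <- gnames
  targets_at <- function(t) vapply(target_fns, function(f) f(t), numeric(1))

  ## minute-0 anchor: steady-state flux implied by the data and targets
  bal0 <- baseline_activities(net, state_at(min(t_grid)),
                              targets_at(min(t_grid)), t = min(t_grid))
  v0 <- bal0$fluxes
  if (is.null(bounds)) {
    ref <- pmax(v0, 0.01 * mean(v0))
    bounds <- list(lower = rep(0, length(v0)), upper = 100 * ref)
  }

  seeds <- spawn_seeds(seed, length(minutes))
  n_flux <- nrow(net$fluxes)
  solutions <- vector("list", length(minutes))
  objectives <- vector("list", length(minutes))
  conv <- vector("list", length(minutes))
  v_prev <- v0
  for (i in seq_along(minutes)) {
    t <- minutes[i]
    prob <- flux_problem(net, slope_at(t), targets_at(t), v_prev = v_prev,
                         bounds = bounds, weights = weights)
    inits <- with_seed(seeds[i],
                       matrix(runif(n_restart * n_flux, init[1], init[2]),
                              n_restart, n_flux))
    sols <- matrix(NA_real_, n_restart, n_flux,
                   dimnames = list(NULL, colnames(net$S)))
    objs <- numeric(n_restart)
    ok <- logical(n_restart)
    for (r in seq_len(n_restart)) {
      res <- solve_flux_restart(prob, inits[r, ])
      sols[r, ] <- res$solution
      objs[r] <- res$objective
      ok[r] <- res$converged
    }
    if (!any(ok)) {
      abort(sprintf("all %d restarts failed to converge at minute %d",
                    n_restart, t))
    }
    solutions[[i]] <- sols
    objectives[[i]] <- objs
    conv[[i]] <- ok
    v_prev <- colMeans(sols[ok, , drop = FALSE])
  }

  ens <- structure(list(
    minutes = minutes,
    solutions = solutions, objectives = objectives, converged = conv,
    slopes = t(vapply(minutes, slope_at, numeric(nrow(pools)))),
    targets = t(vapply(minutes, targets_at, numeric(length(gnames)))),
    baseline = list(fluxes = v0, activities = bal0$activities,
                    state = state_at(min(t_grid))),
    bounds = bounds, weights = weights, init = init,
    n_restart = as.integer(n_restart), seed = seed, net = net
  ), class = "flux_ensemble")
  ens$aggregates <- aggregate_ensemble(ens)
  ens
}

#' Aggregate an ensemble of flux solutions
#'
#' Mean, median and 20th/80th percentile of every flux at every minute,
#' computed over converged restarts only.
#'
#' @param ensemble A [estimate_flux_ensemble()] result.
#' @return Tibble with columns `time_min`, `flux_id`, `flux`,
#'   `enzyme_class`, `mean`, `median`, `p20`, `p80`, `n_converged`.
#' @export
aggregate_ensemble <- function(ensemble) {
  net <- ensemble$net
  purrr::map2_dfr(ensemble$minutes, seq_along(ensemble$minutes),
                  function(t, i) {
    sols <- ensemble$solutions[[i]][ensemble$converged[[i]], , drop = FALSE]
    qs <- apply(sols, 2, quantile, probs = c(0.2, 0.8), names = FALSE)
    tibble::tibble(
      time_min = t,
      flux_id = net$fluxes$id,
      flux = colnames(net$S),
      enzyme_class = net$fluxes$enzyme_class,
      mean = unname(colMeans(sols)),
      median = unname(apply(sols, 2, median)),
      p20 = unname(qs[1, ]), p80 = unname(qs[2, ]),
      n_converged = nrow(sols)
    )
  })
}

#' @export
print.flux_ensemble <- function(x, ...) {
  cat(sprintf(
    "<flux_ensemble> %d minutes x %d restarts, %d fluxes (%.1f%% converged), seed %d\n",
    length(x$minutes), x$n_restart, ncol(x$solutions[[1]]),
    100 * mean(unlist(x$converged)), x$seed))
  invisible(x)
}

#' @export
tidy.flux_ensemble <- function(x, ...) x$aggregates

#' @export
glance.flux_ensemble <- function(x, ...) {
  tibble::tibble(
    n_minutes = length(x$minutes),
    n_restart = x$n_restart,
    n_fluxes = ncol(x$solutions[[1]]),
    frac_converged = mean(unlist(x$converged)),
    mean_objective = mean(unlist(x$objectives)),
    min_objective = min(unlist(x$objectives)),
    seed = x$seed
  )
}

#' Check that the averaged flux fits the slopes as well as its members
#'
#' Computes the slope-fit sum of squared errors `||S v - slope||^2` of the
#' ensemble-mean flux vector and of every individual converged solution at
#' every minute, and reports whether the mean's SSE lies inside the
#' `[min, max]` range of the individual SSEs — the property that justifies
#' using the averaged flux as the time-dependent estimate.
#'
#' @param ensemble A [estimate_flux_ensemble()] result (>= 2 restarts).
#' @return Tibble (`time_min`, `sse_mean_flux`, `sse_min`, `sse_max`,
#'   `within`), with attribute `all_within`.
#' @export
sse_range_check <- function(ensemble) {
  if (ensemble$n_restart < 2L) abort("need an ensemble with >= 2 restarts")
  S <- ensemble$net$S
  out <- purrr::map_dfr(seq_along(ensemble$minutes), function(i) {
    sols <- ensemble$solutions[[i]][ensemble$converged[[i]], , drop = FALSE]
    slope <- ensemble$slopes[i, ]
    sse <- function(v) sum((drop(S %*% v) - slope)^2)
    indiv <- apply(sols, 1, sse)
    m <- sse(colMeans(sols))
    tol <- 1e-9 * max(1, max(indiv))
    tibble::tibble(time_min = ensemble$minutes[i], sse_mean_flux = m,
                   sse_min = min(indiv), sse_max = max(indiv),
                   within = m >= min(indiv) - tol & m <= max(indiv) + tol)
  })
  attr(out, "all_within") <- all(out$within)
  out
}

## correlation with a degenerate-case rule: numerically identical series
## correlate perfectly; a constant series against a varying one is NA
cor_safe <- function(a, b) {
  scale <- max(abs(c(a, b)), 1e-300)
  if (max(abs(a - b)) <= 1e-9 * scale) return(1)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Robustness of flux estimates to concentration noise
#'
#' Perturbs the per-minute interpolated concentrations by independent
#' multiplicative factors from `U(factor_bounds[1], factor_bounds[2])`,
#' re-fits the smoothing spline to the perturbed series (the estimator
#' always consumes splined data), re-runs the flux estimation, and reports
#' the per-flux Pearson correlation between the perturbed and unperturbed
#' mean flux time courses.
#'
#' @param dataset A [generate_dataset()] result.
#' @param factor_bounds Multiplicative perturbation bounds, default
#'   `c(1/1.5, 1.5)`.
#' @param n_repeats Number of perturbation repeats.
#' @param seed Integer seed.
#' @param n_restart,smoothing,... Passed to the estimation runs.
#' @return Tibble (`flux_id`, `flux`, `repeat_id`, `correlation`,
#'   `rel_rms_dev`) with attributes `median_correlation` and
#'   `median_rel_rms_dev`.  The correlation captures shared dynamics and is
#'   only informative when the underlying fluxes actually move; the
#'   relative RMS deviation (per-flux RMS difference between the two mean
#'   courses over their clean mean level) measures closeness of the
#'   estimates irrespective of dynamics.
#' @export
noise_robustness <- function(dataset, factor_bounds = c(1 / 1.5, 1.5),
                             n_repeats = 1L, seed = 1L, n_restart = 100L,
                             smoothing = "gcv", ...) {
  net <- dataset$network
  pm <- preprocess_timeseries(dataset$observations, smoothing = smoothing)
  bt <- export_boundary_table(dataset)
  seeds <- spawn_seeds(seed, n_repeats + 1L)
  ## the clean and perturbed estimations share the restart seed, so the
  ## comparison isolates the data perturbation (common random numbers)
  clean <- estimate_flux_ensemble(pm, bt, net, n_restart = n_restart,
                                  seed = seeds[1], ...)
  clean_mat <- flux_course_matrix(clean)

  out <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    fac <- with_seed(seeds[r + 1L],
                     runif(nrow(pm), factor_bounds[1], factor_bounds[2]))
    pm_pert <- if (all(fac == 1)) pm else pm |>
      dplyr::mutate(value = .data$value * fac) |>
      dplyr::group_by(dplyr::across(dplyr::any_of(c("pool_id", "pool")))) |>
      dplyr::arrange(.data$time_min, .by_group = TRUE) |>
      dplyr::group_modify(function(d, g) {
        fit <- fit_smoothing_spline(d$time_min, d$value,
                                    smoothing = smoothing)
        resample_per_minute(fit, max(d$time_min))
      }) |>
      dplyr::ungroup()
    pert <- estimate_flux_ensemble(pm_pert, bt, net, n_restart = n_restart,
                                   seed = seeds[1], ...)
    pert_mat <- flux_course_matrix(pert)
    tibble::tibble(
      flux_id = net$fluxes$id,
      flux = colnames(net$S),
      repeat_id = r,
      correlation = vapply(seq_len(ncol(clean_mat)), function(j) {
        cor_safe(clean_mat[, j], pert_mat[, j])
      }, numeric(1)),
      rel_rms_dev = vapply(seq_len(ncol(clean_mat)), function(j) {
        sqrt(mean((pert_mat[, j] - clean_mat[, j])^2)) /
          max(mean(clean_mat[, j]), 1e-300)
      }, numeric(1))
    )
  })
  attr(out, "median_correlation") <- median(out$correlation, na.rm = TRUE)
  attr(out, "median_rel_rms_dev") <- median(out$rel_rms_dev, na.rm = TRUE)
  out
}

## minutes x fluxes matrix of ensemble-mean time courses
flux_course_matrix <- function(ensemble) {
  t(vapply(seq_along(ensemble$minutes), function(i) {
    sols <- ensemble$solutions[[i]][ensemble$converged[[i]], , drop = FALSE]
    colMeans(sols)
  }, numeric(ncol(ensemble$solutions[[1]]))))
}
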