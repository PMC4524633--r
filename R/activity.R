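#' Convert estimated fluxes into enzyme-activity proxies
#'
#' Under the mass-action assumption (activities enter linearly, substrates
#' with power 1), each flux factors as activity times the product of its
#' substrate concentrations and boundary drivers.  Dividing the estimated
#' flux by that product recovers a Vmax-like proxy: the product of the
#' rate constant and the enzyme activity.  Proxies are also reported as
#' fold change of their minute-0 value.
#'
#' @param ensemble A [estimate_flux_ensemble()] result.
#' @param minute_tbl The per-minute concentrations used for the
#'   estimation (from [preprocess_timeseries()]).
#' @param statistic Which ensemble aggregate to invert: `"mean"` (default)
#'   or `"median"`.
#' @return Tibble with columns `time_min` (0..30), `flux_id`, `flux`,
#'   `enzyme_class`, `chain`, `proxy`, `fold`.  Minutes at which a
#'   substrate concentration is zero are flagged with `NA` proxies.
#' @export
activity_proxies <- function(ensemble, minute_tbl,
                             statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  net <- ensemble$net
  pools <- net$pools
  measured <- intersect(pools$name, unique(minute_tbl$pool))
  unmeasured <- setdiff(pools$name, measured)
  wide <- tidyr::pivot_wider(minute_tbl, id_cols = "time_min",
                             names_from = "pool", values_from = "value")
  minutes <- c(min(wide$time_min), ensemble$minutes)
  agg <- ensemble$aggregates

  rows <- purrr::map_dfr(minutes, function(t) {
    x <- setNames(rep(NA_real_, nrow(pools)), pools$name)
    x[measured] <- unlist(wide[wide$time_min == t, measured])
    x[unmeasured] <- ensemble$baseline$state[unmeasured]
    dvals <- vapply(net$drivers, function(f) f(t), numeric(1))
    m <- mass_action_factor(net, x, dvals)
    v <- if (t == minutes[1]) {
      ensemble$baseline$fluxes
    } else {
      a <- agg[agg$time_min == t, ]
      a[[statistic]][match(net$fluxes$id, a$flux_id)]
    }
    proxy <- unname(ifelse(m > 0, v / m, NA_real_))
    tibble::tibble(time_min = t, flux_id = net$fluxes$id,
                   flux = colnames(net$S),
                   enzyme_class = net$fluxes$enzyme_class,
                   chain = flux_chain(net), proxy = proxy)
  })
  zero_min <- unique(rows$time_min[is.na(rows$proxy)])
  if (length(zero_min)) {
    warn(sprintf("zero substrate concentration at minute(s) %s; proxies set to NA",
                 paste(zero_min, collapse = ", ")))
  }
  rows |>
    dplyr::group_by(.data$flux_id) |>
    dplyr::mutate(fold = .data$proxy /
                    .data$proxy[.data$time_min == minutes[1]]) |>
    dplyr::ungroup()
}

## chain-class label of each flux, via the ceramide/CoA pool it touches
flux_chain <- function(net) {
  pool_of <- ifelse(is.na(net$fluxes$produces),
                    net$fluxes$consumes, net$fluxes$produces)
  net$pools$chain[pool_of]
}

## smoothing-spline smoother tolerant of constant and zero-valued series
smooth_nonneg <- function(times, values, smoothing = "gcv") {
  if (sd(values) < 1e-12 * max(abs(values), 1e-300)) {
    const <- mean(values)
    return(function(t) rep(const, length(t)))
  }
  fit <- if (identical(smoothing, "gcv")) {
    smooth.spline(times, values, cv = FALSE)
  } else if (identical(smoothing, "interpolate")) {
    smooth.spline(times, values, df = length(unique(times)), cv = FALSE)
  } else {
    smooth.spline(times, values, df = smoothing, cv = FALSE)
  }
  function(t) pmax(predict(fit, t)$y, 0)
}

#' Smooth activity proxies into continuous time trends
#'
#' Fits a cubic smoothing spline to each flux's per-minute activity
#' proxies, floored at zero (activities are nonnegative).  Fluxes with
#' fewer than 4 non-missing minutes are excluded with a warning.
#'
#' @param proxies Output of [activity_proxies()].
#' @param smoothing `"gcv"` (default), `"interpolate"`, or a numeric
#'   equivalent degrees of freedom.
#' @return An `activity_curves` object: named list of functions `f(t)`
#'   plus a per-minute grid tibble.
#' @export
smooth_activities <- function(proxies, smoothing = "gcv") {
  split <- split(proxies, proxies$flux_id)
  funs <- list()
  dropped <- character()
  for (d in split) {
    ok <- !is.na(d$proxy)
    nm <- d$flux[1]
    if (sum(ok) < 4) {
      dropped <- c(dropped, nm)
      next
    }
    funs[[nm]] <- smooth_nonneg(d$time_min[ok], d$proxy[ok], smoothing)
  }
  if (length(dropped)) {
    warn(sprintf("excluded flux(es) with < 4 valid proxies: %s",
                 paste(dropped, collapse = ", ")))
  }
  grid <- sort(unique(proxies$time_min))
  grid_tbl <- purrr::imap_dfr(funs, function(f, nm) {
    tibble::tibble(time_min = grid, flux = nm, value = f(grid))
  })
  structure(list(funs = funs, grid = grid_tbl, smoothing = smoothing),
            class = "activity_curves")
}

#' Wrap known activity trajectories as activity curves
#'
#' Builds the `activity_curves` container directly from a function
#' `t -> per-flux activity vector` (or a constant vector), bypassing proxy
#' smoothing.  Useful for self-consistency checks of the windowed
#' refinement, where the data-generating activities themselves play the
#' role of the smoothed trends.
#'
#' @param net A [ceramide_network()].
#' @param activities A function of time returning one activity per flux,
#'   or a fixed activity vector.
#' @param grid Minutes at which the per-minute grid table is evaluated.
#' @return An `activity_curves` object.
#' @export
as_activity_curves <- function(net, activities, grid = 0:30) {
  act_fn <- if (is.function(activities)) activities
            else function(t) activities
  flux_names <- colnames(net$S)
  ## shared per-time cache: the per-flux functions all evaluate the same
  ## full activity vector, so compute it once per time point
  cache <- new.env(hash = TRUE, parent = emptyenv())
  act_at <- function(tt) {
    key <- format(tt, digits = 15)
    val <- cache[[key]]
    if (is.null(val)) {
      val <- act_fn(tt)
      cache[[key]] <- val
    }
    val
  }
  funs <- lapply(seq_along(flux_names), function(j) {
    force(j)
    function(t) vapply(t, function(tt) act_at(tt)[j], numeric(1))
  })
  names(funs) <- flux_names
  grid_tbl <- purrr::imap_dfr(funs, function(f, nm) {
    tibble::tibble(time_min = grid, flux = nm, value = f(grid))
  })
  structure(list(funs = funs, grid = grid_tbl, smoothing = "exact"),
            class = "activity_curves")
}

#' Activity function of an `activity_curves` object
#'
#' @param curves An `activity_curves` object.
#' @param net A [ceramide_network()] giving the flux order.
#' @return A function `t -> activity vector` suitable for
#'   [simulate_network()].
#' @export
curves_activity_fn <- function(curves, net) {
  flux_names <- colnames(net$S)
  function(t) vapply(flux_names, function(nm) curves$funs[[nm]](t),
                     numeric(1))
}

## adaptive (lsoda) integration over one shooting window; returns states at
## integer minutes t0+1 .. t0+len.  G is the (fine grid x flux) matrix of
## activity-curve times driver products, interpolated linearly; rates are
## Cexp * G(t) * substrate, so the pools see a linear time-varying system.
## Uses the package's compiled right-hand side when the packed parameter
## vector fits its fixed buffer, else an equivalent R closure.
window_simulate <- function(net, x0, t0, len, Cexp, Gmat, tg, dt) {
  S <- net$S
  sub <- net$substrate_idx
  CG <- sweep(Gmat, 2, Cexp, "*")
  packed <- c(nrow(S), ncol(S), nrow(CG), t0, dt,
              as.double(sub), as.double(S), as.double(CG))
  if (length(packed) <= 80000) {
    parms <- c(packed, numeric(80000 - length(packed)))
    sol <- deSolve::lsoda(y = as.numeric(x0), times = t0 + 0:len,
                          func = "ceradyn_derivs", dllname = "ceradyn",
                          initfunc = "ceradyn_init", parms = parms,
                          rtol = 1e-6, atol = 1e-9)
  } else {
    nrowG <- nrow(CG)
    rhs <- function(t, x, parms) {
      u <- (t - t0) / dt
      i <- min(max(floor(u), 0), nrowG - 2)
      w <- u - i
      g <- (1 - w) * CG[i + 1, ] + w * CG[i + 2, ]
      xf <- c(1, pmax(x, 0))[sub + 1L]
      list(drop(S %*% (g * xf)))
    }
    sol <- deSolve::lsoda(y = as.numeric(x0), times = t0 + 0:len,
                          func = rhs, parms = NULL,
                          rtol = 1e-6, atol = 1e-9)
  }
  if (nrow(sol) < len + 1 || anyNA(sol[-1, -1])) {
    abort(sprintf("window simulation failed on [%g, %g] min", t0, t0 + len))
  }
  sol[-1, -1, drop = FALSE]
}

## window integration with forward sensitivities d x / d C via the compiled
## augmented right-hand side; returns states (len x n) and sensitivities
## (len x n x K), or NULL when the packed parameters exceed the buffer
window_sens <- function(net, x0, t0, len, Cvec, expand_idx, Gmat, dt) {
  n <- nrow(net$S); m <- ncol(net$S); K <- length(Cvec)
  packed <- c(n, m, nrow(Gmat), t0, dt, K,
              as.double(net$substrate_idx), as.double(expand_idx),
              as.double(net$S), as.double(Gmat), as.double(Cvec))
  if (length(packed) > 80000 || n * (1 + K) > 2000) return(NULL)
  parms <- c(packed, numeric(80000 - length(packed)))
  y0 <- c(as.numeric(x0), numeric(n * K))
  sol <- deSolve::lsoda(y0, times = t0 + 0:len, func = "ceradyn_sens",
                        dllname = "ceradyn", initfunc = "ceradyn_init",
                        parms = parms, rtol = 1e-6, atol = 1e-9)
  if (nrow(sol) < len + 1 || anyNA(sol[-1, -1])) {
    abort(sprintf("window simulation failed on [%g, %g] min", t0, t0 + len))
  }
  states <- sol[-1, 1 + seq_len(n), drop = FALSE]
  sens <- array(sol[-1, -seq_len(1 + n)], dim = c(len, n, K))
  list(states = states, sens = sens)
}

#' Refine windowed activity coefficients by multiple shooting
#'
#' Splits the 30-minute experiment into consecutive windows (default 3
#' minutes, i.e. 10 windows) and, independently in each window, fits a
#' multiplicative coefficient `C` on the smoothed activity trends: within
#' window `w` the activities are `C[j, w] * f_j(t)`.  Each window is its
#' own initial value problem starting from the splined concentrations at
#' the window start (windows do not chain), and `C` minimizes the sum of
#' squared errors between simulated and splined concentrations at the
#' minutes inside the window, with every measured pool divided by its
#' minute-0 baseline so abundant species do not dominate.  The search runs
#' from `n_inits` random starts per window, retaining the full ensemble of
#' solutions.  With all coefficients equal to 1 the model is unchanged.
#'
#' @param net A [ceramide_network()].
#' @param curves An [smooth_activities()] result covering all fluxes.
#' @param minute_tbl Per-minute splined concentrations
#'   ([preprocess_timeseries()]).
#' @param window_len Window length in minutes (default 3; must divide the
#'   grid span).
#' @param n_inits Random starts per window, in addition to one
#'   deterministic start at the unrefined point `C = 1` (the refinement
#'   adjusts the current activity forms, so the identity is always a
#'   candidate).
#' @param init_bounds Uniform distribution bounds of the random starts
#'   (default `U(0.1, 10)`).
#' @param coef_bounds Box bounds on the coefficients (default
#'   `[0.01, 100]`).
#' @param by `"flux"` (default): one coefficient per flux per window;
#'   `"class"`: one per enzyme class per window.
#' @param unobserved_state Concentrations of pools absent from
#'   `minute_tbl`, held at these values at every window start.
#' @param seed Integer seed.
#' @param dt Fixed RK4 integration step within windows, minutes.
#' @return A `window_coefficients` object: per-window ensembles of
#'   coefficient vectors, their SSEs, and the unrefined (`C = 1`) SSEs.
#' @export
shooting_refine <- function(net, curves, minute_tbl, window_len = 3,
                            n_inits = 5L, init_bounds = c(0.1, 10),
                            coef_bounds = c(0.01, 100),
                            by = c("flux", "class"),
                            unobserved_state = NULL, seed = 1L, dt = 0.01) {
  by <- match.arg(by)
  pools <- net$pools
  flux_names <- colnames(net$S)
  if (!all(flux_names %in% names(curves$funs))) {
    abort(sprintf("`curves` missing flux(es): %s",
                  paste(setdiff(flux_names, names(curves$funs)),
                        collapse = ", ")))
  }
  measured <- intersect(pools$name, unique(minute_tbl$pool))
  unmeasured <- setdiff(pools$name, measured)
  if (is.null(unobserved_state)) {
    unobserved_state <- baseline_state(net)$x0[unmeasured]
  }
  wide <- tidyr::pivot_wider(minute_tbl, id_cols = "time_min",
                             names_from = "pool", values_from = "value")
  t_grid <- sort(wide$time_min)
  t0_all <- min(t_grid); t_max <- max(t_grid)
  n_win <- as.integer(round((t_max - t0_all) / window_len))
  starts <- t0_all + window_len * (seq_len(n_win) - 1)

  midx <- match(measured, pools$name)
  baseline_div <- unlist(wide[wide$time_min == t0_all, measured])
  state_at <- function(t) {
    x <- setNames(rep(NA_real_, nrow(pools)), pools$name)
    x[measured] <- unlist(wide[wide$time_min == t, measured])
    x[unmeasured] <- unobserved_state[unmeasured]
    x
  }

  if (by == "class") {
    classes <- unique(net$fluxes$enzyme_class)
    expand_idx <- match(net$fluxes$enzyme_class, classes)
    coef_names <- classes
  } else {
    expand_idx <- seq_along(flux_names)
    coef_names <- flux_names
  }
  n_coef <- length(coef_names)

  seeds <- spawn_seeds(seed, n_win)
  results <- vector("list", n_win)
  sse_unref <- numeric(n_win)
  for (w in seq_len(n_win)) {
    t0 <- starts[w]
    tg <- seq(t0, t0 + window_len, by = dt)
    Gmat <- vapply(flux_names, function(nm) curves$funs[[nm]](tg),
                   numeric(length(tg)))
    dmat <- t(vapply(tg, function(t) {
      dv <- vapply(net$drivers, function(f) f(t), numeric(1))
      vapply(net$driver_idx, function(i) prod(dv[i]), numeric(1))
    }, numeric(length(flux_names))))
    Gmat <- Gmat * dmat
    x_start <- state_at(t0)
    target <- t(vapply(t0 + seq_len(window_len), state_at,
                       numeric(nrow(pools))))[, midx, drop = FALSE]

    wts <- rep(1 / baseline_div, each = window_len)
    objective <- function(Cfree) {
      sim <- window_simulate(net, x_start, t0, window_len,
                             Cfree[expand_idx], Gmat, tg, dt)
      sum(((sim[, midx, drop = FALSE] - target) * wts)^2)
    }
    ## value and exact gradient (forward sensitivities) in log-coefficient
    ## space, shared between optim's fn and gr through a one-slot cache
    cache <- new.env(parent = emptyenv())
    eval_log <- function(lc) {
      key <- paste(lc, collapse = ",")
      if (!identical(cache$key, key)) {
        Cvec <- exp(lc)
        res <- window_sens(net, x_start, t0, window_len, Cvec,
                           expand_idx, Gmat, dt)
        if (is.null(res)) {   # packed buffer exceeded: finite differences
          cache$obj <- objective(Cvec)
          cache$grad <- NULL
        } else {
          r <- (res$states[, midx, drop = FALSE] - target) * wts
          cache$obj <- sum(r^2)
          cache$grad <- Cvec * vapply(seq_along(Cvec), function(q) {
            sum(2 * wts * r * res$sens[, midx, q])
          }, numeric(1))
        }
        cache$key <- key
      }
      invisible(NULL)
    }
    fn_log <- function(lc) { eval_log(lc); cache$obj }
    gr_log <- function(lc) { eval_log(lc); cache$grad }
    use_grad <- !is.null({ eval_log(rep(0, n_coef)); cache$grad })

    ## the refinement seeks adjustments of the current activity forms, so
    ## the unrefined point C = 1 is always one of the starts; the random
    ## starts map the wider solution space around it
    inits <- rbind(rep(1, n_coef),
                   with_seed(seeds[w],
                             matrix(runif(n_inits * n_coef,
                                          init_bounds[1], init_bounds[2]),
                                    n_inits, n_coef)))
    n_starts <- n_inits + 1L
    sols <- matrix(NA_real_, n_starts, n_coef,
                   dimnames = list(NULL, coef_names))
    sse <- rep(NA_real_, n_starts)
    okv <- logical(n_starts)
    ## search over log-coefficients: multiplicative effects, and the box
    ## bounds become symmetric around C = 1
    for (r in seq_len(n_starts)) {
      fit <- tryCatch(
        optim(log(inits[r, ]), fn_log, if (use_grad) gr_log else NULL,
              method = "L-BFGS-B",
              lower = rep(log(coef_bounds[1]), n_coef),
              upper = rep(log(coef_bounds[2]), n_coef),
              control = list(maxit = 500L, factr = 1e2)),
        error = function(e) NULL)
      if (is.null(fit)) next
      sols[r, ] <- exp(fit$par)
      sse[r] <- fit$value
      okv[r] <- TRUE
    }
    if (!any(okv)) {
      warn(sprintf("window %d (%g-%g min): all starts failed; coefficients missing",
                   w, t0, t0 + window_len))
    }
    sse_unref[w] <- objective(rep(1, n_coef))
    results[[w]] <- list(solutions = sols, sse = sse, ok = okv)
  }

  structure(list(
    windows = tibble::tibble(window = seq_len(n_win), t_start = starts,
                             t_end = starts + window_len),
    coefficients = lapply(results, `[[`, "solutions"),
    sse = lapply(results, `[[`, "sse"),
    ok = lapply(results, `[[`, "ok"),
    sse_unrefined = sse_unref,
    by = by, coef_names = coef_names, expand_idx = expand_idx,
    window_len = window_len, n_inits = as.integer(n_inits),
    init_bounds = init_bounds, coef_bounds = coef_bounds,
    seed = seed, net = net, curves = curves, dt = dt
  ), class = "window_coefficients")
}

#' @export
print.window_coefficients <- function(x, ...) {
  cat(sprintf(
    "<window_coefficients> %d windows x %d min, %d coefficients per window (by %s), %d inits, seed %d\n",
    nrow(x$windows), x$window_len, length(x$coef_names), x$by,
    x$n_inits, x$seed))
  invisible(x)
}

#' Best-fitting coefficient vector of each window
#'
#' Returns, per window, the coefficient vector of the ensemble member with
#' the smallest window SSE — the maximum-fit representative of the
#' solution ensemble.
#'
#' @param coeffs A [shooting_refine()] result.
#' @return Matrix (windows x coefficients) with the per-window best SSE as
#'   attribute `sse`.
#' @export
best_coefficients <- function(coeffs) {
  out <- t(vapply(seq_len(nrow(coeffs$windows)), function(w) {
    s <- coeffs$sse[[w]]
    if (!any(coeffs$ok[[w]])) return(rep(NA_real_, length(coeffs$coef_names)))
    coeffs$coefficients[[w]][which.min(s), ]
  }, numeric(length(coeffs$coef_names))))
  colnames(out) <- coeffs$coef_names
  attr(out, "sse") <- vapply(coeffs$sse, function(s)
    suppressWarnings(min(s, na.rm = TRUE)), numeric(1))
  out
}

#' @export
tidy.window_coefficients <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$windows)), function(w) {
    sols <- x$coefficients[[w]]
    ok <- x$ok[[w]]
    if (!any(ok)) return(tibble::tibble())
    tibble::tibble(
      window = w, t_start = x$windows$t_start[w], t_end = x$windows$t_end[w],
      coef = rep(x$coef_names, each = sum(ok)),
      member = rep(which(ok), times = length(x$coef_names)),
      value = as.vector(sols[ok, , drop = FALSE]),
      sse = rep(x$sse[[w]][ok], times = length(x$coef_names))
    )
  })
}

#' @export
glance.window_coefficients <- function(x, ...) {
  best <- vapply(x$sse, function(s) suppressWarnings(min(s, na.rm = TRUE)),
                 numeric(1))
  tibble::tibble(
    n_windows = nrow(x$windows),
    window_len = x$window_len,
    by = x$by,
    n_inits = x$n_inits,
    mean_best_sse = mean(best[is.finite(best)]),
    frac_improved = mean(best[is.finite(best)] <=
                           x$sse_unrefined[is.finite(best)]),
    seed = x$seed
  )
}

#' Assemble the final per-flux activity trends
#'
#' Combines the refined window coefficients with the smoothed activity
#' curves into per-minute activity trends: within window `w`, member `i`'s
#' trend for flux `j` is `C[j, w, i] * f_j(t)`.  Every trend is normalized
#' to its minute-0 value (fold change of baseline), individual ensemble
#' members are retained, and the averaged trend is their mean.
#' Discontinuities at window boundaries are a property of the windowed
#' optimization and are preserved.
#'
#' @param coeffs A [shooting_refine()] result.
#' @param minutes Minutes at which to report (default 0..30).
#' @return An `activity_report`: list with `trends` (averaged fold
#'   changes: `time_min`, `flux_id`, `flux`, `enzyme_class`, `chain`,
#'   `fold_change_mean`) and `individuals` (per ensemble member).
#' @export
assemble_activity_report <- function(coeffs, minutes = 0:30) {
  net <- coeffs$net
  flux_names <- colnames(net$S)
  len <- coeffs$window_len
  t0_all <- coeffs$windows$t_start[1]
  n_win <- nrow(coeffs$windows)
  win_of <- pmin(pmax(ceiling((minutes - t0_all) / len), 1L), n_win)

  fmat <- vapply(flux_names, function(nm) coeffs$curves$funs[[nm]](minutes),
                 numeric(length(minutes)))
  members <- which(Reduce(`&`, coeffs$ok))
  if (!length(members)) abort("no shooting member converged in every window")

  indiv <- purrr::map_dfr(members, function(i) {
    Cmat <- t(vapply(seq_len(n_win), function(w) {
      coeffs$coefficients[[w]][i, coeffs$expand_idx]
    }, numeric(length(flux_names))))      # windows x fluxes
    trend <- Cmat[win_of, , drop = FALSE] * fmat
    base <- trend[which(minutes == min(minutes))[1], ]
    fold <- sweep(trend, 2, ifelse(base > 0, base, NA_real_), "/")
    tibble::tibble(
      time_min = rep(minutes, times = length(flux_names)),
      flux_id = rep(net$fluxes$id, each = length(minutes)),
      flux = rep(flux_names, each = length(minutes)),
      enzyme_class = rep(net$fluxes$enzyme_class, each = length(minutes)),
      chain = rep(flux_chain(net), each = length(minutes)),
      member = i,
      fold_change = as.vector(fold)
    )
  })
  trends <- indiv |>
    dplyr::group_by(.data$time_min, .data$flux_id, .data$flux,
                    .data$enzyme_class, .data$chain) |>
    dplyr::summarise(fold_change_mean = mean(.data$fold_change),
                     .groups = "drop")
  structure(list(trends = trends, individuals = indiv,
                 members = members),
            class = "activity_report")
}

#' @export
print.activity_report <- function(x, ...) {
  cat(sprintf(
    "<activity_report> %d fluxes x %d minutes, %d ensemble member(s)\n",
    length(unique(x$trends$flux_id)), length(unique(x$trends$time_min)),
    length(x$members)))
  invisible(x)
}

#' @export
tidy.activity_report <- function(x, ...) x$trends
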