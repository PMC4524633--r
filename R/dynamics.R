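#' Evaluate all flux rates of the GMA model
#'
#' Each flux is the product of its activity (rate constant times enzyme
#' activity), its internal substrate concentration (kinetic order 1) and
#' the values of its boundary drivers at time `t`.
#'
#' @param net A [ceramide_network()].
#' @param state Nonnegative concentration vector, one entry per pool.
#' @param activities Nonnegative activity vector, one entry per flux.
#' @param t Time in minutes (drivers are evaluated here).
#' @return Numeric vector of flux rates, named `V1..V53`.
#' @export
#' @examples
#' net <- ceramide_network()
#' v <- flux_rates(net, rep(1, 15), rep(1, 53), 0)
flux_rates <- function(net, state, activities, t = 0) {
  if (length(state) != nrow(net$pools)) {
    abort("`state` must have one entry per pool")
  }
  if (length(activities) != nrow(net$fluxes)) {
    abort("`activities` must have one entry per flux")
  }
  if (any(state < 0)) abort("negative concentrations in `state`")
  if (any(activities < 0)) abort("negative entries in `activities`")
  dvals <- vapply(net$drivers, function(f) f(t), numeric(1))
  setNames(rates_fast(net, state, activities, dvals), colnames(net$S))
}

## hot path shared by the ODE right-hand side and the estimators:
## no validation, driver values precomputed
rates_fast <- function(net, state, activities, dvals) {
  xf <- c(1, state)[net$substrate_idx + 1L]
  df <- vapply(net$driver_idx, function(i) prod(dvals[i]), numeric(1))
  activities * xf * df
}

#' Time derivatives of the pool concentrations
#'
#' Assembles `S %*% v` for the current state: the net production rate of
#' every metabolite pool.
#'
#' @inheritParams flux_rates
#' @return Numeric vector of derivatives, one per pool.
#' @export
network_rhs <- function(net, state, activities, t = 0) {
  drop(net$S %*% flux_rates(net, state, activities, t))
}

#' Simulate the ceramide subsystem
#'
#' Integrates the GMA model with time-varying activities using a
#' stiff-capable adaptive solver ([deSolve::ode()], `lsoda`).
#' Concentrations that undershoot zero by less than the solver tolerance
#' are clipped at zero with a warning.
#'
#' @inheritParams flux_rates
#' @param activities Either a fixed activity vector or a function
#'   `t -> activity vector`.
#' @param x0 Initial concentrations (nonnegative).
#' @param times Output time grid, minutes.
#' @param rtol,atol Solver tolerances (defaults 1e-8 and 1e-10).
#' @return A tibble with columns `time_min`, `pool_id`, `pool`, `value`.
#' @export
#' @examples
#' net <- ceramide_network()
#' base <- baseline_state(net)
#' traj <- simulate_network(net, base$activities, base$x0, 0:10)
simulate_network <- function(net, activities, x0, times = 0:30,
                             rtol = 1e-8, atol = 1e-10) {
  if (any(x0 < 0)) abort("`x0` must be nonnegative")
  act_fn <- if (is.function(activities)) activities else function(t) activities
  a0 <- act_fn(min(times))
  if (length(a0) != nrow(net$fluxes)) {
    abort("`activities` must give one value per flux")
  }
  drv <- net$drivers
  rhs <- function(t, x, parms) {
    dvals <- vapply(drv, function(f) f(t), numeric(1))
    v <- rates_fast(net, pmax(x, 0), act_fn(t), dvals)
    list(drop(net$S %*% v))
  }
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("ODE solver failed near t = %.3f", max(sol[, 1])))
  }
  mat <- sol[, -1, drop = FALSE]
  undershoot <- min(mat)
  if (undershoot < 0) {
    tol <- 100 * max(atol, rtol * max(abs(mat)))
    if (undershoot < -tol) {
      abort(sprintf("trajectory went negative (min %.3e) beyond solver tolerance",
                    undershoot))
    }
    warn(sprintf("clipping small negative concentrations (min %.3e) at 0",
                 undershoot))
    mat <- pmax(mat, 0)
  }
  tibble::tibble(
    time_min = rep(sol[, 1], times = ncol(mat)),
    pool_id = rep(net$pools$id, each = nrow(mat)),
    pool = rep(net$pools$name, each = nrow(mat)),
    value = as.vector(mat)
  )
}

#' Activities that balance the network at a given state
#'
#' Finds the nonnegative flux vector satisfying the steady-state condition
#' `S v = 0` together with boundary-group totals `A v = b`, and converts it
#' to activities by dividing out the mass-action substrate and driver
#' products at `x0`.  The system is underdetermined, so the minimum-norm
#' solution is returned; if that solution dips negative it is polished by a
#' bounded quadratic solve.
#'
#' @inheritParams flux_rates
#' @param x0 Strictly positive state at which to balance.
#' @param boundary_targets Named numeric vector of boundary-group flux
#'   totals (names must match `net$boundary_groups`).
#' @param t Time at which drivers are evaluated (default 0).
#' @param tol Residual tolerance for the balance (default 1e-8).
#' @return A list with `activities`, `fluxes` and the achieved `residual`.
#' @export
baseline_activities <- function(net, x0, boundary_targets, t = 0, tol = 1e-8) {
  if (any(x0 <= 0)) abort("`x0` must be strictly positive")
  gnames <- names(net$boundary_groups)
  if (!all(gnames %in% names(boundary_targets))) {
    abort("`boundary_targets` must cover every boundary group")
  }
  b <- boundary_targets[gnames]
  A <- group_matrix(net)
  C <- rbind(net$S, A)
  rhs <- c(rep(0, nrow(net$S)), b)

  n <- ncol(C)
  free <- rep(TRUE, n)
  ## active-set polish: pin the most negative flux at zero and re-solve the
  ## min-norm system on the remaining ones until all entries are nonnegative
  for (iter in seq_len(n)) {
    v <- numeric(n)
    v[free] <- drop(MASS::ginv(C[, free, drop = FALSE]) %*% rhs)
    if (min(v) >= -tol) break
    free[which.min(v)] <- FALSE
  }
  v <- pmax(v, 0)
  resid <- max(abs(C %*% v - rhs))
  if (resid > tol * max(1, max(abs(b)))) {
    abort(sprintf(
      "no nonnegative activity vector balances the system (residual %.3e)",
      resid))
  }
  dvals <- vapply(net$drivers, function(f) f(t), numeric(1))
  m <- mass_action_factor(net, x0, dvals)
  list(activities = setNames(v / m, colnames(net$S)),
       fluxes = setNames(v, colnames(net$S)),
       residual = resid)
}

## per-flux mass-action factor: substrate concentration times driver product
mass_action_factor <- function(net, state, dvals) {
  xf <- c(1, state)[net$substrate_idx + 1L]
  df <- vapply(net$driver_idx, function(i) prod(dvals[i]), numeric(1))
  xf * df
}

#' Reference baseline operating point of the default network
#'
#' Bundles a reference pre-stress condition: baseline pool concentrations
#' spanning roughly three orders of magnitude across species (mimicking the
#' large spread in ceramide prevalence, with very-long-chain phytoceramide
#' the most abundant species), a hand-constructed strictly positive flux
#' circulation that balances every pool, the implied boundary-group
#' totals, and the activities that realise the minimum-norm balanced flux
#' at that state.
#'
#' @param net A [ceramide_network()] built from the default topology.
#' @return A list with `x0` (named state vector), `boundary_targets`
#'   (named group totals), `fluxes` (minimum-norm baseline fluxes),
#'   `activities`, and `reference_fluxes` (the positive circulation used to
#'   set the group totals).
#' @export
baseline_state <- function(net = ceramide_network()) {
  x0 <- setNames(
    c(0.5, 0.2, 0.1, 2, 20,       # DHC species
      1, 0.5, 0.3, 5, 100,        # PHC species (very long chain dominant)
      0.8, 0.6, 0.4, 1.5, 3),     # fatty-acyl-CoA pools
    net$pools$name
  )
  v <- numeric(nrow(net$fluxes))
  names(v) <- colnames(net$S)
  for (k in 1:5) {
    b <- 5 * (k - 1)
    v[b + 1] <- 2; v[b + 2] <- 1; v[b + 3] <- 1; v[b + 4] <- 1; v[b + 5] <- 1
    p <- 25 + 4 * (k - 1)
    v[p + 1] <- 2; v[p + 2] <- 1; v[p + 3] <- 2; v[p + 4] <- 2
  }
  ## elongation backbone: supplies 4 units of CoA consumption per class
  v["V53"] <- 1; v["V52"] <- 1
  v["V51"] <- 4 + v["V53"]
  v["V48"] <- (4 + v["V51"] + v["V52"]) / 2
  v["V50"] <- v["V48"]
  v["V49"] <- v["V50"] + 4
  v["V47"] <- v["V48"] + v["V49"] + 4
  v["V46"] <- v["V47"] + 4
  stopifnot(max(abs(net$S %*% v)) < 1e-12)

  targets <- drop(group_matrix(net) %*% v)
  bal <- baseline_activities(net, x0, targets)
  list(x0 = x0, boundary_targets = targets,
       fluxes = bal$fluxes, activities = bal$activities,
       reference_fluxes = v)
}
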