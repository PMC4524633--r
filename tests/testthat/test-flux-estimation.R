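test_that("a feasible steady-state point is an exact zero of the objective", {
  net <- test_net()
  bs <- test_baseline()
  prob <- flux_problem(net, slopes = rep(0, 15),
                       boundary_targets = bs$boundary_targets,
                       v_prev = bs$fluxes)
  expect_equal(ceradyn:::qp_objective(prob, bs$fluxes), 0, tolerance = 1e-12)
  res <- solve_flux_restart(prob, init = bs$fluxes)
  expect_lt(res$objective, 1e-20)
  expect_equal(unname(res$solution), unname(bs$fluxes), tolerance = 1e-8)
})

test_that("a fully determined toy problem is recovered from any start", {
  net <- ceramide_network(toy_chain_topology())
  ## truth v = (2, 1.5, 1): slopes are P1' = v1 - v2, P2' = v2 - v3
  truth <- c(2, 1.5, 1)
  prob <- flux_problem(net, slopes = c(0.5, 0.5),
                       boundary_targets = c(inflow = 2, transfer = 1.5,
                                            outflow = 1),
                       bounds = list(lower = rep(0, 3), upper = rep(50, 3)))
  set.seed(3)
  for (i in 1:5) {
    res <- solve_flux_restart(prob, init = runif(3, 0.01, 50))
    expect_equal(unname(res$solution), truth, tolerance = 1e-6)
  }
})

test_that("solves never end worse than they start and respect bounds", {
  net <- test_net()
  bs <- test_baseline()
  prob <- flux_problem(net, slopes = rep(0, 15),
                       boundary_targets = bs$boundary_targets,
                       v_prev = bs$fluxes,
                       bounds = list(lower = rep(0, 53),
                                     upper = rep(40, 53)))
  set.seed(9)
  for (i in 1:100) {
    init <- runif(53, 0.01, 100)
    res <- solve_flux_restart(prob, init)
    init_clipped <- pmin(pmax(init, 0), 40)
    expect_lte(res$objective,
               ceradyn:::qp_objective(prob, init_clipped) + 1e-9)
    expect_true(all(res$solution >= 0 & res$solution <= 40))
  }
})

test_that("zero-objective solutions scale with the problem data", {
  net <- ceramide_network(toy_chain_topology())
  base <- flux_problem(net, slopes = c(0.5, 0.5),
                       boundary_targets = c(inflow = 2, transfer = 1.5,
                                            outflow = 1))
  scaled <- flux_problem(net, slopes = 3 * c(0.5, 0.5),
                         boundary_targets = c(inflow = 6, transfer = 4.5,
                                              outflow = 3))
  r1 <- solve_flux_restart(base, init = rep(1, 3))
  r2 <- solve_flux_restart(scaled, init = rep(1, 3))
  expect_equal(unname(r2$solution), 3 * unname(r1$solution),
               tolerance = 1e-5)
})

test_that("ensembles are reproducible and recover the flat baseline", {
  ens <- flat_ensemble()
  expect_s3_class(ens, "flux_ensemble")
  ens2 <- estimate_flux_ensemble(flat_minutes(), flat_boundary(), test_net(),
                                 n_restart = 10, seed = 21)
  expect_identical(ens$solutions, ens2$solutions)

  truth <- flat_dataset()$baseline$fluxes
  agg <- tidy(ens)
  rel <- abs(agg$mean - truth[agg$flux_id]) / truth[agg$flux_id]
  worst_per_flux <- tapply(rel, agg$flux_id, max)
  expect_gte(mean(worst_per_flux <= 0.05), 0.9)
})

test_that("a single-restart ensemble on a feasible problem is exact", {
  ens <- estimate_flux_ensemble(flat_minutes(), flat_boundary(), test_net(),
                                n_restart = 1, seed = 4)
  agg <- tidy(ens)
  expect_equal(agg$mean, agg$median)
  expect_equal(agg$p20, agg$p80)
  truth <- flat_dataset()$baseline$fluxes
  expect_equal(agg$mean[agg$time_min == 1],
               unname(truth), tolerance = 1e-4)
})

test_that("aggregates match brute-force recomputation and are ordered", {
  ens <- flat_ensemble()
  agg <- tidy(ens)
  expect_true(all(agg$p20 <= agg$median + 1e-12))
  expect_true(all(agg$median <= agg$p80 + 1e-12))
  i <- 3  # minute 3
  sols <- ens$solutions[[i]][ens$converged[[i]], , drop = FALSE]
  sub <- agg[agg$time_min == ens$minutes[i], ]
  expect_equal(sub$mean, unname(colMeans(sols)))
  expect_equal(sub$median, unname(apply(sols, 2, median)))
  expect_equal(sub$p20,
               unname(apply(sols, 2, quantile, probs = 0.2, names = FALSE)))
})

test_that("the averaged flux fits slopes within the individual SSE range", {
  ens <- flat_ensemble()
  rep <- sse_range_check(ens)
  expect_true(attr(rep, "all_within"))
  ## independent recomputation of the slope SSE at one minute
  i <- 5
  sols <- ens$solutions[[i]][ens$converged[[i]], , drop = FALSE]
  slope <- ens$slopes[i, ]
  manual <- sum((drop(test_net()$S %*% colMeans(sols)) - slope)^2)
  expect_equal(rep$sse_mean_flux[rep$time_min == ens$minutes[i]], manual)
  expect_gte(rep$sse_mean_flux[i], rep$sse_min[i] - 1e-12)
})

test_that("identical perturbation bounds give perfect flux correlations", {
  rob <- noise_robustness(flat_dataset(), factor_bounds = c(1, 1),
                          n_repeats = 1, seed = 2, n_restart = 5)
  expect_equal(nrow(rob), 53)
  expect_true(all(rob$correlation == 1))
  expect_equal(attr(rob, "median_correlation"), 1)
})

test_that("degenerate ensemble inputs are rejected", {
  expect_error(estimate_flux_ensemble(flat_minutes(), flat_boundary(),
                                      test_net(), n_restart = 0),
               "n_restart")
  expect_error(estimate_flux_ensemble(flat_minutes(), flat_boundary(),
                                      test_net(), init = c(2, 1)),
               "init")
  expect_error(sse_range_check(
    estimate_flux_ensemble(flat_minutes(), flat_boundary(), test_net(),
                           n_restart = 1, seed = 1)),
    ">= 2 restarts")
})
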