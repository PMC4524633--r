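test_that("activity shapes start at baseline and respect their peaks", {
  t <- seq(0, 30, 0.01)
  for (sh in c("flat", "spike_decay", "delayed_peak", "undershoot_recover",
               "step")) {
    v <- activity_shape(t, sh, peak = 5, t_peak = 1)
    expect_equal(activity_shape(0, sh, peak = 5, t_peak = 1), 1)
    expect_true(all(v >= 0))
  }
  v <- activity_shape(t, "spike_decay", peak = 5, t_peak = 1)
  expect_gte(max(v), 4.9)
  expect_lte(max(v), 5.0)
  expect_equal(t[which.max(v)], 1, tolerance = 0.02)
})

test_that("scenarios assign shapes by class and flux, deterministically", {
  net <- test_net()
  sc <- make_scenario(net, list(), seed = 1)
  expect_true(all(sc$shape == "flat"))
  expect_equal(scenario_multipliers(sc, 12.3), rep(1, 53))

  sc2 <- make_scenario(net, "heat_stress", seed = 7, jitter = 0.1)
  sc3 <- make_scenario(net, "heat_stress", seed = 7, jitter = 0.1)
  expect_identical(sc2$peak, sc3$peak)
  ## per-flux override wins over the class assignment
  expect_equal(sc2$shape[sc2$flux == "V21"], "undershoot_recover")

  expect_error(make_scenario(net, list(IPCase = list(peak = 50))),
               "out of range")
  expect_error(make_scenario(net, list(V99 = list(peak = 2))), "V99")
})

test_that("noise-free datasets reproduce the simulated truth exactly", {
  ds <- flat_dataset()
  expect_equal(ds$observations$value, ds$observations$truth)
  ## flat scenario: steady state, observations constant per pool
  spread <- tapply(ds$observations$value, ds$observations$pool_id,
                   function(v) diff(range(v)) / mean(v))
  expect_lt(max(spread), 1e-6)
  ## fatty-acyl-CoA pools are never observed
  expect_true(all(ds$observations$pool_id <= 10))
  expect_equal(nrow(ds$observations), 7 * 2 * 10)
  ## round trip: re-simulating with the true activities reproduces the
  ## sampled observations
  afn <- ceradyn:::scenario_activity_fn(ds$scenario, ds$baseline$activities)
  tr <- simulate_network(ds$network, afn, ds$baseline$x0,
                         times = unique(ds$observations$time_min))
  lk <- dplyr::left_join(ds$observations,
                         dplyr::rename(tr, sim = "value"),
                         by = c("time_min", "pool_id", "pool"))
  expect_equal(lk$value, lk$sim, tolerance = 1e-8)
})

test_that("replicate noise factors follow the declared uniform law", {
  net <- test_net()
  ds <- generate_dataset(net, seed = 99, noise = c(1 / 1.5, 1.5),
                         n_replicates = 100)
  fac <- ds$observations$value / ds$observations$truth
  expect_equal(fac, ds$observations$noise_factor)
  ks <- suppressWarnings(
    stats::ks.test(fac, stats::punif, 1 / 1.5, 1.5))
  expect_gt(ks$p.value, 0.01)
  ## determinism: same seed, same dataset
  ds2 <- generate_dataset(net, seed = 99, noise = c(1 / 1.5, 1.5),
                          n_replicates = 100)
  expect_identical(ds$observations$value, ds2$observations$value)
})

test_that("boundary tables sum member fluxes and flag uncovered fluxes", {
  ds <- flat_dataset()
  bt <- flat_boundary()
  net <- ds$network
  ## flat scenario: totals constant and equal to the baseline group sums
  base_sums <- drop(ceradyn:::group_matrix(net) %*% ds$baseline$fluxes)
  for (g in names(net$boundary_groups)) {
    vals <- bt$value[bt$group == g]
    expect_equal(vals, rep(base_sums[[g]], 31), tolerance = 1e-6)
  }
  ## totals equal brute-force member sums at every minute
  fl <- ds$truth$fluxes
  for (g in c("synthase_dhc", "ipcase_phc", "acyl_coa_drain")) {
    ids <- net$boundary_groups[[g]]
    manual <- tapply(fl$value[fl$flux_id %in% ids],
                     fl$time_min[fl$flux_id %in% ids], sum)
    expect_equal(bt$value[bt$group == g], as.numeric(manual))
  }
  ## dropping a flux from all groups raises a coverage warning naming it
  groups <- net$boundary_groups
  groups$acyl_coa_drain <- 52L
  expect_warning(export_boundary_table(ds, groups), "53")
})

test_that("dataset files are written as plain tidy text", {
  dir <- tempfile()
  paths <- write_dataset(flat_dataset(), dir)
  expect_true(all(file.exists(paths)))
  obs <- utils::read.csv(paths[["observations"]])
  expect_named(obs, c("time_min", "replicate", "pool", "value"))
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$seed, flat_dataset()$seed)
})
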