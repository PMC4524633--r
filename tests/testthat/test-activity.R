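test_that("proxies invert the mass-action factorisation exactly", {
  ens <- flat_ensemble()
  pm <- flat_minutes()
  px <- activity_proxies(ens, pm)
  expect_equal(nrow(px), 53 * 31)
  expect_equal(px$fold[px$time_min == 0], rep(1, 53))

  ## recomposition: proxy x substrate product equals the input flux at
  ## every estimated minute
  net <- test_net()
  wide <- tidyr::pivot_wider(pm, id_cols = "time_min", names_from = "pool",
                             values_from = "value")
  for (t in c(1, 17, 30)) {
    x <- setNames(rep(NA_real_, 15), net$pools$name)
    x[colnames(wide)[-1]] <- unlist(wide[wide$time_min == t, -1])
    x[is.na(x)] <- ens$baseline$state[is.na(x)]
    dvals <- vapply(net$drivers, function(f) f(t), numeric(1))
    m <- ceradyn:::mass_action_factor(net, x, dvals)
    sub <- px[px$time_min == t, ]
    agg <- ens$aggregates
    v_in <- agg$mean[agg$time_min == t][match(sub$flux_id,
                                              agg$flux_id[agg$time_min == t])]
    expect_equal(unname(sub$proxy * m), unname(v_in), tolerance = 1e-12)
  }
})

test_that("activity smoothing is conservative and can interpolate", {
  ens <- flat_ensemble()
  px <- activity_proxies(ens, flat_minutes())
  cv <- smooth_activities(px)
  expect_length(cv$funs, 53)

  ## constant proxies give a constant smooth
  const <- px[px$flux_id == 46, ]
  f <- cv$funs[["V46"]]
  expect_lt(diff(range(f(seq(0, 30, 0.5)))) / mean(f(0:30)), 1e-6)

  ## fitted values never miss the raw proxies by more than their spread
  for (nm in c("V1", "V21", "V49")) {
    d <- px[px$flux == nm & !is.na(px$proxy), ]
    resid <- cv$funs[[nm]](d$time_min) - d$proxy
    expect_lte(sqrt(mean(resid^2)), sd(d$proxy) + 1e-12)
  }

  ## interpolation-limit smoothing reproduces a wiggly proxy series
  set.seed(2)
  fake <- px[px$flux == "V1", ]
  fake$proxy <- fake$proxy * exp(rnorm(31, 0, 0.2))
  cvi <- smooth_activities(fake, smoothing = "interpolate")
  expect_equal(cvi$funs[["V1"]](fake$time_min), fake$proxy,
               tolerance = 0.01)
})

test_that("activity curves built from known functions evaluate exactly", {
  net <- test_net()
  bs <- test_baseline()
  cv <- as_activity_curves(net, bs$activities)
  expect_equal(vapply(colnames(net$S), function(nm) cv$funs[[nm]](13.7),
                      numeric(1)),
               bs$activities)
  afn <- curves_activity_fn(cv, net)
  expect_equal(afn(4.2), bs$activities)
})

test_that("unit coefficients reproduce the plain windowed simulation", {
  net <- test_net()
  bs <- test_baseline()
  sc <- make_scenario(net, "heat_stress", seed = 3)
  afn <- ceradyn:::scenario_activity_fn(sc, bs$activities)
  t0 <- 3; len <- 3; dt <- 0.05
  tg <- seq(t0, t0 + len, dt)
  Gmat <- t(vapply(tg, afn, numeric(53)))
  x_start <- bs$x0 * exp(0.05)   # off-steady start
  sim <- ceradyn:::window_simulate(net, x_start, t0, len, rep(1, 53),
                                   Gmat, tg, dt)
  ref <- simulate_network(net, afn, x_start, times = t0 + 0:len)
  ref_mat <- matrix(ref$value, nrow = len + 1)[-1, ]
  expect_equal(sim, ref_mat, tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("shooting refinement objects expose a tidy ensemble", {
  net <- test_net()
  bs <- test_baseline()
  ds <- flat_dataset()
  cv <- as_activity_curves(net, bs$activities)
  mt <- truth_minute_table(ds, pools = "all")
  wc <- shooting_refine(net, cv, mt, n_inits = 1, by = "class", seed = 2,
                        window_len = 10)
  expect_equal(nrow(wc$windows), 3)
  td <- tidy(wc)
  expect_true(all(c("window", "coef", "member", "value", "sse") %in%
                    names(td)))
  expect_true(all(td$value >= wc$coef_bounds[1] &
                    td$value <= wc$coef_bounds[2]))
  gl <- glance(wc)
  expect_equal(gl$n_windows, 3)
})

test_that("activity reports normalise to baseline and average members", {
  net <- test_net()
  bs <- test_baseline()
  ds <- flat_dataset()
  cv <- as_activity_curves(net, bs$activities)
  mt <- truth_minute_table(ds, pools = "all")
  wc <- shooting_refine(net, cv, mt, n_inits = 2, by = "class", seed = 2,
                        window_len = 15)
  rep <- assemble_activity_report(wc)
  expect_equal(length(unique(rep$trends$flux_id)), 53)
  expect_equal(rep$trends$fold_change_mean[rep$trends$time_min == 0],
               rep(1, 53))
  ## averaged trend equals the brute-force mean over members
  manual <- rep$individuals |>
    dplyr::group_by(.data$time_min, .data$flux_id) |>
    dplyr::summarise(m = mean(.data$fold_change), .groups = "drop")
  joined <- dplyr::left_join(rep$trends, manual,
                             by = c("time_min", "flux_id"))
  expect_equal(joined$fold_change_mean, joined$m)

  ## single-member report (identity start only): averaged equals individual
  wc1 <- shooting_refine(net, cv, mt, n_inits = 0, by = "class", seed = 2,
                         window_len = 15)
  rep1 <- assemble_activity_report(wc1)
  j <- dplyr::left_join(
    rep1$trends,
    rep1$individuals[, c("time_min", "flux_id", "fold_change")],
    by = c("time_min", "flux_id"))
  expect_equal(j$fold_change_mean, j$fold_change)
})
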