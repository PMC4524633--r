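test_that("flux rates are mass-action products, linear in activities", {
  net <- test_net()
  x <- test_baseline()$x0
  a <- runif(53, 0.5, 2)

  expect_equal(unname(flux_rates(net, x, rep(0, 53), 0)), rep(0, 53))

  ## first-order in the single substrate of a ceramidase flux (V3: X1 -> out)
  r1 <- flux_rates(net, x, a, 0)
  x2 <- x; x2[1] <- 2 * x2[1]
  r2 <- flux_rates(net, x2, a, 0)
  expect_equal(r2[["V3"]], 2 * r1[["V3"]])

  ## hand-computed synthase rate: activity x DHS driver x acyl-CoA pool
  dhs <- net$drivers$DHS(0)
  expect_equal(r1[["V1"]], a[1] * dhs * x[["CoA_C14_C16"]])

  ## homogeneity of degree 1 in the activity vector
  expect_equal(unname(flux_rates(net, x, 3 * a, 0)),
               3 * unname(flux_rates(net, x, a, 0)))
})

test_that("the right-hand side equals brute-force signed flux sums", {
  net <- test_net()
  x <- test_baseline()$x0
  set.seed(4)
  for (rep in 1:5) {
    a <- runif(53, 0, 5)
    v <- flux_rates(net, x, a, 0)
    manual <- numeric(15)
    for (j in seq_len(53)) {
      row <- net$fluxes[net$fluxes$id == j, ]
      if (!is.na(row$consumes)) manual[row$consumes] <- manual[row$consumes] - v[j]
      if (!is.na(row$produces)) manual[row$produces] <- manual[row$produces] + v[j]
    }
    expect_equal(unname(network_rhs(net, x, a, 0)), manual)
  }
  expect_equal(unname(network_rhs(net, x, rep(0, 53), 0)), rep(0, 15))
})

test_that("hydroxylase-only dynamics move mass from DHC to PHC pools", {
  net <- test_net()
  a <- rep(0, 53)
  a[c(4, 9, 14, 19, 24)] <- 1
  d <- network_rhs(net, test_baseline()$x0, a, 0)
  expect_equal(unname(d[1:5]), -unname(d[6:10]))
  expect_equal(unname(d[11:15]), rep(0, 5))
})

test_that("simulation holds a steady state and matches a closed form", {
  net <- test_net()
  bs <- test_baseline()
  tr <- simulate_network(net, bs$activities, bs$x0, 0:30)
  drift <- abs(tr$value - rep(unname(bs$x0), each = 31)) /
    rep(unname(bs$x0), each = 31)
  expect_lt(max(drift), 1e-6)

  ## two-pool chain: inflow u, transfer k12, outflow k2 -- closed-form check
  net2 <- ceramide_network(toy_chain_topology())
  u <- 2; k1 <- 0.7; k2 <- 0.3
  x0 <- c(1, 1)
  tr2 <- simulate_network(net2, c(u, k1, k2), x0, times = seq(0, 5, 0.5))
  p1 <- function(t) u / k1 + (x0[1] - u / k1) * exp(-k1 * t)
  # dP2/dt = k1 P1 - k2 P2, solved by integrating factor
  p2 <- function(t) {
    A <- u / k2
    B <- k1 * (x0[1] - u / k1) / (k2 - k1)
    A + B * exp(-k1 * t) + (x0[2] - A - B) * exp(-k2 * t)
  }
  tt <- seq(0, 5, 0.5)
  expect_equal(tr2$value[tr2$pool == "P1"], p1(tt), tolerance = 1e-7)
  expect_equal(tr2$value[tr2$pool == "P2"], p2(tt), tolerance = 1e-7)
})

test_that("trajectory slopes are consistent with the right-hand side", {
  net <- test_net()
  bs <- test_baseline()
  sc <- make_scenario(net, "heat_stress", seed = 1)
  afn <- ceradyn:::scenario_activity_fn(sc, bs$activities)
  h <- 0.01
  for (t in c(2, 10, 25)) {
    tr <- simulate_network(net, afn, bs$x0, times = c(0, t - h, t, t + h))
    mat <- matrix(tr$value, nrow = 4)
    fd <- (mat[4, ] - mat[2, ]) / (2 * h)
    x_t <- mat[3, ]
    expect_equal(fd, unname(network_rhs(net, x_t, afn(t), t)),
                 tolerance = 1e-4)
  }
})

test_that("baseline activities balance the network", {
  net <- test_net()
  bs <- test_baseline()
  expect_lt(max(abs(network_rhs(net, bs$x0, bs$activities, 0))), 1e-8)
  expect_true(all(bs$fluxes >= 0))

  ## linearity: doubling all boundary targets doubles the balanced fluxes
  bal2 <- baseline_activities(net, bs$x0, 2 * bs$boundary_targets)
  expect_equal(bal2$fluxes, 2 * bs$fluxes, tolerance = 1e-8)
})

test_that("baseline activities on a toy chain match the hand solution", {
  net <- ceramide_network(toy_chain_topology())
  x0 <- c(2, 4)
  targets <- c(inflow = 3, transfer = 3, outflow = 3)
  bal <- baseline_activities(net, x0, targets)
  ## v = (3, 3, 3); a = v / (driver or substrate)
  expect_equal(unname(bal$fluxes), c(3, 3, 3), tolerance = 1e-9)
  expect_equal(unname(bal$activities), c(3 / 1, 3 / 2, 3 / 4),
               tolerance = 1e-9)
  expect_error(baseline_activities(net, x0, c(inflow = 1, transfer = 5,
                                              outflow = 1)),
               "residual")
})
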