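test_that("default network is built with a mass-balanced incidence matrix", {
  net <- test_net()
  expect_s3_class(net, "ceramide_network")
  expect_identical(dim(net$S), c(15L, 53L))
  ## every column has the signed incidence pattern and internal columns
  ## cancel exactly
  internal <- !net$fluxes$is_boundary
  expect_true(all(colSums(net$S[, internal]) == 0))
  expect_true(all(net$S %in% c(-1, 0, 1)))
  ## pool layout: DHC 1-5, PHC 6-10, acyl-CoA 11-15, chain classes in order
  expect_identical(net$pools$role,
                   rep(c("DHC", "PHC", "FattyAcylCoA"), each = 5))
  expect_identical(net$pools$chain[1:5], net$pools$chain[6:10])
})

test_that("enzyme-class memberships follow the pathway layout", {
  net <- test_net()
  cls <- function(k) sort(net$fluxes$id[net$fluxes$enzyme_class == k])
  expect_identical(cls("ceramide_synthase"),
                   sort(c(1L, 6L, 11L, 16L, 21L, 26L, 30L, 34L, 38L, 42L)))
  expect_identical(cls("dihydroceramidase"), c(3L, 8L, 13L, 18L, 23L))
  expect_identical(cls("phytoceramidase"), c(28L, 32L, 36L, 40L, 44L))
  expect_identical(cls("IPCase"),
                   sort(c(2L, 7L, 12L, 17L, 22L, 27L, 31L, 35L, 39L, 43L)))
  expect_identical(cls("DHC_hydroxylase"), c(4L, 9L, 14L, 19L, 24L))
  expect_identical(cls("remodelase"), 46L)
  expect_identical(cls("desaturase"), 49L)
  expect_length(cls("elongase"), 6L)
})

test_that("topology validation names the offending fluxes", {
  topo <- default_ceramide_topology()
  topo$fluxes$consumes[topo$fluxes$id == 3] <- 99L
  expect_error(ceramide_network(topo), "99")
  expect_error(ceramide_network(topo), "\\b3\\b")

  topo2 <- default_ceramide_topology()
  topo2$fluxes$id[2] <- 1L
  expect_error(ceramide_network(topo2), "duplicate")

  topo3 <- default_ceramide_topology()
  topo3$boundary_groups$extra <- 5L   # V5 already in ipc_synthase_dhc
  expect_error(ceramide_network(topo3), "more than one boundary group")
})

test_that("boundary drivers accept constants, tables and functions", {
  topo <- toy_chain_topology()
  topo$drivers$IN <- data.frame(time = c(0, 10), value = c(1, 3))
  net <- ceramide_network(topo)
  r0 <- flux_rates(net, c(1, 1), c(1, 1, 1), 0)
  r5 <- flux_rates(net, c(1, 1), c(1, 1, 1), 5)
  expect_equal(unname(r0[1]), 1)
  expect_equal(unname(r5[1]), 2)   # linear interpolation of the table
})

test_that("topology YAML round-trips through the reader", {
  topo <- toy_chain_topology()
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    pools = lapply(seq_len(nrow(topo$pools)), function(i)
      as.list(topo$pools[i, ])),
    fluxes = lapply(seq_len(nrow(topo$fluxes)), function(i) {
      row <- topo$fluxes[i, ]
      list(id = row$id, enzyme_class = row$enzyme_class,
           consumes = if (is.na(row$consumes)) "" else row$consumes,
           produces = if (is.na(row$produces)) "" else row$produces,
           drivers = paste(row$drivers[[1]], collapse = ","))
    }),
    boundary_groups = topo$boundary_groups,
    drivers = topo$drivers
  ), path)
  rt <- read_ceramide_topology(path)
  net <- ceramide_network(rt)
  expect_identical(dim(net$S), c(2L, 3L))
  expect_identical(net$fluxes$drivers[[1]], "IN")
})
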