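# shared fixtures, computed once per test run

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, expr, envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

test_net <- function() memo("net", ceramide_network())

test_baseline <- function() memo("baseline", baseline_state(test_net()))

## noise-free flat-scenario dataset and its per-minute preprocessing
flat_dataset <- function() {
  memo("flat_ds", generate_dataset(test_net(), seed = 11, noise = c(1, 1)))
}
flat_minutes <- function() {
  memo("flat_pm", preprocess_timeseries(flat_dataset()$observations))
}
flat_boundary <- function() {
  memo("flat_bt", export_boundary_table(flat_dataset()))
}
## small shared ensemble on the flat dataset
flat_ensemble <- function() {
  memo("flat_ens",
       estimate_flux_ensemble(flat_minutes(), flat_boundary(), test_net(),
                              n_restart = 10, seed = 21))
}

## tiny linear-chain topology: driver -> P1 -> P2 -> out, three fluxes
toy_chain_topology <- function() {
  list(
    pools = tibble::tibble(
      id = 1:2, role = c("DHC", "DHC"),
      chain = c("C14/C16", "C18"), name = c("P1", "P2")
    ),
    fluxes = tibble::tibble(
      id = 1:3,
      enzyme_class = c("remodelase", "elongase", "elongase"),
      consumes = c(NA, 1L, 2L),
      produces = c(1L, 2L, NA),
      drivers = list("IN", character(), character())
    ),
    boundary_groups = list(inflow = 1L, transfer = 2L, outflow = 3L),
    drivers = list(IN = 1)
  )
}
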