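#' Default topology of the ceramide subsystem
#'
#' Returns the bundled description of the ceramide subsystem of yeast
#' sphingolipid metabolism: 15 metabolite pools (five dihydroceramide
#' species, five phytoceramide species and five fatty-acyl-CoA pools, one
#' per chain-length class) connected by 53 fluxes grouped into nine enzyme
#' classes.  The dihydroceramide side is wired in blocks of five fluxes per
#' chain class (ceramide synthase, IPCase, dihydroceramidase, DHC
#' hydroxylase, IPC synthase), the phytoceramide side in blocks of four
#' (ceramide synthase, IPCase, phytoceramidase, IPC synthase), and the
#' center column carries fatty-acyl elongation and desaturation plus a
#' remodelase inflow.
#'
#' Sphingoid bases (DHS, PHS), the lumped complex sphingolipid pool (IPC,
#' together with its mannosylated forms) and the free-fatty-acid supply of
#' the remodelase are boundary drivers: time-dependent external inputs, not
#' state variables.
#'
#' @return A list with elements `pools` (tibble), `fluxes` (tibble),
#'   `boundary_groups` (named list of flux ids) and `drivers` (named list of
#'   constants or `data.frame(time, value)` tables).
#' @export
#' @examples
#' topo <- default_ceramide_topology()
#' nrow(topo$fluxes)  # 53
default_ceramide_topology <- function() {
  pools <- tibble::tibble(
    id    = 1:15,
    role  = rep(c("DHC", "PHC", "FattyAcylCoA"), each = 5),
    chain = rep(CHAIN_CLASSES, times = 3),
    name  = paste0(
      rep(c("DHC_", "PHC_", "CoA_"), each = 5),
      gsub("[/:]", "_", rep(CHAIN_CLASSES, times = 3))
    )
  )

  flux <- function(id, enzyme_class, consumes, produces, drivers = character()) {
    tibble::tibble(
      id = as.integer(id), enzyme_class = enzyme_class,
      consumes = as.integer(consumes), produces = as.integer(produces),
      drivers = list(drivers)
    )
  }

  rows <- list()
  for (k in 1:5) {
    b <- 5L * (k - 1L)
    rows <- c(rows, list(
      flux(b + 1L, "ceramide_synthase", 10L + k, k, "DHS"),
      flux(b + 2L, "IPCase",            NA,      k, "IPC"),
      flux(b + 3L, "dihydroceramidase", k,       NA),
      flux(b + 4L, "DHC_hydroxylase",   k,       5L + k),
      flux(b + 5L, "IPC_synthase",      k,       NA)
    ))
  }
  for (k in 1:5) {
    b <- 25L + 4L * (k - 1L)
    rows <- c(rows, list(
      flux(b + 1L, "ceramide_synthase", 10L + k, 5L + k, "PHS"),
      flux(b + 2L, "IPCase",            NA,      5L + k, "IPC"),
      flux(b + 3L, "phytoceramidase",   5L + k,  NA),
      flux(b + 4L, "IPC_synthase",      5L + k,  NA)
    ))
  }
  rows <- c(rows, list(
    flux(46L, "remodelase", NA, 11L, "FFA"),
    flux(47L, "elongase",   11L, 12L),
    flux(48L, "elongase",   12L, 14L),
    flux(49L, "desaturase", 12L, 13L),
    flux(50L, "elongase",   13L, 14L),
    flux(51L, "elongase",   14L, 15L),
    flux(52L, "elongase",   14L, NA),
    flux(53L, "elongase",   15L, NA)
  ))
  fluxes <- dplyr::bind_rows(rows)

  boundary_groups <- list(
    synthase_dhc      = c(1L, 6L, 11L, 16L, 21L),
    synthase_phc      = c(26L, 30L, 34L, 38L, 42L),
    dihydroceramidase = c(3L, 8L, 13L, 18L, 23L),
    phytoceramidase   = c(28L, 32L, 36L, 40L, 44L),
    ipcase_dhc        = c(2L, 7L, 12L, 17L, 22L),
    ipcase_phc        = c(27L, 31L, 35L, 39L, 43L),
    ipc_synthase_dhc  = c(5L, 10L, 15L, 20L, 25L),
    ipc_synthase_phc  = c(29L, 33L, 37L, 41L, 45L),
    hydroxylase       = c(4L, 9L, 14L, 19L, 24L),
    remodelase        = 46L,
    elongation_16_18  = 47L,
    elongation_18_24  = 48L,
    elongation_18_1_24 = 50L,
    elongation_24_26  = 51L,
    desaturation      = 49L,
    acyl_coa_drain    = c(52L, 53L)
  )

  list(
    pools = pools,
    fluxes = fluxes,
    boundary_groups = boundary_groups,
    drivers = list(DHS = 1, PHS = 1, IPC = 1, FFA = 1)
  )
}

#' Build and validate a ceramide reaction network
#'
#' Assembles a [GMA (generalized mass action)] model of the ceramide
#' subsystem from a topology description: the signed stoichiometric
#' incidence matrix `S` (pools x fluxes), the kinetic wiring of every flux
#' (its internal substrate, if any, and its boundary drivers), the
#' enzyme-class labels and the boundary-flux groups that tie subsets of
#' fluxes to known totals.  All kinetic orders are 1 and activities enter
#' linearly, so each flux is
#' \deqn{v_j = a_j \prod_{\mathrm{substrates}} X_i \prod_{\mathrm{drivers}} d(t).}
#'
#' @param topology A topology description as returned by
#'   [default_ceramide_topology()] or [read_ceramide_topology()].
#' @return An object of class `ceramide_network` with components `pools`,
#'   `fluxes`, `S` (pools x fluxes signed incidence matrix),
#'   `boundary_groups`, and per-flux kinetic index vectors.
#' @export
#' @examples
#' net <- ceramide_network()
#' dim(net$S)  # 15 x 53
ceramide_network <- function(topology = default_ceramide_topology()) {
  pools <- tibble::as_tibble(topology$pools)
  fluxes <- tibble::as_tibble(topology$fluxes)
  n_pool <- nrow(pools)
  n_flux <- nrow(fluxes)

  problems <- character()
  dup <- fluxes$id[duplicated(fluxes$id)]
  if (length(dup)) {
    problems <- c(problems, sprintf("duplicate flux id(s): %s",
                                    paste(unique(dup), collapse = ", ")))
  }
  bad <- (!is.na(fluxes$consumes) & !(fluxes$consumes %in% pools$id)) |
    (!is.na(fluxes$produces) & !(fluxes$produces %in% pools$id))
  if (any(bad)) {
    ids <- unique(stats::na.omit(c(fluxes$consumes[bad],
                                   fluxes$produces[bad])))
    ids <- setdiff(ids, pools$id)
    problems <- c(problems,
      sprintf("flux(es) %s reference pool id(s) %s outside 1..%d",
              paste(fluxes$id[bad], collapse = ", "),
              paste(ids, collapse = ", "), n_pool))
  }
  is_boundary <- is.na(fluxes$consumes) | is.na(fluxes$produces) |
    lengths(fluxes$drivers) > 0L
  bad_bal <- fluxes$id[!is_boundary &
                         (is.na(fluxes$consumes) | is.na(fluxes$produces))]
  if (length(bad_bal)) {
    problems <- c(problems,
      sprintf("internal flux(es) %s not mass-balanced (need one consumed and one produced pool)",
              paste(bad_bal, collapse = ", ")))
  }
  groups <- topology$boundary_groups %||% list()
  memb <- unlist(groups, use.names = FALSE)
  multi <- unique(memb[duplicated(memb)])
  if (length(multi)) {
    problems <- c(problems,
      sprintf("flux(es) %s belong to more than one boundary group",
              paste(multi, collapse = ", ")))
  }
  if (length(problems)) {
    abort(c("invalid ceramide network topology", problems))
  }

  S <- matrix(0, n_pool, n_flux,
              dimnames = list(pools$name, paste0("V", fluxes$id)))
  for (r in seq_len(n_flux)) {
    j <- fluxes$id[r]
    if (!is.na(fluxes$consumes[r])) S[fluxes$consumes[r], j] <- -1
    if (!is.na(fluxes$produces[r])) S[fluxes$produces[r], j] <- 1
  }

  driver_names <- names(topology$drivers)
  driver_fn <- lapply(topology$drivers, as_driver_fn)
  driver_idx <- lapply(fluxes$drivers, function(d) {
    i <- match(d, driver_names)
    if (anyNA(i)) {
      abort(sprintf("undeclared boundary driver(s): %s",
                    paste(d[is.na(i)], collapse = ", ")))
    }
    i
  })

  ## order fluxes by id so column j corresponds to flux id j
  ord <- order(fluxes$id)
  fluxes <- fluxes[ord, ]
  driver_idx <- driver_idx[ord]
  is_boundary <- is_boundary[ord]
  fluxes$is_boundary <- is_boundary

  structure(
    list(
      pools = pools,
      fluxes = fluxes,
      S = S,
      boundary_groups = groups,
      drivers = driver_fn,
      driver_idx = driver_idx,
      substrate_idx = ifelse(is.na(fluxes$consumes), 0L, fluxes$consumes)
    ),
    class = "ceramide_network"
  )
}

as_driver_fn <- function(d) {
  if (is.function(d)) return(d)
  if (is.numeric(d) && length(d) == 1L) {
    force(d)
    return(function(t) rep(d, length(t)))
  }
  d <- as.data.frame(d)
  if (!all(c("time", "value") %in% names(d))) {
    abort("driver tables need `time` and `value` columns")
  }
  approxfun(d$time, d$value, rule = 2)
}

#' @export
print.ceramide_network <- function(x, ...) {
  cat(sprintf("<ceramide_network> %d pools, %d fluxes\n",
              nrow(x$pools), nrow(x$fluxes)))
  counts <- table(x$fluxes$enzyme_class)
  cat("enzyme classes:\n")
  for (nm in names(counts)) cat(sprintf("  %-18s %d\n", nm, counts[[nm]]))
  cat(sprintf("boundary groups: %d (%s)\n", length(x$boundary_groups),
              paste(head(names(x$boundary_groups), 4), collapse = ", ")))
  invisible(x)
}

#' Read a network topology from a YAML or JSON file
#'
#' The file mirrors the structure of [default_ceramide_topology()]: a
#' `pools` table, a `fluxes` table (id, enzyme_class, consumes, produces,
#' drivers), `boundary_groups`, and `drivers` given either as constants or
#' as `(time, value)` tables.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` topology file.
#' @return A topology list suitable for [ceramide_network()].
#' @export
read_ceramide_topology <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  tidy_tbl <- function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x) else dplyr::bind_rows(lapply(x, tibble::as_tibble))
  }
  if (!is.data.frame(raw$fluxes)) {
    ## row-wise YAML/JSON entries may mix "" (missing) with integers
    raw$fluxes <- lapply(raw$fluxes, function(row) {
      for (f in c("consumes", "produces")) {
        row[[f]] <- as.character(row[[f]] %||% "")
      }
      row
    })
  }
  fluxes <- tidy_tbl(raw$fluxes)
  if (!is.list(fluxes$drivers)) {
    fluxes$drivers <- lapply(
      strsplit(ifelse(is.na(fluxes$drivers) | fluxes$drivers == "",
                      "", fluxes$drivers), ",\\s*"),
      function(d) d[nzchar(d)]
    )
  }
  fluxes$consumes <- suppressWarnings(as.integer(fluxes$consumes))
  fluxes$produces <- suppressWarnings(as.integer(fluxes$produces))
  list(
    pools = tidy_tbl(raw$pools),
    fluxes = fluxes,
    boundary_groups = lapply(raw$boundary_groups, as.integer),
    drivers = raw$drivers
  )
}

## group incidence matrix: one row per boundary group, 0/1 over fluxes
group_matrix <- function(net) {
  g <- net$boundary_groups
  A <- matrix(0, length(g), nrow(net$fluxes),
              dimnames = list(names(g), colnames(net$S)))
  for (i in seq_along(g)) A[i, g[[i]]] <- 1
  A
}

## warn when fluxes are not covered by any boundary group
check_group_coverage <- function(net) {
  covered <- sort(unique(unlist(net$boundary_groups)))
  missing <- setdiff(net$fluxes$id, covered)
  if (length(missing)) {
    warn(sprintf("flux(es) not covered by any boundary group: %s",
                 paste(missing, collapse = ", ")))
  }
  invisible(missing)
}
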