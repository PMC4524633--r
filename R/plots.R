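#' Plot ensemble flux bands
#'
#' Mean and median flux time courses with the 20th-80th percentile band
#' per flux.
#'
#' @param object A [estimate_flux_ensemble()] result.
#' @param fluxes Optional character vector of flux names (`"V1"`, ...) to
#'   show; defaults to the ceramide synthase fluxes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_ensemble <- function(object, fluxes = NULL, ...) {
  agg <- object$aggregates
  if (is.null(fluxes)) {
    fluxes <- unique(agg$flux[agg$enzyme_class == "ceramide_synthase"])
  }
  d <- agg[agg$flux %in% fluxes, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p20, ymax = .data$p80),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$median), shape = 8,
                        size = 0.8) +
    ggplot2::facet_wrap(~flux, scales = "free_y") +
    ggplot2::labs(x = "time under heat stress (min)", y = "flux",
                  title = "Ensemble flux estimates (mean, median, p20-p80)")
}

#' Plot refined enzyme-activity trends
#'
#' Averaged fold-change trends (line) with the individual shooting-ensemble
#' members (points), faceted per flux.
#'
#' @param object An [assemble_activity_report()] result.
#' @param enzyme_class Optional single enzyme class to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activity_report <- function(object, enzyme_class = NULL, ...) {
  tr <- object$trends
  ind <- object$individuals
  if (!is.null(enzyme_class)) {
    tr <- tr[tr$enzyme_class == enzyme_class, ]
    ind <- ind[ind$enzyme_class == enzyme_class, ]
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(data = ind,
                        ggplot2::aes(y = .data$fold_change),
                        colour = "grey60", size = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fold_change_mean),
                       colour = "royalblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::facet_wrap(~flux, scales = "free_y") +
    ggplot2::labs(x = "time under heat stress (min)",
                  y = "activity fold change",
                  title = "Refined enzyme-activity trends")
}

#' One activity panel per ceramide-facing enzyme class
#'
#' @param report An [assemble_activity_report()] result.
#' @return Named list of ggplot objects, one per class that directly
#'   synthesizes or consumes ceramides (synthase, the two ceramidases,
#'   IPC synthase, IPCase, hydroxylase share a panel list entry each).
#' @export
plot_enzyme_class_panels <- function(report) {
  classes <- c("ceramide_synthase", "dihydroceramidase", "phytoceramidase",
               "IPC_synthase", "IPCase")
  out <- lapply(classes, function(cl) {
    autoplot(report, enzyme_class = cl) +
      ggplot2::ggtitle(gsub("_", " ", cl))
  })
  names(out) <- classes
  out
}

#' Overlay the windowed model reconstruction on the splined data
#'
#' Re-simulates each window with the ensemble-mean coefficients and plots
#' the reconstruction against the splined concentrations, marking window
#' boundaries; discontinuities at the boundaries reflect the windowed
#' optimization.
#'
#' @param coeffs A [shooting_refine()] result.
#' @param minute_tbl The per-minute concentrations used for refinement.
#' @param pools Optional pool names to show (default: all measured).
#' @return A ggplot object.
#' @export
plot_fit_overlay <- function(coeffs, minute_tbl, pools = NULL) {
  sim <- windowed_trajectory(coeffs, minute_tbl)
  if (!is.null(pools)) sim <- sim[sim$pool %in% pools, ]
  bounds <- coeffs$windows$t_start[-1]
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed),
                        colour = "firebrick", size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated,
                                    group = .data$window),
                       colour = "royalblue") +
    ggplot2::geom_vline(xintercept = bounds, linetype = 3,
                        colour = "grey70") +
    ggplot2::facet_wrap(~pool, scales = "free_y") +
    ggplot2::labs(x = "time under heat stress (min)", y = "concentration",
                  title = "Windowed model reconstruction vs splined data")
}

#' Windowed reconstruction of the concentration trajectories
#'
#' Simulates every window from its splined starting state with the
#' ensemble-mean coefficients applied to the smoothed activities.
#'
#' @inheritParams plot_fit_overlay
#' @param statistic Aggregate of the coefficient ensemble, `"mean"` or
#'   `"median"`.
#' @return Tibble (`window`, `time_min`, `pool`, `simulated`, `observed`).
#' @export
windowed_trajectory <- function(coeffs, minute_tbl,
                                statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  net <- coeffs$net
  pools <- net$pools
  flux_names <- colnames(net$S)
  measured <- intersect(pools$name, unique(minute_tbl$pool))
  unmeasured <- setdiff(pools$name, measured)
  unobs <- baseline_state(net)$x0[unmeasured]
  wide <- tidyr::pivot_wider(minute_tbl, id_cols = "time_min",
                             names_from = "pool", values_from = "value")
  state_at <- function(t) {
    x <- setNames(rep(NA_real_, nrow(pools)), pools$name)
    x[measured] <- unlist(wide[wide$time_min == t, measured])
    x[unmeasured] <- unobs[unmeasured]
    x
  }
  agg_fun <- if (statistic == "mean") colMeans else
    function(m) apply(m, 2, median)
  midx <- match(measured, pools$name)
  purrr::map_dfr(seq_len(nrow(coeffs$windows)), function(w) {
    t0 <- coeffs$windows$t_start[w]
    len <- coeffs$window_len
    ok <- coeffs$ok[[w]]
    if (!any(ok)) return(tibble::tibble())
    Cw <- agg_fun(coeffs$coefficients[[w]][ok, , drop = FALSE])
    tg <- seq(t0, t0 + len, by = coeffs$dt)
    Gmat <- vapply(flux_names, function(nm) coeffs$curves$funs[[nm]](tg),
                   numeric(length(tg)))
    dmat <- t(vapply(tg, function(t) {
      dv <- vapply(net$drivers, function(f) f(t), numeric(1))
      vapply(net$driver_idx, function(i) prod(dv[i]), numeric(1))
    }, numeric(length(flux_names))))
    sim <- window_simulate(net, state_at(t0), t0, len,
                           Cw[coeffs$expand_idx], Gmat * dmat, tg,
                           coeffs$dt)
    obs <- t(vapply(t0 + seq_len(len), state_at, numeric(nrow(pools))))
    tibble::tibble(
      window = w,
      time_min = rep(t0 + seq_len(len), times = length(midx)),
      pool = rep(measured, each = len),
      simulated = as.vector(sim[, midx, drop = FALSE]),
      observed = as.vector(obs[, midx, drop = FALSE])
    )
  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
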