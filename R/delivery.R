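#' Machine timing constants
#'
#' Control times and lateral scan speeds of the delivery system.  Note
#' the speeds are in mm per millisecond, so lateral travel is essentially
#' instantaneous compared with spot dwell times.
#'
#' @param t_range_shifter_ms range-shifter control time, ms.
#' @param t_energy_change_ms synchrotron energy change time, ms.
#' @param v_si_mm_per_ms scan speed superior-inferior, mm/ms.
#' @param v_lr_mm_per_ms scan speed left-right, mm/ms.
#' @return object of class `timing_constants`.
#' @export
timing_constants <- function(t_range_shifter_ms = 420,
                             t_energy_change_ms = 150,
                             v_si_mm_per_ms = 100,
                             v_lr_mm_per_ms = 50) {
  stopifnot(t_range_shifter_ms > 0, t_energy_change_ms > 0,
            v_si_mm_per_ms > 0, v_lr_mm_per_ms > 0)
  structure(list(t_range_shifter_ms = t_range_shifter_ms,
                 t_energy_change_ms = t_energy_change_ms,
                 v_si_mm_per_ms = v_si_mm_per_ms,
                 v_lr_mm_per_ms = v_lr_mm_per_ms),
            class = "timing_constants")
}

#' Delivery configuration
#'
#' @param n_rescans number of phase-controlled rescans (1-10).
#' @param strategy `"ungated"` or `"gated"`.
#' @param trace a [respiratory_trace()].
#' @param timing a [timing_constants()].
#' @param base_layer_time_s ungated time budget per layer.  Default one
#'   full respiratory cycle: phase-controlled rescanning tunes the layer
#'   dose rate so the n rescan passes exactly span one breathing period
#'   (the "gating window" of an ungated delivery is the whole cycle), so
#'   per-spot phase coverage approaches uniform as n grows and the total
#'   time is independent of n.  With a gate the window shrinks to the
#'   gate-open duration.
#' @return object of class `delivery_config`.
#' @export
delivery_config <- function(n_rescans, strategy = c("ungated", "gated"),
                            trace, timing = timing_constants(),
                            base_layer_time_s = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(n_rescans >= 1, n_rescans <= 10,
            inherits(trace, "respiratory_trace"))
  gate_window_s <- length(trace$gate_phases) * trace$cycle_s / 10
  if (is.null(base_layer_time_s)) base_layer_time_s <- trace$cycle_s
  structure(list(n_rescans = as.integer(n_rescans), strategy = strategy,
                 trace = trace, timing = timing,
                 gate_window_s = gate_window_s,
                 base_layer_time_s = base_layer_time_s),
            class = "delivery_config")
}

# travel times (s) between consecutive spots of a path: simultaneous
# two-axis sweep, u along LR and v along SI.
path_travel_s <- function(u_mm, v_mm, timing) {
  n <- length(u_mm)
  if (n < 2) return(numeric(0))
  du <- abs(diff(u_mm))
  dv <- abs(diff(v_mm))
  pmax(du / timing$v_lr_mm_per_ms, dv / timing$v_si_mm_per_ms) / 1000
}

#' Time of one scan pass over a layer
#'
#' Sum of spot dwell times (weight / dose_rate) and inter-spot travel,
#' travel between consecutive path spots being
#' max(|du| / v_lr, |dv| / v_si) (simultaneous two-axis sweep).
#'
#' @param layer data frame with `u_mm`, `v_mm`, `weight` in path order.
#' @param dose_rate weight units per second (> 0).
#' @param timing a [timing_constants()].
#' @return pass time in seconds.
#' @export
layer_pass_time <- function(layer, dose_rate, timing = timing_constants()) {
  stopifnot(dose_rate > 0)
  sum(layer$weight) / dose_rate +
    sum(path_travel_s(layer$u_mm, layer$v_mm, timing))
}

#' Schedule phase-controlled rescanning delivery
#'
#' For every iso-energy layer a fixed time budget W is set (gated: the
#' gate-open duration |gate| * cycle / 10; ungated:
#' `base_layer_time_s`).  The layer dose rate is chosen so that the n
#' rescan passes -- each delivering weight/n per spot, the scan path
#' reversing between passes -- exactly fill W, so each pass spans W/n.
#' Gated layers start at gate openings (one layer per breathing cycle,
#' the energy change happening between gates); ungated layers run back
#' to back separated by the energy-change control time.
#'
#' @param spots an optimized `spot_map`.
#' @param cfg a [delivery_config()].
#' @param t_start_s absolute start time of this field's delivery
#'   (nonzero when fields are delivered sequentially).
#' @return a `delivery_schedule`: `events` data frame (t_start_s,
#'   t_end_s, layer, spot, pass, fraction), `layers` summary (start,
#'   budget, dose rate), `total_time_s`, and the config.
#' @export
schedule_pcr <- function(spots, cfg, t_start_s = 0) {
  if (is.null(spots$spot_id)) spots$spot_id <- seq_len(nrow(spots))
  n <- cfg$n_rescans
  tr <- cfg$timing
  W <- if (cfg$strategy == "gated") cfg$gate_window_s else
    cfg$base_layer_time_s
  cycle <- cfg$trace$cycle_s
  t_energy <- tr$t_energy_change_ms / 1000

  layers <- sort(unique(spots$layer))
  ev_list <- vector("list", length(layers))
  lay_list <- vector("list", length(layers))
  t_ready <- t_start_s
  for (li in seq_along(layers)) {
    lay <- spots[spots$layer == layers[li], ]
    lay <- lay[order(lay$path_order), ]
    trav <- path_travel_s(lay$u_mm, lay$v_mm, tr)
    travel_pass <- sum(trav)
    wsum <- sum(lay$weight)
    dwell_budget <- W - n * travel_pass
    if (dwell_budget <= 0)
      stop("travel time alone exceeds the layer time budget (layer ",
           layers[li], ": ", signif(n * travel_pass, 4), " s travel vs ",
           signif(W, 4), " s budget)")
    # a layer can end up with zero total weight after optimization; it
    # still occupies its window but delivers nothing
    rate <- if (wsum > 0) wsum / dwell_budget else 0
    if (cfg$strategy == "gated") {
      # wait for the next gate opening; gates open at absolute times
      # k * cycle on the global phase clock (t = 0 is the gate opening)
      k <- ceiling(t_ready / cycle - 1e-12)
      lay_start <- k * cycle
    } else {
      lay_start <- t_ready
    }
    pass_time <- W / n
    nsp <- nrow(lay)
    evs <- vector("list", n)
    for (pass in seq_len(n) - 1L) {
      fwd <- pass %% 2L == 0L
      ord <- if (fwd) seq_len(nsp) else rev(seq_len(nsp))
      dw <- if (rate > 0) lay$weight[ord] / n / rate else numeric(nsp)
      tv <- if (nsp > 1) (if (fwd) trav else rev(trav)) else numeric(0)
      starts <- lay_start + pass * pass_time +
        cumsum(c(0, dw[-nsp] + tv))
      evs[[pass + 1L]] <- data.frame(
        t_start_s = starts, t_end_s = starts + dw,
        layer = layers[li], spot = lay$spot_id[ord],
        pass = pass + 1L, fraction = 1 / n)
    }
    ev_list[[li]] <- do.call(rbind, evs)
    lay_list[[li]] <- data.frame(layer = layers[li], start_s = lay_start,
                                 budget_s = W, dose_rate = rate,
                                 travel_pass_s = travel_pass)
    t_ready <- lay_start + W + t_energy
  }
  events <- do.call(rbind, ev_list)
  rownames(events) <- NULL
  lay_df <- do.call(rbind, lay_list)
  structure(list(events = events, layers = lay_df,
                 total_time_s = max(events$t_end_s) - t_start_s,
                 t_start_s = t_start_s, config = cfg,
                 n_spots = nrow(spots)),
            class = "delivery_schedule")
}

#' @exportS3Method base::print
print.delivery_schedule <- function(x, ...) {
  cat("delivery_schedule:", nrow(x$events), "events,",
      nrow(x$layers), "layers,", x$config$strategy,
      paste0(x$config$n_rescans, "x rescan;"),
      "total", signif(x$total_time_s, 4), "s\n")
  invisible(x)
}

#' Apportion delivered spot weight to respiratory phases
#'
#' Each scheduled event's weight fraction is split over phases by the
#' exact time overlap of its dwell interval with the periodic phase
#' intervals of [phase_at_time()].  Zero-length events are assigned to
#' the phase at their start time.
#'
#' @param schedule a [schedule_pcr()] result.
#' @param trace a [respiratory_trace()] (defaults to the schedule's).
#' @param strategy delivery strategy (defaults to the schedule's).
#' @return matrix (n_spots x 10) of per-spot, per-phase weight
#'   fractions; rows sum to 1.
#' @export
weight_by_phase <- function(schedule, trace = schedule$config$trace,
                            strategy = schedule$config$strategy) {
  ev <- schedule$events
  nspot <- schedule$n_spots
  labels <- trace$phase_labels
  start <- if (strategy == "gated") trace$start_phase_gated else
    trace$start_phase_ungated
  i0 <- match(start, labels) - 1L
  pd <- trace$cycle_s / 10

  # absolute times: t = 0 of the global phase clock is the strategy's
  # start phase, shared by all sequentially delivered fields
  t0 <- ev$t_start_s
  t1 <- ev$t_end_s
  dur <- t1 - t0
  # a zero-dwell event whose start coincides with its layer's budget end
  # (e.g. a zero-weight spot at the end of the last pass) belongs to the
  # closing phase interval, not the next one
  t0 <- ifelse(dur == 0, pmax(t0 - 1e-9, 0), t0)
  m0 <- floor(t0 / pd + 1e-12)
  m1 <- floor(pmax(t1 - 1e-12, t0) / pd + 1e-12)
  m1 <- pmax(m1, m0)
  nslot <- as.integer(m1 - m0 + 1)

  eid <- rep(seq_len(nrow(ev)), nslot)
  slot <- sequence(nslot) - 1L + rep(m0, nslot)
  s0 <- pmax(slot * pd, t0[eid])
  s1 <- pmin((slot + 1) * pd, t1[eid])
  ov <- pmax(s1 - s0, 0)
  frac <- ifelse(dur[eid] > 0, ov / dur[eid],
                 as.numeric(slot == m0[eid]))
  phase_idx <- (i0 + slot) %% 10 + 1
  wt <- frac * ev$fraction[eid]

  out <- matrix(0, nspot, 10, dimnames = list(NULL, labels))
  acc <- tapply(wt, list(ev$spot[eid], phase_idx), sum)
  ri <- as.integer(rownames(acc))
  ci <- as.integer(colnames(acc))
  acc[is.na(acc)] <- 0
  out[ri, ci] <- acc
  out
}
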