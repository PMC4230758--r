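#' Plan one field on a phantom
#'
#' Builds the field-specific target volume for the strategy's phase set
#' (gate phases when gated, all ten when ungated), caches the field dose
#' geometry, places spots and optimizes their weights.
#'
#' @param phantom a `phantom4d`.
#' @param gantry_angle_deg beam angle, degrees.
#' @param strategy `"ungated"` or `"gated"` (selects envelope phases).
#' @param prescription_gyrbe this field's prescription (for multi-field
#'   plans, the total prescription divided by the number of fields).
#' @param model a [beam_line_model()].
#' @return list of class `field_plan`: `beam`, `ftv`, `fgeom`, `spots`,
#'   `strategy`, `prescription_gyrbe`.
#' @export
plan_field <- function(phantom, gantry_angle_deg, strategy,
                       prescription_gyrbe, model = beam_line_model()) {
  beam <- beam_port(gantry_angle_deg)
  phases <- if (strategy == "gated") phantom$trace$gate_phases else
    phantom$phases
  ftv <- build_ftv(phantom, beam, phases)
  fgeom <- field_geometry(phantom, beam)
  spots <- place_spots(ftv, model)
  spots <- optimize_weights(spots, ftv, fgeom, prescription_gyrbe)
  structure(list(beam = beam, ftv = ftv, fgeom = fgeom, spots = spots,
                 strategy = strategy,
                 prescription_gyrbe = prescription_gyrbe),
            class = "field_plan")
}

#' Planning dose of a set of fields
#'
#' Interplay-free reference: each field's spots spread equally over the
#' strategy's phases (all ten ungated, the gate phases gated), doses
#' warped to T50 and summed over fields.
#'
#' @param fields list of [plan_field()] results.
#' @param phantom a `phantom4d`.
#' @return dose array at T50.
#' @export
plan_planning_dose <- function(fields, phantom) {
  acc <- array(0, phantom$geom$dim)
  for (f in fields) {
    phases <- if (f$strategy == "gated") phantom$trace$gate_phases else
      phantom$phases
    acc <- acc + planning_dose(f$spots, phantom, f$fgeom, phases)
  }
  acc
}

#' Simulated (treatment) dose of one field's timed delivery
#'
#' Schedules the delivery, apportions every spot's weight to
#' respiratory phases by exact time overlap, computes each phase dose on
#' that phase's anatomy, and accumulates at T50.
#'
#' @param field a [plan_field()] result.
#' @param phantom a `phantom4d`.
#' @param cfg a [delivery_config()].
#' @param t_start_s absolute delivery start time of this field.
#' @return list: `dose` (array at T50), `schedule`, `fractions`
#'   (spot x phase matrix).
#' @export
field_treatment_dose <- function(field, phantom, cfg, t_start_s = 0) {
  schedule <- schedule_pcr(field$spots, cfg, t_start_s)
  fr <- weight_by_phase(schedule)
  acc <- array(0, phantom$geom$dim)
  for (p in phantom$phases) {
    wp <- field$spots$weight * fr[, p]
    if (all(wp == 0)) next
    d <- spot_dose(field$spots, field$fgeom, p, weights = wp)
    acc <- acc + warp_to_reference(d, phantom, p)
  }
  list(dose = acc, schedule = schedule, fractions = fr)
}

#' Simulated treatment dose of a multi-field plan
#'
#' Fields are delivered sequentially on the shared global phase clock;
#' each field starts one energy-change time after the previous one ends
#' (gated fields additionally wait for the next gate opening).
#'
#' @param fields list of [plan_field()] results.
#' @param phantom a `phantom4d`.
#' @param cfg a [delivery_config()].
#' @return list: `dose` (T50 array), `schedules` per field,
#'   `total_time_s` (start of first field to end of last).
#' @export
plan_treatment_dose <- function(fields, phantom, cfg) {
  acc <- array(0, phantom$geom$dim)
  schedules <- vector("list", length(fields))
  t0 <- 0
  for (i in seq_along(fields)) {
    res <- field_treatment_dose(fields[[i]], phantom, cfg, t_start_s = t0)
    acc <- acc + res$dose
    schedules[[i]] <- res$schedule
    t0 <- max(res$schedule$events$t_end_s) +
      cfg$timing$t_energy_change_ms / 1000
  }
  list(dose = acc, schedules = schedules,
       total_time_s = max(schedules[[length(fields)]]$events$t_end_s))
}
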