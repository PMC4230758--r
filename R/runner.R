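#' Experiment configuration
#'
#' Drives a full simulation grid: a cohort of phantom realizations
#' (seeded motion-amplitude and cycle draws spanning the observed
#' clinical ranges), beam ports, prescription, rescan numbers,
#' strategies and field counts.
#'
#' @param n_phantoms cohort size.
#' @param master_seed master seed; every phantom's seed and draws derive
#'   from it.
#' @param prescription_gyrbe total prescription (default 48 Gy(RBE) in
#'   one fraction).
#' @param ports gantry angles used when `n_fields = 4`.
#' @param single_port gantry angle of single-field plans (default 340).
#' @param n_rescans rescan numbers to simulate (subset of 1..10).
#' @param strategies subset of `c("ungated", "gated")`.
#' @param field_counts subset of `c(1, 4)`.
#' @param phantom_base a [phantom_params()] whose amplitude/cycle are
#'   overridden per cohort draw (grid size etc. are taken from it).
#' @param amplitude_ranges list of c(min,max) per axis (LR, AP, SI), mm.
#' @param cycle_range_s c(min, max) breathing period, s.
#' @param out_dir optional output directory for the metrics CSV.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(n_phantoms = 3, master_seed = 1,
                              prescription_gyrbe = 48,
                              ports = c(20, 70, 110, 340),
                              single_port = 340,
                              n_rescans = c(1, 4, 8),
                              strategies = c("ungated", "gated"),
                              field_counts = c(1),
                              phantom_base = phantom_params(),
                              amplitude_ranges = list(lr = c(0.7, 2.5),
                                                      ap = c(1.0, 4.7),
                                                      si = c(0.8, 21.8)),
                              cycle_range_s = c(2.7, 5.5),
                              out_dir = NULL) {
  stopifnot(prescription_gyrbe > 0, all(n_rescans >= 1 & n_rescans <= 10),
            all(strategies %in% c("ungated", "gated")),
            all(field_counts %in% c(1, 4)), n_phantoms >= 1)
  structure(list(n_phantoms = as.integer(n_phantoms),
                 master_seed = as.integer(master_seed),
                 prescription_gyrbe = prescription_gyrbe, ports = ports,
                 single_port = single_port, n_rescans = as.integer(n_rescans),
                 strategies = strategies,
                 field_counts = as.integer(field_counts),
                 phantom_base = phantom_base,
                 amplitude_ranges = amplitude_ranges,
                 cycle_range_s = cycle_range_s, out_dir = out_dir),
            class = "experiment_config")
}

#' Serialize / parse an experiment configuration
#'
#' JSON round trip: `config_read(config_write(cfg, path))` reproduces
#' the configuration.
#'
#' @param cfg an [experiment_config()].
#' @param path file path.
#' @return `config_write` returns `path` invisibly; `config_read`
#'   returns the parsed `experiment_config`.
#' @export
config_write <- function(cfg, path) {
  x <- unclass(cfg)
  x$phantom_base <- unclass(x$phantom_base)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname config_write
#' @export
config_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pb <- x$phantom_base
  pb$densities <- as.list(pb$densities)
  x$phantom_base <- do.call(phantom_params, pb[names(pb) %in%
    names(formals(phantom_params))])
  # fields phantom_params() computes are restored from the file
  x$phantom_base[names(pb)] <- pb
  x$phantom_base <- structure(x$phantom_base, class = "phantom_params")
  cfg <- do.call(experiment_config, x[names(x) %in%
    names(formals(experiment_config))])
  cfg
}

#' Sample a phantom cohort
#'
#' Draws per-phantom motion amplitudes (uniform within the configured
#' per-axis ranges), breathing periods, and derived seeds, reproducibly
#' from the master seed.
#'
#' @param cfg an [experiment_config()].
#' @return data frame: phantom, seed, amp_lr, amp_ap, amp_si, cycle_s.
#' @export
sample_cohort <- function(cfg) {
  set.seed(cfg$master_seed)
  n <- cfg$n_phantoms
  data.frame(
    phantom = seq_len(n),
    seed = cfg$master_seed * 1000L + seq_len(n),
    amp_lr = runif(n, cfg$amplitude_ranges$lr[1], cfg$amplitude_ranges$lr[2]),
    amp_ap = runif(n, cfg$amplitude_ranges$ap[1], cfg$amplitude_ranges$ap[2]),
    amp_si = runif(n, cfg$amplitude_ranges$si[1], cfg$amplitude_ranges$si[2]),
    cycle_s = runif(n, cfg$cycle_range_s[1], cfg$cycle_range_s[2]))
}

cohort_phantom <- function(cfg, row) {
  pp <- cfg$phantom_base
  pp$amplitude_mm <- c(row$amp_lr, row$amp_ap, row$amp_si)
  pp$cycle_s <- row$cycle_s
  generate_phantom(pp, seed = row$seed)
}

#' Run the full experiment grid
#'
#' For every (phantom, strategy, field count): plan the fields, compute
#' the planning dose, and for every rescan number simulate the timed
#' delivery and accumulate the treatment dose; all metric rows are
#' collected in one table shaped like a clinical study summary.  A
#' failing cell is logged and skipped; the grid continues.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-cell progress.
#' @return data frame: one row per (phantom, strategy, n_fields,
#'   n_rescans) with dose metrics and delivery time; planning-dose rows
#'   carry `n_rescans = 0` and `time_s = NA`.  Written to
#'   `<out_dir>/metrics.csv` when `out_dir` is set.
#' @export
run_experiment <- function(cfg, verbose = interactive()) {
  cohort <- sample_cohort(cfg)
  rows <- list()
  for (ci in seq_len(nrow(cohort))) {
    phantom <- cohort_phantom(cfg, cohort[ci, ])
    ref_structs <- lapply(phantom$structures, `[[`, "T50")
    for (strategy in cfg$strategies) {
      for (nf in cfg$field_counts) {
        cell <- sprintf("phantom %d %s %d-field", ci, strategy, nf)
        res <- tryCatch({
          angles <- if (nf == 1) cfg$single_port else cfg$ports
          fields <- lapply(angles, function(a)
            plan_field(phantom, a, strategy, cfg$prescription_gyrbe / nf))
          pd <- plan_planning_dose(fields, phantom)
          out <- cbind(
            data.frame(phantom = ci, seed = cohort$seed[ci],
                       amp_si = cohort$amp_si[ci],
                       cycle_s = cohort$cycle_s[ci], strategy = strategy,
                       n_fields = nf, n_rescans = 0L),
            dose_metrics(pd, ref_structs, cfg$prescription_gyrbe),
            data.frame(time_s = NA_real_))
          for (n in cfg$n_rescans) {
            dcfg <- delivery_config(n, strategy, phantom$trace)
            td <- plan_treatment_dose(fields, phantom, dcfg)
            out <- rbind(out, cbind(
              data.frame(phantom = ci, seed = cohort$seed[ci],
                         amp_si = cohort$amp_si[ci],
                         cycle_s = cohort$cycle_s[ci], strategy = strategy,
                         n_fields = nf, n_rescans = n),
              dose_metrics(td$dose, ref_structs, cfg$prescription_gyrbe),
              data.frame(time_s = td$total_time_s)))
          }
          out
        }, error = function(e) {
          message(cell, " failed: ", conditionMessage(e))
          NULL
        })
        if (!is.null(res)) {
          rows[[length(rows) + 1L]] <- res
          if (verbose) message(cell, ": ", nrow(res), " rows")
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(out, file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
  }
  out
}
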