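# Config-driven orchestration: calibrate Windkessel outlets, run the 0D
# network, generate the coil series, couple packing density to a synthetic
# wall-shear field, and compute index maps -- one run directory per
# experiment with a machine-readable summary.
#
# The coupling between coil packing and the wall-shear field is a declared
# synthetic mapping (packing density -> planted low-TAWSS area fraction),
# visible in the config under `coupling`; it exercises the index stage end
# to end and is clearly labelled synthetic.

#' Default experiment configuration
#'
#' A complete, self-contained configuration mirroring a
#' pre/post + coil-length virtual experiment on synthetic anatomy. All
#' units SI except pressures, given in mmHg and converted at load.
#'
#' @param seed integer seed propagated to all stochastic stages.
#' @return nested list understood by [run_experiment()].
#' @export
default_config <- function(seed = 42L) {
  list(
    patient = list(systolic_mmHg = 117, diastolic_mmHg = 82,
                   capillary_pa = POUT_DEFAULT,
                   mean_inflow_m3s = 1e-4,
                   inflow = list(qmax = 4.2e-4, qmin = -0.3e-4)),
    outlets = list(template = "patient1_like", total_area = 8e-4),
    sac = list(shape = "sphere", dimensions = 0.02, resolution = 0.004),
    waveform = list(period = 0.84, n_samples = 84,
                    shape = "two_phase_pulse"),
    coils = list(
      list(total_length = 0.4, morphology = "planar2D"),
      list(total_length = 0.8, morphology = "planar2D"),
      list(total_length = 1.6, morphology = "planar2D")),
    coil_defaults = list(wire_diameter = 6e-4, loop_diameter = 1.8e-2),
    settings = list(time_step = 0.01, steps_per_cycle = 84, n_cycles = 4,
                    convergence_tolerance = 0.01),
    thresholds = list(tawss = 0.4, osi = 0.4, rrt = 10),
    coupling = list(kind = "synthetic_linear", base_low_fraction = 0.02,
                    low_fraction_per_density = 0.5,
                    pattern = "mixed", n_times = 33),
    seed = as.integer(seed))
}

#' Run the virtual-experiment pipeline
#'
#' Executes calibration, 0D simulation, coil generation and wall-index
#' analysis from a configuration, writing every stage's outputs and a
#' consolidated `summary.json` into `out_dir`. Deterministic under a fixed
#' config seed. Stage failures abort with the stage name; outputs written
#' before the failure are retained.
#'
#' @param config nested list as from [default_config()], or a path to a
#'   YAML file with the same structure.
#' @param out_dir run directory (created if missing).
#' @param seed optional override of the config seed.
#' @return the summary list, invisibly; side effect: files in `out_dir`.
#' @export
run_experiment <- function(config = default_config(), out_dir,
                           seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  summary <- list(seed = config$seed)

  # --- calibration -------------------------------------------------------
  cal <- stage("calibration", {
    pc <- config$patient
    ps <- mmHg_to_pa(pc$systolic_mmHg)
    pd <- mmHg_to_pa(pc$diastolic_mmHg)
    if (ps <= pd) stop("systolic pressure must exceed diastolic")
    inflow <- make_waveform("flow", pc$inflow$qmax, pc$inflow$qmin,
                            period = config$waveform$period,
                            n_samples = config$waveform$n_samples,
                            shape = config$waveform$shape)
    patient <- patient_hemodynamics(ps, pd, inflow,
                                    mean_inflow = pc$mean_inflow_m3s,
                                    capillary_pressure = pc$capillary_pa)
    outlets <- make_outlet_set(config$outlets$template,
                               config$outlets$total_area)
    params <- calibrate_windkessel(patient, outlets)
    write_params_csv(params, file.path(out_dir, "windkessel_params.csv"))
    rep <- attr(params, "report")
    jsonlite::write_json(rep, file.path(out_dir, "calibration_report.json"),
                         auto_unbox = TRUE, digits = NA)
    list(params = params, patient = patient, report = rep, ps = ps, pd = pd)
  })
  summary$calibration <- cal$report[c("Pm", "R_total", "C_T")]

  # --- 0D simulation -----------------------------------------------------
  sim <- stage("simulation", {
    inlet <- make_waveform("pressure", cal$ps, cal$pd,
                           period = config$waveform$period,
                           n_samples = config$waveform$n_samples,
                           shape = config$waveform$shape)
    st <- config$settings
    settings <- simulation_settings(time_step = st$time_step,
                                    steps_per_cycle = st$steps_per_cycle,
                                    n_cycles = st$n_cycles,
                                    convergence_tolerance =
                                      st$convergence_tolerance,
                                    pout = config$patient$capillary_pa)
    state <- simulate_network(inlet, cal$params, settings)
    write_traces_csv(state, file.path(out_dir, "traces.csv"))
    errs <- validate_pressures(state, cal$ps, cal$pd)
    conv <- list(cycles_to_convergence = state$cycles_to_convergence,
                 converged = state$converged,
                 pressure_error_systolic = unname(errs["systolic"]),
                 pressure_error_diastolic = unname(errs["diastolic"]))
    jsonlite::write_json(conv, file.path(out_dir, "convergence.json"),
                         auto_unbox = TRUE, digits = NA)
    c(conv, list(state = state))
  })
  summary$simulation <- sim[c("cycles_to_convergence", "converged",
                              "pressure_error_systolic",
                              "pressure_error_diastolic")]

  # --- sac + coils -------------------------------------------------------
  sacres <- stage("sac", {
    sc <- config$sac
    sac <- make_sac(sc$shape, unlist(sc$dimensions), sc$resolution)
    write_stl(sac$surface, file.path(out_dir, "sac.stl"), "sac")
    sac
  })
  coils <- stage("coils", {
    lapply(seq_along(config$coils), function(i) {
      cb <- utils::modifyList(config$coil_defaults, config$coils[[i]])
      spec <- coil_spec(cb$wire_diameter, cb$loop_diameter,
                        cb$total_length, cb$morphology,
                        seed = config$seed + i)
      cl <- generate_coil(spec, sacres)
      write_centerline_csv(cl, file.path(out_dir,
                                         sprintf("coil%d_centerline.csv", i)))
      tube <- sweep_tube(cl, spec$wire_diameter)
      write_stl(tube, file.path(out_dir, sprintf("coil%d_tube.stl", i)),
                sprintf("coil%d", i))
      chk <- check_constraints(cl, spec, sacres)
      jsonlite::write_json(
        list(arc_length = cl$arc_length,
             packing_density = packing_density(spec, sacres),
             min_self_clearance = chk$min_self_clearance,
             min_wall_margin = chk$min_wall_margin, pass = chk$pass),
        file.path(out_dir, sprintf("coil%d_constraints.json", i)),
        auto_unbox = TRUE, digits = NA)
      list(spec = spec, centerline = cl, check = chk)
    })
  })
  summary$coils <- lapply(coils, function(cl) {
    list(total_length = cl$spec$total_length,
         morphology = cl$spec$morphology,
         arc_length = cl$centerline$arc_length,
         packing_density = packing_density(cl$spec, sacres),
         constraints_pass = cl$check$pass)
  })

  # --- wall indices under the synthetic coupling -------------------------
  indices <- stage("wall_indices", {
    cp <- config$coupling
    th <- config$thresholds
    lapply(seq_along(coils), function(i) {
      dens <- packing_density(coils[[i]]$spec, sacres)
      lf <- min(1, cp$base_low_fraction +
                  cp$low_fraction_per_density * dens)
      field <- make_wss_field(sacres, pattern = cp$pattern,
                              low_area_fraction = lf,
                              period = config$waveform$period,
                              n_times = cp$n_times)
      maps <- wall_index_maps(field)
      rep <- threshold_report(maps, th$tawss, th$osi, th$rrt)
      write_index_csv(maps, file.path(out_dir,
                                      sprintf("coil%d_indices.csv", i)))
      out <- list(planted_low_fraction = lf,
                  low_tawss_fraction = rep$low_tawss$fraction,
                  high_osi_fraction = rep$high_osi$fraction,
                  high_rrt_fraction = rep$high_rrt$fraction)
      jsonlite::write_json(out,
                           file.path(out_dir,
                                     sprintf("coil%d_area_fractions.json", i)),
                           auto_unbox = TRUE, digits = NA)
      out
    })
  })
  summary$wall_indices <- indices

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Compare runs metric by metric
#'
#' Reads each run's `summary.json`, flattens it to named numeric metrics
#' and aligns them in a table with per-run columns and a `delta` column
#' (last minus first). Metrics missing from some run are kept and flagged
#' `NA`, never silently dropped; fully disjoint metric sets are an error.
#'
#' @param run_dirs two or more run directories.
#' @return data.frame with `metric`, one column per run, and `delta`.
#' @export
compare_runs <- function(run_dirs) {
  if (length(run_dirs) < 2) stop("need at least two runs to compare")
  flat <- lapply(run_dirs, function(d) {
    s <- jsonlite::read_json(file.path(d, "summary.json"),
                             simplifyVector = TRUE)
    u <- unlist(s)
    u[!is.na(suppressWarnings(as.numeric(u)))]
  })
  keys <- Reduce(union, lapply(flat, names))
  common <- Reduce(intersect, lapply(flat, names))
  if (length(common) == 0) stop("runs share no metrics")
  tab <- data.frame(metric = keys, stringsAsFactors = FALSE)
  for (i in seq_along(run_dirs)) {
    v <- as.numeric(flat[[i]][keys])
    tab[[paste0("run", i)]] <- v
  }
  tab$delta <- tab[[paste0("run", length(run_dirs))]] - tab$run1
  tab
}
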