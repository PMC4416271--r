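# Configuration, orchestration and tidy outputs.
#
# A simulation_config collects every knob of a run in one validated,
# serialisable structure; run_simulation() executes it and writes tidy
# CSV time series, a summary JSON and a log into an output directory.
# nasal_cycle_experiment() runs a congestion state and its mirror image to
# contrast the patent and congested airway roles across a cycle swap.

default_config <- function() {
  list(
    ambient = list(temperature = 23, relative_humidity = 0.45,
                   pressure = 101325),
    geometry = list(source = "synth", n_slices = 120,
                    slice_thickness = 0.78e-3, shape_params = list(),
                    jitter_sd = 0, path = NULL),
    # right side congested by default; 0.2 gives a ~2:1 resistance ratio and
    # a ~2/3 flow share on the patent side, the partitioning reported for a
    # typical mid-cycle subject
    congestion = list(left = 0, right = 0.2),
    waveform = list(shape = "sinusoid", tidal_volume = 500e-6,
                    breath_period = 5, table_path = NULL),
    wall = list(t_anterior = 32, t_posterior = 37),
    asl = list(pcl_span = 4, modulus_ratio = 2, water_fraction = 0.85,
               pcl_hydrated_height = 7.5, supply_max = 7.9,
               supply_unit = "g/cm2/hr", reabsorption_ratio = 3.5),
    solver = list(dt = 1e-3, n_cycles = 8, spin_up = 3,
                  record_stride = 0.05, max_substeps = 500),
    core_temperature = 37,
    seed = 1L
  )
}

#' Build a simulation configuration
#'
#' Starts from the package defaults and merges any overrides (nested lists,
#' merged per key). The default describes an adult breathing room air at
#' rest (23 degC, 45% RH; 500 mL tidal volume at 12 breaths/min) through a
#' synthetic geometry with the right side congested at 0.4.
#'
#' @param ... named overrides, e.g. `congestion = list(left = 0.3)`,
#'   `solver = list(dt = 2e-3)`
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(...) {
  overrides <- list(...)
  cfg <- default_config()
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) {
      stop(sprintf("unknown configuration section '%s'", nm), call. = FALSE)
    }
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(structure(cfg, class = "simulation_config"))
}

#' Read a simulation configuration from JSON
#'
#' The file holds any subset of the sections accepted by
#' [simulation_config()]; missing keys take the package defaults. The file
#' written to `config.json` by [run_simulation()] round-trips.
#'
#' @param path JSON file path
#' @return a `simulation_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(simulation_config, raw)
}

validate_config <- function(cfg) {
  # constructors carry the real invariants; build them once to fail early
  ambient_from_config(cfg)
  wall_model(cfg$wall$t_anterior, cfg$wall$t_posterior)
  do.call(asl_parameters, cfg$asl)
  stopifnot(cfg$solver$dt > 0, cfg$solver$n_cycles >= 1,
            cfg$solver$spin_up >= 0,
            cfg$solver$spin_up < cfg$solver$n_cycles,
            cfg$solver$record_stride > 0)
  for (cc in c(cfg$congestion$left, cfg$congestion$right)) {
    if (!is.finite(cc) || cc < 0 || cc >= 1) {
      stop("congestion fractions must lie in [0, 1)", call. = FALSE)
    }
  }
  if (!cfg$geometry$source %in% c("synth", "file")) {
    stop("geometry$source must be 'synth' or 'file'", call. = FALSE)
  }
  if (cfg$geometry$source == "file" && is.null(cfg$geometry$path)) {
    stop("geometry$source = 'file' needs geometry$path", call. = FALSE)
  }
  cfg
}

ambient_from_config <- function(cfg) {
  ambient_air(cfg$ambient$temperature, cfg$ambient$relative_humidity,
              cfg$ambient$pressure)
}

geometry_from_config <- function(cfg) {
  if (cfg$geometry$source == "synth") {
    synthesize_geometry(
      n_slices = cfg$geometry$n_slices,
      slice_thickness = cfg$geometry$slice_thickness,
      shape_params = cfg$geometry$shape_params,
      congestion_left = cfg$congestion$left,
      congestion_right = cfg$congestion$right,
      jitter_sd = cfg$geometry$jitter_sd
    )
  } else {
    apply_congestion(load_geometry(cfg$geometry$path),
                     cfg$congestion$left, cfg$congestion$right)
  }
}

#' Execute a configured simulation and write its outputs
#'
#' Runs the full pipeline deterministically for the configured seed:
#' geometry (synthetic or from CSV, with congestion applied), resistance
#' network and partitioning ratios, tidal waveform, multi-breath transport
#' solve, dehydration metrics. Writes into `out_dir`:
#' `config.json` (echo), `geometry.csv`, `results.csv`
#' (`side,k,x_over_l,time_s,t_air_c,c_air_kg_m3,he_um`), `asl.csv`
#' (`side,k,x_over_l,time_s,he_um,pcl_um,flag_dry`), `summary.json` and
#' `run.log`. The summary carries no timestamps, so reruns with the same
#' seed are byte-identical.
#'
#' @param config a [simulation_config()]
#' @param out_dir output directory (created if needed)
#' @param quiet suppress progress messages
#' @return invisibly, a list with the `nasal_sim` object, the summary list
#'   and the output paths
#' @export
run_simulation <- function(config = simulation_config(), out_dir = tempfile("nasalrun"),
                           quiet = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  set.seed(config$seed)
  ambient <- ambient_from_config(config)
  say("ambient: %.1f degC, RH %.0f%%, inlet AH %.1f g/m^3",
      ambient$temperature, 100 * ambient$relative_humidity,
      1000 * ambient_vapour_density(ambient))
  say("constants: g = %g m/s^2, R_vapour = %g J/(kg K), Nu = %g",
      GRAVITY, R_VAPOUR, NUSSELT_PLATES)

  geometry <- geometry_from_config(config)
  sa <- surface_area(geometry)
  say("geometry: %d slices/side, surface %.0f/%.0f cm^2, congestion %.2f/%.2f",
      nrow(geometry$left), 1e4 * sa[["left"]], 1e4 * sa[["right"]],
      config$congestion$left, config$congestion$right)

  part <- geometry_partition(geometry, ambient)
  say("resistance sums (m head / (kg/s)): left %.3g, right %.3g; PR %.3f/%.3f",
      part$resistance$sum_left, part$resistance$sum_right,
      part$ratios$pr_left, part$ratios$pr_right)

  rho_amb <- air_transport_properties(ambient$temperature, ambient$pressure)$density
  waveform <- tidal_waveform(
    tidal_volume = config$waveform$tidal_volume,
    breath_period = config$waveform$breath_period,
    shape = config$waveform$shape,
    table_path = config$waveform$table_path,
    air_density = rho_amb
  )
  wall <- wall_model(config$wall$t_anterior, config$wall$t_posterior)
  aslp <- do.call(asl_parameters, config$asl)

  sim <- run_breath_cycles(
    geometry, waveform, part$ratios, wall, ambient, aslp,
    n_cycles = config$solver$n_cycles, dt = config$solver$dt,
    spin_up = config$solver$spin_up,
    record_stride = config$solver$record_stride,
    core_temperature = config$core_temperature,
    max_substeps = config$solver$max_substeps
  )
  say("solve complete: max Re %.0f (laminar assumption %s), audit residual %.2e",
      max(sim$sides$left$diagnostics$max_reynolds,
          sim$sides$right$diagnostics$max_reynolds),
      if (max(sim$sides$left$diagnostics$max_reynolds,
              sim$sides$right$diagnostics$max_reynolds) <= 2000) "holds"
      else "EXCEEDED",
      water_audit_residual(sim))

  paths <- write_outputs(sim, config, aslp, part, out_dir)
  writeLines(log_lines, log_path)
  summary <- jsonlite::read_json(paths$summary)
  invisible(list(sim = sim, summary = summary, paths = c(paths, log = log_path),
                 out_dir = out_dir))
}

sim_tidy_frames <- function(sim, aslp) {
  rows <- function(side) {
    s <- sim$sides[[side]]
    n <- ncol(s$he)
    nt <- length(s$times)
    idx_t <- rep(seq_len(nt), each = n)
    idx_k <- rep(seq_len(n), times = nt)
    he <- as.vector(t(s$he))
    data.frame(
      side = side, k = idx_k, x_over_l = sim$xol[[side]][idx_k],
      time_s = s$times[idx_t],
      t_air_c = as.vector(t(s$t_air)),
      c_air_kg_m3 = as.vector(t(s$c_air)),
      he_um = he,
      pcl_um = aslp$pcl_hydrated_height - aslp$pcl_span * (1 - he / aslp$he_max),
      flag_dry = he <= 1e-12
    )
  }
  rbind(rows("left"), rows("right"))
}

side_summary <- function(s) {
  list(
    min_he_um = min(s$metrics$min_he),
    severely_dehydrated_anterior_fraction =
      s$metrics$severely_dehydrated_anterior_fraction,
    max_time_at_zero_s = max(s$metrics$time_at_zero),
    max_reynolds = s$diagnostics$max_reynolds,
    max_relative_audit_residual =
      max(vapply(s$cycle_audit, function(a) abs(a$relative_residual), 0)),
    dry_cap_events = sum(vapply(s$cycle_audit, function(a) a$dry_cap_events, 0)),
    overflow_kg = sum(vapply(s$cycle_audit, function(a) a$overflow, 0)),
    extrema = lapply(s$extrema, function(e) {
      list(t_air_c = e$t, c_air_kg_m3 = e$c, he_um = e$he)
    })
  )
}

write_outputs <- function(sim, config, aslp, part, out_dir) {
  tidy <- sim_tidy_frames(sim, aslp)
  results_path <- file.path(out_dir, "results.csv")
  asl_path <- file.path(out_dir, "asl.csv")
  utils::write.csv(
    tidy[, c("side", "k", "x_over_l", "time_s", "t_air_c", "c_air_kg_m3", "he_um")],
    results_path, row.names = FALSE, quote = FALSE
  )
  utils::write.csv(
    tidy[, c("side", "k", "x_over_l", "time_s", "he_um", "pcl_um", "flag_dry")],
    asl_path, row.names = FALSE, quote = FALSE
  )
  geom_path <- file.path(out_dir, "geometry.csv")
  write_geometry(sim$geometry, geom_path)
  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), config_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  ambient <- sim$ambient
  summary <- list(
    ambient = list(temperature_c = ambient$temperature,
                   relative_humidity = ambient$relative_humidity,
                   pressure_pa = ambient$pressure,
                   inlet_ah_g_m3 = 1000 * ambient_vapour_density(ambient)),
    congestion = config$congestion,
    partitioning = list(pr_left = sim$ratios$pr_left,
                        pr_right = sim$ratios$pr_right,
                        sum_r_left = part$resistance$sum_left,
                        sum_r_right = part$resistance$sum_right,
                        r_total = part$resistance$r_total),
    surface_area_cm2 = as.list(1e4 * surface_area(sim$geometry)),
    max_gap_mm = 1e3 * max(2 * sim$geometry$left$area_m2 / sim$geometry$left$perimeter_m,
                           2 * sim$geometry$right$area_m2 / sim$geometry$right$perimeter_m),
    asl_parameters = list(he_max_um = aslp$he_max,
                          supply_max = aslp$supply_max,
                          supply_unit = aslp$supply_unit,
                          reabsorption_max = aslp$reabsorption_max),
    sides = lapply(sim$sides, side_summary),
    settings = sim$settings
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(results = results_path, asl = asl_path, geometry = geom_path,
       config = config_path, summary = summary_path)
}

#' Nasal-cycle side-switch experiment
#'
#' Runs the configured congestion state and its mirror image (left/right
#' congestion swapped) and summarises how the dehydrating "air-conditioning"
#' role follows the patent side while the congested side rests. With a
#' symmetric congestion pair the experiment is degenerate and a warning is
#' raised.
#'
#' @param config a [simulation_config()]; the congestion pair defines state A
#' @param out_dir output directory; per-state outputs go to `state_a/`,
#'   `state_b/`, joint summary to `cycle_summary.json`
#' @param quiet suppress progress messages
#' @return invisibly, list with both run results and the joint summary
#' @export
nasal_cycle_experiment <- function(config = simulation_config(),
                                   out_dir = tempfile("nasalcycle"),
                                   quiet = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  cl <- config$congestion$left
  cr <- config$congestion$right
  if (isTRUE(all.equal(cl, cr))) {
    warning("symmetric congestion pair: the side-switch experiment is degenerate",
            call. = FALSE)
  }
  swapped <- config
  swapped$congestion <- list(left = cr, right = cl)
  run_a <- run_simulation(config, file.path(out_dir, "state_a"), quiet = quiet)
  run_b <- run_simulation(swapped, file.path(out_dir, "state_b"), quiet = quiet)

  state_view <- function(run, label) {
    pr <- c(left = run$sim$ratios$pr_left, right = run$sim$ratios$pr_right)
    patent <- names(which.max(pr))
    list(
      label = label,
      pr = as.list(pr),
      patent_side = patent,
      anterior_dehydrated_fraction = lapply(
        run$sim$sides, function(s) s$metrics$severely_dehydrated_anterior_fraction),
      min_he_um = lapply(run$sim$sides, function(s) min(s$metrics$min_he))
    )
  }
  va <- state_view(run_a, "a")
  vb <- state_view(run_b, "b")
  va$congestion <- list(left = cl, right = cr)
  vb$congestion <- list(left = cr, right = cl)
  joint <- list(
    state_a = va, state_b = vb,
    role_swap = list(
      # pure relabelling: state B's left should mirror state A's right
      max_metric_mismatch = max(
        abs(va$min_he_um$left - vb$min_he_um$right),
        abs(va$min_he_um$right - vb$min_he_um$left),
        abs(va$anterior_dehydrated_fraction$left - vb$anterior_dehydrated_fraction$right),
        abs(va$anterior_dehydrated_fraction$right - vb$anterior_dehydrated_fraction$left)
      ),
      patent_carries_majority = va$pr[[va$patent_side]] > 0.5 &&
        vb$pr[[vb$patent_side]] > 0.5
    )
  )
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  joint_path <- file.path(out_dir, "cycle_summary.json")
  jsonlite::write_json(joint, joint_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(state_a = run_a, state_b = run_b, summary = joint,
                 summary_path = joint_path))
}
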