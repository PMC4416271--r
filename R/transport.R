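# Transient heat and water-vapour transport along each passage.
#
# Per-side state: slice air temperature T_a(k) and vapour concentration
# C_a(k). Each outer time step performs, per slice, (i) upwind advection in
# the instantaneous flow direction, (ii) convective heat exchange with the
# prescribed wall temperature, (iii) evaporation/condensation against the
# ASL surface (saturated at the wall temperature), routed through the ASL
# water ledger, and (iv) a supersaturation clip that condenses any excess
# vapour onto the local ASL. Explicit forward-Euler with automatic
# sub-stepping keeps the advective Courant number and the exchange rates
# below one. Vapour advection is written in conservative (flux) form so the
# water audit closes to rounding.

#' Prescribed wall/ASL surface temperature profile
#'
#' Linear in normalized position X/L between an anterior (nasal valve) and
#' posterior (choanae) value, constant in time. The profile stands in for a
#' mucosal blood-temperature distribution; the anterior value is the main
#' tunable.
#'
#' @param t_anterior wall temperature at the nasal valve, degC (default 32)
#' @param t_posterior wall temperature at the choanae, degC (default core 37)
#' @return object of class `wall_model`
#' @export
wall_model <- function(t_anterior = 32, t_posterior = 37) {
  for (t in c(t_anterior, t_posterior)) {
    if (!is.finite(t) || t < 20 || t > 40) {
      stop("wall temperatures must lie in [20, 40] degC", call. = FALSE)
    }
  }
  structure(list(t_anterior = t_anterior, t_posterior = t_posterior),
            class = "wall_model")
}

#' Wall temperatures at normalized positions
#'
#' @param wall a [wall_model()]
#' @param xol normalized positions X/L in \[0, 1\]
#' @return wall temperature per position, degC
#' @export
wall_temperatures <- function(wall, xol) {
  stopifnot(inherits(wall, "wall_model"), all(xol >= 0), all(xol <= 1))
  wall$t_anterior + (wall$t_posterior - wall$t_anterior) * xol
}

NUSSELT_PLATES <- 7.54   # fully developed laminar, parallel plates, const wall T
LEVEQUE_PLATES <- 1.233  # local entrance-region coefficient, Nu_x = 1.233 Gz^(1/3)

#' Heat and mass transfer coefficients of a slice
#'
#' Laminar flow between closely spaced plates at constant wall temperature.
#' The fully developed limit is Nu = 7.54, h = Nu k / Dh. Because the
#' thermal entrance length of the nasal passages is comparable to their
#' whole length, a local thermally developing (Leveque/Graetz) term is
#' blended in whenever the mass flow and the distance from the inlet are
#' supplied: Nu_x = (7.54^3 + (1.233 Gz^(1/3))^3)^(1/3) with the local
#' Graetz number Gz = Re Pr Dh / x. This makes the coefficient increase
#' with flow, so the side carrying the larger flow share also does the
#' larger share of the transfer work. The mass transfer coefficient follows
#' from the Chilton-Colburn analogy, h_m = h / (rho c_p Le^(2/3)),
#' Le = alpha / D_v, so h_m / h is uniform at fixed properties.
#'
#' @param segment data.frame rows with `area_m2`, `perimeter_m` (vectorised)
#' @param air_props property record from [air_transport_properties()]
#' @param mass_flow air mass flow through the slice, kg/s; 0 (default)
#'   gives the fully developed limit
#' @param x distance from the flow inlet, m (required when `mass_flow` > 0)
#' @return list with `h` (W/(m^2 K)), `h_m` (m/s) and `nusselt`
#' @export
transfer_coefficients <- function(segment, air_props, mass_flow = 0, x = NULL) {
  dh <- hydraulic_diameter(segment$area_m2, segment$perimeter_m)
  nu <- NUSSELT_PLATES
  if (any(mass_flow != 0)) {
    if (is.null(x)) stop("x (distance from inlet) needed with mass_flow", call. = FALSE)
    stopifnot(all(x > 0))
    pr <- air_props$dynamic_viscosity * air_props$specific_heat /
      air_props$thermal_conductivity
    re <- 4 * abs(mass_flow) / (segment$perimeter_m * air_props$dynamic_viscosity)
    gz <- re * pr * dh / x
    nu <- (NUSSELT_PLATES^3 + LEVEQUE_PLATES^3 * gz)^(1 / 3)
  }
  h <- nu * air_props$thermal_conductivity / dh
  alpha <- air_props$thermal_conductivity /
    (air_props$density * air_props$specific_heat)
  le <- alpha / air_props$vapour_diffusivity
  h_m <- h / (air_props$density * air_props$specific_heat * le^(2 / 3))
  list(h = h, h_m = h_m, nusselt = nu)
}

# Precompute per-slice constants for one side. Air properties entering the
# exchange coefficients are evaluated at the local wall temperature (the
# film state changes them by a few percent at most over 23-37 degC).
make_side_model <- function(segments, xol, wall, ambient, asl_params,
                            core_temperature = 37, max_substeps = 500) {
  tw <- wall_temperatures(wall, xol)
  props <- air_transport_properties(tw, ambient$pressure)
  tc <- transfer_coefficients(segments, props)
  vol <- segments$area_m2 * segments$length_m
  surf <- segments$perimeter_m * segments$length_m
  # entrance-region factor: Nu^3 = Nu_fd^3 + ent3 * |mdot|, per flow direction
  pr <- props$dynamic_viscosity * props$specific_heat / props$thermal_conductivity
  dh <- hydraulic_diameter(segments$area_m2, segments$perimeter_m)
  total_l <- sum(segments$length_m)
  ent3_base <- LEVEQUE_PLATES^3 * 4 * pr * dh /
    (segments$perimeter_m * props$dynamic_viscosity)
  list(
    n = nrow(segments),
    area = segments$area_m2,
    perimeter = segments$perimeter_m,
    length = segments$length_m,
    vol = vol,
    surf = surf,
    tw = tw,
    csat_w = saturation_vapour_density(tw),
    coef_t = tc$h * surf / (props$density * props$specific_heat * vol),
    coef_c = tc$h_m * surf / vol,     # 1/s on the air concentration
    ent3_fwd = ent3_base / segments$x_m,              # inlet at the nares
    ent3_rev = ent3_base / (total_l - segments$x_m),  # inlet at the choanae
    s_over_v = surf / vol,
    v_over_s = vol / surf,
    inv_vol = 1 / vol,
    ambient = ambient,
    t_in = ambient$temperature,
    c_in = ambient_vapour_density(ambient),
    rho_in = air_transport_properties(ambient$temperature, ambient$pressure)$density,
    t_core = core_temperature,
    c_core = saturation_vapour_density(core_temperature),
    rho_core = air_transport_properties(core_temperature, ambient$pressure)$density,
    asl = asl_params,
    w_max = asl_params$he_max * 1e-6 * RHO_WATER,
    max_substeps = max_substeps,
    max_exchange_rate = max(tc$h * surf / (props$density * props$specific_heat * vol),
                            tc$h_m * surf / vol)
  )
}

# Fresh state: air at wall conditions, ASL fully hydrated.
initial_state <- function(model) {
  list(t_air = model$tw, c_air = model$csat_w,
       he = rep(model$asl$he_max, model$n))
}

empty_audit <- function() {
  list(vap_in = 0, vap_out = 0, supply = 0, reabsorption = 0, overflow = 0,
       delivered_abs = 0, dry_cap_events = 0, overhydration_events = 0)
}

#' Advance one side by one time step
#'
#' Explicit update of air temperature, vapour concentration and ASL ledger
#' for a single passage under the instantaneous signed mass flow (positive =
#' inhalation, anterior to posterior). Sub-steps internally so that the
#' advective Courant number and the exchange rates stay at or below one;
#' raises an error if more than `max_substeps` sub-steps would be required.
#'
#' @param model internal side model from `make_side_model()`
#' @param state list with `t_air`, `c_air` (kg/m^3), `he` (um)
#' @param mdot signed side mass flow, kg/s
#' @param dt outer time step, s
#' @param audit running audit accumulators (see `empty_audit()`)
#' @return list with updated `state` and `audit`
#' @keywords internal
transport_step <- function(model, state, mdot, dt, audit = empty_audit()) {
  q <- if (mdot > 0) mdot / model$rho_in else abs(mdot) / model$rho_core
  # thermally developing enhancement of the exchange coefficients
  ent3 <- if (mdot >= 0) model$ent3_fwd else model$ent3_rev
  enh <- (1 + ent3 * abs(mdot) / NUSSELT_PLATES^3)^(1 / 3)
  coef_t <- model$coef_t * enh
  coef_c <- model$coef_c * enh
  adv_rate <- if (abs(mdot) > 0) q * max(model$inv_vol) else 0
  n_sub <- ceiling(dt * max(adv_rate, max(coef_t), max(coef_c), 1e-9))
  if (n_sub > model$max_substeps) {
    stop(sprintf(
      "stability bound needs %d sub-steps (> limit %d); reduce dt or refine",
      n_sub, model$max_substeps
    ), call. = FALSE)
  }
  h <- dt / n_sub
  # wall exchange is integrated exactly within a sub-step (exponential
  # integrator): unconditionally stable and free of the forward-Euler rate
  # error; the exchange rates still bound n_sub to limit splitting error
  decay_t <- exp(-coef_t * h)
  decay_c <- exp(-coef_c * h)
  t_air <- state$t_air
  c_air <- state$c_air
  w <- state$he * 1e-6 * RHO_WATER  # ledger in kg/m^2
  n <- model$n
  par <- model$asl
  w_max <- model$w_max

  for (s in seq_len(n_sub)) {
    ## (i) upwind advection
    if (mdot > 0) {            # inhalation: ambient enters at the nares
      lam <- h * q * model$inv_vol
      audit$vap_in <- audit$vap_in + q * model$c_in * h
      audit$vap_out <- audit$vap_out + q * c_air[n] * h
      t_air <- t_air + lam * (c(model$t_in, t_air[-n]) - t_air)
      c_air <- c_air + lam * (c(model$c_in, c_air[-n]) - c_air)
    } else if (mdot < 0) {     # exhalation: core air enters at the choanae
      lam <- h * q * model$inv_vol
      audit$vap_in <- audit$vap_in + q * model$c_core * h
      audit$vap_out <- audit$vap_out + q * c_air[1] * h
      t_air <- t_air + lam * (c(t_air[-1], model$t_core) - t_air)
      c_air <- c_air + lam * (c(c_air[-1], model$c_core) - c_air)
    }

    ## (ii) convective heat exchange with the wall (exact relaxation)
    t_air <- model$tw + (t_air - model$tw) * decay_t

    ## (iii) vapour exchange with the ASL surface (saturated at wall temp):
    ## exact relaxation toward csat(T_w) defines the sub-step-average flux,
    ## which the ledger may then cap (dry surface)
    c_relaxed <- model$csat_w + (c_air - model$csat_w) * decay_c
    flux <- (c_relaxed - c_air) * model$v_over_s / h
    led <- asl_ledger_step(w, flux, h, par$supply_max_si,
                           par$reabsorption_max_si, w_max)
    w <- led$w
    c_air <- c_air + model$s_over_v * led$delivered * h
    audit$dry_cap_events <- audit$dry_cap_events + sum(led$dry_capped)
    audit$supply <- audit$supply + sum(led$supply * model$surf) * h
    audit$reabsorption <- audit$reabsorption + sum(led$reabsorption * model$surf) * h
    audit$overflow <- audit$overflow + sum(led$overflow * model$surf)
    audit$delivered_abs <- audit$delivered_abs + sum(abs(led$delivered) * model$surf) * h

    ## (iv) supersaturation clip: excess vapour condenses onto the ASL
    csat_a <- saturation_vapour_density(t_air)
    excess <- pmax(c_air - csat_a, 0)
    if (any(excess > 0)) {
      c_air <- c_air - excess
      w <- w + excess * model$v_over_s
      clip_over <- pmax(w - w_max, 0)
      w <- pmin(w, w_max)
      audit$overflow <- audit$overflow + sum(clip_over * model$surf)
      audit$overhydration_events <- audit$overhydration_events +
        sum(clip_over > 0)
    }
  }
  list(
    state = list(t_air = t_air, c_air = c_air, he = w / RHO_WATER * 1e6),
    audit = audit
  )
}

# water inventory of a side, kg (air vapour + ASL store)
side_water_mass <- function(model, state) {
  sum(state$c_air * model$vol) + sum(state$he * 1e-3 * model$surf)
}

simulate_side <- function(segments, xol, wall, ambient, asl_params, waveform,
                          pr, n_cycles, dt, spin_up, record_stride,
                          core_temperature = 37, max_substeps = 500) {
  model <- make_side_model(segments, xol, wall, ambient, asl_params,
                           core_temperature, max_substeps)
  state <- initial_state(model)
  period <- waveform$period
  steps_per_cycle <- round(period / dt)
  if (abs(steps_per_cycle * dt - period) > 1e-9 * period) {
    steps_per_cycle <- ceiling(period / dt)
  }
  n_steps <- steps_per_cycle * n_cycles
  stride_steps <- max(1L, round(record_stride / dt))
  n_rec <- length(seq(from = spin_up * steps_per_cycle + 1L, to = n_steps,
                      by = stride_steps))
  n <- model$n

  rec_t <- matrix(NA_real_, n_rec, n)
  rec_c <- matrix(NA_real_, n_rec, n)
  rec_he <- matrix(NA_real_, n_rec, n)
  rec_time <- numeric(n_rec)
  rec_phase <- character(n_rec)
  ri <- 0L

  min_he <- rep(Inf, n)
  hit_zero_inhale <- rep(FALSE, n)
  time_at_zero <- rep(0, n)
  extrema <- list(
    inhale = list(t = c(Inf, -Inf), c = c(Inf, -Inf), he = c(Inf, -Inf)),
    exhale = list(t = c(Inf, -Inf), c = c(Inf, -Inf), he = c(Inf, -Inf))
  )
  phase_snaps <- list()
  audit <- empty_audit()
  cycle_audit <- list()
  mass_prev <- side_water_mass(model, state)
  mu_amb <- air_transport_properties(ambient$temperature, ambient$pressure)$dynamic_viscosity
  max_re <- 0
  prev_phase <- NA_character_

  for (step in seq_len(n_steps)) {
    t0 <- (step - 1L) * dt
    mdot <- pr * waveform$fn(t0 + dt / 2)
    phase <- if (mdot > 0) "inhale" else if (mdot < 0) "exhale" else "pause"
    out <- transport_step(model, state, mdot, dt, audit)
    state <- out$state
    audit <- out$audit
    max_re <- max(max_re, 4 * abs(mdot) / (min(model$perimeter) * mu_amb))

    post_spin <- step > spin_up * steps_per_cycle
    if (post_spin) {
      min_he <- pmin(min_he, state$he)
      at_zero <- state$he <= 1e-12
      time_at_zero <- time_at_zero + at_zero * dt
      if (phase == "inhale") hit_zero_inhale <- hit_zero_inhale | at_zero
      if (phase %in% c("inhale", "exhale")) {
        ex <- extrema[[phase]]
        ex$t <- c(min(ex$t[1], min(state$t_air)), max(ex$t[2], max(state$t_air)))
        ex$c <- c(min(ex$c[1], min(state$c_air)), max(ex$c[2], max(state$c_air)))
        ex$he <- c(min(ex$he[1], min(state$he)), max(ex$he[2], max(state$he)))
        extrema[[phase]] <- ex
      }
      if ((step - spin_up * steps_per_cycle - 1L) %% stride_steps == 0L) {
        ri <- ri + 1L
        rec_time[ri] <- step * dt
        rec_phase[ri] <- phase
        rec_t[ri, ] <- state$t_air
        rec_c[ri, ] <- state$c_air
        rec_he[ri, ] <- state$he
      }
    }
    if (!identical(phase, prev_phase) && phase != "pause") {
      cyc <- ceiling(step / steps_per_cycle)
      phase_snaps[[length(phase_snaps) + 1L]] <- list(
        cycle = cyc, phase_entered = phase, time = t0,
        t_air = state$t_air, c_air = state$c_air, he = state$he
      )
      prev_phase <- phase
    }
    if (step %% steps_per_cycle == 0L) {
      mass_now <- side_water_mass(model, state)
      net_in <- audit$vap_in - audit$vap_out + audit$supply -
        audit$reabsorption - audit$overflow
      thru <- audit$vap_in + audit$vap_out + audit$supply +
        audit$reabsorption + audit$delivered_abs
      cycle_audit[[length(cycle_audit) + 1L]] <- list(
        cycle = step %/% steps_per_cycle,
        residual = (mass_now - mass_prev) - net_in,
        relative_residual = ((mass_now - mass_prev) - net_in) / max(thru, 1e-300),
        throughput = thru,
        overflow = audit$overflow,
        dry_cap_events = audit$dry_cap_events
      )
      mass_prev <- mass_now
      audit <- empty_audit()
    }
  }
  ri <- seq_len(ri)
  rows_used <- ri
  metrics <- dehydration_metrics(
    rec_he[rows_used, , drop = FALSE], xol,
    times = rec_time[rows_used],
    inhalation = rec_phase[rows_used] == "inhale"
  )
  # exact step-level tracking overrides the strided view
  metrics$min_he <- min_he
  metrics$time_at_zero <- time_at_zero
  run <- which(!hit_zero_inhale)
  edges <- c((xol[-n] + xol[-1]) / 2, 1)
  metrics$severely_dehydrated_anterior_fraction <-
    if (length(run) == 0L) 1 else if (run[1] == 1L) 0 else edges[run[1] - 1L]

  list(
    times = rec_time[rows_used],
    phase = rec_phase[rows_used],
    t_air = rec_t[rows_used, , drop = FALSE],
    c_air = rec_c[rows_used, , drop = FALSE],
    he = rec_he[rows_used, , drop = FALSE],
    final_state = state,
    metrics = metrics,
    extrema = extrema,
    phase_snapshots = phase_snaps,
    cycle_audit = cycle_audit,
    diagnostics = list(max_reynolds = max_re)
  )
}

#' Run a multi-breath two-airway simulation
#'
#' Simulates both passages over `n_cycles` tidal breaths. Each side carries
#' its partitioned share of the waveform; the two sides are otherwise
#' independent given the shared ambient, wall and ASL parameters. States are
#' recorded at `record_stride` intervals after `spin_up` discarded cycles;
#' per-segment hydration minima, dehydration metrics and the per-cycle water
#' audit are tracked at full step resolution throughout the recorded window.
#'
#' @param geometry a `nasal_geometry`
#' @param waveform a [tidal_waveform()]
#' @param ratios a [partition_ratios()]; defaults to the geometry's own
#'   partitioning at the ambient condition
#' @param wall a [wall_model()]
#' @param ambient an [ambient_air()]
#' @param asl_params an [asl_parameters()]
#' @param n_cycles breaths to simulate (default 8)
#' @param dt outer time step, s (default 1 ms; the solver sub-steps further
#'   whenever stability requires it)
#' @param spin_up cycles discarded before recording (default 3)
#' @param record_stride snapshot interval, s (default 0.05)
#' @param core_temperature nasopharyngeal core temperature, degC
#' @param max_substeps sub-step limit per outer step
#' @return object of class `nasal_sim`
#' @export
run_breath_cycles <- function(geometry, waveform, ratios = NULL,
                              wall = wall_model(), ambient = ambient_air(),
                              asl_params = asl_parameters(),
                              n_cycles = 8, dt = 1e-3, spin_up = 3,
                              record_stride = 0.05, core_temperature = 37,
                              max_substeps = 500) {
  stopifnot(inherits(geometry, "nasal_geometry"),
            inherits(waveform, "breath_waveform"),
            n_cycles >= 1, spin_up >= 0, spin_up < n_cycles, dt > 0)
  if (is.null(ratios)) {
    ratios <- geometry_partition(geometry, ambient)$ratios
  }
  stopifnot(inherits(ratios, "partition_ratios"))
  xol <- normalized_positions(geometry)
  sides <- list(
    left = simulate_side(geometry$left, xol$left, wall, ambient, asl_params,
                         waveform, ratios$pr_left, n_cycles, dt, spin_up,
                         record_stride, core_temperature, max_substeps),
    right = simulate_side(geometry$right, xol$right, wall, ambient, asl_params,
                          waveform, ratios$pr_right, n_cycles, dt, spin_up,
                          record_stride, core_temperature, max_substeps)
  )
  structure(
    list(
      sides = sides,
      xol = xol,
      ratios = ratios,
      geometry = geometry,
      ambient = ambient,
      wall = wall,
      asl_params = asl_params,
      settings = list(n_cycles = n_cycles, dt = dt, spin_up = spin_up,
                      record_stride = record_stride,
                      core_temperature = core_temperature,
                      tidal_volume = waveform$tidal_volume,
                      breath_period = waveform$period)
    ),
    class = "nasal_sim"
  )
}

#' @export
print.nasal_sim <- function(x, ...) {
  cat(sprintf(
    "Nasal air-conditioning run: %d cycles (dt %g s), PR left/right %.2f/%.2f\n",
    x$settings$n_cycles, x$settings$dt, x$ratios$pr_left, x$ratios$pr_right
  ))
  for (side in c("left", "right")) {
    m <- x$sides[[side]]$metrics
    cat(sprintf(
      "  %-5s min H_e %.2f um, severely dehydrated anterior fraction %.2f\n",
      side, min(m$min_he), m$severely_dehydrated_anterior_fraction
    ))
  }
  invisible(x)
}

#' Largest relative water-audit residual of a run
#'
#' @param sim a `nasal_sim`
#' @return max over sides and cycles of |residual| / cycle water throughput
#' @export
water_audit_residual <- function(sim) {
  stopifnot(inherits(sim, "nasal_sim"))
  max(vapply(sim$sides, function(s) {
    max(vapply(s$cycle_audit, function(a) abs(a$relative_residual), 0))
  }, 0))
}
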