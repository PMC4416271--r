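# Airway surface liquid (ASL) hydration ledger.
#
# The ASL is a binary liquid: the periciliary layer (PCL) under a mucus gel
# blanket. Its hydration state is tracked as a single water-equivalent
# height H_e: the water volume per unit area (expressed as a height) that
# can be removed from the fully hydrated ASL before mucociliary transport
# stops. Because the osmotic bulk modulus of the PCL is about twice that of
# the mucus, the mucus layer gives up twice the height of water over the
# full dehydration range (8 um vs 4 um, 12 um total); at 85% water volume
# fraction the removable water equals 10 um. H_e = 10 um is fully hydrated,
# H_e = 0 um is severe dehydration (clearance cessation).

RHO_WATER <- 1000  # kg/m^3

#' Convert an areal water flux to SI
#'
#' @param value flux magnitude
#' @param unit one of `"g/cm2/hr"`, `"mg/cm2/hr"`, `"kg/m2/s"`
#' @return flux in kg/(m^2 s)
#' @export
flux_to_si <- function(value, unit = c("g/cm2/hr", "mg/cm2/hr", "kg/m2/s")) {
  unit <- match.arg(unit)
  switch(unit,
    "g/cm2/hr" = value * 1e-3 / 1e-4 / 3600,
    "mg/cm2/hr" = value * 1e-6 / 1e-4 / 3600,
    "kg/m2/s" = value
  )
}

#' Layer spans and water-equivalent range of the ASL
#'
#' From the PCL height change over the full dehydration range and the
#' PCL:mucus osmotic bulk-modulus ratio, derives the mucus height change
#' (ratio times the PCL change), the total ASL height variation (their
#' sum) and the removable water-equivalent height (the water volume
#' fraction of the total, rounded to the nearest micrometre).
#'
#' @param pcl_span PCL height change over full dehydration, um (default 4)
#' @param modulus_ratio PCL:mucus osmotic bulk-modulus ratio (default 2)
#' @param water_fraction ASL water volume fraction (default 0.85)
#' @return list with `mucus_span`, `total_height_span`, `he_max`, um
#' @examples
#' derive_spans() # mucus 8 um, total 12 um, he_max 10 um
#' @export
derive_spans <- function(pcl_span = 4, modulus_ratio = 2, water_fraction = 0.85) {
  stopifnot(pcl_span > 0, modulus_ratio > 0,
            water_fraction > 0, water_fraction <= 1)
  mucus_span <- modulus_ratio * pcl_span
  total <- pcl_span + mucus_span
  list(
    mucus_span = mucus_span,
    total_height_span = total,
    he_max = round(water_fraction * total)
  )
}

#' ASL model parameters
#'
#' Bundles the layer-geometry constants with the mucosal supply and
#' epithelial reabsorption caps. The supply cap is carried as a
#' (value, unit) pair: the physiological estimate is printed in g/(cm^2 hr)
#' but its basis is uncertain (see the package vignette), so substituting
#' e.g. mg/(cm^2 hr) requires no code change. The reabsorption cap is the
#' supply cap divided by the reabsorption ratio.
#'
#' @param pcl_span,modulus_ratio,water_fraction see [derive_spans()]
#' @param pcl_hydrated_height fully hydrated PCL height, um (default 7.5,
#'   consistent with a 53% / 4 um collapse and the observed 7-10 um range)
#' @param supply_max maximal mucosal ASL supply flux, in `supply_unit`
#' @param supply_unit unit of `supply_max` (default `"g/cm2/hr"`, as printed)
#' @param reabsorption_ratio supply:reabsorption ratio (default 3.5)
#' @return object of class `asl_parameters`; fields `supply_max_si` and
#'   `reabsorption_max_si` hold the caps in kg/(m^2 s), `he_max` the
#'   hydrated water-equivalent height in um
#' @export
asl_parameters <- function(pcl_span = 4, modulus_ratio = 2,
                           water_fraction = 0.85,
                           pcl_hydrated_height = 7.5,
                           supply_max = 7.9, supply_unit = "g/cm2/hr",
                           reabsorption_ratio = 3.5) {
  spans <- derive_spans(pcl_span, modulus_ratio, water_fraction)
  stopifnot(pcl_hydrated_height > pcl_span, supply_max > 0,
            reabsorption_ratio > 0)
  structure(
    list(
      pcl_span = pcl_span,
      mucus_span = spans$mucus_span,
      total_height_span = spans$total_height_span,
      he_max = spans$he_max,
      pcl_hydrated_height = pcl_hydrated_height,
      water_fraction = water_fraction,
      modulus_ratio = modulus_ratio,
      supply_max = supply_max,
      supply_unit = supply_unit,
      reabsorption_ratio = reabsorption_ratio,
      reabsorption_max = supply_max / reabsorption_ratio,
      supply_max_si = flux_to_si(supply_max, supply_unit),
      reabsorption_max_si = flux_to_si(supply_max / reabsorption_ratio, supply_unit)
    ),
    class = "asl_parameters"
  )
}

#' @export
print.asl_parameters <- function(x, ...) {
  cat(sprintf(
    "ASL parameters: he_max %g um (PCL %g + mucus %g um spans), supply <= %g %s, reabsorption <= %g %s\n",
    x$he_max, x$pcl_span, x$mucus_span, x$supply_max, x$supply_unit,
    x$reabsorption_max, x$supply_unit
  ))
  invisible(x)
}

#' Layer heights at a given hydration state
#'
#' Linear interpolation between the fully hydrated and severely dehydrated
#' endpoint states: the PCL collapses from its hydrated height by
#' `pcl_span` and the mucus blanket thins by `mucus_span` as H_e falls
#' from `he_max` to 0.
#'
#' @param he water-equivalent height(s), um, in \[0, he_max\]
#' @param params an [asl_parameters()] object
#' @return list with `pcl_height` and `mucus_height_change`, um
#' @export
layer_heights <- function(he, params = asl_parameters()) {
  stopifnot(inherits(params, "asl_parameters"))
  if (any(!is.finite(he)) || any(he < 0) || any(he > params$he_max)) {
    stop(sprintf("he must lie in [0, %g] um", params$he_max), call. = FALSE)
  }
  depletion <- 1 - he / params$he_max
  list(
    pcl_height = params$pcl_hydrated_height - params$pcl_span * depletion,
    mucus_height_change = -params$mucus_span * depletion
  )
}

#' Advance the ASL water ledger one time step
#'
#' Demand-led bookkeeping, vectorised over segments. Positive
#' `evaporation_flux` is water leaving the ASL surface for the air; negative
#' values are condensation credits. Mucosal supply activates to meet the
#' evaporative demand plus any hydration deficit, capped at the supply
#' maximum. When the ledger would exceed `he_max` (condensation on an
#' already full ASL), epithelial reabsorption removes the excess up to its
#' cap; any remainder is clamped at `he_max` and reported as over-hydration
#' overflow. When the surface is dry, the flux actually delivered to the
#' air is limited to what supply can provide (dry-surface cap, flagged).
#'
#' @param he water-equivalent height(s), um
#' @param evaporation_flux water flux to air, kg/(m^2 s); negative =
#'   condensation
#' @param dt time step, s
#' @param params an [asl_parameters()] object
#' @return list: `he` (updated, um), `delivered_flux` (flux actually
#'   exchanged with the air, kg/(m^2 s)), `supply_flux`,
#'   `reabsorption_flux`, `overflow_flux` (same units), and logical flags
#'   `dry_capped`, `overhydrated`. The balance
#'   delivered + d(store)/dt - supply + reabsorption + overflow = 0
#'   holds to rounding.
#' @export
update_asl <- function(he, evaporation_flux, dt, params = asl_parameters()) {
  stopifnot(inherits(params, "asl_parameters"), dt > 0)
  if (any(!is.finite(he)) || any(he < 0) || any(he > params$he_max * (1 + 1e-9))) {
    stop(sprintf("he must lie in [0, %g] um", params$he_max), call. = FALSE)
  }
  w <- he * 1e-6 * RHO_WATER          # stored water, kg/m^2
  w_max <- params$he_max * 1e-6 * RHO_WATER
  core <- asl_ledger_step(w, evaporation_flux, dt,
                          params$supply_max_si, params$reabsorption_max_si,
                          w_max)
  list(
    he = core$w / RHO_WATER * 1e6,
    delivered_flux = core$delivered,
    supply_flux = core$supply,
    reabsorption_flux = core$reabsorption,
    overflow_flux = core$overflow / dt,
    dry_capped = core$dry_capped,
    overhydrated = core$overflow > 0
  )
}

# Ledger core in SI mass-per-area units, shared by update_asl() and the
# transport solver. `flux` > 0 evaporates, < 0 condenses; `overflow` is
# returned as mass per area lost to the hard clamp this step.
asl_ledger_step <- function(w, flux, dt, supply_max, reabs_max, w_max) {
  deficit <- pmax(w_max - w, 0)
  evap <- pmax(flux, 0)
  cond <- flux - evap                         # <= 0
  supply <- pmin(evap + pmax(deficit / dt + cond, 0), supply_max)
  delivered <- pmin(flux, w / dt + supply)    # dry-surface cap
  w_new <- w + (supply - delivered) * dt
  over <- pmax(w_new - w_max, 0)
  reabs <- pmin(over / dt, reabs_max)
  w_new <- w_new - reabs * dt
  overflow <- pmax(w_new - w_max, 0)
  w_new <- pmin(pmax(w_new, 0), w_max)
  list(w = w_new, delivered = delivered, supply = supply,
       reabsorption = reabs, overflow = overflow,
       dry_capped = delivered < flux)
}

#' Dehydration metrics over a hydration history
#'
#' Summarises a per-segment H_e time history: the minimum height each
#' segment reached, the time each spent severely dehydrated (H_e = 0), and
#' the severely dehydrated anterior fraction: the largest X/L such that
#' every segment anterior to it reached H_e = 0 at some instant of the
#' inhalation phase.
#'
#' @param he_history numeric matrix, time steps x segments, um
#' @param positions per-segment X/L midpoints, increasing in \[0, 1\]
#' @param times optional time stamps (rows); used for dwell times
#' @param inhalation optional logical mask over rows marking the
#'   inhalation phase (default: all rows)
#' @return list with `min_he` (per segment),
#'   `severely_dehydrated_anterior_fraction` and `time_at_zero` (s per
#'   segment; counts full steps spent at zero)
#' @export
dehydration_metrics <- function(he_history, positions, times = NULL,
                                inhalation = NULL) {
  he_history <- as.matrix(he_history)
  if (nrow(he_history) == 0L) stop("empty hydration history", call. = FALSE)
  stopifnot(ncol(he_history) == length(positions),
            !is.unsorted(positions))
  if (is.null(inhalation)) inhalation <- rep(TRUE, nrow(he_history))
  n <- length(positions)
  zero_tol <- 1e-12
  min_he <- apply(he_history, 2, min)
  inh <- he_history[inhalation, , drop = FALSE]
  hit_zero <- if (nrow(inh)) apply(inh, 2, min) <= zero_tol else rep(FALSE, n)
  # upper slice edges from midpoints (last edge = 1)
  edges <- c((positions[-n] + positions[-1]) / 2, 1)[seq_len(n)]
  if (n == 1L) edges <- 1
  run <- which(!hit_zero)
  fraction <- if (length(run) == 0L) 1 else if (run[1] == 1L) 0 else edges[run[1] - 1L]
  dt_row <- if (!is.null(times) && length(times) > 1) {
    stats::median(diff(times))
  } else 1
  time_at_zero <- colSums(he_history <= zero_tol) * dt_row
  list(
    min_he = min_he,
    severely_dehydrated_anterior_fraction = fraction,
    time_at_zero = time_at_zero
  )
}
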