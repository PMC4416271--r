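# Laminar resistance network and tidal airflow partitioning.
#
# Each slice behaves as a short run of closely spaced parallel plates, for
# which the Darcy friction factor is f = 24/Re. Composing the friction
# factor with the Darcy-Weisbach head loss and dividing by the mass flow
# gives a flow-independent specific resistance per slice,
#   R(k) = 3 mu P(k)^2 l / (4 rho^2 A(k)^3 g),
# in metres of head per unit mass flow. Side resistances add in series;
# the two passages combine in parallel, and each side's share of the tidal
# flow is PR_side = R_total / sum(R_side).

GRAVITY <- 9.81  # m/s^2

#' Slice Reynolds number from mass flow
#'
#' Re = 4 mdot / (P mu), equivalent to rho V Dh / mu with V = mdot/(rho A)
#' and Dh = 4A/P. The magnitude of the flow is used, so the same value
#' applies during exhalation.
#'
#' @param mass_flow air mass flow through the slice, kg/s
#' @param segment one-row data.frame (or list) with `perimeter_m`
#' @param viscosity dynamic viscosity of air, Pa s
#' @return Reynolds number (dimensionless)
#' @export
reynolds_number <- function(mass_flow, segment, viscosity) {
  stopifnot(all(viscosity > 0), all(segment$perimeter_m > 0))
  4 * abs(mass_flow) / (segment$perimeter_m * viscosity)
}

#' Parallel-plate laminar friction factor
#'
#' f = 24 / Re. The model assumes laminar flow throughout the nose; if Re
#' exceeds `laminar_threshold` a warning is raised (once per call) since the
#' correlation is then outside its regime.
#'
#' @param re Reynolds number(s), > 0
#' @param laminar_threshold laminar-regime ceiling (default 2000)
#' @param warn emit the out-of-regime warning (solvers pass `FALSE` and
#'   track max Re as a diagnostic instead)
#' @return Darcy friction factor
#' @export
friction_factor <- function(re, laminar_threshold = 2000, warn = TRUE) {
  if (any(!is.finite(re)) || any(re <= 0)) {
    stop("Reynolds number must be positive", call. = FALSE)
  }
  if (warn && any(re > laminar_threshold)) {
    warning(sprintf(
      "Re = %.0f exceeds the laminar threshold (%g); f = 24/Re assumes laminar flow",
      max(re), laminar_threshold
    ), call. = FALSE)
  }
  24 / re
}

#' Darcy-Weisbach head loss
#'
#' h_f = f l V^2 / (2 g Dh), in metres of head.
#'
#' @param f Darcy friction factor
#' @param l duct length, m
#' @param velocity mean velocity V, m/s
#' @param dh hydraulic diameter, m
#' @return head loss, m
#' @export
head_loss <- function(f, l, velocity, dh) {
  if (any(l <= 0) || any(dh <= 0)) {
    stop("duct length and hydraulic diameter must be positive", call. = FALSE)
  }
  f * l * velocity^2 / (2 * GRAVITY * dh)
}

#' Specific laminar flow resistance of a slice
#'
#' Head loss per unit mass flow, R = 3 mu P^2 l / (4 rho^2 A^3 g). Because
#' the flow is laminar this is independent of the flow rate, which is what
#' makes the breath-long partitioning ratios constants.
#'
#' @param segment data.frame rows (or list) with `area_m2`, `perimeter_m`,
#'   `length_m`
#' @param viscosity dynamic viscosity, Pa s
#' @param density air density, kg/m^3
#' @return resistance in m of head per (kg/s), vectorised over rows
#' @export
specific_resistance <- function(segment, viscosity, density) {
  stopifnot(all(segment$area_m2 > 0), all(segment$perimeter_m > 0),
            all(segment$length_m > 0), viscosity > 0, density > 0)
  3 * viscosity * segment$perimeter_m^2 * segment$length_m /
    (4 * density^2 * segment$area_m2^3 * GRAVITY)
}

#' Series and parallel resistance of the two passages
#'
#' @param r_left,r_right per-slice resistances of each side
#' @return list with `sum_left`, `sum_right` (series sums) and `r_total`
#'   (parallel combination), satisfying r_total < min(sum_left, sum_right)
#' @export
total_resistance <- function(r_left, r_right) {
  if (length(r_left) == 0L || length(r_right) == 0L) {
    stop("both sides need at least one resistance value", call. = FALSE)
  }
  stopifnot(all(r_left > 0), all(r_right > 0))
  sum_left <- sum(r_left)
  sum_right <- sum(r_right)
  list(
    sum_left = sum_left,
    sum_right = sum_right,
    r_total = 1 / (1 / sum_left + 1 / sum_right)
  )
}

#' Inter-nasal airflow partitioning ratios
#'
#' PR_side = R_total / sum(R_side) from the parallel-network analysis; the
#' two ratios sum to one algebraically and the lower-resistance (patent)
#' side carries the larger share.
#'
#' @param sum_left,sum_right series resistance sums of each side
#' @return object of class `partition_ratios` with `pr_left`, `pr_right`
#' @examples
#' partition_ratios(2, 4) # patent left side carries 2/3 of the flow
#' @export
partition_ratios <- function(sum_left, sum_right) {
  stopifnot(sum_left > 0, sum_right > 0)
  r_total <- 1 / (1 / sum_left + 1 / sum_right)
  structure(
    list(pr_left = r_total / sum_left, pr_right = r_total / sum_right),
    class = "partition_ratios"
  )
}

#' @export
print.partition_ratios <- function(x, ...) {
  cat(sprintf("Flow partitioning: left %.1f%% / right %.1f%%\n",
              100 * x$pr_left, 100 * x$pr_right))
  invisible(x)
}

#' Partitioning ratios for a geometry
#'
#' Convenience wrapper: per-slice resistances from [specific_resistance()]
#' at the ambient air properties, summed per side and combined.
#'
#' @param geometry a `nasal_geometry`
#' @param ambient an [ambient_air()] condition (air properties evaluated at
#'   the inhaled-air state)
#' @return list with `ratios` (a `partition_ratios`), `resistance` (the
#'   [total_resistance()] record) and `per_slice` resistances
#' @export
geometry_partition <- function(geometry, ambient = ambient_air()) {
  stopifnot(inherits(geometry, "nasal_geometry"))
  props <- air_transport_properties(ambient$temperature, ambient$pressure)
  r_l <- specific_resistance(geometry$left, props$dynamic_viscosity, props$density)
  r_r <- specific_resistance(geometry$right, props$dynamic_viscosity, props$density)
  res <- total_resistance(r_l, r_r)
  list(
    ratios = partition_ratios(res$sum_left, res$sum_right),
    resistance = res,
    per_slice = list(left = r_l, right = r_r)
  )
}

#' Tidal breathing waveform
#'
#' Either an analytic sinusoid, mdot(t) = (pi Vt rho / Tp) sin(2 pi t / Tp)
#' (positive = inhalation; the inhaled-phase volume integral equals the
#' tidal volume), or a measured trace read from a CSV with columns
#' `time_s,mass_flow_kg_s` spanning one period. Table traces whose inhaled
#' and exhaled volumes differ by more than 1% are rejected.
#'
#' @param tidal_volume tidal volume, m^3 (default 500 mL)
#' @param breath_period breath period, s (default 5 s, 12 breaths/min)
#' @param shape `"sinusoid"` or `"table"`
#' @param table_path CSV path for `shape = "table"`
#' @param air_density density used to convert volume to mass flow, kg/m^3
#' @param n_samples number of samples stored in the `times`/`mass_flow`
#'   record (the sinusoid is also available in closed form via `$fn`)
#' @return object of class `breath_waveform` with fields `fn` (mass flow at
#'   arbitrary time, periodic), `times`, `mass_flow`, `period`,
#'   `tidal_volume`
#' @export
tidal_waveform <- function(tidal_volume = 500e-6, breath_period = 5,
                           shape = c("sinusoid", "table"),
                           table_path = NULL, air_density = 1.19,
                           n_samples = 501) {
  shape <- match.arg(shape)
  stopifnot(tidal_volume > 0, breath_period > 0, air_density > 0)
  if (shape == "sinusoid") {
    peak <- pi * tidal_volume * air_density / breath_period
    fn <- function(t) peak * sin(2 * pi * (t %% breath_period) / breath_period)
    times <- seq(0, breath_period, length.out = n_samples)
    wf <- list(fn = fn, times = times, mass_flow = fn(times),
               period = breath_period, tidal_volume = tidal_volume,
               air_density = air_density, shape = shape)
  } else {
    if (is.null(table_path)) stop("table shape needs table_path", call. = FALSE)
    tab <- utils::read.csv(table_path, stringsAsFactors = FALSE)
    if (!all(c("time_s", "mass_flow_kg_s") %in% names(tab))) {
      stop("waveform CSV needs columns time_s,mass_flow_kg_s", call. = FALSE)
    }
    if (is.unsorted(tab$time_s, strictly = TRUE)) {
      stop("waveform CSV times must be strictly increasing", call. = FALSE)
    }
    period <- max(tab$time_s) - min(tab$time_s)
    t0 <- min(tab$time_s)
    q <- tab$mass_flow_kg_s / air_density
    vol_in <- trapz(tab$time_s, pmax(q, 0))
    vol_ex <- trapz(tab$time_s, pmax(-q, 0))
    if (abs(vol_in - vol_ex) > 0.01 * max(vol_in, vol_ex)) {
      stop(sprintf(
        "waveform trace volume imbalance %.1f%% exceeds 1%%: inhaled %.1f mL, exhaled %.1f mL",
        100 * abs(vol_in - vol_ex) / max(vol_in, vol_ex),
        1e6 * vol_in, 1e6 * vol_ex
      ), call. = FALSE)
    }
    base_fn <- stats::approxfun(tab$time_s, tab$mass_flow_kg_s, rule = 2)
    fn <- function(t) base_fn(t0 + (t %% period))
    wf <- list(fn = fn, times = tab$time_s - t0, mass_flow = tab$mass_flow_kg_s,
               period = period, tidal_volume = vol_in,
               air_density = air_density, shape = shape)
  }
  structure(wf, class = "breath_waveform")
}

# trapezoidal quadrature
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)

#' Apportion a tidal waveform between the two passages
#'
#' Each side carries the instantaneous total flow scaled by its constant
#' partitioning ratio; the two sides sum to the input trace exactly.
#'
#' @param waveform a [tidal_waveform()]
#' @param ratios a [partition_ratios()]
#' @param times evaluation times (default the waveform's stored samples)
#' @return data.frame with `time_s`, `total`, `left`, `right` mass flows, kg/s
#' @export
apportion_flow <- function(waveform, ratios, times = waveform$times) {
  stopifnot(inherits(waveform, "breath_waveform"),
            inherits(ratios, "partition_ratios"))
  total <- waveform$fn(times)
  data.frame(time_s = times, total = total,
             left = total * ratios$pr_left,
             right = total * ratios$pr_right)
}
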