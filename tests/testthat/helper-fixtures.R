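# Shared fixtures. Simulations are scaled down from the default run
# (fewer, thicker slices; fewer cycles; coarser dt) so the whole suite
# stays fast; the full-resolution run is exercised in test-acceptance.R.

scaled_geometry <- function(n = 24, congestion_left = 0, congestion_right = 0.2,
                            ...) {
  synthesize_geometry(
    n_slices = n, slice_thickness = 9.4e-2 / n,
    congestion_left = congestion_left, congestion_right = congestion_right,
    ...
  )
}

scaled_waveform <- function(period = 4) {
  rho <- air_transport_properties(23)$density
  tidal_waveform(tidal_volume = 500e-6, breath_period = period,
                 air_density = rho)
}

# "demonstration world": identical to the defaults except the supply cap is
# read in mg/cm2/hr, the substitution under which ASL dehydration dynamics
# are visible (see the methods vignette / README)
demo_asl <- function() asl_parameters(supply_unit = "mg/cm2/hr")

scaled_sim <- function(n = 24, congestion = c(0, 0.2), asl = demo_asl(),
                       n_cycles = 5, dt = 2e-3, spin_up = 2, period = 4,
                       record_stride = 0.1, ...) {
  run_breath_cycles(
    scaled_geometry(n, congestion[1], congestion[2]),
    scaled_waveform(period),
    asl_params = asl, n_cycles = n_cycles, dt = dt, spin_up = spin_up,
    record_stride = record_stride, ...
  )
}

# computed once per test run, reused across files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

demo_sim <- function() cached("demo_sim", scaled_sim())

scaled_config <- function(...) {
  simulation_config(
    geometry = list(n_slices = 16, slice_thickness = 9.4e-2 / 16),
    waveform = list(breath_period = 4),
    solver = list(dt = 2e-3, n_cycles = 3, spin_up = 1, record_stride = 0.2),
    ...
  )
}

random_segment <- function() {
  area <- runif(1, 3e-5, 3e-4)
  # perimeter well above the isoperimetric bound: narrow slit shapes
  perimeter <- runif(1, 3, 10) * sqrt(4 * pi * area)
  data.frame(k = 1L, x_m = runif(1, 1e-3, 0.09),
             length_m = runif(1, 5e-4, 5e-3),
             area_m2 = area, perimeter_m = perimeter)
}
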