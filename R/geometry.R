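# Segmented two-passage nasal geometry.
#
# Each passage is a series of coronal "lumps": slabs of thickness l with
# slab-averaged cross-sectional area A(k) and perimeter P(k), ordered
# anterior (nasal valve) to posterior (choanae). The local hydraulic
# diameter Dh = 4A/P is the characteristic length for the laminar duct
# correlations. Cross-sections are narrow folded slits, so the effective
# airway gap (~2A/P for a wide slit) stays below ~3 mm.

GEOMETRY_CSV_COLUMNS <- c("side", "k", "x_m", "length_m", "area_m2", "perimeter_m")

#' Hydraulic diameter of a duct cross-section
#'
#' The standard convention Dh = 4 A / P. For a circle this returns the
#' diameter; for wide parallel plates of gap b it tends to 2 b.
#'
#' @param area cross-sectional area, m^2
#' @param perimeter wetted perimeter, m
#' @return hydraulic diameter, m
#' @export
hydraulic_diameter <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(area <= 0) ||
      any(!is.finite(perimeter)) || any(perimeter <= 0)) {
    stop("area and perimeter must be positive and finite", call. = FALSE)
  }
  4 * area / perimeter
}

# smooth C1 interpolant on [0,1]
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

validate_segments <- function(df, side = "?") {
  required <- c("k", "x_m", "length_m", "area_m2", "perimeter_m")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("geometry side '%s' missing columns: %s", side,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$area_m2) | df$area_m2 <= 0 |
                 !is.finite(df$perimeter_m) | df$perimeter_m <= 0 |
                 !is.finite(df$length_m) | df$length_m <= 0)
  if (length(bad)) {
    stop(sprintf("geometry side '%s': segment k=%d violates A>0, P>0, l>0",
                 side, df$k[bad[1]]), call. = FALSE)
  }
  # isoperimetric bound: no closed curve encloses more area than a circle
  iso <- which(df$perimeter_m^2 < 4 * pi * df$area_m2 * (1 - 1e-12))
  if (length(iso)) {
    stop(sprintf("geometry side '%s': segment k=%d violates P^2 >= 4*pi*A",
                 side, df$k[iso[1]]), call. = FALSE)
  }
  if (is.unsorted(df$x_m, strictly = TRUE)) {
    stop(sprintf("geometry side '%s': segments must be ordered anterior to posterior",
                 side), call. = FALSE)
  }
  df$dh_m <- hydraulic_diameter(df$area_m2, df$perimeter_m)
  df
}

new_nasal_geometry <- function(left, right, slice_thickness) {
  structure(
    list(
      left = validate_segments(left, "left"),
      right = validate_segments(right, "right"),
      slice_thickness = slice_thickness
    ),
    class = "nasal_geometry"
  )
}

#' Synthesize a two-passage nasal geometry
#'
#' Builds a smooth stand-in for an MRI-derived airway profile. Each coronal
#' cross-section is modelled as a folded slit of developed width w and gap b
#' (A = w b, P = 2 (w + b)): narrow at the nasal valve, widest over the
#' turbinate region, tapering toward the choanae. Defaults give a passage of
#' about 9.4 cm with a one-side mucosal surface area near 100 cm^2 and an
#' effective gap nowhere above 3 mm.
#'
#' Vascular congestion of a side is modelled as mucosal engorgement that
#' narrows the gap: the area of every slice is scaled by (1 - c) with the
#' perimeter held, which leaves wall surface available for exchange while
#' raising the side's flow resistance steeply (R scales with A^-3).
#'
#' @param n_slices number of coronal slices per side (>= 2)
#' @param slice_thickness slab thickness, m (default 0.78 mm, typical MRI)
#' @param shape_params list with `width_valve`, `width_peak`, `width_choana`
#'   (developed slit widths, m), `peak_position` (X/L of the widest section),
#'   `gap_base` and `gap_amplitude` (airway gap profile, m)
#' @param congestion_left,congestion_right congestion fraction in \[0, 1)
#' @param jitter_sd multiplicative smooth jitter SD on the width profile
#'   (both sides jittered independently; uses the current RNG state)
#' @return a `nasal_geometry`; attribute `max_gap_m` reports the largest
#'   effective gap (2A/P) as a diagnostic of the narrow-slit assumption
#' @export
synthesize_geometry <- function(n_slices = 120,
                                slice_thickness = 0.78e-3,
                                shape_params = list(),
                                congestion_left = 0,
                                congestion_right = 0,
                                jitter_sd = 0) {
  if (!is.numeric(n_slices) || n_slices < 2) {
    stop("n_slices must be at least 2", call. = FALSE)
  }
  stopifnot(slice_thickness > 0, jitter_sd >= 0)
  for (cc in c(congestion_left, congestion_right)) {
    if (!is.finite(cc) || cc < 0 || cc >= 1) {
      stop("congestion fractions must lie in [0, 1)", call. = FALSE)
    }
  }
  sp <- utils::modifyList(list(
    width_valve = 0.015,   # m, developed width at the nasal valve
    width_peak = 0.070,    # m, widest (turbinate) section
    width_choana = 0.040,  # m, at the choanae
    peak_position = 0.35,  # X/L of the widest section
    gap_base = 2.5e-3,     # m, airway gap profile
    gap_amplitude = 0.3e-3
  ), shape_params)
  with(sp, {
    ok <- all(is.finite(c(width_valve, width_peak, width_choana,
                          peak_position, gap_base, gap_amplitude))) &&
      width_valve > 0 && width_peak > 0 && width_choana > 0 &&
      peak_position > 0 && peak_position < 1 &&
      gap_base > 0 && gap_base + abs(gap_amplitude) <= 3.2e-3
    if (!ok) stop("shape_params produce non-physical sections", call. = FALSE)
  })

  n <- as.integer(n_slices)
  l <- slice_thickness
  x_mid <- (seq_len(n) - 0.5) * l
  xi <- x_mid / (n * l)

  width_profile <- function(jitter) {
    w <- ifelse(
      xi <= sp$peak_position,
      sp$width_valve + (sp$width_peak - sp$width_valve) *
        smoothstep(xi / sp$peak_position),
      sp$width_peak + (sp$width_choana - sp$width_peak) *
        smoothstep((xi - sp$peak_position) / (1 - sp$peak_position))
    )
    w * jitter
  }
  smooth_jitter <- function() {
    if (jitter_sd <= 0) return(rep(1, n))
    # low-order Fourier perturbation: smooth along the passage
    ph <- stats::runif(3, 0, 2 * pi)
    am <- stats::rnorm(3, 0, jitter_sd / sqrt(3))
    j <- 1 + am[1] * sin(pi * xi + ph[1]) +
      am[2] * sin(2 * pi * xi + ph[2]) + am[3] * sin(3 * pi * xi + ph[3])
    pmax(j, 0.2)
  }
  gap <- sp$gap_base + sp$gap_amplitude * sin(pi * xi)

  make_side <- function(congestion) {
    w <- width_profile(smooth_jitter())
    area <- w * gap * (1 - congestion)   # engorgement narrows the gap
    perim <- 2 * (w + gap)               # wall length unchanged
    data.frame(
      k = seq_len(n), x_m = x_mid, length_m = l,
      area_m2 = area, perimeter_m = perim
    )
  }
  geom <- new_nasal_geometry(
    left = make_side(congestion_left),
    right = make_side(congestion_right),
    slice_thickness = l
  )
  attr(geom, "max_gap_m") <- max(
    2 * geom$left$area_m2 / geom$left$perimeter_m,
    2 * geom$right$area_m2 / geom$right$perimeter_m
  )
  geom
}

#' Read a two-passage geometry from CSV
#'
#' Expects the canonical dialect written by [write_geometry()]: columns
#' `side,k,x_m,length_m,area_m2,perimeter_m`, one row per slice per side,
#' ordered anterior to posterior. When the two sides differ in slice count
#' or passage length they are resampled by linear interpolation of A and P
#' onto a common normalized-position grid, so that slice k on the left faces
#' slice k on the right.
#'
#' @param path CSV file path
#' @param resample if `TRUE` (default) align both sides to a common X/L grid
#' @return a `nasal_geometry`
#' @export
load_geometry <- function(path, resample = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  missing <- setdiff(GEOMETRY_CSV_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing columns %s", path, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (col in setdiff(GEOMETRY_CSV_COLUMNS, "side")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("%s: malformed value in column '%s' at data row %d",
                   path, col, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  sides <- split(df, df$side)
  if (!setequal(names(sides), c("left", "right"))) {
    stop(sprintf("%s: 'side' must contain exactly 'left' and 'right'", path),
         call. = FALSE)
  }
  left <- sides$left[order(sides$left$k), setdiff(GEOMETRY_CSV_COLUMNS, "side")]
  right <- sides$right[order(sides$right$k), setdiff(GEOMETRY_CSV_COLUMNS, "side")]
  rownames(left) <- rownames(right) <- NULL
  geom <- new_nasal_geometry(left, right, stats::median(c(left$length_m, right$length_m)))
  if (resample && (nrow(left) != nrow(right) ||
                   abs(sum(left$length_m) - sum(right$length_m)) > 1e-12)) {
    geom <- resample_geometry(geom, max(nrow(left), nrow(right)))
  }
  geom
}

#' Resample both sides of a geometry onto a common normalized grid
#'
#' @param geometry a `nasal_geometry`
#' @param n number of slices in the common grid
#' @return a `nasal_geometry` with `n` slices per side; per-side slice
#'   thickness is the side's passage length divided by `n`
#' @keywords internal
resample_geometry <- function(geometry, n) {
  stopifnot(inherits(geometry, "nasal_geometry"), n >= 2)
  resample_side <- function(df) {
    total <- sum(df$length_m)
    xol <- (df$x_m + df$length_m / 2) / total  # upper-edge positions unused; midpoints
    xol_mid <- df$x_m / total
    grid <- (seq_len(n) - 0.5) / n
    l_new <- total / n
    data.frame(
      k = seq_len(n),
      x_m = grid * total,
      length_m = l_new,
      area_m2 = stats::approx(xol_mid, df$area_m2, xout = grid, rule = 2)$y,
      perimeter_m = stats::approx(xol_mid, df$perimeter_m, xout = grid, rule = 2)$y
    )
  }
  new_nasal_geometry(resample_side(geometry$left), resample_side(geometry$right),
                     slice_thickness = NA_real_)
}

#' Write a geometry to the canonical CSV dialect
#'
#' @param geometry a `nasal_geometry`
#' @param path output CSV path
#' @return invisibly, `path`
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "nasal_geometry"))
  fmt <- function(df, side) {
    cbind(side = side, df[, setdiff(GEOMETRY_CSV_COLUMNS, "side")])
  }
  out <- rbind(fmt(geometry$left, "left"), fmt(geometry$right, "right"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply congestion to an existing geometry
#'
#' Scales per-slice areas by (1 - c) on each side with perimeters held,
#' the same engorgement model used by [synthesize_geometry()].
#'
#' @param geometry a `nasal_geometry`
#' @param congestion_left,congestion_right fractions in \[0, 1)
#' @return a congested `nasal_geometry`
#' @export
apply_congestion <- function(geometry, congestion_left = 0, congestion_right = 0) {
  stopifnot(inherits(geometry, "nasal_geometry"))
  for (cc in c(congestion_left, congestion_right)) {
    if (!is.finite(cc) || cc < 0 || cc >= 1) {
      stop("congestion fractions must lie in [0, 1)", call. = FALSE)
    }
  }
  left <- geometry$left
  right <- geometry$right
  left$area_m2 <- left$area_m2 * (1 - congestion_left)
  right$area_m2 <- right$area_m2 * (1 - congestion_right)
  new_nasal_geometry(left[, setdiff(GEOMETRY_CSV_COLUMNS, "side")],
                     right[, setdiff(GEOMETRY_CSV_COLUMNS, "side")],
                     geometry$slice_thickness)
}

#' Normalized axial positions X/L
#'
#' Midpoint positions of every slice divided by the side's passage length;
#' 0 is the anterior nasal valve, 1 the posterior choanae.
#'
#' @param geometry a `nasal_geometry`
#' @return list with numeric vectors `left` and `right` in \[0, 1\]
#' @export
normalized_positions <- function(geometry) {
  stopifnot(inherits(geometry, "nasal_geometry"))
  one <- function(df) df$x_m / sum(df$length_m)
  list(left = one(geometry$left), right = one(geometry$right))
}

#' One-side mucosal surface area
#'
#' @param geometry a `nasal_geometry`
#' @return named vector, m^2 per side (sum of P(k) * l over slices)
#' @export
surface_area <- function(geometry) {
  stopifnot(inherits(geometry, "nasal_geometry"))
  c(left = sum(geometry$left$perimeter_m * geometry$left$length_m),
    right = sum(geometry$right$perimeter_m * geometry$right$length_m))
}

#' @export
print.nasal_geometry <- function(x, ...) {
  sa <- surface_area(x)
  cat(sprintf(
    "Nasal geometry: %d + %d slices, passage lengths %.1f / %.1f cm, surface %.0f / %.0f cm^2\n",
    nrow(x$left), nrow(x$right),
    100 * sum(x$left$length_m), 100 * sum(x$right$length_m),
    1e4 * sa[["left"]], 1e4 * sa[["right"]]
  ))
  invisible(x)
}
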