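#' Studded eel-tile geometry
#'
#' Geometry of a dual-density studded tile: 50 mm high tapered studs of two
#' diameters, the small studs at 45.45 mm centre-to-centre spacing and the
#' large studs at 83.3 mm. Defaults are the commercial tile dimensions.
#'
#' @param small_base,small_top Small-stud base/top diameters (m).
#' @param small_spacing Small-stud centre-to-centre spacing (m).
#' @param large_base,large_top Large-stud base/top diameters (m).
#' @param large_spacing Large-stud centre-to-centre spacing (m).
#' @param stud_height Stud height (m).
#' @param walls Mark one-cell-thick wall columns at the lateral edges.
#' @return An object of class `eel_stud_layout`.
#' @export
stud_layout <- function(small_base = 1.48e-2, small_top = 1.17e-2,
                        small_spacing = 4.545e-2,
                        large_base = 2.96e-2, large_top = 2.34e-2,
                        large_spacing = 8.33e-2,
                        stud_height = 5.0e-2, walls = TRUE) {
  if (small_top > small_base || large_top > large_base) {
    abort("Top diameters must not exceed base diameters (studs taper upward).")
  }
  if (small_spacing <= small_base || large_spacing <= large_base) {
    abort("Centre-to-centre spacing must exceed the base diameter.")
  }
  structure(
    list(
      small_base = small_base, small_top = small_top,
      small_spacing = small_spacing,
      large_base = large_base, large_top = large_top,
      large_spacing = large_spacing,
      stud_height = stud_height, walls = walls
    ),
    class = "eel_stud_layout"
  )
}

#' Flow scenario for a pass installation
#'
#' @param angle_deg Installation angle of the pass from horizontal, degrees
#'   (> 0). Conventional design points are 8, 11, 14, 17 and 20 degrees.
#' @param q_m2s Nominal inflow discharge per unit width, m^2/s (> 0).
#' @param length_m,width_m Pass length and modelled sub-domain width (m).
#'   The default width (45 mm) is one small-stud spacing: the spanwise
#'   repeating unit of the small-stud sub-domain, which [mirror_spanwise()]
#'   can extend.
#' @param discharge_split Two-element ratio of unit discharge carried by the
#'   small- versus large-stud sub-domains (default `c(45, 83)`, the ratio of
#'   the centre-to-centre spacings).
#' @param n_cal Calibrated Manning-type roughness coefficient; the default
#'   is calibrated once against the validated installation (11 degrees,
#'   3.33e-3 m^2/s giving 0.299 m/s over 5.58 mm).
#' @param q_fraction Fraction of the nominal unit discharge carried by the
#'   modelled small-stud sub-domain; the default comes from the same
#'   calibration. See [manning_calibration()].
#' @param seed Seed for optional perturbation noise in [generate_field()].
#' @return An object of class `eel_flow_scenario`.
#' @export
flow_scenario <- function(angle_deg, q_m2s, length_m = 1.25, width_m = 4.5e-2,
                          discharge_split = c(45, 83),
                          n_cal = NULL, q_fraction = NULL, seed = 1L) {
  if (!is.numeric(angle_deg) || angle_deg <= 0 || angle_deg >= 90) {
    abort("`angle_deg` must be in (0, 90).")
  }
  if (!is.numeric(q_m2s) || q_m2s <= 0) abort("`q_m2s` must be positive.")
  cal <- manning_calibration()
  structure(
    list(
      angle_deg = angle_deg, q_m2s = q_m2s,
      length_m = length_m, width_m = width_m,
      discharge_split = discharge_split,
      n_cal = if (is.null(n_cal)) cal$n_cal else n_cal,
      q_fraction = if (is.null(q_fraction)) cal$q_fraction else q_fraction,
      seed = as.integer(seed)
    ),
    class = "eel_flow_scenario"
  )
}

#' Calibration constants of the Manning-type bulk-flow closure
#'
#' The closure `U = (1/n_cal) * h^(2/3) * sqrt(sin(theta))`, `U * h = q_eff`
#' is calibrated once against the validated installation: at 11 degrees and
#' a nominal unit discharge of 3.33e-3 m^2/s the small-stud sub-domain
#' carries a mean near-bed speed of 0.299 m/s over a mean depth of 5.58 mm.
#' Because the tile distributes discharge between the small- and large-stud
#' sub-domains, the sub-domain's effective unit discharge is a fraction of
#' the nominal value: `q_fraction = U * h / q` at the anchor. `n_cal` then
#' follows by inverting the closure there.
#'
#' @return List with `n_cal` (~0.0460) and `q_fraction` (~0.501), both
#'   computed from the anchor values.
#' @export
manning_calibration <- function() {
  u_anchor <- 0.299     # m/s, validated sub-domain mean speed
  h_anchor <- 5.58e-3   # m, validated mean depth
  theta_anchor <- 11    # degrees
  q_anchor <- 3.33e-3   # m^2/s nominal unit discharge
  list(
    n_cal = h_anchor^(2 / 3) * sqrt(sin(theta_anchor * pi / 180)) / u_anchor,
    q_fraction = u_anchor * h_anchor / q_anchor
  )
}

#' Bulk mean speed and depth for a scenario
#'
#' Solves the Manning-type closure for the modelled sub-domain by 1-D root
#' finding in the depth: `(1/n) * h^(2/3) * sqrt(sin(theta)) * h = q_eff`
#' with `q_eff = q_fraction * q`, then `U = q_eff / h`.
#'
#' @param scenario An [flow_scenario()].
#' @return A one-row tibble with `mean_speed` (m/s), `mean_depth` (m) and
#'   `q_eff` (m^2/s, the sub-domain unit discharge, equal to
#'   `mean_speed * mean_depth`).
#' @export
#' @examples
#' bulk_flow(flow_scenario(11, 3.33e-3))  # ~0.299 m/s over ~5.58 mm
bulk_flow <- function(scenario) {
  stopifnot(inherits(scenario, "eel_flow_scenario"))
  q_eff <- scenario$q_fraction * scenario$q_m2s
  s <- sqrt(sin(scenario$angle_deg * pi / 180))
  n <- scenario$n_cal
  f <- function(h) h^(5 / 3) * s / n - q_eff
  root <- uniroot(f, lower = 1e-8, upper = 10, tol = 1e-14)
  if (abs(root$f.root) > 1e-8 * q_eff) {
    abort(sprintf("Bulk-flow closure did not converge (residual %.3g).", root$f.root))
  }
  h <- root$root
  tibble::tibble(mean_speed = q_eff / h, mean_depth = h, q_eff = q_eff)
}

# stud centres for the modelled sub-domain, staggered rows:
# even rows centre a stud mid-width, odd rows place (half) studs at the
# lateral edges, so shielded lanes sit at the walls and the centre and the
# fast lanes at one- and three-quarter width, as observed over small studs.
stud_centres <- function(layout, length_m, width_m, large = FALSE) {
  s <- if (large) layout$large_spacing else layout$small_spacing
  x_rows <- seq(s / 2, length_m - s / 4, by = s)
  centres <- NULL
  for (k in seq_along(x_rows)) {
    z <- if (k %% 2L == 1L) width_m / 2 else c(0, width_m)
    centres <- rbind(centres, cbind(x = x_rows[k], z = z))
  }
  centres
}

#' Boolean stud-footprint mask on a grid
#'
#' Marks grid cells whose centroid lies inside any stud's circular cross
#' section at the sampling height (the tapered diameter is interpolated
#' linearly between base and top), plus one-cell-thick wall columns when the
#' layout has walls.
#'
#' @param layout An [stud_layout()].
#' @param grid An [grid_spec()] covering the modelled sub-domain.
#' @param sample_height Height above the bed at which the footprint is
#'   taken (m); must be below the stud height.
#' @param length_m,width_m Physical extent matching `grid` (defaults derived
#'   from the grid).
#' @param large Use the large-stud geometry instead of the small.
#' @return Logical matrix, `TRUE` where a cell is inside a stud or wall.
#' @export
stud_mask <- function(layout, grid, sample_height = 3e-3,
                      length_m = grid$n_streamwise * grid$cell_size,
                      width_m = grid$n_spanwise * grid$cell_size,
                      large = FALSE) {
  stopifnot(inherits(layout, "eel_stud_layout"), inherits(grid, "eel_grid_spec"))
  if (sample_height > layout$stud_height) {
    abort("`sample_height` must not exceed the stud height.")
  }
  base <- if (large) layout$large_base else layout$small_base
  top <- if (large) layout$large_top else layout$small_top
  frac <- sample_height / layout$stud_height
  diam <- base + (top - base) * frac
  r2 <- (diam / 2)^2
  d <- grid$cell_size
  xs <- (seq_len(grid$n_streamwise) - 0.5) * d
  zs <- (seq_len(grid$n_spanwise) - 0.5) * d
  mask <- matrix(FALSE, grid$n_streamwise, grid$n_spanwise)
  centres <- stud_centres(layout, length_m, width_m, large)
  for (k in seq_len(nrow(centres))) {
    dx2 <- (xs - centres[k, "x"])^2
    dz2 <- (zs - centres[k, "z"])^2
    mask <- mask | outer(dx2, dz2, `+`) <= r2
  }
  if (layout$walls && grid$n_spanwise >= 2L) {
    mask[, c(1L, grid$n_spanwise)] <- TRUE
  }
  mask
}

#' Generate a CFD-like near-bed velocity and depth field
#'
#' Parametric emulation of the time-averaged flow through the stud array at
#' the sampling plane: a stagnation deficit ahead of each stud, an
#' exponential wake deficit behind it, convergence acceleration between stud
#' columns arising from mean-renormalisation, stud and wall cells as nodata,
#' and a depth field anticorrelated with speed (deep sheltered lanes,
#' shallow fast lanes). The wetted spatial mean speed equals the bulk speed
#' from [bulk_flow()] exactly, and the wetted mean depth is scaled so that
#' `U * h` matches the sub-domain unit discharge.
#'
#' @param scenario An [flow_scenario()].
#' @param layout An [stud_layout()].
#' @param grid Optional [grid_spec()]; defaults to a 0.5 mm raster covering
#'   `scenario$length_m` by `scenario$width_m`.
#' @param sample_height Sampling-plane height (m).
#' @param stagnation_deficit,wake_deficit Relative amplitude of the
#'   stagnation and wake speed deficits (calibration constants; defaults
#'   0.6 and 0.4 bracket the observed shielded-lane/fast-lane spread).
#' @param wake_length Wake decay length in stud base diameters (default 1).
#' @param noise_sd Standard deviation of optional multiplicative lognormal
#'   perturbation noise (default 0 = off); seeded from `scenario$seed`.
#' @param large Emulate the large-stud sub-domain (with its share of the
#'   discharge split) instead of the small.
#' @return List with elements `velocity` ([velocity_field()]) and `depth`
#'   ([depth_field()]).
#' @export
generate_field <- function(scenario, layout = stud_layout(), grid = NULL,
                           sample_height = 3e-3,
                           stagnation_deficit = 0.7, wake_deficit = 0.5,
                           wake_length = 2, noise_sd = 0, large = FALSE) {
  stopifnot(inherits(scenario, "eel_flow_scenario"))
  if (is.null(grid)) {
    grid <- grid_spec(
      max(2L, round(scenario$length_m / 5e-4)),
      max(1L, round(scenario$width_m / 5e-4))
    )
  }
  base_d <- if (large) layout$large_base else layout$small_base
  if (base_d < 2 * grid$cell_size) {
    abort("Grid too coarse to resolve a stud (base diameter < 2 cells).")
  }
  scn <- scenario
  if (large) {
    # reuse the closure with the large-stud share of the discharge split
    split <- scenario$discharge_split
    scn$q_fraction <- scenario$q_fraction * split[2L] / split[1L]
  }
  bulk <- bulk_flow(scn)
  length_m <- grid$n_streamwise * grid$cell_size
  width_m <- grid$n_spanwise * grid$cell_size

  d <- grid$cell_size
  xs <- (seq_len(grid$n_streamwise) - 0.5) * d
  zs <- (seq_len(grid$n_spanwise) - 0.5) * d
  frac <- sample_height / layout$stud_height
  top <- if (large) layout$large_top else layout$small_top
  radius <- (base_d + (top - base_d) * frac) / 2

  shape <- matrix(1, grid$n_streamwise, grid$n_spanwise)
  centres <- stud_centres(layout, length_m, width_m, large)
  decay <- wake_length * base_d
  for (k in seq_len(nrow(centres))) {
    cx <- centres[k, "x"]
    cz <- centres[k, "z"]
    dz <- zs - cz
    lat <- exp(-(dz / radius)^2)                       # lateral footprint
    # upstream (small x) face: stagnation deficit, Gaussian in approach
    # distance; downstream: wake deficit with exponential streamwise decay
    dx <- xs - cx
    up <- dx <= 0
    stag <- numeric(length(xs))
    stag[up] <- stagnation_deficit *
      exp(-(pmax(abs(dx[up]) - radius, 0) / radius)^2)
    wake <- numeric(length(xs))
    dn <- dx > 0
    wake[dn] <- wake_deficit * exp(-pmax(dx[dn] - radius, 0) / decay)
    deficit <- outer(stag + wake, lat)
    shape <- shape * pmax(1 - deficit, 0.05)
  }

  mask <- stud_mask(layout, grid, sample_height,
                    length_m = length_m, width_m = width_m, large = large)
  shape[mask] <- NA_real_

  if (noise_sd > 0) {
    set.seed(scenario$seed)
    shape <- shape * matrix(
      rlnorm(length(shape), -noise_sd^2 / 2, noise_sd),
      nrow(shape), ncol(shape)
    )
  }

  wet <- !is.na(shape)
  if (!any(wet)) abort("Generated field has no wetted cells.")
  speed <- shape * (bulk$mean_speed / mean(shape[wet]))

  # depth anticorrelated with the speed shape, rescaled to the bulk depth
  dshape <- 2 - speed / bulk$mean_speed
  dshape <- pmax(dshape, 0.1)
  depth <- dshape * (bulk$mean_depth / mean(dshape[wet]))
  depth[!wet] <- NA_real_

  list(
    velocity = velocity_field(speed, grid, sample_height = sample_height,
                              angle_deg = scenario$angle_deg,
                              q_m2s = scenario$q_m2s),
    depth = depth_field(depth, grid)
  )
}
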