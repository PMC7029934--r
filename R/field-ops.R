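#' Regrid scattered velocity samples onto a regular grid
#'
#' Piecewise-linear (Delaunay barycentric) interpolation of irregular CFD
#' point samples onto the cell centroids of a regular grid, mirroring the
#' conventional preprocessing of near-bed velocity planes. Grid cells whose
#' centroid falls outside the convex hull of the samples become nodata.
#'
#' @param points Data frame with numeric columns `x` (streamwise position,
#'   m, measured from the upstream edge), `z` (spanwise position, m) and
#'   `speed` (m/s). At least three non-collinear points are required.
#' @param target An [grid_spec()] describing the output raster.
#' @param sample_height,angle_deg,q_m2s Metadata forwarded to the output
#'   field.
#' @return An [velocity_field()] on `target`.
#' @export
regrid_linear <- function(points, target, sample_height = 3e-3,
                          angle_deg = NA_real_, q_m2s = NA_real_) {
  stopifnot(inherits(target, "eel_grid_spec"))
  points <- as.data.frame(points)
  if (!all(c("x", "z", "speed") %in% names(points))) {
    abort("`points` must have columns x, z, speed.")
  }
  if (nrow(points) < 3L) abort("Need at least 3 sample points.")
  xy <- cbind(points$x, points$z)
  if (qr(sweep(xy, 2L, colMeans(xy)))$rank < 2L) {
    abort("Sample points are collinear; no planar interpolation is possible.")
  }
  d <- target$cell_size
  xo <- (seq_len(target$n_streamwise) - 0.5) * d
  zo <- (seq_len(target$n_spanwise) - 0.5) * d
  nodes <- expand.grid(x = xo, z = zo)
  out <- interp::interpp(
    x = points$x, y = points$z, z = points$speed,
    xo = nodes$x, yo = nodes$z, duplicate = "mean"
  )
  speed <- matrix(out$z, target$n_streamwise, target$n_spanwise)
  speed[!is.na(speed) & speed < 0] <- 0
  velocity_field(speed, target, sample_height = sample_height,
                 angle_deg = angle_deg, q_m2s = q_m2s)
}

#' Temporal average of a sequence of velocity snapshots
#'
#' Arithmetic per-cell mean of the snapshots whose times fall inside the
#' averaging window. A cell that is nodata in any contributing snapshot is
#' nodata in the average: a sometimes-dry cell has no defined time-averaged
#' swimming environment.
#'
#' @param fields List of [velocity_field()] objects sharing one grid.
#' @param times Numeric vector of snapshot times (s), parallel to `fields`.
#' @param window Two-element numeric `c(start, end)` in seconds; snapshots
#'   with `start <= t <= end` contribute.
#' @return A single averaged [velocity_field()] with `window` recorded.
#' @export
temporal_average <- function(fields, times = seq_along(fields),
                             window = range(times)) {
  if (length(fields) == 0L) abort("`fields` is empty.")
  if (length(times) != length(fields)) abort("`times` must parallel `fields`.")
  if (length(window) != 2L || window[2L] < window[1L]) {
    abort("`window` must be c(start, end) with end >= start.")
  }
  g <- fields[[1L]]$grid
  for (f in fields) {
    if (!same_grid(f$grid, g)) abort("All snapshots must share the same grid.")
  }
  keep <- times >= window[1L] & times <= window[2L]
  if (!any(keep)) abort("Averaging window contains no snapshots.")
  stack <- lapply(fields[keep], function(f) f$speed)
  avg <- Reduce(`+`, stack) / length(stack)  # NA propagates (any-nodata rule)
  velocity_field(avg, g,
                 sample_height = fields[[1L]]$sample_height,
                 angle_deg = fields[[1L]]$angle_deg,
                 q_m2s = fields[[1L]]$q_m2s,
                 window = as.numeric(window))
}

#' Mirror a field in the spanwise direction
#'
#' CFD of the stud array exploits spanwise symmetry and simulates a half (or
#' third) width domain; mirroring about the last spanwise column's outer edge
#' restores the full width. The output has twice the spanwise extent and is
#' symmetric about its spanwise midline.
#'
#' @param field A velocity or depth field.
#' @return A field of the same class with `n_spanwise` doubled.
#' @export
mirror_spanwise <- function(field) {
  if (inherits(field, "eel_velocity_field")) {
    m <- field$speed
    g <- field$grid
    out <- cbind(m, m[, rev(seq_len(ncol(m))), drop = FALSE])
    velocity_field(out, grid_spec(g$n_streamwise, 2L * g$n_spanwise, g$cell_size),
                   sample_height = field$sample_height,
                   angle_deg = field$angle_deg, q_m2s = field$q_m2s,
                   window = field$window)
  } else if (inherits(field, "eel_depth_field")) {
    m <- field$depth
    g <- field$grid
    out <- cbind(m, m[, rev(seq_len(ncol(m))), drop = FALSE])
    depth_field(out, grid_spec(g$n_streamwise, 2L * g$n_spanwise, g$cell_size))
  } else {
    abort("`field` must be a velocity or depth field.")
  }
}

#' Bulk hydraulic summary of a velocity/depth field pair
#'
#' Spatial means over wetted cells plus the derived Reynolds numbers and
#' unit discharge. Two Reynolds length scales are conventional for studded
#' tiles: the mean flow depth and the stud diameter.
#'
#' @param field An [velocity_field()].
#' @param depth An [depth_field()] on the same grid, or `NULL` if depth is
#'   unavailable (depth-based quantities are then `NA`).
#' @param nu Kinematic viscosity of water in m^2/s. The default is the
#'   value for water at about 21.8 degrees C.
#' @param stud_diameter Stud diameter used as the alternative Reynolds
#'   length scale, in metres (default: small-stud base diameter).
#' @return A one-row tibble with columns `mean_speed`, `mean_depth`,
#'   `re_depth`, `re_stud`, `q_unit` (= U * mean depth, m^2/s).
#' @export
#' @examples
#' f <- velocity_field(matrix(0.299, 4, 4))
#' d <- depth_field(matrix(5.58e-3, 4, 4))
#' hydraulic_summary(f, d)  # re_depth close to 1740
hydraulic_summary <- function(field, depth = NULL, nu = 9.6e-7,
                              stud_diameter = 1.48e-2) {
  if (!is.numeric(nu) || nu <= 0) abort("`nu` must be positive.")
  wet <- !is.na(field$speed)
  if (!any(wet)) abort("Field is entirely nodata; no bulk summary exists.")
  U <- mean(field$speed[wet])
  if (!is.null(depth)) {
    if (!same_grid(depth$grid, field$grid)) abort("Depth grid mismatch.")
    dwet <- !is.na(depth$depth)
    hbar <- mean(depth$depth[dwet])
  } else {
    hbar <- NA_real_
  }
  tibble::tibble(
    mean_speed = U,
    mean_depth = hbar,
    re_depth = U * hbar / nu,
    re_stud = U * stud_diameter / nu,
    q_unit = U * hbar
  )
}
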