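#' Grid specification for near-bed field rasters
#'
#' Defines the regular raster on which velocity, depth and classified fields
#' live. Row index `i` runs from 1 at the upstream-most edge of the pass (the
#' success line) to `n_streamwise` at the downstream-most edge (where agents
#' are spawned); column index `j` runs across the pass. Cell centroids sit at
#' `((i - 0.5) * cell_size, (j - 0.5) * cell_size)`.
#'
#' @param n_streamwise Number of cells along the ascent axis (>= 2).
#' @param n_spanwise Number of cells across the pass (>= 1).
#' @param cell_size Cell edge length in metres. Default 0.5 mm, the
#'   resolution at which near-bed CFD planes are conventionally regridded.
#'
#' @return An object of class `eel_grid_spec`.
#' @export
#' @examples
#' grid_spec(100, 54)
grid_spec <- function(n_streamwise, n_spanwise, cell_size = 5e-4) {
  n_streamwise <- as.integer(n_streamwise)
  n_spanwise <- as.integer(n_spanwise)
  if (is.na(n_streamwise) || n_streamwise < 2L) {
    abort("`n_streamwise` must be an integer >= 2.")
  }
  if (is.na(n_spanwise) || n_spanwise < 1L) {
    abort("`n_spanwise` must be an integer >= 1.")
  }
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    abort("`cell_size` must be a single positive number (metres).")
  }
  structure(
    list(
      n_streamwise = n_streamwise,
      n_spanwise = n_spanwise,
      cell_size = as.numeric(cell_size)
    ),
    class = "eel_grid_spec"
  )
}

#' @export
format.eel_grid_spec <- function(x, ...) {
  sprintf(
    "<eel_grid_spec> %d x %d cells @ %.4g mm (%.3g x %.3g m)",
    x$n_streamwise, x$n_spanwise, x$cell_size * 1e3,
    x$n_streamwise * x$cell_size, x$n_spanwise * x$cell_size
  )
}

#' @export
print.eel_grid_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Gridded near-bed velocity field
#'
#' Stores the time-averaged velocity magnitude sampled on a plane a few
#' millimetres above the tile bed. Cells containing no water (studs, walls,
#' dry patches) are `NA` and form the nodata mask.
#'
#' @param speed Numeric matrix (`n_streamwise` x `n_spanwise`) of speeds in
#'   m/s; `NA` marks nodata cells. Row 1 is the upstream-most edge.
#' @param grid An [grid_spec()]; defaults to one matching `dim(speed)`.
#' @param sample_height Height of the extraction plane above the bed in
#'   metres (default 3 mm).
#' @param angle_deg,q_m2s Optional scenario metadata: installation angle in
#'   degrees and nominal unit discharge in m^2/s.
#' @param window Optional two-element numeric, the temporal averaging window
#'   in seconds.
#'
#' @return An object of class `eel_velocity_field`.
#' @export
velocity_field <- function(speed, grid = NULL, sample_height = 3e-3,
                           angle_deg = NA_real_, q_m2s = NA_real_,
                           window = NULL) {
  speed <- as.matrix(speed)
  storage.mode(speed) <- "double"
  if (is.null(grid)) {
    grid <- grid_spec(nrow(speed), ncol(speed))
  }
  stopifnot(inherits(grid, "eel_grid_spec"))
  if (nrow(speed) != grid$n_streamwise || ncol(speed) != grid$n_spanwise) {
    abort("`speed` dimensions do not match `grid`.")
  }
  if (any(speed < 0, na.rm = TRUE)) {
    abort("Speeds must be non-negative where defined.")
  }
  if (!is.numeric(sample_height) || sample_height <= 0) {
    abort("`sample_height` must be positive (metres).")
  }
  structure(
    list(
      grid = grid,
      speed = speed,
      sample_height = as.numeric(sample_height),
      angle_deg = as.numeric(angle_deg),
      q_m2s = as.numeric(q_m2s),
      window = window
    ),
    class = "eel_velocity_field"
  )
}

#' Gridded water-depth field
#'
#' @param depth Numeric matrix of local water depths in metres; `NA` marks
#'   nodata (dry or solid) cells.
#' @inheritParams velocity_field
#' @return An object of class `eel_depth_field`.
#' @export
depth_field <- function(depth, grid = NULL) {
  depth <- as.matrix(depth)
  storage.mode(depth) <- "double"
  if (is.null(grid)) {
    grid <- grid_spec(nrow(depth), ncol(depth))
  }
  stopifnot(inherits(grid, "eel_grid_spec"))
  if (nrow(depth) != grid$n_streamwise || ncol(depth) != grid$n_spanwise) {
    abort("`depth` dimensions do not match `grid`.")
  }
  if (any(depth < 0, na.rm = TRUE)) {
    abort("Depths must be non-negative where defined.")
  }
  structure(list(grid = grid, depth = depth), class = "eel_depth_field")
}

#' @export
print.eel_velocity_field <- function(x, ...) {
  cat(format(x$grid), "\n")
  wet <- !is.na(x$speed)
  cat(sprintf(
    "velocity field @ %.3g mm: mean %.3f m/s over %d wetted cells (%d nodata)\n",
    x$sample_height * 1e3, mean(x$speed[wet]), sum(wet), sum(!wet)
  ))
  if (!is.na(x$angle_deg)) {
    cat(sprintf("scenario: angle %.3g deg, q %.3g m^2/s\n", x$angle_deg, x$q_m2s))
  }
  invisible(x)
}

#' @export
print.eel_depth_field <- function(x, ...) {
  cat(format(x$grid), "\n")
  wet <- !is.na(x$depth)
  cat(sprintf(
    "depth field: mean %.3g mm over %d wetted cells\n",
    mean(x$depth[wet]) * 1e3, sum(wet)
  ))
  invisible(x)
}

# shared helper: nodata mask as a logical matrix
nodata_mask <- function(field) {
  if (inherits(field, "eel_velocity_field")) return(is.na(field$speed))
  if (inherits(field, "eel_depth_field")) return(is.na(field$depth))
  abort("Not a field object.")
}

same_grid <- function(a, b) {
  identical(
    a[c("n_streamwise", "n_spanwise")],
    b[c("n_streamwise", "n_spanwise")]
  ) && isTRUE(all.equal(a$cell_size, b$cell_size))
}
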