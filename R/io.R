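#' Read a gridded field from a delimited-text grid file
#'
#' The grid format is plain whitespace-delimited text with `#`-prefixed
#' header lines (`kind`, `cell_size_m`, `n_streamwise`, `n_spanwise`,
#' `sample_height_m`, `nodata`, `units`, plus optional scenario metadata),
#' followed by the body in row-major order with the streamwise index
#' increasing down the file. Nodata cells carry a negative sentinel (-1 by
#' default) that can never collide with a real speed or depth. Velocity,
#' depth and integer-coded classified grids share the format, distinguished
#' by the `kind` header.
#'
#' @param path Path to a grid file written by [write_grid()].
#' @return An [velocity_field()], [depth_field()] or classified field
#'   (see [classify_field()]) according to the file's `kind` header.
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("Grid file not found: %s", path))
  lines <- readLines(path)
  is_header <- grepl("^#", lines)
  n_header <- match(FALSE, is_header, nomatch = length(lines) + 1L) - 1L
  header <- lines[seq_len(n_header)]
  body <- lines[seq.int(n_header + 1L, length.out = length(lines) - n_header)]
  body <- body[nzchar(trimws(body))]

  hval <- function(key, required = TRUE) {
    pat <- paste0("^#\\s*", key, "\\s+")
    hit <- grep(pat, header, value = TRUE)
    if (length(hit) == 0L) {
      if (required) abort(sprintf("Malformed header in %s: missing `%s`.", path, key))
      return(NA_character_)
    }
    trimws(sub(pat, "", hit[[1L]]))
  }

  kind <- hval("kind")
  cell_size <- as.numeric(hval("cell_size_m"))
  n_i <- as.integer(hval("n_streamwise"))
  n_j <- as.integer(hval("n_spanwise"))
  sentinel <- as.numeric(hval("nodata"))
  if (anyNA(c(cell_size, n_i, n_j, sentinel))) {
    abort(sprintf("Malformed header in %s: non-numeric metadata.", path))
  }
  if (length(body) != n_i) {
    abort(sprintf(
      "Body of %s has %d data rows but header declares n_streamwise %d (first body line is line %d).",
      path, length(body), n_i, n_header + 1L
    ))
  }
  vals <- lapply(seq_along(body), function(k) {
    row <- scan(text = body[[k]], what = double(), quiet = TRUE)
    if (length(row) != n_j) {
      abort(sprintf(
        "Line %d of %s has %d values but header declares n_spanwise %d.",
        n_header + k, path, length(row), n_j
      ))
    }
    row
  })
  m <- do.call(rbind, vals)
  grid <- grid_spec(n_i, n_j, cell_size)

  if (kind == "classified") {
    m[m == sentinel] <- 2
    cls <- matrix(as.integer(m), n_i, n_j)
    if (!all(cls %in% 0:2)) abort(sprintf("Classified body of %s has codes outside 0:2.", path))
    thr <- as.numeric(hval("threshold_m_s", required = FALSE))
    return(new_classified_field(cls, grid, threshold = thr))
  }

  m[m == sentinel] <- NA_real_
  if (kind == "velocity") {
    velocity_field(
      m, grid,
      sample_height = as.numeric(hval("sample_height_m")),
      angle_deg = as.numeric(hval("angle_deg", required = FALSE)),
      q_m2s = as.numeric(hval("q_m2s", required = FALSE))
    )
  } else if (kind == "depth") {
    depth_field(m, grid)
  } else {
    abort(sprintf("Unknown grid kind `%s` in %s.", kind, path))
  }
}

#' Write a gridded field to a delimited-text grid file
#'
#' @param field A velocity, depth or classified field object.
#' @param path Output path.
#' @param sentinel Negative nodata sentinel written in place of `NA` cells.
#' @return `path`, invisibly. The file round-trips through [read_grid()].
#' @export
write_grid <- function(field, path, sentinel = -1) {
  if (sentinel >= 0) abort("`sentinel` must be negative so it cannot collide with data.")
  g <- if (inherits(field, "eel_classified_field")) field$grid else field$grid
  header <- c("# eelpass grid v1")
  fmt <- function(x) sprintf("%.17g", x)

  if (inherits(field, "eel_velocity_field")) {
    header <- c(
      header, "# kind velocity",
      paste("# cell_size_m", fmt(g$cell_size)),
      paste("# n_streamwise", g$n_streamwise),
      paste("# n_spanwise", g$n_spanwise),
      paste("# sample_height_m", fmt(field$sample_height)),
      paste("# nodata", fmt(sentinel)),
      "# units m_s-1"
    )
    if (!is.na(field$angle_deg)) header <- c(header, paste("# angle_deg", fmt(field$angle_deg)))
    if (!is.na(field$q_m2s)) header <- c(header, paste("# q_m2s", fmt(field$q_m2s)))
    m <- field$speed
  } else if (inherits(field, "eel_depth_field")) {
    header <- c(
      header, "# kind depth",
      paste("# cell_size_m", fmt(g$cell_size)),
      paste("# n_streamwise", g$n_streamwise),
      paste("# n_spanwise", g$n_spanwise),
      paste("# nodata", fmt(sentinel)),
      "# units m"
    )
    m <- field$depth
  } else if (inherits(field, "eel_classified_field")) {
    header <- c(
      header, "# kind classified",
      paste("# cell_size_m", fmt(g$cell_size)),
      paste("# n_streamwise", g$n_streamwise),
      paste("# n_spanwise", g$n_spanwise),
      paste("# nodata", fmt(sentinel)),
      "# classes passable:0,impassable:1,boundary:2"
    )
    if (!is.null(field$threshold) && !is.na(field$threshold)) {
      header <- c(header, paste("# threshold_m_s", fmt(field$threshold)))
    }
    m <- field$class
  } else {
    abort("`field` must be a velocity, depth or classified field.")
  }

  m[is.na(m)] <- sentinel
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}
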