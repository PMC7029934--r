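#' @rdname classify_field
#' @export
CLASS_PASSABLE <- 0L

#' @rdname classify_field
#' @export
CLASS_IMPASSABLE <- 1L

#' @rdname classify_field
#' @export
CLASS_BOUNDARY <- 2L

# internal constructor shared with read_grid()
new_classified_field <- function(class, grid, threshold = NA_real_,
                                 source = NULL) {
  storage.mode(class) <- "integer"
  stopifnot(all(class %in% 0:2))
  structure(
    list(grid = grid, class = class, threshold = as.numeric(threshold),
         source = source),
    class = "eel_classified_field"
  )
}

#' Classify a velocity field against a swimming-speed threshold
#'
#' Every cell is assigned exactly one class: *passable* where the
#' time-averaged speed is strictly below the threshold (typically an elver's
#' median burst swimming speed), *impassable* where the speed is greater
#' than or equal to the threshold, and *boundary* where the cell holds no
#' water (studs, walls, dry cells) and so can never be occupied.
#'
#' @param field An [velocity_field()].
#' @param threshold Threshold speed in m/s (> 0).
#' @return An object of class `eel_classified_field` whose `class` matrix
#'   uses the integer coding `passable = 0`, `impassable = 1`,
#'   `boundary = 2` (also exported as `CLASS_PASSABLE` etc.).
#' @export
#' @examples
#' f <- velocity_field(matrix(seq(0.1, 0.9, by = 0.1), 3, 3))
#' cf <- classify_field(f, 0.5)
#' area_fractions(cf)
classify_field <- function(field, threshold) {
  stopifnot(inherits(field, "eel_velocity_field"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a single positive speed (m/s).")
  }
  cls <- matrix(CLASS_BOUNDARY, field$grid$n_streamwise, field$grid$n_spanwise)
  wet <- !is.na(field$speed)
  cls[wet] <- ifelse(field$speed[wet] < threshold, CLASS_PASSABLE, CLASS_IMPASSABLE)
  new_classified_field(cls, field$grid, threshold = threshold)
}

#' @export
print.eel_classified_field <- function(x, ...) {
  cat(format(x$grid), "\n")
  fr <- area_fractions(x)
  cat(sprintf(
    "classified @ threshold %.3g m/s: %.1f%% passable, %.1f%% impassable, %.1f%% boundary\n",
    x$threshold, 100 * fr$passable, 100 * fr$impassable, 100 * fr$boundary
  ))
  invisible(x)
}

#' Area fractions of a classified field
#'
#' @param cf An `eel_classified_field`.
#' @return A one-row tibble with the passable/impassable/boundary fractions
#'   of all cells (summing to 1) and `passable_wetted`, the passable
#'   fraction of non-boundary cells.
#' @export
area_fractions <- function(cf) {
  stopifnot(inherits(cf, "eel_classified_field"))
  n <- length(cf$class)
  if (n == 0L) abort("Empty grid.")
  np <- sum(cf$class == CLASS_PASSABLE)
  ni <- sum(cf$class == CLASS_IMPASSABLE)
  nb <- sum(cf$class == CLASS_BOUNDARY)
  tibble::tibble(
    passable = np / n,
    impassable = ni / n,
    boundary = nb / n,
    passable_wetted = if (n > nb) np / (n - nb) else NA_real_
  )
}

#' Test for a continuous passable path up the pass
#'
#' Breadth-first search over the first-order Moore (8-neighbour) adjacency
#' of passable cells, from the downstream-most row to the upstream-most row.
#' This is the same adjacency the movement models use, so a path exists
#' exactly when an automaton could in principle ascend.
#'
#' @param cf An `eel_classified_field`.
#' @return A list with `reachable` (logical) and `path`: when reachable, a
#'   two-column matrix of (i, j) cells tracing one shortest witness path
#'   from the downstream edge to the upstream edge; otherwise `NULL`.
#' @export
has_continuous_path <- function(cf) {
  stopifnot(inherits(cf, "eel_classified_field"))
  cls <- cf$class
  n_i <- nrow(cls)
  n_j <- ncol(cls)
  passable <- cls == CLASS_PASSABLE
  n_cells <- n_i * n_j
  # BFS from all passable cells on the downstream edge (row n_i);
  # cells addressed by linear index, queue preallocated
  parent <- integer(n_cells)          # 0 = seed / unvisited
  visited <- logical(n_cells)
  lin <- function(ii, jj) ii + (jj - 1L) * n_i
  seeds <- lin(n_i, which(passable[n_i, ]))
  queue <- integer(n_cells)
  n_q <- length(seeds)
  if (n_q > 0L) {
    queue[seq_len(n_q)] <- seeds
    visited[seeds] <- TRUE
  }
  head_k <- 1L
  goal <- if (n_i == 1L && n_q > 0L) seeds[1L] else NA_integer_
  while (is.na(goal) && head_k <= n_q) {
    cur <- queue[head_k]
    ci <- ((cur - 1L) %% n_i) + 1L
    cj <- ((cur - 1L) %/% n_i) + 1L
    for (di in -1:1) {
      ii <- ci + di
      if (ii < 1L || ii > n_i) next
      for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        jj <- cj + dj
        if (jj < 1L || jj > n_j) next
        nb <- lin(ii, jj)
        if (visited[nb] || !passable[nb]) next
        visited[nb] <- TRUE
        parent[nb] <- cur
        n_q <- n_q + 1L
        queue[n_q] <- nb
        if (ii == 1L) goal <- nb
      }
      if (!is.na(goal)) break
    }
    head_k <- head_k + 1L
  }
  if (is.na(goal)) {
    return(list(reachable = FALSE, path = NULL))
  }
  # walk parents back to the seed row
  rev_path <- integer(0)
  cur <- goal
  while (cur != 0L) {
    rev_path <- c(rev_path, cur)
    cur <- parent[cur]
  }
  cells <- rev(rev_path)
  path <- cbind(i = ((cells - 1L) %% n_i) + 1L, j = ((cells - 1L) %/% n_i) + 1L)
  list(reachable = TRUE, path = path)
}
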