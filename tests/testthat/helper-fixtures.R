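# Fixture builders shared across the suite; everything is generated in code.

# uniform wetted velocity field
uniform_field <- function(n_i, n_j, speed = 0.2, ...) {
  velocity_field(matrix(speed, n_i, n_j), ...)
}

# all-passable classified grid
open_grid <- function(n_i, n_j, threshold = 0.3) {
  classify_field(uniform_field(n_i, n_j, threshold / 2), threshold)
}

# grid with one fully impassable spanwise row (no 8-connected path)
blocked_grid <- function(n_i = 20, n_j = 10, row = floor(n_i / 2)) {
  m <- matrix(0.1, n_i, n_j)
  m[row, ] <- 0.9
  classify_field(velocity_field(m), 0.5)
}

# 10 x 6 cul-de-sac: a passable corridor up column 2 dead-ends at row 4;
# column 5 runs all the way to the success line; the spawn row connects the
# two. Oscillating agents at the dead end must fall back to re-route.
cul_de_sac_grid <- function() {
  cls <- matrix(CLASS_IMPASSABLE, 10, 6)
  cls[10, ] <- CLASS_PASSABLE        # spawn row
  cls[4:10, 2] <- CLASS_PASSABLE     # dead-end corridor
  cls[1:10, 5] <- CLASS_PASSABLE     # through-route
  f <- velocity_field(matrix(0.1, 10, 6))
  cf <- classify_field(f, 0.5)
  cf$class <- cls
  cf
}

# random classified grid from iid uniform speeds
random_grid <- function(n_i, n_j, threshold, seed) {
  set.seed(seed)
  classify_field(velocity_field(matrix(runif(n_i * n_j), n_i, n_j)), threshold)
}

# independent connectivity oracle: igraph components over Moore adjacency
igraph_path_exists <- function(cf) {
  cls <- cf$class
  n_i <- nrow(cls)
  n_j <- ncol(cls)
  id <- function(i, j) (j - 1L) * n_i + i
  pass <- which(cls == CLASS_PASSABLE, arr.ind = TRUE)
  if (nrow(pass) == 0L) return(FALSE)
  edges <- integer(0)
  for (k in seq_len(nrow(pass))) {
    i <- pass[k, 1L]; j <- pass[k, 2L]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      ii <- i + di; jj <- j + dj
      if (ii < 1L || ii > n_i || jj < 1L || jj > n_j) next
      if (cls[ii, jj] != CLASS_PASSABLE) next
      edges <- c(edges, id(i, j), id(ii, jj))
    }
  }
  g <- igraph::make_empty_graph(n = n_i * n_j, directed = FALSE)
  if (length(edges) > 0L) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  down <- id(n_i, which(cls[n_i, ] == CLASS_PASSABLE))
  up <- id(1L, which(cls[1L, ] == CLASS_PASSABLE))
  length(down) > 0L && length(up) > 0L && any(comp[down] %in% comp[up])
}

# reference speed-quantile triple used across swim/IBM tests
triple_log_symmetric <- function() speed_quantiles(0.07, 0.20, 0.30, 0.45)
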