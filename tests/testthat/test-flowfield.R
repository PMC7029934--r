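test_that("grid files round-trip bit-exactly and validate their headers", {
  f <- velocity_field(matrix(0.30, 3, 3), sample_height = 3e-3,
                      angle_deg = 11, q_m2s = 3.33e-3)
  path <- withr::local_tempfile(fileext = ".grid")
  write_grid(f, path)
  g <- read_grid(path)
  expect_identical(g$speed, f$speed)
  expect_identical(g$grid, f$grid)
  expect_equal(g$sample_height, f$sample_height)
  expect_equal(g$angle_deg, 11)

  # a second write of the read field reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".grid")
  write_grid(g, path2)
  expect_identical(readLines(path), readLines(path2))

  # nodata mask preserved with exactly one masked cell
  m <- matrix(0.2, 3, 3)
  m[2, 2] <- NA
  write_grid(velocity_field(m), path)
  expect_identical(sum(is.na(read_grid(path)$speed)), 1L)

  # body shorter than the header declares -> parse error naming the line
  lines <- readLines(path)
  writeLines(head(lines, -1), path)
  expect_error(read_grid(path), "data rows but header declares")

  # non-negative sentinel would collide with real speeds
  expect_error(write_grid(f, path, sentinel = 0.5), "negative")
})

test_that("classified grids share the format with integer coding", {
  cf <- classify_field(velocity_field(matrix(c(0.1, 0.9), 2, 3)), 0.5)
  path <- withr::local_tempfile(fileext = ".grid")
  write_grid(cf, path)
  back <- read_grid(path)
  expect_s3_class(back, "eel_classified_field")
  expect_identical(back$class, cf$class)
  expect_equal(back$threshold, 0.5)
})

test_that("linear regridding reproduces planar fields and hull behaviour", {
  # plane speed = a + b x + c z reproduced exactly at interior nodes
  set.seed(1)
  pts <- data.frame(x = runif(40), z = runif(40))
  pts$speed <- 0.1 + 0.2 * pts$x + 0.05 * pts$z
  # pin the corners so the unit square is inside the hull
  pts <- rbind(pts, data.frame(x = c(0, 0, 1, 1), z = c(0, 1, 0, 1),
                               speed = 0.1 + 0.2 * c(0, 0, 1, 1) +
                                 0.05 * c(0, 1, 0, 1)))
  target <- grid_spec(4, 4, cell_size = 0.2)  # nodes at 0.1 .. 0.7
  vf <- regrid_linear(pts, target)
  nodes <- expand.grid(x = (1:4 - 0.5) * 0.2, z = (1:4 - 0.5) * 0.2)
  expect_equal(as.vector(vf$speed),
               0.1 + 0.2 * nodes$x + 0.05 * nodes$z, tolerance = 1e-9)

  # sample exactly on a grid node is reproduced
  pts2 <- data.frame(
    x = c(1 / 6, 0, 0, 1, 1), z = c(1 / 6, 0, 1, 0, 1),
    speed = c(0.42, 0.1, 0.1, 0.1, 0.1)
  )
  vf2 <- regrid_linear(pts2, grid_spec(3, 3, cell_size = 1 / 3))
  expect_equal(vf2$speed[1, 1], 0.42, tolerance = 1e-9)

  # 4-point unit square with speeds 0,0,1,1 -> 0.5 at the centre
  sq <- data.frame(x = c(0, 1, 0, 1), z = c(0, 0, 1, 1),
                   speed = c(0, 0, 1, 1))
  vf3 <- regrid_linear(sq, grid_spec(3, 3, cell_size = 1 / 3))
  expect_equal(vf3$speed[2, 2], 0.5, tolerance = 1e-9)

  # cells outside the convex hull become nodata
  tri <- data.frame(x = c(0, 1, 0), z = c(0, 0, 1), speed = c(1, 1, 1))
  vf4 <- regrid_linear(tri, grid_spec(3, 3, cell_size = 1 / 3))
  expect_true(is.na(vf4$speed[3, 3]))  # node (5/6, 5/6) is outside

  # collinear samples are rejected
  col <- data.frame(x = 1:5, z = 2 * (1:5), speed = runif(5))
  expect_error(regrid_linear(col, grid_spec(3, 3)), "collinear")
})

test_that("temporal averaging follows the window and nodata rules", {
  f <- function(v) uniform_field(3, 3, v)
  # constant sequence -> same field
  avg <- temporal_average(list(f(0.3), f(0.3)), times = c(8.5, 9.5),
                          window = c(8, 10))
  expect_equal(avg$speed, f(0.3)$speed)
  # two snapshots 0.2 / 0.4 -> 0.3
  avg2 <- temporal_average(list(f(0.2), f(0.4)), times = c(8.5, 9.5))
  expect_equal(avg2$speed, matrix(0.3, 3, 3))
  # invariant to duplicating the snapshot list
  avg3 <- temporal_average(list(f(0.2), f(0.4), f(0.2), f(0.4)),
                           times = rep(c(8.5, 9.5), 2))
  expect_equal(avg3$speed, avg2$speed)
  # window excluding all snapshots errors
  expect_error(
    temporal_average(list(f(0.2)), times = 5, window = c(8, 10)),
    "no snapshots"
  )
  # any-nodata propagates
  wet <- f(0.2)
  dry <- f(0.4)
  dry$speed[1, 1] <- NA
  avg4 <- temporal_average(list(wet, dry), times = c(1, 2))
  expect_true(is.na(avg4$speed[1, 1]))
  expect_equal(avg4$speed[2, 2], 0.3)
  # mismatched grids error
  expect_error(temporal_average(list(f(0.2), uniform_field(4, 3)),
                                times = c(1, 2)), "same grid")
})

test_that("spanwise mirroring doubles the width symmetrically", {
  m <- matrix(runif(12), 3, 4)
  f <- velocity_field(m)
  out <- mirror_spanwise(f)
  expect_equal(out$grid$n_spanwise, 8L)
  nj <- 4L
  for (j in seq_len(nj)) {
    expect_equal(out$speed[, j], out$speed[, 2L * nj + 1L - j])
  }
  # left half of the output regenerates the output (idempotent rebuild)
  left <- velocity_field(out$speed[, 1:nj], f$grid)
  expect_equal(mirror_spanwise(left)$speed, out$speed)
  # single column -> two identical columns
  one <- velocity_field(matrix(0.2, 3, 1))
  expect_equal(mirror_spanwise(one)$speed, matrix(0.2, 3, 2))
})

test_that("hydraulic summary reproduces the validated Reynolds number", {
  f <- uniform_field(4, 4, 0.299)
  d <- depth_field(matrix(5.58e-3, 4, 4))
  s <- hydraulic_summary(f, d, nu = 9.6e-7)
  expect_equal(round(s$re_depth / 10) * 10, 1740)
  expect_equal(s$q_unit, 0.299 * 5.58e-3)
  # degenerate limits
  z <- hydraulic_summary(uniform_field(2, 2, 0), depth_field(matrix(1, 2, 2)), nu = 1)
  expect_equal(z$re_depth, 0)
  expect_equal(z$re_stud, 0)
  u1 <- hydraulic_summary(uniform_field(2, 2, 1), depth_field(matrix(1, 2, 2)),
                          nu = 1)
  expect_equal(u1$re_depth, 1)
  # homogeneity: scaling speeds by c scales U, Re, q by c
  set.seed(2)
  m <- matrix(runif(9, 0.1, 0.5), 3, 3)
  dd <- depth_field(matrix(runif(9, 1e-3, 8e-3), 3, 3))
  s1 <- hydraulic_summary(velocity_field(m), dd)
  s3 <- hydraulic_summary(velocity_field(3 * m), dd)
  expect_equal(s3$mean_speed, 3 * s1$mean_speed)
  expect_equal(s3$re_depth, 3 * s1$re_depth)
  expect_equal(s3$q_unit, 3 * s1$q_unit)
  # all-nodata field errors
  expect_error(
    hydraulic_summary(velocity_field(matrix(NA_real_, 2, 2)), dd),
    "nodata"
  )
})
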