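test_that("per-agent viability equals classification at the burst speed", {
  set.seed(21)
  m <- matrix(runif(30, 0.1, 0.5), 6, 5)
  m[3, 3] <- NA
  f <- velocity_field(m)
  v <- 0.32
  cf <- classify_field(f, v)
  for (pos in list(c(3, 2), c(2, 4), c(5, 3))) {
    g_ibm <- viable_neighbors(pos, f, v, "normal")
    g_ca <- prioritized_neighbors(pos, cf, "normal")
    expect_identical(g_ibm$upstream, g_ca$upstream)
    expect_identical(g_ibm$cross, g_ca$cross)
    # downstream differs by design: IBM allows any wet downstream cell
    expect_true(nrow(g_ibm$downstream) >= nrow(g_ca$downstream))
  }
  # destination speed equal to burst speed is not viable (strict rule)
  fe <- uniform_field(3, 3, 0.30)
  ge <- viable_neighbors(c(2, 2), fe, 0.30, "normal")
  expect_equal(nrow(ge$upstream), 0L)
  expect_equal(nrow(ge$cross), 0L)
  # agent faster than everything sees the full CA partition
  gfast <- viable_neighbors(c(2, 2), fe, 1.0, "normal")
  expect_equal(vapply(gfast, nrow, integer(1)),
               c(upstream = 3L, cross = 2L, downstream = 3L))
})

test_that("move times follow the relative-velocity arithmetic", {
  expect_equal(move_time(5e-4, 0.3, 0.2, "upstream"), 5e-3)
  expect_equal(move_time(5e-4 * sqrt(2), 0.3, 0.2, "upstream"),
               7.0710678e-3, tolerance = 1e-6)
  # still water: distance / burst speed in any direction
  expect_equal(move_time(1e-3, 0.25, 0, "cross"), 4e-3)
  expect_equal(move_time(1e-3, 0.25, 0, "downstream"), 4e-3)
  # flow-assisted downstream
  expect_equal(move_time(5e-4, 0.3, 0.2, "downstream"), 1e-3)
  # non-positive relative speed on an upstream move is a contract violation
  expect_error(move_time(5e-4, 0.2, 0.3, "upstream"), "burst_speed > water_speed")
  expect_error(move_time(5e-4, 0.3, 0.3, "cross"), "burst_speed > water_speed")
})

test_that("uniform-field ascents match the closed-form time budget", {
  # 2500-cell, width-1 pass at 0.5 mm: ascent covers 1.25 m less one cell
  uf <- uniform_field(2500, 1, 0.2)
  # degenerate speeds v = 0.3: ascent time 1.2495/0.1 = 12.495 s -> all pass
  d3 <- fit_lognormal(speed_quantiles(0.07, 0.3, 0.3, 0.3))
  r3 <- run_ibm(uf, d3, ibm_config(n_agents = 30, max_timesteps = 3000, seed = 1))
  expect_equal(r3$efficiency, 100)
  expect_equal(unique(round(r3$agents$ascent_s, 6)), round(2499 * 5e-4 / 0.1, 6))
  # v = 0.25: required time ~25 s > 20 s -> exhaustion, 0%
  d25 <- fit_lognormal(speed_quantiles(0.07, 0.25, 0.25, 0.25))
  r25 <- run_ibm(uf, d25, ibm_config(n_agents = 30, max_timesteps = 3000, seed = 1))
  expect_equal(r25$efficiency, 0)
  expect_true(all(r25$agents$outcome == "exhausted"))
  expect_true(all(r25$agents$elapsed_s > 20))
  # heterogeneous speeds: efficiency approaches 100 (1 - F(u + L/T))
  dist <- fit_lognormal(triple_log_symmetric())
  r <- run_ibm(uf, dist, ibm_config(n_agents = 2000, max_timesteps = 4000, seed = 8))
  oracle <- 100 * (1 - plnorm(0.2 + 1.25 / 20, dist$meanlog, dist$sdlog))
  expect_lt(abs(r$efficiency - oracle), 3)
  # passed agents: elapsed within one move of the budget; L_max scaling
  passed <- r$agents[r$agents$outcome == "passed", ]
  one_move <- 5e-4 / (passed$burst_speed - 0.2)
  expect_true(all(passed$elapsed_s <= 20 + one_move))
  expect_equal(passed$l_max, 1.25 * 20 / passed$ascent_s)
})

test_that("maximum pass length scales linearly with the time budget", {
  expect_equal(max_pass_length(10, 1.25, 20), 2.5)
  expect_equal(max_pass_length(20, 1.25, 20), 1.25)
  expect_equal(max_pass_length(40, 1.25, 20), 0.625)
  expect_error(max_pass_length(0), "positive")
})

test_that("IBM efficiency is monotone in water speed and median burst speed", {
  dist <- fit_lognormal(triple_log_symmetric())
  cfg <- ibm_config(n_agents = 400, max_timesteps = 2000, seed = 13)
  effs_u <- vapply(c(0.10, 0.20, 0.30, 0.40), function(u) {
    run_ibm(uniform_field(1000, 1, u), dist, cfg)$efficiency
  }, numeric(1))
  expect_true(all(diff(effs_u) <= 0))
  # higher median burst speed (same log spread) -> no worse
  effs_v <- vapply(c(0.25, 0.35, 0.45), function(v50) {
    d <- fit_lognormal(speed_quantiles(0.07, v50 / 1.5, v50, v50 * 1.5))
    run_ibm(uniform_field(1000, 1, 0.25), d, cfg)$efficiency
  }, numeric(1))
  expect_true(all(diff(effs_v) >= 0))
})

test_that("IBM with exhaustion never beats the median-threshold CA on open fields", {
  # near-critical uniform field: CA at the median threshold passes everyone,
  # the IBM loses the slow tail of the burst-speed distribution
  dist <- fit_lognormal(triple_log_symmetric())
  uf <- uniform_field(800, 3, 0.28)  # just under the 0.30 median
  ca <- run_ca(classify_field(uf, exp(dist$meanlog)),
               ca_config(n_agents = 300, seed = 6))
  ibm <- run_ibm(uf, dist, ibm_config(n_agents = 300, max_timesteps = 2000, seed = 6))
  expect_equal(ca$efficiency, 100)
  expect_lte(ibm$efficiency, ca$efficiency)
})

test_that("the compiled IBM engine matches the pure-R reference draw for draw", {
  set.seed(31)
  m <- matrix(runif(60, 0.15, 0.45), 12, 5)
  m[6, 3] <- NA
  f <- velocity_field(m)
  dist <- fit_lognormal(triple_log_symmetric())
  cfg <- ibm_config(n_agents = 12, max_timesteps = 300, seed = 17)
  expect_identical(run_ibm(f, dist, cfg)$agents,
                   run_ibm(f, dist, cfg, engine = "r")$agents)
  # and under the free-fallback switch
  cfg2 <- ibm_config(n_agents = 8, max_timesteps = 200, seed = 23,
                     fallback_time_mode = "free")
  expect_identical(run_ibm(f, dist, cfg2)$agents,
                   run_ibm(f, dist, cfg2, engine = "r")$agents)
})
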