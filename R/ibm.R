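#' Configuration for the individual-based passage model
#'
#' Extends [ca_config()] with the burst-endurance budget and the move-time
#' accounting switches.
#'
#' @inheritParams ca_config
#' @param burst_duration Total time (s) an elver can sustain burst swimming;
#'   the standard endurance budget is 20 s.
#' @param diagonal_factor Distance multiplier for diagonal moves (default
#'   `sqrt(2)`, the Euclidean centroid distance; set to 1 to charge all
#'   moves one cell).
#' @param fallback_time_mode `"assisted"` charges downstream (fall-back)
#'   moves `distance / (burst_speed + water_speed)`; `"free"` charges them
#'   nothing (sensitivity switch).
#' @return An object of class `eel_ibm_config` (also an `eel_ca_config`).
#' @export
ibm_config <- function(n_agents = 1000, max_timesteps = 10000,
                       stuck_window = 20, stuck_threshold = 2,
                       fallback_moves = 30, seed = 1L,
                       stuck_mode = c("rolling", "block"),
                       burst_duration = 20,
                       diagonal_factor = sqrt(2),
                       fallback_time_mode = c("assisted", "free")) {
  cfg <- ca_config(n_agents, max_timesteps, stuck_window, stuck_threshold,
                   fallback_moves, seed, stuck_mode)
  if (!is.numeric(burst_duration) || burst_duration <= 0) {
    abort("`burst_duration` must be positive (seconds).")
  }
  cfg$burst_duration <- as.numeric(burst_duration)
  cfg$diagonal_factor <- as.numeric(diagonal_factor)
  cfg$fallback_time_mode <- match.arg(fallback_time_mode)
  class(cfg) <- c("eel_ibm_config", class(cfg))
  cfg
}

#' Viable neighbour groups for an individual agent
#'
#' Same Moore-neighbourhood partition and priority as
#' [prioritized_neighbors()], but admissibility is per-agent: an upstream or
#' cross-stream destination is viable only when the agent's burst speed
#' strictly exceeds the water speed at the destination centroid
#' (equivalently, the cell is passable at threshold = that agent's burst
#' speed); downstream destinations need only be wet.
#'
#' @param pos Length-2 integer `c(i, j)`.
#' @param field An [velocity_field()].
#' @param burst_speed The agent's burst swimming speed (m/s).
#' @param mode `"normal"` or `"fallback"`.
#' @return Named list of (i, j) matrices in priority order.
#' @export
viable_neighbors <- function(pos, field, burst_speed,
                             mode = c("normal", "fallback")) {
  mode <- match.arg(mode)
  admissible <- function(ii, jj, up_or_cross) {
    u <- field$speed[ii, jj]
    if (is.na(u)) return(FALSE)
    if (up_or_cross) return(burst_speed - u > 0)
    TRUE
  }
  neighbor_groups(pos, field$grid, mode, admissible)
}

#' Time to make one move
#'
#' Upstream and cross-stream moves are made at the relative speed
#' `burst_speed - water_speed`; downstream (fall-back) moves are
#' flow-assisted at `burst_speed + water_speed`. Orthogonal moves cover one
#' cell, diagonal moves `sqrt(2)` cells.
#'
#' @param distance Move distance in metres.
#' @param burst_speed,water_speed Speeds in m/s; `water_speed` is the
#'   velocity magnitude at the destination centroid.
#' @param direction One of `"upstream"`, `"cross"`, `"downstream"`.
#' @return Move duration in seconds.
#' @export
#' @examples
#' move_time(5e-4, 0.3, 0.2, "upstream")  # 5 ms
move_time <- function(distance, burst_speed, water_speed,
                      direction = c("upstream", "cross", "downstream")) {
  direction <- match.arg(direction)
  if (direction == "downstream") {
    return(distance / (burst_speed + water_speed))
  }
  rel <- burst_speed - water_speed
  if (rel <= 0) {
    abort("Upstream/cross-stream move requires burst_speed > water_speed.")
  }
  distance / rel
}

#' Run the individual-based passage model
#'
#' Each agent is assigned a burst swimming speed once at creation (a
#' lognormal draw), then moves under the CA mechanics with per-agent
#' viability, accruing the time of every move; an agent whose accumulated
#' swim time exceeds the burst-endurance budget is `exhausted`, one still
#' inside the domain at the timestep cap is `timed_out`, and one reaching
#' the upstream edge is `passed` (its ascent time is recorded and converted
#' to a maximum ascendable pass length). Deterministic given `config$seed`.
#'
#' @param field An [velocity_field()].
#' @param dist An `eel_burst_dist` from [fit_lognormal()].
#' @param config An [ibm_config()].
#' @param engine `"cpp"` (default) or `"r"` (reference; same seed, same
#'   result).
#' @return An `eel_passage_result` whose agents carry `burst_speed`,
#'   `elapsed_s`, `ascent_s` (passed agents) and `l_max` (0 for failures).
#' @export
run_ibm <- function(field, dist, config = ibm_config(),
                    engine = c("cpp", "r")) {
  stopifnot(inherits(field, "eel_velocity_field"),
            inherits(dist, "eel_burst_dist"))
  if (!inherits(config, "eel_ibm_config")) {
    abort("`config` must come from ibm_config().")
  }
  engine <- match.arg(engine)
  set.seed(config$seed)
  if (engine == "cpp") {
    raw <- ibm_engine_cpp(
      field$speed, config$n_agents, config$max_timesteps,
      config$stuck_window, config$stuck_threshold, config$fallback_moves,
      config$stuck_mode == "block",
      dist$meanlog, dist$sdlog,
      config$burst_duration, field$grid$cell_size, config$diagonal_factor,
      config$fallback_time_mode == "assisted"
    )
  } else {
    raw <- ibm_engine_r(field, dist, config)
  }
  sim_length <- field$grid$n_streamwise * field$grid$cell_size
  outcome <- c("active", "passed", "timed_out", "exhausted")[raw$outcome + 1L]
  ascent <- ifelse(outcome == "passed", raw$elapsed, NA_real_)
  l_max <- numeric(config$n_agents)
  ok <- outcome == "passed" & !is.na(ascent) & ascent > 0
  l_max[ok] <- max_pass_length(ascent[ok], sim_length, config$burst_duration)
  agents <- tibble::tibble(
    id = seq_len(config$n_agents),
    outcome = outcome,
    moves = raw$moves,
    spawn_j = raw$spawn_j,
    final_i = raw$final_i,
    final_j = raw$final_j,
    burst_speed = raw$burst,
    elapsed_s = raw$elapsed,
    ascent_s = ascent,
    l_max = l_max
  )
  new_passage_result(agents, model = "ibm", config = config,
                     scenario = list(
                       grid = field$grid,
                       angle_deg = field$angle_deg, q_m2s = field$q_m2s,
                       meanlog = dist$meanlog, sdlog = dist$sdlog,
                       sim_length = sim_length
                     ))
}

# pure-R reference engine; consumes the same RNG stream as ibm_engine_cpp
ibm_engine_r <- function(field, dist, config) {
  n <- config$n_agents
  g <- field$grid
  out <- list(outcome = integer(n), moves = integer(n), spawn_j = integer(n),
              elapsed = numeric(n), burst = numeric(n),
              final_i = integer(n), final_j = integer(n))
  open <- which(!is.na(field$speed[g$n_streamwise, ]))
  if (length(open) == 0L) abort("Downstream edge is entirely boundary; nowhere to spawn.")
  for (a in seq_len(n)) {
    j <- open[min(floor(runif(1L) * length(open)) + 1L, length(open))]
    v <- rlnorm(1L, dist$meanlog, dist$sdlog)
    agent <- new_agent(c(g$n_streamwise, j))
    agent$burst_speed <- v
    out$spawn_j[a] <- j
    if (agent$i == 1L) agent$outcome <- "passed"
    t <- 0L
    while (agent$outcome == "active" && t < config$max_timesteps) {
      groups <- viable_neighbors(
        c(agent$i, agent$j), field, v,
        mode = if (agent$mode == "normal") "normal" else "fallback"
      )
      agent <- apply_move(agent, groups)
      if (agent$i != agent$prev_i || agent$j != agent$prev_j) {
        diag <- agent$i != agent$prev_i && agent$j != agent$prev_j
        dist_m <- g$cell_size * if (diag) config$diagonal_factor else 1
        u <- field$speed[agent$i, agent$j]
        if (agent$moved_down) {
          if (config$fallback_time_mode == "assisted") {
            agent$elapsed <- agent$elapsed + move_time(dist_m, v, u, "downstream")
          }
        } else {
          dir <- if (agent$i < agent$prev_i) "upstream" else "cross"
          agent$elapsed <- agent$elapsed + move_time(dist_m, v, u, dir)
        }
      }
      if (agent$i == 1L) {
        agent$outcome <- "passed"
      } else if (agent$elapsed > config$burst_duration) {
        agent$outcome <- "exhausted"
      } else {
        agent <- update_stuck_state(agent, config)
      }
      t <- t + 1L
    }
    out$outcome[a] <- switch(agent$outcome,
                             passed = 1L, exhausted = 3L, 2L)
    out$moves[a] <- agent$moves
    out$elapsed[a] <- agent$elapsed
    out$burst[a] <- v
    out$final_i[a] <- agent$i
    out$final_j[a] <- agent$j
  }
  out
}

#' Maximum ascendable pass length from a simulated ascent time
#'
#' Flow conditions are approximately uniform along the pass, so the
#' maximum pass length an agent could ascend before exhausting its burst
#' budget scales linearly:
#' `L_max = simulated_length * burst_duration / ascent_time`.
#'
#' @param ascent_time Simulated ascent time(s) in seconds (> 0).
#' @param simulated_length Length of the simulated pass in metres.
#' @param burst_duration Burst-endurance budget in seconds (default 20).
#' @return Maximum pass length(s) in metres.
#' @export
#' @examples
#' max_pass_length(10, 1.25)  # 2.5 m
max_pass_length <- function(ascent_time, simulated_length = 1.25,
                            burst_duration = 20) {
  if (any(ascent_time <= 0)) abort("`ascent_time` must be positive.")
  simulated_length * burst_duration / ascent_time
}
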