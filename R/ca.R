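#' Configuration for the cellular-automata passage model
#'
#' Defaults follow the published sensitivity analyses: 1000 automata, a cap
#' of 10,000 timesteps, stuck detection over a 20-move window with a 2-cell
#' net-progress threshold, and 30 forced fall-back moves.
#'
#' @param n_agents Number of automata spawned.
#' @param max_timesteps Simulation cap; agents still inside the domain at
#'   the cap are failed passages (`timed_out`).
#' @param stuck_window Number of trailing moves over which net streamwise
#'   progress is assessed.
#' @param stuck_threshold An agent whose net progress toward the upstream
#'   edge over `stuck_window` moves is `<=` this many cells is stuck.
#' @param fallback_moves Number of forced fall-back moves once stuck.
#' @param seed Integer seed; every run is deterministic given the seed.
#' @param stuck_mode `"rolling"` assesses the stuck rule every move once the
#'   window is full; `"block"` assesses it in disjoint 20-move blocks
#'   (provided for sensitivity studies).
#' @return An object of class `eel_ca_config`.
#' @export
ca_config <- function(n_agents = 1000, max_timesteps = 10000,
                      stuck_window = 20, stuck_threshold = 2,
                      fallback_moves = 30, seed = 1L,
                      stuck_mode = c("rolling", "block")) {
  stuck_mode <- match.arg(stuck_mode)
  cfg <- list(
    n_agents = as.integer(n_agents),
    max_timesteps = as.integer(max_timesteps),
    stuck_window = as.integer(stuck_window),
    stuck_threshold = as.integer(stuck_threshold),
    fallback_moves = as.integer(fallback_moves),
    seed = as.integer(seed),
    stuck_mode = stuck_mode
  )
  if (any(unlist(cfg[1:5]) <= 0L)) abort("All counts must be positive.")
  if (cfg$stuck_threshold >= cfg$stuck_window) {
    abort("`stuck_threshold` must be smaller than `stuck_window`.")
  }
  structure(cfg, class = "eel_ca_config")
}

#' Spawn agents on the downstream edge
#'
#' Positions are drawn uniformly with replacement from the non-boundary
#' cells of the downstream-most row. Agents never interact, so coincident
#' spawns are allowed.
#'
#' @param cf An `eel_classified_field` (or velocity field for the IBM,
#'   where any wetted cell is spawnable).
#' @param n Number of agents.
#' @param seed Optional seed applied before drawing.
#' @return Tibble with columns `i` (always the downstream row) and `j`.
#' @export
spawn_agents <- function(cf, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(cf, "eel_classified_field")) {
    open <- which(cf$class[cf$grid$n_streamwise, ] != CLASS_BOUNDARY)
  } else if (inherits(cf, "eel_velocity_field")) {
    open <- which(!is.na(cf$speed[cf$grid$n_streamwise, ]))
  } else {
    abort("`cf` must be a classified or velocity field.")
  }
  if (length(open) == 0L) {
    abort("Downstream edge is entirely boundary; nowhere to spawn.")
  }
  idx <- pmin(floor(runif(n) * length(open)) + 1L, length(open))
  tibble::tibble(i = rep(cf$grid$n_streamwise, n), j = open[idx])
}

#' Prioritised Moore-neighbourhood groups around a position
#'
#' The eight first-order Moore neighbours are partitioned by streamwise
#' offset into upstream (3 cells), cross-stream (2) and downstream (3)
#' groups; off-grid, boundary and impassable cells are removed. In normal
#' mode the group priority is upstream, cross-stream, downstream; in
#' fall-back mode the order reverses.
#'
#' @param pos Length-2 integer `c(i, j)`.
#' @param cf An `eel_classified_field`.
#' @param mode `"normal"` or `"fallback"`.
#' @return Named list of (i, j) matrices in priority order.
#' @export
prioritized_neighbors <- function(pos, cf, mode = c("normal", "fallback")) {
  mode <- match.arg(mode)
  admissible <- function(ii, jj, up_or_cross) {
    cf$class[ii, jj] == CLASS_PASSABLE
  }
  neighbor_groups(pos, cf$grid, mode, admissible)
}

# shared group construction for CA (class test) and IBM (per-agent test)
neighbor_groups <- function(pos, grid, mode, admissible) {
  i <- pos[[1L]]
  j <- pos[[2L]]
  stopifnot(i >= 1L, i <= grid$n_streamwise, j >= 1L, j <= grid$n_spanwise)
  one <- function(di) {
    ii <- i + di
    if (ii < 1L || ii > grid$n_streamwise) {
      return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
    }
    djs <- if (di == 0L) c(-1L, 1L) else -1:1
    out <- NULL
    for (dj in djs) {
      jj <- j + dj
      if (jj < 1L || jj > grid$n_spanwise) next
      if (!admissible(ii, jj, di <= 0L)) next
      out <- rbind(out, c(ii, jj))
    }
    if (is.null(out)) out <- matrix(integer(0), 0L, 2L)
    colnames(out) <- c("i", "j")
    out
  }
  groups <- list(upstream = one(-1L), cross = one(0L), downstream = one(1L))
  if (mode == "fallback") groups <- rev(groups)
  groups
}

# fresh agent record at a spawn position
new_agent <- function(pos) {
  list(
    i = as.integer(pos[[1L]]), j = as.integer(pos[[2L]]),
    mode = "normal", fallback_left = 0L,
    hist = as.integer(pos[[1L]]),  # streamwise positions since last reset
    moves = 0L, outcome = "active",
    burst_speed = NA_real_, elapsed = 0
  )
}

#' Advance one agent by one move
#'
#' Selects the destination uniformly at random from the highest-priority
#' non-empty neighbour group (consuming one uniform draw); if every group is
#' empty the agent stays put and the move is still counted. Stuck and
#' fall-back bookkeeping is then applied via [update_stuck_state()].
#'
#' @param agent An agent record (internally created; see [run_ca()]).
#' @param cf An `eel_classified_field`.
#' @param config An [ca_config()].
#' @return The updated agent record.
#' @export
step_agent <- function(agent, cf, config = ca_config()) {
  groups <- prioritized_neighbors(
    c(agent$i, agent$j), cf,
    mode = if (agent$mode == "normal") "normal" else "fallback"
  )
  agent <- apply_move(agent, groups)
  if (agent$i == 1L) {
    agent$outcome <- "passed"
    return(agent)
  }
  update_stuck_state(agent, config)
}

# destination choice shared by CA and IBM reference paths; one runif draw
# iff some group is non-empty (parity with the compiled engine)
apply_move <- function(agent, groups) {
  for (g in groups) {
    k <- nrow(g)
    if (k > 0L) {
      c_idx <- min(floor(runif(1L) * k) + 1L, k)
      agent$moved_down <- g[c_idx, "i"] > agent$i
      agent$prev_i <- agent$i
      agent$prev_j <- agent$j
      agent$i <- as.integer(g[c_idx, "i"])
      agent$j <- as.integer(g[c_idx, "j"])
      agent$moves <- agent$moves + 1L
      return(agent)
    }
  }
  agent$moved_down <- FALSE
  agent$prev_i <- agent$i
  agent$prev_j <- agent$j
  agent$moves <- agent$moves + 1L
  agent
}

#' Apply the stuck / fall-back rules after a move
#'
#' In normal mode, once the trailing window holds `stuck_window` moves, an
#' agent whose net streamwise progress toward the upstream edge is
#' `<= stuck_threshold` cells switches to fall-back mode for exactly
#' `fallback_moves` moves (during which the assessment is suspended); on
#' exit the window buffer resets so the agent has a full window to re-route
#' before it can be flagged again.
#'
#' @inheritParams step_agent
#' @return The updated agent record.
#' @export
update_stuck_state <- function(agent, config = ca_config()) {
  if (agent$mode == "fallback") {
    agent$fallback_left <- agent$fallback_left - 1L
    if (agent$fallback_left == 0L) {
      agent$mode <- "normal"
      agent$hist <- agent$i
    }
    return(agent)
  }
  agent$hist <- c(agent$hist, agent$i)
  count <- length(agent$hist) - 1L
  w <- config$stuck_window
  if (count >= w) {
    assess <- if (config$stuck_mode == "block") count == w else TRUE
    if (assess) {
      i_old <- agent$hist[[length(agent$hist) - w]]
      if (i_old - agent$i <= config$stuck_threshold) {
        agent$mode <- "fallback"
        agent$fallback_left <- config$fallback_moves
      } else if (config$stuck_mode == "block") {
        agent$hist <- agent$i
      }
    }
  }
  agent
}

#' Run the cellular-automata passage model
#'
#' Simulates `n_agents` independent automata on a classified field, each
#' from a random downstream-edge spawn to either the upstream edge
#' (`passed`) or the timestep cap (`timed_out`). Efficiency is the
#' percentage of automata that passed. Deterministic given `config$seed`.
#'
#' @param cf An `eel_classified_field`.
#' @param config An [ca_config()].
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference
#'   built from [step_agent()]; identical results for the same seed).
#' @return An `eel_passage_result`; see [tidy()] / [glance()] methods.
#' @export
#' @examples
#' f <- velocity_field(matrix(0.2, 30, 8))
#' res <- run_ca(classify_field(f, 0.3), ca_config(n_agents = 50))
#' glance(res)
run_ca <- function(cf, config = ca_config(), engine = c("cpp", "r")) {
  stopifnot(inherits(cf, "eel_classified_field"))
  engine <- match.arg(engine)
  set.seed(config$seed)
  if (engine == "cpp") {
    raw <- ca_engine_cpp(
      cf$class, config$n_agents, config$max_timesteps,
      config$stuck_window, config$stuck_threshold, config$fallback_moves,
      config$stuck_mode == "block"
    )
  } else {
    raw <- ca_engine_r(cf, config)
  }
  agents <- tibble::tibble(
    id = seq_len(config$n_agents),
    outcome = c("active", "passed", "timed_out")[raw$outcome + 1L],
    moves = raw$moves,
    spawn_j = raw$spawn_j,
    final_i = raw$final_i,
    final_j = raw$final_j
  )
  new_passage_result(agents, model = "ca", config = config,
                     scenario = list(threshold = cf$threshold,
                                     grid = cf$grid))
}

# pure-R reference engine; consumes the same RNG stream as ca_engine_cpp
ca_engine_r <- function(cf, config) {
  n <- config$n_agents
  out <- list(outcome = integer(n), moves = integer(n), spawn_j = integer(n),
              final_i = integer(n), final_j = integer(n))
  open <- which(cf$class[cf$grid$n_streamwise, ] != CLASS_BOUNDARY)
  if (length(open) == 0L) abort("Downstream edge is entirely boundary; nowhere to spawn.")
  for (a in seq_len(n)) {
    j <- open[min(floor(runif(1L) * length(open)) + 1L, length(open))]
    agent <- new_agent(c(cf$grid$n_streamwise, j))
    out$spawn_j[a] <- j
    if (agent$i == 1L) agent$outcome <- "passed"
    t <- 0L
    while (agent$outcome == "active" && t < config$max_timesteps) {
      agent <- step_agent(agent, cf, config)
      t <- t + 1L
    }
    out$outcome[a] <- switch(agent$outcome, passed = 1L, active = 2L, 2L)
    out$moves[a] <- agent$moves
    out$final_i[a] <- agent$i
    out$final_j[a] <- agent$j
  }
  out
}

# shared result container ---------------------------------------------------

new_passage_result <- function(agents, model, config, scenario) {
  n_passed <- sum(agents$outcome == "passed")
  structure(
    list(
      agents = agents,
      model = model,
      n_agents = nrow(agents),
      n_passed = n_passed,
      efficiency = 100 * n_passed / nrow(agents),
      config = config,
      scenario = scenario
    ),
    class = "eel_passage_result"
  )
}

#' @export
print.eel_passage_result <- function(x, ...) {
  cat(sprintf(
    "<eel_passage_result> %s model: %d/%d agents passed (efficiency %.1f%%)\n",
    toupper(x$model), x$n_passed, x$n_agents, x$efficiency
  ))
  invisible(x)
}
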