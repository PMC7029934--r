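#' Run the full passage pipeline for one scenario
#'
#' Generates (or loads) the near-bed velocity field, classifies it when the
#' CA model is requested, runs the movement model and returns the result
#' bundle, optionally writing grid files, the per-agent CSV and a summary
#' JSON. Identical config and seed give byte-identical CSV/JSON payloads.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   `angle_deg`, `q_m2s` (scenario); `model` (`"ca"` or `"ibm"`);
#'   `elver_length` (m) and `percentile` (10/50/90, CA threshold choice);
#'   optional `length_m`, `width_m`, `grid_file` (load instead of
#'   generate), `speed_table` (path), `n_agents`, `max_timesteps`,
#'   `stuck_window`, `stuck_threshold`, `fallback_moves`, `burst_duration`,
#'   `seed`, `out_dir`.
#' @return List with `field`, `depth`, `classified` (CA only), `result`
#'   (an `eel_passage_result`) and `summary` (one-row tibble).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  model <- match.arg(cfg$model %||% "ibm", c("ca", "ibm"))
  seed <- as.integer(cfg$seed %||% 1L)
  elver_length <- cfg$elver_length %||% 0.07
  percentile <- cfg$percentile %||% 50

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  if (!is.null(cfg$grid_file)) {
    field <- stage("load-field", read_grid(cfg$grid_file))
    depth <- NULL
  } else {
    scn <- stage("scenario", flow_scenario(
      angle_deg = cfg$angle_deg, q_m2s = cfg$q_m2s,
      length_m = cfg$length_m %||% 1.25,
      width_m = cfg$width_m %||% 4.5e-2,
      seed = seed
    ))
    gen <- stage("synth-field", generate_field(scn))
    field <- gen$velocity
    depth <- gen$depth
  }

  table <- stage("speed-table", read_speed_table(cfg$speed_table))

  run_args <- cfg[names(cfg) %in% c(
    "n_agents", "max_timesteps", "stuck_window", "stuck_threshold",
    "fallback_moves", "stuck_mode", "burst_duration", "diagonal_factor",
    "fallback_time_mode"
  )]

  classified <- NULL
  if (model == "ca") {
    thr <- stage("threshold",
                 quantiles_for_length(table, elver_length, percentile))
    classified <- stage("classify", classify_field(field, thr))
    ca_cfg <- do.call(ca_config, c(
      run_args[names(run_args) %in% names(formals(ca_config))],
      list(seed = seed)
    ))
    result <- stage("run-ca", run_ca(classified, ca_cfg))
  } else {
    dist <- stage("fit-speeds", burst_dist_for_length(table, elver_length))
    ibm_cfg <- do.call(ibm_config, c(run_args, list(seed = seed)))
    result <- stage("run-ibm", run_ibm(field, dist, ibm_cfg))
  }
  result$scenario$elver_length <- elver_length
  result$scenario$percentile <- percentile
  result$scenario$angle_deg <- result$scenario$angle_deg %||%
    cfg$angle_deg %||% field$angle_deg
  result$scenario$q_m2s <- result$scenario$q_m2s %||%
    cfg$q_m2s %||% field$q_m2s

  summary <- glance(result)
  summary$angle_deg <- result$scenario$angle_deg
  summary$q_m2s <- result$scenario$q_m2s
  summary$elver_length <- elver_length

  if (!is.null(cfg$out_dir)) {
    stage("write-outputs", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_grid(field, file.path(cfg$out_dir, "velocity.grid"))
      if (!is.null(depth)) write_grid(depth, file.path(cfg$out_dir, "depth.grid"))
      if (!is.null(classified)) {
        write_grid(classified, file.path(cfg$out_dir, "classified.grid"))
      }
      utils::write.csv(tidy(result), file.path(cfg$out_dir, "agents.csv"),
                       row.names = FALSE)
      echo <- cfg[setdiff(names(cfg), "out_dir")]  # payload independent of destination
      payload <- list(
        summary = as.list(summary),
        config = echo[order(names(echo))],
        seed = seed
      )
      jsonlite::write_json(payload, file.path(cfg$out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  list(field = field, depth = depth, classified = classified,
       result = result, summary = summary)
}

#' Sweep scenarios over angles, discharges and elver lengths
#'
#' Runs one pipeline per combination and aggregates the summaries and the
#' per-agent maximum pass lengths into the long table behind a design
#' chart.
#'
#' @param angles Installation angles in degrees.
#' @param discharges Unit discharges in m^2/s.
#' @param elver_lengths Elver body lengths in m.
#' @param model `"ibm"` (default) or `"ca"`.
#' @param base_config Named list of additional [run_pipeline()] entries
#'   shared by every run (agent counts, pass length, seed, ...).
#' @return List with `summaries` (one row per scenario), `l_max` (long
#'   tibble of per-agent maximum pass lengths, IBM only), `results`
#'   (the `eel_passage_result` objects) and `failures` (tibble of
#'   scenarios whose run errored, with the message).
#' @export
sweep_scenarios <- function(angles, discharges, elver_lengths,
                            model = "ibm", base_config = list()) {
  grid <- expand.grid(angle_deg = angles, q_m2s = discharges,
                      elver_length = elver_lengths, KEEP.OUT.ATTRS = FALSE)
  results <- vector("list", nrow(grid))
  summaries <- vector("list", nrow(grid))
  failures <- list()
  for (k in seq_len(nrow(grid))) {
    cfg <- utils::modifyList(base_config, c(as.list(grid[k, ]), model = model))
    run <- tryCatch(run_pipeline(cfg), error = identity)
    if (inherits(run, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        angle_deg = grid$angle_deg[k], q_m2s = grid$q_m2s[k],
        elver_length = grid$elver_length[k],
        error = conditionMessage(run)
      )
      next
    }
    results[[k]] <- run$result
    summaries[[k]] <- run$summary
  }
  keep <- !vapply(results, is.null, logical(1))
  l_max <- NULL
  if (model == "ibm" && any(keep)) {
    l_max <- purrr::map_dfr(results[keep], function(r) {
      tibble::tibble(
        angle_deg = r$scenario$angle_deg, q_m2s = r$scenario$q_m2s,
        elver_length = r$scenario$elver_length,
        l_max = r$agents$l_max
      )
    })
  }
  list(
    summaries = dplyr::bind_rows(summaries),
    l_max = l_max,
    results = results[keep],
    failures = dplyr::bind_rows(failures)
  )
}
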