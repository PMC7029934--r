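#' Passage efficiency from observed attempt counts
#'
#' Efficiency is successes divided by attempts, as a percentage. Field
#' observations sometimes log attempts at the centre of the pass that
#' cannot be assigned to a stud type and carry no successes; with
#' `reallocate = TRUE` half of those unassigned attempts are added to the
#' denominator (the even-split convention).
#'
#' Counts may be fractional, since reported values are means over trials.
#'
#' @param successes,attempts Assigned success and attempt counts.
#' @param unassigned_attempts Attempts not assigned to this stud type
#'   (default 0).
#' @param reallocate Add half of `unassigned_attempts` to the denominator.
#' @return Efficiency in percent (full precision; round for display).
#' @export
#' @examples
#' efficiency_from_counts(11.7, 14.1)                    # 83.0
#' efficiency_from_counts(11.7, 14.1, 3.5, reallocate = TRUE)  # 73.8
efficiency_from_counts <- function(successes, attempts,
                                   unassigned_attempts = 0,
                                   reallocate = FALSE) {
  if (any(c(successes, attempts, unassigned_attempts) < 0)) {
    abort("Counts must be non-negative.")
  }
  denom <- attempts + if (reallocate) unassigned_attempts / 2 else 0
  if (denom <= 0) abort("Attempts must be positive.")
  100 * successes / denom
}

#' Unit discharge from mean velocity and depth
#'
#' @param mean_velocity Mean inflow velocity (m/s).
#' @param depth Flow depth (m).
#' @return Discharge per unit width, m^2/s.
#' @export
#' @examples
#' unit_discharge(8.0e-3, 0.278)  # 2.22e-3
unit_discharge <- function(mean_velocity, depth) {
  if (any(c(mean_velocity, depth) < 0)) abort("Inputs must be non-negative.")
  mean_velocity * depth
}

#' Flow depth at the pass entrance from a weir rating
#'
#' Design helper inverting the weir rating `q = alpha * (y_b + h)^(3/2)`:
#' `h = (q/alpha)^(2/3) - y_b`. A negative result means the pass entrance
#' sits above the water line for that discharge.
#'
#' @param q Unit discharge (m^2/s, >= 0).
#' @param alpha Weir coefficient (> 0).
#' @param crest_elevation Elevation `y_b` of the pass entrance at the weir
#'   crest (m).
#' @return List with `depth` (m) and `submerged` (logical; `FALSE` when the
#'   entrance is above the water line).
#' @export
weir_entrance_depth <- function(q, alpha, crest_elevation = 0) {
  if (q < 0 || alpha <= 0) abort("Need q >= 0 and alpha > 0.")
  h <- (q / alpha)^(2 / 3) - crest_elevation
  list(depth = h, submerged = h >= 0)
}

#' Design-chart table: pass length against angle at target efficiencies
#'
#' For each scenario the per-agent maximum ascendable pass lengths (failed
#' agents contribute `L_max = 0`) are interrogated at the target
#' efficiencies: the pass length achieving efficiency `e` is the largest
#' length that at least `e`% of agents could ascend, i.e. the upper
#' `e`-percent point of the L_max distribution.
#'
#' @param results List of `eel_passage_result` objects from [run_ibm()]
#'   (each carrying scenario metadata), or a long tibble with columns
#'   `angle_deg`, `q_m2s`, `elver_length`, `l_max`.
#' @param targets Target efficiencies in percent (default `c(40, 60, 80)`).
#' @return A tibble of class `eel_design_chart` with columns `angle_deg`,
#'   `q_m2s`, `elver_length`, `target_pct`, `pass_length_m`.
#' @export
design_chart <- function(results, targets = c(40, 60, 80)) {
  if (length(results) == 0L) abort("`results` is empty.")
  if (inherits(results, "eel_passage_result")) results <- list(results)
  if (is.data.frame(results)) {
    tab <- tibble::as_tibble(results)
  } else {
    tab <- purrr::map_dfr(results, function(r) {
      if (!"l_max" %in% names(r$agents)) {
        abort("Results must carry per-agent l_max (run the IBM).")
      }
      tibble::tibble(
        angle_deg = r$scenario$angle_deg %||% NA_real_,
        q_m2s = r$scenario$q_m2s %||% NA_real_,
        elver_length = r$scenario$elver_length %||% NA_real_,
        l_max = r$agents$l_max
      )
    })
  }
  out <- tab |>
    dplyr::group_by(.data$angle_deg, .data$q_m2s, .data$elver_length) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        target_pct = targets,
        pass_length_m = vapply(targets, function(e) upper_quantile(d$l_max, e),
                               numeric(1))
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("eel_design_chart", class(out))
  out
}

# largest L with at least pct% of values >= L (descending order statistic);
# pct above the pass rate correctly returns 0 because failures carry L = 0
upper_quantile <- function(x, pct) {
  n <- length(x)
  k <- ceiling(n * pct / 100)
  if (k < 1L) k <- 1L
  if (k > n) return(0)
  sort(x, decreasing = TRUE)[k]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
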