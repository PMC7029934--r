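#' Burst-swimming-speed quantile triple
#'
#' Median, 10th and 90th percentile burst swimming speeds for elvers of a
#' given body length. Swimming-performance models report these quantiles per
#' length (and season/temperature); they are the only published summary of
#' the burst-speed distribution, so the package fits a lognormal to them.
#'
#' @param elver_length Body length in metres.
#' @param q10,q50,q90 10th/50th/90th percentile burst speeds (m/s), with
#'   `0 < q10 <= q50 <= q90`.
#' @param season,temperature_c Optional metadata.
#' @return A one-row tibble of class `eel_speed_quantiles`.
#' @export
speed_quantiles <- function(elver_length, q10, q50, q90,
                            season = NA_character_, temperature_c = NA_real_) {
  if (!(q10 > 0 && q10 <= q50 && q50 <= q90)) {
    abort("Quantiles must satisfy 0 < q10 <= q50 <= q90.")
  }
  out <- tibble::tibble(
    elver_length = as.numeric(elver_length),
    q10 = as.numeric(q10), q50 = as.numeric(q50), q90 = as.numeric(q90),
    season = season, temperature_c = temperature_c
  )
  class(out) <- c("eel_speed_quantiles", class(out))
  out
}

# standard-normal 90th percentile used throughout the quantile fit
Z90 <- qnorm(0.9)

#' Fit a lognormal burst-speed distribution to a quantile triple
#'
#' A lognormal has two parameters but the triple supplies three constraints,
#' so the fit pins the log-median (`meanlog = log(q50)`) and takes `sdlog`
#' as the least-squares compromise between the two one-sided tail
#' estimates:
#' `sdlog = ((log(q90) - log(q50)) + (log(q50) - log(q10))) / (2 * qnorm(0.9))`.
#' For a log-symmetric triple this reproduces all three quantiles exactly.
#'
#' @param q A [speed_quantiles()] row (or anything with `q10`, `q50`, `q90`).
#' @return An object of class `eel_burst_dist` with fields `meanlog`,
#'   `sdlog`, and `fitted` (the fitted 10/50/90 quantiles for inspection).
#' @export
#' @examples
#' fit_lognormal(speed_quantiles(0.07, 0.20, 0.30, 0.45))
fit_lognormal <- function(q) {
  if (!(q$q10 > 0 && q$q10 <= q$q50 && q$q50 <= q$q90)) {
    abort("Quantiles must satisfy 0 < q10 <= q50 <= q90.")
  }
  meanlog <- log(q$q50)
  sdlog <- ((log(q$q90) - log(q$q50)) + (log(q$q50) - log(q$q10))) / (2 * Z90)
  structure(
    list(
      meanlog = meanlog,
      sdlog = sdlog,
      fitted = c(
        q10 = qlnorm(0.1, meanlog, sdlog),
        q50 = exp(meanlog),
        q90 = qlnorm(0.9, meanlog, sdlog)
      ),
      source = q
    ),
    class = "eel_burst_dist"
  )
}

#' @export
print.eel_burst_dist <- function(x, ...) {
  cat(sprintf(
    "<eel_burst_dist> meanlog %.4f (median %.3f m/s), sdlog %.4f\n",
    x$meanlog, exp(x$meanlog), x$sdlog
  ))
  cat(sprintf("fitted q10/q50/q90: %.3f / %.3f / %.3f m/s\n",
              x$fitted[1L], x$fitted[2L], x$fitted[3L]))
  invisible(x)
}

#' Sample burst swimming speeds
#'
#' Independent lognormal draws from a fitted burst-speed distribution, one
#' per agent. Reproducible under [set.seed()].
#'
#' @param dist An `eel_burst_dist` from [fit_lognormal()].
#' @param n Number of draws (>= 1).
#' @param seed Optional integer seed applied before drawing.
#' @return Numeric vector of length `n` (m/s).
#' @export
sample_speeds <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "eel_burst_dist"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (dist$sdlog == 0) return(rep(exp(dist$meanlog), n))
  rlnorm(n, dist$meanlog, dist$sdlog)
}

#' Interpolate a burst-speed quantile at an arbitrary elver length
#'
#' Linear interpolation of the requested percentile between the bracketing
#' tabulated lengths. No extrapolation: lengths outside the table's range
#' are an error, since burst-speed scaling beyond the measured size range is
#' not defensible.
#'
#' @param table Data frame of quantile rows (columns `elver_length`, `q10`,
#'   `q50`, `q90`), e.g. from [read_speed_table()].
#' @param length Elver body length in metres.
#' @param percentile One of 10, 50, 90.
#' @return Interpolated speed in m/s.
#' @export
quantiles_for_length <- function(table, length, percentile = 50) {
  table <- as.data.frame(table)
  col <- switch(as.character(percentile),
    "10" = "q10", "50" = "q50", "90" = "q90",
    abort("`percentile` must be 10, 50 or 90.")
  )
  rng <- range(table$elver_length)
  if (length < rng[1L] || length > rng[2L]) {
    abort(sprintf(
      "Length %.3g m is outside the tabulated range [%.3g, %.3g] m; no extrapolation.",
      length, rng[1L], rng[2L]
    ))
  }
  approx(table$elver_length, table[[col]], xout = length, ties = "ordered")$y
}

#' Fit the burst-speed distribution for a given elver length
#'
#' Convenience wrapper: interpolates all three quantiles at `length` and
#' fits the lognormal.
#'
#' @inheritParams quantiles_for_length
#' @return An `eel_burst_dist`.
#' @export
burst_dist_for_length <- function(table, length) {
  fit_lognormal(list(
    q10 = quantiles_for_length(table, length, 10),
    q50 = quantiles_for_length(table, length, 50),
    q90 = quantiles_for_length(table, length, 90)
  ))
}

#' Read a burst-speed quantile table
#'
#' Delimited text with columns `length_m`, `q10`, `q50`, `q90` and optional
#' `season`, `temperature_C`. The table shipped with the package
#' (`system.file("extdata", "burst_speed_quantiles_synthetic.tsv",
#' package = "eelpass")`) contains synthetic placeholder values, clearly
#' marked non-biological; replace it with licensed swimming-performance
#' output for real assessments.
#'
#' @param path Path to the table; defaults to the shipped synthetic table.
#' @return A tibble with columns `elver_length`, `q10`, `q50`, `q90`,
#'   `season`, `temperature_c`, sorted by length.
#' @export
read_speed_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "burst_speed_quantiles_synthetic.tsv",
                        package = "eelpass")
  }
  raw <- utils::read.delim(path, comment.char = "#", strip.white = TRUE)
  need <- c("length_m", "q10", "q50", "q90")
  if (!all(need %in% names(raw))) {
    abort(sprintf("Speed table %s must have columns %s.", path,
                  paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    elver_length = raw$length_m,
    q10 = raw$q10, q50 = raw$q50, q90 = raw$q90,
    season = if ("season" %in% names(raw)) raw$season else NA_character_,
    temperature_c = if ("temperature_C" %in% names(raw)) raw$temperature_C else NA_real_
  )
  bad <- !(out$q10 > 0 & out$q10 <= out$q50 & out$q50 <= out$q90)
  if (any(bad)) abort("Speed table rows violate 0 < q10 <= q50 <= q90.")
  dplyr::arrange(out, .data$elver_length)
}
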