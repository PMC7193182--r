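#' Construct a head impulse trace
#'
#' A head impulse is a uniformly sampled head angular-velocity record, the
#' rotating-frame forcing of the whole pipeline. vHIT devices sample at
#' 250 Hz (0.004 s per frame) and record 0.7 s per impulse; velocities are
#' in degrees per second.
#'
#' @param velocity_dps numeric vector of head angular velocity, deg/s.
#' @param sample_interval sampling interval in seconds (default 0.004).
#' @param side impulse side, `"right"` or `"left"`. The gain conventions of
#'   this package apply to right-side impulses.
#' @param label free-text label carried through reports.
#' @return A tibble of class `head_impulse` with columns `time_s` (half-open
#'   grid `0, dt, ..., (n-1) dt`) and `velocity_dps`, plus attributes
#'   `sample_interval`, `side`, `label`.
#' @export
#' @examples
#' imp <- head_impulse(rep(0, 175))
#' impulse_duration(imp)
head_impulse <- function(velocity_dps, sample_interval = 0.004,
                         side = c("right", "left"), label = "") {
  side <- match.arg(side)
  check_positive_scalar(sample_interval, "sample_interval")
  if (length(velocity_dps) < 1 || any(!is.finite(velocity_dps))) {
    abort_validation("`velocity_dps` must be non-empty and finite throughout.")
  }
  n <- length(velocity_dps)
  out <- tibble(
    time_s = (seq_len(n) - 1) * sample_interval,
    velocity_dps = as.numeric(velocity_dps)
  )
  structure(out,
    class = c("head_impulse", class(out)),
    sample_interval = sample_interval,
    side = side,
    label = label
  )
}

#' @rdname head_impulse
#' @param imp a `head_impulse`.
#' @return `impulse_duration()`: the record duration `n * sample_interval`
#'   in seconds.
#' @export
impulse_duration <- function(imp) {
  nrow(imp) * attr(imp, "sample_interval")
}

check_head_impulse <- function(imp) {
  if (!inherits(imp, "head_impulse")) {
    abort_validation("Expected a `head_impulse` (see `head_impulse()` or `read_vhit_csv()`).")
  }
  invisible(imp)
}

#' Read a vHIT head-velocity CSV
#'
#' Expects the two-column dialect `time_s,head_velocity_dps` with a uniform
#' 0.004 s time grid. Non-uniform sampling (beyond 1e-6 s) and non-numeric
#' rows are rejected with the offending row named.
#'
#' @param path CSV file path.
#' @param side,label metadata attached to the returned impulse.
#' @return A `head_impulse`.
#' @export
read_vhit_csv <- function(path, side = "right", label = "") {
  if (!file.exists(path)) {
    abort_io(sprintf("vHIT CSV not found: '%s'", path))
  }
  df <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) abort_parse(sprintf("Could not parse '%s': %s", path, conditionMessage(e)))
  )
  if (!all(c("time_s", "head_velocity_dps") %in% names(df))) {
    abort_parse("CSV must have columns `time_s` and `head_velocity_dps`.")
  }
  if (nrow(df) == 0) {
    abort_parse("CSV has a header but no data rows.")
  }
  t <- suppressWarnings(as.numeric(df$time_s))
  v <- suppressWarnings(as.numeric(df$head_velocity_dps))
  bad <- which(!is.finite(t) | !is.finite(v))
  if (length(bad) > 0) {
    abort_parse(sprintf("Non-numeric value in data row %d.", bad[1]))
  }
  if (nrow(df) >= 2) {
    dt <- diff(t)
    off <- which(abs(dt - 0.004) > 1e-6)
    if (length(off) > 0) {
      abort_parse(sprintf(
        "Non-uniform sampling at data row %d: step %.6f s, expected 0.004 s.",
        off[1] + 1, dt[off[1]]
      ))
    }
  }
  head_impulse(v, sample_interval = 0.004, side = side, label = label)
}

#' Write a head impulse in the vHIT CSV dialect
#'
#' Emits the same `time_s,head_velocity_dps` dialect read by
#' [read_vhit_csv()], so traces round-trip.
#'
#' @param imp a `head_impulse`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_vhit_csv <- function(imp, path) {
  check_head_impulse(imp)
  df <- tibble(time_s = imp$time_s, head_velocity_dps = imp$velocity_dps)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Zero-phase low-pass filter a head impulse
#'
#' Butterworth low-pass applied forward and backward (zero phase, DC gain
#' 1). The record is extended by odd reflection at both ends before
#' filtering so edge transients fall outside the returned trace.
#'
#' @param imp a `head_impulse`.
#' @param cutoff_hz cutoff frequency, 0 < cutoff < Nyquist (125 Hz at the
#'   vHIT rate). Default 30 Hz, which passes the < 15 Hz impulse band
#'   untouched.
#' @param order Butterworth design order (default 4).
#' @return A filtered `head_impulse` of the same length and metadata.
#' @export
lowpass_filter <- function(imp, cutoff_hz = 30, order = 4) {
  check_head_impulse(imp)
  check_positive_scalar(cutoff_hz, "cutoff_hz")
  dt <- attr(imp, "sample_interval")
  nyquist <- 1 / (2 * dt)
  if (cutoff_hz >= nyquist) {
    abort_validation(sprintf(
      "`cutoff_hz` (%.6g Hz) must be below the Nyquist frequency (%.6g Hz).",
      cutoff_hz, nyquist
    ))
  }
  v <- imp$velocity_dps
  n <- length(v)
  pad <- min(n - 1, 90L)
  # odd (point-symmetric) reflection preserves level and slope at the ends
  pre <- 2 * v[1] - v[seq(pad + 1, 2)]
  post <- 2 * v[n] - v[seq(n - 1, n - pad)]
  ext <- c(pre, v, post)
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  fwd <- signal::filter(bf, ext)
  bwd <- rev(signal::filter(bf, rev(as.numeric(fwd))))
  out <- bwd[seq(pad + 1, pad + n)]
  head_impulse(out, sample_interval = dt,
               side = attr(imp, "side"), label = attr(imp, "label"))
}

#' Head angular acceleration
#'
#' Differentiates the head-velocity trace (central differences in the
#' interior, one-sided at the ends) and converts to rad/s^2, the forcing
#' term of the rigid-limit pressure law.
#'
#' @param imp a `head_impulse` with at least 3 samples.
#' @return A tibble of class `acceleration_trace` with columns `time_s` and
#'   `accel_rad_s2`, same length as the input.
#' @export
angular_acceleration <- function(imp) {
  check_head_impulse(imp)
  v <- deg2rad(imp$velocity_dps)
  n <- length(v)
  if (n < 3) {
    abort_validation("Need at least 3 samples to differentiate.")
  }
  dt <- attr(imp, "sample_interval")
  a <- numeric(n)
  a[1] <- (v[2] - v[1]) / dt
  a[n] <- (v[n] - v[n - 1]) / dt
  a[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  out <- tibble(time_s = imp$time_s, accel_rad_s2 = a)
  structure(out,
    class = c("acceleration_trace", class(out)),
    sample_interval = dt
  )
}

#' Peak head velocity
#'
#' Maximum absolute velocity of the record, reported as a signed-positive
#' value (right-side convention).
#'
#' @param imp a `head_impulse`.
#' @return Peak velocity in deg/s.
#' @export
peak_velocity <- function(imp) {
  check_head_impulse(imp)
  max(abs(imp$velocity_dps))
}

#' @method autoplot head_impulse
#' @export
autoplot.head_impulse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$velocity_dps)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(
      x = "time (s)", y = "head velocity (deg/s)",
      title = attr(object, "label") %||% NULL
    ) +
    ggplot2::theme_minimal()
}
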