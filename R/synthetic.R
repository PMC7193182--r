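#' Synthesize a vHIT-like head impulse
#'
#' Generates a bell-shaped head-velocity record of physiological duration
#' inside the standard 0.7 s, 250 Hz vHIT window. The default profile is a
#' Gaussian bell `peak * exp(-(t - t0)^2 / (2 sigma^2))` with
#' `sigma = active_duration / 6` and `t0 = onset_time + active_duration / 2`
#' (snapped to the sampling grid so the sampled maximum equals the requested
#' peak exactly);
#' a raised-cosine (Hann) bell of the same peak and active width is
#' available for waveform-robustness checks. Optional additive Gaussian
#' noise is seeded for bit-reproducibility.
#'
#' @param peak_velocity peak head velocity, deg/s (> 0).
#' @param active_duration width of the active phase of the bell, s
#'   (default 0.15, a typical clinical head impulse).
#' @param onset_time start of the active phase, s (default 0.1).
#' @param noise_sd standard deviation of additive Gaussian noise, deg/s
#'   (default 0, noiseless).
#' @param seed integer seed used when `noise_sd > 0`; the same seed gives
#'   bit-identical traces.
#' @param profile `"gaussian"` (default) or `"raised_cosine"`.
#' @param duration record length, s (default 0.7).
#' @param sample_interval sampling interval, s (default 0.004).
#' @param label free-text label.
#' @return A `head_impulse`.
#' @export
#' @examples
#' imp <- synth_impulse(249.47)
#' peak_velocity(imp)
synth_impulse <- function(peak_velocity,
                          active_duration = 0.15,
                          onset_time = 0.1,
                          noise_sd = 0,
                          seed = NULL,
                          profile = c("gaussian", "raised_cosine"),
                          duration = 0.7,
                          sample_interval = 0.004,
                          label = "") {
  profile <- match.arg(profile)
  check_positive_scalar(peak_velocity, "peak_velocity")
  check_positive_scalar(active_duration, "active_duration")
  check_nonneg_scalar(onset_time, "onset_time")
  check_nonneg_scalar(noise_sd, "noise_sd")
  check_positive_scalar(duration, "duration")
  if (onset_time + active_duration > duration + 1e-12) {
    abort_validation("`onset_time + active_duration` must fit inside the record duration.")
  }
  n <- round(duration / sample_interval)
  t <- (seq_len(n) - 1) * sample_interval
  # snap the bell centre to the sampling grid so the sampled maximum equals
  # the requested peak exactly
  t0 <- round((onset_time + active_duration / 2) / sample_interval) * sample_interval
  if (profile == "gaussian") {
    sigma <- active_duration / 6
    v <- peak_velocity * exp(-(t - t0)^2 / (2 * sigma^2))
  } else {
    u <- (t - t0) / active_duration
    v <- ifelse(abs(u) <= 0.5, peak_velocity * cos(pi * u)^2, 0)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv())) {
        get(".Random.seed", envir = globalenv())
      }
      on.exit(
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
        add = TRUE
      )
      set.seed(as.integer(seed))
    }
    v <- v + rnorm(n, sd = noise_sd)
  }
  head_impulse(v, sample_interval = sample_interval, side = "right", label = label)
}

#' The six-impulse reference grid
#'
#' Six noiseless right-side synthetic impulses with incrementally
#' increasing peak velocities 102.62, 137.46, 140.50, 173.81, 209.11 and
#' 249.47 deg/s, labelled I-VI. These are the study conditions of the
#' experiment grid: each is run against the three hydrops geometries for
#' the full 18-run experiment.
#'
#' @param active_duration,onset_time,profile passed to [synth_impulse()].
#' @return A named list of 6 `head_impulse` objects (names `I`..`VI`),
#'   peaks sorted ascending.
#' @export
#' @examples
#' grid <- impulse_grid()
#' vapply(grid, peak_velocity, numeric(1))
impulse_grid <- function(active_duration = 0.15, onset_time = 0.1,
                         profile = "gaussian") {
  peaks <- c(102.62, 137.46, 140.50, 173.81, 209.11, 249.47)
  labels <- c("I", "II", "III", "IV", "V", "VI")
  out <- map2(peaks, labels, function(p, l) {
    synth_impulse(p, active_duration = active_duration, onset_time = onset_time,
                  profile = profile, label = l)
  })
  names(out) <- labels
  out
}

#' Write the reference grid as vHIT CSV fixtures
#'
#' Emits the six grid impulses as `impulse_I.csv` .. `impulse_VI.csv` in
#' the standard vHIT dialect.
#'
#' @param dir output directory (created if missing).
#' @param ... passed to [impulse_grid()].
#' @return Invisibly, the written file paths.
#' @export
write_impulse_fixtures <- function(dir, ...) {
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  grid <- impulse_grid(...)
  paths <- imap(grid, function(imp, lab) {
    p <- file.path(dir, paste0("impulse_", lab, ".csv"))
    write_vhit_csv(imp, p)
    p
  })
  invisible(unlist(paths))
}
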