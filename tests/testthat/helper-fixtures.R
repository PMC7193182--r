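# Shared test helpers: hand-built traces and independent oracles.

# construct a pressure_trace directly from a sensor-mean series, for tests
# that exercise downstream operations on synthetic pressure histories
fake_pressure_trace <- function(p_mean, dt = 0.004) {
  out <- tibble::tibble(
    time_s = (seq_along(p_mean) - 1) * dt,
    p_mean_pa = as.numeric(p_mean)
  )
  structure(out,
    class = c("pressure_trace", class(out)),
    sample_interval = dt,
    sensors = "mean",
    impulse_label = ""
  )
}

# O(n^2) brute-force quadrature of the exponentially weighted pressure
# integral, with the same right-endpoint sample convention as the
# recursion but summed directly; independent oracle for the recursion.
brute_force_vc <- function(p_mean, dt, tau, gamma) {
  n <- length(p_mean)
  vc <- numeric(n)
  for (i in seq_len(n)) {
    k <- seq_len(i)
    vc[i] <- sum((dt / gamma) * p_mean[k] * exp(-(i - k) * dt / tau))
  }
  vc
}

# polygonal (shoelace) quadrature of the outer sensor path with the step
# lumen profile, the independent oracle for enclosed_area(geom, "outer");
# the path includes the radial connectors at segment boundaries, so both
# radii are sampled at each boundary angle
polygon_outer_area <- function(geom, n_vertices = 1e5) {
  angles <- geom$segments$subtended_angle
  radii <- geom$centerline_radius + geom$segments$lumen_radius
  starts <- c(0, cumsum(utils::head(angles, -1)))
  theta <- c()
  r <- c()
  for (i in seq_along(angles)) {
    m <- max(2, round(n_vertices * angles[i] / (2 * pi)))
    th <- starts[i] + angles[i] * (seq_len(m) - 1) / (m - 1)
    theta <- c(theta, th)
    r <- c(r, rep(radii[i], m))
  }
  x <- r * cos(theta)
  y <- r * sin(theta)
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

# a single-segment loop whose lumen is all duct: the idealised geometry in
# which both sensor paths are exact circles
all_duct_geometry <- function(R = 3.2, lumen = 0.225) {
  labyrinth_geometry(
    centerline_radius = R,
    segments = tibble::tibble(
      name = "duct", subtended_angle = 2 * pi, lumen_radius = lumen
    ),
    hydrops_state = "none"
  )
}

# ramp-velocity impulse with constant angular acceleration (rad/s^2)
ramp_impulse <- function(accel_rad_s2, n = 175, dt = 0.004) {
  t <- (seq_len(n) - 1) * dt
  head_impulse(accel_rad_s2 * (180 / pi) * t, sample_interval = dt)
}
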