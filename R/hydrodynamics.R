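#' Endolymph fluid properties
#'
#' Endolymph is modelled with the thermodynamic properties of water:
#' density 1000 kg/m^3 and kinematic viscosity 1e-6 m^2/s. The dynamic
#' viscosity is derived as `mu = rho * nu`.
#'
#' @param density fluid density rho, kg/m^3.
#' @param kinematic_viscosity kinematic viscosity nu, m^2/s.
#' @return An object of class `fluid_properties` with fields `density`,
#'   `kinematic_viscosity`, `dynamic_viscosity`.
#' @export
fluid_properties <- function(density = 1000, kinematic_viscosity = 1e-6) {
  check_positive_scalar(density, "density")
  check_positive_scalar(kinematic_viscosity, "kinematic_viscosity")
  structure(
    list(
      density = density,
      kinematic_viscosity = kinematic_viscosity,
      dynamic_viscosity = density * kinematic_viscosity
    ),
    class = "fluid_properties"
  )
}

#' Transcupular pressure during a head impulse
#'
#' Rigid-wall, rigid-cupula reduction of the rotating-frame incompressible
#' flow problem. With rigid walls and a rigid cupula sealing the loop,
#' incompressibility forces zero endolymph flow relative to the walls, so
#' the pressure field does nothing but balance the inertial forcing of the
#' frame. Integrating the azimuthal momentum balance around a closed planar
#' path through sensor i gives the pressure difference sustained across the
#' cupula along that path:
#'
#'   dP_i(t) = 2 * rho * A_i * dOmega/dt
#'
#' where A_i is the planar area enclosed by the path. Two sensor paths are
#' used, mirroring pressure receptors at the middle and superior (outer
#' wall) points of the ampullar region: the `"middle"` path is the
#' centerline circle, the `"outer"` path follows the outer wall. The
#' exported quantity of interest is the sensor mean.
#'
#' Because there is no relative flow in this limit, viscous stresses vanish
#' and the law is exact within the reduction; the chain is therefore linear
#' in the head-velocity trace.
#'
#' @param imp a right-side `head_impulse`.
#' @param geom a `labyrinth_geometry`.
#' @param fluid a [fluid_properties()] object.
#' @param sensors character vector of sensor paths, subset of
#'   `c("middle", "outer")` (both by default).
#' @return A tibble of class `pressure_trace` with columns `time_s`, one
#'   `p_<sensor>_pa` column per sensor (the outer sensor column is named
#'   `p_superior_pa`), and `p_mean_pa`, the arithmetic sensor mean.
#' @export
#' @examples
#' tr <- transcupular_pressure(synth_impulse(150), make_normal_geometry())
#' pressure_increment(tr)
transcupular_pressure <- function(imp, geom, fluid = fluid_properties(),
                                  sensors = c("middle", "outer")) {
  check_head_impulse(imp)
  if (!inherits(geom, "labyrinth_geometry")) {
    abort_validation("`geom` must be a labyrinth_geometry.")
  }
  if (!inherits(fluid, "fluid_properties")) {
    abort_validation("`fluid` must be a fluid_properties object.")
  }
  if (attr(imp, "side") != "right") {
    abort_validation("The pressure model is defined for right-side impulses.")
  }
  sensors <- unique(sensors)
  if (length(sensors) == 0 || !all(sensors %in% c("middle", "outer"))) {
    abort_validation("`sensors` must be a non-empty subset of c('middle', 'outer').")
  }
  acc <- angular_acceleration(imp)
  out <- tibble(time_s = acc$time_s)
  series <- list()
  for (s in sensors) {
    area_m2 <- enclosed_area(geom, s) * 1e-6  # mm^2 -> m^2
    series[[s]] <- 2 * fluid$density * area_m2 * acc$accel_rad_s2
    col <- if (s == "outer") "p_superior_pa" else paste0("p_", s, "_pa")
    out[[col]] <- series[[s]]
  }
  out$p_mean_pa <- Reduce(`+`, series) / length(series)
  structure(out,
    class = c("pressure_trace", class(out)),
    sample_interval = attr(imp, "sample_interval"),
    sensors = sensors,
    impulse_label = attr(imp, "label")
  )
}

check_pressure_trace <- function(trace) {
  if (!inherits(trace, "pressure_trace")) {
    abort_validation("Expected a `pressure_trace` (see `transcupular_pressure()`).")
  }
  invisible(trace)
}

#' Ampullar pressure increment
#'
#' The per-impulse scalar pressure outcome: the maximum absolute value of
#' the sensor-mean transcupular pressure over the record.
#'
#' @param trace a `pressure_trace`.
#' @return Pressure increment in Pa.
#' @export
pressure_increment <- function(trace) {
  check_pressure_trace(trace)
  if (nrow(trace) == 0) {
    abort_validation("Pressure trace is empty.")
  }
  max(abs(trace$p_mean_pa))
}

#' Hydropic pressure enhancement factor
#'
#' Ratio of ampullar pressure increments, hydropic over normal, for the
#' same impulse and fluid. By linearity of the pressure law this equals the
#' ratio of sensor-mean enclosed areas and is independent of the impulse
#' peak and waveform.
#'
#' @param hydropic,normal `pressure_trace` objects from the same impulse.
#' @return Dimensionless enhancement factor.
#' @export
enhancement_factor <- function(hydropic, normal) {
  check_pressure_trace(hydropic)
  check_pressure_trace(normal)
  denom <- pressure_increment(normal)
  if (denom == 0) {
    abort_validation("Normal pressure increment is zero; enhancement factor undefined.")
  }
  pressure_increment(hydropic) / denom
}

#' Write a pressure trace as CSV
#'
#' Emits `time_s,p_middle_pa,p_superior_pa,p_mean_pa` (whichever sensor
#' columns are present).
#'
#' @param trace a `pressure_trace`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pressure_csv <- function(trace, path) {
  check_pressure_trace(trace)
  readr::write_csv(as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' @method autoplot pressure_trace
#' @export
autoplot.pressure_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"time_s",
                              names_to = "sensor", values_to = "pressure_pa")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$pressure_pa,
                                     colour = .data$sensor)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "transcupular pressure (Pa)") +
    ggplot2::theme_minimal()
}
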