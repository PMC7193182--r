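#' Cupular transduction parameters
#'
#' Constants of the overdamped torsion-pendulum model of the cupula. The
#' cupular time constant and damping coefficient are
#'
#'   tau_c = 8 mu beta_d R / (pi b_d^4 K)
#'   gamma = 8 mu beta_d R / (pi b_d^4)
#'
#' so that `tau_c = gamma / K` identically. Defaults follow the classical
#' human horizontal-canal modelling values: endolymph dynamic viscosity
#' `mu = 1e-3` Pa s, duct subtended angle `beta_d = 4.6` rad, major radius
#' `R = 3.2e-3` m, duct hydraulic radius `b_d = 1.6e-4` m, cupular elastic
#' constant `K = 1.3e10` Pa/m^3, giving `tau_c ~ 4.4` s - long against the
#' ~0.15 s impulse, which puts the cupula in the overdamped-integrator
#' regime where its volume displacement tracks head velocity.
#'
#' These transduction constants describe the (unchanged) cupula/ampulla and
#' are held fixed across hydrops geometries.
#'
#' @param dynamic_viscosity mu, Pa s.
#' @param duct_angle beta_d, rad.
#' @param major_radius R, m.
#' @param duct_radius b_d, m.
#' @param cupular_stiffness K, Pa/m^3.
#' @return An object of class `cupula_params` with the given fields plus
#'   derived `tau_c` (s) and `gamma` (Pa s/m^3).
#' @export
#' @examples
#' p <- cupula_params()
#' p$tau_c
cupula_params <- function(dynamic_viscosity = 1e-3,
                          duct_angle = 4.6,
                          major_radius = 3.2e-3,
                          duct_radius = 1.6e-4,
                          cupular_stiffness = 1.3e10) {
  check_positive_scalar(dynamic_viscosity, "dynamic_viscosity")
  check_positive_scalar(duct_angle, "duct_angle")
  check_positive_scalar(major_radius, "major_radius")
  check_positive_scalar(duct_radius, "duct_radius")
  check_positive_scalar(cupular_stiffness, "cupular_stiffness")
  p <- list(
    dynamic_viscosity = dynamic_viscosity,
    duct_angle = duct_angle,
    major_radius = major_radius,
    duct_radius = duct_radius,
    cupular_stiffness = cupular_stiffness
  )
  p$gamma <- 8 * dynamic_viscosity * duct_angle * major_radius / (pi * duct_radius^4)
  p$tau_c <- p$gamma / cupular_stiffness
  structure(p, class = "cupula_params")
}

check_cupula_params <- function(p) {
  if (!inherits(p, "cupula_params")) {
    abort_validation("Expected a `cupula_params` object.")
  }
  if (p$tau_c <= 0 || p$gamma <= 0) {
    abort_validation("Derived tau_c and gamma must be positive.")
  }
  invisible(p)
}

#' Cupular time constant
#'
#' `tau_c = 8 mu beta_d R / (pi b_d^4 K)`, the relaxation time of cupular
#' return.
#'
#' @param p a [cupula_params()] object.
#' @return tau_c in seconds.
#' @export
cupular_time_constant <- function(p) {
  check_cupula_params(p)
  p$tau_c
}

#' Cupular damping coefficient
#'
#' `gamma = 8 mu beta_d R / (pi b_d^4)`; note `gamma = tau_c * K`.
#'
#' @param p a [cupula_params()] object.
#' @return gamma in Pa s/m^3.
#' @export
cupular_damping <- function(p) {
  check_cupula_params(p)
  p$gamma
}

#' Cupular volume displacement from transcupular pressure
#'
#' Evaluates the causal exponentially weighted pressure integral
#'
#'   Vc(t) = (1/gamma) * integral_{-inf}^{t} dPc(t') exp(-(t - t')/tau_c) dt'
#'
#' on the sensor-mean pressure series, assuming rest (zero pressure) before
#' the record. Discretely, each pressure sample is treated as acting over
#' the sampling interval ending at its timestamp, which gives the exact
#' exponential recursion
#'
#'   Vc[n] = Vc[n-1] * exp(-dt/tau_c) + (dt/gamma) * dPc[n]
#'
#' @param trace a `pressure_trace`.
#' @param p a [cupula_params()] object.
#' @return A tibble of class `cupula_response` with columns `time_s` and
#'   `vc_pl` (cupular volume displacement, picolitres).
#' @export
cupular_volume_displacement <- function(trace, p = cupula_params()) {
  check_pressure_trace(trace)
  check_cupula_params(p)
  dt <- attr(trace, "sample_interval")
  decay <- exp(-dt / p$tau_c)
  gain <- dt / p$gamma
  press <- trace$p_mean_pa
  n <- length(press)
  vc <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc * decay + gain * press[i]
    vc[i] <- acc
  }
  out <- tibble(time_s = trace$time_s, vc_pl = vc * PL_PER_M3)
  structure(out,
    class = c("cupula_response", class(out)),
    sample_interval = dt,
    impulse_label = attr(trace, "impulse_label")
  )
}

check_cupula_response <- function(resp) {
  if (!inherits(resp, "cupula_response")) {
    abort_validation("Expected a `cupula_response` (see `cupular_volume_displacement()`).")
  }
  invisible(resp)
}

#' Equivalent head velocity sensed by the cupula
#'
#' Applies the human cupular sensitivity Omega_0 / Vc ~ 5.6e-2 deg/(pL s)
#' pointwise to the volume-displacement series, together with the pipeline
#' calibration scale (see [calibrate_response_scale()]): the whole chain is
#' linear, so the scale is a single scalar pinned once on the normal
#' geometry.
#'
#' @param resp a `cupula_response`.
#' @param conversion cupular sensitivity, deg/(pL s); default 5.6e-2.
#' @param scale calibration scale of the chain (default 1, uncalibrated).
#' @return The `cupula_response` with an added `omega_equiv_dps` column.
#' @export
equivalent_head_velocity <- function(resp, conversion = 5.6e-2, scale = 1) {
  check_cupula_response(resp)
  check_positive_scalar(conversion, "conversion")
  check_positive_scalar(scale, "scale")
  resp$omega_equiv_dps <- conversion * scale * resp$vc_pl
  resp
}

#' Write a cupular response as CSV
#'
#' Emits `time_s,vc_pl,omega_equiv_dps` (columns present in the response).
#'
#' @param resp a `cupula_response`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_response_csv <- function(resp, path) {
  check_cupula_response(resp)
  readr::write_csv(as_tibble(resp), path, progress = FALSE)
  invisible(path)
}

#' @method autoplot cupula_response
#' @export
autoplot.cupula_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$vc_pl)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(x = "time (s)", y = "cupular volume displacement (pL)") +
    ggplot2::theme_minimal()
}
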