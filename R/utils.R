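# Internal helpers: unit conversion and classed error conditions.
#
# Degrees are the external (clinical) unit for angular velocity; radians are
# used inside the physics. All conversions funnel through these two helpers
# so the factor lives in exactly one place.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# one picolitre in cubic metres
PL_PER_M3 <- 1e15

abort_validation <- function(message, ...) {
  abort(message, class = "vestsim_error_validation", ...)
}

abort_constraint <- function(message, ...) {
  abort(message, class = "vestsim_error_constraint", ...)
}

abort_parse <- function(message, ...) {
  abort(message, class = "vestsim_error_parse", ...)
}

abort_io <- function(message, ...) {
  abort(message, class = "vestsim_error_io", ...)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_validation(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    abort_validation(sprintf("`%s` must be a single non-negative finite number.", name))
  }
  invisible(x)
}

# trapezoidal integral; thin wrapper so the quadrature rule is swappable
trapezoid <- function(x, y) pracma::trapz(x, y)
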