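#' Default geometry configuration
#'
#' Parameters of the reduced planar-loop representation of the membranous
#' labyrinth of the horizontal semicircular canal. The loop is a circle of
#' radius `centerline_radius_mm` in the canal plane, partitioned into three
#' segments (semicircular duct, utricle, ampulla) that together subtend the
#' full 2*pi; each segment carries a local lumen radius, the half-width of
#' the endolymph lumen normal to the centerline.
#'
#' The duct lumen diameter (0.45 mm normal, dilated by `dilation_factor` to
#' 1.3 mm under canal hydrops) and the osseous canal diameter (1.53 mm, the
#' hard upper bound any dilated duct must still fit inside) are anatomical
#' givens. The centerline radius and the utricle segment are the model's
#' free parameters: they were calibrated once so that the sensor-mean
#' pressure enhancement of the default hydropic geometries equals 1.140
#' (canal hydrops) and 1.100 (utricular hydrops), and are frozen here.
#' The utricle angle is the remainder `2*pi - duct_angle - ampulla_angle`,
#' so the segment angles always close the loop exactly.
#'
#' @param ... named overrides for any of the configuration entries.
#'
#' @return A named list with entries `centerline_radius_mm`,
#'   `duct_diameter_mm`, `duct_angle_rad`, `ampulla_angle_rad`,
#'   `utricle_lumen_radius_mm`, `ampulla_lumen_radius_mm`,
#'   `osseous_canal_diameter_mm`, `dilation_factor`,
#'   `utricular_dilation_factor`.
#' @export
#' @examples
#' geometry_config()
#' geometry_config(centerline_radius_mm = 3.0)
geometry_config <- function(...) {
  config <- list(
    centerline_radius_mm      = 2.3430,
    duct_diameter_mm          = 0.45,
    duct_angle_rad            = 4.6,
    ampulla_angle_rad         = 0.2,
    utricle_lumen_radius_mm   = 0.4130,
    ampulla_lumen_radius_mm   = 0.45,
    osseous_canal_diameter_mm = 1.53,
    dilation_factor           = 1.3 / 0.45,
    utricular_dilation_factor = 3
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    abort_validation(paste0(
      "Unknown geometry config entr", if (length(unknown) > 1) "ies: " else "y: ",
      paste(unknown, collapse = ", ")
    ))
  }
  config[names(overrides)] <- overrides
  config
}

#' Read a geometry configuration from JSON
#'
#' @param path path to a JSON file whose keys are a subset of the entries of
#'   [geometry_config()]; missing keys take the frozen defaults.
#' @return A geometry configuration list.
#' @export
read_geometry_config <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("Geometry config file not found: '%s'", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(geometry_config, as.list(raw))
}

#' Construct a labyrinth geometry
#'
#' Low-level constructor with full validation. Most callers want
#' [make_normal_geometry()] plus the hydrops operators.
#'
#' @param centerline_radius major radius of the planar loop, mm.
#' @param segments a data frame with columns `name` (one of `"duct"`,
#'   `"utricle"`, `"ampulla"`), `subtended_angle` (rad, positive, summing to
#'   2*pi) and `lumen_radius` (mm, positive).
#' @param hydrops_state one of `"none"`, `"canal"`, `"utricular"`.
#' @param dilation_factor linear scale applied to the dilated segment's
#'   lumen radius (recorded for provenance; 1 for a normal geometry).
#' @param osseous_canal_diameter diameter of the bony canal, mm; the duct
#'   lumen diameter may never exceed it.
#'
#' @return An object of class `labyrinth_geometry`.
#' @export
labyrinth_geometry <- function(centerline_radius,
                               segments,
                               hydrops_state = c("none", "canal", "utricular"),
                               dilation_factor = 1,
                               osseous_canal_diameter = 1.53) {
  hydrops_state <- match.arg(hydrops_state)
  check_positive_scalar(centerline_radius, "centerline_radius")
  check_positive_scalar(osseous_canal_diameter, "osseous_canal_diameter")
  check_positive_scalar(dilation_factor, "dilation_factor")

  segments <- as_tibble(segments)
  required <- c("name", "subtended_angle", "lumen_radius")
  if (!all(required %in% names(segments))) {
    abort_validation("`segments` needs columns name, subtended_angle, lumen_radius.")
  }
  if (!all(segments$name %in% c("duct", "utricle", "ampulla"))) {
    abort_validation("Segment names must be duct, utricle or ampulla.")
  }
  if (any(!is.finite(segments$subtended_angle)) || any(segments$subtended_angle <= 0)) {
    abort_validation("All segment subtended angles must be positive and finite.")
  }
  if (any(!is.finite(segments$lumen_radius)) || any(segments$lumen_radius <= 0)) {
    abort_validation("All segment lumen radii must be positive and finite.")
  }
  if (abs(sum(segments$subtended_angle) - 2 * pi) > 1e-9) {
    abort_validation("Segment subtended angles must sum to 2*pi (tolerance 1e-9).")
  }
  if (centerline_radius <= max(segments$lumen_radius)) {
    abort_validation(
      "centerline_radius must exceed every lumen radius (loop must not self-intersect)."
    )
  }
  duct <- segments[segments$name == "duct", ]
  if (nrow(duct) == 1 && 2 * duct$lumen_radius > osseous_canal_diameter + 1e-12) {
    abort_constraint(sprintf(
      "Duct lumen diameter %.4g mm exceeds the osseous canal limit of %.4g mm.",
      2 * duct$lumen_radius, osseous_canal_diameter
    ))
  }

  structure(
    list(
      centerline_radius = centerline_radius,
      segments = segments,
      hydrops_state = hydrops_state,
      dilation_factor = dilation_factor,
      osseous_canal_diameter = osseous_canal_diameter
    ),
    class = "labyrinth_geometry"
  )
}

#' @export
print.labyrinth_geometry <- function(x, ...) {
  cat(sprintf(
    "<labyrinth_geometry> hydrops: %s | centerline radius %.4g mm | osseous limit %.3g mm\n",
    x$hydrops_state, x$centerline_radius, x$osseous_canal_diameter
  ))
  print(x$segments)
  invisible(x)
}

#' Build the normal (no hydrops) labyrinth geometry
#'
#' Assembles the three-segment planar loop from a configuration: the
#' semicircular duct (lumen diameter 0.45 mm by default), the utricle and
#' the ampulla, in that order around the loop.
#'
#' @param config a configuration list from [geometry_config()] or
#'   [read_geometry_config()].
#' @return A `labyrinth_geometry` with `hydrops_state = "none"`.
#' @export
#' @examples
#' geom <- make_normal_geometry()
#' enclosed_area(geom, "middle")
make_normal_geometry <- function(config = geometry_config()) {
  for (key in c("centerline_radius_mm", "duct_diameter_mm", "duct_angle_rad",
                "ampulla_angle_rad", "utricle_lumen_radius_mm",
                "ampulla_lumen_radius_mm", "osseous_canal_diameter_mm")) {
    check_positive_scalar(config[[key]], key)
  }
  utricle_angle <- 2 * pi - config$duct_angle_rad - config$ampulla_angle_rad
  if (utricle_angle <= 0) {
    abort_validation("duct_angle_rad + ampulla_angle_rad must be < 2*pi.")
  }
  segments <- tibble(
    name = c("duct", "utricle", "ampulla"),
    subtended_angle = c(config$duct_angle_rad, utricle_angle, config$ampulla_angle_rad),
    lumen_radius = c(
      config$duct_diameter_mm / 2,
      config$utricle_lumen_radius_mm,
      config$ampulla_lumen_radius_mm
    )
  )
  labyrinth_geometry(
    centerline_radius = config$centerline_radius_mm,
    segments = segments,
    hydrops_state = "none",
    dilation_factor = 1,
    osseous_canal_diameter = config$osseous_canal_diameter_mm
  )
}

stop_if_not_normal <- function(geom) {
  if (!inherits(geom, "labyrinth_geometry")) {
    abort_validation("`geom` must be a labyrinth_geometry.")
  }
  if (geom$hydrops_state != "none") {
    abort_validation("Hydrops can only be applied to a hydrops_state = 'none' geometry.")
  }
  invisible(geom)
}

#' Apply canal hydrops to a normal geometry
#'
#' Uniformly dilates the semicircular-duct lumen by `factor`. The default
#' factor takes the 0.45 mm duct to the 1.3 mm hydropic diameter; the result
#' must still fit inside the 1.53 mm osseous canal or construction fails.
#'
#' @param geom a `labyrinth_geometry` with `hydrops_state = "none"`.
#' @param factor linear dilation factor, `>= 1`.
#' @return A new `labyrinth_geometry` with `hydrops_state = "canal"`.
#' @export
#' @examples
#' hyd <- apply_canal_hydrops(make_normal_geometry())
#' hyd$segments
apply_canal_hydrops <- function(geom, factor = 1.3 / 0.45) {
  stop_if_not_normal(geom)
  check_positive_scalar(factor, "factor")
  if (factor < 1) {
    abort_validation("Canal hydrops `factor` must be >= 1 (dilation, not shrinkage).")
  }
  segments <- geom$segments
  segments$lumen_radius[segments$name == "duct"] <-
    factor * segments$lumen_radius[segments$name == "duct"]
  labyrinth_geometry(
    centerline_radius = geom$centerline_radius,
    segments = segments,
    hydrops_state = "canal",
    dilation_factor = factor,
    osseous_canal_diameter = geom$osseous_canal_diameter
  )
}

#' Apply utricular hydrops to a normal geometry
#'
#' Uniformly dilates the utricle lumen by `factor` (default x3, the same
#' uniform expansion used for the canal-hydrops duct). The duct and ampulla
#' segments are untouched.
#'
#' @inheritParams apply_canal_hydrops
#' @return A new `labyrinth_geometry` with `hydrops_state = "utricular"`.
#' @export
apply_utricular_hydrops <- function(geom, factor = 3) {
  stop_if_not_normal(geom)
  check_positive_scalar(factor, "factor")
  if (factor < 1) {
    abort_validation("Utricular hydrops `factor` must be >= 1 (dilation, not shrinkage).")
  }
  segments <- geom$segments
  segments$lumen_radius[segments$name == "utricle"] <-
    factor * segments$lumen_radius[segments$name == "utricle"]
  labyrinth_geometry(
    centerline_radius = geom$centerline_radius,
    segments = segments,
    hydrops_state = "utricular",
    dilation_factor = factor,
    osseous_canal_diameter = geom$osseous_canal_diameter
  )
}

#' The three study geometries
#'
#' Convenience wrapper returning the normal, canal-hydrops and
#' utricular-hydrops geometries built from one configuration.
#'
#' @param config a configuration list from [geometry_config()].
#' @return A named list `list(none = , canal = , utricular = )`.
#' @export
default_geometries <- function(config = geometry_config()) {
  normal <- make_normal_geometry(config)
  list(
    none = normal,
    canal = apply_canal_hydrops(normal, config$dilation_factor),
    utricular = apply_utricular_hydrops(normal, config$utricular_dilation_factor)
  )
}

#' Area enclosed by a sensor path
#'
#' The reduced pressure law needs the planar area enclosed by the closed
#' path through each pressure sensor. The `"middle"` path runs along the
#' lumen centerline, a circle of radius R, so its area is `pi * R^2`. The
#' `"outer"` path (the superior wall) follows the local outer wall at radius
#' `R + b(theta)`, with `b(theta)` the lumen radius of the segment at
#' `theta`; its area is the polar integral `0.5 * sum((R + b_i)^2 *
#' dtheta_i)` over segments.
#'
#' @param geom a `labyrinth_geometry`.
#' @param path `"middle"` or `"outer"`.
#' @return Enclosed area in mm^2.
#' @export
#' @examples
#' enclosed_area(make_normal_geometry(), "outer")
enclosed_area <- function(geom, path = c("middle", "outer")) {
  if (!inherits(geom, "labyrinth_geometry")) {
    abort_validation("`geom` must be a labyrinth_geometry.")
  }
  path <- match.arg(path)
  R <- geom$centerline_radius
  if (path == "middle") {
    return(pi * R^2)
  }
  sum(0.5 * (R + geom$segments$lumen_radius)^2 * geom$segments$subtended_angle)
}
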