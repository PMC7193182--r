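#' Simulation configuration
#'
#' One bundle covering every tunable of the pipeline: geometry, fluid,
#' cupular transduction, the low-pass filter applied to recorded traces,
#' the AUC gain window, and the aVOR mapping.
#'
#' @param geometry a [geometry_config()] list.
#' @param density,kinematic_viscosity endolymph properties (SI).
#' @param cupula a [cupula_params()] object.
#' @param filter_cutoff_hz low-pass cutoff applied to *recorded* vHIT CSV
#'   traces before simulation (synthetic impulses are already band-limited
#'   and are used as generated).
#' @param window_threshold_dps on/off head-velocity threshold (deg/s)
#'   defining the AUC analysis window.
#' @param conversion cupular sensitivity, deg/(pL s).
#' @param vor_gain normofunctional aVOR gain between equivalent head
#'   velocity and eye velocity (default 1).
#' @param reference_label grid impulse on which the chain scale is pinned
#'   so the normal geometry yields AUC gain exactly 1 (default `"IV"`).
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(geometry = geometry_config(),
                       density = 1000,
                       kinematic_viscosity = 1e-6,
                       cupula = cupula_params(),
                       filter_cutoff_hz = 30,
                       window_threshold_dps = 20,
                       conversion = 5.6e-2,
                       vor_gain = 1,
                       reference_label = "IV") {
  structure(
    list(
      geometry = geometry,
      density = density,
      kinematic_viscosity = kinematic_viscosity,
      cupula = cupula,
      filter_cutoff_hz = filter_cutoff_hz,
      window_threshold_dps = window_threshold_dps,
      conversion = conversion,
      vor_gain = vor_gain,
      reference_label = reference_label
    ),
    class = "sim_config"
  )
}

#' Read a simulation configuration from JSON
#'
#' Top-level keys mirror the arguments of [sim_config()]; `geometry` is a
#' nested object with [geometry_config()] keys and `cupula` a nested object
#' with [cupula_params()] arguments. Missing keys take the defaults.
#'
#' @param path JSON file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort_io(sprintf("Config file not found: '%s'", path))
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$geometry)) args$geometry <- do.call(geometry_config, as.list(raw$geometry))
  if (!is.null(raw$cupula)) args$cupula <- do.call(cupula_params, as.list(raw$cupula))
  for (key in c("density", "kinematic_viscosity", "filter_cutoff_hz",
                "window_threshold_dps", "conversion", "vor_gain", "reference_label")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  do.call(sim_config, args)
}

#' Predicted eye velocity
#'
#' Applies the normofunctional aVOR mapping: the eye-velocity trace is the
#' equivalent head velocity sensed by the cupula scaled by the aVOR gain
#' (default 1).
#'
#' @param resp a `cupula_response` carrying `omega_equiv_dps` (see
#'   [equivalent_head_velocity()]).
#' @param vor_gain aVOR gain applied between cupular signal and eye.
#' @return A tibble with columns `time_s` and `eye_velocity_dps`.
#' @export
predict_eye_velocity <- function(resp, vor_gain = 1) {
  check_cupula_response(resp)
  check_positive_scalar(vor_gain, "vor_gain")
  if (!"omega_equiv_dps" %in% names(resp)) {
    abort_validation("Response has no `omega_equiv_dps`; run equivalent_head_velocity() first.")
  }
  tibble(time_s = resp$time_s, eye_velocity_dps = vor_gain * resp$omega_equiv_dps)
}

# indices of the AUC analysis window: onset = first sample with |head| >=
# threshold, offset = first subsequent sample below it (end of record if
# none); the closing sample is included so the window covers the crossing.
auc_window <- function(head_v, threshold) {
  on <- which(abs(head_v) >= threshold)
  if (length(on) == 0) {
    abort_validation(sprintf(
      "Head velocity never reaches the %g deg/s window threshold.", threshold
    ))
  }
  i1 <- on[1]
  after <- which(abs(head_v) < threshold)
  after <- after[after > i1]
  i2 <- if (length(after) == 0) length(head_v) else after[1]
  seq(i1, i2)
}

#' Area-under-curve aVOR gain
#'
#' Trapezoidal area of the absolute eye-velocity trace divided by the
#' trapezoidal area of the absolute head-velocity trace over the impulse
#' window. The window opens at the first sample where head velocity reaches
#' `threshold_dps` and closes at the first subsequent sample below it.
#'
#' @param eye eye-velocity trace: a tibble from [predict_eye_velocity()]
#'   or a numeric vector sampled like `head`.
#' @param head the driving `head_impulse`.
#' @param threshold_dps window on/off threshold, deg/s (default 20).
#' @return The dimensionless aVOR gain.
#' @export
#' @examples
#' imp <- synth_impulse(150)
#' auc_gain(imp$velocity_dps, imp)  # eye = head gives gain 1
auc_gain <- function(eye, head, threshold_dps = 20) {
  check_head_impulse(head)
  eye_v <- if (is.data.frame(eye)) eye$eye_velocity_dps else as.numeric(eye)
  if (length(eye_v) != nrow(head)) {
    abort_validation("`eye` and `head` must share the sampling grid.")
  }
  idx <- auc_window(head$velocity_dps, threshold_dps)
  t <- head$time_s[idx]
  head_area <- trapezoid(t, abs(head$velocity_dps[idx]))
  if (head_area == 0) {
    abort_validation("Head-velocity area is zero over the window; gain undefined.")
  }
  trapezoid(t, abs(eye_v[idx])) / head_area
}

# full chain for one impulse and one geometry at a given calibration scale
simulate_one <- function(imp, geom, config, scale) {
  fluid <- fluid_properties(config$density, config$kinematic_viscosity)
  press <- transcupular_pressure(imp, geom, fluid)
  resp <- cupular_volume_displacement(press, config$cupula)
  resp <- equivalent_head_velocity(resp, conversion = config$conversion, scale = scale)
  eye <- predict_eye_velocity(resp, vor_gain = config$vor_gain)
  list(
    pressure = press,
    response = resp,
    eye = eye,
    pressure_increment = pressure_increment(press),
    eye_peak = max(abs(eye$eye_velocity_dps)),
    head_peak = peak_velocity(imp),
    avor_gain = auc_gain(eye, imp, config$window_threshold_dps)
  )
}

#' Calibrate the response-chain scale
#'
#' The reduced model resolves ratios, not the absolute pressure scale of
#' the labyrinth, so the linear pressure-to-eye chain carries one free
#' scalar. It is pinned by requiring the normal (no hydrops) geometry to
#' produce an AUC aVOR gain of exactly 1 on the reference grid impulse
#' (impulse IV by default), and then frozen for all models and impulses.
#'
#' @param geom_normal the `hydrops_state = "none"` geometry.
#' @param reference the reference `head_impulse` (grid impulse IV by
#'   default).
#' @param config a [sim_config()].
#' @return The scalar calibration scale.
#' @export
calibrate_response_scale <- function(geom_normal,
                                     reference = NULL,
                                     config = sim_config()) {
  if (is.null(reference)) {
    reference <- impulse_grid()[[config$reference_label]]
  }
  if (!identical(geom_normal$hydrops_state, "none")) {
    abort_validation("Calibration must use the hydrops_state = 'none' geometry.")
  }
  raw <- simulate_one(reference, geom_normal, config, scale = 1)
  1 / raw$avor_gain
}

#' Run one impulse through one geometry
#'
#' Single calibrated pipeline run, returning the full traces along with the
#' scalar outcomes. Useful for inspecting individual simulations; the grid
#' runner [run_experiment()] wraps this.
#'
#' @param imp a `head_impulse`.
#' @param geom a `labyrinth_geometry`.
#' @param config a [sim_config()].
#' @param scale chain calibration scale; if `NULL` it is computed with
#'   [calibrate_response_scale()] from the default normal geometry.
#' @return A list with elements `pressure`, `response`, `eye`,
#'   `pressure_increment`, `eye_peak`, `head_peak`, `avor_gain`.
#' @export
simulate_impulse <- function(imp, geom, config = sim_config(), scale = NULL) {
  check_head_impulse(imp)
  if (is.null(scale)) {
    scale <- calibrate_response_scale(make_normal_geometry(config$geometry),
                                      config = config)
  }
  simulate_one(imp, geom, config, scale)
}

#' Run the 3-model x 6-impulse experiment grid
#'
#' Calibrates the chain once on the normal geometry, then runs every
#' impulse of the grid through the normal, canal-hydrops and
#' utricular-hydrops geometries, collecting per-run pressure increments,
#' eye-velocity peaks and AUC aVOR gains, plus per-model means and sample
#' standard deviations.
#'
#' @param grid named list of `head_impulse` objects (default
#'   [impulse_grid()]).
#' @param geometries named list of the three geometries (default
#'   [default_geometries()] built from `config$geometry`).
#' @param config a [sim_config()].
#' @return An object of class `experiment_report`: a list with `results`
#'   (tibble, one row per model x impulse, columns `model`,
#'   `impulse_label`, `head_peak`, `eye_peak`, `pressure_increment`,
#'   `avor_gain`), `summary` (per-model mean/sd of gain, pressure increment
#'   and eye peak), and `scale` (the calibration scalar).
#' @export
#' @examples
#' report <- run_experiment()
#' glance(report)
run_experiment <- function(grid = impulse_grid(),
                           geometries = NULL,
                           config = sim_config()) {
  if (is.null(geometries)) {
    geometries <- default_geometries(config$geometry)
  }
  if (!all(c("none", "canal", "utricular") %in% names(geometries))) {
    abort_validation("`geometries` must be a named list with none, canal and utricular.")
  }
  scale <- calibrate_response_scale(geometries$none, config = config)

  rows <- list()
  for (model in c("none", "canal", "utricular")) {
    for (lab in names(grid)) {
      run <- tryCatch(
        simulate_one(grid[[lab]], geometries[[model]], config, scale),
        error = function(e) {
          abort(sprintf("Run failed for model '%s', impulse '%s': %s",
                        model, lab, conditionMessage(e)),
                class = class(e)[1], parent = e)
        }
      )
      rows[[length(rows) + 1]] <- tibble(
        model = model,
        impulse_label = lab,
        head_peak = run$head_peak,
        eye_peak = run$eye_peak,
        pressure_increment = run$pressure_increment,
        avor_gain = run$avor_gain
      )
    }
  }
  results <- bind_rows(rows)
  results$model <- factor(results$model, levels = c("none", "canal", "utricular"))

  summary <- results |>
    group_by(.data$model) |>
    summarise(
      n = n(),
      mean_gain = mean(.data$avor_gain),
      sd_gain = sd(.data$avor_gain),
      mean_pressure_increment = mean(.data$pressure_increment),
      sd_pressure_increment = sd(.data$pressure_increment),
      mean_eye_peak = mean(.data$eye_peak),
      sd_eye_peak = sd(.data$eye_peak),
      .groups = "drop"
    )

  structure(
    list(results = results, summary = summary, scale = scale, config = config),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>", nrow(x$results), "runs | calibration scale",
      format(x$scale, digits = 6), "\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy experiment_report
#' @export
tidy.experiment_report <- function(x, ...) {
  x$results
}

#' @method glance experiment_report
#' @export
glance.experiment_report <- function(x, ...) {
  wide <- x$summary |>
    select("model", "mean_gain", "sd_gain") |>
    tidyr::pivot_wider(names_from = "model",
                       values_from = c("mean_gain", "sd_gain"))
  wide$scale <- x$scale
  wide
}

#' @method autoplot experiment_report
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$impulse_label, y = .data$avor_gain,
                                   colour = .data$model, group = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "impulse", y = "AUC aVOR gain", colour = "hydrops model") +
    ggplot2::theme_minimal()
}

model_display <- c(
  none = "No Hydrops",
  canal = "Canal Hydrops",
  utricular = "Utricular Hydrops"
)

#' Write an experiment report to disk
#'
#' Emits `table1.csv` (per-run pressure increment, eye peak, head peak),
#' `table2.csv` (per-run aVOR gain) and `summary.json` (per-model means and
#' standard deviations plus the calibration scale). Output is byte-stable
#' across reruns on the same inputs.
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "experiment_report")) {
    abort_validation("`report` must be an experiment_report.")
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort_io(sprintf("Cannot create output directory '%s'.", dir))
  }
  res <- report$results |>
    mutate(hydrops_model = unname(model_display[as.character(.data$model)]))

  t1 <- res |>
    select(impulse = "impulse_label", "hydrops_model",
           pressure_increment_pa = "pressure_increment",
           eye_velocity_peak_dps = "eye_peak",
           head_velocity_peak_dps = "head_peak")
  t2 <- res |>
    select(impulse = "impulse_label", "hydrops_model",
           avor_gain = "avor_gain")

  p1 <- file.path(dir, "table1.csv")
  p2 <- file.path(dir, "table2.csv")
  p3 <- file.path(dir, "summary.json")
  readr::write_csv(t1, p1, progress = FALSE)
  readr::write_csv(t2, p2, progress = FALSE)

  summ <- report$summary
  summ_list <- lapply(seq_len(nrow(summ)), function(i) as.list(summ[i, -1]))
  names(summ_list) <- as.character(summ$model)
  jsonlite::write_json(
    list(calibration_scale = report$scale, models = summ_list),
    p3, auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  invisible(c(p1, p2, p3))
}
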