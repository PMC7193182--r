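test_that("fluid properties derive dynamic viscosity consistently", {
  fl <- fluid_properties()
  expect_equal(fl$dynamic_viscosity, fl$density * fl$kinematic_viscosity,
               tolerance = 1e-12)
  expect_equal(fl$kinematic_viscosity, 1e-6)
  expect_error(fluid_properties(density = -1), class = "vestsim_error_validation")
})

test_that("pressure under constant angular acceleration matches 2*rho*A*alpha", {
  geom <- all_duct_geometry(R = 3.2, lumen = 0.225)
  imp <- ramp_impulse(100)  # 100 rad/s^2
  tr <- transcupular_pressure(imp, geom)
  expected_mid <- 2 * 1000 * (pi * 3.2^2) * 1e-6 * 100   # ~6.434 Pa
  expect_equal(tr$p_middle_pa, rep(expected_mid, nrow(tr)), tolerance = 1e-9)
  expected_sup <- 2 * 1000 * (pi * 3.425^2) * 1e-6 * 100
  expect_equal(tr$p_superior_pa, rep(expected_sup, nrow(tr)), tolerance = 1e-9)
  expect_equal(tr$p_mean_pa, (tr$p_middle_pa + tr$p_superior_pa) / 2,
               tolerance = 1e-12)
})

test_that("constant-velocity rotation produces zero pressure", {
  tr <- transcupular_pressure(head_impulse(rep(120, 100)), make_normal_geometry())
  expect_equal(tr$p_mean_pa, rep(0, 100))
  expect_equal(pressure_increment(tr), 0)
})

test_that("the pressure law is exactly linear in the head-velocity trace", {
  geom <- make_normal_geometry()
  imp1 <- synth_impulse(100)
  imp3 <- head_impulse(3 * imp1$velocity_dps)
  tr1 <- transcupular_pressure(imp1, geom)
  tr3 <- transcupular_pressure(imp3, geom)
  expect_equal(tr3$p_mean_pa, 3 * tr1$p_mean_pa, tolerance = 1e-14)
  expect_equal(tr3$p_superior_pa, 3 * tr1$p_superior_pa, tolerance = 1e-14)
  expect_equal(pressure_increment(tr3), 3 * pressure_increment(tr1))
})

test_that("pressure integrates to zero over impulses returning to rest", {
  geom <- make_normal_geometry()
  for (peak in c(102.62, 249.47)) {
    tr <- transcupular_pressure(synth_impulse(peak), geom)
    for (col in c("p_middle_pa", "p_superior_pa", "p_mean_pa")) {
      net <- pracma::trapz(tr$time_s, tr[[col]])
      expect_lt(abs(net), 0.005 * max(abs(tr[[col]])) * 0.7)
    }
  }
})

test_that("pressure increment follows the max-abs rule and scales linearly", {
  tr <- fake_pressure_trace(c(0, 1.5, -2.0, 0))
  expect_equal(pressure_increment(tr), 2.0)
  expect_equal(pressure_increment(fake_pressure_trace(rep(0, 4))), 0)
})

test_that("single-segment canal enhancement matches the circle-area closed form", {
  geom <- all_duct_geometry(R = 3.2, lumen = 0.225)
  hyd <- apply_canal_hydrops(geom, 1.3 / 0.45)
  imp <- synth_impulse(173.81)
  factor <- enhancement_factor(
    transcupular_pressure(imp, hyd),
    transcupular_pressure(imp, geom)
  )
  closed_form <- (pi * 3.2^2 + pi * 3.85^2) / (pi * 3.2^2 + pi * 3.425^2)
  expect_equal(factor, closed_form, tolerance = 1e-12)
  expect_equal(factor, 1.1405, tolerance = 5e-4)
})

test_that("default hydropic geometries give the calibrated enhancement factors", {
  geoms <- default_geometries()
  imp <- synth_impulse(173.81)
  trn <- transcupular_pressure(imp, geoms$none)
  canal <- enhancement_factor(transcupular_pressure(imp, geoms$canal), trn)
  utric <- enhancement_factor(transcupular_pressure(imp, geoms$utricular), trn)
  expect_equal(canal, 1.14, tolerance = 1e-4)
  expect_equal(utric, 1.10, tolerance = 1e-4)
  expect_gt(canal, utric)
  expect_gt(utric, 1)
})

test_that("enhancement factor is invariant to impulse peak and waveform", {
  geoms <- default_geometries()
  factors <- vapply(
    list(synth_impulse(102.62), synth_impulse(249.47),
         synth_impulse(173.81, profile = "raised_cosine")),
    function(imp) {
      enhancement_factor(
        transcupular_pressure(imp, geoms$canal),
        transcupular_pressure(imp, geoms$none)
      )
    },
    numeric(1)
  )
  expect_equal(factors[2], factors[1], tolerance = 1e-12)
  expect_equal(factors[3], factors[1], tolerance = 1e-12)
})

test_that("enhancement factor increases strictly with the dilation factor", {
  geom <- make_normal_geometry()
  imp <- synth_impulse(150)
  trn <- transcupular_pressure(imp, geom)
  factors <- vapply(c(1.2, 1.8, 2.4, 1.3 / 0.45), function(f) {
    enhancement_factor(transcupular_pressure(imp, apply_canal_hydrops(geom, f)), trn)
  }, numeric(1))
  expect_true(all(diff(factors) > 0))

  # undefined for a zero normal increment
  expect_error(
    enhancement_factor(trn, fake_pressure_trace(rep(0, 10))),
    class = "vestsim_error_validation"
  )
})
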