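# Calibration, position dose rates, the distance sweep, placement
# selection, and the prescription-time arithmetic.

test_that("calibration is exact at the reference point and linear", {
  curve <- structure(data.frame(depth_mm = seq(0.5, 8, 0.5),
                                value = 1e-10 * exp(-seq(0.5, 8, 0.5) / 2),
                                rel_unc = 0),
                     class = c("depth_dose_curve", "data.frame"))
  cert <- certificate_data(2, 80, seq(0.5, 8, 0.5),
                           80 * exp(-(seq(0.5, 8, 0.5) - 2) / 2))
  s <- calibrate(curve, cert)
  v2 <- stats::approx(curve$depth_mm, curve$value, 2)$y
  expect_equal(1000 * s * v2, cert$reference_dose_rate)
  # doubling the certified rate doubles the calibrated field
  cert2 <- certificate_data(2, 160, cert$table$depth_mm,
                            2 * cert$table$dose_rate)
  expect_equal(calibrate(curve, cert2), 2 * s)
  # zero simulated dose is rejected
  bad <- curve; bad$value <- bad$value * 0
  expect_error(calibrate(bad, cert), class = "ruplaque_invalid_input")
})

test_that("position rates from the MC field reproduce voxel values and flag outside points", {
  g <- fx_small_run()
  fld <- calibrated_field(g, scale = 2e9, component = "beta")
  idx <- which(grid_dose(g, "beta") > 0, arr.ind = TRUE)[10, ]
  ctr <- g$origin + (idx - 0.5) * g$h
  r <- position_dose_rates(fld, matrix(ctr, 1))
  expect_equal(r$rate_mGy_min,
               1000 * 2e9 * grid_dose(g, "beta")[idx[1], idx[2], idx[3]])
  expect_error(position_dose_rates(fld, matrix(c(50, 0, 0), 1)),
               class = "ruplaque_invalid_input")
})

test_that("kernel and MC backends agree at the reference positions", {
  cs <- fx_case()
  pp <- place_plaque(cs$plaque, cs$eye, 2, cs$contact_angle_deg)
  pos <- locate_positions(cs$eye)
  g <- run_mc(fx_source(), cs$plaque, pp,
              transport_config(n_histories = 5e5, seed = 77,
                               include_gammas = FALSE),
              grid = eye_grid(cs$eye))
  mc <- position_dose_rates(calibrated_field(g, 1, component = "beta"), pos)
  kr <- position_dose_rates(
    calibrated_field(list(plaque = cs$plaque, placement = pp,
                          kernel = fx_kernel()), 1), pos)
  # statistical tolerance: the per-position MC uncertainty at this size is
  # several percent, so allow 3 sigma on top of a 10% model band
  for (i in 1:6) {
    tol <- 0.10 + 3 * mc$rel_unc[i]
    expect_lt(abs(mc$rate_mGy_min[i] / kr$rate_mGy_min[i] - 1), tol)
  }
})

test_that("sweeping a single distance matches a direct evaluation", {
  cs <- fx_case()
  sw1 <- sweep_distance(cs$plaque, cs$eye, fx_kernel(), scale = 1e9,
                        d_grid = 2, contact_angle_deg = cs$contact_angle_deg)
  expect_equal(nrow(sw1), 1)
  full <- fx_sweep()
  ratio <- as.numeric(sw1[1, paste0("r", 1:6)]) /
    as.numeric(full[full$d_mm == 2, paste0("r", 1:6)])
  expect_equal(ratio / ratio[1], rep(1, 6), tolerance = 1e-6)
})

test_that("placement selection applies the anatomical constraint", {
  sw <- data.frame(d_mm = 0:4, feasible = c(TRUE, TRUE, TRUE, TRUE, TRUE),
                   r1 = 1:5, r2 = 1:5, r3 = 1:5, r4 = 1:5, r5 = 1:5,
                   r6 = 1:5)
  class(sw) <- c("sweep_table", "data.frame")
  expect_equal(select_placement(sw, d_min = 2), 2)
  expect_equal(select_placement(sw, d_min = 0), 0)
  sw$feasible <- FALSE
  expect_error(select_placement(sw, 2), class = "ruplaque_infeasible")
})

test_that("required time and delivered dose reproduce the clinical arithmetic", {
  expect_equal(round_half_up(required_time(40, 25.5), 1), 26.1)
  # the printed 26.2 h corresponds to an unrounded rate near 25.45 mGy/min
  expect_equal(round_half_up(required_time(40, 25.45), 1), 26.2)
  expect_equal(round_half_up(delivered_dose(25.5, 47.0), 1), 71.9)
  expect_equal(round_half_up(delivered_dose(19.5, 47.0), 1), 55.0)
  expect_lt(required_time(40, 1e9), 1e-6)  # rate -> infinity: time -> 0
  expect_equal(required_time(80, 25.5), 2 * required_time(40, 25.5))
  expect_equal(delivered_dose(25.5, 0), 0)
  expect_error(required_time(40, 0), class = "ruplaque_invalid_input")
  expect_error(delivered_dose(-1, 2), class = "ruplaque_invalid_input")
})

test_that("delivered dose after the required time returns the prescription exactly", {
  set.seed(3)
  for (i in 1:50) {
    rate <- stats::runif(1, 1, 200)
    dose <- stats::runif(1, 1, 100)
    expect_equal(delivered_dose(rate, required_time(dose, rate)), dose,
                 tolerance = 1e-12)
  }
})

test_that("the prescription minimum is taken over the coverage positions only", {
  # optic-disc points (5, 6) are evaluated, never prescribed to
  rates <- c(25.5, 40, 50, 30, 10, 9)
  plan <- plan_from_rates(rates, prescription_dose = 40)
  expect_equal(plan$limiting_position, 1)
  expect_equal(plan$limiting_rate, 25.5)
  plan2 <- plan_from_rates(rates, coverage_positions = 2:3)
  expect_equal(plan2$limiting_position, 2)
})

test_that("plan_from_rates reproduces the reported delivered doses", {
  rates <- c(25.5, NA, NA, NA, 21.4, 19.5)
  plan <- plan_from_rates(rates, prescription_dose = 40, attach_time = 47.0)
  expect_equal(round_half_up(plan$delivered_Gy[1], 1), 71.9)
  expect_equal(round_half_up(plan$delivered_Gy[6], 1), 55.0)
  # attach time omitted -> delivered at the required time
  plan0 <- plan_from_rates(rates, prescription_dose = 40)
  expect_equal(plan0$attach_time_h, plan0$required_time_h)
  expect_equal(plan0$delivered_Gy[1], 40)
})

test_that("planning outputs scale linearly with the certificate rate", {
  full <- fx_sweep()
  p1 <- build_plan(full, d_min = 2, prescription_dose = 40)
  sw2 <- full
  sw2[paste0("r", 1:6)] <- sw2[paste0("r", 1:6)] * 3
  p2 <- build_plan(sw2, d_min = 2, prescription_dose = 40)
  expect_equal(p2$limiting_rate, 3 * p1$limiting_rate)
  expect_equal(p2$required_time_h, p1$required_time_h / 3)
})

test_that("certificate files round-trip", {
  cert <- certificate_data(2, 129.6, seq(0.5, 10, 0.5),
                           129.6 * exp(-(seq(0.5, 10, 0.5) - 2) / 3))
  f <- tempfile(fileext = ".tsv")
  write_certificate(cert, f)
  cert2 <- read_certificate(f)
  expect_equal(cert2$reference_depth, cert$reference_depth)
  expect_equal(cert2$reference_dose_rate, cert$reference_dose_rate)
  expect_equal(cert2$table$dose_rate, cert$table$dose_rate,
               tolerance = 1e-6)
})
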