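# Beta spectrum construction, gamma-line selection and emission sampling.

simpson <- function(x, y) {
  # independent quadrature oracle (composite Simpson on an odd grid)
  n <- length(x)
  if (n %% 2 == 0) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  h <- (x[n] - x[1]) / (n - 1)
  h / 3 * (y[1] + y[n] + 4 * sum(y[seq(2, n - 1, 2)]) +
             2 * sum(y[seq(3, n - 2, 2)]))
}

test_that("spectrum is normalized and vanishes at the endpoint for a range of inputs", {
  for (q in c(0.5, 1.0, 2.0, 3.541)) {
    sp <- build_beta_spectrum(endpoint_energy = q, grid_size = 401)
    expect_equal(ruplaque:::trapz(sp$energy_grid, sp$density), 1,
                 tolerance = 1e-6)
    expect_true(all(sp$density >= 0))
    expect_equal(sp$density[length(sp$density)], 0)
  }
  expect_error(build_beta_spectrum(endpoint_energy = -1),
               class = "ruplaque_invalid_input")
  expect_error(build_beta_spectrum(grid_size = 100),
               class = "ruplaque_invalid_input")
})

test_that("mean energy matches an independent quadrature of the returned density", {
  sp <- build_beta_spectrum(endpoint_energy = 3.541, daughter_z = 46,
                            grid_size = 801)
  oracle <- simpson(sp$energy_grid, sp$energy_grid * sp$density) /
    simpson(sp$energy_grid, sp$density)
  expect_equal(spectrum_mean_energy(sp), oracle, tolerance = 5e-4)
})

test_that("statistical shape with unit Fermi function peaks at the analytic stationary point", {
  q <- 1.0
  sp <- build_beta_spectrum(endpoint_energy = q, grid_size = 2001,
                            fermi = FALSE)
  me <- ruplaque:::ELECTRON_REST_MEV
  shape <- function(e) sqrt(e * (e + 2 * me)) * (e + me) * (q - e)^2
  analytic_peak <- stats::optimize(shape, c(1e-6, q), maximum = TRUE)$maximum
  grid_peak <- sp$energy_grid[which.max(sp$density)]
  expect_lt(abs(grid_peak - analytic_peak), diff(sp$energy_grid[1:2]) * 1.5)
})

test_that("gamma line selection is strict, order preserving and idempotent", {
  lines <- data.frame(energy_MeV = c(0.5, 0.62, 1.05, 1.1, 2.0),
                      intensity_per_decay = c(0.20, 0.10, 0.001, 5e-4, 1e-4))
  kept <- select_gamma_lines(lines, 6e-4)
  expect_equal(nrow(kept), 3)
  expect_equal(kept$energy_MeV, c(0.5, 0.62, 1.05))
  # exactly at the threshold -> excluded ("more than" per decay)
  at_thr <- data.frame(energy_MeV = 1, intensity_per_decay = 6e-4)
  expect_equal(nrow(select_gamma_lines(at_thr, 6e-4)), 0)
  # below threshold -> excluded
  below <- data.frame(energy_MeV = 1, intensity_per_decay = 5e-4)
  expect_equal(nrow(select_gamma_lines(below, 6e-4)), 0)
  expect_identical(select_gamma_lines(kept, 6e-4), kept)
  expect_equal(nrow(select_gamma_lines(lines[0, ], 6e-4)), 0)
})

test_that("the bundled line table filters at load and the source term enforces it", {
  src <- fx_source()
  expect_true(all(src$gammas$intensity_per_decay > src$gamma_threshold))
  raw <- read_gamma_lines()
  expect_gt(nrow(raw), nrow(src$gammas))  # sub-threshold lines exist
  expect_error(source_term(src$beta, raw, 6e-4),
               class = "ruplaque_invalid_input")
})

test_that("emission sampling is deterministic, respects the source and matches the CDF", {
  src <- fx_source()
  beta_only <- source_term(src$beta, src$gammas[0, ], 6e-4)
  set.seed(42)
  em <- sample_emission(beta_only, 200)
  expect_true(all(em$kind == "beta"))
  set.seed(99); a <- sample_emission(src, 500)
  set.seed(99); b <- sample_emission(src, 500)
  expect_identical(a, b)

  set.seed(1)
  es <- sample_emission(beta_only, 1e5)$energy
  # Kolmogorov-Smirnov distance against an independent empirical-CDF oracle
  cdf_tab <- ruplaque:::spectrum_cdf(src$beta)
  ks <- suppressWarnings(stats::ks.test(
    es, function(q) stats::approx(src$beta$energy_grid, cdf_tab, q,
                                  yleft = 0, yright = 1)$y))
  expect_lt(unname(ks$statistic), 1.628 / sqrt(1e5))  # 1% critical value
  # empirical mean within 3 standard errors of the quadrature mean
  mu <- spectrum_mean_energy(src$beta)
  se <- stats::sd(es) / sqrt(length(es))
  expect_lt(abs(mean(es) - mu), 3 * se)
})

test_that("spectrum export/import round-trips", {
  sp <- build_beta_spectrum()
  f <- tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  sp2 <- read_spectrum(f)
  expect_equal(sp2$energy_grid, sp$energy_grid, tolerance = 1e-8)
  expect_equal(sp2$density, sp$density, tolerance = 1e-6)
})
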