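# Deterministic dose-point-kernel engine and the cap surface integral.

test_that("kernel conserves the spectrum mean energy and rejects bad input", {
  K <- fx_kernel_coarse()
  expect_equal(kernel_energy_integral(K), K$mean_beta_energy,
               tolerance = 0.01)
  bad <- fx_source()$beta
  bad$density <- bad$density * 2
  expect_error(build_point_kernel(bad), class = "ruplaque_invalid_input")
})

test_that("a spectrum concentrated at one energy reduces to the monoenergetic kernel", {
  e0 <- 1.0
  eg <- seq(e0 - 0.01, e0 + 0.01, length.out = 300)
  dens <- exp(-((eg - e0) / 0.003)^2)
  dens <- dens / ruplaque:::trapz(eg, dens)
  sp <- structure(list(energy_grid = eg, density = dens,
                       endpoint_energy = max(eg), daughter_z = 46),
                  class = "beta_spectrum")
  Kn <- build_point_kernel(sp, n_groups = 4, ds = 0.04, drho = 0.04,
                           n_mu = 64, legendre_order = 48)
  mono <- point_kernel_mono(e0, ds = 0.04, drho = 0.04, n_mu = 64,
                            legendre_order = 48,
                            rho_max = max(Kn$radii) + 0.04)
  sel <- Kn$radii > 1 & Kn$radii < 3.5
  mv <- stats::approx(mono$radius_mm, mono$deposit_MeV, Kn$radii[sel])$y
  expect_equal(Kn$deposit_MeV[sel], mv, tolerance = 0.02)
})

test_that("kernel vanishes beyond the endpoint CSDA range", {
  K <- fx_kernel_coarse()
  r_end <- csda_range_water_mm(fx_source()$beta$endpoint_energy)
  expect_equal(kernel_value(K, r_end + 0.5), 0)
  expect_equal(sum(K$deposit_MeV[K$radii > r_end + 0.2]), 0, tolerance = 1e-9)
})

test_that("on-axis cap dose matches a 1-D ring-reduced oracle", {
  K <- fx_kernel()
  pl <- plaque_model()
  pc <- placement_concentric(pl)
  f_ag <- silver_weq_factor(K$mean_beta_energy)
  excess <- (f_ag - 1) * pl$window_thickness
  Rem <- pl$emission_radius
  for (depth in c(1.05, 2.05, 4.05)) {
    # displaced field point (planar-limit window model), 1-D ring reduction
    z_eff <- depth + excess
    integrand <- function(th) {
      dd <- sqrt(Rem^2 * sin(th)^2 +
                   (pl$curvature_radius - Rem * cos(th) - z_eff)^2)
      kernel_value(K, dd) * sin(th)
    }
    num <- stats::integrate(integrand, 0, pl$active_half_angle,
                            rel.tol = 1e-8, subdivisions = 500)$value
    den <- 1 - cos(pl$active_half_angle)
    oracle <- num / den
    got <- cap_dose(pl, pc, c(0, 0, depth), K, rel_tol = 1e-4)
    expect_equal(got, oracle, tolerance = 2e-3)
  }
})

test_that("mirror-symmetric points receive equal dose", {
  K <- fx_kernel_coarse()
  pl <- plaque_model()
  pc <- placement_concentric(pl)
  v <- cap_dose(pl, pc, rbind(c(1.5, 0.7, 2), c(-1.5, -0.7, 2)), K)
  expect_equal(v[1], v[2], tolerance = 1e-6)
})

test_that("points beyond three CSDA ranges receive zero dose", {
  K <- fx_kernel_coarse()
  pl <- plaque_model()
  pc <- placement_concentric(pl)
  r3 <- 3 * csda_range_water_mm(fx_source()$beta$endpoint_energy)
  expect_equal(cap_dose(pl, pc, c(0, 0, r3), K), 0)
})

test_that("quadrature refinement is converged at the working resolution", {
  K <- fx_kernel_coarse()
  pl <- plaque_model()
  pc <- placement_concentric(pl)
  pts <- rbind(c(0, 0, 1.05), c(0, 0, 3.05), c(3, 0, 2.05), c(6.5, 0, 2.05))
  a <- ruplaque:::cap_dose_fixed(pl, pc, pts, K, 256, 512,
                                 silver_weq_factor(K$mean_beta_energy))
  b <- ruplaque:::cap_dose_fixed(pl, pc, pts, K, 512, 1024,
                                 silver_weq_factor(K$mean_beta_energy))
  expect_lt(max(abs(a - b) / b), 0.002)
})

test_that("kernel table export/import round-trips", {
  K <- fx_kernel_coarse()
  f <- tempfile(fileext = ".tsv")
  write_kernel(K, f)
  K2 <- read_kernel(f, mean_beta_energy = K$mean_beta_energy)
  expect_equal(K2$dose_per_decay_at_r, K$dose_per_decay_at_r,
               tolerance = 1e-6)
  expect_equal(K2$radii, K$radii, tolerance = 1e-8)
})
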