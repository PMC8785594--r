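# Shared fixtures, memoised across test files.  Everything is generated in
# code; the heavier Monte Carlo runs and the spectrum kernel are built once
# per test session.

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

fx_source <- function() memo("source", ru106_source_term())

# full-resolution kernel (matches the validation workflow)
fx_kernel <- function() memo("kernel", build_point_kernel(fx_source()$beta))

# coarse kernel for cheap geometric checks
fx_kernel_coarse <- function() {
  memo("kernel_coarse",
       build_point_kernel(fx_source()$beta, n_groups = 6, ds = 0.04,
                          drho = 0.04, n_mu = 64, legendre_order = 48))
}

# concentric validation run (engine cross-check conditions: water behind
# the backing so both engines model the same medium)
fx_val_run <- function() {
  memo("val_run", {
    run_mc(fx_source(), plaque_model(), placement_concentric(plaque_model()),
           transport_config(n_histories = 1e6, seed = 101,
                            backing = "transmit"))
  })
}

# bare point source in water (direct kernel cross-check)
fx_point_run <- function() {
  memo("point_run", {
    run_mc(fx_source(),
           config = transport_config(n_histories = 2e5, seed = 7,
                                     include_gammas = FALSE),
           mode = "point")
  })
}

# small, fast plaque run for bookkeeping/determinism checks
fx_small_run <- function(seed = 5, n = 2e4) {
  run_mc(fx_source(), plaque_model(), placement_concentric(plaque_model()),
         transport_config(n_histories = n, seed = seed),
         grid = validation_grid(half_width = 4, z_range = c(-1, 5)))
}

# coarse-voxel run: enough deposits per voxel for stable variance
# estimates in the statistical-scaling checks
fx_coarse_run <- function(seed, n) {
  run_mc(fx_source(), plaque_model(), placement_concentric(plaque_model()),
         transport_config(n_histories = n, seed = seed,
                          scoring_voxel = 0.25),
         grid = list(origin = c(-4, -4, -1), n = c(32L, 32L, 24L), h = 0.25))
}

# default case objects and kernel-backend sweep
fx_case <- function() memo("case", case_objects(gen_case()))

fx_sweep <- function() {
  memo("sweep", {
    cs <- fx_case()
    kcurve <- kernel_depth_dose(cs$plaque, fx_kernel(),
                                depths = seq(0.05, 10.05, 0.1))
    cert <- gen_certificate(synthetic_certificate_spec(noise_sd = 0),
                            shape = data.frame(depth_mm = kcurve$depth_mm,
                                               value = kcurve$value))
    scale <- calibrate(kcurve, cert)
    sweep_distance(cs$plaque, cs$eye, fx_kernel(), scale,
                   d_grid = cs$plan$d_grid,
                   contact_angle_deg = cs$contact_angle_deg)
  })
}
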