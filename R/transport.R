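# R surface of the Monte Carlo dose engine: configuration, grid
# construction, the run wrapper, per-voxel uncertainty, and extraction of
# depth-dose curves and lateral profiles.

#' Transport configuration
#'
#' @param n_histories number of decays to simulate (>= 1).
#' @param seed integer RNG seed for the engine's PCG32 stream.
#' @param cutoff_range_water electron termination criterion: residual CSDA
#'   range in water, mm; residual energy is deposited locally.
#' @param target_uncertainty target dose-weighted relative standard error
#'   for uncertainty-driven stopping (used by the validation workflow).
#' @param scoring_voxel voxel edge of the scoring grid, mm.
#' @param step_weq condensed-history step in water-equivalent mm.
#' @param include_gammas transport the retained gamma lines (scored as a
#'   separate dose component).
#' @param n_batches number of batches for energy-conservation bookkeeping
#'   and batch-means uncertainty.
#' @param backing `"absorb"` terminates electrons crossing the outer
#'   backing surface (physical applicator, treatment default);
#'   `"transmit"` places water behind the shell so electrons may re-enter,
#'   which matches the unbounded-medium assumption of the deterministic
#'   kernel and is used for engine cross-validation.
#' @return object of class `transport_config`.
#' @export
transport_config <- function(n_histories = 1e6, seed = 1,
                             cutoff_range_water = 0.1,
                             target_uncertainty = 0.05,
                             scoring_voxel = 0.1, step_weq = 0.02,
                             include_gammas = TRUE, n_batches = 10,
                             backing = c("absorb", "transmit")) {
  backing <- match.arg(backing)
  if (cutoff_range_water <= 0) stop_invalid("cutoff range must be positive")
  if (scoring_voxel <= 0) stop_invalid("scoring voxel must be positive")
  if (step_weq <= 0 || step_weq > 0.02 + 1e-12) {
    stop_invalid("step must be positive and at most 0.02 mm water-equivalent")
  }
  structure(list(n_histories = as.integer(n_histories), seed = seed,
                 cutoff_range_water = cutoff_range_water,
                 target_uncertainty = target_uncertainty,
                 scoring_voxel = scoring_voxel, step_weq = step_weq,
                 include_gammas = include_gammas,
                 n_batches = as.integer(n_batches),
                 backing = backing),
            class = "transport_config")
}

#' Scoring grid specifications
#'
#' `validation_grid()` is a box in the concentric validation frame (cap
#' pole at the origin, water on the +z side); `eye_grid()` covers the eye
#' sphere plus a margin.
#'
#' @param voxel voxel edge, mm.
#' @param half_width lateral half-width, mm.
#' @param z_range axial range, mm.
#' @return list with `origin`, `n`, `h`.
#' @export
validation_grid <- function(voxel = 0.1, half_width = 10,
                            z_range = c(-1, 9)) {
  n_xy <- round(2 * half_width / voxel)
  n_z <- round(diff(z_range) / voxel)
  list(origin = c(-half_width, -half_width, z_range[1]),
       n = c(n_xy, n_xy, n_z), h = voxel)
}

#' @rdname validation_grid
#' @param eye an `eye_model`.
#' @param margin margin beyond the eye sphere, mm (>= 2 per the grid
#'   coverage contract).
#' @export
eye_grid <- function(eye, voxel = 0.1, margin = 2.2) {
  half <- eye$eye_radius + margin
  n <- round(2 * half / voxel)
  list(origin = c(-half, -half, -half), n = c(n, n, n), h = voxel)
}

#' Run the Monte Carlo dose engine
#'
#' Tracks one beta per decay (plus the retained gamma lines with their
#' per-decay intensities) from the active layer of the placed plaque, or
#' from a bare isotropic point source, and scores dose per decay on the
#' voxel grid with history-by-history variance.
#'
#' @param source a `source_term`.
#' @param plaque a `plaque_model` (ignored in point mode).
#' @param placement a `plaque_placement` (ignored in point mode).
#' @param config a `transport_config`.
#' @param grid grid spec from [validation_grid()] or [eye_grid()]; default
#'   a validation grid (plaque mode) or a centered box (point mode).
#' @param mode `"plaque"` or `"point"` (bare point source in unbounded
#'   water, used for direct kernel cross-checks).
#' @return object of class `dose_grid`.
#' @export
run_mc <- function(source, plaque = NULL, placement = NULL,
                   config = transport_config(), grid = NULL,
                   mode = c("plaque", "point")) {
  mode <- match.arg(mode)
  stopifnot(inherits(source, "source_term"),
            inherits(config, "transport_config"))
  if (config$n_histories < 1) stop_invalid("zero-history run rejected")
  if (mode == "plaque") {
    stopifnot(inherits(plaque, "plaque_model"),
              inherits(placement, "plaque_placement"))
    if (is.null(grid)) grid <- validation_grid(config$scoring_voxel)
    b <- perp_basis(placement$axis)
    geom <- list(mode = 1L, center = placement$center,
                 axis = placement$axis, e1 = b$e1, e2 = b$e2,
                 r_inner = plaque$curvature_radius,
                 r_outer = plaque$outer_radius,
                 r_emission = plaque$emission_radius,
                 cap_half_angle = plaque$cap_half_angle,
                 active_half_angle = plaque$active_half_angle,
                 backing_absorb = (config$backing == "absorb"))
  } else {
    if (is.null(grid)) {
      grid <- list(origin = c(-10, -10, -10), n = c(200L, 200L, 200L),
                   h = config$scoring_voxel)
    }
    geom <- list(mode = 0L)
  }
  tw <- physics_tables()$water
  tp <- physics_tables()$photon
  phys <- list(energy = tw$energy_MeV,
               sw_per_mm = tw$stopping_MeV_cm2_g * 0.1,
               range_mm = tw$csda_range_g_cm2 * 10,
               f_silver = silver_weq_factor(tw$energy_MeV),
               photon_energy = tp$energy_MeV,
               photon_mu_per_mm = tp$mu_cm2_g * 0.1,
               photon_muen_per_mm = tp$muen_cm2_g * 0.1,
               f_photon_silver = SILVER_PHOTON_WEQ)
  qt <- spectrum_quantile_table(source$beta)
  has_g <- config$include_gammas && nrow(source$gammas) > 0
  gE <- if (has_g) source$gammas$energy_MeV else numeric(0)
  gI <- if (has_g) source$gammas$intensity_per_decay else numeric(0)
  cfg <- list(cutoff_range_water = config$cutoff_range_water,
              step_weq = config$step_weq,
              include_gammas = has_g,
              n_batches = config$n_batches)
  raw <- mc_run_cpp(config$n_histories, config$seed, qt, gE, gI,
                    geom, list(origin = grid$origin, n = as.integer(grid$n),
                               h = grid$h),
                    phys, cfg)
  n <- config$n_histories
  conv <- MEV_TO_J / (grid$h^3 * 1e-6)  # MeV per voxel -> Gy (water voxel)
  dims <- as.integer(grid$n)
  mk <- function(v, p = 1) array(v * conv^p / n, dim = dims)
  tallies <- data.frame(
    batch = seq_len(config$n_batches),
    emitted_MeV = as.numeric(raw$batch_emitted),
    deposited_grid_MeV = as.numeric(raw$batch_dep_grid),
    deposited_outside_MeV = as.numeric(raw$batch_dep_outside),
    absorbed_backing_MeV = as.numeric(raw$batch_absorbed_backing),
    gamma_residual_MeV = as.numeric(raw$batch_gamma_residual)
  )
  structure(list(
    origin = grid$origin, h = grid$h, dim = dims,
    n_histories = n, seed = config$seed, mode = mode,
    beta = mk(raw$beta_sum),
    beta_ssq = array(as.numeric(raw$beta_ssq) * conv^2, dim = dims),
    gamma = if (has_g) mk(raw$gamma_sum) else NULL,
    gamma_ssq = if (has_g) array(as.numeric(raw$gamma_ssq) * conv^2,
                                 dim = dims) else NULL,
    tallies = tallies,
    config = config,
    placement = if (mode == "plaque") placement else NULL,
    plaque = if (mode == "plaque") plaque else NULL
  ), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf(
    "dose grid: %d x %d x %d voxels (%.2f mm), %s mode, %d histories, seed %g\n",
    x$dim[1], x$dim[2], x$dim[3], x$h, x$mode, x$n_histories, x$seed))
  invisible(x)
}

#' Dose component of a grid
#'
#' @param grid a `dose_grid`.
#' @param component `"total"`, `"beta"` or `"gamma"`.
#' @return array of dose per decay, Gy.
#' @export
grid_dose <- function(grid, component = c("total", "beta", "gamma")) {
  component <- match.arg(component)
  if (component == "beta") return(grid$beta)
  if (component == "gamma") {
    if (is.null(grid$gamma)) stop_invalid("grid has no gamma component")
    return(grid$gamma)
  }
  if (is.null(grid$gamma)) grid$beta else grid$beta + grid$gamma
}

# per-voxel relative standard error of the per-decay mean
grid_rel_unc <- function(grid, component = c("total", "beta", "gamma")) {
  component <- match.arg(component)
  n <- grid$n_histories
  vmean <- function(mean_arr, ssq_arr) {
    s2 <- pmax(ssq_arr / n - mean_arr^2, 0) * n / (n - 1)
    s2 / n
  }
  if (component == "beta" || is.null(grid$gamma)) {
    m <- grid$beta; v <- vmean(grid$beta, grid$beta_ssq)
  } else if (component == "gamma") {
    m <- grid$gamma; v <- vmean(grid$gamma, grid$gamma_ssq)
  } else {
    # beta and gamma treated as independent components (covariance ignored)
    m <- grid$beta + grid$gamma
    v <- vmean(grid$beta, grid$beta_ssq) + vmean(grid$gamma, grid$gamma_ssq)
  }
  out <- array(0, dim = dim(m))
  nz <- m > 0
  out[nz] <- sqrt(v[nz]) / m[nz]
  out
}

#' Dose-weighted mean relative uncertainty over a region
#'
#' @param grid a `dose_grid`.
#' @param region logical array (same dim as the grid) or voxel indices;
#'   `NULL` selects all voxels with positive dose.
#' @param component dose component.
#' @return dose-weighted mean relative standard error (fraction).
#' @export
estimate_uncertainty <- function(grid, region = NULL,
                                 component = c("total", "beta", "gamma")) {
  component <- match.arg(component)
  d <- grid_dose(grid, component)
  r <- grid_rel_unc(grid, component)
  if (is.null(region)) region <- d > 0
  dv <- d[region]; rv <- r[region]
  if (length(dv) == 0) stop_invalid("empty region for uncertainty estimate")
  if (sum(dv) == 0) return(0)
  sum(dv * rv) / sum(dv)
}

# voxel center coordinates relative to the placement axis:
# t = depth along -axis from the inner-surface pole, r = off-axis distance
.grid_axis_coords <- function(grid) {
  placement <- grid$placement
  plaque <- grid$plaque
  if (is.null(placement)) {  # point mode: axis +z from the origin
    pole <- c(0, 0, 0); dirn <- c(0, 0, 1)
  } else {
    pole <- placement_pole(plaque, placement)
    dirn <- -placement$axis
  }
  cx <- grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$h
  cy <- grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$h
  cz <- grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$h
  X <- array(rep(cx, times = grid$dim[2] * grid$dim[3]), dim = grid$dim)
  Y <- array(rep(rep(cy, each = grid$dim[1]), times = grid$dim[3]),
             dim = grid$dim)
  Z <- array(rep(cz, each = grid$dim[1] * grid$dim[2]), dim = grid$dim)
  dx <- X - pole[1]; dy <- Y - pole[2]; dz <- Z - pole[3]
  t <- dx * dirn[1] + dy * dirn[2] + dz * dirn[3]
  r2 <- pmax(dx^2 + dy^2 + dz^2 - t^2, 0)
  list(t = t, r = sqrt(r2), b = perp_basis(dirn),
       s = dx * perp_basis(dirn)$e1[1] + dy * perp_basis(dirn)$e1[2] +
         dz * perp_basis(dirn)$e1[3])
}

#' Extract the central-axis depth-dose curve
#'
#' Averages voxels within `avg_radius` of the central axis, binned by depth
#' from the midpoint of the inner surface (scoring-grid resolution).  The
#' small averaging disc emulates a finite detector area and reduces
#' statistical noise; bin uncertainties assume independent voxels.
#'
#' @param grid a `dose_grid` (plaque or point mode).
#' @param max_depth deepest bin, mm.
#' @param avg_radius off-axis averaging radius, mm.
#' @param component dose component.
#' @return `depth_dose_curve` data.frame: `depth_mm`, `value` (Gy/decay),
#'   `rel_unc`, `n_vox`.
#' @export
extract_depth_dose <- function(grid, max_depth = 8, avg_radius = 0.25,
                               component = c("beta", "total", "gamma")) {
  component <- match.arg(component)
  co <- .grid_axis_coords(grid)
  d <- grid_dose(grid, component)
  ru <- grid_rel_unc(grid, component)
  sel <- co$r <= avg_radius & co$t > 0 & co$t <= max_depth + grid$h / 2
  if (!any(sel)) stop_invalid("central axis does not intersect the grid")
  bins <- floor(co$t[sel] / grid$h)
  dv <- d[sel]; rv <- ru[sel]
  val <- tapply(dv, bins, mean)
  nv <- tapply(dv, bins, length)
  se <- sqrt(tapply((dv * rv)^2, bins, sum)) / nv
  depth <- (as.numeric(names(val)) + 0.5) * grid$h
  if (max(depth) < max_depth - grid$h) {
    stop_invalid("central axis exits the grid before %.1f mm depth", max_depth)
  }
  structure(data.frame(depth_mm = depth, value = as.numeric(val),
                       rel_unc = ifelse(val > 0, as.numeric(se) / as.numeric(val), 0),
                       n_vox = as.numeric(nv)),
            class = c("depth_dose_curve", "data.frame"),
            engine = "mc")
}

#' Extract a lateral dose profile at fixed depth
#'
#' Averages voxels whose depth from the inner surface lies in the scoring
#' window, binned by off-axis distance (or by the signed in-plane
#' transverse coordinate with `signed = TRUE`).
#'
#' @param grid a `dose_grid`.
#' @param depth_window depth scoring window, mm (default the 2.25-2.35 mm
#'   window used for the 2.3 mm profile).
#' @param r_max maximum off-axis distance, mm.
#' @param signed use the signed transverse coordinate restricted to a thin
#'   slab (|second transverse coordinate| <= 0.35 mm).
#' @param component dose component.
#' @return `lateral_profile` data.frame: `off_axis_mm`, `value`,
#'   `rel_unc`, `n_vox`.
#' @export
extract_lateral_profile <- function(grid, depth_window = c(2.25, 2.35),
                                    r_max = 9.5, signed = FALSE,
                                    component = c("beta", "total", "gamma")) {
  component <- match.arg(component)
  if (diff(depth_window) <= 0) stop_invalid("empty depth window")
  co <- .grid_axis_coords(grid)
  d <- grid_dose(grid, component)
  ru <- grid_rel_unc(grid, component)
  in_win <- co$t >= depth_window[1] & co$t < depth_window[2]
  if (!any(in_win)) stop_invalid("depth window outside the grid")
  if (signed) {
    perp2 <- sqrt(pmax(co$r^2 - co$s^2, 0))
    sel <- in_win & abs(co$s) <= r_max & perp2 <= 0.35
    coord <- co$s[sel]
  } else {
    sel <- in_win & co$r <= r_max
    coord <- co$r[sel]
  }
  bins <- round(coord / grid$h)
  dv <- d[sel]; rv <- ru[sel]
  val <- tapply(dv, bins, mean)
  nv <- tapply(dv, bins, length)
  se <- sqrt(tapply((dv * rv)^2, bins, sum)) / nv
  structure(data.frame(off_axis_mm = as.numeric(names(val)) * grid$h,
                       value = as.numeric(val),
                       rel_unc = ifelse(val > 0, as.numeric(se) / as.numeric(val), 0),
                       n_vox = as.numeric(nv)),
            class = c("lateral_profile", "data.frame"),
            engine = "mc", depth = mean(depth_window))
}

#' Radial dose profile around a point source
#'
#' Spherical-shell average of a point-mode run, for direct comparison with
#' the dose-point kernel.
#'
#' @param grid a `dose_grid` from a point-mode run.
#' @param r_max outermost shell, mm.
#' @param component dose component.
#' @return data.frame `radius_mm`, `value` (Gy/decay), `rel_unc`, `n_vox`.
#' @export
extract_radial_dose <- function(grid, r_max = 9,
                                component = c("beta", "total", "gamma")) {
  component <- match.arg(component)
  if (grid$mode != "point") stop_invalid("radial extraction needs a point-mode grid")
  d <- grid_dose(grid, component)
  ru <- grid_rel_unc(grid, component)
  cx <- grid$origin[1] + (seq_len(grid$dim[1]) - 0.5) * grid$h
  cy <- grid$origin[2] + (seq_len(grid$dim[2]) - 0.5) * grid$h
  cz <- grid$origin[3] + (seq_len(grid$dim[3]) - 0.5) * grid$h
  X <- array(rep(cx, times = grid$dim[2] * grid$dim[3]), dim = grid$dim)
  Y <- array(rep(rep(cy, each = grid$dim[1]), times = grid$dim[3]),
             dim = grid$dim)
  Z <- array(rep(cz, each = grid$dim[1] * grid$dim[2]), dim = grid$dim)
  r <- sqrt(X^2 + Y^2 + Z^2)
  sel <- r <= r_max
  bins <- floor(r[sel] / grid$h)
  dv <- d[sel]; rv <- ru[sel]
  val <- tapply(dv, bins, mean)
  nv <- tapply(dv, bins, length)
  se <- sqrt(tapply((dv * rv)^2, bins, sum)) / nv
  data.frame(radius_mm = (as.numeric(names(val)) + 0.5) * grid$h,
             value = as.numeric(val),
             rel_unc = ifelse(val > 0, as.numeric(se) / as.numeric(val), 0),
             n_vox = as.numeric(nv))
}

#' Trilinear interpolation of a dose component at arbitrary points
#'
#' @param grid a `dose_grid`.
#' @param points n x 3 matrix of points, mm.
#' @param component dose component.
#' @return list with `value` (Gy/decay) and `rel_unc` at each point.
#' @export
grid_interp <- function(grid, points, component = c("total", "beta", "gamma")) {
  component <- match.arg(component)
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  d <- grid_dose(grid, component)
  ru <- grid_rel_unc(grid, component)
  val <- numeric(nrow(points)); unc <- numeric(nrow(points))
  for (ip in seq_len(nrow(points))) {
    f <- (points[ip, ] - grid$origin) / grid$h - 0.5
    i0 <- floor(f); w <- f - i0; i0 <- as.integer(i0) + 1L
    if (any(i0 < 1) || any(i0 + 1 > grid$dim)) {
      stop_invalid("interpolation point outside the dose grid")
    }
    acc <- 0; acc_v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) w[1] else 1 - w[1]) *
            (if (dy) w[2] else 1 - w[2]) *
            (if (dz) w[3] else 1 - w[3])
      v <- d[i0[1] + dx, i0[2] + dy, i0[3] + dz]
      r <- ru[i0[1] + dx, i0[2] + dy, i0[3] + dz]
      acc <- acc + wt * v
      acc_v <- acc_v + (wt * v * r)^2
    }
    val[ip] <- acc
    unc[ip] <- if (acc > 0) sqrt(acc_v) / acc else 0
  }
  list(value = val, rel_unc = unc)
}

#' Persist / load a dose grid
#'
#' Run-time artifact container (RDS) carrying the dose arrays and their
#' metadata (origin, voxel size, histories, seed).
#'
#' @param grid a `dose_grid`.
#' @param path file path.
#' @export
save_dose_grid <- function(grid, path) {
  saveRDS(grid, path)
  invisible(path)
}

#' @rdname save_dose_grid
#' @export
load_dose_grid <- function(path) {
  g <- readRDS(path)
  stopifnot(inherits(g, "dose_grid"))
  g
}
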