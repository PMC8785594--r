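# Deterministic dose-point-kernel engine: monoenergetic kernels from the
# phase-space transport solver, superposed over the beta spectrum, and
# numerically integrated over the active spherical-cap source.  Serves as
# the independent cross-check oracle for the Monte Carlo engine and as the
# fast backend for placement planning.

MEV_TO_J <- 1.602176634e-13

#' Monoenergetic electron dose-point kernel in water
#'
#' Radial dose distribution around an isotropic point source of
#' monoenergetic electrons in unbounded water, computed by deterministic
#' phase-space transport (see the methods vignette).  Shares stopping-power
#' data and the multiple-scattering law with the Monte Carlo engine but uses
#' entirely different numerics.
#'
#' @param energy initial kinetic energy, MeV.
#' @param ds path-length step, mm (water-equivalent).
#' @param drho radial bin width, mm.
#' @param n_mu number of direction-cosine quadrature nodes.
#' @param legendre_order maximum Legendre order for the scattering
#'   convolution.
#' @param cutoff_range_water residual-range cutoff, mm.
#' @param rho_max radial extent of the kernel grid, mm (default: CSDA range
#'   plus 1 mm).
#' @return data.frame with `radius_mm` (bin centers) and `deposit_MeV`
#'   (energy deposited per emission in each spherical shell).
#' @export
point_kernel_mono <- function(energy, ds = 0.02, drho = 0.02, n_mu = 96,
                              legendre_order = 64, cutoff_range_water = 0.1,
                              rho_max = NULL) {
  if (energy <= 0) stop_invalid("kernel energy must be positive")
  if (is.null(rho_max)) rho_max <- csda_range_water_mm(energy) + 1
  t <- physics_tables()$water
  out <- dpk_solve_cpp(energy, t$energy_MeV, t$stopping_MeV_cm2_g * 0.1,
                       t$csda_range_g_cm2 * 10, cutoff_range_water,
                       ds, drho, n_mu, legendre_order, rho_max)
  data.frame(radius_mm = out$radii, deposit_MeV = out$deposit_MeV)
}

#' Build the beta dose-point kernel for a spectrum
#'
#' Superposes monoenergetic kernels at the conditional mean energies of
#' equal-probability spectrum groups, weighted by the group probabilities.
#'
#' @param spectrum a normalized `beta_spectrum`.
#' @param n_groups number of equal-probability energy groups.
#' @param ds,drho,n_mu,legendre_order,cutoff_range_water numerics passed to
#'   [point_kernel_mono()].
#' @return object of class `point_kernel` with fields `radii` (mm),
#'   `dose_per_decay_at_r` (Gy per beta decay at radius r in water),
#'   `deposit_MeV` (per-shell energy), `mean_beta_energy` (MeV) and the
#'   solver settings.
#' @export
build_point_kernel <- function(spectrum, n_groups = 16, ds = 0.02,
                               drho = 0.02, n_mu = 96, legendre_order = 64,
                               cutoff_range_water = 0.1) {
  stopifnot(inherits(spectrum, "beta_spectrum"))
  norm <- trapz(spectrum$energy_grid, spectrum$density)
  if (abs(norm - 1) > 1e-6) {
    stop_invalid("spectrum is not normalized (integral %.8f)", norm)
  }
  grp <- spectrum_groups(spectrum, n_groups)
  rho_max <- csda_range_water_mm(max(grp$energy)) + 1
  dep <- NULL
  for (j in seq_len(nrow(grp))) {
    k <- point_kernel_mono(grp$energy[j], ds = ds, drho = drho, n_mu = n_mu,
                           legendre_order = legendre_order,
                           cutoff_range_water = cutoff_range_water,
                           rho_max = rho_max)
    if (is.null(dep)) {
      radii <- k$radius_mm
      dep <- grp$prob[j] * k$deposit_MeV
    } else {
      dep <- dep + grp$prob[j] * k$deposit_MeV
    }
  }
  shell_mass_g <- 4 * pi * radii^2 * drho * 1e-3  # water, rho = 1 g/cm^3
  kGy <- dep * MEV_TO_J / (shell_mass_g * 1e-3)   # J per kg per decay
  structure(list(
    radii = radii,
    dose_per_decay_at_r = kGy,
    deposit_MeV = dep,
    mean_beta_energy = spectrum_mean_energy(spectrum),
    groups = grp, drho = drho,
    settings = list(ds = ds, n_mu = n_mu, legendre_order = legendre_order,
                    cutoff_range_water = cutoff_range_water)
  ), class = "point_kernel")
}

# equal-probability groups: probabilities and conditional mean energies
spectrum_groups <- function(spectrum, n_groups) {
  e <- seq(min(spectrum$energy_grid), spectrum$endpoint_energy,
           length.out = 4000)
  d <- stats::approx(spectrum$energy_grid, spectrum$density, e, rule = 2)$y
  de <- e[2] - e[1]
  p <- d * de
  p <- p / sum(p)
  cdf <- cumsum(p)
  edges <- findInterval(cdf, seq(0, 1, length.out = n_groups + 1),
                        rightmost.closed = TRUE)
  edges[edges < 1] <- 1
  edges[edges > n_groups] <- n_groups
  prob <- as.numeric(tapply(p, edges, sum))
  emean <- as.numeric(tapply(p * e, edges, sum)) / prob
  data.frame(group = seq_along(prob), prob = prob, energy = emean)
}

#' Kernel energy-conservation integral
#'
#' @param kernel a `point_kernel`.
#' @return total energy carried by the kernel,
#'   `sum(4 pi r^2 rho K(r) dr)`, MeV per decay.
#' @export
kernel_energy_integral <- function(kernel) {
  sum(kernel$deposit_MeV)
}

#' @export
print.point_kernel <- function(x, ...) {
  cat(sprintf(
    "beta dose-point kernel: %d groups, mean energy %.3f MeV, support %.1f mm, energy integral %.4f MeV\n",
    nrow(x$groups), x$mean_beta_energy, max(x$radii),
    kernel_energy_integral(x)))
  invisible(x)
}

#' Evaluate a point kernel at arbitrary radii
#'
#' Linear interpolation; zero beyond the kernel support.
#'
#' @param kernel a `point_kernel`.
#' @param r radii, mm.
#' @return dose per decay, Gy.
#' @export
kernel_value <- function(kernel, r) {
  out <- stats::approx(kernel$radii, kernel$dose_per_decay_at_r, r,
                       yleft = kernel$dose_per_decay_at_r[1], yright = 0)$y
  out[r > max(kernel$radii)] <- 0
  out
}

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
gauss_legendre_r <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = 2))
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  ev <- eigen(J, symmetric = TRUE)
  ord <- order(ev$values)
  list(nodes = ev$values[ord], weights = 2 * ev$vectors[1, ord]^2)
}

#' Dose per decay from the active cap source at arbitrary points
#'
#' Numerical surface integral of the point kernel over the active portion
#' of the emission layer, with the silver window folded in through a
#' water-equivalence model (`window_model`, see below and the methods
#' vignette).  Quadrature is refined (doubling both angular resolutions)
#' until the result changes by less than `rel_tol`; refinement is
#' restricted to points that have not yet converged, and non-convergence
#' raises a warning of class `ruplaque_quadrature` carrying the achieved
#' tolerance.
#'
#' @param plaque a `plaque_model`.
#' @param placement a `plaque_placement`.
#' @param points numeric vector (length 3) or n x 3 matrix of eye-frame
#'   points, mm; points must lie in the medium (water side).
#' @param kernel a `point_kernel`.
#' @param rel_tol relative convergence tolerance.
#' @param n_theta,n_phi starting quadrature resolution.
#' @param max_refine maximum number of doublings.
#' @param f_silver water-equivalence factor of silver (default: evaluated
#'   at the kernel's mean beta energy).
#' @param window_model silver-window treatment.  `"shift"` (default)
#'   removes the window and displaces the field point away from the shell
#'   by the water-equivalent excess of a normal crossing — exact in the
#'   planar limit under density scaling.  `"curved"` adds the extra
#'   straight-ray path of the curved-shell chord beyond the locally planar
#'   chord; `"blend"` is the midpoint of the two; `"chord"`, `"plane"` and
#'   `"normal"` are simpler per-ray scaled-distance variants kept for
#'   comparison.
#' @return dose per decay at each point, Gy.
#' @export
cap_dose <- function(plaque, placement, points, kernel, rel_tol = 1e-3,
                     n_theta = 64, n_phi = 128, max_refine = 4,
                     f_silver = NULL,
                     window_model = c("shift", "blend", "curved", "hybrid", "chord", "plane", "normal")) {
  window_model <- match.arg(window_model)
  if (window_model == "blend") {
    # midpoint of the two bracketing window treatments: the displaced-point
    # planar-limit model (no obliquity penalty, over-predicts close to the
    # window) and the curved-chord model (straight-ray penalty,
    # under-predicts there); see the methods vignette
    a <- cap_dose(plaque, placement, points, kernel, rel_tol, n_theta,
                  n_phi, max_refine, f_silver, window_model = "shift")
    b <- cap_dose(plaque, placement, points, kernel, rel_tol, n_theta,
                  n_phi, max_refine, f_silver, window_model = "curved")
    return((a + b) / 2)
  }
  stopifnot(inherits(plaque, "plaque_model"),
            inherits(placement, "plaque_placement"),
            inherits(kernel, "point_kernel"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  if (ncol(points) != 3) stop_invalid("points must be n x 3")
  if (is.null(f_silver)) {
    me <- kernel$mean_beta_energy
    if (!is.finite(me)) me <- 1.41
    f_silver <- silver_weq_factor(me)
  }

  out <- cap_dose_fixed(plaque, placement, points, kernel,
                        n_theta, n_phi, f_silver, window_model)
  todo <- seq_len(nrow(points))
  achieved <- Inf
  for (i in seq_len(max_refine)) {
    n_theta <- n_theta * 2L
    n_phi <- n_phi * 2L
    cur <- cap_dose_fixed(plaque, placement, points[todo, , drop = FALSE],
                          kernel, n_theta, n_phi, f_silver, window_model)
    rel <- ifelse(cur > 0, abs(cur - out[todo]) / cur, 0)
    out[todo] <- cur
    achieved <- max(rel)
    todo <- todo[rel >= rel_tol]   # refine only unconverged points
    if (length(todo) == 0) return(out)
  }
  warning(warningCondition(
    sprintf("cap dose quadrature did not reach rel_tol %.1e (achieved %.1e)",
            rel_tol, achieved),
    class = "ruplaque_quadrature"))
  out
}

cap_dose_fixed <- function(plaque, placement, points, kernel,
                           n_theta, n_phi, f_silver,
                           window_model = "shift") {
  Rem <- plaque$emission_radius
  wth <- plaque$window_thickness
  gl <- gauss_legendre_r(n_theta)
  clo <- cos(plaque$active_half_angle)
  cth <- (gl$nodes + 1) / 2 * (1 - clo) + clo   # cos(theta) in [clo, 1]
  wq <- gl$weights / 2                          # area weights, sum = 1
  phis <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  b <- perp_basis(placement$axis)
  sth <- sqrt(pmax(0, 1 - cth^2))
  # source directions: n_theta*n_phi x 3
  dirs <- matrix(0, n_theta * n_phi, 3)
  for (j in seq_len(3)) {
    dirs[, j] <- rep(cth, n_phi) * placement$axis[j] +
      rep(sth, n_phi) * (rep(cos(phis), each = n_theta) * b$e1[j] +
                         rep(sin(phis), each = n_theta) * b$e2[j])
  }
  S <- matrix(placement$center, n_theta * n_phi, 3, byrow = TRUE) + Rem * dirs
  w_node <- rep(wq, n_phi) / n_phi
  out <- numeric(nrow(points))
  points0 <- points
  if (window_model %in% c("shift", "hybrid", "curved")) {
    # planar-scaling window treatment: the silver window is removed and the
    # field point is displaced away from the shell by the water-equivalent
    # excess of a normal crossing (exact in the planar limit)
    excess <- (f_silver - 1) * wth
    dirn <- t(apply(points, 1, function(p) unit(placement$center - p)))
    points <- points + excess * dirn
  }
  ss <- rowSums(S^2)
  sdir <- rowSums(S * dirs)
  # process points in blocks with BLAS matrix products
  blk <- max(1L, floor(2e6 / nrow(S)))
  for (i0 in seq(1, nrow(points), by = blk)) {
    ii <- i0:min(i0 + blk - 1, nrow(points))
    P <- points[ii, , drop = FALSE]
    SP <- S %*% t(P)                       # m x b
    d <- sqrt(pmax(outer(ss, rowSums(P^2), "+") - 2 * SP, 0))
    # obliquity through the silver window: angle to the inward normal (-dir)
    cosb <- -(dirs %*% t(P) - sdir) / pmax(d, 1e-12)
    # exact geometric chord of the ray inside the spherical silver shell:
    # inward rays exit through the inner-surface sphere; rays that miss it
    # (grazing/outward) exit through the outer backing sphere
    Rin <- plaque$curvature_radius
    Rout2 <- plaque$outer_radius^2
    disc_in <- Rem^2 * cosb^2 - (Rem^2 - Rin^2)
    t_in <- Rem * cosb - sqrt(pmax(disc_in, 0))
    t_out <- Rem * cosb + sqrt(pmax(Rem^2 * cosb^2 + Rout2 - Rem^2, 0))
    t_sil <- ifelse(cosb > 0 & disc_in >= 0, t_in, t_out)
    t_sil <- pmin(t_sil, d)
    if (window_model == "shift") {
      t_sil <- 0
    } else if (window_model == "curved") {
      # planar-limit displaced-point base plus the extra water-equivalent
      # path of the curved-shell chord beyond the locally planar chord
      # (zero for near-normal and grazing rays, positive at moderate
      # obliquity where the concave shell lengthens the crossing)
      P0 <- points0[ii, , drop = FALSE]
      d0 <- sqrt(pmax(outer(ss, rowSums(P0^2), "+") - 2 * S %*% t(P0), 0))
      cosb0 <- -(dirs %*% t(P0) - sdir) / pmax(d0, 1e-12)
      disc0 <- Rem^2 * cosb0^2 - (Rem^2 - Rin^2)
      t_ch <- ifelse(cosb0 > 0 & disc0 >= 0,
                     Rem * cosb0 - sqrt(pmax(disc0, 0)), 0)
      t_pl <- ifelse(cosb0 > 0, wth / pmax(cosb0, 1e-3), Inf)
      extra <- (f_silver - 1) * pmax(pmin(t_ch, d0) - t_pl, 0)
      de <- d + extra
      kv <- matrix(kernel_value(kernel, de), nrow(S))
      out[ii] <- as.numeric(crossprod(kv, w_node))
      next
    } else if (window_model == "hybrid") {
      # displaced-point (planar-limit) contribution, bounded by the
      # straight-ray chord contribution: each is exact in a complementary
      # limit and over-predicts outside it, so take the smaller
      P0 <- points0[ii, , drop = FALSE]
      d0 <- sqrt(pmax(outer(ss, rowSums(P0^2), "+") - 2 * S %*% t(P0), 0))
      k_shift <- kernel_value(kernel, d)            # d is shifted-point dist
      de_ch <- d0 + (f_silver - 1) * t_sil
      k_chord <- kernel_value(kernel, de_ch) * (de_ch / pmax(d0, kernel$drho))^2
      kv <- matrix(pmin(k_shift, k_chord), nrow(S))
      out[ii] <- as.numeric(crossprod(kv, w_node))
      next
    } else if (window_model == "normal") {
      # normal-incidence crossing for rays reaching the water side: lateral
      # transport is delegated to the in-water kernel spread
      t_sil <- ifelse(cosb > 0 & disc_in >= 0, wth, t_sil)
    } else if (window_model == "plane") {
      # locally planar slab: obliquity to the surface normal, unclamped
      # (exact for the planar-source limit under density scaling)
      t_sil <- ifelse(cosb > 0, wth / pmax(cosb, 1e-3), t_sil)
    }
    d_eff <- d + (f_silver - 1) * t_sil
    # attenuation at the water-equivalent distance, inverse-square
    # spreading at the geometric distance (standard scaled-kernel split)
    dg <- pmax(d, kernel$drho)
    kv <- matrix(kernel_value(kernel, d_eff), nrow(S))
    out[ii] <- as.numeric(crossprod(kv * (d_eff / dg)^2, w_node))
  }
  out
}

#' Central-axis depth dose of the plaque from the kernel engine
#'
#' @param plaque a `plaque_model`.
#' @param kernel a `point_kernel`.
#' @param depths depths from the midpoint of the inner surface along the
#'   central axis, mm.
#' @param placement placement to evaluate in (default: concentric
#'   reference frame).
#' @param avg_radius radius of a transverse averaging disc, mm (0 = pure
#'   axis values); use the same disc as the Monte Carlo extraction when
#'   comparing curves.
#' @param ... passed to [cap_dose()].
#' @return object of class `depth_dose_curve`: data.frame with `depth_mm`,
#'   `value` (Gy per decay), `rel_unc` (0 for the deterministic engine).
#' @export
kernel_depth_dose <- function(plaque, kernel, depths = seq(0.05, 8.05, 0.1),
                              placement = placement_concentric(plaque),
                              avg_radius = 0, ...) {
  pole <- placement_pole(plaque, placement)
  axis_pts <- matrix(pole, length(depths), 3, byrow = TRUE) -
    outer(depths, placement$axis)
  if (avg_radius <= 0) {
    v <- cap_dose(plaque, placement, axis_pts, kernel, ...)
  } else {
    # area-weighted rings reproducing a finite detector disc
    rr <- seq(0.05, avg_radius - 0.05, 0.1)
    b <- perp_basis(placement$axis)
    v <- rep(0, length(depths))
    for (r in rr) {
      v <- v + r * cap_dose(plaque, placement,
                            axis_pts + matrix(r * b$e1, length(depths), 3,
                                              byrow = TRUE),
                            kernel, ...)
    }
    v <- v / sum(rr)
  }
  structure(data.frame(depth_mm = depths, value = v, rel_unc = 0),
            class = c("depth_dose_curve", "data.frame"),
            engine = "kernel")
}

#' Lateral dose profile from the kernel engine
#'
#' @param plaque,kernel,placement as in [kernel_depth_dose()].
#' @param depth depth of the profile plane, mm.
#' @param off_axis off-axis distances (signed, along the first transverse
#'   basis vector), mm.
#' @param ... passed to [cap_dose()].
#' @return data.frame `off_axis_mm`, `value`, `rel_unc`.
#' @export
kernel_lateral_profile <- function(plaque, kernel, depth = 2.3,
                                   off_axis = seq(-9.5, 9.5, 0.1),
                                   placement = placement_concentric(plaque),
                                   ...) {
  pole <- placement_pole(plaque, placement)
  b <- perp_basis(placement$axis)
  ctr <- pole - depth * placement$axis
  pts <- matrix(ctr, length(off_axis), 3, byrow = TRUE) +
    outer(off_axis, b$e1)
  v <- cap_dose(plaque, placement, pts, kernel, ...)
  structure(data.frame(off_axis_mm = off_axis, value = v, rel_unc = 0),
            class = c("lateral_profile", "data.frame"),
            engine = "kernel", depth = depth)
}

#' Export / import a point kernel as a delimited table
#'
#' @param kernel a `point_kernel`.
#' @param path TSV path.
#' @return invisibly `path` (write) or a `point_kernel` (read).
#' @export
write_kernel <- function(kernel, path) {
  utils::write.table(
    data.frame(radius_mm = kernel$radii,
               dose_per_decay_Gy = kernel$dose_per_decay_at_r,
               deposit_MeV = kernel$deposit_MeV),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @param mean_beta_energy stored mean energy when reading, MeV.
#' @export
read_kernel <- function(path, mean_beta_energy = NA_real_) {
  t <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(radii = t$radius_mm,
                 dose_per_decay_at_r = t$dose_per_decay_Gy,
                 deposit_MeV = t$deposit_MeV,
                 mean_beta_energy = mean_beta_energy,
                 groups = NULL, drho = diff(t$radius_mm[1:2]),
                 settings = NULL),
            class = "point_kernel")
}
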