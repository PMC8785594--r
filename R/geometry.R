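# Geometry of the concave plaque applicator, the (infant) eye, the tilted
# placement parameterized by the posterior-edge distance d, and the six
# anatomical reference positions.
#
# Coordinate convention: eye-centered frame, posterior pole along +x, the
# horizontal evaluation plane is z = 0.  In-plane angles are measured from
# the posterior pole axis in degrees, positive toward the temporal side
# (+y).  All lengths in mm.

#' Concave plaque applicator model
#'
#' A spherical-cap applicator with three concentric silver layers (inner
#' window, source-bearing middle layer, outer backing) and a peripheral
#' inactive rim.  The emitter is a uniform surface density over the active
#' portion of the middle layer; a surface point is active iff its
#' along-surface distance from the cap edge exceeds `inactive_rim`.
#'
#' @param curvature_radius inner-surface radius of curvature, mm (adult
#'   applicators are designed between 12 and 14 mm).
#' @param cap_diameter chord diameter of the cap, mm.
#' @param layer_thicknesses thicknesses (inner, middle, outer), mm, silver.
#' @param inactive_rim width of the source-free peripheral band measured
#'   along the cap surface from the edge, mm.
#' @return object of class `plaque_model`.
#' @export
plaque_model <- function(curvature_radius = 12, cap_diameter = 15.3,
                         layer_thicknesses = c(0.1, 0.2, 0.3),
                         inactive_rim = 0.8) {
  if (curvature_radius <= 0 || cap_diameter <= 0) {
    stop_invalid("plaque radii must be positive")
  }
  if (cap_diameter / 2 >= curvature_radius) {
    stop_invalid("cap chord radius must be smaller than the curvature radius")
  }
  if (inactive_rim < 0 || inactive_rim >= cap_diameter / 2) {
    stop_invalid("inactive rim (%.2f mm) must be in [0, cap radius)", inactive_rim)
  }
  alpha <- asin((cap_diameter / 2) / curvature_radius)
  alpha_act <- alpha - inactive_rim / curvature_radius
  if (alpha_act <= 0) stop_invalid("inactive rim leaves no active area")
  structure(list(
    curvature_radius = curvature_radius,
    cap_diameter = cap_diameter,
    layer_thicknesses = layer_thicknesses,
    inactive_rim = inactive_rim,
    cap_half_angle = alpha,
    active_half_angle = alpha_act,
    # emission surface: mid-plane of the source-bearing middle layer
    emission_radius = curvature_radius + layer_thicknesses[1] +
      layer_thicknesses[2] / 2,
    outer_radius = curvature_radius + sum(layer_thicknesses),
    # silver traversed from the emission surface to the concave side
    window_thickness = layer_thicknesses[1] + layer_thicknesses[2] / 2
  ), class = "plaque_model")
}

#' @export
print.plaque_model <- function(x, ...) {
  cat(sprintf(
    "plaque: curvature radius %.1f mm, cap diameter %.1f mm, rim %.1f mm, active chord %.2f mm\n",
    x$curvature_radius, x$cap_diameter, x$inactive_rim,
    active_chord_diameter(x)))
  invisible(x)
}

#' Chord diameter of the active source area
#'
#' @param plaque a `plaque_model`.
#' @return closed-form chord diameter of the active cap region, mm.
#' @export
active_chord_diameter <- function(plaque) {
  2 * plaque$curvature_radius * sin(plaque$active_half_angle)
}

#' Classify a cap surface point as active or inactive
#'
#' @param plaque a `plaque_model`.
#' @param theta polar angle(s) of surface points from the cap axis, radians.
#' @return logical: active source region?
#' @export
is_active_cap_point <- function(plaque, theta) {
  along <- plaque$curvature_radius * (plaque$cap_half_angle - theta)
  theta <= plaque$cap_half_angle & along > plaque$inactive_rim
}

#' Eye model with case-specific anatomy
#'
#' Angular positions are in-plane angles (degrees) from the posterior pole,
#' positive toward the temporal side.  Defaults describe a small infant eye
#' with a juxtapapillary tumor whose medial edge reaches the temporal edge
#' of the optic disc; the exact angles are declared reconstructions of a
#' schematic clinical geometry (see the methods vignette).
#'
#' @param eye_radius mm.
#' @param optic_disc_center_deg in-plane angle of the disc center (nasal
#'   side is negative).
#' @param optic_disc_diameter mm.
#' @param sheath_diameter optic nerve sheath diameter, mm, used for the
#'   default sheath lateral edge.
#' @param sheath_lateral_edge_deg temporal edge of the optic sheath at the
#'   sclera; default derived from `sheath_diameter`.
#' @param tumor_lateral_edge_deg temporal edge of the tumor.
#' @param tumor_medial_edge_deg nasal edge of the tumor; defaults to the
#'   temporal edge of the optic disc (juxtapapillary case).
#' @param reference_height dose reference height above the retinal surface, mm.
#' @return object of class `eye_model`.
#' @export
eye_model <- function(eye_radius = 9,
                      optic_disc_center_deg = -15,
                      optic_disc_diameter = 1.5,
                      sheath_diameter = 3.2,
                      sheath_lateral_edge_deg = NULL,
                      tumor_lateral_edge_deg = 26,
                      tumor_medial_edge_deg = NULL,
                      reference_height = 1) {
  if (eye_radius <= 0) stop_invalid("eye radius must be positive")
  if (reference_height < 0) stop_invalid("reference height must be >= 0")
  disc_half_deg <- rad2deg((optic_disc_diameter / 2) / eye_radius)
  disc_lateral_edge_deg <- optic_disc_center_deg + disc_half_deg
  if (is.null(sheath_lateral_edge_deg)) {
    sheath_lateral_edge_deg <- optic_disc_center_deg +
      rad2deg((sheath_diameter / 2) / eye_radius)
  }
  if (is.null(tumor_medial_edge_deg)) {
    tumor_medial_edge_deg <- disc_lateral_edge_deg
  }
  if (tumor_medial_edge_deg < disc_lateral_edge_deg - 1e-9) {
    stop_invalid("tumor medial edge (%.2f deg) extends beyond the optic disc edge (%.2f deg)",
                 tumor_medial_edge_deg, disc_lateral_edge_deg)
  }
  if (tumor_medial_edge_deg >= tumor_lateral_edge_deg) {
    stop_invalid("tumor edges must be ordered medial -> lateral")
  }
  structure(list(
    eye_radius = eye_radius,
    optic_disc_center_deg = optic_disc_center_deg,
    optic_disc_diameter = optic_disc_diameter,
    disc_lateral_edge_deg = disc_lateral_edge_deg,
    sheath_lateral_edge_deg = sheath_lateral_edge_deg,
    tumor_lateral_edge_deg = tumor_lateral_edge_deg,
    tumor_medial_edge_deg = tumor_medial_edge_deg,
    reference_height = reference_height
  ), class = "eye_model")
}

#' @export
print.eye_model <- function(x, ...) {
  cat(sprintf(
    "eye: radius %.1f mm; disc edge %.1f deg, sheath edge %.1f deg, tumor %.1f..%.1f deg\n",
    x$eye_radius, x$disc_lateral_edge_deg, x$sheath_lateral_edge_deg,
    x$tumor_medial_edge_deg, x$tumor_lateral_edge_deg))
  invisible(x)
}

#' Locate the six dose reference positions
#'
#' Positions 1-4 bracket the tumor edges (1: reference height above the
#' sheath lateral edge; 2: reference height above the tumor lateral edge;
#' 3/4: retinal surface at the tumor/sheath lateral edge); positions 5 and 6
#' probe the optic disc (5: retinal surface at the disc lateral edge;
#' 6: 1 mm deep, radially outward, from position 5).  "Above" means radially
#' inward (toward the eye center).
#'
#' @param eye an `eye_model`.
#' @return object of class `reference_positions`: 6 x 3 matrix of eye-frame
#'   coordinates (mm), rows `p1`..`p6`.
#' @export
locate_positions <- function(eye) {
  stopifnot(inherits(eye, "eye_model"))
  R <- eye$eye_radius
  h <- eye$reference_height
  phi_sheath <- deg2rad(eye$sheath_lateral_edge_deg)
  phi_tl <- deg2rad(eye$tumor_lateral_edge_deg)
  phi_dl <- deg2rad(eye$disc_lateral_edge_deg)
  p <- rbind(
    p1 = (R - h) * u_phi(phi_sheath),
    p2 = (R - h) * u_phi(phi_tl),
    p3 = R * u_phi(phi_tl),
    p4 = R * u_phi(phi_sheath),
    p5 = R * u_phi(phi_dl),
    p6 = (R + 1) * u_phi(phi_dl)
  )
  colnames(p) <- c("x", "y", "z")
  structure(p, class = c("reference_positions", "matrix", "array"))
}

#' Tilted plaque placement against the eye
#'
#' Physical placement model with a fixed anterior suture site.  For large
#' enough `d` the anterior inner-surface edge is pinned to the sclera at
#' `contact_angle_deg` and the in-plane tilt about that point is solved so
#' the gap between the posterior inner-surface edge and the eyeball equals
#' `d` (a 1-D root find, tolerance 1e-3 mm); tilting lifts the posterior
#' edge and simultaneously advances its footprint toward the optic disc.
#' For small `d` this pose would push the cap midsection into the eye
#' (the applicator's curvature radius exceeds the infant eye radius), so
#' the plaque instead rides tangentially on the sclera with the anterior
#' edge floating radially above the suture site -- the regime the paper's
#' clinical narrative describes as difficult to fixate; such poses are
#' returned with `mode = "riding"`.
#'
#' @param plaque a `plaque_model`.
#' @param eye an `eye_model`; requires `curvature_radius >= eye_radius`.
#' @param d edge distance: gap between the posterior plaque edge and the
#'   eyeball, mm (>= 0).
#' @param contact_angle_deg in-plane angle of the anterior-edge suture
#'   site.
#' @return object of class `plaque_placement` with the plaque `center`,
#'   unit `axis` (from the center of curvature to the cap pole), contact
#'   and edge points, tilt angle, realized gap, and `mode`
#'   (`"pinned"`/`"riding"`).
#' @export
place_plaque <- function(plaque, eye, d, contact_angle_deg = 105) {
  stopifnot(inherits(plaque, "plaque_model"), inherits(eye, "eye_model"))
  if (d < 0) stop_invalid("edge distance d must be >= 0 (got %g)", d)
  if (plaque$curvature_radius < eye$eye_radius) {
    stop_invalid("placement model assumes curvature radius >= eye radius")
  }
  Re <- eye$eye_radius
  Rp <- plaque$curvature_radius
  alpha <- plaque$cap_half_angle
  phi_c <- deg2rad(contact_angle_deg)
  tgrid <- seq(-alpha, alpha, length.out = 481)

  clearance_min2d <- function(Cp, psi) {
    px <- Cp[1] + Rp * cos(psi + tgrid)
    py <- Cp[2] + Rp * sin(psi + tgrid)
    min(sqrt(px^2 + py^2)) - Re
  }
  center_of <- function(ra, psi) ra * u_phi(phi_c) - Rp * u_phi(psi + alpha)
  gap_of <- function(ra, psi) {
    vnorm(center_of(ra, psi) + Rp * u_phi(psi - alpha)) - Re
  }

  # --- pinned branch: anterior edge on the sclera, rotate to gap d -------
  psi0 <- phi_c - alpha
  psis <- seq(psi0 - 1.3, psi0 + 0.7, length.out = 400)
  g <- vapply(psis, function(p) gap_of(Re, p), numeric(1)) - d
  sgn <- which(g[-1] * g[-length(g)] <= 0)
  mode <- NULL
  if (length(sgn) > 0) {
    i <- sgn[length(sgn)]
    psi <- stats::uniroot(function(p) gap_of(Re, p) - d,
                          c(psis[i], psis[i + 1]), tol = 1e-12)$root
    ra <- Re
    if (clearance_min2d(center_of(ra, psi), psi) >= -1e-4) mode <- "pinned"
  }

  # --- riding branch: anterior edge floats on the suture ray -------------
  if (is.null(mode)) {
    solve_contact <- function(psi) {
      f <- function(ra) clearance_min2d(center_of(ra, psi), psi)
      if (f(Re) >= -1e-9) return(Re)
      stats::uniroot(f, c(Re, Re + 3 * Rp), tol = 1e-10)$root
    }
    gap_ride <- function(psi) gap_of(solve_contact(psi), psi) - d
    gr <- vapply(psis, gap_ride, numeric(1))
    sgn <- which(gr[-1] * gr[-length(gr)] <= 0)
    if (length(sgn) == 0) {
      stop_infeasible("no tilt angle realizes edge distance d = %g mm", d)
    }
    i <- sgn[length(sgn)]
    psi <- stats::uniroot(gap_ride, c(psis[i], psis[i + 1]), tol = 1e-12)$root
    ra <- solve_contact(psi)
    mode <- "riding"
  }

  Cp <- center_of(ra, psi)
  axis <- u_phi(psi)
  post_edge <- Cp + Rp * u_phi(psi - alpha)
  ant_edge <- Cp + Rp * u_phi(psi + alpha)
  realized <- vnorm(post_edge) - Re
  if (abs(realized - d) > 1e-3) {
    stop_infeasible("placement gap solved to %.4g mm, outside tolerance",
                    realized - d)
  }
  if (placement_min_clearance(plaque, Cp, axis, Re) < -1e-3) {
    stop_infeasible("plaque inner surface would penetrate the eye at d = %g mm", d)
  }
  # realized contact point (closest cap point to the sclera)
  cl <- sqrt((Cp[1] + Rp * cos(psi + tgrid))^2 +
             (Cp[2] + Rp * sin(psi + tgrid))^2) - Re
  tc <- tgrid[which.min(cl)]
  contact <- Re * unit(Cp + Rp * u_phi(psi + tc))
  structure(list(
    center = Cp, axis = axis,
    contact_point = contact,
    contact_angle_deg = rad2deg(atan2(contact[2], contact[1])),
    suture_angle_deg = contact_angle_deg,
    anterior_edge = ant_edge,
    anterior_edge_float = vnorm(ant_edge) - Re,
    posterior_edge = post_edge,
    edge_distance_d = d, realized_gap = realized,
    axis_angle_deg = rad2deg(psi),
    tilt_deg = rad2deg(phi_c - psi),
    mode = mode, fixable = identical(mode, "pinned"),
    eye_radius = Re
  ), class = "plaque_placement")
}

# minimum of (|surface point| - eye radius) over the inner cap surface
placement_min_clearance <- function(plaque, center, axis, eye_radius,
                                    n_theta = 80, n_az = 72) {
  b <- perp_basis(axis)
  th <- seq(0, plaque$cap_half_angle, length.out = n_theta)
  az <- seq(0, 2 * pi, length.out = n_az + 1)[-1]
  ct <- cos(th); st <- sin(th)
  best <- Inf
  for (a in az) {
    dirs <- outer(ct, axis) + outer(st, cos(a) * b$e1 + sin(a) * b$e2)
    pts <- matrix(center, n_theta, 3, byrow = TRUE) +
      plaque$curvature_radius * dirs
    best <- min(best, sqrt(rowSums(pts^2)) - eye_radius)
  }
  best
}

#' Gap between the plaque inner surface and the sclera
#'
#' Distance from the scleral surface to the plaque inner sphere along the
#' outward radial direction, evaluated at in-plane angles.
#'
#' @param placement a `plaque_placement`.
#' @param plaque the `plaque_model` it was built from.
#' @param phi_deg in-plane scleral angles, degrees.
#' @return gaps in mm (plaque sphere radius minus distance from the plaque
#'   center to the scleral point; positive = stand-off).
#' @export
placement_gap_profile <- function(placement, plaque, phi_deg) {
  vapply(deg2rad(phi_deg), function(phi) {
    s <- placement$eye_radius * u_phi(phi)
    plaque$curvature_radius - vnorm(s - placement$center)
  }, numeric(1))
}

#' Concentric reference placement
#'
#' Places the plaque in a plain water frame with the cap pole at the origin
#' and the axis along -z (water on the +z side).  This is the configuration
#' used for depth-dose validation against a certificate.
#'
#' @param plaque a `plaque_model`.
#' @return `plaque_placement` object (no eye).
#' @export
placement_concentric <- function(plaque) {
  structure(list(
    center = c(0, 0, plaque$curvature_radius),
    axis = c(0, 0, -1),
    contact_point = c(0, 0, 0), contact_angle_deg = NA_real_,
    posterior_edge = NULL,
    edge_distance_d = 0, realized_gap = 0,
    axis_angle_deg = NA_real_, tilt_deg = 0,
    eye_radius = NA_real_
  ), class = "plaque_placement")
}

#' @export
print.plaque_placement <- function(x, ...) {
  if (is.na(x$tilt_deg) || is.null(x$posterior_edge)) {
    cat("concentric reference placement (validation frame)\n")
  } else {
    cat(sprintf(
      "tilted placement: d = %.3f mm (realized %.4f), contact at %.1f deg, tilt %.2f deg\n",
      x$edge_distance_d, x$realized_gap, x$contact_angle_deg, x$tilt_deg))
  }
  invisible(x)
}

# pole of the inner surface (depth-dose origin)
placement_pole <- function(plaque, placement) {
  placement$center + plaque$curvature_radius * placement$axis
}
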