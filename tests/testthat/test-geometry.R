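# Plaque construction, eye anatomy, reference positions and the tilted
# placement.

test_that("active area boundary matches a dense-mesh classification oracle", {
  pl <- plaque_model(cap_diameter = 15.3, inactive_rim = 0.8)
  th <- seq(0, pl$cap_half_angle, length.out = 20001)
  active <- is_active_cap_point(pl, th)
  mesh_chord <- 2 * pl$curvature_radius * sin(max(th[active]))
  expect_equal(mesh_chord, active_chord_diameter(pl),
               tolerance = 2 * diff(th[1:2]))
  # rim contains the cap edge
  expect_false(is_active_cap_point(pl, pl$cap_half_angle))
  # degenerate rim: full cap active
  pl0 <- plaque_model(inactive_rim = 0)
  expect_equal(active_chord_diameter(pl0), pl0$cap_diameter)
  expect_error(plaque_model(inactive_rim = 8),
               class = "ruplaque_invalid_input")
})

test_that("reference positions satisfy their distance and surface invariants", {
  eye <- eye_model()
  p <- locate_positions(eye)
  expect_equal(sqrt(sum((p["p1", ] - p["p4", ])^2)), eye$reference_height)
  expect_equal(sqrt(sum((p["p2", ] - p["p3", ])^2)), eye$reference_height)
  expect_equal(sqrt(sum((p["p5", ] - p["p6", ])^2)), 1)
  r <- sqrt(rowSums(p^2))
  expect_equal(unname(r[c("p3", "p4", "p5")]), rep(eye$eye_radius, 3))
  # points "above" the retina lie inside the sphere (vitreous side)
  expect_true(all(r[c("p1", "p2")] < eye$eye_radius))
  # degenerate reference height
  eye0 <- eye_model(reference_height = 0)
  p0 <- locate_positions(eye0)
  expect_equal(p0["p1", ], p0["p4", ])
  expect_equal(p0["p2", ], p0["p3", ])
})

test_that("inconsistent anatomy is rejected", {
  expect_error(eye_model(tumor_medial_edge_deg = -20),
               class = "ruplaque_invalid_input")
  expect_error(eye_model(eye_radius = -1), class = "ruplaque_invalid_input")
})

test_that("placement realizes the requested posterior-edge gap without penetration", {
  pl <- plaque_model()
  eye <- eye_model()
  for (d in c(0, 0.5, 1, 2, 3, 4)) {
    pp <- place_plaque(pl, eye, d)
    expect_lt(abs(pp$realized_gap - d), 1e-3)
    expect_gte(ruplaque:::placement_min_clearance(pl, pp$center, pp$axis,
                                                  eye$eye_radius), -1e-3)
    # some part of the cap is in contact with the sclera
    expect_lt(abs(sqrt(sum(pp$contact_point^2)) - eye$eye_radius), 1e-6)
  }
  expect_error(place_plaque(pl, eye, -1), class = "ruplaque_invalid_input")
})

test_that("tilt angle grows monotonically with the edge distance", {
  pl <- plaque_model()
  eye <- eye_model()
  tilts <- vapply(seq(0, 4, 0.5),
                  function(d) place_plaque(pl, eye, d)$tilt_deg, numeric(1))
  dt <- diff(tilts)
  expect_true(all(dt > 0) || all(dt < 0))
})

test_that("matched curvature gives conformal contact with zero gap everywhere", {
  pl <- plaque_model(curvature_radius = 9, cap_diameter = 12)
  eye <- eye_model()
  pp <- place_plaque(pl, eye, 0)
  expect_lt(abs(pp$realized_gap), 1e-6)
  th <- seq(-pl$cap_half_angle, pl$cap_half_angle, length.out = 101)
  pts <- t(vapply(th, function(t) {
    pp$center + pl$curvature_radius *
      ruplaque:::u_phi(ruplaque:::deg2rad(pp$axis_angle_deg) + t)
  }, numeric(3)))
  expect_lt(max(abs(sqrt(rowSums(pts^2)) - eye$eye_radius)), 1e-6)
})

test_that("geometry is invariant under a global rotation", {
  rot <- 37.3  # degrees, applied to every angular input
  eye1 <- eye_model()
  eye2 <- eye_model(optic_disc_center_deg = -15 + rot,
                    tumor_lateral_edge_deg = 26 + rot)
  p1 <- locate_positions(eye1); p2 <- locate_positions(eye2)
  pl <- plaque_model()
  pp1 <- place_plaque(pl, eye1, 2, contact_angle_deg = 105)
  pp2 <- place_plaque(pl, eye2, 2, contact_angle_deg = 105 + rot)
  all1 <- rbind(unclass(p1), center = pp1$center, edge = pp1$posterior_edge)
  all2 <- rbind(unclass(p2), center = pp2$center, edge = pp2$posterior_edge)
  expect_equal(as.numeric(dist(all1)), as.numeric(dist(all2)),
               tolerance = 1e-9)
})
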