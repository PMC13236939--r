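E_EFF <- foundation_modulus(6, 0.49)

test_that("joint coordinate system is orthonormal, centred and equivariant", {
  s <- default_cohort()[[4]]
  jcs <- build_jcs(s)
  B <- cbind(jcs$X, jcs$Y, jcs$Z)
  expect_lt(max(abs(crossprod(B) - diag(3))), 1e-10)
  expect_equal(jcs$origin,
               (s$landmarks$medial_epicondyle + s$landmarks$lateral_epicondyle) / 2)
  # rigidly transforming the specimen transforms the JCS by the same map
  R <- varusknee:::rotation_about_axis(c(1, 2, 3), 0.6)
  tr <- c(5, -1, 2)
  s2 <- varusknee:::apply_rigid_to_specimen(s, R, tr)
  jcs2 <- build_jcs(s2)
  expect_equal(jcs2$origin, as.numeric(R %*% jcs$origin) + tr, tolerance = 1e-10)
  expect_equal(jcs2$X, as.numeric(R %*% jcs$X), tolerance = 1e-10)
  expect_equal(jcs2$Z, as.numeric(R %*% jcs$Z), tolerance = 1e-10)
  # degenerate landmarks are rejected
  s$landmarks$lateral_epicondyle <- s$landmarks$medial_epicondyle
  expect_error(build_jcs(s), "coincident")
})

test_that("flexion posing is a rigid femoral rotation with an exact inverse", {
  s <- nominal_specimen(generator_config(nominal = coarse_nominal()))
  jcs <- build_jcs(s)
  expect_identical(pose_flexion(s, jcs, 0)$femur$vertices, s$femur$vertices)
  p <- pose_flexion(s, jcs, 80)
  back <- pose_flexion(p, jcs, -80)
  expect_lt(max(abs(back$femur$vertices - s$femur$vertices)), 1e-10)
  # rigidity: inter-vertex distances preserved
  idx <- seq(1, nrow(s$femur$vertices), by = 97)
  d0 <- dist(s$femur$vertices[idx, ])
  d1 <- dist(p$femur$vertices[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-10)
  # tibia is fixed
  expect_identical(p$tibia_fibula$vertices, s$tibia_fibula$vertices)
})

test_that("load redistribution is exact and conserves the total", {
  expect_equal(redistribute_load(2.94, 0), c(medial = 1.47, lateral = 1.47))
  expect_equal(redistribute_load(2.94, 50), c(medial = 2.205, lateral = 0.735))
  expect_equal(redistribute_load(2.94, 100), c(medial = 2.94, lateral = 0))
  for (lv in c(0, 50, 100))
    expect_identical(sum(redistribute_load(2.94, lv)), 2.94)
  expect_error(redistribute_load(2.94, 25), "unsupported")
})

test_that("gap field matches the paraboloid oracle and is linear in approach", {
  s <- sphere_plane_specimen(radius = 2, gap0 = 0.1, edge = 0.05)
  jcs <- build_jcs(s)
  g <- compartment_gap_field(s, jcs, "medial", pinball = 1)
  r <- sqrt(g$x^2 + g$y^2)
  sel <- r <= 0.5
  parab <- 0.1 + r[sel]^2 / (2 * 2)
  expect_lt(max(abs(g$gap[sel] - parab) / parab), 0.01)
  # translating the femur toward the tibia reduces every gap by that amount
  s2 <- s
  s2$femur$vertices[, 3] <- s2$femur$vertices[, 3] + 0.2
  g2 <- compartment_gap_field(s2, jcs, "medial", pinball = 1)
  common <- intersect(g$face, g2$face)
  expect_lt(max(abs(g2$gap[match(common, g2$face)] -
                      (g$gap[match(common, g$face)] - 0.2))), 1e-9)
  # a side with no opposing femoral surface yields an empty field
  gl <- compartment_gap_field(s, jcs, "lateral")
  expect_identical(nrow(gl), 0L)
})

test_that("indentation solve matches the closed-form sphere solution", {
  s <- sphere_plane_specimen(radius = 2, gap0 = 0, edge = 0.05)
  jcs <- build_jcs(s)
  g <- compartment_gap_field(s, jcs, "medial", pinball = 0.1)
  res <- solve_indentation(g, E_EFF, 0.5, 1.47)
  u_cf <- sqrt(1.47 * 0.5 / (pi * E_EFF * 2))
  expect_lt(abs(res$indentation - u_cf) / u_cf, 0.02)
  expect_lt(abs(res$peak_pressure - E_EFF * u_cf / 0.5) / (E_EFF * u_cf / 0.5), 0.02)
  expect_lt(abs(res$contact_area - 2 * pi * 2 * u_cf) / (2 * pi * 2 * u_cf), 0.02)
  expect_lt(abs(res$achieved_force - 1.47), 1e-6)
  # doubling the force raises the approach by sqrt(2)
  res2 <- solve_indentation(g, E_EFF, 0.5, 2 * 1.47)
  expect_equal(res2$indentation / res$indentation, sqrt(2), tolerance = 5e-3)
  # zero target: no contact at all
  res0 <- solve_indentation(g, E_EFF, 0.5, 0)
  expect_identical(res0$peak_pressure, 0)
  expect_identical(res0$contact_area, 0)
  expect_error(solve_indentation(g, E_EFF, 0.5, -1), ">= 0")
})

test_that("results are invariant to gap-preserving tangential motion", {
  # spinning the spherical indenter about its own axis slides the surface
  # tangentially without changing the gap field: frictionless contact must
  # give identical results
  s <- sphere_plane_specimen(radius = 2, gap0 = 0, edge = 0.05)
  jcs <- build_jcs(s)
  res <- solve_indentation(compartment_gap_field(s, jcs, "medial"),
                           E_EFF, 0.5, 1.47)
  ctr <- c(0, 0, 5 - 0 - 2)               # sphere centre used by the article
  s2 <- s
  s2$femur$vertices <- varusknee:::transform_points(
    s2$femur$vertices, varusknee:::rotation_about_axis(c(0, 0, 1), 0.3), ctr)
  res2 <- solve_indentation(compartment_gap_field(s2, jcs, "medial"),
                            E_EFF, 0.5, 1.47)
  expect_equal(res2$indentation, res$indentation, tolerance = 1e-3)
  expect_equal(res2$contact_area, res$contact_area, tolerance = 0.02)
})

test_that("fraction mode conserves force and unloads the lateral side at 100%", {
  s <- default_cohort()[[1]]
  for (lv in c(0, 50, 100)) {
    out <- solve_load_case_fraction(s, material_set(),
                                    load_case(varus_level = lv))
    expect_lt(abs(out$medial$achieved_force + out$lateral$achieved_force - 2.94),
              1e-4)
    expect_true(all(out$medial$pressure_field$pressure >= 0))
    expect_lte(out$medial$contact_area,
               attr(out$medial$pressure_field, "patch_area") %||% Inf)
  }
  out100 <- solve_load_case_fraction(s, material_set(),
                                     load_case(varus_level = 100))
  expect_identical(out100$lateral$peak_pressure, 0)
  expect_identical(out100$lateral$contact_area, 0)
  expect_error(solve_load_case_fraction(s, material_set(),
                                        load_case(mode = "angle", varus_angle = 3)),
               "fraction")
})

test_that("angle mode is symmetric at zero varus and shifts load medially", {
  s <- nominal_specimen()
  out0 <- solve_load_case_angle(s, material_set(),
                                load_case(mode = "angle", varus_angle = 0))
  expect_lt(abs(out0$medial$achieved_force - out0$lateral$achieved_force) /
              out0$medial$achieved_force, 0.01)
  fr <- vapply(c(0, 3, 6), function(a) {
    solve_load_case_angle(s, material_set(),
                          load_case(mode = "angle", varus_angle = a))$medial_fraction
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
  # with zero-stiffness ligaments the contact force carries the whole load
  m0 <- material_set(ligament_table = list(
    ACL = c(stiffness = 0, pretension = 0.05),
    PCL = c(stiffness = 0, pretension = 0.05),
    MCL = c(stiffness = 0, pretension = 0.04),
    LCL = c(stiffness = 0, pretension = 0.04)))
  out6 <- solve_load_case_angle(s, m0, load_case(mode = "angle", varus_angle = 6))
  expect_lt(abs(out6$medial$achieved_force + out6$lateral$achieved_force - 2.94),
            1e-4)
  expect_true(all(out6$ligament_forces == 0))
})
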