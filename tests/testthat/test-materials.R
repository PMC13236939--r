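test_that("density-modulus power law evaluates and validates correctly", {
  expect_identical(density_to_modulus(1), 8362.8)
  expect_identical(density_to_modulus(0), 0)
  expect_equal(density_to_modulus(0.5), 8362.8 * exp(2.56 * log(0.5)),
               tolerance = 1e-12)
  expect_equal(round(density_to_modulus(0.5), 1), 1418.1)
  expect_error(density_to_modulus(-0.1), "rho")
  rho <- seq(0, 3, by = 0.01)
  E <- density_to_modulus(rho)
  expect_true(all(diff(E) > 0))
})

test_that("foundation modulus matches the confined-compression constant", {
  expect_identical(foundation_modulus(6, 0), 6)
  expect_equal(foundation_modulus(6, 0.49), 6 * 0.51 / (1.49 * 0.02),
               tolerance = 1e-12)
  expect_equal(foundation_modulus(6, 0.49), 102.6846, tolerance = 1e-4)
  expect_equal(foundation_modulus(12, 0.3), 2 * foundation_modulus(6, 0.3))
  expect_error(foundation_modulus(6, 0.499), "nu")
  expect_error(foundation_modulus(6, -0.01), "nu")
  expect_error(foundation_modulus(0, 0.3), "positive")
})

test_that("ligament springs are tension-only with slack-length pretension", {
  # at the reference pose the ligament carries k * L_ref * pretension
  expect_equal(ligament_force(10, 10, 35, 0.05), 17.5)
  # slack below L0 = (1 - pretension) * L_ref
  expect_identical(ligament_force(9.4, 10, 35, 0.05), 0)
  expect_identical(ligament_force(9.5, 10, 35, 0.05), 0)
  # piecewise linear, continuous, non-decreasing
  L <- seq(8, 12, by = 0.01)
  f <- ligament_force(L, 10, 35, 0.05)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 0))
  expect_equal(max(abs(diff(f))), 35 * 0.01, tolerance = 1e-9)
  expect_error(ligament_force(-1, 10, 35, 0.05), "positive")
  expect_error(ligament_force(10, 0, 35, 0.05), "positive")
})

test_that("material set defaults and validation follow the study constants", {
  m <- material_set()
  expect_equal(m$cartilage_E, 6)
  expect_equal(m$cartilage_nu, 0.49)
  expect_equal(m$cartilage_thickness, 0.25)
  expect_equal(m$bone_law$a, 8362.8)
  expect_equal(m$bone_law$exponent, 2.56)
  expect_equal(unname(m$ligament_table$ACL), c(35, 0.05))
  expect_equal(unname(m$ligament_table$MCL), c(20, 0.04))
  expect_identical(m$friction, 0)
  expect_error(material_set(cartilage_nu = 0.5), "nu")
  expect_error(material_set(ligament_table = list(ACL = c(stiffness = 35, pretension = 0.5))),
               "pretension")
})
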