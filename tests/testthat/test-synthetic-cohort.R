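test_that("cohort has the bilateral structure and right-side representation", {
  coh <- default_cohort()
  expect_length(coh, 10L)
  ids <- vapply(coh, `[[`, integer(1), "animal_id")
  expect_equal(as.integer(table(ids)), rep(2L, 5))
  expect_true(all(vapply(coh, `[[`, character(1), "representation") == "right"))
  mir <- vapply(coh, `[[`, logical(1), "is_mirrored")
  side <- vapply(coh, `[[`, character(1), "side_as_acquired")
  expect_equal(mir, side == "left")
  # shared template topology
  f0 <- coh[[1]]$femur$faces
  for (s in coh) expect_identical(s$femur$faces, f0)
  # epicondyle landmarks distinct, all four ligaments present
  for (s in coh) {
    expect_gt(sum((s$landmarks$medial_epicondyle -
                     s$landmarks$lateral_epicondyle)^2), 1)
    expect_setequal(s$ligaments$name, c("ACL", "PCL", "MCL", "LCL"))
  }
  # densities finite and non-negative
  for (s in coh)
    for (b in c("femur", "tibia_fibula", "patella")) {
      expect_true(all(is.finite(s[[b]]$vertex_density)))
      expect_true(all(s[[b]]$vertex_density >= 0))
    }
})

test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_animals = 2, seed = 33,
                          nominal = coarse_nominal())
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  for (i in seq_along(c1)) {
    expect_identical(c1[[i]]$femur$vertices, c2[[i]]$femur$vertices)
    expect_identical(c1[[i]]$tibia_fibula$vertex_density,
                     c2[[i]]$tibia_fibula$vertex_density)
  }
  c3 <- generate_cohort(generator_config(n_animals = 2, seed = 34,
                                         nominal = coarse_nominal()))
  expect_false(identical(c1[[1]]$femur$vertices, c3[[1]]$femur$vertices))
})

test_that("zero-variance cohort collapses to identical specimens", {
  coh <- generate_cohort(zero_variance_config(nominal = coarse_nominal()))
  v0 <- coh[[1]]$femur$vertices
  for (s in coh) {
    expect_equal(s$femur$vertices, v0, tolerance = 1e-14)
    expect_identical(s$femur$faces, coh[[1]]$femur$faces)
  }
})

test_that("between-animal variation SD controls total shape variance", {
  trace_of <- function(sd_mult, seed) {
    sdb <- lapply(generator_config()$sd_between, function(x) x * sd_mult)
    coh <- generate_cohort(generator_config(
      n_animals = 3, seed = seed, nominal = coarse_nominal(),
      sd_between = sdb, pose_jitter_deg = 0, pose_jitter_mm = 0))
    X <- do.call(rbind, lapply(coh, function(s)
      as.numeric(t(s$femur$vertices))))
    sum(apply(X, 2, var))
  }
  seeds <- c(11, 12, 13)
  lo <- mean(vapply(seeds, function(s) trace_of(1, s), numeric(1)))
  hi <- mean(vapply(seeds, function(s) trace_of(3, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("mirroring is an involution that preserves area and anatomy", {
  s <- default_cohort()[[2]]
  m <- mirror_specimen(s)
  expect_false(identical(m$is_mirrored, s$is_mirrored))
  expect_equal(m$femur$vertices[, 1], -s$femur$vertices[, 1])
  # area preserved (isometry)
  expect_lt(abs(mesh_area(m$femur) - mesh_area(s$femur)) / mesh_area(s$femur),
            1e-9)
  mm <- mirror_specimen(m)
  expect_equal(mm$femur$vertices, s$femur$vertices, tolerance = 1e-15)
  expect_identical(mm$femur$faces, s$femur$faces)
  expect_equal(mm$landmarks$medial_epicondyle, s$landmarks$medial_epicondyle)
  expect_identical(mm$is_mirrored, s$is_mirrored)
})

test_that("right-side representation has the medial epicondyle at negative X", {
  s <- nominal_specimen()
  jcs <- build_jcs(s)
  med_x <- sum((s$landmarks$medial_epicondyle - jcs$origin) * jcs$X)
  lat_x <- sum((s$landmarks$lateral_epicondyle - jcs$origin) * jcs$X)
  expect_lt(med_x, 0)
  expect_gt(lat_x, 0)
})

test_that("generator configuration is validated", {
  expect_error(generator_config(n_animals = 0), "positive")
  expect_error(generator_config(sd_between = list(scale = -0.1)), ">= 0")
  expect_error(generator_config(pose_jitter_mm = -1), ">= 0")
})

test_that("film emulator obeys the clipping, floor and averaging rules", {
  # identity settings reproduce the true peak and area exactly
  f0 <- identity_film()
  p <- c(0.3, 0.8, 1.2); a <- c(1, 2, 0.5)
  m <- emulate_pressure_film(p, f0, areas = a)
  expect_equal(m[["peak_pressure"]], 1.2)
  expect_equal(m[["contact_area"]], 3.5)
  # uniform field at half the floor registers nothing
  f <- film_model(detection_floor = 0.4, saturation_ceiling = 2.5,
                  multiplicative_noise_sd = 0, quantization_step = 0)
  m2 <- emulate_pressure_film(rep(0.2, 5), f, areas = rep(1, 5))
  expect_equal(unname(m2), c(0, 0))
  # clip/floor rules: 1 and 3 MPa on 1 mm^2 each, floor 0.2, ceiling 2.5
  f3 <- film_model(detection_floor = 0.2, saturation_ceiling = 2.5,
                   multiplicative_noise_sd = 0, quantization_step = 0)
  m3 <- emulate_pressure_film(c(1, 3), f3, areas = c(1, 1))
  expect_equal(m3[["peak_pressure"]], 2.5)
  expect_equal(m3[["contact_area"]], 2)
  # empty field: zero peak and area, no error
  expect_equal(unname(emulate_pressure_film(numeric(0), f3)), c(0, 0))
  # deterministic given the seed
  fn <- film_model(multiplicative_noise_sd = 0.1, seed = 5)
  expect_identical(emulate_pressure_film(p, fn, areas = a),
                   emulate_pressure_film(p, fn, areas = a))
  expect_error(emulate_pressure_film(c(-1, 2), f3, areas = c(1, 1)), ">= 0")
})
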