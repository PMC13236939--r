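test_that("shape vectorization is an exact inverse pair", {
  s <- default_cohort()[[1]]
  v <- to_shape_vector(s, w_s = 2, w_a = 0.5)
  s2 <- from_shape_vector(v, s$template, w_s = 2, w_a = 0.5)
  expect_equal(s2$femur$vertices, s$femur$vertices, tolerance = 1e-12)
  expect_equal(s2$patella$vertex_density, s$patella$vertex_density,
               tolerance = 1e-12)
  # identical specimens vectorize identically
  expect_identical(to_shape_vector(s), to_shape_vector(s))
  expect_error(to_shape_vector(s, w_a = 0), "w_a")
  expect_error(to_shape_vector(s, w_s = 0), "w_s")
})

test_that("GPA is invariant to rigid motions and reduces the objective", {
  s <- nominal_specimen(generator_config(nominal = coarse_nominal()))
  v0 <- to_shape_vector(s)
  rigid_copy <- function(axis, ang, tr) {
    s2 <- varusknee:::apply_rigid_to_specimen(
      s, varusknee:::rotation_about_axis(axis, ang), tr)
    to_shape_vector(s2)
  }
  copies <- list(v0,
                 rigid_copy(c(0, 0, 1), 0.4, c(1, -2, 0.5)),
                 rigid_copy(c(1, 1, 0), -0.7, c(0, 3, 1)))
  g <- gpa_align(copies)
  pts <- lapply(g$aligned, varusknee:::shape_points,
                layout = attr(v0, "layout"))
  for (i in 2:3)
    expect_lt(sqrt(mean((pts[[i]] - pts[[1]])^2)), 1e-8)
  # idempotence: aligning aligned data changes nothing
  g2 <- gpa_align(g$aligned)
  expect_lt(max(abs(g2$aligned[[1]] - g$aligned[[1]])), 1e-9)
  # consensus centred at the origin
  expect_lt(max(abs(colMeans(g$mean_shape))), 1e-10)

  # objective decreases for noisy rigid copies
  set.seed(9)
  noisy <- lapply(1:3, function(i) {
    vi <- rigid_copy(stats::rnorm(3), stats::rnorm(1, 0, 0.3),
                     stats::rnorm(3))
    vi[seq_len(attr(v0, "layout")$n_shape)] <-
      vi[seq_len(attr(v0, "layout")$n_shape)] + stats::rnorm(attr(v0, "layout")$n_shape, 0, 0.01)
    vi
  })
  ss_of <- function(vs) {
    P <- lapply(vs, varusknee:::shape_points, layout = attr(v0, "layout"))
    P <- lapply(P, function(p) sweep(p, 2, colMeans(p)))
    M <- Reduce(`+`, P) / length(P)
    sum(vapply(P, function(p) sum((p - M)^2), numeric(1)))
  }
  gn <- gpa_align(noisy)
  expect_lt(ss_of(gn$aligned), ss_of(noisy))
  expect_error(gpa_align(noisy[1]), "at least two")
})

test_that("PCA matches the explicit covariance eigendecomposition", {
  coh <- default_cohort()
  model <- build_ssam(coh)
  # rebuild the aligned, weighted data matrix exactly as the model does
  raw <- lapply(coh, to_shape_vector)
  g <- gpa_align(raw)
  X <- do.call(rbind, g$aligned)
  sh <- seq_len(model$layout$n_shape)
  ap <- model$layout$n_shape + seq_len(model$layout$n_app)
  X[, sh] <- model$w_s * X[, sh]
  X[, ap] <- model$w_a * X[, ap]
  Xc <- sweep(X, 2, colMeans(X))
  # dual (Gram) eigendecomposition as an independent oracle
  G <- Xc %*% t(Xc) / (nrow(X) - 1)
  ev <- eigen(G, symmetric = TRUE)
  expect_equal(model$sd^2, ev$values[seq_along(model$sd)], tolerance = 1e-8)
  # total variance equals the trace of the sample covariance
  expect_equal(sum(model$sd^2), sum(apply(X, 2, var)),
               tolerance = 1e-8 * sum(model$sd^2))
  # components match the oracle eigenvectors wherever the spectrum is
  # well separated (nearly equal eigenvalues mix their eigenvectors)
  lam <- ev$values[seq_len(model$n_components)]
  gaps <- vapply(seq_along(lam), function(j) {
    nb <- abs(lam[j] - lam[setdiff(seq_along(lam), j)])
    if (length(nb)) min(nb) / lam[1] else 1
  }, numeric(1))
  for (j in which(gaps > 1e-3)) {
    cj <- drop(crossprod(Xc, ev$vectors[, j]))
    cj <- cj / sqrt(sum(cj^2))
    expect_gt(abs(sum(cj * model$components[, j])), 1 - 1e-6)
  }
  # orthonormality
  CtC <- crossprod(model$components)
  expect_lt(max(abs(CtC - diag(model$n_components))), 1e-8)
  expect_true(all(diff(model$sd) <= 1e-12))
})

test_that("rank bound, zero-variance collapse and weight balancing hold", {
  coh <- default_cohort()
  m9 <- build_ssam(coh[1:9])
  expect_lte(m9$n_components, 8L)
  expect_error(build_ssam(coh[1:5], n_components = 5), "n_training")
  zc <- generate_cohort(zero_variance_config(nominal = coarse_nominal()))
  mz <- build_ssam(zc)
  expect_identical(mz$n_components, 0L)
  rz <- reconstruct_specimen(mz, numeric(0))
  # model reproduces the specimen exactly, up to the GPA centring translation
  all_pts <- rbind(zc[[1]]$femur$vertices, zc[[1]]$tibia_fibula$vertices,
                   zc[[1]]$patella$vertices)
  expected <- sweep(zc[[1]]$femur$vertices, 2, colMeans(all_pts))
  expect_equal(rz$femur$vertices, expected, tolerance = 1e-8)
  # equal-variance appearance weighting
  m <- build_ssam(coh)
  raw <- lapply(coh, to_shape_vector)
  g <- gpa_align(raw)
  X <- do.call(rbind, g$aligned)
  sh <- seq_len(m$layout$n_shape)
  ap <- m$layout$n_shape + seq_len(m$layout$n_app)
  vs <- sum(apply(X[, sh], 2, var))
  va <- sum(apply(X[, ap], 2, var))
  expect_equal(m$w_a^2 * va, vs, tolerance = 1e-6 * vs)
})

test_that("constrained sampling respects the count and the SD limits", {
  model <- build_ssam(default_cohort()[1:6])
  k <- model$n_components
  inst <- sample_ssam(model, n_per_component = 20, limit_sd = 3, seed = 4)
  expect_length(inst, 20 * k)
  b <- attr(inst, "coefficients")
  expect_true(all(abs(b) <= 3))
  expect_true(all(rowSums(b != 0) <= 1))
  # determinism
  inst2 <- sample_ssam(model, n_per_component = 20, limit_sd = 3, seed = 4)
  expect_equal(attr(inst2, "coefficients"), b)
  # zero limit collapses every instance to the mean
  inst0 <- sample_ssam(model, n_per_component = 2, limit_sd = 0, seed = 1)
  mean_spec <- reconstruct_specimen(model, numeric(k))
  for (i in seq_along(inst0))
    expect_equal(inst0[[i]]$femur$vertices, mean_spec$femur$vertices,
                 tolerance = 1e-12)
})

test_that("fitting projects exactly and reconstruction is affine", {
  model <- build_ssam(default_cohort()[1:8])
  k <- model$n_components
  mean_spec <- reconstruct_specimen(model, numeric(k))
  b0 <- fit_coefficients(model, mean_spec, align = TRUE)
  expect_lt(max(abs(b0)), 1e-6)
  # constructed target at +2 SD along the first component
  b_in <- numeric(k); b_in[1] <- 2
  target <- reconstruct_specimen(model, b_in)
  b_out <- fit_coefficients(model, target, clip = TRUE, align = TRUE)
  expect_equal(as.numeric(b_out), b_in, tolerance = 1e-6)
  # span property: training member reconstructs exactly with the full basis
  tr <- default_cohort()[[3]]
  model_tr <- build_ssam(default_cohort()[-10])
  b_tr <- fit_coefficients(model_tr, tr, clip = FALSE, align = TRUE)
  rec <- reconstruct_specimen(model_tr, b_tr)
  tv <- varusknee:::model_space_vector(model_tr, tr, align = TRUE)
  pts_t <- varusknee:::shape_points(tv / model_tr$w_s, model_tr$layout)
  pts_r <- rbind(rec$femur$vertices, rec$tibia_fibula$vertices,
                 rec$patella$vertices)
  expect_lt(sqrt(mean((pts_t - pts_r)^2)), 1e-8)
  # affine map: reconstruct(a + b) - reconstruct(a) = reconstruct(b) - reconstruct(0)
  a <- stats::rnorm(k, 0, 0.5); bb <- stats::rnorm(k, 0, 0.5)
  d1 <- reconstruct_specimen(model, a + bb)$femur$vertices -
    reconstruct_specimen(model, a)$femur$vertices
  d2 <- reconstruct_specimen(model, bb)$femur$vertices -
    reconstruct_specimen(model, numeric(k))$femur$vertices
  expect_lt(max(abs(d1 - d2)), 1e-10)
  # clipping bounds extreme fits
  b_far <- numeric(k); b_far[1] <- 5
  far <- reconstruct_specimen(model, b_far)
  expect_equal(max(abs(fit_coefficients(model, far, clip = TRUE))), 3)
})

test_that("reconstruction error is non-increasing in retained components", {
  coh <- default_cohort()
  target <- coh[[10]]
  errs <- vapply(1:6, function(k) {
    m <- build_ssam(coh[1:8], n_components = k)
    b <- fit_coefficients(m, target, clip = FALSE, align = TRUE)
    tv <- varusknee:::model_space_vector(m, target, align = TRUE)
    resid <- tv - m$mean -
      if (k > 0) drop(m$components %*% (as.numeric(b) * m$sd)) else 0
    sqrt(mean(resid^2))   # full weighted residual (shape + appearance)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("leave-one-out prediction beats the mean-shape baseline", {
  loo <- default_loo()
  all_rows <- loo$errors[loo$errors$body == "all", ]
  expect_identical(nrow(all_rows), 10L)
  # baseline: zero retained components reconstructs the training mean
  base <- loo_validate(default_cohort(), n_components = 0)
  base_rows <- base$errors[base$errors$body == "all", ]
  expect_lt(mean(all_rows$rms_mm), mean(base_rows$rms_mm))
  expect_true(all(all_rows$rms_mm <= all_rows$max_mm))
})
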