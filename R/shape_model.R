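#' Vectorize a knee specimen for the shape-appearance model
#'
#' Concatenates, in fixed template order, the flattened vertex coordinates
#' of femur, tibia-fibula and patella (shape block, weighted by `w_s`) and
#' the per-vertex equivalent mineral densities (appearance block, weighted
#' by `w_a`).  The map is deterministic and invertible given the template
#' and the weights.
#'
#' @param s a `knee_specimen` on the cohort template topology.
#' @param w_s,w_a positive block weights (shape in mm, appearance in
#'   g/cm^3).  `w_a = 0` is only admissible when the appearance block is
#'   excluded.
#' @param include_appearance include the density block?
#' @return numeric vector with attribute `layout`.
#' @export
to_shape_vector <- function(s, w_s = 1, w_a = 1, include_appearance = TRUE) {
  if (w_s <= 0) stop("w_s must be positive")
  if (include_appearance && w_a <= 0)
    stop("w_a must be positive when the appearance block is included")
  tpl <- s$template
  for (b in specimen_bodies())
    if (nrow(s[[b]]$vertices) != tpl$n_vertices[[b]])
      stop("specimen is not on the template topology (", b, ")")
  shape <- unlist(lapply(specimen_bodies(),
                         function(b) as.numeric(t(s[[b]]$vertices))),
                  use.names = FALSE)
  app <- if (include_appearance)
    unlist(lapply(specimen_bodies(),
                  function(b) s[[b]]$vertex_density %||%
                    rep(0, tpl$n_vertices[[b]])), use.names = FALSE)
  else numeric(0)
  out <- c(w_s * shape, w_a * app)
  attr(out, "layout") <- list(n_shape = length(shape), n_app = length(app),
                              w_s = w_s, w_a = w_a)
  out
}

#' @rdname to_shape_vector
#' @param vec a shape vector as produced by [to_shape_vector()].
#' @param template the cohort template (e.g. `s$template`).
#' @export
from_shape_vector <- function(vec, template, w_s = 1, w_a = 1) {
  nv <- template$n_vertices
  n_shape <- 3 * sum(nv)
  shape <- vec[seq_len(n_shape)] / w_s
  has_app <- length(vec) > n_shape
  app <- if (has_app) vec[(n_shape + 1):length(vec)] / w_a
  s <- list(animal_id = NA_integer_, side_as_acquired = NA_character_,
            is_mirrored = FALSE, representation = "right")
  off <- 0L; aoff <- 0L
  for (b in specimen_bodies()) {
    k <- nv[[b]]
    V <- matrix(shape[off + seq_len(3 * k)], ncol = 3, byrow = TRUE)
    dens <- if (has_app) pmax(0, app[aoff + seq_len(k)])
    s[[b]] <- surface_mesh(V, template$faces[[b]], vertex_density = dens,
                           face_region = template$face_region[[b]], body = b)
    off <- off + 3L * k; aoff <- aoff + k
  }
  s$landmarks <- lapply(template$tethers, function(th)
    apply_tether(th, s[[th$body]]$vertices))
  names(s$landmarks) <- names(template$tethers)
  s$landmark_body <- vapply(template$tethers, `[[`, character(1), "body")
  s$cartilage <- template$cartilage
  lig <- template$ligaments
  par <- template$nominal
  R80 <- rotation_about_axis(c(1, 0, 0), -deg2rad(par$flexion_design))
  lig$reference_length <- vapply(seq_len(nrow(lig)), function(i) {
    o <- s[[lig$origin_body[i]]]$vertices[lig$origin_vertex[i], ]
    ins <- s[[lig$insertion_body[i]]]$vertices[lig$insertion_vertex[i], ]
    L <- sqrt(sum((as.numeric(R80 %*% o) - ins)^2))
    L * (1 + par$ligament_recruitment_margin) / (1 - lig$pretension_default[i])
  }, numeric(1))
  s$ligaments <- lig
  s$template <- template
  s$params <- NULL
  structure(s, class = "knee_specimen")
}

shape_points <- function(vec, layout) {
  matrix(vec[seq_len(layout$n_shape)], ncol = 3, byrow = TRUE)
}

# Rigid Procrustes superimposition of A onto B (k x 3 point matrices).
procrustes_rigid <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  list(R = R, ca = ca, cb = cb,
       aligned = sweep(Ac %*% t(R), 2, cb, "+"))
}

#' Generalized Procrustes alignment of a cohort of shape vectors
#'
#' Rigid-only (no scaling) generalized Procrustes analysis of the shape
#' blocks; the appearance blocks are untouched.  Each shape is iteratively
#' superimposed on the running mean until the mean changes by less than
#' 1e-10 RMS (at most 100 iterations); the consensus is centred at the
#' origin.
#'
#' @param vectors list of shape vectors (equal length, >= 2) from
#'   [to_shape_vector()].
#' @return list with `aligned` (list of aligned vectors), `mean_shape`
#'   (consensus k x 3 point matrix) and `iterations`.
#' @export
gpa_align <- function(vectors) {
  if (length(vectors) < 2) stop("need at least two shape vectors")
  layout <- attr(vectors[[1]], "layout")
  if (is.null(layout)) stop("vectors must carry a layout attribute")
  lens <- vapply(vectors, length, integer(1))
  if (length(unique(lens)) != 1) stop("shape vectors differ in length")
  pts <- lapply(vectors, shape_points, layout = layout)
  if (max(vapply(pts, function(p) max(abs(sweep(p, 2, colMeans(p)))),
                 numeric(1))) < 1e-12)
    stop("degenerate configuration: all points coincident")
  pts <- lapply(pts, function(p) sweep(p, 2, colMeans(p)))
  mean_shape <- pts[[1]]
  iterations <- 0L
  for (iter in seq_len(100L)) {
    iterations <- iter
    pts <- lapply(pts, function(p) procrustes_rigid(p, mean_shape)$aligned)
    new_mean <- Reduce(`+`, pts) / length(pts)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < 1e-10) break
  }
  aligned <- mapply(function(v, p) {
    v[seq_len(layout$n_shape)] <- as.numeric(t(p))
    v
  }, vectors, pts, SIMPLIFY = FALSE)
  list(aligned = aligned, mean_shape = mean_shape, iterations = iterations)
}

#' Build the statistical shape and appearance model
#'
#' Generalized Procrustes alignment of the training specimens followed by
#' principal component analysis of the concatenated (weighted) shape and
#' appearance vectors.  Component standard deviations are the square roots
#' of the PCA eigenvalues; component signs are fixed by making the
#' largest-magnitude loading positive, so builds are reproducible.
#'
#' @param training list of >= 2 `knee_specimen` objects on one template.
#' @param w_s shape-block weight (default 1).
#' @param w_a appearance-block weight; `NULL` (default) chooses it so the
#'   two blocks contribute equal total variance on the training set.
#' @param n_components number of retained components; `NULL` keeps every
#'   component with a nonzero eigenvalue (at most n_training - 1).
#' @return an object of class `ssa_model`.
#' @export
build_ssam <- function(training, w_s = 1, w_a = NULL, n_components = NULL) {
  n <- length(training)
  if (n < 2) stop("need at least two training specimens")
  if (!is.null(n_components) && n_components > n - 1)
    stop("n_components may not exceed n_training - 1")
  raw <- lapply(training, to_shape_vector, w_s = 1, w_a = 1)
  layout <- attr(raw[[1]], "layout")
  g <- gpa_align(raw)
  X0 <- do.call(rbind, g$aligned)
  sh <- seq_len(layout$n_shape)
  ap <- layout$n_shape + seq_len(layout$n_app)
  var_s <- sum(apply(X0[, sh, drop = FALSE], 2, stats::var))
  var_a <- sum(apply(X0[, ap, drop = FALSE], 2, stats::var))
  if (is.null(w_a))
    w_a <- if (var_a > 1e-12 * max(var_s, 1e-300)) w_s * sqrt(var_s / var_a) else w_s
  X <- X0
  X[, sh] <- w_s * X[, sh]
  if (length(ap)) X[, ap] <- w_a * X[, ap]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  sdv <- sv$d / sqrt(n - 1)
  nonzero <- sdv > max(sdv[1], 0) * 1e-8
  k_max <- min(sum(nonzero), n - 1L)
  k <- if (is.null(n_components)) k_max else min(n_components, k_max)
  comps <- sv$v[, seq_len(k), drop = FALSE]
  if (k > 0) {
    for (j in seq_len(k)) {
      i <- which.max(abs(comps[, j]))
      if (comps[i, j] < 0) comps[, j] <- -comps[, j]
    }
  }
  structure(list(template = training[[1]]$template,
                 mean = mu, components = comps,
                 sd = sdv[seq_len(k)], n_components = k,
                 w_s = w_s, w_a = w_a, layout = layout,
                 mean_shape = g$mean_shape, n_training = n),
            class = "ssa_model")
}

#' @export
print.ssa_model <- function(x, ...) {
  cat(sprintf("<ssa_model: %d components from %d training limbs, w_a = %.3g>\n",
              x$n_components, x$n_training, x$w_a))
  if (x$n_components > 0)
    cat(" component SDs:", signif(x$sd, 3), "\n")
  invisible(x)
}

# weighted, GPA-aligned vector of a target specimen in model space
model_space_vector <- function(model, target, align = TRUE) {
  v <- to_shape_vector(target, w_s = 1, w_a = 1)
  layout <- model$layout
  if (length(v) != layout$n_shape + layout$n_app)
    stop("target is not on the model template topology")
  if (align) {
    p <- shape_points(v, layout)
    p <- procrustes_rigid(p, model$mean_shape)$aligned
    v[seq_len(layout$n_shape)] <- as.numeric(t(p))
  }
  sh <- seq_len(layout$n_shape)
  v[sh] <- model$w_s * v[sh]
  if (layout$n_app)
    v[layout$n_shape + seq_len(layout$n_app)] <-
      model$w_a * v[layout$n_shape + seq_len(layout$n_app)]
  v
}

#' Fit shape-model coefficients to a target specimen
#'
#' Least-squares projection of the (GPA-aligned, weighted) target vector on
#' the component basis, expressed in SD units:
#' b_i = components_i . (target - mean) / sd_i.  With `clip = TRUE`
#' (default, mirroring the sampling constraint) coefficients are clamped to
#' [-3, 3]; unclipped fits leave a residual orthogonal to the basis.
#'
#' @param model an `ssa_model`.
#' @param target a `knee_specimen` on the model template.
#' @param clip clamp coefficients to +/- 3 SD?
#' @param align rigidly align the target to the model consensus first?
#' @return numeric coefficient vector (class `shape_coefficients`).
#' @export
fit_coefficients <- function(model, target, clip = TRUE, align = TRUE) {
  v <- model_space_vector(model, target, align = align)
  if (model$n_components == 0) {
    b <- numeric(0)
  } else {
    proj <- drop(crossprod(model$components, v - model$mean))
    b <- proj / model$sd
    if (clip) b <- pmin(3, pmax(-3, b))
  }
  structure(b, class = "shape_coefficients", clipped = clip)
}

#' Reconstruct a specimen from shape-model coefficients
#'
#' mean + sum_i b_i * sd_i * component_i, un-weighted and de-vectorized to a
#' full specimen; landmarks and ligament attachments are transported with
#' their tethered template vertices.
#'
#' @param model an `ssa_model`.
#' @param b coefficients in SD units (length `n_components`).
#' @return a `knee_specimen`.
#' @export
reconstruct_specimen <- function(model, b) {
  if (length(b) != model$n_components)
    stop("coefficient length does not match n_components")
  v <- model$mean
  if (length(b))
    v <- v + drop(model$components %*% (as.numeric(b) * model$sd))
  from_shape_vector(v, model$template, w_s = model$w_s, w_a = model$w_a)
}

#' Sample constrained instances from the shape model
#'
#' For each retained principal component, draws `n_per_component`
#' coefficients uniformly within +/- `limit_sd` standard deviations (all
#' other coefficients zero) and reconstructs the corresponding specimens —
#' the resampling scheme used to explore the model space (20 draws per
#' component within +/- 3 SD by default).
#'
#' @param model an `ssa_model`.
#' @param n_per_component draws per component (default 20).
#' @param limit_sd coefficient bound in SD units (default 3).
#' @param seed RNG seed.
#' @return list of `knee_specimen`; attribute `coefficients` holds the
#'   sampled coefficient matrix.
#' @export
sample_ssam <- function(model, n_per_component = 20, limit_sd = 3, seed = 1) {
  set.seed(seed)
  k <- model$n_components
  out <- vector("list", k * n_per_component)
  coef <- matrix(0, k * n_per_component, max(k, 1))
  idx <- 0L
  for (j in seq_len(k)) {
    draws <- stats::runif(n_per_component, -limit_sd, limit_sd)
    for (d in draws) {
      idx <- idx + 1L
      b <- numeric(k); b[j] <- d
      coef[idx, seq_len(k)] <- b
      out[[idx]] <- reconstruct_specimen(model, b)
    }
  }
  attr(out, "coefficients") <- coef[seq_len(idx), , drop = FALSE]
  out
}

#' Limb-level leave-one-out validation of the shape model
#'
#' Each limb is sequentially designated the target while a model is built
#' on the remaining limbs (the contralateral limb of the same animal stays
#' in the training set); the model is fitted to the target and the
#' reconstruction compared with the (GPA-aligned) original, reporting RMS
#' and maximum surface error per body.
#'
#' @param cohort list of >= 3 `knee_specimen` on one template.
#' @param w_s,w_a,n_components,clip passed to [build_ssam()] /
#'   [fit_coefficients()].
#' @return list with `errors` (data frame: limb, body, rms_mm, max_mm, with
#'   `body = "all"` rows for the overall error) and `predicted` (the
#'   reconstructed specimens, carrying the target metadata).
#' @export
loo_validate <- function(cohort, w_s = 1, w_a = NULL, n_components = NULL,
                         clip = TRUE) {
  n <- length(cohort)
  if (n < 3) stop("leave-one-out requires at least 3 limbs")
  rows <- list(); preds <- vector("list", n)
  for (i in seq_len(n)) {
    model <- build_ssam(cohort[-i], w_s = w_s, w_a = w_a,
                        n_components = n_components)
    target <- cohort[[i]]
    b <- fit_coefficients(model, target, clip = clip, align = TRUE)
    recon <- reconstruct_specimen(model, b)
    tv <- model_space_vector(model, target, align = TRUE)
    layout <- model$layout
    tgt_pts <- shape_points(tv / model$w_s, layout)
    rec_pts <- do.call(rbind, lapply(specimen_bodies(),
                                     function(bd) recon[[bd]]$vertices))
    derr <- sqrt(rowSums((tgt_pts - rec_pts)^2))
    off <- 0L
    for (bd in specimen_bodies()) {
      k <- model$template$n_vertices[[bd]]
      e <- derr[off + seq_len(k)]
      rows[[length(rows) + 1L]] <-
        data.frame(limb = i, body = bd, rms_mm = sqrt(mean(e^2)),
                   max_mm = max(e))
      off <- off + k
    }
    rows[[length(rows) + 1L]] <-
      data.frame(limb = i, body = "all", rms_mm = sqrt(mean(derr^2)),
                 max_mm = max(derr))
    recon$animal_id <- target$animal_id
    recon$side_as_acquired <- target$side_as_acquired
    recon$is_mirrored <- target$is_mirrored
    preds[[i]] <- recon
  }
  list(errors = do.call(rbind, rows), predicted = preds)
}
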