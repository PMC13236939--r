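#' Joint coordinate system of a knee specimen
#'
#' Origin at the midpoint of the femoral epicondyles; X along the
#' epicondylar line pointing laterally; Z perpendicular to the tibial
#' plateau, directed from femur to tibia (adjusted minimally to be
#' orthogonal to X); Y = X x Z.  With this construction Y points posteriorly
#' in right-side representation; the varus rotation sign is defined about
#' this Y so that positive angles load the medial compartment.
#'
#' @param s a `knee_specimen` with landmarks present.
#' @return object of class `joint_cs` with fields `origin`, `X`, `Y`, `Z`.
#' @export
build_jcs <- function(s) {
  lm <- s$landmarks
  med <- lm$medial_epicondyle; lat <- lm$lateral_epicondyle
  ex <- lat - med
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9) stop("epicondyle landmarks are coincident")
  X <- ex / nx
  zr <- lm$plateau_normal_ref - lm$plateau_center
  nz <- sqrt(sum(zr^2))
  if (nz < 1e-9) stop("degenerate plateau normal reference")
  Zr <- zr / nz
  Z <- Zr - sum(Zr * X) * X
  nz2 <- sqrt(sum(Z^2))
  if (nz2 < 1e-9) stop("plateau normal parallel to epicondylar axis")
  Z <- Z / nz2
  Y <- c(X[2] * Z[3] - X[3] * Z[2], X[3] * Z[1] - X[1] * Z[3],
         X[1] * Z[2] - X[2] * Z[1])
  structure(list(origin = (med + lat) / 2, X = X, Y = Y, Z = Z),
            class = "joint_cs")
}

#' @export
print.joint_cs <- function(x, ...) {
  cat("<joint_cs>\n origin:", signif(x$origin, 4), "\n X:", signif(x$X, 4),
      "\n Y:", signif(x$Y, 4), "\n Z:", signif(x$Z, 4), "\n")
  invisible(x)
}

rotate_femur <- function(s, R, origin) {
  s$femur$vertices <- transform_points(s$femur$vertices, R, origin)
  for (nm in names(s$landmarks))
    if (identical(s$landmark_body[[nm]], "femur"))
      s$landmarks[[nm]] <- as.numeric(transform_points(rbind(s$landmarks[[nm]]), R, origin))
  s
}

#' Pose the knee at a flexion angle
#'
#' Rotates the femur (tibia fixed, as the distal tibia-fibula is fully
#' constrained) about the JCS X axis through the JCS origin.  Positive
#' flexion brings the posterior condylar caps of the extended femur over the
#' tibial plateau; zero flexion leaves the femur unchanged.
#'
#' @param s a `knee_specimen`.
#' @param jcs its [build_jcs()] frame.
#' @param flexion flexion angle in degrees.
#' @return the posed specimen.
#' @export
pose_flexion <- function(s, jcs, flexion) {
  if (flexion == 0) return(s)
  rotate_femur(s, rotation_about_axis(jcs$X, -deg2rad(flexion)), jcs$origin)
}

#' Apply a varus angulation to the femur
#'
#' Rotates the femur about the JCS Y axis through the JCS origin; positive
#' angles engage the medial compartment.
#'
#' @inheritParams pose_flexion
#' @param varus_angle varus angle in degrees.
#' @export
pose_varus <- function(s, jcs, varus_angle) {
  if (varus_angle == 0) return(s)
  rotate_femur(s, rotation_about_axis(jcs$Y, deg2rad(varus_angle)), jcs$origin)
}

#' Varus loading description
#'
#' @param total_force total compressive load in N (default 2.94 N,
#'   about one body weight of a 300 g rat).
#' @param flexion flexion angle in degrees (default 80, the standing pose).
#' @param mode `"fraction"` (prescribed compartment load redistribution at
#'   0/50/100 % varus) or `"angle"` (prescribed femoral varus angulation;
#'   3 degrees corresponds to the 50 % and 6 degrees to the 100 % condition).
#' @param varus_level varus level in percent, one of 0, 50, 100.
#' @param varus_angle varus angle in degrees, within [0, 10].
#' @param pinball contact-search cutoff radius in mm (default 0.1).
#' @return object of class `load_case`.
#' @export
load_case <- function(total_force = 2.94, flexion = 80,
                      mode = c("fraction", "angle"),
                      varus_level = 0, varus_angle = 0, pinball = 0.1) {
  mode <- match.arg(mode)
  if (total_force <= 0) stop("total_force must be positive")
  if (mode == "fraction" && !varus_level %in% c(0, 50, 100))
    stop("varus_level must be one of 0, 50, 100")
  if (mode == "angle" && (varus_angle < 0 || varus_angle > 10))
    stop("varus_angle must lie in [0, 10] degrees")
  structure(list(total_force = total_force, flexion = flexion, mode = mode,
                 varus_level = varus_level, varus_angle = varus_angle,
                 pinball = pinball),
            class = "load_case")
}

#' Prescribed varus load redistribution between compartments
#'
#' Neutral loading splits the total force evenly between the compartments;
#' at 50 % varus the medial compartment bears 50 % more and the lateral 50 %
#' less than neutral; at 100 % varus the whole load is concentrated on the
#' medial compartment and the lateral compartment is unloaded.  The sum
#' always equals the total.
#'
#' @param total total compressive force in N.
#' @param varus_level 0, 50 or 100 (percent).
#' @return named numeric vector `c(medial =, lateral =)` in N.
#' @examples
#' redistribute_load(2.94, 0)    # 1.47 / 1.47
#' redistribute_load(2.94, 50)   # 2.205 / 0.735
#' redistribute_load(2.94, 100)  # 2.94 / 0
#' @export
redistribute_load <- function(total, varus_level) {
  if (!varus_level %in% c(0, 50, 100))
    stop("unsupported varus level: ", varus_level)
  half <- total / 2
  f <- switch(as.character(varus_level),
              "0" = c(half, half),
              "50" = c(1.5 * half, 0.5 * half),
              "100" = c(total, 0))
  c(medial = f[1], lateral = f[2])
}

vertex_normals <- function(mesh) {
  fn <- mesh_face_normals(mesh)
  fa <- mesh_face_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  w <- fn * fa
  for (j in 1:3) {
    idx <- mesh$faces[, j]
    for (k in 1:3)
      n[, k] <- n[, k] + unname(tapply_add(w[, k], idx, nrow(mesh$vertices)))
  }
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg
  out
}

# Offset cartilage outer surface of a patch: host mesh vertices moved along
# outward vertex normals by the patch thickness.
offset_surface <- function(mesh, thickness) {
  vn <- vertex_normals(mesh)
  mesh$vertices + thickness * vn
}

# Interpolate the z of a triangulated surface at query points (x, y).
# Returns the z closest to the tibia (max z) where multiple sheets cover a
# point; NA where no triangle covers it.
interp_surface_z <- function(verts, faces, qx, qy) {
  nq <- length(qx)
  out <- rep(NA_real_, nq)
  ax <- verts[faces[, 1], 1]; ay <- verts[faces[, 1], 2]; az <- verts[faces[, 1], 3]
  bx <- verts[faces[, 2], 1]; by <- verts[faces[, 2], 2]; bz <- verts[faces[, 2], 3]
  cx <- verts[faces[, 3], 1]; cy <- verts[faces[, 3], 2]; cz <- verts[faces[, 3], 3]
  ord <- order(qx)
  qxs <- qx[ord]; qys <- qy[ord]
  xmin <- pmin(ax, bx, cx); xmax <- pmax(ax, bx, cx)
  ymin <- pmin(ay, by, cy); ymax <- pmax(ay, by, cy)
  for (f in seq_along(ax)) {
    lo <- findInterval(xmin[f], qxs) + 1L
    hi <- findInterval(xmax[f], qxs)
    if (hi < lo) next
    sel <- lo:hi
    sel <- sel[qys[sel] >= ymin[f] & qys[sel] <= ymax[f]]
    if (!length(sel)) next
    # barycentric coordinates in the xy projection
    d <- (by[f] - cy[f]) * (ax[f] - cx[f]) + (cx[f] - bx[f]) * (ay[f] - cy[f])
    if (abs(d) < 1e-14) next
    l1 <- ((by[f] - cy[f]) * (qxs[sel] - cx[f]) +
             (cx[f] - bx[f]) * (qys[sel] - cy[f])) / d
    l2 <- ((cy[f] - ay[f]) * (qxs[sel] - cx[f]) +
             (ax[f] - cx[f]) * (qys[sel] - cy[f])) / d
    l3 <- 1 - l1 - l2
    eps <- -1e-9
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (!any(inside)) next
    zi <- l1[inside] * az[f] + l2[inside] * bz[f] + l3[inside] * cz[f]
    tgt <- ord[sel[inside]]
    repl <- is.na(out[tgt]) | zi > out[tgt]
    out[tgt[repl]] <- zi[repl]
  }
  out
}

#' Initial gap field of one tibiofemoral compartment
#'
#' For every tibial-plateau cartilage element of the given side, the
#' separation along the JCS -Z direction between the opposing outer
#' cartilage surfaces: each bone surface is offset outward along its vertex
#' normals by its cartilage thickness, and the femoral offset surface is
#' interpolated above each tibial element centroid.  Elements farther apart
#' than the pinball radius, or with no opposing femoral surface, are
#' excluded from the candidate contact set.  Gaps may be negative (initial
#' interpenetration).
#'
#' @param s a posed `knee_specimen`.
#' @param jcs its joint coordinate system.
#' @param side `"medial"` or `"lateral"`.
#' @param pinball candidate cutoff distance in mm.
#' @return data frame with one row per candidate tibial element: centroid
#'   (JCS coordinates), `area` (true element area, mm^2), `proj_area`
#'   (projected on the plateau plane), `gap` (mm) and `face` (host face
#'   index).  Attributes: `side`, `patch_area` (total tibial patch area),
#'   `thickness_total` (femoral + tibial layer thickness).
#' @export
compartment_gap_field <- function(s, jcs, side = c("medial", "lateral"),
                                  pinball = 0.1) {
  side <- match.arg(side)
  Rloc <- cbind(jcs$X, jcs$Y, jcs$Z)
  to_local <- function(p) sweep(p, 2, jcs$origin) %*% Rloc

  tib_patch <- s$cartilage[[paste0("tibia_", side)]]
  fem_patch <- s$cartilage[[paste0("femur_", side)]]
  tib <- s[[tib_patch$host_body]]
  fem <- s[[fem_patch$host_body]]

  empty <- function(patch_area = 0) {
    out <- data.frame(face = integer(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), area = numeric(0),
                      proj_area = numeric(0), gap = numeric(0))
    attr(out, "side") <- side
    attr(out, "patch_area") <- patch_area
    attr(out, "thickness_total") <- tib_patch$thickness + fem_patch$thickness
    out
  }
  if (!length(fem_patch$faces)) return(empty())

  tib_off <- to_local(offset_surface(tib, tib_patch$thickness))
  fem_off <- to_local(offset_surface(fem, fem_patch$thickness))

  tf <- tib$faces[tib_patch$faces, , drop = FALSE]
  a <- tib_off[tf[, 1], , drop = FALSE]
  b <- tib_off[tf[, 2], , drop = FALSE]
  cc <- tib_off[tf[, 3], , drop = FALSE]
  cent <- (a + b + cc) / 3
  cr <- cross3(b - a, cc - a)
  area <- 0.5 * sqrt(rowSums(cr^2))
  proj_area <- 0.5 * abs(cr[, 3])
  patch_area <- sum(area)

  ff <- fem$faces[fem_patch$faces, , drop = FALSE]
  zf <- interp_surface_z(fem_off, ff, cent[, 1], cent[, 2])
  gap <- cent[, 3] - zf

  keep <- !is.na(gap) & gap <= pinball
  out <- data.frame(face = tib_patch$faces[keep], x = cent[keep, 1],
                    y = cent[keep, 2], z = cent[keep, 3],
                    area = area[keep], proj_area = proj_area[keep],
                    gap = gap[keep])
  attr(out, "side") <- side
  attr(out, "patch_area") <- patch_area
  attr(out, "thickness_total") <- tib_patch$thickness + fem_patch$thickness
  out
}

foundation_force <- function(gap_df, kf, u) {
  sum(kf * pmax(0, u - gap_df$gap) * gap_df$proj_area)
}

compartment_result <- function(gap_df, kf, u, side, prescribed = NA_real_) {
  p <- kf * pmax(0, u - gap_df$gap)
  achieved <- sum(p * gap_df$proj_area)
  field <- gap_df
  field$pressure <- p
  peak <- if (length(p) && any(p > 0)) p[which.max(p)] else 0
  structure(list(side = side, prescribed_force = prescribed,
                 achieved_force = achieved,
                 peak_pressure = peak,
                 contact_area = sum(gap_df$area[p > 0]),
                 indentation = u, pressure_field = field),
            class = "compartment_result")
}

#' Solve the elastic-foundation indentation of one compartment
#'
#' Finds the rigid approach u >= min gap such that the total foundation
#' force F(u) = sum_i (E_eff / t) * max(0, u - g_i) * A_i equals the target,
#' by bisection on a geometrically grown bracket (force tolerance 1e-6 N,
#' at most 200 iterations).  Element pressures are
#' (E_eff / t) * max(0, u - g_i); the peak pressure is the maximum element
#' pressure (ties broken by lowest element index) and the contact area the
#' summed area of elements with positive pressure.  A zero target force
#' yields a zero pressure field.
#'
#' @param gap_df gap field from [compartment_gap_field()] (or any data frame
#'   with `gap`, `area`, `proj_area` columns).
#' @param E_eff foundation (confined) modulus, MPa.
#' @param total_thickness total resting thickness of the two cartilage
#'   layers in series, mm.
#' @param target_force compartment force to equilibrate, N (>= 0).
#' @param tol force tolerance, N.
#' @param max_iter bisection iteration cap.
#' @return a `compartment_result`.
#' @export
solve_indentation <- function(gap_df, E_eff, total_thickness, target_force,
                              tol = 1e-6, max_iter = 200) {
  if (target_force < 0) stop("target_force must be >= 0")
  if (E_eff <= 0 || total_thickness <= 0)
    stop("E_eff and total_thickness must be positive")
  kf <- E_eff / total_thickness
  side <- attr(gap_df, "side") %||% "medial"
  if (nrow(gap_df) == 0 || target_force == 0) {
    u0 <- if (nrow(gap_df)) min(0, min(gap_df$gap)) else 0
    return(compartment_result(gap_df, kf, u0, side, target_force))
  }
  lo <- min(gap_df$gap)          # F(lo) = 0
  hi <- lo + max(1e-4, 0.05 * abs(lo))
  it <- 0L
  while (foundation_force(gap_df, kf, hi) < target_force) {
    hi <- lo + 2 * (hi - lo)
    it <- it + 1L
    if (it > 100L) stop("failed to bracket the target force")
  }
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- foundation_force(gap_df, kf, mid)
    if (abs(fm - target_force) <= tol) {
      return(compartment_result(gap_df, kf, mid, side, target_force))
    }
    if (fm < target_force) lo <- mid else hi <- mid
  }
  stop("indentation solve did not converge within ", max_iter, " iterations")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ligament_state <- function(s, materials, jcs, femur_dz = 0) {
  lig <- s$ligaments
  out <- data.frame(name = lig$name, length = NA_real_, tension = NA_real_,
                    dz = NA_real_)
  for (i in seq_len(nrow(lig))) {
    o <- s[[lig$origin_body[i]]]$vertices[lig$origin_vertex[i], ] +
      femur_dz * jcs$Z
    ins <- s[[lig$insertion_body[i]]]$vertices[lig$insertion_vertex[i], ]
    d <- ins - o
    L <- sqrt(sum(d^2))
    mt <- materials$ligament_table[[lig$name[i]]]
    tension <- ligament_force(L, lig$reference_length[i], mt[["stiffness"]],
                              mt[["pretension"]])
    out$length[i] <- L
    out$tension[i] <- tension
    out$dz[i] <- sum(d / L * jcs$Z)   # vertical (femur->tibia) direction cosine
  }
  out
}

contact_outcome <- function(medial, lateral, lig, total_force, mode, case) {
  structure(list(medial = medial, lateral = lateral,
                 ligament_forces = stats::setNames(lig$tension, lig$name),
                 equilibrium_residual =
                   abs(medial$achieved_force + lateral$achieved_force -
                         sum(lig$tension * lig$dz) * (mode == "angle") -
                         total_force),
                 mode = mode, case = case),
            class = "contact_outcome")
}

#' @export
print.contact_outcome <- function(x, ...) {
  cat(sprintf("<contact_outcome (%s): medial %.3f N / %.3f MPa / %.2f mm^2; lateral %.3f N / %.3f MPa / %.2f mm^2>\n",
              x$mode, x$medial$achieved_force, x$medial$peak_pressure,
              x$medial$contact_area, x$lateral$achieved_force,
              x$lateral$peak_pressure, x$lateral$contact_area))
  invisible(x)
}

#' Solve a prescribed-redistribution (fraction mode) load case
#'
#' The study's main loading experiment: the total compressive load is
#' redistributed between the compartments according to the varus level and
#' each compartment is equilibrated independently by the elastic-foundation
#' solver.  Ligament tensions are reported at the posed configuration but do
#' not enter the force balance in this mode, so the achieved compartment
#' forces sum to the prescribed total by construction.
#'
#' @param s a `knee_specimen`.
#' @param materials a [material_set()].
#' @param case a [load_case()] with `mode = "fraction"`.
#' @return a `contact_outcome`.
#' @export
solve_load_case_fraction <- function(s, materials = material_set(),
                                     case = load_case()) {
  if (!identical(case$mode, "fraction")) stop("case mode must be 'fraction'")
  jcs <- build_jcs(s)
  posed <- pose_flexion(s, jcs, case$flexion)
  E_eff <- foundation_modulus(materials$cartilage_E, materials$cartilage_nu)
  forces <- redistribute_load(case$total_force, case$varus_level)
  res <- list()
  for (side in c("medial", "lateral")) {
    gap <- compartment_gap_field(posed, jcs, side, case$pinball)
    if (nrow(gap) == 0 && forces[[side]] > 0)
      stop("no candidate contact elements in loaded ", side, " compartment")
    res[[side]] <- solve_indentation(gap, E_eff, attr(gap, "thickness_total"),
                                     forces[[side]])
  }
  lig <- ligament_state(posed, materials, jcs)
  contact_outcome(res$medial, res$lateral, lig, case$total_force,
                  "fraction", case)
}

#' Solve a prescribed-angulation (angle mode) load case
#'
#' The experimental-equivalence mode: the femur is rotated by the varus
#' angle about the JCS Y axis (3 degrees corresponds to the 50 % and
#' 6 degrees to the 100 % redistribution condition) and a single vertical
#' translation of the rigid femur is solved so that the total contact force
#' plus the vertical components of the ligament tensions balances the
#' applied load.  Compartment forces then emerge from the geometry.
#'
#' @inheritParams solve_load_case_fraction
#' @param case a [load_case()] with `mode = "angle"`.
#' @return a `contact_outcome`; element `medial_fraction` of the case
#'   records the emergent medial force share.
#' @export
solve_load_case_angle <- function(s, materials = material_set(),
                                  case = load_case(mode = "angle")) {
  if (!identical(case$mode, "angle")) stop("case mode must be 'angle'")
  jcs <- build_jcs(s)
  posed <- pose_flexion(s, jcs, case$flexion)
  posed <- pose_varus(posed, jcs, case$varus_angle)
  E_eff <- foundation_modulus(materials$cartilage_E, materials$cartilage_nu)
  gaps <- lapply(c(medial = "medial", lateral = "lateral"), function(side)
    compartment_gap_field(posed, jcs, side, case$pinball))
  if (all(vapply(gaps, nrow, integer(1)) == 0))
    stop("no candidate contact elements in either compartment")
  kf <- lapply(gaps, function(g)
    E_eff / attr(g, "thickness_total"))

  balance <- function(u) {
    fc <- foundation_force(gaps$medial, kf$medial, u) +
      foundation_force(gaps$lateral, kf$lateral, u)
    lig <- ligament_state(posed, materials, jcs, femur_dz = u)
    fc - sum(lig$tension * lig$dz) - case$total_force
  }
  lo <- min(vapply(gaps, function(g)
    if (nrow(g)) min(g$gap) else Inf, numeric(1))) - 0.5
  hi <- lo + 0.5
  it <- 0L
  while (balance(hi) < 0) {
    hi <- lo + 2 * (hi - lo); it <- it + 1L
    if (it > 100L) stop("failed to bracket equilibrium")
  }
  if (balance(lo) > 0) stop("equilibrium bracket invalid at lower bound")
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    bm <- balance(mid)
    if (abs(bm) <= 1e-6) break
    if (bm < 0) lo <- mid else hi <- mid
  }
  if (abs(bm) > 1e-6) stop("angle-mode equilibrium did not converge")
  u <- mid
  med <- compartment_result(gaps$medial, kf$medial, u, "medial")
  lat <- compartment_result(gaps$lateral, kf$lateral, u, "lateral")
  lig <- ligament_state(posed, materials, jcs, femur_dz = u)
  out <- contact_outcome(med, lat, lig, case$total_force, "angle", case)
  tot <- med$achieved_force + lat$achieved_force
  out$medial_fraction <- if (tot > 0) med$achieved_force / tot else NA_real_
  out
}
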