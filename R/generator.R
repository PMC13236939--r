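#' Configuration of the synthetic rat-knee cohort generator
#'
#' The generator emulates a bilateral micro-CT cohort: `n_animals` animals
#' with two hind limbs each, every limb a deformation of one template grid
#' (so all specimens share face topology and are in vertex-wise
#' correspondence by construction).  Left limbs are produced in left-side
#' representation and mirrored back to right-side representation, as in the
#' source imaging protocol.
#'
#' Geometry model (all lengths mm, right-side representation, +X lateral,
#' +Z pointing from femur to tibia):
#' * the femoral condylar region is a spherical sheet of radius
#'   `joint_radius` about the epicondylar midpoint, carrying two quadric
#'   condylar caps whose surfaces recede from the sphere as
#'   `s^2 / (2 * conformity_radius)` with `s` the arc distance from the cap
#'   centre (centres at frontal offset `condyle_offset` either side of the
#'   midline);
#' * the tibial plateau is a near-concentric spherical dish whose frontal
#'   centre sits `plateau_drop` below the epicondylar origin; this small
#'   eccentricity is what converts a varus rotation of the femur into
#'   medial-compartment engagement while the near-concentricity lets the
#'   femur slide over the dish without losing bicompartmental contact;
#' * shafts are cylinders, the patella a free ellipsoid (carried through
#'   the shape model but never loaded).
#'
#' The nominal articular dimensions are a design calibration of the package
#' (chosen once so that the nominal specimen reproduces specimen-scale
#' contact areas under the standard load; see the methods vignette); the
#' study-level constants (cohort layout 5 x 2, mesh resolution 0.3 / 0.2 mm,
#' cartilage thickness 0.25 mm) are fixed defaults.
#'
#' @param n_animals number of animals (default 5).
#' @param limbs_per_animal limbs per animal (default 2: left + right).
#' @param seed master RNG seed for the cohort.
#' @param nominal named list of nominal geometry/density parameters; any
#'   subset may be supplied to override the defaults (see
#'   `generator_nominal_defaults()`).
#' @param sd_between,sd_within named lists of relative (coefficient of
#'   variation) standard deviations for the varied parameters, between
#'   animals and within an animal (left-right), respectively.
#' @param pose_jitter_deg,pose_jitter_mm SD of the random rigid acquisition
#'   pose applied per limb (rotation in degrees, translation in mm).
#' @param edge_bone,edge_patella target mesh edge lengths (mm) for the bone
#'   and patella grids.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_animals = 5, limbs_per_animal = 2, seed = 1,
                             nominal = list(),
                             sd_between = list(),
                             sd_within = list(),
                             pose_jitter_deg = 1.5, pose_jitter_mm = 0.2,
                             edge_bone = 0.3, edge_patella = 0.2) {
  if (n_animals < 1 || limbs_per_animal < 1)
    stop("n_animals and limbs_per_animal must be positive")
  nom <- utils::modifyList(generator_nominal_defaults(), nominal)
  sdb <- utils::modifyList(generator_sd_defaults("between"), sd_between)
  sdw <- utils::modifyList(generator_sd_defaults("within"), sd_within)
  if (any(unlist(sdb) < 0) || any(unlist(sdw) < 0))
    stop("variation SDs must be >= 0")
  if (pose_jitter_deg < 0 || pose_jitter_mm < 0)
    stop("pose jitter SDs must be >= 0")
  structure(list(n_animals = as.integer(n_animals),
                 limbs_per_animal = as.integer(limbs_per_animal),
                 seed = as.integer(seed),
                 nominal = nom, sd_between = sdb, sd_within = sdw,
                 pose_jitter_deg = pose_jitter_deg,
                 pose_jitter_mm = pose_jitter_mm,
                 edge_bone = edge_bone, edge_patella = edge_patella),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
generator_nominal_defaults <- function() {
  list(
    scale             = 1,      # global size multiplier
    joint_radius      = 6.0,    # femoral condylar sphere radius about the epicondylar origin
    condyle_offset    = 2.2,    # frontal offset of each condylar cap centre
    conformity_radius = 483,    # articular conformity (gap curvature) radius
    plateau_drop      = 0.013,  # tibial dish frontal-centre drop below the origin
    clearance         = 0,      # articular clearance at the cap centres
    cartilage_thickness = 0.25, # one layer; the contact law stacks two
    patch_halfwidth_frontal  = 2.6,  # tibial compartment patch half-extent
    patch_halfwidth_sagittal = 1.9,
    femur_sheet_a = 0.84, femur_sheet_b = 0.37,   # half-extents (rad) of the condylar sheet
    tibia_sheet_a = 0.825, tibia_sheet_b = 0.33,  # half-extents (rad) of the plateau dish
    femur_articular_edge = 0.1,  # refined mesh edge on the articular sheets
    tibia_articular_edge = 0.15, # (contact-region refinement below the average bone edge)
    flexion_design = 80,        # flexion (deg) at which the joint articulates (standing pose)
    epicondyle_halfspan = 3.4,
    femur_shaft_length = 8, femur_shaft_radius = 1.6, femur_shaft_offset = 3,
    tibia_shaft_length = 8, tibia_shaft_radius = 1.8, tibia_shaft_offset = 1.5,
    patella_semiaxes = c(1.5, 1.0, 0.7),
    patella_angle = -1.25, patella_dist = 4.8,
    density_cortical = 1.2, density_trabecular = 0.6,  # g/cm^3
    ligament_recruitment_margin = 0.2)
}

generator_varied_params <- c("scale", "condyle_offset", "conformity_radius",
                             "plateau_drop", "density_cortical",
                             "density_trabecular")

generator_sd_defaults <- function(which = c("between", "within")) {
  which <- match.arg(which)
  if (which == "between")
    list(scale = 0.02, condyle_offset = 0.015, conformity_radius = 0.05,
         plateau_drop = 0.04, density_cortical = 0.04,
         density_trabecular = 0.04)
  else
    list(scale = 0.005, condyle_offset = 0.004, conformity_radius = 0.015,
         plateau_drop = 0.01, density_cortical = 0.01,
         density_trabecular = 0.01)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config: %d animals x %d limbs, seed %d, edges %.2g/%.2g mm>\n",
              x$n_animals, x$limbs_per_animal, x$seed, x$edge_bone, x$edge_patella))
  invisible(x)
}

# Direction on the unit sphere: a = frontal angle (+ lateral), b = sagittal.
dhat <- function(a, b) cbind(sin(a), cos(a) * sin(b), cos(a) * cos(b))

deg2rad <- function(x) x * pi / 180

grid_count <- function(extent, edge, odd = FALSE) {
  n <- max(3L, as.integer(round(extent / edge)) + 1L)
  if (odd && n %% 2L == 0L) n <- n + 1L
  n
}

# Build one body part and return vertices plus bookkeeping
tube_part <- function(p0, axis, len, radius, n_axial, n_around) {
  axis <- axis / sqrt(sum(axis^2))
  e1 <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  u <- seq(0, 1, length.out = n_axial)
  v <- seq(0, 2 * pi, length.out = n_around + 1L)  # seam duplicated
  grid_mesh(u, v, function(uu, vv) {
    ctr <- matrix(p0, length(uu), 3, byrow = TRUE) +
      outer(uu * len, axis)
    ctr + radius * (outer(cos(vv), e1) + outer(sin(vv), e2))
  })
}

orient_outward <- function(part, outward_fun) {
  # flip winding of faces whose normal disagrees with the outward reference
  v <- part$vertices; f <- part$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  n <- cross3(b - a, c_ - a)
  ref <- outward_fun((a + b + c_) / 3)
  flip <- rowSums(n * ref) < 0
  if (mean(flip) > 0.5) part$faces <- f[, c(1L, 3L, 2L), drop = FALSE]
  part
}

# Resolution and parameter-space layout shared by every specimen of a cohort
cohort_layout <- function(config) {
  nom <- config$nominal
  rho <- nom$joint_radius
  fa <- nom$femur_sheet_a; fb <- nom$femur_sheet_b
  ta <- nom$tibia_sheet_a; tb <- nom$tibia_sheet_b
  b0 <- -deg2rad(nom$flexion_design)
  eb <- config$edge_bone
  shaft_edge <- 1.6 * eb
  list(
    b0 = b0,
    femur_sheet = list(a = seq(-fa, fa, length.out = grid_count(2 * fa * rho, nom$femur_articular_edge)),
                       b = seq(b0 - fb, b0 + fb, length.out = grid_count(2 * fb * rho, nom$femur_articular_edge))),
    tibia_sheet = list(a = seq(-ta, ta, length.out = grid_count(2 * ta * rho, nom$tibia_articular_edge, odd = TRUE)),
                       b = seq(-tb, tb, length.out = grid_count(2 * tb * rho, nom$tibia_articular_edge, odd = TRUE))),
    femur_shaft = list(n_axial = grid_count(nom$femur_shaft_length, shaft_edge),
                       n_around = grid_count(2 * pi * nom$femur_shaft_radius, shaft_edge)),
    tibia_shaft = list(n_axial = grid_count(nom$tibia_shaft_length, shaft_edge),
                       n_around = grid_count(2 * pi * nom$tibia_shaft_radius, shaft_edge)),
    patella = list(n_polar = grid_count(pi * mean(nom$patella_semiaxes[2:3]),
                                        config$edge_patella),
                   n_azim = grid_count(2 * pi * mean(nom$patella_semiaxes[1:2]),
                                       config$edge_patella)))
}

# Construct the three body meshes of one limb from a parameter list.
# Returns meshes plus the per-part vertex index ranges and parameter grids.
build_bodies <- function(par, layout) {
  rho  <- par$joint_radius * par$scale
  xc   <- par$condyle_offset * par$scale
  Rc   <- par$conformity_radius * par$scale
  e    <- par$plateau_drop * par$scale
  a_c  <- asin(xc / rho)
  b0   <- layout$b0

  # femoral condylar sheet: sphere minus quadric cap deficits
  cap_deficit <- function(aa, bb) {
    s_m <- rho * (aa + a_c); s_l <- rho * (aa - a_c)
    t_ <- rho * (bb - b0)
    pmin((s_m^2 + t_^2), (s_l^2 + t_^2)) / (2 * Rc)
  }
  sheet <- grid_mesh(layout$femur_sheet$a, layout$femur_sheet$b, function(aa, bb) {
    (rho - cap_deficit(aa, bb)) * dhat(aa, bb)
  })
  sheet$vertices <- as.matrix(sheet$vertices)
  sheet <- orient_outward(sheet, function(p) p)  # outward = away from origin

  v_sh <- c(0, -sin(b0), -cos(b0))               # proximal shaft direction
  fsh <- tube_part(par$femur_shaft_offset * par$scale * v_sh, v_sh,
                   par$femur_shaft_length * par$scale,
                   par$femur_shaft_radius * par$scale,
                   layout$femur_shaft$n_axial, layout$femur_shaft$n_around)
  fsh <- orient_outward(fsh, function(p) {
    ax <- matrix(v_sh, nrow(p), 3, byrow = TRUE)
    p - rowSums(p * ax) * ax
  })

  # tibial plateau dish: near-concentric sphere, frontal centre dropped by e
  rho_t <- rho + 2 * par$cartilage_thickness + par$clearance - e * cos(a_c)
  o_t <- c(0, 0, e)
  dish <- grid_mesh(layout$tibia_sheet$a, layout$tibia_sheet$b, function(aa, bb) {
    sweep(rho_t * dhat(aa, bb), 2, o_t, "+")
  })
  dish <- orient_outward(dish, function(p) -sweep(p, 2, o_t))  # outward = toward femur

  tsh <- tube_part(c(0, 0, rho + par$tibia_shaft_offset * par$scale), c(0, 0, 1),
                   par$tibia_shaft_length * par$scale,
                   par$tibia_shaft_radius * par$scale,
                   layout$tibia_shaft$n_axial, layout$tibia_shaft$n_around)
  tsh <- orient_outward(tsh, function(p) {
    cbind(p[, 1], p[, 2], 0)
  })

  # patella: free ellipsoid anterior-proximal to the condyles
  ctr <- par$patella_dist * par$scale * dhat(0, b0 + par$patella_angle)[1, ]
  sa <- par$patella_semiaxes * par$scale
  u <- seq(0.25, pi - 0.25, length.out = layout$patella$n_polar)
  v <- seq(0, 2 * pi, length.out = layout$patella$n_azim + 1L)
  w3 <- dhat(0, b0 + par$patella_angle)[1, ]
  w1 <- c(1, 0, 0)
  w2 <- c(w3[2] * w1[3] - w3[3] * w1[2], w3[3] * w1[1] - w3[1] * w1[3],
          w3[1] * w1[2] - w3[2] * w1[1])
  pat <- grid_mesh(u, v, function(uu, vv) {
    loc <- cbind(sa[1] * sin(uu) * cos(vv), sa[2] * sin(uu) * sin(vv),
                 sa[3] * cos(uu))
    sweep(loc %*% rbind(w1, w2, w3), 2, ctr, "+")
  })
  pat <- orient_outward(pat, function(p) sweep(p, 2, ctr))

  list(sheet = sheet, femur_shaft = fsh, dish = dish, tibia_shaft = tsh,
       patella = pat, rho = rho, rho_t = rho_t, o_t = o_t, a_c = a_c, b0 = b0)
}

assemble_body <- function(parts, body) {
  nv <- vapply(parts, function(p) nrow(p$vertices), integer(1))
  off <- cumsum(c(0L, nv[-length(nv)]))
  verts <- do.call(rbind, lapply(parts, `[[`, "vertices"))
  faces <- do.call(rbind, mapply(function(p, o) p$faces + o, parts, off,
                                 SIMPLIFY = FALSE))
  list(mesh = surface_mesh(verts, faces, body = body),
       offsets = off, n_vertices = nv)
}

blend_density <- function(dist_mm, trab, cort, start = 4.5, width = 4) {
  w <- pmin(1, pmax(0, (dist_mm - start) / width))
  (1 - w) * trab + w * cort
}

# Affine tether: express an (interior) landmark point as an affine
# combination of nearby template vertices, so reconstructed specimens can
# transport it.  Minimum-norm weights subject to sum-to-one and exactness.
affine_tether <- function(vertices, point, k = 28) {
  d2 <- rowSums(sweep(vertices, 2, point)^2)
  idx <- order(d2)[seq_len(min(k, nrow(vertices)))]
  V <- vertices[idx, , drop = FALSE]
  Cmat <- cbind(V, 1)                     # k x 4 constraints (transposed use)
  n <- length(idx)
  KKT <- rbind(cbind(2 * diag(n), Cmat), cbind(t(Cmat), matrix(0, 4, 4)))
  rhs <- c(rep(0, n), point, 1)
  w <- solve(KKT, rhs)[seq_len(n)]
  list(idx = idx, w = w)
}

apply_tether <- function(tether, vertices) {
  as.numeric(t(vertices[tether$idx, , drop = FALSE]) %*% tether$w)
}

# Build one specimen in right-side representation (generation frame:
# epicondylar midpoint at the origin, extension pose).
build_specimen <- function(par, layout, template = NULL) {
  parts <- build_bodies(par, layout)
  fem <- assemble_body(parts[c("sheet", "femur_shaft")], "femur")
  tib <- assemble_body(parts[c("dish", "tibia_shaft")], "tibia_fibula")
  pat <- assemble_body(parts["patella"], "patella")

  rho <- parts$rho; a_c <- parts$a_c; b0 <- parts$b0

  if (is.null(template)) {
    template <- make_template(par, layout, parts, fem, tib, pat)
  }

  # densities: trabecular at the joint, cortical along the shafts
  trab <- par$density_trabecular; cort <- par$density_cortical
  fem_d <- numeric(nrow(fem$mesh$vertices))
  sheet_n <- fem$n_vertices[[1]]
  fem_d[seq_len(sheet_n)] <- trab
  sh_idx <- (sheet_n + 1):nrow(fem$mesh$vertices)
  fem_d[sh_idx] <- blend_density(sqrt(rowSums(fem$mesh$vertices[sh_idx, ]^2)),
                                 trab, cort,
                                 start = (par$femur_shaft_offset + 1) * par$scale,
                                 width = 4 * par$scale)
  tib_d <- numeric(nrow(tib$mesh$vertices))
  dish_n <- tib$n_vertices[[1]]
  tib_d[seq_len(dish_n)] <- trab
  tsh_idx <- (dish_n + 1):nrow(tib$mesh$vertices)
  tib_d[tsh_idx] <- blend_density(tib$mesh$vertices[tsh_idx, 3] - rho, trab, cort,
                                  start = (par$tibia_shaft_offset + 1) * par$scale,
                                  width = 4 * par$scale)
  pat_d <- rep(0.5 * (trab + cort), nrow(pat$mesh$vertices))

  fem$mesh$vertex_density <- fem_d
  tib$mesh$vertex_density <- tib_d
  pat$mesh$vertex_density <- pat_d
  fem$mesh$face_region <- template$face_region$femur
  tib$mesh$face_region <- template$face_region$tibia_fibula
  pat$mesh$face_region <- template$face_region$patella

  # analytic landmarks (exact for generated specimens; reconstructed
  # specimens recover them through the template tethers)
  w_epi <- par$epicondyle_halfspan * par$scale
  landmarks <- list(
    medial_epicondyle  = c(-w_epi, 0, 0),
    lateral_epicondyle = c(w_epi, 0, 0),
    plateau_center     = parts$o_t + parts$rho_t * c(0, 0, 1),
    plateau_normal_ref = parts$o_t + parts$rho_t * c(0, 0, 1) + c(0, 0, 1.2 * par$scale))

  # ligament reference lengths: standing-pose lengths plus a recruitment
  # margin, so the tension-only springs are slack in the neutral standing
  # pose and engage only beyond the margin
  R80 <- rotation_about_axis(c(1, 0, 0), -deg2rad(par$flexion_design))
  lig <- template$ligaments
  meshes <- list(femur = fem$mesh, tibia_fibula = tib$mesh, patella = pat$mesh)
  lig$reference_length <- vapply(seq_len(nrow(lig)), function(i) {
    o <- meshes[[lig$origin_body[i]]]$vertices[lig$origin_vertex[i], ]
    ins <- meshes[[lig$insertion_body[i]]]$vertices[lig$insertion_vertex[i], ]
    o_posed <- as.numeric(R80 %*% o)
    L <- sqrt(sum((o_posed - ins)^2))
    L * (1 + par$ligament_recruitment_margin) / (1 - lig$pretension_default[i])
  }, numeric(1))

  structure(list(animal_id = NA_integer_, side_as_acquired = NA_character_,
                 is_mirrored = FALSE, representation = "right",
                 femur = fem$mesh, tibia_fibula = tib$mesh, patella = pat$mesh,
                 landmarks = landmarks,
                 landmark_body = c(medial_epicondyle = "femur",
                                   lateral_epicondyle = "femur",
                                   plateau_center = "tibia_fibula",
                                   plateau_normal_ref = "tibia_fibula"),
                 cartilage = template$cartilage,
                 ligaments = lig,
                 template = template,
                 params = par),
            class = "knee_specimen")
}

make_template <- function(par, layout, parts, fem, tib, pat) {
  rho <- parts$rho; a_c <- parts$a_c; b0 <- parts$b0

  # face regions / cartilage patches from the parameter grids
  sheet <- parts$sheet; dish <- parts$dish
  sheet_nf <- nrow(sheet$faces)
  fem_regions <- rep("other", nrow(fem$mesh$faces))
  fc <- (sheet$u[sheet$faces[, 1]] + sheet$u[sheet$faces[, 2]] +
           sheet$u[sheet$faces[, 3]]) / 3
  fcb <- (sheet$v[sheet$faces[, 1]] + sheet$v[sheet$faces[, 2]] +
            sheet$v[sheet$faces[, 3]]) / 3
  s_m <- rho * (fc + a_c); s_l <- rho * (fc - a_c); t_ <- rho * (fcb - b0)
  phf <- par$patch_halfwidth_frontal * par$scale
  phs <- par$patch_halfwidth_sagittal * par$scale
  rpf <- sqrt(phf^2 + phs^2)
  fem_regions[seq_len(sheet_nf)][s_m^2 + t_^2 <= rpf^2 & fc < 0] <- "medial"
  fem_regions[seq_len(sheet_nf)][s_l^2 + t_^2 <= rpf^2 & fc >= 0] <- "lateral"

  dish_nf <- nrow(dish$faces)
  tib_regions <- rep("other", nrow(tib$mesh$faces))
  dc <- (dish$u[dish$faces[, 1]] + dish$u[dish$faces[, 2]] +
           dish$u[dish$faces[, 3]]) / 3
  dcb <- (dish$v[dish$faces[, 1]] + dish$v[dish$faces[, 2]] +
            dish$v[dish$faces[, 3]]) / 3
  in_patch <- function(centre_a) {
    abs(rho * (dc - centre_a)) <= phf & abs(rho * dcb) <= phs
  }
  tib_regions[seq_len(dish_nf)][in_patch(-a_c)] <- "medial"
  tib_regions[seq_len(dish_nf)][in_patch(a_c)] <- "lateral"

  cartilage <- list(
    femur_medial = list(host_body = "femur", side = "medial",
                        faces = which(fem_regions == "medial"),
                        thickness = par$cartilage_thickness),
    femur_lateral = list(host_body = "femur", side = "lateral",
                         faces = which(fem_regions == "lateral"),
                         thickness = par$cartilage_thickness),
    tibia_medial = list(host_body = "tibia_fibula", side = "medial",
                        faces = which(tib_regions == "medial"),
                        thickness = par$cartilage_thickness),
    tibia_lateral = list(host_body = "tibia_fibula", side = "lateral",
                         faces = which(tib_regions == "lateral"),
                         thickness = par$cartilage_thickness))

  # ligament attachments: nearest template vertices to anatomical anchors
  rho_t <- parts$rho_t; o_t <- parts$o_t
  nearest <- function(mesh, p) which.min(rowSums(sweep(mesh$vertices, 2, p)^2))
  anchors <- list(
    ACL = list(o = rho * dhat(0.22, b0 + 0.05)[1, ],
               i = o_t + rho_t * dhat(0.03, -0.22)[1, ]),
    PCL = list(o = rho * dhat(-0.22, b0 - 0.05)[1, ],
               i = o_t + rho_t * dhat(-0.03, 0.25)[1, ]),
    MCL = list(o = rho * dhat(-0.80, b0)[1, ],
               i = c(-par$tibia_shaft_radius * par$scale, 0, rho + 4 * par$scale)),
    LCL = list(o = rho * dhat(0.80, b0)[1, ],
               i = c(par$tibia_shaft_radius * par$scale, 0, rho + 4 * par$scale)))
  pret <- c(ACL = 0.05, PCL = 0.05, MCL = 0.04, LCL = 0.04)
  ligaments <- data.frame(
    name = names(anchors),
    origin_body = "femur", insertion_body = "tibia_fibula",
    origin_vertex = vapply(anchors, function(a) nearest(fem$mesh, a$o), integer(1)),
    insertion_vertex = vapply(anchors, function(a) nearest(tib$mesh, a$i), integer(1)),
    pretension_default = pret[names(anchors)],
    reference_length = NA_real_,
    stringsAsFactors = FALSE)
  rownames(ligaments) <- NULL

  w_epi <- par$epicondyle_halfspan * par$scale
  tethers <- list(
    medial_epicondyle = c(list(body = "femur"),
                          affine_tether(fem$mesh$vertices, c(-w_epi, 0, 0))),
    lateral_epicondyle = c(list(body = "femur"),
                           affine_tether(fem$mesh$vertices, c(w_epi, 0, 0))),
    plateau_center = c(list(body = "tibia_fibula"),
                       affine_tether(tib$mesh$vertices, o_t + rho_t * c(0, 0, 1))),
    plateau_normal_ref = c(list(body = "tibia_fibula"),
                           affine_tether(tib$mesh$vertices,
                                         o_t + rho_t * c(0, 0, 1) + c(0, 0, 1.2 * par$scale))))

  list(faces = list(femur = fem$mesh$faces, tibia_fibula = tib$mesh$faces,
                    patella = pat$mesh$faces),
       n_vertices = c(femur = nrow(fem$mesh$vertices),
                      tibia_fibula = nrow(tib$mesh$vertices),
                      patella = nrow(pat$mesh$vertices)),
       face_region = list(femur = fem_regions, tibia_fibula = tib_regions,
                          patella = rep("other", nrow(pat$mesh$faces))),
       cartilage = cartilage, ligaments = ligaments, tethers = tethers,
       nominal = par, layout = layout)
}

specimen_bodies <- function() c("femur", "tibia_fibula", "patella")

#' @export
print.knee_specimen <- function(x, ...) {
  cat(sprintf("<knee_specimen: animal %s, %s limb%s, %d+%d+%d vertices>\n",
              x$animal_id, x$side_as_acquired,
              if (isTRUE(x$is_mirrored)) " (mirrored)" else "",
              nrow(x$femur$vertices), nrow(x$tibia_fibula$vertices),
              nrow(x$patella$vertices)))
  invisible(x)
}

# Deterministic per-limb RNG substream
limb_seed <- function(master, animal, limb) {
  as.integer((as.numeric(master) %% 1000003) * 2011 +
               animal * 131071 + limb * 8191) %% 2147483647L
}

draw_params <- function(nominal, animal_mult, sd_within) {
  par <- nominal
  for (nm in generator_varied_params) {
    m <- animal_mult[[nm]] * (1 + stats::rnorm(1, 0, sd_within[[nm]]))
    par[[nm]] <- nominal[[nm]] * max(m, 0.2)
  }
  par
}

apply_rigid_to_specimen <- function(s, R, translation = c(0, 0, 0),
                                    origin = c(0, 0, 0)) {
  for (b in specimen_bodies())
    s[[b]]$vertices <- transform_points(s[[b]]$vertices, R, origin, translation)
  s$landmarks <- lapply(s$landmarks, function(p)
    as.numeric(transform_points(rbind(p), R, origin, translation)))
  s
}

reflect_specimen_geometry <- function(s) {
  for (b in specimen_bodies()) s[[b]] <- mirror_mesh(s[[b]])
  s$landmarks <- lapply(s$landmarks, function(p) c(-p[1], p[2], p[3]))
  s
}

#' Mirror a knee specimen across the sagittal plane
#'
#' Converts between left- and right-side representations: reflects all
#' vertices, landmarks and ligament attachment geometry across the plane
#' x = 0 and flips the face winding so outward orientation is preserved.
#' Anatomical labels (medial/lateral) are invariant under reflection.
#' Mirroring twice restores the specimen exactly.
#'
#' @param s a `knee_specimen`.
#' @return the mirrored specimen, with `is_mirrored` and `representation`
#'   toggled.
#' @export
mirror_specimen <- function(s) {
  s <- reflect_specimen_geometry(s)
  s$representation <- if (identical(s$representation, "left")) "right" else "left"
  s$is_mirrored <- !isTRUE(s$is_mirrored)
  s
}

#' Generate a synthetic bilateral rat-knee cohort
#'
#' Draws per-animal parameters from the between-animal distributions and
#' per-limb parameters from the within-animal distributions around each
#' animal value, builds every limb on the shared template grid, applies a
#' random rigid acquisition pose, and mirrors left limbs back to right-side
#' representation.  Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list of `knee_specimen` objects (class `knee_cohort`), with the
#'   shared template attached as attribute `template`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  layout <- cohort_layout(config)
  template <- NULL
  specimens <- vector("list", config$n_animals * config$limbs_per_animal)
  k <- 0L
  for (animal in seq_len(config$n_animals)) {
    set.seed(limb_seed(config$seed, animal, 0L))
    animal_mult <- lapply(config$sd_between[generator_varied_params],
                          function(sd) 1 + stats::rnorm(1, 0, sd))
    names(animal_mult) <- generator_varied_params
    for (limb in seq_len(config$limbs_per_animal)) {
      set.seed(limb_seed(config$seed, animal, limb))
      par <- draw_params(config$nominal, animal_mult, config$sd_within)
      if (is.null(template)) {
        nom_spec <- build_specimen(config$nominal, layout)
        template <- nom_spec$template
      }
      s <- build_specimen(par, layout, template)
      s$animal_id <- animal
      side <- if (limb %% 2L == 1L) "left" else "right"
      s$side_as_acquired <- side
      if (side == "left") {
        s <- reflect_specimen_geometry(s)
        s$representation <- "left"
      }
      # acquisition pose jitter in the as-acquired frame
      if (config$pose_jitter_deg > 0 || config$pose_jitter_mm > 0) {
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        ang <- deg2rad(stats::rnorm(1, 0, config$pose_jitter_deg))
        tr <- stats::rnorm(3, 0, config$pose_jitter_mm)
        s <- apply_rigid_to_specimen(s, rotation_about_axis(ax, ang), tr)
      }
      if (side == "left") s <- mirror_specimen(s)
      k <- k + 1L
      specimens[[k]] <- s
    }
  }
  structure(specimens, class = "knee_cohort", template = template,
            config = config)
}

#' Nominal (zero-variance) specimen
#'
#' The deterministic specimen at the generator's nominal parameters, with an
#' optional uniform geometric scale factor.  Used by the nominal-geometry
#' calibration and as a convenient single test article.
#'
#' @param config a [generator_config()].
#' @param scale uniform scale multiplier applied on top of the nominal scale.
#' @return a `knee_specimen`.
#' @export
nominal_specimen <- function(config = generator_config(), scale = 1) {
  layout <- cohort_layout(config)
  par <- config$nominal
  par$scale <- par$scale * scale
  s <- build_specimen(par, layout)
  s$animal_id <- 0L
  s$side_as_acquired <- "right"
  s
}
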