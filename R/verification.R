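#' Sphere-on-plane verification specimen
#'
#' A minimal single-compartment test article for verifying the
#' elastic-foundation solver against the closed-form solution: a rigid
#' spherical indenter (outer cartilage surface of radius `radius`) over a
#' flat foundation, meshed at a prescribed element size.  For this geometry
#' the closed form is F = pi * E_eff * R * u^2 / t, the contact area
#' 2 * pi * R * u and the peak pressure E_eff * u / t, with u the
#' indentation beyond the closest approach `gap0`.
#'
#' The article is a structurally complete `knee_specimen` (one populated
#' compartment, no ligaments), so it runs through [compartment_gap_field()]
#' and [solve_indentation()] exactly like cohort specimens.
#'
#' @param radius radius of the spherical contact surface, mm.
#' @param gap0 closest distance between the outer surfaces, mm.
#' @param halfwidth half-extent of the meshed square patch, mm.
#' @param edge target element edge length, mm.
#' @param thickness cartilage layer thickness per surface, mm.
#' @return a `knee_specimen` whose medial compartment is the sphere-plane
#'   pair.
#' @export
sphere_plane_specimen <- function(radius = 2, gap0 = 0, halfwidth = 0.8,
                                  edge = 0.05, thickness = 0.25) {
  n <- grid_count(2 * halfwidth, edge)
  xs <- seq(-halfwidth, halfwidth, length.out = n)
  z_plane <- 5                      # outer foundation plane
  plane <- grid_mesh(xs, xs, function(xx, yy)
    cbind(xx, yy, z_plane + thickness))   # bone plane; outer = bone - thickness
  plane <- orient_outward(plane, function(p) cbind(0 * p[, 1], 0, -1))

  rb <- radius - thickness              # bone sphere; outer = bone + thickness
  cz <- z_plane - gap0 - radius         # sphere centre on the joint axis
  rmax <- 0.98 * rb
  cap <- grid_mesh(xs, xs, function(xx, yy) {
    r2 <- pmin(xx^2 + yy^2, rmax^2)
    cbind(xx, yy, cz + sqrt(rb^2 - r2))
  })
  cap <- orient_outward(cap, function(p) sweep(p, 2, c(0, 0, cz)))

  fem <- surface_mesh(cap$vertices, cap$faces, body = "femur")
  tib <- surface_mesh(plane$vertices, plane$faces, body = "tibia_fibula")
  pat <- surface_mesh(matrix(c(0, -4, 0, 1, -4, 0, 0, -5, 0), 3, 3, byrow = TRUE),
                      matrix(c(1L, 2L, 3L), 1), body = "patella")
  cart <- list(
    femur_medial = list(host_body = "femur", side = "medial",
                        faces = seq_len(nrow(fem$faces)), thickness = thickness),
    femur_lateral = list(host_body = "femur", side = "lateral",
                         faces = integer(0), thickness = thickness),
    tibia_medial = list(host_body = "tibia_fibula", side = "medial",
                        faces = seq_len(nrow(tib$faces)), thickness = thickness),
    tibia_lateral = list(host_body = "tibia_fibula", side = "lateral",
                         faces = integer(0), thickness = thickness))
  ligaments <- data.frame(name = character(0), origin_body = character(0),
                          insertion_body = character(0),
                          origin_vertex = integer(0),
                          insertion_vertex = integer(0),
                          pretension_default = numeric(0),
                          reference_length = numeric(0))
  structure(list(animal_id = 0L, side_as_acquired = "right",
                 is_mirrored = FALSE, representation = "right",
                 femur = fem, tibia_fibula = tib, patella = pat,
                 landmarks = list(medial_epicondyle = c(-1, 0, 0),
                                  lateral_epicondyle = c(1, 0, 0),
                                  plateau_center = c(0, 0, z_plane),
                                  plateau_normal_ref = c(0, 0, z_plane + 1)),
                 landmark_body = c(medial_epicondyle = "femur",
                                   lateral_epicondyle = "femur",
                                   plateau_center = "tibia_fibula",
                                   plateau_normal_ref = "tibia_fibula"),
                 cartilage = cart, ligaments = ligaments,
                 template = NULL, params = NULL),
            class = "knee_specimen")
}
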