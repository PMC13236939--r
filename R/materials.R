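#' Constitutive constants for the rat knee contact model
#'
#' Bundles the material laws used throughout the contact stage: linear
#' elastic articular cartilage (E = 6 MPa, nu = 0.49, two 0.25 mm layers),
#' the rat-specific bone density-modulus power law
#' E = 8362.8 rho^2.56 (MPa, rho in g/cm^3), tension-only ligament springs
#' (ACL/PCL 35 N/mm with 5 % pretension, MCL/LCL 20 N/mm with 4 %), and a
#' frictionless articular interface.
#'
#' Bone is treated as rigid by the elastic-foundation contact solver (its
#' modulus is three orders of magnitude above cartilage), but the
#' density-modulus law is carried in full through the appearance block of
#' the shape model and is available for export.
#'
#' @param cartilage_E cartilage Young's modulus, MPa.
#' @param cartilage_nu cartilage Poisson ratio, in (0, 0.5).
#' @param cartilage_thickness thickness of one cartilage layer, mm.
#' @param bone_law list with `a` (MPa) and `exponent` for the power law.
#' @param density_scale multiplicative conversion applied to incoming
#'   densities before the power law (the calibration's native unit is
#'   assumed g/cm^3; set this if your densities are in other units).
#' @param ligament_table named list, one `c(stiffness, pretension)` pair per
#'   ligament (N/mm, dimensionless fraction; zero stiffness disables a
#'   ligament, used diagnostically).
#' @param friction articular friction coefficient (0 = frictionless).
#' @return An object of class `material_set`.
#' @export
material_set <- function(cartilage_E = 6,
                         cartilage_nu = 0.49,
                         cartilage_thickness = 0.25,
                         bone_law = list(a = 8362.8, exponent = 2.56),
                         density_scale = 1,
                         ligament_table = list(
                           ACL = c(stiffness = 35, pretension = 0.05),
                           PCL = c(stiffness = 35, pretension = 0.05),
                           MCL = c(stiffness = 20, pretension = 0.04),
                           LCL = c(stiffness = 20, pretension = 0.04)),
                         friction = 0) {
  if (!(cartilage_nu > 0 && cartilage_nu < 0.5))
    stop("cartilage_nu must lie in (0, 0.5)")
  if (cartilage_E <= 0 || cartilage_thickness <= 0)
    stop("cartilage_E and cartilage_thickness must be positive")
  for (nm in names(ligament_table)) {
    lt <- ligament_table[[nm]]
    if (lt[["stiffness"]] < 0) stop("ligament stiffness must be >= 0: ", nm)
    p <- lt[["pretension"]]
    if (p < 0 || p > 0.2) stop("ligament pretension must lie in [0, 0.2]: ", nm)
  }
  structure(list(cartilage_E = cartilage_E, cartilage_nu = cartilage_nu,
                 cartilage_thickness = cartilage_thickness,
                 bone_law = bone_law, density_scale = density_scale,
                 ligament_table = ligament_table, friction = friction),
            class = "material_set")
}

#' Bone compressive modulus from equivalent mineral density
#'
#' Power-law density-modulus relationship for rat bone,
#' E = a * rho^exponent with a = 8362.8 MPa and exponent = 2.56 by default,
#' rho the micro-CT equivalent mineral density in g/cm^3 and E in MPa.
#' Strictly monotone increasing and zero at zero density.
#'
#' @param rho equivalent mineral density, g/cm^3 (vectorised, must be >= 0).
#' @param law list with elements `a` and `exponent`.
#' @return modulus in MPa.
#' @examples
#' density_to_modulus(1)    # 8362.8
#' density_to_modulus(0.5)  # about 1417.9
#' @export
density_to_modulus <- function(rho, law = list(a = 8362.8, exponent = 2.56)) {
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("rho must be finite and >= 0")
  law$a * rho^law$exponent
}

#' Confined (elastic-foundation) modulus of a thin elastic layer
#'
#' The bed-of-springs contact model uses the confined compression modulus
#' E (1 - nu) / ((1 + nu) (1 - 2 nu)) of the cartilage layer.  The constant
#' diverges as nu -> 0.5; values of nu >= 0.499 are rejected.
#'
#' @param E Young's modulus, MPa.
#' @param nu Poisson ratio in [0, 0.499).
#' @return foundation modulus in MPa.
#' @examples
#' foundation_modulus(6, 0.49)  # about 102.68
#' @export
foundation_modulus <- function(E, nu) {
  if (any(nu < 0) || any(nu >= 0.499))
    stop("nu must lie in [0, 0.499)")
  if (any(E <= 0)) stop("E must be positive")
  E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
}

#' Tension-only ligament spring force
#'
#' Each ligament is a linear tension-only spring.  Pretension is interpreted
#' as reference-pose engineering strain through a shortened slack length
#' L0 = (1 - pretension) * reference_length, so at the reference pose the
#' ligament carries stiffness * reference_length * pretension and it carries
#' no force whenever the current length is below L0.
#'
#' @param current_length,reference_length lengths in mm (positive).
#' @param stiffness spring stiffness, N/mm.
#' @param pretension pretension strain fraction in [0, 0.2].
#' @return tension in N (never negative).
#' @examples
#' ligament_force(10, 10, 35, 0.05)  # 17.5 N
#' ligament_force(9, 10, 35, 0.05)   # 0 N (slack)
#' @export
ligament_force <- function(current_length, reference_length, stiffness,
                           pretension) {
  if (any(current_length <= 0) || any(reference_length <= 0))
    stop("ligament lengths must be positive")
  L0 <- reference_length * (1 - pretension)
  stiffness * pmax(0, current_length - L0)
}
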