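Package: varusknee
Title: Statistical Shape-Appearance Modelling and Elastic-Foundation
    Contact Mechanics of the Rat Tibiofemoral Joint
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale comparative biomechanics of the rat knee
    under progressive varus loading.  Generates a statistically structured
    synthetic bilateral rat-knee cohort (shared-topology surface meshes of
    femur, tibia-fibula and patella with per-vertex equivalent mineral
    density, anatomical landmarks, ligament attachments and articular
    cartilage patches), builds a PCA-based statistical shape and appearance
    model with generalized Procrustes alignment and limb-level leave-one-out
    validation, and solves tibiofemoral contact with an elastic-foundation
    (bed-of-springs) model of the thin cartilage layers under prescribed
    varus load redistribution or prescribed varus angulation.  Includes
    tension-only ligament springs, a density-modulus power law for rat bone,
    a pressure-sensitive-film measurement emulator, knee-level statistics
    (Shapiro-Wilk, one-way ANOVA, Tukey HSD) and an end-to-end seeded study
    pipeline with summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
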