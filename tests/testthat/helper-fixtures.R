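# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

zero_sds <- function() {
  nms <- c("scale", "condyle_offset", "conformity_radius", "plateau_drop",
           "density_cortical", "density_trabecular")
  stats::setNames(as.list(rep(0, length(nms))), nms)
}

zero_variance_config <- function(seed = 1, ...) {
  generator_config(seed = seed, sd_between = zero_sds(), sd_within = zero_sds(),
                   pose_jitter_deg = 0, pose_jitter_mm = 0, ...)
}

# coarser articular meshes for fast unit tests (acceptance uses defaults)
coarse_nominal <- function(extra = list()) {
  utils::modifyList(list(femur_articular_edge = 0.2,
                         tibia_articular_edge = 0.3), extra)
}

default_cohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generate_cohort(generator_config(seed = 101))
  .fixtures$cohort
}

default_loo <- function() {
  if (is.null(.fixtures$loo))
    .fixtures$loo <- loo_validate(default_cohort())
  .fixtures$loo
}

default_study <- function() {
  if (is.null(.fixtures$study))
    .fixtures$study <- suppressMessages(
      run_study(run_config(seed = 101),
                out_dir = file.path(tempdir(), "varusknee_accept_study")))
  .fixtures$study
}

identity_film <- function() {
  film_model(detection_floor = 0, saturation_ceiling = Inf,
             multiplicative_noise_sd = 0, quantization_step = 0, n_trials = 3)
}
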