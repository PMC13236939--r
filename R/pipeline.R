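#' Full study configuration
#'
#' Aggregates every stage configuration: cohort generator, shape-model
#' settings, materials, the load-case grids of both modes, the film model,
#' and the master seed.  The optional `calibration` block holds target
#' specimen-scale outputs for [calibrate_nominal_geometry()].
#'
#' @param generator a [generator_config()].
#' @param materials a [material_set()].
#' @param film a [film_model()].
#' @param ssam list of shape-model settings: `w_s`, `w_a` (NULL = equal
#'   block variance), `n_components` (NULL = all nonzero), `clip`,
#'   `limit_sd`, `n_per_component`.
#' @param total_force,flexion,pinball shared loading constants.
#' @param varus_levels fraction-mode levels (percent).
#' @param varus_angles angle-mode angles (degrees), mapped 0/3/6 to the
#'   0/50/100 % levels.
#' @param seed master seed (propagated to the generator and film stages).
#' @param calibration optional list, e.g.
#'   `list(medial_area_100 = 8.3, mode = "angle")`.
#' @return object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       materials = material_set(),
                       film = film_model(),
                       ssam = list(w_s = 1, w_a = NULL, n_components = NULL,
                                   clip = TRUE, limit_sd = 3,
                                   n_per_component = 20),
                       total_force = 2.94, flexion = 80, pinball = 0.1,
                       varus_levels = c(0, 50, 100),
                       varus_angles = c(0, 3, 6),
                       seed = 1, calibration = NULL) {
  generator$seed <- as.integer(seed)
  structure(list(generator = generator, materials = materials, film = film,
                 ssam = ssam, total_force = total_force, flexion = flexion,
                 pinball = pinball, varus_levels = varus_levels,
                 varus_angles = varus_angles, seed = as.integer(seed),
                 calibration = calibration),
            class = "run_config")
}

angle_to_level <- function(angle) c(`0` = 0, `3` = 50, `6` = 100)[as.character(angle)]

# fraction-mode solves for several levels, reusing the posed gap fields
solve_fraction_series <- function(s, materials, levels, total_force = 2.94,
                                  flexion = 80, pinball = 0.1) {
  jcs <- build_jcs(s)
  posed <- pose_flexion(s, jcs, flexion)
  E_eff <- foundation_modulus(materials$cartilage_E, materials$cartilage_nu)
  gaps <- lapply(c(medial = "medial", lateral = "lateral"), function(side)
    compartment_gap_field(posed, jcs, side, pinball))
  lig <- ligament_state(posed, materials, jcs)
  lapply(levels, function(lv) {
    forces <- redistribute_load(total_force, lv)
    med <- solve_indentation(gaps$medial, E_eff,
                             attr(gaps$medial, "thickness_total"),
                             forces[["medial"]])
    lat <- solve_indentation(gaps$lateral, E_eff,
                             attr(gaps$lateral, "thickness_total"),
                             forces[["lateral"]])
    contact_outcome(med, lat, lig, total_force, "fraction",
                    load_case(total_force, flexion, "fraction", lv,
                              pinball = pinball))
  })
}

outcome_records <- function(outcome, knee_id, model_type, level) {
  rbind(study_record(knee_id, model_type, level, "medial",
                     outcome$medial$peak_pressure, outcome$medial$contact_area),
        study_record(knee_id, model_type, level, "lateral",
                     outcome$lateral$peak_pressure, outcome$lateral$contact_area))
}

#' Run the complete seeded study
#'
#' Generates the cohort, performs the limb-level leave-one-out shape-model
#' validation, solves the fraction-mode load cases for both the
#' specimen-specific and the shape-model-predicted geometry of every limb,
#' emulates the repeated-trial film experiment on the specimen-specific
#' pressure fields of the same load cases, runs the knee-level statistics and writes
#' all tables, records and a manifest to the output directory.  Re-running
#' with the same configuration is bit-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; default a fresh tempdir
#'   subdirectory).
#' @return invisibly, a list with `records`, `loo`, `tables`, `stats`,
#'   `cohort` and `paths`.
#' @export
run_study <- function(config, out_dir = file.path(tempdir(), "varusknee_study")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    message(sprintf("[varusknee] %-12s %s", stage, sprintf(...)))
  }
  stage <- "generate"
  res <- tryCatch({
    log_stage(stage, "cohort of %d x %d limbs (seed %d)",
              config$generator$n_animals, config$generator$limbs_per_animal,
              config$seed)
    cohort <- generate_cohort(config$generator)

    stage <- "ssam-loo"
    log_stage(stage, "leave-one-out over %d limbs", length(cohort))
    loo <- loo_validate(cohort, w_s = config$ssam$w_s, w_a = config$ssam$w_a,
                        n_components = config$ssam$n_components,
                        clip = config$ssam$clip %||% TRUE)
    utils::write.csv(loo$errors, file.path(out_dir, "loo_errors.csv"),
                     row.names = FALSE)

    stage <- "solve"
    recs <- list()
    for (i in seq_along(cohort)) {
      sam <- solve_fraction_series(cohort[[i]], config$materials,
                                   config$varus_levels, config$total_force,
                                   config$flexion, config$pinball)
      ssm <- solve_fraction_series(loo$predicted[[i]], config$materials,
                                   config$varus_levels, config$total_force,
                                   config$flexion, config$pinball)
      for (j in seq_along(config$varus_levels)) {
        lv <- config$varus_levels[j]
        recs[[length(recs) + 1L]] <- outcome_records(sam[[j]], i, "sample_fea", lv)
        recs[[length(recs) + 1L]] <- outcome_records(ssm[[j]], i, "ssam_fea", lv)
      }
      stage <- "film"
      for (j in seq_along(config$varus_levels)) {
        lv <- config$varus_levels[j]
        for (comp in c("medial", "lateral")) {
          m <- emulate_pressure_film(sam[[j]][[comp]], config$film,
                                     seed = limb_seed(config$seed + 577,
                                                      i, lv + match(comp, c("medial", "lateral"))))
          recs[[length(recs) + 1L]] <-
            study_record(i, "experiment_sim", lv, comp,
                         m[["peak_pressure"]], m[["contact_area"]])
        }
      }
      stage <- "solve"
    }
    records <- do.call(rbind, recs)
    records <- records[order(records$knee_id,
                             match(records$model_type, record_levels$model_type),
                             records$varus_level, records$compartment), ]
    rownames(records) <- NULL
    utils::write.csv(records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)

    stage <- "stats"
    log_stage(stage, "summaries over %d records", nrow(records))
    tables <- make_summary_tables(records)
    stats_sum <- compare_study_groups(records)
    utils::write.csv(tables$pressure_table,
                     file.path(out_dir, "peak_pressure_table.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$area_table,
                     file.path(out_dir, "contact_area_table.csv"),
                     row.names = FALSE)
    utils::write.csv(tables$delta_table, file.path(out_dir, "delta_table.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_sum$anova, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_sum$shapiro, file.path(out_dir, "shapiro.csv"),
                     row.names = FALSE)

    manifest <- list(package = "varusknee",
                     version = as.character(utils::packageVersion("varusknee")),
                     seed = config$seed,
                     n_limbs = length(cohort),
                     n_records = nrow(records),
                     skipped_comparisons = stats_sum$skipped,
                     config = config_to_list(config))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(records = records, loo = loo, tables = tables, stats = stats_sum,
         cohort = cohort, paths = list(dir = out_dir))
  }, error = function(e) {
    stop(sprintf("study failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}

#' Calibrate the nominal geometry scale to a target contact area
#'
#' One-dimensional root-finding on a uniform scale factor of the nominal
#' articular geometry so that the zero-variance nominal specimen's solve
#' reproduces a target medial contact area at the 100 % varus condition
#' within 1 %.  The target condition is evaluated in angle mode at 6
#' degrees by default (the condition under which the specimen-scale
#' compartment areas are both nonzero) or in fraction mode at 100 %.
#'
#' @param config a [run_config()] (or [generator_config()]).
#' @param targets list with `medial_area_100` (mm^2) and optionally
#'   `mode` (`"angle"` or `"fraction"`).
#' @param bracket scale search interval (default [0.25, 4]).
#' @return the input config with the generator's nominal scale updated;
#'   attributes `scale` and `achieved_area` record the calibration.
#' @export
calibrate_nominal_geometry <- function(config, targets, bracket = c(0.25, 4)) {
  gen <- if (inherits(config, "run_config")) config$generator else config
  stopifnot(inherits(gen, "generator_config"))
  target <- targets$medial_area_100
  if (is.null(target) || target <= 0) stop("targets$medial_area_100 must be positive")
  mode <- targets$mode %||% "angle"
  mat <- if (inherits(config, "run_config")) config$materials else material_set()
  tf <- if (inherits(config, "run_config")) config$total_force else 2.94
  fx <- if (inherits(config, "run_config")) config$flexion else 80
  medial_area <- function(scale) {
    s <- nominal_specimen(gen, scale = scale)
    out <- if (mode == "angle")
      solve_load_case_angle(s, mat, load_case(tf, fx, "angle", varus_angle = 6))
    else
      solve_load_case_fraction(s, mat, load_case(tf, fx, "fraction", 100))
    out$medial$contact_area
  }
  g <- function(s) medial_area(s) - target
  g1 <- g(1)
  if (abs(g1) <= 0.005 * target) {
    scale <- 1; achieved <- g1 + target   # nominal already matches
  } else {
    # the angle-mode response need not be monotone over the full bracket;
    # scan for sign changes and root-find in the interval nearest unity
    grid <- sort(unique(c(bracket[1], 0.35, 0.5, 0.7, 0.85, 1, 1.2, 1.5,
                          2, 2.8, bracket[2])))
    grid <- grid[grid >= bracket[1] & grid <= bracket[2]]
    gv <- vapply(grid, function(s) if (s == 1) g1 else g(s), numeric(1))
    ch <- which(gv[-1] * gv[-length(gv)] <= 0)
    if (!length(ch))
      stop("calibration target unreachable within scale bracket [",
           bracket[1], ", ", bracket[2], "]")
    mid <- (grid[ch] + grid[ch + 1L]) / 2
    k <- ch[which.min(abs(log(mid)))]
    root <- stats::uniroot(g, interval = c(grid[k], grid[k + 1L]), tol = 1e-4,
                           f.lower = gv[k], f.upper = gv[k + 1L])
    scale <- root$root
    achieved <- medial_area(scale)
    if (abs(achieved - target) / target > 0.01)
      stop("calibration did not reach the target within 1%")
  }
  gen$nominal$scale <- gen$nominal$scale * scale
  if (inherits(config, "run_config")) config$generator <- gen else config <- gen
  attr(config, "scale") <- scale
  attr(config, "achieved_area") <- achieved
  config
}

# Config serialization -------------------------------------------------------

config_to_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    } else if (is.atomic(x) && !is.null(names(x))) {
      x <- as.list(x)   # keep element names through YAML/JSON maps
    }
    x
  }
  strip(unclass(config))
}

#' Write / read a run configuration as YAML or JSON
#'
#' Lossless round trip of the full study configuration; the format follows
#' the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lst <- config_to_list(config)
  if (grepl("\\.json$", path))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  else
    yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  denull <- function(x) if (length(x) == 0) NULL else x
  nominal <- lapply(lst$generator$nominal, function(x) unname(unlist(x)))
  gen <- do.call(generator_config, c(
    lst$generator[c("n_animals", "limbs_per_animal", "seed",
                    "pose_jitter_deg", "pose_jitter_mm",
                    "edge_bone", "edge_patella")],
    list(nominal = nominal,
         sd_between = lapply(lst$generator$sd_between, unlist),
         sd_within = lapply(lst$generator$sd_within, unlist))))
  mat_args <- lst$materials
  mat_args$bone_law <- lapply(mat_args$bone_law, unlist)
  mat_args$ligament_table <- lapply(mat_args$ligament_table, function(l)
    c(stiffness = l[["stiffness"]], pretension = l[["pretension"]]))
  mat <- do.call(material_set, mat_args)
  film <- do.call(film_model, lapply(lst$film, unlist))
  ssam <- lapply(lst$ssam, denull)
  run_config(generator = gen, materials = mat, film = film,
             ssam = ssam,
             total_force = lst$total_force, flexion = lst$flexion,
             pinball = lst$pinball, varus_levels = unlist(lst$varus_levels),
             varus_angles = unlist(lst$varus_angles), seed = lst$seed,
             calibration = denull(lst$calibration))
}
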