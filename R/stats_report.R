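#' Shapiro-Wilk normality test
#'
#' Thin wrapper with the study's preconditions made explicit: sample sizes
#' between 3 and 5000, and a hard error (rather than a spurious p-value)
#' for degenerate constant samples.
#'
#' @param values numeric sample.
#' @return list with `W` and `p`.
#' @export
test_normality <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0)
    stop("normality test undefined for a constant sample")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = unname(sw$p.value))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within sum-of-squares
#' decomposition, p from the F distribution), computed with [stats::aov()].
#'
#' @param groups list of numeric samples, one per group (>= 2 groups, each
#'   with >= 2 values).
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least two values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::sd(y) == 0)
    stop("F undefined: zero within-group and between-group variance")
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1],
       df_between = tab[["Df"]][1],
       df_within = tab[["Df"]][2],
       p = tab[["Pr(>F)"]][1])
}

#' Tukey honest significant difference test
#'
#' Studentized-range adjusted pairwise comparisons after a one-way ANOVA,
#' computed with [stats::TukeyHSD()].  With two groups it reduces to the
#' pooled two-sample t-test.
#'
#' @param groups list of numeric samples (named or not).
#' @return data frame with columns `pair`, `difference`, `p_adjusted`.
#' @export
tukey_hsd <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least two values")
  nms <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nms
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nms, vapply(groups, length, integer(1))), levels = nms)
  if (stats::sd(y) == 0)
    stop("Tukey HSD undefined: zero within-group and between-group variance")
  th <- stats::TukeyHSD(stats::aov(y ~ g))$g
  data.frame(pair = rownames(th), difference = th[, "diff"],
             p_adjusted = th[, "p adj"], row.names = NULL)
}

#' Knee-level study records
#'
#' Assemble a study record table from its components; one record per
#' (knee, model type, varus level, compartment).
#'
#' @param knee_id,model_type,varus_level,compartment,peak_pressure,contact_area
#'   record fields; `model_type` in `sample_fea`, `ssam_fea`,
#'   `experiment_sim`, `varus_level` in 0/50/100, `compartment` in
#'   medial/lateral.
#' @return a `data.frame` of study records.
#' @export
study_record <- function(knee_id, model_type, varus_level, compartment,
                         peak_pressure, contact_area) {
  model_type <- match.arg(model_type,
                          c("sample_fea", "ssam_fea", "experiment_sim"))
  compartment <- match.arg(compartment, c("medial", "lateral"))
  if (!varus_level %in% c(0, 50, 100)) stop("varus_level must be 0/50/100")
  if (!is.finite(peak_pressure) || !is.finite(contact_area) ||
      peak_pressure < 0 || contact_area < 0)
    stop("outcome values must be finite and >= 0")
  data.frame(knee_id = knee_id, model_type = model_type,
             varus_level = varus_level, compartment = compartment,
             peak_pressure = peak_pressure, contact_area = contact_area,
             stringsAsFactors = FALSE)
}

record_levels <- list(model_type = c("sample_fea", "ssam_fea", "experiment_sim"),
                      varus_level = c(0, 50, 100),
                      compartment = c("medial", "lateral"))

#' Summary tables and varus-induced deltas
#'
#' Group means per (model type, varus level, compartment), rounded to two
#' decimals for presentation, for both outcomes; plus the delta table of
#' differences relative to the neutral (0 %) level computed on the rounded
#' means, and the maximum-over-model-type aggregates.  Two aggregate
#' variants are exposed for each outcome: over the FEA model types only
#' (specimen-specific and shape-model-predicted) and over all model types
#' including the emulated experiment — the two conventions give different
#' answers for some outcomes, so both are reported rather than resolved.
#'
#' @param records study record data frame (complete factorial over the
#'   model types, levels and compartments present; missing cells are an
#'   error listing the absent combinations).
#' @return list with `pressure_table`, `area_table`, `delta_table` and
#'   `aggregates`.
#' @export
make_summary_tables <- function(records) {
  req <- c("knee_id", "model_type", "varus_level", "compartment",
           "peak_pressure", "contact_area")
  if (!all(req %in% names(records))) stop("records are missing columns")
  types <- intersect(record_levels$model_type, unique(records$model_type))
  full <- expand.grid(model_type = types,
                      varus_level = record_levels$varus_level,
                      compartment = record_levels$compartment,
                      stringsAsFactors = FALSE)
  have <- unique(records[, c("model_type", "varus_level", "compartment")])
  key <- function(d) paste(d$model_type, d$varus_level, d$compartment)
  missing <- full[!key(full) %in% key(have), ]
  if (nrow(missing))
    stop("incomplete records; absent combinations: ",
         paste(key(missing), collapse = "; "))

  mean_table <- function(col) {
    agg <- stats::aggregate(records[[col]],
                            by = records[c("model_type", "varus_level",
                                           "compartment")], FUN = mean)
    names(agg)[4] <- "mean"
    agg$mean_rounded <- round(agg$mean, 2)
    agg <- agg[order(agg$varus_level, match(agg$model_type, types),
                     agg$compartment), ]
    rownames(agg) <- NULL
    agg
  }
  pt <- mean_table("peak_pressure")
  at <- mean_table("contact_area")

  delta_of <- function(tab, outcome) {
    base <- tab[tab$varus_level == 0, ]
    rows <- tab[tab$varus_level != 0, ]
    base_key <- paste(base$model_type, base$compartment)
    b <- base$mean_rounded[match(paste(rows$model_type, rows$compartment),
                                 base_key)]
    data.frame(outcome = outcome, model_type = rows$model_type,
               compartment = rows$compartment, varus_level = rows$varus_level,
               delta = rows$mean_rounded - b, stringsAsFactors = FALSE)
  }
  delta <- rbind(delta_of(pt, "peak_pressure"), delta_of(at, "contact_area"))
  rownames(delta) <- NULL

  fea <- c("sample_fea", "ssam_fea")
  agg_max <- function(outcome, comp, sign, subset_types) {
    d <- delta[delta$outcome == outcome & delta$compartment == comp &
                 delta$model_type %in% subset_types, "delta"]
    if (!length(d)) return(NA_real_)
    max(sign * d)
  }
  aggregates <- list(
    max_medial_pressure_increase_fea = agg_max("peak_pressure", "medial", 1, fea),
    max_lateral_pressure_decrease_fea = agg_max("peak_pressure", "lateral", -1, fea),
    max_medial_pressure_increase_all = agg_max("peak_pressure", "medial", 1, types),
    max_lateral_pressure_decrease_all = agg_max("peak_pressure", "lateral", -1, types),
    max_medial_area_increase_fea = agg_max("contact_area", "medial", 1, fea),
    max_lateral_area_decrease_fea = agg_max("contact_area", "lateral", -1, fea),
    max_medial_area_increase_all = agg_max("contact_area", "medial", 1, types),
    max_lateral_area_decrease_all = agg_max("contact_area", "lateral", -1, types))

  list(pressure_table = pt, area_table = at, delta_table = delta,
       aggregates = aggregates)
}

#' Knee-level statistical comparison of the study records
#'
#' For each outcome and compartment, runs (a) one-way ANOVAs across varus
#' levels within each model type and (b) one-way ANOVAs across model types
#' within each level (with Tukey HSD when more than two groups), plus
#' Shapiro-Wilk normality per group.  Degenerate cells (zero total
#' variance, e.g. the exactly unloaded lateral compartment at 100 % varus
#' under prescribed redistribution) are skipped and listed.
#'
#' @param records study record data frame.
#' @param model_types subset of model types to compare (default all
#'   present).
#' @return list with `anova` (data frame), `shapiro` (data frame) and
#'   `skipped` (character).
#' @export
compare_study_groups <- function(records, model_types = NULL) {
  if (is.null(model_types)) model_types <- unique(records$model_type)
  records <- records[records$model_type %in% model_types, ]
  outcomes <- c("peak_pressure", "contact_area")
  anova_rows <- list(); shapiro_rows <- list(); skipped <- character(0)
  add_anova <- function(groups, label) {
    ok <- tryCatch({
      a <- anova_oneway(groups)
      anova_rows[[length(anova_rows) + 1L]] <<-
        data.frame(comparison = label, F = a$F, df_between = a$df_between,
                   df_within = a$df_within, p = a$p, stringsAsFactors = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) skipped <<- c(skipped, label)
  }
  for (outc in outcomes) for (comp in c("medial", "lateral")) {
    sub <- records[records$compartment == comp, ]
    for (mt in unique(sub$model_type)) {
      gg <- split(sub[[outc]][sub$model_type == mt],
                  sub$varus_level[sub$model_type == mt])
      add_anova(gg, sprintf("%s|%s|levels within %s", outc, comp, mt))
    }
    for (lv in unique(sub$varus_level)) {
      gg <- split(sub[[outc]][sub$varus_level == lv],
                  sub$model_type[sub$varus_level == lv])
      add_anova(gg, sprintf("%s|%s|model types at %d%%", outc, comp, lv))
      for (mt in names(gg)) {
        p <- tryCatch(test_normality(gg[[mt]])$p, error = function(e) NA_real_)
        shapiro_rows[[length(shapiro_rows) + 1L]] <-
          data.frame(outcome = outc, compartment = comp, varus_level = lv,
                     model_type = mt, shapiro_p = p, stringsAsFactors = FALSE)
      }
    }
  }
  list(anova = do.call(rbind, anova_rows),
       shapiro = do.call(rbind, shapiro_rows),
       skipped = skipped)
}
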