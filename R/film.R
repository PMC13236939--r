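#' Pressure-sensitive film measurement model
#'
#' Emulates the physical validation measurement: a pressure-sensitive film
#' inserted between the articular surfaces registers pressures between a
#' detection floor and a saturation ceiling, with multiplicative
#' (lognormal) response noise and a finite densitometric quantization step;
#' each loading condition is measured in repeated trials and the trial
#' means are reported.  The default floor/ceiling bracket the pressure
#' range of the standard load cases; three trials per condition follow the
#' experimental averaging protocol.
#'
#' @param detection_floor minimum registrable pressure, MPa.
#' @param saturation_ceiling saturation pressure, MPa (> floor).
#' @param multiplicative_noise_sd SD of the lognormal response noise
#'   (fraction; 0 disables noise).
#' @param quantization_step densitometric quantization, MPa (0 disables).
#' @param n_trials repeated trials per condition (>= 1, default 3).
#' @param seed RNG seed.
#' @return object of class `film_model`.
#' @export
film_model <- function(detection_floor = 0.05, saturation_ceiling = 2.5,
                       multiplicative_noise_sd = 0.05,
                       quantization_step = 0.01, n_trials = 3, seed = 1) {
  if (!(detection_floor >= 0 && detection_floor < saturation_ceiling))
    stop("need 0 <= detection_floor < saturation_ceiling")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (multiplicative_noise_sd < 0 || quantization_step < 0)
    stop("noise SD and quantization step must be >= 0")
  structure(list(detection_floor = detection_floor,
                 saturation_ceiling = saturation_ceiling,
                 multiplicative_noise_sd = multiplicative_noise_sd,
                 quantization_step = quantization_step,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "film_model")
}

#' Emulated film measurement of a contact pressure field
#'
#' Per trial, each element pressure is multiplied by mean-one lognormal
#' noise, clipped to [0, ceiling], zeroed below the detection floor and
#' quantized; the trial peak is the maximum registered pressure and the
#' trial area the summed element area above the floor.  The mean over
#' `n_trials` trials is returned.  An empty field measures zero peak and
#' zero area.
#'
#' @param field either a `compartment_result` (its pressure field is used)
#'   or a numeric vector of element pressures (MPa, >= 0).
#' @param film a [film_model()].
#' @param areas element areas in mm^2 (required when `field` is a vector).
#' @param seed RNG seed (defaults to the film's).
#' @return named vector `c(peak_pressure =, contact_area =)`.
#' @export
emulate_pressure_film <- function(field, film = film_model(), areas = NULL,
                                  seed = film$seed) {
  if (inherits(field, "compartment_result")) {
    areas <- field$pressure_field$area
    field <- field$pressure_field$pressure
  }
  field <- as.numeric(field)
  if (any(field < 0)) stop("pressures must be >= 0")
  if (length(field) == 0)
    return(c(peak_pressure = 0, contact_area = 0))
  if (is.null(areas) || length(areas) != length(field))
    stop("areas must match the pressure field")
  set.seed(seed)
  sdl <- film$multiplicative_noise_sd
  peaks <- areas_out <- numeric(film$n_trials)
  for (t in seq_len(film$n_trials)) {
    p <- field
    if (sdl > 0)
      p <- p * stats::rlnorm(length(p), meanlog = -sdl^2 / 2, sdlog = sdl)
    p <- pmin(p, film$saturation_ceiling)
    p[p < film$detection_floor] <- 0
    if (film$quantization_step > 0)
      p <- round(p / film$quantization_step) * film$quantization_step
    peaks[t] <- if (any(p > 0)) max(p) else 0
    areas_out[t] <- sum(areas[p > 0])
  }
  c(peak_pressure = mean(peaks), contact_area = mean(areas_out))
}
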