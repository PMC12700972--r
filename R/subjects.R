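# Subject profiles: anthropometry, breathing pattern and mucus parameters.

#' Construct a subject profile
#'
#' Bundles the anthropometric, ventilatory and mucociliary parameters that
#' drive all stages of the simulation. The breathing cycle must close:
#' `t_inhale + t_exhale = 60 / f_B` (no pause is modelled).
#'
#' @param height_cm standing height, cm.
#' @param frc_cm3 functional residual capacity, cm^3.
#' @param vt_cm3 tidal volume, cm^3.
#' @param f_b breathing frequency, 1/min.
#' @param t_inhale,t_exhale durations of inhalation and exhalation, s.
#' @param asthma logical; apply probabilistic airway contraction and the
#'   asthma mucus parameters.
#' @param mucus_velocity_trachea tracheal mucus velocity, mm/min.
#' @param mucus_gel_multiplier multiplier on the gel (mucus) layer
#'   thickness (3 for severe asthma).
#' @param id short label used in outputs.
#' @return An object of class `subject_profile` (a named list).
#' @export
#' @examples
#' subject_profile(176, 3300, 500, 12, 2.5, 2.5)
subject_profile <- function(height_cm, frc_cm3, vt_cm3, f_b,
                            t_inhale, t_exhale, asthma = FALSE,
                            mucus_velocity_trachea = 11.8,
                            mucus_gel_multiplier = 1,
                            id = "custom") {
  vals <- c(height_cm, frc_cm3, vt_cm3, f_b, t_inhale, t_exhale,
            mucus_velocity_trachea, mucus_gel_multiplier)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all subject parameters must be positive and finite")
  if (vt_cm3 >= frc_cm3)
    stop("tidal volume must be smaller than FRC")
  if (abs(t_inhale + t_exhale - 60 / f_b) > 1e-6)
    stop("t_inhale + t_exhale must equal 60 / f_B")
  structure(list(
    id = id, height_cm = height_cm, frc_cm3 = frc_cm3, vt_cm3 = vt_cm3,
    f_b = f_b, t_inhale = t_inhale, t_exhale = t_exhale,
    asthma = isTRUE(asthma),
    mucus_velocity_trachea = mucus_velocity_trachea,
    mucus_gel_multiplier = mucus_gel_multiplier
  ), class = "subject_profile")
}

#' Built-in subject presets
#'
#' Three reference subjects: a healthy adult Caucasian man (height 176 cm),
#' a 5-year-old child (height 110 cm) and an adult man with severe asthma.
#' The asthmatic breathes asymmetrically (1 s in, 1.4 s out) with elevated
#' FRC and frequency, slower tracheal mucus (6.3 mm/min) and a three-fold
#' thicker gel layer; the child's mucus moves at 2.7 mm/min.
#'
#' @param preset one of `"healthy_adult"`, `"child_5y"`, `"severe_asthma"`.
#' @return A [subject_profile()].
#' @export
#' @examples
#' subject_preset("healthy_adult")$vt_cm3  # 500
subject_preset <- function(preset = c("healthy_adult", "child_5y",
                                      "severe_asthma")) {
  preset <- match.arg(preset)
  switch(preset,
    healthy_adult = subject_profile(176, 3300, 500, 12, 2.5, 2.5,
                                    asthma = FALSE,
                                    mucus_velocity_trachea = 11.8,
                                    id = "healthy_adult"),
    child_5y = subject_profile(110, 767, 213, 25, 1.2, 1.2,
                               asthma = FALSE,
                               mucus_velocity_trachea = 2.7,
                               id = "child_5y"),
    severe_asthma = subject_profile(176, 4000, 500, 25, 1.0, 1.4,
                                    asthma = TRUE,
                                    mucus_velocity_trachea = 6.3,
                                    mucus_gel_multiplier = 3,
                                    id = "severe_asthma")
  )
}

#' Height-derived linear scale factor
#'
#' Paediatric (or other) airway dimensions are obtained from the reference
#' adult morphometry by a single linear factor, the ratio of the subject's
#' height to the 176 cm reference height.
#'
#' @param subject a [subject_profile()].
#' @param reference_height_cm reference adult height, cm.
#' @return Dimensionless scale factor (1 for the reference adult).
#' @export
height_scale_factor <- function(subject, reference_height_cm = 176) {
  if (!is.numeric(subject$height_cm) || subject$height_cm <= 0)
    stop("subject height must be positive")
  subject$height_cm / reference_height_cm
}

#' Hourly inhaled air volume
#'
#' Minute ventilation `VT x f_B` converted to m^3/h. Reported values are
#' conventionally rounded to two decimals.
#'
#' @param subject a [subject_profile()].
#' @param rounded round to 2 decimals (reporting convention).
#' @return Inhaled air volume in m^3/h.
#' @export
#' @examples
#' inhaled_air_volume(subject_preset("healthy_adult"))  # 0.36
inhaled_air_volume <- function(subject, rounded = FALSE) {
  v <- subject$vt_cm3 * subject$f_b * 60 / 1e6
  if (rounded) round(v, 2) else v
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile '%s'> height %g cm, FRC %g cm3, VT %g cm3, f_B %g/min\n",
    x$id, x$height_cm, x$frc_cm3, x$vt_cm3, x$f_b))
  cat(sprintf("  inhale %g s / exhale %g s, asthma: %s\n",
              x$t_inhale, x$t_exhale, x$asthma))
  cat(sprintf("  mucus: %g mm/min tracheal, gel multiplier %g\n",
              x$mucus_velocity_trachea, x$mucus_gel_multiplier))
  invisible(x)
}
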