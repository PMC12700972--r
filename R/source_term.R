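# Radon-progeny source term: activity concentrations, attached/unattached
# partition by potential alpha energy, and inhaled atom counts.
#
# The internal currency of the simulation is atoms, not activity: the
# deposition rate of a nuclide is the number of its atoms inhaled per hour
# times the deposition fraction of its carrier aerosol mode.

#' Construct an exposure scenario
#'
#' Defaults describe a world-average indoor dwelling: 40 Bq/m^3 radon,
#' progeny activity ratios 0.58/0.44/0.29 (equilibrium factor ~0.4), 6 % of
#' the potential alpha energy concentration carried by unattached clusters
#' (split 90/10 between Po-218 and Pb-214), attached mode with 230 nm
#' activity median aerodynamic diameter, unattached mode at 0.8 nm.
#'
#' @param radon_bq_m3 radon activity concentration, Bq/m^3.
#' @param activity_ratios named/ordered fractions of the radon activity for
#'   Po-218, Pb-214, Bi-214.
#' @param unattached_paec_fraction fraction of total PAEC on unattached
#'   clusters.
#' @param unattached_split PAEC split of the unattached fraction between
#'   Po-218 and Pb-214 (must sum to 1).
#' @param amad_nm activity median aerodynamic diameter of the attached
#'   mode, nm.
#' @param gsd geometric standard deviation of the attached size
#'   distribution (set 1 for a monodisperse test mode).
#' @param amtd_nm thermodynamic diameter of the unattached mode, nm.
#' @param duration_h exposure duration, h.
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(radon_bq_m3 = 40,
                              activity_ratios = c(Po218 = 0.58,
                                                  Pb214 = 0.44,
                                                  Bi214 = 0.29),
                              unattached_paec_fraction = 0.06,
                              unattached_split = c(Po218 = 0.9,
                                                   Pb214 = 0.1),
                              amad_nm = 230, gsd = 2.0, amtd_nm = 0.8,
                              duration_h = 1) {
  if (radon_bq_m3 < 0) stop("radon concentration must be non-negative")
  if (any(activity_ratios < 0 | activity_ratios > 1))
    stop("activity ratios must lie in [0, 1]")
  if (unattached_paec_fraction < 0 || unattached_paec_fraction > 1)
    stop("unattached PAEC fraction must lie in [0, 1]")
  if (abs(sum(unattached_split) - 1) > 1e-12)
    stop("unattached split must sum to 1")
  structure(list(
    radon_bq_m3 = radon_bq_m3,
    activity_ratios = activity_ratios,
    unattached_paec_fraction = unattached_paec_fraction,
    unattached_split = unattached_split,
    amad_nm = amad_nm, gsd = gsd, amtd_nm = amtd_nm,
    duration_h = duration_h
  ), class = "exposure_scenario")
}

#' Potential-alpha-energy weighting coefficients of the progeny
#'
#' Per-nuclide PAEC contribution per unit activity: the remaining chain
#' alpha energy per atom divided by the decay constant, normalised over
#' Po-218, Pb-214 and Bi-214. Computed at runtime from the nuclear
#' constants rather than hard-coded.
#'
#' @return Named numeric vector (sums to 1).
#' @export
paec_weights <- function() {
  nd <- nuclide_data()
  nd <- nd[nd$name %in% c("Po218", "Pb214", "Bi214"), ]
  w <- nd$potential_alpha_MeV / nd$lambda
  stats::setNames(w / sum(w), nd$name)
}

#' Equilibrium factor from progeny activity ratios
#'
#' `F = sum_i k_i ratio_i` with the PAEC weights `k_i` from
#' [paec_weights()]. Ratios of 0.58/0.44/0.29 yield F ~ 0.4; secular
#' equilibrium (all ratios 1) yields exactly 1.
#'
#' @param activity_ratios three fractions (Po-218, Pb-214, Bi-214).
#' @return Dimensionless equilibrium factor.
#' @export
#' @examples
#' equilibrium_factor(c(0.58, 0.44, 0.29))
equilibrium_factor <- function(activity_ratios) {
  if (length(activity_ratios) != 3 || any(activity_ratios < 0))
    stop("need three non-negative activity ratios")
  sum(paec_weights() * as.numeric(activity_ratios))
}

#' Per-nuclide attached and unattached activity concentrations
#'
#' Total per-nuclide activity is the radon concentration times the activity
#' ratio. The unattached activity of Po-218 and Pb-214 is set so that the
#' unattached share of the total potential alpha energy concentration
#' equals `unattached_paec_fraction`, split 90/10 (by PAEC) between them;
#' Bi-214 is entirely attached. Attached activity is the remainder.
#'
#' @param scenario an [exposure_scenario()].
#' @return data.frame with columns `nuclide`, `mode`
#'   (attached/unattached) and `activity_bq_m3`.
#' @export
progeny_activity_concentrations <- function(scenario) {
  nd <- nuclide_data()
  nuc <- c("Po218", "Pb214", "Bi214")
  lam <- stats::setNames(nd$lambda, nd$name)[nuc]
  epot <- stats::setNames(nd$potential_alpha_MeV, nd$name)[nuc]
  total <- scenario$radon_bq_m3 * as.numeric(scenario$activity_ratios)
  names(total) <- nuc
  paec_per_bq <- epot / lam                 # MeV per (Bq/m^3)
  paec_total <- sum(total * paec_per_bq)
  unatt <- c(Po218 = 0, Pb214 = 0, Bi214 = 0)
  for (nm in names(scenario$unattached_split)) {
    unatt[nm] <- scenario$unattached_split[[nm]] *
      scenario$unattached_paec_fraction * paec_total / paec_per_bq[[nm]]
  }
  if (any(unatt > total + 1e-12))
    stop("inconsistent scenario: unattached activity exceeds total")
  data.frame(
    nuclide = rep(nuc, 2),
    mode = rep(c("attached", "unattached"), each = 3),
    activity_bq_m3 = c(total - unatt, unatt),
    stringsAsFactors = FALSE
  )
}

#' Number of progeny atoms inhaled per hour
#'
#' For each nuclide and carrier mode, atoms inhaled per hour equal the
#' activity concentration times the inhaled air volume divided by the
#' decay constant (activity-to-atoms conversion).
#'
#' @param concentrations output of [progeny_activity_concentrations()].
#' @param inhaled_air_volume_m3_h inhaled air volume, m^3/h.
#' @return The input data.frame with an added `atoms_per_h` column.
#' @export
atoms_inhaled_per_hour <- function(concentrations, inhaled_air_volume_m3_h) {
  if (inhaled_air_volume_m3_h <= 0) stop("inhaled air volume must be > 0")
  nd <- nuclide_data()
  lam <- stats::setNames(nd$lambda, nd$name)
  # atoms/m^3 = C / lambda, so atoms/h = C * V / lambda
  concentrations$atoms_per_h <- concentrations$activity_bq_m3 *
    inhaled_air_volume_m3_h / lam[concentrations$nuclide]
  concentrations
}

#' Sample activity-weighted particle diameters for a carrier mode
#'
#' Attached-mode diameters are lognormal around the AMAD with the
#' scenario's geometric standard deviation; the unattached mode is the
#' fixed cluster size (AMTD).
#'
#' @param scenario an [exposure_scenario()].
#' @param mode `"attached"` or `"unattached"`.
#' @param n number of particles.
#' @param seed integer seed.
#' @return Diameters in nm.
#' @export
sample_particle_diameters <- function(scenario, mode, n, seed = 1) {
  if (mode == "unattached") return(rep(scenario$amtd_nm, n))
  set.seed(.substream_seed(seed, "source"))
  stats::rlnorm(n, log(scenario$amad_nm), log(scenario$gsd))
}
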