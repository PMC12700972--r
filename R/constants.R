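# Physical constants, nuclear data and compiled configuration tables.
#
# Everything the simulation needs that is not a user-facing parameter lives
# here as versioned configuration: nuclide data for the short-lived radon
# progeny chain, ambient-air constants for aerosol mechanics, a compiled
# bronchial/acinar morphometry table, the asthma contraction table, the
# alpha stopping-power table for unit-density soft tissue, and the target
# cell depth-distribution weights.

.phys <- list(
  k_boltzmann = 1.380649e-23,  # J/K
  temperature = 293.15,        # K
  air_viscosity = 1.81e-5,     # Pa s
  mean_free_path_um = 0.0665,  # air, ~20 C, 101.325 kPa
  gravity = 9.81,              # m/s^2
  particle_density = 1000      # kg/m^3 (unit density spheres)
)

#' Nuclear data for the short-lived radon progeny chain
#'
#' Half-lives and alpha energies for the chain
#' Po-218 -> Pb-214 -> Bi-214 -> Po-214 -> (Pb-210, treated as stable here).
#' Pb-214 and Bi-214 are beta emitters; their potential alpha energy is the
#' 7.69 MeV of the Po-214 decay that every atom of the chain still has ahead
#' of it. Po-214's half-life (0.164 ms) is negligible against any transport
#' time scale, so its decay is treated as instantaneous after Bi-214.
#'
#' @return A data.frame with one row per nuclide: `name`, `half_life_s`,
#'   `lambda` (decay constant, 1/s), `alpha_energy_MeV` (`NA` for the beta
#'   emitters) and `potential_alpha_MeV` (remaining chain alpha energy per
#'   atom).
#' @export
#' @examples
#' nuclide_data()
nuclide_data <- function() {
  half <- c(Po218 = 185.88, Pb214 = 1608, Bi214 = 1194, Po214 = 1.643e-4)
  data.frame(
    name = names(half),
    half_life_s = unname(half),
    lambda = log(2) / unname(half),
    alpha_energy_MeV = c(6.00, NA, NA, 7.69),
    potential_alpha_MeV = c(6.00 + 7.69, 7.69, 7.69, 7.69),
    stringsAsFactors = FALSE
  )
}

#' Cunningham slip correction factor
#'
#' @param d_um particle diameter in micrometres.
#' @return Dimensionless slip correction (>= 1).
#' @export
cunningham <- function(d_um) {
  stopifnot(all(d_um > 0))
  kn <- 2 * .phys$mean_free_path_um / d_um
  1 + kn * (1.257 + 0.4 * exp(-1.1 / kn))
}

#' Brownian diffusion coefficient of an airborne particle
#'
#' Stokes-Einstein with slip correction.
#'
#' @param d_um particle diameter in micrometres.
#' @return Diffusion coefficient in cm^2/s.
#' @export
diffusion_coefficient <- function(d_um) {
  cc <- cunningham(d_um)
  d_m <- d_um * 1e-6
  d_si <- .phys$k_boltzmann * .phys$temperature * cc /
    (3 * pi * .phys$air_viscosity * d_m)  # m^2/s
  d_si * 1e4
}

#' Gravitational settling velocity
#'
#' @param d_um particle diameter in micrometres.
#' @param rho_p particle density in kg/m^3.
#' @return Terminal settling velocity in cm/s.
#' @export
settling_velocity <- function(d_um, rho_p = .phys$particle_density) {
  cc <- cunningham(d_um)
  d_m <- d_um * 1e-6
  v <- rho_p * d_m^2 * .phys$gravity * cc / (18 * .phys$air_viscosity)  # m/s
  v * 100
}

#' Compiled airway morphometry tables
#'
#' Per-generation central values (lognormal medians) and log-scale
#' dispersions of bronchial airway lengths and diameters for a reference
#' adult (height 176 cm), an acinar continuation, the distribution of the
#' bronchial/acinar boundary generation along a path, and the angle and
#' correlation parameters used by the stochastic path sampler. The central
#' values are a compiled approximation to the classic regularised human
#' morphometry (trachea = generation 1); the boundary distribution reflects
#' the stochastic variability of path depth (mean ~14.3 bronchial
#' generations, range 11-21).
#'
#' @param height_scale linear scale factor applied to all central dimensions
#'   (1 for the 176 cm reference adult).
#' @return A list with elements `bronchial` (data.frame: generation,
#'   length_um, diam_um, sigma_log_len, sigma_log_diam), `acinar`
#'   (data.frame: step, length_um, diam_um), `boundary` (data.frame:
#'   generation, prob), `rho_parent_daughter`, `branching_angle_mean`,
#'   `branching_angle_sd` (radians), `et_dead_space_cm3` and `scale`.
#' @export
anatomy_tables <- function(height_scale = 1) {
  stopifnot(is.numeric(height_scale), height_scale > 0)
  len_mm <- c(120, 47.6, 19.0, 7.6, 12.7, 10.7, 9.0, 7.6, 6.4, 5.4, 4.6,
              3.9, 3.3, 2.7, 2.3, 2.0, 1.65, 1.41, 1.17, 0.99, 0.83)
  diam_mm <- c(18, 12.2, 8.3, 5.6, 4.5, 3.5, 2.8, 2.3, 1.86, 1.54, 1.30,
               1.09, 0.95, 0.82, 0.74, 0.66, 0.60, 0.54, 0.50, 0.47, 0.45)
  bronchial <- data.frame(
    generation = seq_along(len_mm),
    length_um = len_mm * 1000 * height_scale,
    diam_um = diam_mm * 1000 * height_scale,
    sigma_log_len = rep(0.35, length(len_mm)),
    sigma_log_diam = rep(0.25, length(len_mm))
  )
  acinar <- data.frame(
    step = 1:9,
    length_um = c(1.40, 1.33, 1.12, 0.93, 0.83, 0.70, 0.70, 0.70, 0.70) *
      1000 * height_scale,
    diam_um = c(0.50, 0.50, 0.49, 0.40, 0.38, 0.36, 0.32, 0.29, 0.25) *
      1000 * height_scale
  )
  boundary <- data.frame(
    generation = 11:21,
    prob = c(0.04, 0.12, 0.20, 0.24, 0.18, 0.10, 0.06, 0.03, 0.015, 0.01,
             0.005)
  )
  list(
    bronchial = bronchial,
    acinar = acinar,
    boundary = boundary,
    rho_parent_daughter = 0.7,
    branching_angle_mean = 0.61,
    branching_angle_sd = 0.17,
    et_dead_space_cm3 = 50 * height_scale^3,
    scale = height_scale
  )
}

#' Probability and extent of airway contraction in severe asthma
#'
#' Per-generation probability that a bronchial airway is contracted and the
#' relative diameter reduction when it is. The trachea is never contracted;
#' from generation 9 to 21 the values are constant (75 %, 25 %).
#'
#' @return data.frame with columns `generation` (1-21), `probability` and
#'   `extent`, both fractions in `[0, 1]`.
#' @export
contraction_table <- function() {
  data.frame(
    generation = 1:21,
    probability = c(0, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.75,
                    rep(0.75, 13)),
    extent = c(0, 0.03, 0.05, 0.08, 0.10, 0.15, 0.20, 0.20, rep(0.25, 13))
  )
}

#' Alpha-particle stopping power in unit-density soft tissue
#'
#' Compiled electronic stopping powers (standard evaluated values,
#' unit-density tissue approximated by water) on an energy grid covering the
#' radon-progeny alpha energies. The corresponding continuous-slowing-down
#' ranges are about 48 um at 6.00 MeV and 69 um at 7.69 MeV.
#'
#' @return data.frame with columns `energy_MeV` and `stopping_keV_um`.
#' @export
stopping_power_table <- function() {
  data.frame(
    energy_MeV = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0,
                   1.25, 1.5, 1.75, 2.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.0, 5.5,
                   6.0, 6.5, 7.0, 7.5, 8.0, 8.5, 9.0, 9.5, 10.0),
    stopping_keV_um = c(95, 126, 157, 178, 188, 193, 196, 197, 196, 193,
                        190, 181, 172, 163, 154, 139, 127, 117, 110, 103,
                        97, 91, 87, 83, 79, 76, 73, 70, 68, 66, 64)
  )
}

#' Depth grid for target cells in the bronchial epithelium
#'
#' 25 depths from 2 to 50 micrometres below the top of the epithelium.
#' @return numeric vector of length 25 (micrometres).
#' @export
target_depth_grid <- function() seq(2, 50, by = 2)

#' Depth-distribution weights of basal and secretory cell nuclei
#'
#' Normalised weights over the 25-depth target grid for each airway region
#' class (large bronchi, diameter > 3 mm; bronchi, 1-3 mm; terminal
#' bronchioles, < 1 mm) and cell type. The profiles are a synthetic,
#' editable stand-in for measured depth distributions: unimodal profiles
#' whose means shift shallower as the epithelium thins distally, with basal
#' nuclei deeper than secretory nuclei. Terminal bronchioles contain no
#' basal cells, so their basal weights are structurally zero.
#'
#' @return data.frame with columns `region`, `cell_type`, `depth_um`,
#'   `weight`; weights sum to 1 within each (region, cell_type) except the
#'   all-zero terminal-bronchiole basal row set.
#' @export
cell_depth_weights <- function() {
  grid <- target_depth_grid()
  prof <- function(mean, sd) {
    w <- stats::dnorm(grid, mean, sd)
    w / sum(w)
  }
  spec <- list(
    large_bronchi = list(basal = prof(42, 7), secretory = prof(22, 9)),
    bronchi = list(basal = prof(28, 6), secretory = prof(14, 6)),
    terminal_bronchioles = list(basal = rep(0, length(grid)),
                                secretory = prof(8, 3))
  )
  do.call(rbind, lapply(names(spec), function(reg) {
    do.call(rbind, lapply(names(spec[[reg]]), function(ct) {
      data.frame(region = reg, cell_type = ct, depth_um = grid,
                 weight = spec[[reg]][[ct]], stringsAsFactors = FALSE)
    }))
  }))
}

#' Default microdosimetry parameters
#'
#' The nucleus is modelled as a unit-density sphere. Absolute dose
#' magnitudes scale inversely with the nucleus mass; ratios between
#' subjects, generations and cell types do not depend on it.
#'
#' @return list with `nucleus_diam_um`, `tissue_density_g_cm3`,
#'   `n_samples` (default Monte Carlo sample size per generation/energy/cell
#'   type) and `slab_mode` (use plane-parallel instead of cylindrical layer
#'   geometry).
#' @export
dosimetry_defaults <- function() {
  list(nucleus_diam_um = 8, tissue_density_g_cm3 = 1.0,
       n_samples = 1e5, slab_mode = FALSE)
}

#' Extrathoracic (nasal) deposition correlation constants
#'
#' Empirical nasal efficiency in the diffusion regime follows the
#' turbulent-diffusion form `1 - exp(-a D^p Q^-q)` (D in cm^2/s, Q in
#' L/min); in the impaction regime the classic logarithmic Stokes-parameter
#' form `-b0 + b1 log10(rho d_ae^2 Q)` (d_ae in um, Q in L/min) clamped to
#' `[0, 1]`. The diffusion coefficients are anchored so that the reference
#' adult nasal efficiencies match reported ultrafine (cluster-size) and
#' accumulation-mode deposition at quiet nose breathing.
#'
#' The efficiency of the nasal filter also depends on the size of the
#' nasal passage itself: at matched flow a child's smaller nose is the
#' more efficient diffusion filter. This enters as a multiplicative
#' `h^-size_exp` on the diffusion exponent, with `h` the height-derived
#' linear scale of the subject (1 for the reference adult).
#'
#' @return list of the constants used by [extrathoracic_efficiency()].
#' @export
extrathoracic_constants <- function() {
  list(diff_a = 24.7, diff_p = 0.42, diff_q = 0.40, size_exp = 0.39,
       imp_b0 = 0.62, imp_b1 = 0.475)
}

# internal: derive a reproducible sub-seed from a master seed and stage tag
.substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  offs <- c(geometry = 1, deposition = 2, decay = 3, dosimetry = 4,
            source = 5, misc = 6)
  o <- offs[[stage]]
  as.integer((abs(seed) + o * 1000003) %% 2147483629)
}
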