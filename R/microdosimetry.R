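# Alpha-particle microdosimetry of the bronchial epithelium.
#
# Decay sites are uniform over the gel (mucus) annulus of a cylindrical
# airway; alpha particles travel on straight lines (continuous slowing
# down, no straggling), crossing lumen air (no energy loss), gel, sol and
# epithelial tissue (unit density) to reach target cell nuclei at 2-50 um
# below the top of the epithelium. Ray/layer intersections are exact
# cylinder chords; a plane-parallel slab mode exists for comparison.

# cached fine-grained range/energy lookup built from the stopping table
.dosim_cache <- new.env(parent = emptyenv())

.range_lookup <- function() {
  if (!is.null(.dosim_cache$egrid)) return(invisible(NULL))
  tab <- stopping_power_table()
  sp <- stats::splinefun(tab$energy_MeV, tab$stopping_keV_um,
                         method = "monoH.FC")
  eg <- seq(0.05, 10, by = 0.005)
  inv_s <- 1 / sp(eg)                       # um per keV
  rg <- 0.4 + c(0, cumsum((inv_s[-1] + inv_s[-length(inv_s)]) / 2 *
                            diff(eg) * 1000))
  .dosim_cache$egrid <- eg
  .dosim_cache$rgrid <- rg
  .dosim_cache$stop_fun <- sp
  invisible(NULL)
}

#' Alpha-particle CSDA range in unit-density tissue
#'
#' Continuous-slowing-down range obtained by integrating the reciprocal of
#' the embedded stopping-power table; strictly increasing in energy
#' (about 48 um at 6.00 MeV and 69 um at 7.69 MeV).
#'
#' @param energy_MeV alpha energy, MeV; must lie in (0, 10].
#' @return Range in micrometres.
#' @export
#' @examples
#' alpha_range(c(6.00, 7.69))
alpha_range <- function(energy_MeV) {
  if (any(!is.finite(energy_MeV)) || any(energy_MeV <= 0) ||
      any(energy_MeV > 10))
    stop("energy must lie in (0, 10] MeV")
  .range_lookup()
  out <- numeric(length(energy_MeV))
  lo <- energy_MeV < 0.05
  out[lo] <- 0.4 * energy_MeV[lo] / 0.05
  out[!lo] <- stats::approx(.dosim_cache$egrid, .dosim_cache$rgrid,
                            energy_MeV[!lo])$y
  out
}

#' Residual alpha energy after traversing tissue
#'
#' Range-inversion of the continuous-slowing-down approximation: the
#' residual energy after a traversed tissue-equivalent path `x` satisfies
#' `range(E_res) = range(E0) - x`, and is 0 once the full range is spent.
#'
#' @param energy0_MeV initial energy, MeV.
#' @param traversed_um traversed tissue-equivalent path, micrometres.
#' @return Residual energy in MeV (0 if the range is exhausted).
#' @export
#' @examples
#' energy_on_arrival(6.00, 0)     # 6
#' energy_on_arrival(6.00, 1e4)   # 0
energy_on_arrival <- function(energy0_MeV, traversed_um) {
  stopifnot(all(traversed_um >= 0))
  .range_lookup()
  r_res <- alpha_range(energy0_MeV) - traversed_um
  out <- numeric(length(r_res))
  ok <- r_res > .dosim_cache$rgrid[1]
  if (any(ok))
    out[ok] <- stats::approx(.dosim_cache$rgrid, .dosim_cache$egrid,
                             r_res[ok])$y
  tiny <- !ok & r_res > 0
  out[tiny] <- 0.05 * pmax(r_res[tiny], 0) / 0.4
  pmax(out, 0)
}

# internal, vectorised: time-in-cylinder overlap helper.
# For rays x(t) = (r0 + t wx, t wy, t wz), returns the length of t in
# [0, tmax] with cylindrical radius < R.
.len_inside <- function(r0, wx, s2, R, tmax) {
  disc <- r0^2 * wx^2 - s2 * (r0^2 - R^2)
  out <- numeric(length(r0))
  ok <- disc > 0 & s2 > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-r0[ok] * wx[ok] - sq) / s2[ok]
    t2 <- (-r0[ok] * wx[ok] + sq) / s2[ok]
    out[ok] <- pmax(0, pmin(t2, tmax[ok]) - pmax(t1, 0))
  }
  out
}

# internal, vectorised chord computation. Emission at radius r0 (inside the
# gel), direction (wx, wy, wz); layer boundaries: lumen < rl, gel
# [rl, rg), sol [rg, re), tissue beyond; target shell at rt >= re.
# Returns list of per-layer path lengths and total path tt, plus the
# cosine of the crossing angle at the target shell.
.chords_to_shell <- function(r0, wx, wy, rl, rg, re, rt) {
  s2 <- wx^2 + wy^2
  miss <- s2 <= 0
  s2e <- ifelse(miss, 1, s2)
  disc <- r0^2 * wx^2 + s2e * (rt^2 - r0^2)
  tt <- (-r0 * wx + sqrt(pmax(disc, 0))) / s2e
  tt[miss] <- Inf
  l_lum <- .len_inside(r0, wx, s2e, rl, tt)
  l_g <- .len_inside(r0, wx, s2e, rg, tt) - l_lum
  l_e <- .len_inside(r0, wx, s2e, re, tt)
  l_sol <- l_e - l_g - l_lum
  l_tis <- tt - l_e
  # crossing angle at the target shell
  px <- r0 + tt * wx
  py <- tt * wy
  cosg <- abs(px * wx + py * wy) / rt
  cosg[miss] <- 0
  list(lumen = l_lum, gel = pmax(l_g, 0), sol = pmax(l_sol, 0),
       tissue = pmax(l_tis, 0), total = tt, cos_gamma = cosg)
}

#' Layer chords of an alpha track to a target depth
#'
#' Exact ray/cylinder intersection lengths of the straight track from an
#' emission point in the gel layer to its first crossing of the target
#' shell (nucleus-centre depth below the epithelium top). The lumen is
#' crossed without energy loss; gel, sol and tissue count as unit-density
#' material. A track with no radial component never reaches the shell
#' ("miss").
#'
#' @param track list with `radius_um` (emission radius) and `direction`
#'   (unit 3-vector; x is the radial axis through the emission point).
#' @param tube list with `diam_um` (lumen diameter), `gel_um`, `sol_um`.
#' @param target_depth_um depth of the target below the epithelium top.
#' @return list with `lumen`, `gel`, `sol`, `tissue` chord lengths (um),
#'   `total`, `cos_gamma`, and `miss` (logical).
#' @export
chord_through_layers <- function(track, tube, target_depth_um) {
  rl <- tube$diam_um / 2
  rg <- rl + tube$gel_um
  re <- rg + tube$sol_um
  rt <- re + target_depth_um
  w <- track$direction / sqrt(sum(track$direction^2))
  ch <- .chords_to_shell(track$radius_um, w[1], w[2], rl, rg, re, rt)
  ch$miss <- !is.finite(ch$total)
  ch
}

#' Hit probability and energy delivered to target cell nuclei
#'
#' Monte Carlo estimate, per airway generation geometry and alpha energy,
#' of (i) the probability that an isotropically emitted alpha from the gel
#' layer reaches a target-cell nucleus depth with residual energy (the
#' reach probability used as a weighting factor), (ii) the mean energy
#' imparted in a nucleus chord conditional on reaching it, and (iii) the
#' expected energy imparted per decay to one nucleus of the sampled cell
#' population, which folds in the geometric chance `pi rho^2 sec(gamma) / A`
#' that the crossing track actually passes through a specific nucleus on
#' the shell (`A` = shell area of the tube).
#'
#' Emission radii are uniform over the gel layer; target depths are drawn
#' from the cell-type weights. If all weights are zero (basal cells in
#' terminal bronchioles) every estimate is exactly zero.
#'
#' @param tube list with `diam_um`, `length_um`, `gel_um`, `sol_um`.
#' @param depth_weights data.frame with `depth_um`, `weight` for the cell
#'   type in this tube's region class.
#' @param energy0_MeV initial alpha energy (6.00 or 7.69).
#' @param nucleus_diam_um nucleus diameter, um.
#' @param n_samples Monte Carlo samples.
#' @param seed integer seed.
#' @param slab_mode use plane-parallel layers instead of cylinder chords.
#' @return An object of class `hit_statistics`: list with `p_hit`,
#'   `p_hit_se`, `mean_energy_MeV`, `mean_energy_se`,
#'   `energy_per_nucleus_MeV`, `energy_per_nucleus_se`, `n`, `seed`.
#' @export
hit_probability_and_energy <- function(tube, depth_weights, energy0_MeV,
                                       nucleus_diam_um = 8,
                                       n_samples = 1e4, seed = 1,
                                       slab_mode = FALSE) {
  stopifnot(n_samples >= 1, energy0_MeV > 0)
  if (sum(depth_weights$weight) <= 0) {
    return(structure(list(p_hit = 0, p_hit_se = 0, mean_energy_MeV = 0,
                          mean_energy_se = 0, energy_per_nucleus_MeV = 0,
                          energy_per_nucleus_se = 0, n = n_samples,
                          seed = seed), class = "hit_statistics"))
  }
  set.seed(.substream_seed(seed, "dosimetry"))
  n <- n_samples
  rl <- tube$diam_um / 2
  rg <- rl + tube$gel_um
  re <- rg + tube$sol_um
  rho <- nucleus_diam_um / 2

  r0 <- stats::runif(n, rl, rg)
  x <- depth_weights$depth_um[sample.int(nrow(depth_weights), n,
                                         replace = TRUE,
                                         prob = depth_weights$weight)]
  rt <- re + x
  wz <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - wz^2, 0))
  wx <- s * cos(phi)
  wy <- s * sin(phi)

  if (slab_mode) {
    reach_geom <- wx > 0
    sec <- ifelse(reach_geom, 1 / wx, Inf)
    l_tis <- ifelse(reach_geom, ((rg - r0) + (re - rg) + x) * sec, Inf)
    cosg <- ifelse(reach_geom, wx, 0)
  } else {
    ch <- .chords_to_shell(r0, wx, wy, rl, rg, re, rt)
    l_tis <- ch$gel + ch$sol + ch$tissue
    l_tis[!is.finite(ch$total)] <- Inf
    cosg <- ch$cos_gamma
  }
  e_arr <- ifelse(is.finite(l_tis), energy_on_arrival(energy0_MeV, l_tis), 0)
  hit <- e_arr > 0

  b <- rho * sqrt(stats::runif(n))
  chord <- 2 * sqrt(pmax(rho^2 - b^2, 0))
  e_dep <- numeric(n)
  if (any(hit))
    e_dep[hit] <- e_arr[hit] - energy_on_arrival(e_arr[hit], chord[hit])

  p_hit <- mean(hit)
  p_se <- sqrt(p_hit * (1 - p_hit) / n)
  e_mean <- if (any(hit)) mean(e_dep[hit]) else 0
  e_se <- if (sum(hit) > 1) stats::sd(e_dep[hit]) / sqrt(sum(hit)) else 0

  # per-nucleus energy: geometric factor pi rho^2 sec(gamma) / shell area,
  # grazing crossings capped to keep the estimator finite
  area <- 2 * pi * rt * tube$length_um
  sec_g <- pmin(1 / pmax(cosg, 1e-6), 50)
  w_pair <- ifelse(hit, pi * rho^2 * sec_g / area, 0)
  epn <- w_pair * e_dep
  structure(list(
    p_hit = p_hit, p_hit_se = p_se,
    mean_energy_MeV = e_mean, mean_energy_se = e_se,
    energy_per_nucleus_MeV = mean(epn),
    energy_per_nucleus_se = stats::sd(epn) / sqrt(n),
    n = n, seed = seed
  ), class = "hit_statistics")
}

#' Hit statistics for every bronchial generation of a subject
#'
#' Uses the subject-scaled per-generation central tube dimensions (with the
#' expected contraction factor for asthmatics), the subject's gel/sol
#' thicknesses and the region-class cell-depth weights.
#'
#' @param subject a [subject_profile()].
#' @param tables subject-scaled anatomy tables.
#' @param n_samples Monte Carlo samples per (generation, cell type,
#'   energy).
#' @param seed master seed.
#' @param nucleus_diam_um nucleus diameter, um.
#' @param slab_mode see [hit_probability_and_energy()].
#' @return data.frame with generation, cell_type, energy_MeV, p_hit,
#'   mean_energy_MeV, energy_per_nucleus_MeV and standard errors.
#' @export
hit_stats_for_subject <- function(subject,
                                  tables = scale_tables_for_subject(
                                    anatomy_tables(), subject),
                                  n_samples = 1e4, seed = 1,
                                  nucleus_diam_um =
                                    dosimetry_defaults()$nucleus_diam_um,
                                  slab_mode = FALSE) {
  cw <- cell_depth_weights()
  ct <- contraction_table()
  br <- tables$bronchial
  rows <- list()
  for (g in br$generation) {
    d <- br$diam_um[g]
    if (subject$asthma)
      d <- d * (1 - ct$probability[g] * ct$extent[g])
    mt <- mucus_thickness(g, d, subject, tables)
    tube <- list(diam_um = d, length_um = br$length_um[g],
                 gel_um = mt$gel_um, sol_um = mt$sol_um)
    reg <- classify_region(d)
    for (cell in c("basal", "secretory")) {
      wdf <- cw[cw$region == reg & cw$cell_type == cell,
                c("depth_um", "weight")]
      for (e0 in c(6.00, 7.69)) {
        hs <- hit_probability_and_energy(
          tube, wdf, e0, nucleus_diam_um = nucleus_diam_um,
          n_samples = n_samples,
          seed = seed + g * 101 + round(e0 * 10) +
            7 * (cell == "secretory"),
          slab_mode = slab_mode)
        rows[[length(rows) + 1]] <- data.frame(
          generation = g, cell_type = cell, energy_MeV = e0,
          p_hit = hs$p_hit, p_hit_se = hs$p_hit_se,
          mean_energy_MeV = hs$mean_energy_MeV,
          energy_per_nucleus_MeV = hs$energy_per_nucleus_MeV,
          energy_per_nucleus_se = hs$energy_per_nucleus_se)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Absorbed dose rates in basal and secretory cell nuclei
#'
#' Combines a per-generation alpha-decay tally with the hit statistics:
#' for each generation and cell type the dose rate is the sum over alpha
#' energies of (decays per hour) x (expected energy imparted per decay to
#' one nucleus) divided by the nucleus mass. Acinar tallies (generation 0)
#' are excluded from the bronchial dose.
#'
#' @param tally a `decay_tally` from [decay_tally()].
#' @param stats hit statistics from [hit_stats_for_subject()].
#' @param nucleus_diam_um,tissue_density_g_cm3 nucleus geometry/density.
#' @return An object of class `dose_rate_spectrum`: data.frame `table`
#'   with generation, cell_type, dose_rate_uGy_per_h, dose_rate_se; plus
#'   `subject_id`.
#' @export
dose_rate <- function(tally, stats,
                      nucleus_diam_um = dosimetry_defaults()$nucleus_diam_um,
                      tissue_density_g_cm3 =
                        dosimetry_defaults()$tissue_density_g_cm3) {
  tt <- tally$table
  tt <- tt[tt$generation >= 1, ]
  gens <- sort(unique(tt$generation))
  if (!all(gens %in% unique(stats$generation)))
    stop("decay tally and hit statistics are on different generation grids")
  mass_kg <- tissue_density_g_cm3 * 4 / 3 * pi *
    (nucleus_diam_um / 2 * 1e-4)^3 / 1000
  mev_to_j <- 1.602176634e-13
  rows <- list()
  for (g in gens) {
    dec <- c(`6` = tt$alpha_6.00_per_h[tt$generation == g],
             `7.69` = tt$alpha_7.69_per_h[tt$generation == g])
    for (cell in unique(stats$cell_type)) {
      s6 <- stats[stats$generation == g & stats$cell_type == cell &
                    stats$energy_MeV == 6.00, ]
      s7 <- stats[stats$generation == g & stats$cell_type == cell &
                    stats$energy_MeV == 7.69, ]
      e_j <- (dec[1] * s6$energy_per_nucleus_MeV +
                dec[2] * s7$energy_per_nucleus_MeV) * mev_to_j
      se_j <- sqrt((dec[1] * s6$energy_per_nucleus_se)^2 +
                     (dec[2] * s7$energy_per_nucleus_se)^2) * mev_to_j
      rows[[length(rows) + 1]] <- data.frame(
        generation = g, cell_type = cell,
        dose_rate_uGy_per_h = unname(e_j / mass_kg * 1e6),
        dose_rate_se = unname(se_j / mass_kg * 1e6))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(table = out, subject_id = tally$subject$id),
            class = "dose_rate_spectrum")
}
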