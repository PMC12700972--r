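# Monte Carlo aerosol transport: nasal (extrathoracic) filtering plus
# plug-flow transport down a sampled airway path over one breathing cycle.
#
# A particle inhaled at a uniformly random time within the inhalation phase
# is advected by square-wave flow. The volume of air inhaled behind it sets
# its penetration depth against the cumulative airway volume (anatomical
# dead space, bronchial tubes, FRC-scaled acinar compartments). At every
# tube transit a Bernoulli trial with the combined
# diffusion/sedimentation/impaction efficiency decides deposition; the
# deepest segment accrues the end-inspiratory dwell. Exhalation retraces
# the path at the expiratory flow, ending with a second nasal pass.
# Particles still airborne afterwards are exhaled.

#' Nasal (extrathoracic) deposition efficiency
#'
#' Combined efficiency `1 - (1 - eta_diff)(1 - eta_imp)` of the empirical
#' diffusion and impaction correlations for nose breathing (constants in
#' [extrathoracic_constants()]). Efficiency tends to 1 for vanishing
#' particle size (diffusion) and for large inertial parameter (impaction).
#'
#' @param diameter_nm particle diameter, nm.
#' @param flow_cm3_s airflow through the nose, cm^3/s.
#' @param mode carrier mode (kept for interface symmetry; both modes use
#'   the same correlations).
#' @param size_scale height-derived linear scale of the subject's nasal
#'   passage (1 = reference adult).
#' @param constants correlation constants, see [extrathoracic_constants()].
#' @return Deposition probability per pass, in `[0, 1]`.
#' @export
#' @examples
#' extrathoracic_efficiency(0.8, 200)   # unattached cluster, quiet adult
#' extrathoracic_efficiency(230, 200)   # attached mode
extrathoracic_efficiency <- function(diameter_nm, flow_cm3_s,
                                     mode = "attached", size_scale = 1,
                                     constants = extrathoracic_constants()) {
  stopifnot(all(diameter_nm > 0), all(flow_cm3_s > 0), size_scale > 0)
  d_um <- diameter_nm / 1000
  dc <- diffusion_coefficient(d_um)          # cm^2/s
  q_lpm <- flow_cm3_s * 60 / 1000
  eta_d <- 1 - exp(-constants$diff_a * dc^constants$diff_p *
                     q_lpm^(-constants$diff_q) *
                     size_scale^(-constants$size_exp))
  eta_i <- pmin(1, pmax(0, -constants$imp_b0 +
                          constants$imp_b1 * log10(d_um^2 * q_lpm)))
  pmin(1, pmax(0, 1 - (1 - eta_d) * (1 - eta_i)))
}

# internal, fully vectorised: combined tube deposition probability.
# d_t_um/l_um: tube diameter/length; dp_nm particle diameter; q_cm3_s flow
# through the single tube (0 for a parked parcel); t_s residence time;
# grav/branch angles in radians. Diffusion uses the residence-time form of
# the Graetz parameter, Delta = D t / (4 R^2), which reduces to the
# classic flow form pi D L / (4 Q) when t = V/Q.
.tube_mech_prob <- function(d_t_um, l_um, dp_nm, q_cm3_s, t_s, grav, branch) {
  d_um <- dp_nm / 1000
  dc <- diffusion_coefficient(d_um)                  # cm^2/s
  r_cm <- d_t_um / 2e4
  delta <- dc * t_s / (4 * r_cm^2)
  eta_diff <- 1 - 0.819 * exp(-14.63 * delta) -
    0.0976 * exp(-89.22 * delta) - 0.0325 * exp(-228 * delta) -
    0.0509 * exp(-125.9 * delta^(2 / 3))
  eta_diff <- pmin(1, pmax(0, eta_diff))

  vs <- settling_velocity(d_um)                      # cm/s
  eta_sed <- 1 - exp(-4 * vs * t_s * cos(grav) / (pi * d_t_um / 1e4))

  area <- pi * r_cm^2
  u_ms <- ifelse(q_cm3_s > 0, q_cm3_s / area, 0) * 0.01   # m/s
  dp_m <- dp_nm * 1e-9
  stk <- .phys$particle_density * dp_m^2 * cunningham(d_um) * u_ms /
    (18 * .phys$air_viscosity * d_t_um * 1e-6)
  eta_imp <- pmin(1, 1.606 * stk * sin(branch))

  pmin(1, pmax(0, 1 - (1 - eta_diff) * (1 - eta_sed) * (1 - eta_imp)))
}

#' Deposition probability in a single airway tube
#'
#' Combined probability `1 - (1 - p_diff)(1 - p_sed)(1 - p_imp)` of
#' Brownian diffusion (Ingham-type efficiency in residence-time form),
#' gravitational settling in an inclined tube, and inertial impaction
#' (Stokes-number correlation weighted by the branching angle). With zero
#' residence time and zero flow the probability is 0.
#'
#' @param tube a list or one-row data.frame with `diam_um`, `length_um`,
#'   `gravity_angle_rad`, `branching_angle_rad`.
#' @param diameter_nm particle diameter, nm.
#' @param flow_cm3_s airflow through the tube, cm^3/s (0 when parked).
#' @param residence_s residence time in the tube, s.
#' @return Deposition probability in `[0, 1]`.
#' @export
tube_deposition_probability <- function(tube, diameter_nm, flow_cm3_s,
                                        residence_s) {
  stopifnot(tube$diam_um > 0, diameter_nm > 0, flow_cm3_s >= 0,
            residence_s >= 0)
  .tube_mech_prob(tube$diam_um, tube$length_um, diameter_nm, flow_cm3_s,
                  residence_s, tube$gravity_angle_rad,
                  tube$branching_angle_rad)
}

#' Breathing pattern of a subject
#'
#' @param subject a [subject_profile()].
#' @return list with tidal volume, phase durations, pause (0) and route.
#' @export
breathing_pattern <- function(subject) {
  list(vt_cm3 = subject$vt_cm3, t_inhale = subject$t_inhale,
       t_exhale = subject$t_exhale, pause = 0, route = "nasal")
}

# internal: first index at which a particle deposits given the ordered
# per-segment probability matrix (n x m) and one uniform draw per particle.
# Returns m+1 for "exhaled". Exactly equivalent to sequential Bernoulli
# trials down the columns.
.deposit_index <- function(pmat, u) {
  .transport_tally(pmat, u)$idx
}

# internal: analog fate draw plus expected-value (survival-weighted)
# deposition tallies per column. The expected weight of column j is
# p_j * prod_{k<j} (1 - p_k); the exhaled weight is the survival of the
# whole sequence. Expected weights are the low-variance estimator of the
# deposition fractions; the integer fates keep exact particle accounting.
.transport_tally <- function(pmat, u) {
  n <- nrow(pmat)
  m <- ncol(pmat)
  surv <- rep(1, n)
  cdf <- rep(0, n)
  idx <- rep.int(m + 1L, n)
  undecided <- rep(TRUE, n)
  w <- matrix(0, n, m)
  for (j in seq_len(m)) {
    w[, j] <- surv * pmat[, j]
    cdf <- cdf + w[, j]
    hit <- undecided & (u < cdf)
    idx[hit] <- j
    undecided <- undecided & !hit
    surv <- surv * (1 - pmat[, j])
  }
  list(idx = idx, w = w, exhaled_w = surv)
}

# internal engine: simulate n histories for one carrier mode.
# mats: path matrices from .sample_path_matrices (possibly contracted);
# dp_nm: per-particle diameters (nm). Returns per-particle fate labels.
.run_histories <- function(mats, dp_nm, subject, tables, seed) {
  n <- length(dp_nm)
  ng <- ncol(mats$diam)          # bronchial generations (21)
  nseg <- ng + ncol(mats$ac_diam)
  q_in <- subject$vt_cm3 / subject$t_inhale
  q_ex <- subject$vt_cm3 / subject$t_exhale
  v_et <- tables$et_dead_space_cm3

  # segment geometry: bronchial cols then acinar cols, re-ragged per path
  gb <- mats$gb
  segj <- matrix(rep(seq_len(nseg), each = n), n, nseg)
  is_br <- segj <= gb
  d_seg <- matrix(0, n, nseg)
  l_seg <- matrix(0, n, nseg)
  g_seg <- matrix(0, n, nseg)
  b_seg <- matrix(0, n, nseg)
  for (j in seq_len(nseg)) {
    br <- j <= gb
    kb <- if (j <= ng) which(br) else integer(0)
    ka <- which(!br & (j - gb) <= ncol(mats$ac_diam))
    if (length(kb)) {
      d_seg[kb, j] <- mats$diam[kb, j]
      l_seg[kb, j] <- mats$len[kb, j]
      g_seg[kb, j] <- mats$grav[kb, j]
      b_seg[kb, j] <- mats$branch[kb, j]
    }
    if (length(ka)) {
      d_seg[ka, j] <- mats$ac_diam[cbind(ka, j - gb[ka])]
      l_seg[ka, j] <- mats$ac_len[cbind(ka, j - gb[ka])]
      g_seg[ka, j] <- mats$grav[cbind(ka, ng + j - gb[ka])]
      b_seg[ka, j] <- mats$branch[cbind(ka, ng + j - gb[ka])]
    }
  }
  active <- d_seg > 0

  mult <- matrix(2^(pmin(segj, nseg) - 1), n, nseg)
  v_gen <- pi / 4 * (d_seg / 1e4)^2 * (l_seg / 1e4) * mult   # cm^3
  # acinar compartments: volume from FRC, doubling per step
  cum_br <- t(apply(v_gen * is_br, 1, cumsum))
  v_br_tot <- cum_br[, nseg]
  v_ac_avail <- pmax(subject$frc_cm3 - v_et - v_br_tot, 50 * tables$scale^3)
  for (j in seq_len(nseg)) {
    ka <- which(j > gb & (j - gb) <= ncol(mats$ac_diam))
    if (length(ka)) {
      k_step <- j - gb[ka]
      v_gen[ka, j] <- v_ac_avail[ka] * 2^(k_step - 1) / (2^9 - 1)
    }
  }
  v_cum_prev <- matrix(0, n, nseg)   # cumulative volume up to segment entry
  acc <- rep(v_et, n)
  for (j in seq_len(nseg)) {
    v_cum_prev[, j] <- acc
    acc <- acc + v_gen[, j]
  }

  set.seed(.substream_seed(seed, "deposition"))
  t0 <- stats::runif(n, 0, subject$t_inhale)
  v_pen <- subject$vt_cm3 * (1 - t0 / subject$t_inhale)
  u <- stats::runif(n)

  reached <- (v_cum_prev < v_pen) & active     # parcel enters segment j
  smax <- rowSums(reached)                     # 0 = stays extrathoracic

  # residence times
  t_in_seg <- v_gen / q_in
  t_ex_seg <- v_gen / q_ex
  deep <- matrix(FALSE, n, nseg)
  deep[cbind(seq_len(n), pmax(smax, 1))] <- smax > 0
  v_into_deep <- pmax(v_pen - v_cum_prev[cbind(seq_len(n), pmax(smax, 1))], 0)
  dwell_deep <- v_into_deep * (1 / q_in + 1 / q_ex)

  p_in <- .tube_mech_prob(d_seg, l_seg, dp_nm, q_in / mult, t_in_seg,
                          g_seg, b_seg)
  p_ex <- .tube_mech_prob(d_seg, l_seg, dp_nm, q_ex / mult, t_ex_seg,
                          g_seg, b_seg)
  p_deep <- .tube_mech_prob(d_seg, l_seg, dp_nm, 0, dwell_deep,
                            g_seg, b_seg)
  transit <- reached & !deep
  p_in <- ifelse(transit, p_in, 0) + ifelse(deep, p_deep, 0)
  p_ex <- ifelse(transit, p_ex, 0)
  p_in[!active] <- 0
  p_ex[!active] <- 0

  eta_in <- extrathoracic_efficiency(dp_nm, q_in, size_scale = tables$scale)
  eta_ex <- extrathoracic_efficiency(dp_nm, q_ex, size_scale = tables$scale)

  # ordered sequence: nasal in, segments 1..nseg in, segments nseg..1 out,
  # nasal out
  pbig <- cbind(eta_in, p_in, p_ex[, rev(seq_len(nseg)), drop = FALSE],
                eta_ex)
  tt <- .transport_tally(pbig, u)
  idx <- tt$idx

  # expected-value tallies: per-segment weights summed over both passes
  w_et <- tt$w[, 1] + tt$w[, 2 * nseg + 2]
  w_seg <- tt$w[, 1 + seq_len(nseg)] +
    tt$w[, 2 * nseg + 2 - seq_len(nseg)]
  seg_is_br <- segj <= gb

  fate_region <- rep("exhaled", n)
  fate_gen <- rep(NA_integer_, n)
  seg_of <- function(col) ifelse(col <= 1 + nseg, col - 1L,
                                 2L * nseg + 2L - col)
  dep <- idx <= 2 * nseg + 2
  et <- dep & (idx == 1L | idx == 2L * nseg + 2L)
  fate_region[et] <- "extrathoracic"
  lung <- dep & !et
  if (any(lung)) {
    s <- seg_of(idx[lung])
    gbl <- gb[lung]
    br <- s <= gbl
    fate_region[lung][br] <- "bronchial"
    fate_region[lung][!br] <- "acinar"
    fate_gen[lung] <- as.integer(s)
  }
  list(region = fate_region, generation = fate_gen, smax = smax,
       diam_nm = dp_nm, w_et = w_et, w_seg = w_seg,
       w_exhaled = tt$exhaled_w, seg_is_br = seg_is_br, gb = gb)
}

#' Run the deposition stage for a subject
#'
#' Simulates `n_histories` particle histories per carrier mode through the
#' nasal passage and a freshly sampled stochastic airway path each, over
#' one breathing cycle. Deposition fractions per region/generation are the
#' deposited counts over the number inhaled; deposition rates multiply the
#' fractions by the number of atoms of each nuclide inhaled per hour.
#'
#' @param scenario an [exposure_scenario()].
#' @param subject a [subject_profile()].
#' @param n_histories Monte Carlo histories per mode.
#' @param seed master seed.
#' @param modes carrier modes to simulate.
#' @param tables reference-scale [anatomy_tables()]; scaled internally.
#' @return An object of class `deposition_spectrum`: list with `table`
#'   (region, generation, nuclide, mode, fraction, fraction_se,
#'   rate_atoms_per_h), `mode_fractions` (per region x mode, nuclide
#'   independent), `extrathoracic` (named per-mode totals), `n_histories`,
#'   `seed`, `subject`, `scenario`.
#' @export
#' @examples
#' \donttest{
#' dep <- run_deposition(exposure_scenario(), subject_preset("healthy_adult"),
#'                       n_histories = 2000, seed = 1)
#' dep$extrathoracic
#' }
run_deposition <- function(scenario, subject, n_histories = 1e4, seed = 1,
                           modes = c("attached", "unattached"),
                           tables = anatomy_tables()) {
  stopifnot(n_histories >= 1)
  tab_s <- scale_tables_for_subject(tables, subject)
  conc <- progeny_activity_concentrations(scenario)
  inv <- atoms_inhaled_per_hour(conc, inhaled_air_volume(subject))

  rows <- list()
  mode_frac <- list()
  et_tot <- c()
  for (m in seq_along(modes)) {
    mode <- modes[m]
    sm <- seed + 7919 * (m - 1)
    mats <- .sample_path_matrices(tab_s, n_histories, sm)
    if (subject$asthma)
      mats <- .apply_contraction_matrices(mats, contraction_table(), sm)
    dp <- sample_particle_diameters(scenario, mode, n_histories, sm)
    fate <- .run_histories(mats, dp, subject, tab_s, sm)

    stopifnot(length(fate$region) == n_histories)  # every history decided
    # expected-value scoring: per-particle deposition weights per region
    wb <- fate$w_seg * fate$seg_is_br
    contrib <- cbind(fate$w_et, wb[, 1:21],
                     rowSums(fate$w_seg * !fate$seg_is_br),
                     fate$w_exhaled)
    frac <- colMeans(contrib)
    se <- apply(contrib, 2, stats::sd) / sqrt(n_histories)
    fr <- data.frame(
      region = c("extrathoracic", rep("bronchial", 21), "acinar",
                 "exhaled"),
      generation = c(NA, 1:21, NA, NA),
      mode = mode, fraction = frac, fraction_se = se,
      stringsAsFactors = FALSE
    )
    mode_frac[[mode]] <- fr
    et_tot[mode] <- fr$fraction[fr$region == "extrathoracic"]

    inv_m <- inv[inv$mode == mode, ]
    for (k in seq_len(nrow(inv_m))) {
      r <- fr[fr$region != "exhaled", ]
      r$nuclide <- inv_m$nuclide[k]
      r$rate_atoms_per_h <- r$fraction * inv_m$atoms_per_h[k]
      rows[[length(rows) + 1]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(
    table = out[, c("region", "generation", "nuclide", "mode", "fraction",
                    "fraction_se", "rate_atoms_per_h")],
    mode_fractions = mode_frac,
    extrathoracic = et_tot,
    n_histories = n_histories, seed = seed,
    subject = subject, scenario = scenario
  ), class = "deposition_spectrum")
}

#' Total bronchial deposition rate per airway generation
#'
#' Sums deposition rates over nuclides and carrier modes.
#'
#' @param dep a `deposition_spectrum` from [run_deposition()].
#' @return data.frame with `generation` (1-21) and `rate_atoms_per_h`.
#' @export
bronchial_deposition_rates <- function(dep) {
  b <- dep$table[dep$table$region == "bronchial", ]
  agg <- stats::aggregate(rate_atoms_per_h ~ generation, b, sum)
  agg[order(agg$generation), ]
}

#' Generation of maximum bronchial deposition rate
#'
#' @param dep a `deposition_spectrum`.
#' @return Integer generation index with the highest summed (attached +
#'   unattached, all nuclides) deposition rate.
#' @export
peak_deposition_generation <- function(dep) {
  r <- bronchial_deposition_rates(dep)
  as.integer(r$generation[which.max(r$rate_atoms_per_h)])
}

#' Simulate a single particle along a given path
#'
#' Single-history wrapper around the transport engine, useful for tracing:
#' the particle is inhaled at a random time in the inhalation phase,
#' advected down the supplied path and back, with Bernoulli deposition
#' trials in every tube and nasal passes on both ends.
#'
#' @param particle list with `diameter_nm` and `mode`.
#' @param path an `airway_path` from [sample_airway_path()].
#' @param subject a [subject_profile()] (supplies the breathing pattern).
#' @param seed integer seed.
#' @param tables scaled anatomy tables matching the path's subject.
#' @return list with `fate` (`"deposited"` or `"exhaled"`), `region` and
#'   `generation` (NA unless deposited in the lung).
#' @export
simulate_particle <- function(particle, path, subject, seed = 1,
                              tables = anatomy_tables()) {
  ng <- 21
  gb <- path$boundary_generation
  pad <- function(x, fill = NA) c(x, rep(fill, ng - length(x)))
  t <- path$tubes
  mats <- list(
    diam = matrix(pad(t$diam_um, 1), 1),
    len = matrix(pad(t$length_um, 1), 1),
    grav = matrix(c(pad(t$gravity_angle_rad, 0),
                    path$acinar_tubes$gravity_angle_rad), 1),
    branch = matrix(c(pad(t$branching_angle_rad, 0),
                      path$acinar_tubes$branching_angle_rad), 1),
    gb = gb,
    ac_diam = matrix(path$acinar_tubes$diam_um, 1),
    ac_len = matrix(path$acinar_tubes$length_um, 1),
    contracted = matrix(pad(t$is_contracted, FALSE), 1)
  )
  mats$diam[is.na(mats$diam)] <- 1
  mats$len[is.na(mats$len)] <- 1
  fate <- .run_histories(mats, particle$diameter_nm, subject, tables, seed)
  list(fate = if (fate$region[1] == "exhaled") "exhaled" else "deposited",
       region = fate$region[1], generation = fate$generation[1])
}
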