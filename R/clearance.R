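# Mucociliary clearance with decay-chain transport.
#
# Deposited progeny immediately join the mucus escalator and ride it
# proximally; the chain Po-218 -> Pb-214 -> Bi-214 -> Po-214 evolves on the
# way and the airway generation of every alpha decay (6.00 MeV from Po-218,
# 7.69 MeV from Po-214, assigned to the parent Bi-214 decay site because of
# Po-214's negligible half-life) is tallied. Atoms are tracked until they
# leave the trachea or decay through the chain; acinar deposits are not
# cleared and decay in place.

#' Mucus velocity in an airway generation
#'
#' The tracheal velocity attenuates by a factor 0.67 per generation:
#' `v(g) = v_trachea * 0.67^(g - 1)`.
#'
#' @param generation airway generation(s), 1 = trachea.
#' @param v_trachea_mm_min tracheal mucus velocity, mm/min.
#' @return Velocity in mm/min.
#' @export
#' @examples
#' mucus_velocity(1:3, 11.8)
mucus_velocity <- function(generation, v_trachea_mm_min = 11.8) {
  if (any(generation < 1)) stop("generation must be >= 1")
  v_trachea_mm_min * 0.67^(generation - 1)
}

#' Gel and sol layer thickness in an airway generation
#'
#' Anchored at the healthy-adult generation-3 values (gel 5 um atop a 6 um
#' sol layer) and scaled proportionally to the local tube diameter.
#' Children's layers are additionally scaled down by the height ratio;
#' severe asthma multiplies the gel layer (mucus hypersecretion) by the
#' subject's gel multiplier.
#'
#' @param generation airway generation (used only for documentation of the
#'   anchor; the scaling argument is the diameter).
#' @param tube_diam_um local tube diameter, um.
#' @param subject a [subject_profile()].
#' @param tables subject-scaled anatomy tables (supply the generation-3
#'   reference diameter).
#' @return list with `gel_um` and `sol_um`.
#' @export
#' @examples
#' ad <- subject_preset("healthy_adult")
#' tb <- scale_tables_for_subject(anatomy_tables(), ad)
#' mucus_thickness(3, tb$bronchial$diam_um[3], ad, tb)  # gel 5, sol 6
mucus_thickness <- function(generation, tube_diam_um, subject,
                            tables = scale_tables_for_subject(
                              anatomy_tables(), subject)) {
  stopifnot(all(tube_diam_um > 0))
  d3 <- tables$bronchial$diam_um[3]
  h <- height_scale_factor(subject)
  ratio <- tube_diam_um / d3
  list(gel_um = 5 * h * ratio * subject$mucus_gel_multiplier,
       sol_um = 6 * h * ratio)
}

#' Proximal transit schedule of a deposited atom
#'
#' Residence intervals per generation for an atom deposited on the mucus of
#' a bronchial tube, moving proximally at the local mucus velocity until it
#' exits the trachea. The deposit tube contributes only its remaining
#' (proximal) portion.
#'
#' @param deposit_generation bronchial generation of deposition.
#' @param axial_fraction position along the deposit tube, 0 = proximal end,
#'   1 = distal end.
#' @param lengths_um per-generation tube lengths (index = generation).
#' @param v_trachea_mm_min tracheal mucus velocity, mm/min.
#' @return data.frame with `generation`, `entry_s`, `exit_s` (strictly
#'   increasing), proximal order (deposit generation first, trachea last).
#' @export
transit_schedule <- function(deposit_generation, axial_fraction,
                             lengths_um, v_trachea_mm_min = 11.8) {
  g0 <- deposit_generation
  if (g0 < 1 || g0 > length(lengths_um))
    stop("deposit generation outside the bronchial range")
  stopifnot(axial_fraction >= 0, axial_fraction <= 1)
  gens <- g0:1
  len_mm <- lengths_um[gens] / 1000
  len_mm[1] <- len_mm[1] * axial_fraction     # remaining proximal portion
  v <- mucus_velocity(gens, v_trachea_mm_min)
  res_s <- len_mm / v * 60
  exit <- cumsum(res_s)
  data.frame(generation = gens, entry_s = c(0, exit[-length(exit)]),
             exit_s = exit)
}

# internal: Bateman abundances for the sub-chain starting at `start`
# (index into lambdas). Returns matrix: rows = times, cols = species
# start..3 (Po218, Pb214, Bi214 numbering), abundance per initial atom.
.bateman <- function(t, lambda, start) {
  ns <- length(lambda)
  out <- matrix(0, length(t), ns)
  for (j in start:ns) {
    li <- lambda[start:j]
    coef <- prod(li[-length(li)])
    s <- 0
    for (i in seq_along(li)) {
      denom <- prod(li[-i] - li[i])
      if (length(li) == 1) denom <- 1
      s <- s + exp(-li[i] * t) / denom
    }
    out[, j] <- coef * s
  }
  out
}

# internal: expected cumulative alpha decays by time t for one atom
# deposited as `start_nuclide`. Returns list of functions cum6(t), cum769(t).
.chain_cum_alpha <- function(start_nuclide) {
  nd <- nuclide_data()
  lambda <- nd$lambda[match(c("Po218", "Pb214", "Bi214"), nd$name)]
  start <- match(start_nuclide, c("Po218", "Pb214", "Bi214"))
  if (is.na(start)) stop("unknown start nuclide: ", start_nuclide)
  cum6 <- function(t) {
    if (start > 1) return(rep(0, length(t)))
    1 - exp(-lambda[1] * t)
  }
  cum769 <- function(t) {
    nb <- .bateman(t, lambda, start)
    # every atom eventually decays through Bi-214 -> Po-214; the cumulative
    # number of 7.69 MeV decays is 1 minus what is still upstream of it
    1 - rowSums(nb[, start:3, drop = FALSE])
  }
  list(cum6 = cum6, cum769 = cum769)
}

#' Expected alpha decays per generation for scheduled atoms (analytic)
#'
#' For each atom (a starting nuclide plus a residence schedule), integrates
#' the decay chain over each residence interval and tallies the expected
#' number of 6.00 MeV (Po-218) and 7.69 MeV (Po-214) alpha decays per
#' generation. Decays after the atom exits the trachea are not tallied.
#' An infinite final interval (`exit_s = Inf`) represents an uncleared
#' (e.g. acinar) deposit.
#'
#' @param atoms data.frame with columns `nuclide` and `weight` (atoms per
#'   hour represented by this row).
#' @param schedules list of schedules (one per row of `atoms`), each as
#'   returned by [transit_schedule()].
#' @return data.frame: `generation`, `alpha_6.00_per_h`,
#'   `alpha_7.69_per_h`.
#' @export
chain_decay_tally <- function(atoms, schedules) {
  stopifnot(nrow(atoms) == length(schedules))
  acc <- new.env()
  add <- function(gen, e6, e769) {
    key <- as.character(gen)
    cur <- if (!is.null(acc[[key]])) acc[[key]] else c(0, 0)
    acc[[key]] <- cur + c(e6, e769)
  }
  for (i in seq_len(nrow(atoms))) {
    cf <- .chain_cum_alpha(atoms$nuclide[i])
    sch <- schedules[[i]]
    w <- atoms$weight[i]
    c6 <- cf$cum6(c(sch$entry_s, sch$exit_s[nrow(sch)]))
    c769 <- cf$cum769(c(sch$entry_s, sch$exit_s[nrow(sch)]))
    for (k in seq_len(nrow(sch))) {
      add(sch$generation[k], w * (c6[k + 1] - c6[k]),
          w * (c769[k + 1] - c769[k]))
    }
  }
  gens <- sort(as.integer(ls(acc)))
  out <- data.frame(
    generation = gens,
    alpha_6.00_per_h = vapply(gens, function(g) acc[[as.character(g)]][1],
                              0),
    alpha_7.69_per_h = vapply(gens, function(g) acc[[as.character(g)]][2],
                              0)
  )
  out[order(out$generation), ]
}

#' Monte Carlo cross-check of the analytic chain tally
#'
#' Samples explicit exponential decay times down the chain for `n` atoms
#' per input row and tallies alpha decays by the generation occupied at the
#' decay time. Used to validate [chain_decay_tally()].
#'
#' @inheritParams chain_decay_tally
#' @param n Monte Carlo atoms per row.
#' @param seed integer seed.
#' @return Same layout as [chain_decay_tally()] plus `alpha_6.00_se`,
#'   `alpha_7.69_se` (binomial standard errors scaled to the row weights).
#' @export
chain_decay_tally_mc <- function(atoms, schedules, n = 1e5, seed = 1) {
  set.seed(.substream_seed(seed, "decay"))
  nd <- nuclide_data()
  lambda <- nd$lambda[match(c("Po218", "Pb214", "Bi214"), nd$name)]
  gens <- sort(unique(unlist(lapply(schedules, `[[`, "generation"))))
  t6 <- t769 <- v6 <- v769 <- stats::setNames(rep(0, length(gens)),
                                              as.character(gens))
  for (i in seq_len(nrow(atoms))) {
    start <- match(atoms$nuclide[i], c("Po218", "Pb214", "Bi214"))
    sch <- schedules[[i]]
    w <- atoms$weight[i]
    brk <- c(sch$entry_s, sch$exit_s[nrow(sch)])
    t_dec6 <- rep(Inf, n)
    t_cur <- rep(0, n)
    for (s in start:3) {
      dt <- stats::rexp(n, lambda[s])
      t_cur <- t_cur + dt
      if (s == 1) t_dec6 <- t_cur
    }
    t_dec769 <- t_cur   # Bi-214 decay time; Po-214 instantaneous
    tally1 <- function(td) {
      k <- findInterval(td, brk)
      k[td >= brk[length(brk)]] <- 0L    # after trachea exit
      gidx <- rep(0L, length(k))
      ok <- k >= 1 & k <= nrow(sch)
      gidx[ok] <- match(sch$generation[k[ok]], gens)
      tabulate(gidx, nbins = length(gens))
    }
    c6 <- tally1(t_dec6)
    c769 <- tally1(t_dec769)
    t6 <- t6 + w * c6 / n
    t769 <- t769 + w * c769 / n
    # half-count floor keeps the error estimate honest in zero-count bins
    v6 <- v6 + w^2 * (pmax(c6, 0.5) / n) * (1 - c6 / n) / n
    v769 <- v769 + w^2 * (pmax(c769, 0.5) / n) * (1 - c769 / n) / n
  }
  data.frame(generation = gens,
             alpha_6.00_per_h = unname(t6),
             alpha_7.69_per_h = unname(t769),
             alpha_6.00_se = sqrt(unname(v6)),
             alpha_7.69_se = sqrt(unname(v769)))
}

#' Decay tally for a deposition spectrum
#'
#' Pipeline stage: converts per-generation deposition rates into expected
#' alpha-decay rates per generation. Bronchial deposits ride the mucus
#' escalator (axial deposit position averaged over a uniform grid along the
#' tube); acinar deposits decay in place (infinite residence, tallied under
#' generation 0 as "acinar"). Deposits occur uniformly over the exposure
#' hour and every decay between deposition and trachea exit is credited to
#' that hour of exposure.
#'
#' @param dep a `deposition_spectrum` from [run_deposition()].
#' @param tables subject-scaled anatomy tables (central lengths drive the
#'   transit schedules).
#' @param n_axial axial positions averaged per deposit tube.
#' @param mode `"analytic"` (default) or `"mc"`.
#' @param mc_n,seed Monte Carlo controls when `mode = "mc"`.
#' @return An object of class `decay_tally`: data.frame `table`
#'   (`generation` with 0 = acinar, `alpha_6.00_per_h`,
#'   `alpha_7.69_per_h`), plus `subject` and `mode`.
#' @export
decay_tally <- function(dep,
                        tables = scale_tables_for_subject(anatomy_tables(),
                                                          dep$subject),
                        n_axial = 5, mode = c("analytic", "mc"),
                        mc_n = 1e4, seed = 1) {
  mode <- match.arg(mode)
  subject <- dep$subject
  lengths <- tables$bronchial$length_um
  vtr <- subject$mucus_velocity_trachea
  tab <- dep$table
  br <- tab[tab$region == "bronchial" & tab$rate_atoms_per_h > 0, ]
  ax <- (seq_len(n_axial) - 0.5) / n_axial

  atoms <- list()
  schedules <- list()
  for (i in seq_len(nrow(br))) {
    for (a in ax) {
      atoms[[length(atoms) + 1]] <- data.frame(
        nuclide = br$nuclide[i], weight = br$rate_atoms_per_h[i] / n_axial)
      schedules[[length(schedules) + 1]] <-
        transit_schedule(br$generation[i], a, lengths, vtr)
    }
  }
  ac <- tab[tab$region == "acinar" & tab$rate_atoms_per_h > 0, ]
  for (i in seq_len(nrow(ac))) {
    atoms[[length(atoms) + 1]] <- data.frame(
      nuclide = ac$nuclide[i], weight = ac$rate_atoms_per_h[i])
    schedules[[length(schedules) + 1]] <-
      data.frame(generation = 0L, entry_s = 0, exit_s = Inf)
  }
  atoms <- do.call(rbind, atoms)
  res <- if (mode == "analytic") chain_decay_tally(atoms, schedules)
         else chain_decay_tally_mc(atoms, schedules, n = mc_n, seed = seed)
  structure(list(table = res, subject = subject, mode = mode),
            class = "decay_tally")
}
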