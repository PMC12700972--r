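# Alpha transport and cell-nucleus dosimetry.

test_that("CSDA range is monotone and matches a quadrature oracle", {
  expect_gt(alpha_range(7.69), alpha_range(6.00))
  e <- seq(0.5, 10, by = 0.5)
  expect_true(all(diff(alpha_range(e)) > 0))
  # independent oracle: adaptive quadrature of 1/S on a spline of the table
  tab <- stopping_power_table()
  sfun <- stats::splinefun(tab$energy_MeV, tab$stopping_keV_um,
                           method = "monoH.FC")
  oracle <- function(E) 0.4 + stats::integrate(
    function(x) 1000 / sfun(x), 0.05, E, rel.tol = 1e-7,
    subdivisions = 400)$value
  for (E in c(1, 3, 6, 7.69)) {
    expect_equal(alpha_range(E), oracle(E), tolerance = 1e-4)
  }
  expect_error(alpha_range(0), "MeV")
  expect_error(alpha_range(11), "MeV")
})

test_that("residual energy obeys the CSDA identities", {
  expect_equal(energy_on_arrival(6, 0), 6)
  expect_equal(energy_on_arrival(6, alpha_range(6)), 0)
  expect_equal(energy_on_arrival(6, 1e4), 0)
  for (x in c(5, 15, 30)) {
    e1 <- energy_on_arrival(6, x)
    expect_equal(alpha_range(e1), alpha_range(6) - x, tolerance = 0.02)
    # two successive legs equal one combined leg
    expect_equal(energy_on_arrival(e1, 10), energy_on_arrival(6, x + 10),
                 tolerance = 0.005)
  }
})

test_that("layer chords agree with a fine ray-marching oracle", {
  tube <- list(diam_um = 2000, gel_um = 5, sol_um = 6)
  rl <- tube$diam_um / 2
  set.seed(4)
  n <- 1000
  r0 <- runif(n, rl, rl + tube$gel_um)
  wz <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - wz^2)
  wx <- s * cos(phi)
  wy <- s * sin(phi)
  depth <- 20
  rt <- rl + tube$gel_um + tube$sol_um + depth
  ch <- radonlung:::.chords_to_shell(r0, wx, wy, rl, rl + tube$gel_um,
                                     rl + tube$gel_um + tube$sol_um, rt)
  # oracle: step the ray at 0.01 um and accumulate per-material lengths
  step <- 0.01
  for (i in sample.int(n, 60)) {
    tt <- ch$total[i]
    if (!is.finite(tt) || tt > 6000) next
    tgrid <- seq(step / 2, tt, by = step)
    r <- sqrt((r0[i] + tgrid * wx[i])^2 + (tgrid * wy[i])^2)
    l_lum <- step * sum(r < rl)
    l_gel <- step * sum(r >= rl & r < rl + tube$gel_um)
    l_sol <- step * sum(r >= rl + tube$gel_um &
                          r < rl + tube$gel_um + tube$sol_um)
    l_tis <- step * sum(r >= rl + tube$gel_um + tube$sol_um)
    expect_lt(abs(l_lum - ch$lumen[i]), 0.05)
    expect_lt(abs(l_gel - ch$gel[i]), 0.05)
    expect_lt(abs(l_sol - ch$sol[i]), 0.05)
    expect_lt(abs(l_tis - ch$tissue[i]), 0.05)
  }
  # radially outward track from the gel: no lumen, gel chord = remaining gel
  out <- chord_through_layers(list(radius_um = rl + 1,
                                   direction = c(1, 0, 0)),
                              tube, 20)
  expect_equal(out$lumen, 0)
  expect_equal(out$gel, tube$gel_um - 1)
  expect_equal(out$sol, tube$sol_um)
  expect_equal(out$tissue, 20)
  # diametral track crosses the full lumen
  inw <- chord_through_layers(list(radius_um = rl + 1,
                                   direction = c(-1, 0, 0)),
                              tube, 20)
  expect_equal(inw$lumen, tube$diam_um)
  # pure axial track never reaches the shell
  ax <- chord_through_layers(list(radius_um = rl + 1,
                                  direction = c(0, 0, 1)),
                             tube, 20)
  expect_true(ax$miss)
})

test_that("hit probability vanishes beyond the alpha range", {
  deep <- uniform_depth_weights(50)
  thick <- list(diam_um = 600, length_um = 1650, gel_um = 30, sol_um = 6)
  hs <- hit_probability_and_energy(thick, deep, 6.00, n_samples = 2000,
                                   seed = 1)
  # 30 um gel + 6 um sol + 50 um depth > 48 um range
  expect_equal(hs$p_hit, 0)
  expect_equal(hs$energy_per_nucleus_MeV, 0)
})

test_that("tripling the gel layer lowers hit probability and energy", {
  w <- uniform_depth_weights(c(6, 14, 22))
  for (e0 in c(6.00, 7.69)) {
    h1 <- hit_probability_and_energy(small_tube, w, e0,
                                     n_samples = 20000, seed = 3)
    t3 <- small_tube
    t3$gel_um <- 3 * small_tube$gel_um
    h3 <- hit_probability_and_energy(t3, w, e0, n_samples = 20000,
                                     seed = 3)
    expect_lt(h3$p_hit, h1$p_hit)
    expect_lt(h3$energy_per_nucleus_MeV, h1$energy_per_nucleus_MeV)
    expect_lte(h1$mean_energy_MeV, e0)
  }
})

test_that("hit probability decreases with target depth", {
  p <- vapply(c(4, 16, 30, 44), function(d) {
    hit_probability_and_energy(small_tube, uniform_depth_weights(d), 6.00,
                               n_samples = 8000, seed = 2)$p_hit
  }, 0)
  expect_true(all(diff(p) < 0))
})

test_that("restricted estimator matches an unrestricted pair-sampling oracle", {
  # oracle: place nuclei uniformly on the target shell of a short tube and
  # fire isotropic alphas; count actual ray/sphere intersections
  tube <- list(diam_um = 500, length_um = 400, gel_um = 2, sol_um = 2.4)
  depth <- 10
  rho <- 4
  e0 <- 7.69
  rl <- tube$diam_um / 2
  rg <- rl + tube$gel_um
  re <- rg + tube$sol_um
  rt <- re + depth
  set.seed(9)
  n <- 1e6
  r0 <- runif(n, rl, rg)
  wz <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(pmax(1 - wz^2, 0))
  wx <- s * cos(phi)
  wy <- s * sin(phi)
  phn <- runif(n, 0, 2 * pi)
  zn <- runif(n, -tube$length_um / 2, tube$length_um / 2)
  cx <- rt * cos(phn)
  cy <- rt * sin(phn)
  # closest approach of the ray to the nucleus centre
  dx <- cx - r0
  dy <- cy
  dz <- zn
  tca <- dx * wx + dy * wy + dz * wz
  d2 <- dx^2 + dy^2 + dz^2 - pmin(tca, Inf)^2 * 0
  b2 <- dx^2 + dy^2 + dz^2 - tca^2
  hit_geom <- tca > 0 & b2 < rho^2
  # energy at the shell along hitting rays via the package chord engine
  ch <- radonlung:::.chords_to_shell(r0, wx, wy, rl, rg, re, rt)
  l_tis <- ch$gel + ch$sol + ch$tissue
  e_arr <- numeric(n)
  fin <- is.finite(l_tis)
  e_arr[fin] <- energy_on_arrival(e0, l_tis[fin])
  hit <- hit_geom & e_arr > 0
  chord <- 2 * sqrt(pmax(rho^2 - b2, 0))
  e_dep <- numeric(n)
  e_dep[hit] <- e_arr[hit] -
    energy_on_arrival(pmax(e_arr[hit], 1e-6), chord[hit])
  oracle_epn <- mean(ifelse(hit, e_dep, 0))
  oracle_se <- sd(ifelse(hit, e_dep, 0)) / sqrt(n)

  hs <- hit_probability_and_energy(tube, uniform_depth_weights(depth), e0,
                                   nucleus_diam_um = 2 * rho,
                                   n_samples = 2e5, seed = 5)
  expect_lt(abs(hs$energy_per_nucleus_MeV - oracle_epn),
            3 * sqrt(oracle_se^2 + hs$energy_per_nucleus_se^2))
})

test_that("dose rates are linear in the tally and zero without decays", {
  hs <- hit_stats_for_subject(adult, n_samples = 400, seed = 1)
  gens <- 1:21
  mk_tally <- function(f) structure(list(
    table = data.frame(generation = gens,
                       alpha_6.00_per_h = f * gens,
                       alpha_7.69_per_h = f * rev(gens)),
    subject = adult, mode = "analytic"), class = "decay_tally")
  d1 <- dose_rate(mk_tally(1), hs)
  d2 <- dose_rate(mk_tally(2), hs)
  expect_equal(d2$table$dose_rate_uGy_per_h,
               2 * d1$table$dose_rate_uGy_per_h)
  d0 <- dose_rate(mk_tally(0), hs)
  expect_true(all(d0$table$dose_rate_uGy_per_h == 0))
  # closed form: one 7.69 MeV decay, one generation
  s <- hs[hs$generation == 5 & hs$cell_type == "basal" &
            hs$energy_MeV == 7.69, ]
  t1 <- structure(list(table = data.frame(generation = 5L,
                                          alpha_6.00_per_h = 0,
                                          alpha_7.69_per_h = 1),
                       subject = adult, mode = "analytic"),
                  class = "decay_tally")
  dd <- dose_rate(t1, hs)
  m_kg <- 4 / 3 * pi * (4e-4)^3 / 1000
  want <- s$energy_per_nucleus_MeV * 1.602176634e-13 / m_kg * 1e6
  got <- dd$table$dose_rate_uGy_per_h[dd$table$generation == 5 &
                                        dd$table$cell_type == "basal"]
  expect_equal(got, want)
})

test_that("terminal bronchioles receive no basal dose", {
  hs <- hit_stats_for_subject(adult, n_samples = 300, seed = 7)
  tb <- scale_tables_for_subject(anatomy_tables(), adult)
  term <- tb$bronchial$generation[tb$bronchial$diam_um < 1000]
  bas <- hs[hs$cell_type == "basal" & hs$generation %in% term, ]
  expect_true(all(bas$p_hit == 0))
  expect_true(all(bas$energy_per_nucleus_MeV == 0))
})
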