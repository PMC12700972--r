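# Mucociliary clearance and decay-chain tallying.

test_that("mucus velocity follows the per-generation attenuation", {
  expect_equal(mucus_velocity(1, 11.8), 11.8)
  expect_equal(mucus_velocity(2, 11.8), 11.8 * 0.67)
  expect_equal(mucus_velocity(1, 2.7), 2.7)
  v <- mucus_velocity(1:21, 11.8)
  expect_true(all(diff(v) < 0))
  expect_error(mucus_velocity(0), ">= 1")
})

test_that("gel/sol thickness anchors at generation 3 and scales", {
  tb_a <- scale_tables_for_subject(anatomy_tables(), adult)
  mt <- mucus_thickness(3, tb_a$bronchial$diam_um[3], adult, tb_a)
  expect_equal(mt$gel_um, 5)
  expect_equal(mt$sol_um, 6)
  tb_s <- scale_tables_for_subject(anatomy_tables(), asthmatic)
  ms <- mucus_thickness(3, tb_s$bronchial$diam_um[3], asthmatic, tb_s)
  expect_equal(ms$gel_um, 15)
  expect_equal(ms$sol_um, 6)
  tb_c <- scale_tables_for_subject(anatomy_tables(), child)
  mc <- mucus_thickness(3, tb_c$bronchial$diam_um[3], child, tb_c)
  expect_equal(mc$gel_um, 5 * 110 / 176)
  # proportional to the local diameter
  m10 <- mucus_thickness(10, tb_a$bronchial$diam_um[10], adult, tb_a)
  expect_equal(m10$gel_um / mt$gel_um,
               tb_a$bronchial$diam_um[10] / tb_a$bronchial$diam_um[3])
})

test_that("transit schedules are additive along the escalator", {
  len <- anatomy_tables()$bronchial$length_um
  sch <- transit_schedule(10, 1, len, 11.8)
  expect_equal(sch$generation, 10:1)
  expect_true(all(diff(sch$exit_s) > 0))
  expect_true(all(sch$exit_s > sch$entry_s))
  # brute-force sum of the per-generation residence times
  res <- (len[10:1] / 1000) / (11.8 * 0.67^(9:0)) * 60
  expect_equal(sch$exit_s[10], sum(res))
  # halving velocity doubles every residence time
  sch2 <- transit_schedule(10, 1, len, 11.8 / 2)
  expect_equal(sch2$exit_s, 2 * sch$exit_s)
  # a deposit at the proximal end of the trachea exits immediately
  s0 <- transit_schedule(1, 0, len, 11.8)
  expect_equal(s0$exit_s, 0)
  expect_error(transit_schedule(25, 0.5, len), "bronchial range")
})

test_that("chain tallies honour the decay chain's structure", {
  nd <- nuclide_data()
  t12 <- nd$half_life_s[nd$name == "Po218"]
  # one Po-218 half-life in a single generation: 0.5 expected 6 MeV decays
  sch <- data.frame(generation = 5L, entry_s = 0, exit_s = t12)
  t <- chain_decay_tally(data.frame(nuclide = "Po218", weight = 1),
                         list(sch))
  expect_equal(t$alpha_6.00_per_h, 0.5, tolerance = 1e-9)
  # a Pb-214 atom never yields a 6 MeV decay
  schi <- data.frame(generation = 2L, entry_s = 0, exit_s = Inf)
  tp <- chain_decay_tally(data.frame(nuclide = "Pb214", weight = 1),
                          list(schi))
  expect_equal(tp$alpha_6.00_per_h, 0)
  expect_equal(tp$alpha_7.69_per_h, 1)
  # infinite horizon: every atom decays through Po-214 exactly once
  for (nuc in c("Po218", "Pb214", "Bi214")) {
    ti <- chain_decay_tally(data.frame(nuclide = nuc, weight = 1),
                            list(schi))
    expect_equal(sum(ti$alpha_7.69_per_h), 1, tolerance = 1e-9)
  }
  # with clearance the tallied decays can only be fewer
  schc <- transit_schedule(8, 0.7, anatomy_tables()$bronchial$length_um,
                           11.8)
  tc <- chain_decay_tally(data.frame(nuclide = "Po218", weight = 1),
                          list(schc))
  expect_lte(sum(tc$alpha_7.69_per_h), 1)
  expect_lte(sum(tc$alpha_6.00_per_h), 1)
})

test_that("analytic tally matches Monte Carlo decay-time sampling", {
  len <- anatomy_tables()$bronchial$length_um
  atoms <- data.frame(nuclide = c("Po218", "Pb214", "Bi214"),
                      weight = c(1, 1, 1))
  schedules <- list(transit_schedule(8, 0.5, len, 11.8),
                    transit_schedule(12, 0.3, len, 11.8),
                    transit_schedule(5, 0.9, len, 11.8))
  ana <- chain_decay_tally(atoms, schedules)
  mc <- chain_decay_tally_mc(atoms, schedules, n = 1e5, seed = 2)
  m <- merge(ana, mc, by = "generation", suffixes = c("_a", "_m"))
  expect_true(all(abs(m$alpha_6.00_per_h_a - m$alpha_6.00_per_h_m) <=
                    3 * m$alpha_6.00_se + 1e-6))
  expect_true(all(abs(m$alpha_7.69_per_h_a - m$alpha_7.69_per_h_m) <=
                    3 * m$alpha_7.69_se + 1e-6))
})

test_that("slower asthmatic mucus leaves more decays in the airways", {
  dep <- cached_deposition("healthy_adult")
  tb <- scale_tables_for_subject(anatomy_tables(), adult)
  t_fast <- decay_tally(dep, tables = tb)
  # identical deposits, asthmatic tracheal velocity
  dep_slow <- dep
  dep_slow$subject$mucus_velocity_trachea <- 6.3
  t_slow <- decay_tally(dep_slow, tables = tb)
  bron <- function(t) t$table[t$table$generation >= 1, ]
  expect_gte(sum(bron(t_slow)$alpha_6.00_per_h),
             sum(bron(t_fast)$alpha_6.00_per_h))
  expect_gte(sum(bron(t_slow)$alpha_7.69_per_h),
             sum(bron(t_fast)$alpha_7.69_per_h))
})

test_that("pipeline tally respects the chain bound", {
  dep <- cached_deposition("healthy_adult")
  tal <- decay_tally(dep)
  expect_true(all(tal$table$alpha_6.00_per_h >= 0))
  dep_tab <- dep$table
  total_atoms <- sum(dep_tab$rate_atoms_per_h[dep_tab$region %in%
                                                c("bronchial", "acinar")])
  expect_lte(sum(tal$table$alpha_7.69_per_h), total_atoms + 1e-9)
})
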