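# Stochastic airway geometry sampler.

test_that("height scaling is the simple height ratio", {
  expect_equal(height_scale_factor(adult), 1)
  expect_equal(height_scale_factor(child), 110 / 176)
  tiny <- subject_profile(88, 3300, 500, 12, 2.5, 2.5)
  tb <- scale_tables_for_subject(anatomy_tables(), tiny,
                                 frc_acinar_scaling = FALSE)
  ref <- anatomy_tables()
  expect_equal(tb$bronchial$diam_um, ref$bronchial$diam_um / 2)
  expect_equal(tb$bronchial$length_um, ref$bronchial$length_um / 2)
  expect_equal(tb$acinar$diam_um, ref$acinar$diam_um / 2)
  expect_error(height_scale_factor(list(height_cm = -3)), "positive")
})

test_that("adult tables are returned unchanged and child scales down", {
  ad <- scale_tables_for_subject(anatomy_tables(), adult)
  expect_equal(ad$bronchial, anatomy_tables()$bronchial)
  ch <- scale_tables_for_subject(anatomy_tables(), child)
  expect_equal(ch$bronchial$diam_um,
               anatomy_tables()$bronchial$diam_um * 110 / 176)
})

test_that("path sampling is seed-deterministic and respects structure", {
  tb <- anatomy_tables()
  p1 <- sample_airway_path(tb, seed = 5)
  p2 <- sample_airway_path(tb, seed = 5)
  expect_identical(p1, p2)
  p3 <- sample_airway_path(tb, seed = 6)
  expect_false(identical(p1$tubes$diam_um, p3$tubes$diam_um))
  # generations strictly increasing, bronchial before acinar
  expect_equal(p1$tubes$generation, seq_len(p1$boundary_generation))
  expect_equal(p1$acinar_tubes$generation,
               p1$boundary_generation + 1:9)
  expect_true(all(p1$tubes$length_um > 0 & p1$tubes$diam_um > 0))
})

test_that("zero dispersion reproduces the central-value path", {
  tb <- anatomy_tables()
  tb$bronchial$sigma_log_len[] <- 0
  tb$bronchial$sigma_log_diam[] <- 0
  p <- sample_airway_path(tb, seed = 3)
  g <- p$tubes$generation
  expect_equal(p$tubes$diam_um, tb$bronchial$diam_um[g])
  expect_equal(p$tubes$length_um, tb$bronchial$length_um[g])
})

test_that("sampled diameters centre on the table medians", {
  tb <- anatomy_tables()
  m <- radonlung:::.sample_path_matrices(tb, 10000, seed = 2)
  med <- apply(m$diam, 2, stats::median)
  expect_true(all(abs(med / tb$bronchial$diam_um - 1) < 0.05))
  # boundary generations follow the configured distribution
  expect_true(all(m$gb >= 11 & m$gb <= 21))
})

test_that("asthma contraction matches the per-generation table", {
  tb <- anatomy_tables()
  ct <- contraction_table()
  expect_equal(ct$probability[1], 0)
  expect_equal(ct$extent[4], 0.08)
  expect_equal(ct$probability[4], 0.30)
  expect_true(all(ct$probability[9:21] == 0.75 & ct$extent[9:21] == 0.25))

  m <- radonlung:::.sample_path_matrices(tb, 10000, seed = 4)
  base <- m$diam
  mc <- radonlung:::.apply_contraction_matrices(m, ct, seed = 4)
  # contracted iff diameter reduced, never the trachea, correct extent
  expect_true(all(mc$diam <= base))
  expect_true(all(mc$diam[!mc$contracted] == base[!mc$contracted]))
  expect_false(any(mc$contracted[, 1]))
  shr <- mc$diam[, 4] / base[, 4]
  expect_true(all(abs(shr[mc$contracted[, 4]] - 0.92) < 1e-12))
  expect_true(all(abs(mc$diam[, 10][mc$contracted[, 10]] /
                        base[, 10][mc$contracted[, 10]] - 0.75) < 1e-12))
  # observed contraction frequency within 3 binomial SE of the table
  for (g in c(2, 4, 8, 15)) {
    p <- ct$probability[g]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(mc$contracted[, g]) - p), 3 * se + 1e-12)
  }
})

test_that("single-path contraction API works and validates its table", {
  p <- sample_airway_path(anatomy_tables(), seed = 9)
  pc <- apply_asthma_contraction(p, seed = 9)
  expect_true(all(pc$tubes$diam_um <= p$tubes$diam_um))
  expect_false(pc$tubes$is_contracted[1])
  bad <- contraction_table()
  bad$extent[3] <- 1.4
  expect_error(apply_asthma_contraction(p, bad), "\\[0, 1\\]")
})

test_that("region classification uses strict 3 mm / 1 mm thresholds", {
  expect_equal(classify_region(3500), "large_bronchi")
  expect_equal(classify_region(2000), "bronchi")
  expect_equal(classify_region(800), "terminal_bronchioles")
  expect_equal(classify_region(3000), "bronchi")
  expect_equal(classify_region(1000), "terminal_bronchioles")
  expect_equal(classify_region(c(5000, 1500, 10)),
               c("large_bronchi", "bronchi", "terminal_bronchioles"))
  expect_error(classify_region(0), "positive")
  expect_error(classify_region(-1), "positive")
})

test_that("subject profile validation catches inconsistent inputs", {
  expect_error(subject_profile(176, 400, 500, 12, 2.5, 2.5), "FRC")
  expect_error(subject_profile(176, 3300, 500, 12, 2.0, 2.5), "60")
  expect_error(subject_profile(-1, 3300, 500, 12, 2.5, 2.5), "positive")
})

test_that("paths export to a tidy table", {
  p <- sample_airway_path(anatomy_tables(), seed = 1)
  df <- airway_paths_to_df(list(p, p))
  expect_true(all(c("path_id", "generation", "diam_um", "region_class",
                    "part") %in% names(df)))
  expect_equal(unique(df$path_id), 1:2)
  expect_equal(sum(df$part == "acinar"), 18)
})
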