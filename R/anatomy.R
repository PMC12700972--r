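# Stochastic airway geometry: the synthetic-data stage of the simulation.
#
# Root-to-terminal airway paths are sampled independently (no sibling
# airways): per-generation lengths and diameters are lognormal around the
# compiled morphometry medians, successive diameters are correlated, the
# bronchial/acinar boundary generation is drawn from its own distribution,
# and an acinar continuation is appended. For asthmatic subjects each
# bronchial tube is contracted independently with the per-generation
# probability and extent of the contraction table.

#' Scale morphometry tables to a subject
#'
#' Bronchial dimensions are multiplied by the height-derived linear factor
#' (176 cm reference adult returns the tables unchanged); acinar dimensions
#' are scaled by `(FRC / 3300 cm^3)^(1/3)` so acinar airway volume tracks
#' the subject's functional residual capacity. Relative (log-scale)
#' dispersions are kept.
#'
#' @param tables output of [anatomy_tables()] at reference scale.
#' @param subject a [subject_profile()].
#' @param frc_acinar_scaling logical; scale the acinar part by the cube
#'   root of the FRC ratio (otherwise the height factor is used there too).
#' @return Scaled tables (same structure as [anatomy_tables()]).
#' @export
#' @examples
#' ad <- scale_tables_for_subject(anatomy_tables(), subject_preset("healthy_adult"))
#' ad$bronchial$diam_um[1]  # unchanged: 18000
scale_tables_for_subject <- function(tables, subject,
                                     frc_acinar_scaling = TRUE) {
  h <- height_scale_factor(subject)
  a <- if (frc_acinar_scaling) (subject$frc_cm3 / 3300)^(1 / 3) else h
  tables$bronchial$length_um <- tables$bronchial$length_um * h
  tables$bronchial$diam_um <- tables$bronchial$diam_um * h
  tables$acinar$length_um <- tables$acinar$length_um * a
  tables$acinar$diam_um <- tables$acinar$diam_um * a
  tables$et_dead_space_cm3 <- tables$et_dead_space_cm3 * h^3
  tables$scale <- tables$scale * h
  tables
}

# internal: vectorised sampler used by both the public single-path API and
# the deposition engine. Returns matrices over n paths x 21 bronchial
# generations plus the acinar continuation (9 steps). Degenerate draws
# (daughter diameter exceeding the parent by more than 50 %) are rejected
# and redrawn, up to 100 attempts per tube.
.sample_path_matrices <- function(tables, n, seed) {
  set.seed(.substream_seed(seed, "geometry"))
  br <- tables$bronchial
  ng <- nrow(br)
  rho <- tables$rho_parent_daughter

  z <- matrix(0, n, ng)
  z[, 1] <- stats::rnorm(n)
  diam <- matrix(0, n, ng)
  diam[, 1] <- br$diam_um[1] * exp(br$sigma_log_diam[1] * z[, 1])
  for (g in 2:ng) {
    zg <- rho * z[, g - 1] + sqrt(1 - rho^2) * stats::rnorm(n)
    d <- br$diam_um[g] * exp(br$sigma_log_diam[g] * zg)
    bad <- d > 1.5 * diam[, g - 1]
    tries <- 0
    while (any(bad)) {
      tries <- tries + 1
      if (tries > 100) stop("airway sampler: resample cap exceeded")
      k <- which(bad)
      zg[k] <- rho * z[k, g - 1] + sqrt(1 - rho^2) * stats::rnorm(length(k))
      d[k] <- br$diam_um[g] * exp(br$sigma_log_diam[g] * zg[k])
      bad[k] <- d[k] > 1.5 * diam[k, g - 1]
    }
    z[, g] <- zg
    diam[, g] <- d
  }
  len <- matrix(stats::rnorm(n * ng), n, ng)
  len <- sweep(exp(sweep(len, 2, br$sigma_log_len, `*`)), 2, br$length_um, `*`)

  grav <- matrix(asin(stats::runif(n * (ng + 9))), n, ng + 9)
  branch <- matrix(pmin(pi / 2, pmax(0, stats::rnorm(
    n * (ng + 9), tables$branching_angle_mean, tables$branching_angle_sd
  ))), n, ng + 9)

  gb <- sample(tables$boundary$generation, n, replace = TRUE,
               prob = tables$boundary$prob)

  ac <- tables$acinar
  ac_diam <- sweep(exp(0.15 * matrix(stats::rnorm(n * 9), n, 9)), 2,
                   ac$diam_um, `*`)
  ac_len <- sweep(exp(0.15 * matrix(stats::rnorm(n * 9), n, 9)), 2,
                  ac$length_um, `*`)

  list(diam = diam, len = len, grav = grav, branch = branch, gb = gb,
       ac_diam = ac_diam, ac_len = ac_len,
       contracted = matrix(FALSE, n, ng))
}

# internal: apply the contraction table to the matrices of a path ensemble
.apply_contraction_matrices <- function(mats, table, seed) {
  .validate_contraction_table(table)
  set.seed(.substream_seed(seed, "geometry") %% 2147483629 + 17L)
  n <- nrow(mats$diam)
  ng <- ncol(mats$diam)
  pr <- rep(0, ng)
  ex <- rep(0, ng)
  idx <- table$generation[table$generation <= ng]
  pr[idx] <- table$probability[table$generation <= ng]
  ex[idx] <- table$extent[table$generation <= ng]
  hit <- matrix(stats::runif(n * ng), n, ng) <
    matrix(pr, n, ng, byrow = TRUE)
  fac <- 1 - matrix(ex, n, ng, byrow = TRUE) * hit
  mats$diam <- mats$diam * fac
  mats$contracted <- hit
  mats
}

.validate_contraction_table <- function(table) {
  if (!all(c("generation", "probability", "extent") %in% names(table)))
    stop("contraction table needs generation/probability/extent columns")
  if (any(table$probability < 0 | table$probability > 1) ||
      any(table$extent < 0 | table$extent > 1))
    stop("contraction probabilities and extents must lie in [0, 1]")
  invisible(TRUE)
}

#' Sample one stochastic airway path
#'
#' Draws a complete root-to-terminal path: bronchial tubes from generation
#' 1 (trachea) to the sampled bronchial/acinar boundary, followed by the
#' acinar continuation. The same seed always reproduces the same path.
#'
#' @param tables (scaled) morphometry tables, see [anatomy_tables()] and
#'   [scale_tables_for_subject()].
#' @param seed integer seed.
#' @return An object of class `airway_path`: list with `tubes` (bronchial
#'   part; data.frame with generation, length_um, diam_um,
#'   gravity_angle_rad, branching_angle_rad, region_class, is_contracted),
#'   `acinar_tubes`, and `boundary_generation`.
#' @export
#' @examples
#' p <- sample_airway_path(anatomy_tables(), seed = 1)
#' head(p$tubes)
sample_airway_path <- function(tables, seed) {
  m <- .sample_path_matrices(tables, 1, seed)
  gb <- m$gb[1]
  tubes <- data.frame(
    generation = seq_len(gb),
    length_um = m$len[1, seq_len(gb)],
    diam_um = m$diam[1, seq_len(gb)],
    gravity_angle_rad = m$grav[1, seq_len(gb)],
    branching_angle_rad = m$branch[1, seq_len(gb)],
    is_contracted = m$contracted[1, seq_len(gb)]
  )
  tubes$region_class <- classify_region(tubes$diam_um)
  acinar <- data.frame(
    generation = gb + 1:9,
    length_um = m$ac_len[1, ],
    diam_um = m$ac_diam[1, ],
    gravity_angle_rad = m$grav[1, 21 + 1:9],
    branching_angle_rad = m$branch[1, 21 + 1:9],
    is_contracted = FALSE
  )
  structure(list(tubes = tubes, acinar_tubes = acinar,
                 boundary_generation = gb, seed = seed),
            class = "airway_path")
}

#' Apply asthma-type airway contraction to a path
#'
#' Each bronchial tube is contracted independently with its generation's
#' probability; a contracted tube's diameter is reduced by the generation's
#' extent. Generations beyond the table are left unchanged; acinar tubes
#' are never contracted.
#'
#' @param path an [sample_airway_path()] result.
#' @param table a contraction table, see [contraction_table()].
#' @param seed integer seed for the Bernoulli draws.
#' @return The path with contracted diameters and updated `is_contracted`.
#' @export
apply_asthma_contraction <- function(path, table = contraction_table(),
                                     seed = 1) {
  .validate_contraction_table(table)
  set.seed(.substream_seed(seed, "geometry") %% 2147483629 + 17L)
  t <- path$tubes
  pr <- ex <- rep(0, nrow(t))
  m <- match(t$generation, table$generation)
  ok <- !is.na(m)
  pr[ok] <- table$probability[m[ok]]
  ex[ok] <- table$extent[m[ok]]
  hit <- stats::runif(nrow(t)) < pr
  t$diam_um <- t$diam_um * (1 - ex * hit)
  t$is_contracted <- hit
  t$region_class <- classify_region(t$diam_um)
  path$tubes <- t
  path
}

#' Classify an airway by its diameter
#'
#' Large bronchi have diameters above 3 mm, bronchi between 1 and 3 mm, and
#' terminal bronchioles below 1 mm. The classification is tied to the tube
#' diameter rather than the generation number because in a stochastic
#' geometry the same generation can fall in different regions on different
#' paths. Diameters of exactly 3 mm classify as bronchi and exactly 1 mm as
#' terminal bronchioles (strict "larger than" thresholds).
#'
#' @param diameter_um airway diameter(s), micrometres.
#' @return character vector in
#'   `{"large_bronchi", "bronchi", "terminal_bronchioles"}`.
#' @export
#' @examples
#' classify_region(c(3500, 2000, 800))
classify_region <- function(diameter_um) {
  if (!all(is.finite(diameter_um)) || any(diameter_um <= 0))
    stop("diameter must be positive")
  ifelse(diameter_um > 3000, "large_bronchi",
         ifelse(diameter_um > 1000, "bronchi", "terminal_bronchioles"))
}

#' Flatten airway paths to a tabular export
#'
#' @param paths a list of `airway_path` objects (or a single one).
#' @return data.frame with one row per tube: path_id, generation,
#'   length_um, diam_um, gravity_angle_rad, branching_angle_rad,
#'   region_class, is_contracted, part (bronchial/acinar).
#' @export
airway_paths_to_df <- function(paths) {
  if (inherits(paths, "airway_path")) paths <- list(paths)
  do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    b <- p$tubes
    b$part <- "bronchial"
    a <- p$acinar_tubes
    a$region_class <- "acinar"
    a$part <- "acinar"
    out <- rbind(b[, c("generation", "length_um", "diam_um",
                       "gravity_angle_rad", "branching_angle_rad",
                       "region_class", "is_contracted", "part")],
                 a[, c("generation", "length_um", "diam_um",
                       "gravity_angle_rad", "branching_angle_rad",
                       "region_class", "is_contracted", "part")])
    cbind(path_id = i, out)
  }))
}
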