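prep_strings <- function(t, params = string_params()) {
  t <- assign_compartments(t, linkage_distance = 1e6, min_size = 1)
  detect_strings(t, params)
}

test_that("is_tandem implements the geometric restraints", {
  o <- diag(3)
  p0 <- c(0, 0, 0)
  expect_true(is_tandem(p0, c(0, 0, 105), o, o))          # coaxial, in window
  expect_false(is_tandem(p0, c(105, 0, 0), o, o))         # side-by-side
  expect_false(is_tandem(p0, c(0, 0, 160), o, o))         # too far
  expect_false(is_tandem(p0, c(0, 0, 60), o, o))          # too close
  # antiparallel axes are allowed (same or opposite direction)
  expect_true(is_tandem(p0, c(0, 0, 105), o, cbxpack:::rot_x(180)))
  # perpendicular partner axis is not
  expect_false(is_tandem(p0, c(0, 0, 105), o, cbxpack:::rot_x(90)))
  # axis must lie along the string: tilt the displacement past tolerance
  d <- 105 * c(sin(40 * pi / 180), 0, cos(40 * pi / 180))
  expect_false(is_tandem(p0, d, o, o))
})

test_that("tandem pairs grow monotonically with the tolerances", {
  set.seed(51)
  for (rep in 1:20) {
    inst <- random_string_instance()
    narrow <- string_params(d_min = 95, d_max = 115, axis_parallel_tol = 10,
                            axis_displacement_tol = 15)
    wide <- string_params(d_min = 85, d_max = 130, axis_parallel_tol = 25,
                          axis_displacement_tol = 30)
    n <- nrow(inst$pos)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- is_tandem(inst$pos[i, ], inst$pos[j, ],
                     inst$orients[, , i], inst$orients[, , j], narrow)
      b <- is_tandem(inst$pos[i, ], inst$pos[j, ],
                     inst$orients[, , i], inst$orients[, , j], wide)
      if (a) expect_true(b)
    }
  }
})

test_that("detect_strings traces planted chains and honors min length", {
  t <- straight_string_table(5)
  s <- prep_strings(t, string_params(min_string_length = 3))
  expect_equal(length(s$strings), 1)
  expect_equal(s$strings[[1]]$length, 5)
  expect_equal(s$strings[[1]]$particle_ids, sprintf("p%04d", 1:5))
  expect_equal(s$strings[[1]]$step_distances_A, rep(105, 4), tolerance = 1e-9)
  # break the middle particle: fragments of 2 fail a min length of 3
  tb <- t
  tb$tilt_deg[3] <- tb$tilt_deg[3] + 90
  sb <- prep_strings(tb, string_params(min_string_length = 3))
  expect_equal(length(sb$strings), 0)
  sb2 <- prep_strings(tb, string_params(min_string_length = 2))
  expect_equal(sort(vapply(sb2$strings, `[[`, 0L, "length")), c(2L, 2L))
})

test_that("detect_strings equals the exhaustive maximal-path oracle", {
  set.seed(52)
  params <- string_params()
  for (rep in 1:60) {
    inst <- random_string_instance()
    t <- table_from_geometry(inst$pos, inst$orients)
    s <- prep_strings(t, params)
    axes <- t(vapply(seq_len(nrow(inst$pos)),
                     function(i) inst$orients[, 3, i], numeric(3)))
    oracle <- enumerate_strings_oracle(inst$pos, axes, params)
    expect_same_strings(s, oracle)
    # no particle may sit on two strings
    rows <- unlist(lapply(s$strings, `[[`, "rows"))
    expect_equal(anyDuplicated(rows), 0)
  }
})

test_that("string detection is invariant under rigid motions and D4 moves", {
  set.seed(53)
  cfg <- generator_config("halo", seed = 53, fp_rate = 0)
  sim <- generate_halo(cfg, 2)
  t <- assign_compartments(sim$table)
  base <- detect_strings(t)
  sig <- function(s) lapply(s$strings, function(x) x$particle_ids)
  # global rigid motion
  R <- cbxpack:::rotation_about_axis(c(-1, 1, 2), 123)
  moved <- assign_compartments(transform_particles(sim$table, R, c(300, 40, -80)))
  expect_identical(sig(detect_strings(moved)), sig(base))
  # right-multiply random particles by random D4 elements
  els <- sym_elements(point_symmetry("D", 4))
  ori <- particle_orientations(t)
  df <- as.data.frame(t)
  for (i in sample(nrow(df), 40)) {
    e <- matrix_to_euler(ori[, , i] %*% els[[sample(8, 1)]])
    df$rot_deg[i] <- e[1]; df$tilt_deg[i] <- e[2]; df$psi_deg[i] <- e[3]
  }
  t2 <- assign_compartments(particle_table(df[, cbxpack:::PT_COLUMNS]))
  expect_identical(sig(detect_strings(t2)), sig(base))
})

test_that("string statistics recover a planted noise-free bundle exactly", {
  cfg <- generator_config("halo", seed = 54, pos_jitter_sd = 0,
                          ang_jitter_sd = 0, fp_rate = 0,
                          string_count_mean = 12, string_count_sd = 0,
                          string_count_min = 12, string_count_max = 12,
                          count_mean = 0, count_sd = 0, count_min = 0,
                          count_max = 0)   # strings only, no background
  sim <- generate_halo(cfg, 1)
  t <- assign_compartments(sim$table)
  s <- detect_strings(t)
  st <- string_statistics(s, t)
  planted <- sort(sim$truth$strings$length)
  expect_equal(sort(st$lengths), planted)
  expect_equal(unname(st$count), length(planted))
  expect_equal(st$frac_in_strings, 1)
})

test_that("string twists recover the planted per-step rotation", {
  t <- straight_string_table(6, twist = 0, axis = c(1, 1, 0))
  s <- prep_strings(t)
  tw <- string_twists(s, t)
  expect_equal(tw$steps, rep(0, 5), tolerance = 1e-9)
  t2 <- straight_string_table(8, twist = 7.3, axis = c(0.2, -0.5, 1))
  s2 <- prep_strings(t2)
  tw2 <- string_twists(s2, t2)
  expect_equal(tw2$steps, rep(7.3, 7), tolerance = 1e-6)
  expect_equal(tw2$mean_deg, 7.3, tolerance = 1e-6)
})

test_that("coordination counts parallel lattice neighbors", {
  # two parallel strings: one neighbor each
  t <- rbind_tables(straight_string_table(4),
                    straight_string_table(4, origin = c(110, 0, 0),
                                          spin0 = 30))
  s <- prep_strings(t)
  co <- string_coordination(s)
  expect_equal(co$coordination, c(1L, 1L))
  expect_equal(co$modal_coordination, 1L)
  # hexagonal 7-string bundle: central string has 6 neighbors
  cfg <- generator_config("halo", seed = 55, pos_jitter_sd = 0,
                          ang_jitter_sd = 0, fp_rate = 0,
                          string_count_mean = 7, string_count_sd = 0,
                          string_count_min = 7, string_count_max = 7,
                          string_length_mean = 4, string_length_sd = 0,
                          string_length_min = 4, string_length_max = 4,
                          count_mean = 0, count_sd = 0, count_min = 0,
                          count_max = 0)
  sim <- generate_halo(cfg, 1)
  th <- assign_compartments(sim$table)
  sh <- detect_strings(th)
  coh <- string_coordination(sh)
  expect_equal(length(sh$strings), 7)
  expect_equal(sort(coh$coordination), c(rep(3L, 6), 6L))
  expect_equal(max(coh$coordination), 6L)
})

test_that("classification follows the four ordering classes", {
  expect_equal(classify_compartment(integer(0)), "random")
  expect_equal(classify_compartment(c(2, 2)), "random")
  expect_equal(classify_compartment(c(2, 4)), "short")
  expect_equal(classify_compartment(c(6, 6)), "short")
  expect_equal(classify_compartment(c(8, rep(2, 5))), "moderate")
  expect_equal(classify_compartment(c(8, rep(7, 5))), "high")
  expect_equal(classify_compartment(rep(7, 5)), "high")
  expect_equal(classify_compartment(rep(7, 4)), "moderate")
})

test_that("population summary computes ordered and in-string fractions", {
  # fabricate: 2 compartments, one ordered with 20 of 250 particles in strings
  df <- data.frame(
    particle_id = sprintf("p%04d", 1:400), tomogram_id = "t",
    x_A = stats::runif(400, 0, 4000), y_A = 0, z_A = 0,
    rot_deg = 0, tilt_deg = 0, psi_deg = 0, score = 0.2)
  t <- particle_table(df)
  t$compartment_id <- rep(c("c1", "c2"), c(250, 150))
  strings <- structure(list(strings = list(
    list(particle_ids = df$particle_id[1:12], rows = 1:12,
         compartment_id = "c1", length = 12L),
    list(particle_ids = df$particle_id[13:20], rows = 13:20,
         compartment_id = "c1", length = 8L)),
    assignment = rep(NA_integer_, 400)), class = "cbx_strings")
  classes <- c(c1 = "moderate", c2 = "random")
  ps <- population_summary(classes, strings, t)
  expect_equal(ps$ordered_fraction, 0.5)
  expect_equal(ps$in_string_fraction, 0.08)
  expect_equal(unname(ps$class_counts), c(1L, 0L, 1L, 0L))
  # all random -> ordered fraction 0 and no in-string denominator
  ps0 <- population_summary(c(c1 = "random", c2 = "random"), strings, t)
  expect_equal(ps0$ordered_fraction, 0)
})
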