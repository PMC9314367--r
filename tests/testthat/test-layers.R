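test_that("single-linkage assignment separates well-spaced clouds", {
  set.seed(31)
  cloud <- function(ctr, n = 30) sweep(matrix(stats::rnorm(3 * n, sd = 60), n, 3), 2, ctr, `+`)
  pos <- rbind(cloud(c(0, 0, 0)), cloud(c(5000, 0, 0)))
  t <- table_from_geometry(pos, cbxpack:::random_rotations(60))
  t <- assign_compartments(t)
  expect_equal(length(unique(stats::na.omit(t$compartment_id))), 2)
  expect_equal(length(unique(t$compartment_id[1:30])), 1)
  # one cloud -> one compartment holding everything
  t1 <- table_from_geometry(cloud(c(0, 0, 0), 40), cbxpack:::random_rotations(40))
  t1 <- assign_compartments(t1)
  expect_equal(as.vector(table(t1$compartment_id)), 40L)
  # tiny components stay unassigned
  pos2 <- rbind(cloud(c(0, 0, 0), 30), cloud(c(5000, 0, 0), 5))
  t2 <- table_from_geometry(pos2, cbxpack:::random_rotations(35))
  t2 <- assign_compartments(t2, min_size = 20)
  expect_true(all(is.na(t2$compartment_id[31:35])))
  # empty input passes through
  empty <- t2[0, , drop = FALSE]; class(empty) <- class(t2)
  expect_equal(nrow(assign_compartments(empty)), 0)
})

test_that("assignment matches ground truth on a multi-carboxysome tomogram", {
  cfg <- generator_config("halo", seed = 32, fp_rate = 0)
  sim <- generate_halo(cfg, 4)
  t <- assign_compartments(sim$table)
  tab <- table(sim$truth$particles$cbx_id, t$compartment_id, useNA = "ifany")
  # every planted carboxysome maps to exactly one detected compartment
  expect_equal(nrow(tab), 4)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("filtering removes low scores, strays and false positives", {
  cfg <- generator_config("halo", seed = 33, fp_rate = 0.05)
  sim <- generate_halo(cfg, 4)
  t <- assign_compartments(sim$table)
  tf <- filter_particles(t)
  rep_ <- attr(tf, "filter_report")
  expect_equal(rep_$kept, nrow(tf))
  is_fp <- sim$truth$particles$label == "false_positive"
  kept_fp <- sum(tf$particle_id %in% sim$truth$particles$particle_id[is_fp])
  expect_gte(1 - kept_fp / sum(is_fp), 0.9)   # >= 90% of planted FPs removed
  kept_true <- sum(tf$particle_id %in% sim$truth$particles$particle_id[!is_fp])
  expect_gte(kept_true / sum(!is_fp), 0.97)   # nearly all true particles kept
  # identity when everything is clean and close
  clean <- generate_halo(generator_config("halo", seed = 34, fp_rate = 0), 1)
  tc <- assign_compartments(clean$table)
  expect_equal(nrow(filter_particles(tc)), nrow(tc))
  # a particle far from every center is dropped
  far <- as.data.frame(tc)[1, ]
  far$particle_id <- "stray"; far$x_A <- far$x_A + 10000
  t3 <- particle_table(rbind(as.data.frame(tc)[, names(far)], far))
  t3 <- assign_compartments(t3)
  expect_false("stray" %in% filter_particles(t3)$particle_id)
})

test_that("compartment geometry reproduces planted radii and angles", {
  cfg <- generator_config("cyanobium", seed = 35, pos_jitter_sd = 0,
                          ang_jitter_sd = 0)
  sim <- generate_cyanobium(cfg, 2)
  t <- assign_compartments(sim$table)
  geom <- compartment_geometry(t)
  expect_equal(nrow(geom$compartments), 2)
  r <- geom$table$r_A
  planted <- cfg$layer_radii[sim$truth$particles$layer]
  expect_equal(r, planted, tolerance = 1e-6)
  th <- geom$table$theta_deg
  expect_equal(th[is.finite(th)], rep(15, sum(is.finite(th))), tolerance = 1e-6)
})

test_that("degenerate and tangential axes give theta of NA, 0 or 90", {
  # symmetric point set (mean exactly at the origin): one particle at the
  # center, six on the +-x/+-y/+-z axes
  pos <- rbind(c(0, 0, 0), c(300, 0, 0), c(-300, 0, 0), c(0, 300, 0),
               c(0, -300, 0), c(0, 0, 300), c(0, 0, -300))
  ori <- array(diag(3), c(3, 3, 7))
  ori[, , 2] <- cbxpack:::rot_y(90)    # axis = +x = radial -> 0 deg
  t <- table_from_geometry(pos, ori)
  t <- assign_compartments(t, linkage_distance = 1000, min_size = 1)
  geom <- compartment_geometry(t)
  th <- geom$table$theta_deg
  expect_true(is.na(th[1]))                      # r = 0: undefined, excluded
  expect_equal(th[2], 0, tolerance = 1e-9)       # axis radial
  expect_equal(th[3], 90, tolerance = 1e-9)      # z-axis vs -x radial
  expect_equal(th[4], 90, tolerance = 1e-9)      # z-axis vs +y radial
  expect_equal(th[6], 0, tolerance = 1e-9)       # axis = radial = +z
  expect_equal(th[7], 0, tolerance = 1e-9)       # antiparallel folds to 0
})

test_that("radial profile finds a single planted shell at its radius", {
  cfg <- generator_config("cyanobium", seed = 36, layer_radii = 300,
                          pos_jitter_sd = 0, ang_jitter_sd = 0,
                          count_mean = 70, count_sd = 0,
                          count_min = 70, count_max = 70)
  sim <- generate_cyanobium(cfg, 1)
  geom <- compartment_geometry(assign_compartments(sim$table))
  rp <- radial_profile(geom)
  expect_equal(length(rp$peaks_A), 1)
  expect_lt(abs(rp$peaks_A - 300), 5)
  expect_equal(sum(rp$counts), 70)
  # all particles assigned to the single layer
  expect_true(all(stats::na.omit(rp$layer) == 1))
})

test_that("close shells may merge but the peak count reports it", {
  cfg <- generator_config("cyanobium", seed = 37, layer_radii = c(300, 330),
                          pos_jitter_sd = 2, count_mean = 80, count_sd = 0,
                          count_min = 80, count_max = 80)
  sim <- generate_cyanobium(cfg, 2)
  geom <- compartment_geometry(assign_compartments(sim$table))
  rp <- radial_profile(geom, bandwidth = 8)
  # resolution bound: 30 A apart at 8 A bandwidth -> one or two peaks, and the
  # count is reported rather than silently collapsed
  expect_true(length(rp$peaks_A) %in% c(1, 2))
  expect_true(all(rp$peaks_A > 280 & rp$peaks_A < 350))
})

test_that("peak detection agrees with an independent kernel-sum grid scan", {
  set.seed(38)
  for (i in 1:25) {
    mu <- stats::runif(1, 150, 450)
    r <- stats::rnorm(400, mu, stats::runif(1, 4, 10))
    t <- table_from_geometry(cbind(r, 0, 0) %*% diag(3),
                             cbxpack:::random_rotations(400))
    # fabricate a geometry object directly: r values are what matters
    g <- structure(list(
      table = within(as.data.frame(t), {
        compartment_id <- "c1"; r_A <- r; theta_deg <- NA_real_
      }),
      compartments = data.frame(compartment_id = "c1", tomogram_id = "t",
                                n = 400, cx = 0, cy = 0, cz = 0,
                                mean_median_gap = 0, small = FALSE)),
      class = "cbx_geometry")
    rp <- radial_profile(g, bandwidth = 8)
    # independent oracle: explicit gaussian kernel sum on a fine grid
    grid <- seq(0, max(r) + 30, by = 0.25)
    dens <- vapply(grid, function(x) sum(stats::dnorm(x, r, 8)), numeric(1))
    expect_equal(length(rp$peaks_A), 1)
    expect_lt(abs(rp$peaks_A - grid[which.max(dens)]), 1)
  }
})

test_that("angular profile: radial axes give mode 0; random axes follow sin",
{
  cfg <- generator_config("cyanobium", seed = 39, layer_tilt = 0,
                          pos_jitter_sd = 0, ang_jitter_sd = 0)
  sim <- generate_cyanobium(cfg, 1)
  geom <- compartment_geometry(assign_compartments(sim$table))
  ap <- angular_profile(geom)
  expect_equal(ap$mode_deg, 1.25)   # midpoint of the first 2.5-degree bin
  # uniform random axes: theta has density sin(theta) on [0, 90]
  set.seed(40)
  n <- 4000
  pos <- cbxpack:::runif_sphere_surface(n, 300)
  t <- table_from_geometry(pos, cbxpack:::random_rotations(n))
  geom2 <- compartment_geometry(assign_compartments(t, linkage_distance = 1e5))
  th <- geom2$table$theta_deg
  ks <- stats::ks.test(th, function(q) 1 - cos(q * pi / 180))
  expect_gt(ks$p.value, 0.01)
})

test_that("nearest-neighbor distances: chains and pairs", {
  pos <- cbind(seq(0, 900, by = 100), 0, 0)
  t <- table_from_geometry(pos, cbxpack:::random_rotations(10))
  geom <- compartment_geometry(assign_compartments(t, linkage_distance = 150,
                                                   min_size = 2))
  nn <- neighbor_distances(geom)
  expect_equal(unname(nn$nn_A), rep(100, 10))
  expect_equal(unname(nn$summary["mean"]), 100)
  pos2 <- rbind(c(0, 0, 0), c(0, 0, 120))
  t2 <- table_from_geometry(pos2, cbxpack:::random_rotations(2))
  geom2 <- compartment_geometry(assign_compartments(t2, min_size = 2))
  expect_equal(unname(neighbor_distances(geom2)$nn_A), c(120, 120))
})

test_that("particle counts recover the planted population", {
  cfg <- generator_config("halo", seed = 41, fp_rate = 0)
  sim <- generate_halo(cfg, 6)
  geom <- compartment_geometry(filter_particles(assign_compartments(sim$table)))
  cp <- count_particles(geom)
  planted <- table(sim$truth$particles$cbx_id)
  expect_equal(sort(unname(cp$counts)), sort(as.vector(planted)),
               tolerance = 0.02)
  expect_equal(cp$mean, mean(planted), tolerance = 0.02)
})

test_that("layer statistics are invariant under a global rigid motion", {
  cfg <- generator_config("cyanobium", seed = 43)
  sim <- generate_cyanobium(cfg, 2)
  R <- cbxpack:::rotation_about_axis(c(1, 2, 3), 55)
  moved <- transform_particles(sim$table, R, shift = c(1000, -500, 250))
  g1 <- compartment_geometry(assign_compartments(sim$table))
  g2 <- compartment_geometry(assign_compartments(moved))
  expect_equal(g2$table$r_A, g1$table$r_A, tolerance = 1e-6)
  expect_equal(g2$table$theta_deg, g1$table$theta_deg, tolerance = 1e-6)
  expect_equal(radial_profile(g2)$peaks_A, radial_profile(g1)$peaks_A,
               tolerance = 1e-6)
})
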