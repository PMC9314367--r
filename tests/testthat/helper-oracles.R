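# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the code paths they check: the twist oracle uses
# transverse-vector projection plus explicit group-orbit enumeration; the
# string oracle re-derives tandem pairs by direct per-pair arithmetic and
# enumerates maximal simple paths by exhaustive DFS.

wrap180 <- function(a) ((a + 180) %% 360) - 180

# signed twist about the shared axis via transverse projection; exact when the
# two orientations share their symmetry axis
transverse_twist <- function(o1, o2) {
  u <- o1[, 3]
  p1 <- o1[, 1]
  p2 <- o2[, 1] - sum(o2[, 1] * u) * u
  cr <- c(p1[2] * p2[3] - p1[3] * p2[2],
          p1[3] * p2[1] - p1[1] * p2[3],
          p1[1] * p2[2] - p1[2] * p2[1])
  atan2(sum(u * cr), sum(p1 * p2)) * 180 / pi
}

# brute-force canonical twist: minimum over the full two-sided group orbit,
# restricted to the axis-aligned combinations (the others violate the
# collinearity precondition)
orbit_twist_oracle <- function(o1, o2, sym = point_symmetry("D", 4)) {
  best <- Inf
  for (g1 in sym_elements(sym)) for (g2 in sym_elements(sym)) {
    a <- o1 %*% g1
    b <- o2 %*% g2
    if (sum(a[, 3] * b[, 3]) < 1 - 1e-9) next
    best <- min(best, abs(wrap180(transverse_twist(a, b))))
  }
  best
}

# orbit-enumeration oracle for fold_to_range
fold_oracle <- function(angle, order, signed) {
  period <- 360 / order
  cand <- as.vector(outer(if (signed) c(angle, -angle) else angle,
                          (-10:10) * period, `+`))
  min(cand[cand >= -1e-12])
}

# exhaustive string detector: direct pair recomputation, the same greedy
# branch resolution, then DFS enumeration of all maximal simple paths
enumerate_strings_oracle <- function(pos, axes, params) {
  n <- nrow(pos)
  ei <- integer(0); ej <- integer(0); esc <- numeric(0)
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    disp <- pos[j, ] - pos[i, ]
    d <- sqrt(sum(disp^2))
    if (d < params$d_min || d > params$d_max) next
    if (axis_angle(axes[i, ], axes[j, ]) > params$axis_parallel_tol) next
    ai <- axis_angle(axes[i, ], disp)
    aj <- axis_angle(axes[j, ], disp)
    if (ai > params$axis_displacement_tol || aj > params$axis_displacement_tol) next
    ei <- c(ei, i); ej <- c(ej, j); esc <- c(esc, ai + aj)
  }
  ord <- order(esc, ei, ej)
  deg <- integer(n); comp <- seq_len(n)
  adj <- vector("list", n)
  for (e in ord) {
    i <- ei[e]; j <- ej[e]
    if (deg[i] >= 2L || deg[j] >= 2L) next
    if (comp[i] == comp[j]) next
    comp[comp == comp[j]] <- comp[i]
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  paths <- list()
  extend <- function(path) {
    nxt <- setdiff(adj[[path[length(path)]]], path)
    if (!length(nxt)) {
      if (!length(setdiff(adj[[path[1]]], path)))
        paths[[length(paths) + 1L]] <<- path
    } else for (v in nxt) extend(c(path, v))
  }
  for (s in seq_len(n)) if (length(adj[[s]])) extend(s)
  paths <- unique(lapply(paths, function(p)
    if (p[1] > p[length(p)]) rev(p) else p))
  Filter(function(p) length(p) >= params$min_string_length, paths)
}

# ---- fixture builders ---------------------------------------------------------

rand_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

# particle table from explicit positions (n x 3) and orientations (3 x 3 x n)
table_from_geometry <- function(pos, orients, tomogram = "tomo_001",
                                score = NA_real_) {
  n <- nrow(pos)
  e <- t(vapply(seq_len(n), function(i) matrix_to_euler(orients[, , i]),
                numeric(3)))
  particle_table(data.frame(
    particle_id = sprintf("p%04d", seq_len(n)), tomogram_id = tomogram,
    x_A = pos[, 1], y_A = pos[, 2], z_A = pos[, 3],
    rot_deg = e[, 1], tilt_deg = e[, 2], psi_deg = e[, 3],
    score = score, stringsAsFactors = FALSE))
}

# straight string of L particles along `axis` with per-step twist
straight_string_table <- function(L, step = 105, twist = 7.3,
                                  axis = c(0, 0, 1), spin0 = 0,
                                  origin = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  base <- cbxpack:::frame_from_axis(axis) %*% cbxpack:::rot_z(spin0)
  pos <- t(vapply(seq_len(L) - 1, function(k) origin + k * step * axis,
                  numeric(3)))
  orients <- array(0, c(3, 3, L))
  for (k in seq_len(L))
    orients[, , k] <- cbxpack:::rotation_about_axis(axis, (k - 1) * twist) %*% base
  table_from_geometry(pos, orients)
}

# random small instance for the string oracle: a planted string plus clutter
random_string_instance <- function() {
  n_extra <- sample(0:6, 1)
  L <- sample(0:6, 1)
  pos <- matrix(stats::runif(3 * n_extra, 0, 450), ncol = 3)
  orients <- if (n_extra) cbxpack:::random_rotations(n_extra) else array(0, c(3, 3, 0))
  if (L >= 2) {
    ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
    st <- straight_string_table(L, step = stats::runif(1, 90, 125),
                                twist = stats::runif(1, 0, 20), axis = ax,
                                origin = stats::runif(3, 100, 300))
    spos <- particle_positions(st)
    sori <- particle_orientations(st)
    # perturb to exercise tolerance boundaries
    spos <- spos + matrix(stats::rnorm(3 * L, sd = 6), ncol = 3)
    J <- cbxpack:::jitter_rotations(L, 6)
    for (k in seq_len(L)) sori[, , k] <- J[, , k] %*% sori[, , k]
    pos <- rbind(pos, spos)
    orients <- array(c(orients, sori), c(3, 3, n_extra + L))
  }
  n <- nrow(pos)
  if (n < 2) return(random_string_instance())
  list(pos = pos, orients = orients)
}

expect_same_strings <- function(detected, oracle_paths) {
  det <- lapply(detected$strings, function(s) {
    p <- s$rows
    if (p[1] > p[length(p)]) rev(p) else p
  })
  canon <- function(l) l[order(vapply(l, function(p) paste(p, collapse = ","), ""))]
  expect_identical(canon(det), canon(oracle_paths))
}

# concatenate two particle tables with disambiguated ids
rbind_tables <- function(a, b) {
  ad <- as.data.frame(a)[, cbxpack:::PT_COLUMNS]
  bd <- as.data.frame(b)[, cbxpack:::PT_COLUMNS]
  bd$particle_id <- paste0("b_", bd$particle_id)
  particle_table(rbind(ad, bd))
}
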