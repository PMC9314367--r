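# Synthetic carboxysome generator with planted ground truth.
#
# Two presets encode the two experimentally characterized packing regimes:
#   * "cyanobium": three concentric shells of particles (radii 208/308/413 A)
#     with the fourfold axis tilted ~15 deg off the radial direction, counts
#     Normal(224, 26) per carboxysome;
#   * "halo": a central bundle of near-parallel strings of axially stacked
#     particles on a hexagonal lattice (spacing 110 A, axial step 105 A,
#     7.3 deg twist per step; string count Normal(12, 6), length Normal(5, 2)
#     clipped to [2, 9]), a disordered remainder filling the compartment to a
#     total of Normal(274, 72) particles.
# Positional/angular jitter, false positives outside the compartment and
# simulated cross-correlation scores make every downstream filter testable.
# Each generated particle carries exactly one ground-truth label.

#' Generator configuration
#'
#' Builds a validated configuration for the synthetic carboxysome generator.
#' Presets carry the layer / string parameters of the two characterized
#' alpha-carboxysome types; any field can be overridden by name.
#'
#' @param preset `"cyanobium"`, `"halo"` or `"custom"` (custom starts from the
#'   halo geometry with no strings planted unless overridden).
#' @param ... Named overrides of any config field, e.g. `pos_jitter_sd = 0`.
#'   Fields: `layer_radii` (A), `layer_tilt` (deg), `count_mean`, `count_sd`,
#'   `count_min`, `count_max` (particles per carboxysome),
#'   `string_count_mean/sd/min/max`, `string_length_mean/sd/min/max`,
#'   `string_step` (A along the axis), `lattice_spacing` (A between adjacent
#'   strings), `step_twist` (deg per tandem step), `compartment_radius` (A),
#'   `min_separation` (A), `pos_jitter_sd` (A), `ang_jitter_sd` (deg),
#'   `fp_rate` (fraction of spurious particles in \[0,1)), `score_true`,
#'   `score_fp` (uniform score ranges), `class_mix` (4 fractions for
#'   [generate_population()]), `carboxysomes_per_tomogram`, `tomogram_spacing`
#'   (A), `seed`.
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config("cyanobium", pos_jitter_sd = 0, seed = 1)
#' @export
generator_config <- function(preset = c("cyanobium", "halo", "custom"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    # concentric-layer geometry (cyanobium regime)
    layer_radii = c(208, 308, 413),
    layer_tilt = 15,
    # particle counts per carboxysome
    count_mean = 224, count_sd = 26, count_min = 100, count_max = 300,
    # string-bundle geometry (halo regime)
    string_count_mean = 12, string_count_sd = 6,
    string_count_min = 2, string_count_max = 35,
    string_length_mean = 5, string_length_sd = 2,
    string_length_min = 2, string_length_max = 9,
    string_step = 105, lattice_spacing = 110, step_twist = 7.3,
    # compartment envelope and packing
    compartment_radius = 480, min_separation = 90,
    # noise model
    pos_jitter_sd = 4, ang_jitter_sd = 3, fp_rate = 0,
    score_true = c(0.1, 0.3), score_fp = c(0.0, 0.12),
    # ordering-class mixture for generate_population (random, short, moderate, high)
    class_mix = c(0.62, 0, 0.19, 0.19),
    # tomogram layout
    carboxysomes_per_tomogram = 4, tomogram_spacing = 1600,
    seed = 1L)
  if (preset == "halo") {
    base$count_mean <- 274; base$count_sd <- 72
    base$count_min <- 50; base$count_max <- 450
    base$compartment_radius <- 500
  }
  if (preset == "custom") {
    base$count_mean <- 274; base$count_sd <- 72
    base$count_min <- 50; base$count_max <- 450
    base$compartment_radius <- 500
    base$string_count_mean <- 0; base$string_count_sd <- 0
    base$string_count_min <- 0
  }
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stopf("unknown generator config field(s): %s", paste(unknown, collapse = ", "))
  base[names(over)] <- over
  validate_generator_config(structure(base, class = "generator_config"))
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (any(layer_radii <= 0) || is.unsorted(layer_radii, strictly = TRUE))
      stopf("layer_radii must be positive and strictly increasing")
    if (string_length_min < 2) stopf("string_length_min must be >= 2")
    if (any(c(count_sd, string_count_sd, string_length_sd,
              pos_jitter_sd, ang_jitter_sd) < 0))
      stopf("all jitter/sd fields must be >= 0")
    if (fp_rate < 0 || fp_rate >= 1) stopf("fp_rate must lie in [0, 1)")
    if (min_separation <= 0 || string_step <= 0 || lattice_spacing <= 0)
      stopf("distances must be positive")
    if (length(class_mix) != 4 || any(class_mix < 0))
      stopf("class_mix must be 4 non-negative fractions")
  })
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config preset=%s seed=%s>\n", x$preset, x$seed))
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Read / write generator configs as YAML
#'
#' The file may name a `preset`; remaining keys override preset defaults
#' (preset inheritance).
#'
#' @param path YAML file.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "custom"
  y$preset <- NULL
  do.call(generator_config, c(list(preset = preset), y))
}

#' @rdname read_generator_config
#' @param cfg A [generator_config()].
#' @export
write_generator_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---- internal sampling helpers ------------------------------------------------

draw_count <- function(n, mean, sd, lo, hi) {
  pmin(pmax(round(stats::rnorm(n, mean, sd)), lo), hi)
}

# uniform random points on a sphere of radius r (n x 3)
runif_sphere_surface <- function(n, r) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  r * cbind(s * cos(phi), s * sin(phi), z)
}

# uniform random points in a spherical shell r_in..r_out (volume-weighted)
runif_sphere_volume <- function(n, r_out, r_in = 0) {
  u <- stats::runif(n)
  r <- (r_in^3 + u * (r_out^3 - r_in^3))^(1 / 3)
  runif_sphere_surface(n, 1) * r
}

# Sequentially place n points drawn by `propose(k)` (k x 3) subject to a
# minimum pairwise separation against `existing` and among themselves.
place_with_separation <- function(n, propose, min_sep, existing = NULL,
                                  max_batches = 60, batch = 256,
                                  context = "particles") {
  placed <- matrix(numeric(0), 0, 3)
  all_pts <- if (is.null(existing)) placed else existing
  min2 <- min_sep^2
  for (i in seq_len(n)) {
    ok <- FALSE
    for (b in seq_len(max_batches)) {
      cand <- propose(batch)
      if (nrow(all_pts)) {
        for (j in seq_len(nrow(cand))) {
          d2 <- (all_pts[, 1] - cand[j, 1])^2 + (all_pts[, 2] - cand[j, 2])^2 +
                (all_pts[, 3] - cand[j, 3])^2
          if (min(d2) >= min2) {
            placed <- rbind(placed, cand[j, ]); all_pts <- rbind(all_pts, cand[j, ])
            ok <- TRUE; break
          }
        }
      } else {
        placed <- rbind(placed, cand[1, ]); all_pts <- rbind(all_pts, cand[1, ])
        ok <- TRUE
      }
      if (ok) break
    }
    if (!ok)
      stopf(paste0("cannot place %d %s at min_separation %.0f A ",
                   "(placed %d); reduce the count or the separation"),
            n, context, min_sep, i - 1)
  }
  placed
}

# orientation with fourfold axis along `axis` tilted by `tilt` deg toward a
# random azimuth, with a uniform random spin about the final axis
tilted_orientation <- function(axis, tilt) {
  A <- frame_from_axis(axis)
  # tilt toward a random azimuth, then spin: A Rz(phi) Ry(tilt) Rz(spin)
  A %*% rot_z(stats::runif(1, 0, 360)) %*% rot_y(tilt) %*%
    rot_z(stats::runif(1, 0, 360))
}

euler_df <- function(orients) {
  n <- dim(orients)[3]
  e <- matrix(0, n, 3)
  for (i in seq_len(n)) e[i, ] <- matrix_to_euler(orients[, , i])
  e
}

# apply positional and angular jitter to (pos, orients); returns both
apply_jitter <- function(pos, orients, pos_sd, ang_sd) {
  n <- nrow(pos)
  if (pos_sd > 0)
    pos <- pos + matrix(stats::rnorm(3 * n, sd = pos_sd), n, 3)
  if (ang_sd > 0) {
    J <- jitter_rotations(n, ang_sd)
    for (i in seq_len(n)) orients[, , i] <- J[, , i] %*% orients[, , i]
  }
  list(pos = pos, orients = orients)
}

# Iteratively co-locate the sample mean with the planted center while keeping
# every particle exactly on its planted shell.  The analysis defines the
# compartment center as the mean member position, so the synthetic compartment
# is built with that mean exactly at its geometric center; alternating a rigid
# re-centering with a radial re-projection converges in a few iterations.
center_on_shells <- function(pos, radii, iters = 200, tol = 1e-9) {
  for (it in seq_len(iters)) {
    m <- colMeans(pos)
    if (sqrt(sum(m^2)) < tol) break
    pos <- sweep(pos, 2, m)
    r <- sqrt(rowSums(pos^2))
    pos <- pos * (radii / r)
  }
  pos
}

# hexagonal lattice sites (2D) ordered center-outward: (0,0), ring 1, ring 2...
hex_lattice_sites <- function(n, spacing) {
  pts <- matrix(0, 1, 2)
  ring <- 1
  while (nrow(pts) < n) {
    # ring r: start at (r, 0) in axial coords, walk the 6 edges
    ax <- c(ring, 0)
    dirs <- matrix(c(-1, 1, -1, 0, 0, -1, 1, -1, 1, 0, 0, 1), 6, 2, byrow = TRUE)
    for (d in seq_len(6)) for (s in seq_len(ring)) {
      pts <- rbind(pts, ax)
      ax <- ax + dirs[d, ]
    }
    ring <- ring + 1
  }
  ax2xy <- function(a) spacing * c(a[1] + a[2] / 2, a[2] * sqrt(3) / 2)
  t(apply(pts[seq_len(n), , drop = FALSE], 1, ax2xy))
}

carboxysome_centers <- function(n, cfg) {
  per <- cfg$carboxysomes_per_tomogram
  sp <- cfg$tomogram_spacing
  idx <- seq_len(n) - 1L
  tomo <- idx %/% per
  slot <- idx %% per
  # slots laid out on a coarse cubic grid inside each tomogram
  k <- ceiling(per^(1 / 3))
  centers <- cbind((slot %% k) * sp, ((slot %/% k) %% k) * sp,
                   (slot %/% (k * k)) * sp)
  list(tomogram = sprintf("tomo_%03d", tomo + 1L), centers = centers)
}

sample_scores <- function(n, range) stats::runif(n, range[1], range[2])

# assemble one carboxysome's raw pieces into per-particle records
finish_carboxysome <- function(cfg, pos, orients, label, layer, string_id,
                               center, tomogram) {
  n_true <- nrow(pos)
  n_fp <- if (cfg$fp_rate > 0) round(n_true * cfg$fp_rate) else 0L
  if (n_fp > 0) {
    r_out <- cfg$compartment_radius
    fp_pos <- runif_sphere_volume(n_fp, r_out + 400, r_out + 50)
    fp_or <- random_rotations(n_fp)
    pos <- rbind(pos, fp_pos)
    orients <- array(c(orients, fp_or), c(3, 3, n_true + n_fp))
    label <- c(label, rep("false_positive", n_fp))
    layer <- c(layer, rep(NA_integer_, n_fp))
    string_id <- c(string_id, rep(NA_character_, n_fp))
  }
  score <- c(sample_scores(n_true, cfg$score_true),
             sample_scores(n_fp, cfg$score_fp))
  e <- euler_df(orients)
  data.frame(tomogram_id = tomogram,
             x_A = pos[, 1] + center[1], y_A = pos[, 2] + center[2],
             z_A = pos[, 3] + center[3],
             rot_deg = e[, 1], tilt_deg = e[, 2], psi_deg = e[, 3],
             score = score, label = label, layer = layer,
             string_id = string_id, stringsAsFactors = FALSE)
}

# ---- generators ---------------------------------------------------------------

#' Generate concentric-layer (Cyanobium-type) carboxysomes
#'
#' Each carboxysome draws a total particle count from a clipped normal,
#' splits it across the configured shells in proportion to shell area, places
#' particles on each shell by rejection sampling with the minimum 3D
#' separation enforced, and orients every particle with its fourfold axis
#' along the radial direction tilted by `layer_tilt` toward a random azimuth
#' with a random spin.  Gaussian positional/angular jitter, false positives
#' outside the outer shell and simulated scores are then applied.
#'
#' @param cfg A [generator_config()] (any preset; the layer fields are used).
#' @param n_carboxysomes Number of carboxysomes to generate.
#' @return List with `table` (a [particle_table()]) and `truth` (ground-truth
#'   sidecar: `$particles`, `$compartments` data.frames).
#' @export
generate_cyanobium <- function(cfg, n_carboxysomes = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    layout <- carboxysome_centers(n_carboxysomes, cfg)
    parts <- vector("list", n_carboxysomes)
    comps <- vector("list", n_carboxysomes)
    for (ci in seq_len(n_carboxysomes)) {
      count <- draw_count(1, cfg$count_mean, cfg$count_sd,
                          cfg$count_min, cfg$count_max)
      area <- cfg$layer_radii^2
      n_layer <- round(count * area / sum(area))
      n_layer[length(n_layer)] <- count - sum(n_layer[-length(n_layer)])
      pos <- matrix(numeric(0), 0, 3)
      layer_idx <- integer(0)
      for (li in seq_along(cfg$layer_radii)) {
        r <- cfg$layer_radii[li]
        p <- place_with_separation(
          n_layer[li], function(k) runif_sphere_surface(k, r),
          cfg$min_separation, existing = pos,
          context = sprintf("shell-%d particles", li))
        pos <- rbind(pos, p)
        layer_idx <- c(layer_idx, rep(li, n_layer[li]))
      }
      pos <- center_on_shells(pos, cfg$layer_radii[layer_idx])
      n <- nrow(pos)
      orients <- array(0, c(3, 3, n))
      for (i in seq_len(n))
        orients[, , i] <- tilted_orientation(pos[i, ], cfg$layer_tilt)
      jit <- apply_jitter(pos, orients, cfg$pos_jitter_sd, cfg$ang_jitter_sd)
      parts[[ci]] <- finish_carboxysome(
        cfg, jit$pos, jit$orients, rep("layer", n), layer_idx,
        rep(NA_character_, n), layout$centers[ci, ], layout$tomogram[ci])
      parts[[ci]]$cbx_id <- sprintf("cbx_%03d", ci)
      comps[[ci]] <- data.frame(
        cbx_id = sprintf("cbx_%03d", ci), tomogram_id = layout$tomogram[ci],
        class = "layered", cx = layout$centers[ci, 1],
        cy = layout$centers[ci, 2], cz = layout$centers[ci, 3],
        n_true = n, n_fp = sum(parts[[ci]]$label == "false_positive"),
        stringsAsFactors = FALSE)
    }
    build_output(parts, comps, strings = NULL)
  })
}

# shared assembly of the particle table + ground truth from per-cbx pieces
build_output <- function(parts, comps, strings) {
  df <- do.call(rbind, parts)
  df$particle_id <- sprintf("p%06d", seq_len(nrow(df)))
  tab <- particle_table(df[, PT_COLUMNS])
  truth <- list(
    particles = data.frame(particle_id = df$particle_id, cbx_id = df$cbx_id,
                           label = df$label, layer = df$layer,
                           string_id = df$string_id, stringsAsFactors = FALSE),
    compartments = do.call(rbind, comps),
    strings = if (is.null(strings)) NULL else do.call(rbind, strings))
  list(table = tab, truth = truth)
}

# plant one bundle of strings; returns positions/orients/string ids plus
# per-string records.  lengths: integer vector, one per string.
plant_string_bundle <- function(cfg, lengths, cbx_tag) {
  n_strings <- length(lengths)
  if (n_strings == 0)
    return(list(pos = matrix(numeric(0), 0, 3),
                orients = array(0, c(3, 3, 0)),
                string_id = character(0), records = NULL))
  axis <- unit3(stats::rnorm(3))
  A <- frame_from_axis(axis)        # lattice plane is perpendicular to axis
  sites <- hex_lattice_sites(n_strings, cfg$lattice_spacing)
  r_max <- cfg$compartment_radius - 10
  pos_list <- list(); ori_list <- list(); sid <- character(0); recs <- list()
  for (si in seq_len(n_strings)) {
    L <- lengths[si]
    base <- A %*% c(sites[si, 1], sites[si, 2], 0)
    offset <- stats::runif(1, -cfg$string_step / 2, cfg$string_step / 2)
    zs <- (seq_len(L) - (L + 1) / 2) * cfg$string_step + offset
    p <- t(vapply(zs, function(z) as.vector(base + z * axis), numeric(3)))
    keep <- sqrt(rowSums(p^2)) <= r_max       # crop at the compartment envelope
    # keep a contiguous run so the string stays a string
    if (!all(keep)) {
      runs <- rle(keep)
      if (!any(runs$values)) next
      ends <- cumsum(runs$lengths)
      wi <- which(runs$values)[which.max(runs$lengths[runs$values])]
      keep_idx <- seq(ends[wi] - runs$lengths[wi] + 1L, ends[wi])
    } else keep_idx <- seq_len(L)
    if (length(keep_idx) < 2) next
    p <- p[keep_idx, , drop = FALSE]
    Lr <- nrow(p)
    base_or <- A %*% rot_z(stats::runif(1, 0, 360))
    ors <- array(0, c(3, 3, Lr))
    for (k in seq_len(Lr))
      ors[, , k] <- rotation_about_axis(axis, (keep_idx[k] - 1) * cfg$step_twist) %*% base_or
    id <- sprintf("%s_s%02d", cbx_tag, si)
    pos_list[[length(pos_list) + 1L]] <- p
    ori_list[[length(ori_list) + 1L]] <- ors
    sid <- c(sid, rep(id, Lr))
    recs[[length(recs) + 1L]] <- data.frame(
      string_id = id, cbx_id = cbx_tag, length = Lr,
      ax = axis[1], ay = axis[2], az = axis[3],
      step_twist = cfg$step_twist, stringsAsFactors = FALSE)
  }
  if (!length(pos_list))
    return(list(pos = matrix(numeric(0), 0, 3),
                orients = array(0, c(3, 3, 0)),
                string_id = character(0), records = NULL))
  pos <- do.call(rbind, pos_list)
  n <- nrow(pos)
  orients <- array(0, c(3, 3, n))
  at <- 0
  for (o in ori_list) {
    k <- dim(o)[3]
    orients[, , at + seq_len(k)] <- o
    at <- at + k
  }
  list(pos = pos, orients = orients, string_id = sid,
       records = do.call(rbind, recs))
}

# background (disordered) particles filling a carboxysome to n_total
fill_background <- function(cfg, n_bg, existing) {
  if (n_bg <= 0)
    return(list(pos = matrix(numeric(0), 0, 3), orients = array(0, c(3, 3, 0))))
  pos <- place_with_separation(
    n_bg, function(k) runif_sphere_volume(k, cfg$compartment_radius),
    cfg$min_separation, existing = existing, context = "background particles")
  list(pos = pos, orients = random_rotations(n_bg))
}

string_lengths_preset <- function(cfg, n_strings) {
  pmin(pmax(round(stats::rnorm(n_strings, cfg$string_length_mean,
                               cfg$string_length_sd)),
            cfg$string_length_min), cfg$string_length_max)
}

# one halo-type carboxysome; lengths chosen by `length_fun(n_strings)`
generate_halo_one <- function(cfg, ci, center, tomogram, n_strings, lengths) {
  cbx_tag <- sprintf("cbx_%03d", ci)
  bundle <- plant_string_bundle(cfg, lengths, cbx_tag)
  count <- draw_count(1, cfg$count_mean, cfg$count_sd, cfg$count_min, cfg$count_max)
  n_bg <- max(0L, count - nrow(bundle$pos))
  bg <- fill_background(cfg, n_bg, existing = bundle$pos)
  pos <- rbind(bundle$pos, bg$pos)
  # rigid re-centering: the defined center (mean member position) coincides
  # with the planted center without disturbing string/lattice geometry
  pos <- sweep(pos, 2, colMeans(pos))
  n <- nrow(pos)
  orients <- array(0, c(3, 3, n))
  ns <- nrow(bundle$pos)
  if (ns > 0) orients[, , seq_len(ns)] <- bundle$orients
  if (n_bg > 0) orients[, , ns + seq_len(n_bg)] <- bg$orients
  label <- c(rep("string", ns), rep("background", n_bg))
  string_id <- c(bundle$string_id, rep(NA_character_, n_bg))
  jit <- apply_jitter(pos, orients, cfg$pos_jitter_sd, cfg$ang_jitter_sd)
  part <- finish_carboxysome(cfg, jit$pos, jit$orients, label,
                             rep(NA_integer_, length(label)), string_id,
                             center, tomogram)
  part$cbx_id <- cbx_tag
  realized <- if (is.null(bundle$records)) integer(0) else bundle$records$length
  comp <- data.frame(
    cbx_id = cbx_tag, tomogram_id = tomogram,
    class = classify_lengths(realized),
    cx = center[1], cy = center[2], cz = center[3],
    n_true = n, n_fp = sum(part$label == "false_positive"),
    stringsAsFactors = FALSE)
  list(part = part, comp = comp, strings = bundle$records)
}

# the four ordering classes from a vector of (planted or detected) string lengths
classify_lengths <- function(lengths, short_min = 3, long_min = 7, high_count = 5) {
  L <- if (length(lengths)) max(lengths) else 0L
  if (L < short_min) "random"
  else if (L < long_min) "short"
  else if (sum(lengths >= long_min) >= high_count) "high"
  else "moderate"
}

#' Generate spiral string-bundle (Halo-type) carboxysomes
#'
#' Per carboxysome: a string count is drawn from a clipped normal and the
#' strings are laid out on a hexagonal lattice perpendicular to a random
#' common bundle axis, centered in the compartment.  Each string stacks
#' particles along the axis at `string_step` spacing with the fourfold axis
#' along the string and a `step_twist` rotation per step.  The remaining
#' particle budget is filled with disordered background particles respecting
#' the minimum separation; jitter, false positives and scores as in
#' [generate_cyanobium()].  Strings are cropped at the compartment envelope;
#' realized (post-crop) lengths are recorded in the ground truth.
#'
#' @inheritParams generate_cyanobium
#' @return List with `table` and `truth` (including `truth$strings` with
#'   planted axis and per-step twist).
#' @export
generate_halo <- function(cfg, n_carboxysomes = 1) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    layout <- carboxysome_centers(n_carboxysomes, cfg)
    parts <- list(); comps <- list(); strs <- list()
    for (ci in seq_len(n_carboxysomes)) {
      n_strings <- draw_count(1, cfg$string_count_mean, cfg$string_count_sd,
                              cfg$string_count_min, cfg$string_count_max)
      lengths <- string_lengths_preset(cfg, n_strings)
      one <- generate_halo_one(cfg, ci, layout$centers[ci, ],
                               layout$tomogram[ci], n_strings, lengths)
      parts[[ci]] <- one$part; comps[[ci]] <- one$comp
      if (!is.null(one$strings)) strs[[length(strs) + 1L]] <- one$strings
    }
    build_output(parts, comps, if (length(strs)) strs else NULL)
  })
}

#' Generate a mixed population with planted ordering classes
#'
#' Draws a planted ordering class per carboxysome from `class_mix`
#' (random, short, moderate, high) and plants the matching string regime:
#' no strings for `random`; 1-4 strings of length 3-6 for `short`; one long
#' string (length >= 7) for `moderate`; five long strings for `high`.  The
#' ordered-class regimes are calibrated so that strings hold ~8% of the
#' particles of ordered carboxysomes, matching the reported in-string
#' fraction.  Everything else follows the halo generator.
#'
#' @inheritParams generate_cyanobium
#' @param class_mix Four fractions summing to 1 (default from `cfg`).
#' @return List with `table` and `truth`; `truth$compartments$class` holds the
#'   planted class (re-derived from realized string lengths after cropping).
#' @export
generate_population <- function(cfg, n_carboxysomes = 1,
                                class_mix = cfg$class_mix) {
  stopifnot(inherits(cfg, "generator_config"))
  if (abs(sum(class_mix) - 1) > 1e-8)
    stopf("class_mix fractions must sum to 1")
  with_seed(cfg$seed, {
    layout <- carboxysome_centers(n_carboxysomes, cfg)
    classes <- sample(c("random", "short", "moderate", "high"),
                      n_carboxysomes, replace = TRUE, prob = class_mix)
    long_lengths <- function(k) sample(7:9, k, replace = TRUE,
                                       prob = c(0.6, 0.3, 0.1))
    parts <- list(); comps <- list(); strs <- list()
    for (ci in seq_len(n_carboxysomes)) {
      lengths <- switch(classes[ci],
        random = integer(0),
        short = sample(3:6, sample(1:4, 1), replace = TRUE),
        moderate = long_lengths(1),
        high = long_lengths(5))
      one <- generate_halo_one(cfg, ci, layout$centers[ci, ],
                               layout$tomogram[ci], length(lengths), lengths)
      parts[[ci]] <- one$part; comps[[ci]] <- one$comp
      if (!is.null(one$strings)) strs[[length(strs) + 1L]] <- one$strings
    }
    build_output(parts, comps, if (length(strs)) strs else NULL)
  })
}

#' Write the ground-truth sidecar tables
#'
#' @param truth The `truth` element returned by a generator.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$particles, file.path(dir, "truth_particles.csv"),
                   row.names = FALSE)
  utils::write.csv(truth$compartments, file.path(dir, "truth_compartments.csv"),
                   row.names = FALSE)
  if (!is.null(truth$strings))
    utils::write.csv(truth$strings, file.path(dir, "truth_strings.csv"),
                     row.names = FALSE)
  invisible(dir)
}
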