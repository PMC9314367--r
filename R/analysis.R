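# The central analysis front end: one call runs compartment assignment,
# filtering, layer and string analyses, and returns a classed object with the
# usual print / summary / coef / plot / simulate methods.

#' Analyze the spatial organization of carboxysome cargo
#'
#' Runs the full metadata analysis on a particle table: single-linkage
#' compartment assignment, score/distance filtering, per-compartment radial
#' and angular geometry with concentric-layer detection, nearest-neighbor
#' distances, tandem-string tracing with per-step D4 twists, hexagonal-bundle
#' coordination, and the four-class ordering classification with population
#' summaries.
#'
#' @param t A [particle_table()].
#' @param linkage_distance,min_compartment_size Compartment assignment
#'   parameters (see [assign_compartments()]).
#' @param score_min,max_center_distance Filtering parameters (see
#'   [filter_particles()]).
#' @param string_params A [string_params()].
#' @param sym Particle point symmetry (default D4).
#' @param radial,angular Optional named lists of overrides passed on to
#'   [radial_profile()] / [angular_profile()] (e.g.
#'   `radial = list(bandwidth = 8)`).
#' @param class_thresholds Named list with `short_min`, `long_min`,
#'   `high_count` for [classify_compartment()].
#' @return An object of class `cbx_analysis`.
#' @examples
#' sim <- generate_cyanobium(generator_config("cyanobium", seed = 1), 2)
#' fit <- analyze_carboxysomes(sim$table)
#' coef(fit)["radius_outer_A"]
#' @export
analyze_carboxysomes <- function(t,
                                 linkage_distance = 200,
                                 min_compartment_size = 20,
                                 score_min = 0.1,
                                 max_center_distance = 550,
                                 string_params = cbxpack::string_params(),
                                 sym = point_symmetry("D", 4),
                                 radial = list(), angular = list(),
                                 class_thresholds = list(short_min = 3,
                                                         long_min = 7,
                                                         high_count = 5)) {
  stopifnot(inherits(t, "particle_table"))
  t <- assign_compartments(t, linkage_distance, min_compartment_size)
  tf <- filter_particles(t, score_min, max_center_distance)
  filter_report <- attr(tf, "filter_report")
  geom <- compartment_geometry(tf)
  rp <- do.call(radial_profile, c(list(geom), radial))
  ap <- do.call(angular_profile, c(list(geom), angular))
  nn <- neighbor_distances(geom)
  counts <- count_particles(geom)
  strings <- detect_strings(geom$table, string_params)
  stats_ <- string_statistics(strings, geom$table)
  coordn <- string_coordination(strings,
                                axis_parallel_tol = string_params$axis_parallel_tol)
  twists <- string_twists(strings, geom$table, sym = sym)
  cids <- geom$compartments$compartment_id
  lens_by_comp <- lapply(stats::setNames(cids, cids), function(cid)
    vapply(strings$strings[vapply(strings$strings, function(s)
      s$compartment_id == cid, TRUE)], `[[`, 0L, "length"))
  classes <- vapply(lens_by_comp, function(L)
    classify_compartment(L, class_thresholds$short_min,
                         class_thresholds$long_min,
                         class_thresholds$high_count), "")
  pop <- population_summary(classes, strings, geom$table,
                            ordered_min_length = class_thresholds$short_min)
  structure(list(
    table = geom$table, compartments = geom$compartments,
    filter_report = filter_report,
    radial = rp, angular = ap, neighbors = nn, counts = counts,
    strings = strings, string_stats = stats_, coordination = coordn,
    twists = twists, classes = classes, population = pop,
    params = list(linkage_distance = linkage_distance,
                  min_compartment_size = min_compartment_size,
                  score_min = score_min,
                  max_center_distance = max_center_distance,
                  string_params = string_params, sym = sym,
                  class_thresholds = class_thresholds)),
    class = "cbx_analysis")
}

#' Headline estimates of a carboxysome analysis
#'
#' @param object A `cbx_analysis`.
#' @param ... Unused.
#' @return Named numeric vector: compartment count and mean/sd particle
#'   count, detected layer radii (`radius_1_A` innermost ... and
#'   `radius_outer_A`), angular mode/mean, nearest-neighbor mean, string
#'   count/length means, twist mean, ordered fraction and in-string particle
#'   fraction (both as percentages).
#' @export
coef.cbx_analysis <- function(object, ...) {
  pk <- object$radial$peaks_A
  out <- c(n_compartments = nrow(object$compartments),
           count_mean = object$counts$mean, count_sd = object$counts$sd)
  if (length(pk)) {
    rad <- stats::setNames(pk, sprintf("radius_%d_A", seq_along(pk)))
    out <- c(out, rad, radius_inner_A = pk[1], radius_outer_A = pk[length(pk)])
  }
  c(out,
    theta_mode_deg = object$angular$mode_deg,
    theta_mean_deg = object$angular$mean_deg,
    nn_mean_A = unname(object$neighbors$summary["mean"]),
    string_count_mean = object$string_stats$count_mean,
    string_length_mean = object$string_stats$length_mean,
    twist_mean_deg = object$twists$mean_deg,
    modal_coordination = object$coordination$modal_coordination,
    ordered_pct = 100 * object$population$ordered_fraction,
    in_string_pct = 100 * object$population$in_string_fraction)
}

#' @export
print.cbx_analysis <- function(x, ...) {
  cat("Carboxysome cargo spatial analysis\n")
  cat(sprintf("  particles: %d kept of %d (%d low-score, %d unassigned, %d stray)\n",
              x$filter_report$kept, x$filter_report$input,
              x$filter_report$dropped_low_score,
              x$filter_report$dropped_unassigned, x$filter_report$dropped_far))
  cat(sprintf("  compartments: %d (count %.1f +/- %.1f)\n",
              nrow(x$compartments), x$counts$mean, x$counts$sd %||% NA))
  if (length(x$radial$peaks_A))
    cat(sprintf("  layers: %d peak(s) at %s A\n", length(x$radial$peaks_A),
                paste(sprintf("%.0f", x$radial$peaks_A), collapse = ", ")))
  cat(sprintf("  radial-angle mode: %.2f deg (mean %.2f)\n",
              x$angular$mode_deg, x$angular$mean_deg))
  ns <- length(x$strings$strings)
  cat(sprintf("  strings: %d (count %.1f +/- %.1f per compartment, length %.2f +/- %.2f)\n",
              ns, x$string_stats$count_mean, x$string_stats$count_sd %||% NA,
              x$string_stats$length_mean, x$string_stats$length_sd %||% NA))
  if (is.finite(x$twists$mean_deg %||% NA))
    cat(sprintf("  twist per step: %.2f +/- %.2f deg (D4-folded)\n",
                x$twists$mean_deg, x$twists$sd_deg %||% NA))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(x$population$class_counts),
                            x$population$class_counts), collapse = " ")))
  cat(sprintf("  ordered: %.1f%%; particles in strings of ordered compartments: %.1f%%\n",
              100 * x$population$ordered_fraction,
              100 * x$population$in_string_fraction))
  invisible(x)
}

#' @export
summary.cbx_analysis <- function(object, ...) {
  structure(list(coef = coef(object), filter = object$filter_report,
                 compartments = object$compartments,
                 class_counts = object$population$class_counts),
            class = "summary.cbx_analysis")
}

#' @export
print.summary.cbx_analysis <- function(x, ...) {
  cat("Estimates:\n")
  print(round(x$coef, 3))
  cat("\nCompartments:\n")
  print(x$compartments, digits = 4)
  invisible(x)
}

#' Diagnostic plots for a carboxysome analysis
#'
#' Four base-graphics panels: pooled radial histogram with the smoothed
#' density and detected layer radii; pooled angular histogram with the mode;
#' string-length histogram; per-compartment particle counts.
#'
#' @param x A `cbx_analysis`.
#' @param which Subset of panels 1:4.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.cbx_analysis <- function(x, which = 1:4, ...) {
  mf <- if (length(which) > 2) c(2, 2) else c(1, length(which))
  op <- graphics::par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  rows <- !is.na(x$table$r_A)
  if (1 %in% which && any(rows)) {
    r <- x$table$r_A[rows]
    graphics::hist(r, breaks = x$radial$breaks, freq = FALSE,
                   main = "Radial distance", xlab = "r (Å)",
                   col = "grey85", border = "white", ...)
    if (!is.null(x$radial$density)) graphics::lines(x$radial$density, lwd = 2)
    graphics::abline(v = x$radial$peaks_A, col = 2, lty = 2)
  }
  if (2 %in% which) {
    th <- x$table$theta_deg[is.finite(x$table$theta_deg)]
    if (length(th)) {
      graphics::hist(th, breaks = x$angular$breaks, freq = FALSE,
                     main = "Axis vs radial direction", xlab = "θ (deg)",
                     col = "grey85", border = "white", ...)
      graphics::abline(v = x$angular$mode_deg, col = 2, lty = 2)
    }
  }
  if (3 %in% which && length(x$string_stats$lengths)) {
    graphics::hist(x$string_stats$lengths,
                   breaks = seq(1.5, max(x$string_stats$lengths) + 0.5, 1),
                   main = "String lengths", xlab = "Rubiscos per string",
                   col = "grey85", border = "white")
  }
  if (4 %in% which && length(x$counts$counts)) {
    graphics::hist(x$counts$counts, main = "Particles per compartment",
                   xlab = "count", col = "grey85", border = "white")
  }
  invisible(x)
}

#' Simulate new data from the estimated organization
#'
#' Builds a generator configuration from the fitted layer radii, tilt mode
#' and string statistics and generates new synthetic carboxysomes of the
#' matching regime (layered when concentric peaks dominate, string bundles
#' otherwise).
#'
#' @param object A `cbx_analysis`.
#' @param nsim Number of carboxysomes to simulate.
#' @param seed RNG seed.
#' @param ... Unused.
#' @return A generator result (list with `table`, `truth`).
#' @export
simulate.cbx_analysis <- function(object, nsim = 1, seed = 1, ...) {
  est <- coef(object)
  # radial axis alignment (a low angular mean) is the signature of the
  # concentric-layer regime; string bundles leave the pooled angle ~sin-like
  layered <- length(object$radial$peaks_A) >= 2 &&
    is.finite(object$angular$mean_deg) && object$angular$mean_deg < 35
  if (layered) {
    cfg <- generator_config(
      "cyanobium", seed = seed,
      layer_radii = sort(object$radial$peaks_A),
      layer_tilt = est[["theta_mode_deg"]],
      count_mean = est[["count_mean"]],
      count_sd = max(1, est[["count_sd"]], na.rm = TRUE))
    generate_cyanobium(cfg, nsim)
  } else {
    cfg <- generator_config(
      "halo", seed = seed,
      count_mean = est[["count_mean"]],
      count_sd = max(1, est[["count_sd"]], na.rm = TRUE),
      string_count_mean = max(0, est[["string_count_mean"]], na.rm = TRUE),
      string_length_mean = max(2, est[["string_length_mean"]], na.rm = TRUE),
      step_twist = if (is.finite(est[["twist_mean_deg"]]))
        est[["twist_mean_deg"]] else 0)
    generate_halo(cfg, nsim)
  }
}
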