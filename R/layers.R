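# Per-compartment geometry: compartment assignment, score/distance filtering,
# radial and angular distributions, concentric-layer (shell) detection,
# nearest-neighbor distances and particle counts.
#
# The compartment center is the plain arithmetic mean of member positions,
# exactly the definition used when the radial and angular distributions were
# introduced for carboxysome cargo; a robustness note is attached when the
# mean and the medoid disagree by more than 30 A.

#' Cluster particles into compartments
#'
#' Single-linkage connected components at `linkage_distance` within each
#' tomogram.  Components smaller than `min_size` are left unassigned (NA).
#'
#' @param t A [particle_table()].
#' @param linkage_distance Linkage cutoff in Angstrom (default 200, about two
#'   particle diameters).
#' @param min_size Minimum component size to count as a compartment (default 20).
#' @return The table with a `compartment_id` column (`<tomogram>/c<k>` or NA).
#' @export
assign_compartments <- function(t, linkage_distance = 200, min_size = 20) {
  stopifnot(inherits(t, "particle_table"))
  t$compartment_id <- rep(NA_character_, nrow(t))
  if (nrow(t) == 0) return(t)
  for (tomo in unique(t$tomogram_id)) {
    rows <- which(t$tomogram_id == tomo)
    pos <- particle_positions(t)[rows, , drop = FALSE]
    if (length(rows) == 1) {
      member <- 1L
    } else {
      hc <- stats::hclust(stats::dist(pos), method = "single")
      member <- stats::cutree(hc, h = linkage_distance)
    }
    sizes <- table(member)
    keep <- as.integer(names(sizes)[sizes >= min_size])
    # stable ids ordered by first occurrence
    rank <- integer(max(member)); next_id <- 1L
    for (m in member) if (m %in% keep && rank[m] == 0L) {
      rank[m] <- next_id; next_id <- next_id + 1L
    }
    lab <- ifelse(member %in% keep,
                  sprintf("%s/c%d", tomo, rank[member]), NA_character_)
    t$compartment_id[rows] <- lab
  }
  t
}

#' Remove false positives and stray particles
#'
#' Drops particles whose score falls below `score_min`, particles farther than
#' `max_center_distance` from their compartment center (center = mean member
#' position), and particles in no compartment.  A per-reason accounting is
#' attached as the `"filter_report"` attribute.
#'
#' @param t A [particle_table()] with compartments assigned.
#' @param score_min Minimum template-matching score (default 0.1, the lower
#'   edge of the displayed cross-correlation range; NA scores are kept).
#' @param max_center_distance Maximum distance from the compartment center in
#'   Angstrom (default 550).
#' @return Filtered [particle_table()] with attribute `filter_report`.
#' @export
filter_particles <- function(t, score_min = 0.1, max_center_distance = 550) {
  stopifnot(inherits(t, "particle_table"))
  if (!"compartment_id" %in% names(t))
    stopf("assign_compartments() must be run before filter_particles()")
  n0 <- nrow(t)
  low_score <- !is.na(t$score) & t$score < score_min
  unassigned <- is.na(t$compartment_id)
  pos <- particle_positions(t)
  too_far <- rep(FALSE, n0)
  for (cid in unique(stats::na.omit(t$compartment_id))) {
    rows <- which(t$compartment_id == cid)
    ctr <- colMeans(pos[rows, , drop = FALSE])
    d <- sqrt(rowSums(sweep(pos[rows, , drop = FALSE], 2, ctr)^2))
    too_far[rows] <- d > max_center_distance
  }
  drop <- low_score | unassigned | too_far
  out <- t[!drop, , drop = FALSE]
  attr(out, "pixel_size") <- attr(t, "pixel_size")
  class(out) <- class(t)
  attr(out, "filter_report") <- list(
    input = n0, kept = nrow(out),
    dropped_low_score = sum(low_score),
    dropped_unassigned = sum(unassigned & !low_score),
    dropped_far = sum(too_far & !low_score & !unassigned))
  out
}

#' Per-compartment radial geometry
#'
#' For every assigned compartment: center = mean member position, per-particle
#' radial distance `r = |p - center|` and radial angle `theta` = undirected
#' angle between the radial vector and the particle fourfold axis.  Particles
#' closer than `min_radius` to the center have an ill-conditioned radial
#' vector and get `theta = NA`; compartments smaller than `min_size` are
#' flagged and excluded from pooled distributions.
#'
#' @param t A filtered [particle_table()] with compartments assigned.
#' @param min_size Minimum compartment size for distributions (default 4).
#' @param min_radius Radius (A) under which theta is undefined (default 20).
#' @return An object of class `cbx_geometry`: `$table` (augmented with
#'   `r_A`, `theta_deg`), `$compartments` (one row per compartment with
#'   center, n, and a mean-vs-medoid robustness gap).
#' @export
compartment_geometry <- function(t, min_size = 4, min_radius = 20) {
  stopifnot(inherits(t, "particle_table"))
  if (!"compartment_id" %in% names(t))
    stopf("assign_compartments() must be run before compartment_geometry()")
  pos <- particle_positions(t)
  axes <- particle_axes(t)
  t$r_A <- NA_real_
  t$theta_deg <- NA_real_
  cids <- unique(stats::na.omit(t$compartment_id))
  recs <- vector("list", length(cids))
  for (k in seq_along(cids)) {
    rows <- which(t$compartment_id == cids[k])
    p <- pos[rows, , drop = FALSE]
    ctr <- colMeans(p)
    v <- sweep(p, 2, ctr)
    r <- sqrt(rowSums(v^2))
    theta <- rep(NA_real_, length(rows))
    okr <- r >= min_radius
    theta[okr] <- axis_angles(v[okr, , drop = FALSE] / r[okr],
                              axes[rows[okr], , drop = FALSE])
    t$r_A[rows] <- r
    t$theta_deg[rows] <- theta
    # robustness note on the plain-mean center: compare against the
    # coordinate-wise median, which stray particles barely move
    med <- apply(p, 2, stats::median)
    recs[[k]] <- data.frame(
      compartment_id = cids[k], tomogram_id = t$tomogram_id[rows[1]],
      n = length(rows), cx = ctr[1], cy = ctr[2], cz = ctr[3],
      mean_median_gap = sqrt(sum((ctr - med)^2)),
      small = length(rows) < min_size, stringsAsFactors = FALSE)
  }
  comps <- if (length(recs)) do.call(rbind, recs) else
    data.frame(compartment_id = character(0), tomogram_id = character(0),
               n = integer(0), cx = numeric(0), cy = numeric(0),
               cz = numeric(0), mean_median_gap = numeric(0),
               small = logical(0))
  if (any(comps$mean_median_gap > 30))
    message(sum(comps$mean_median_gap > 30),
            " compartment(s) have mean/median centers > 30 A apart; ",
            "the plain-mean center may be skewed by stray particles")
  structure(list(table = t, compartments = comps,
                 min_size = min_size, min_radius = min_radius),
            class = "cbx_geometry")
}

#' @export
print.cbx_geometry <- function(x, ...) {
  cat(sprintf("<cbx_geometry: %d compartment(s), %d particles>\n",
              nrow(x$compartments), nrow(x$table)))
  invisible(x)
}

pooled_rows <- function(geom) {
  good <- geom$compartments$compartment_id[!geom$compartments$small]
  which(geom$table$compartment_id %in% good)
}

# local maxima of a KDE curve with a minimum peak separation and a minimum
# topographic prominence (fraction of the global maximum)
find_peaks <- function(x, y, min_separation, min_prominence_frac) {
  n <- length(y)
  if (n < 3) return(integer(0))
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    higher_l <- which(y[seq_len(i - 1)] > y[i])
    higher_r <- which(y[(i + 1):n] > y[i]) + i
    vl <- min(y[(if (length(higher_l)) max(higher_l) else 1):i])
    vr <- min(y[i:(if (length(higher_r)) min(higher_r) else n)])
    y[i] - max(vl, vr)
  }, numeric(1))
  keep <- cand[prom >= min_prominence_frac * max(y)]
  if (!length(keep)) return(integer(0))
  # greedy separation filter, highest first
  keep <- keep[order(y[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in keep)
    if (!length(sel) || all(abs(x[i] - x[sel]) >= min_separation))
      sel <- c(sel, i)
  sort(sel)
}

#' Pooled radial-distance profile with concentric-layer detection
#'
#' Histograms the radial distances, smooths them with a Gaussian kernel
#' density estimate and reports the local maxima as layer radii, subject to a
#' minimum peak separation and prominence.  Each particle is assigned to the
#' nearest detected layer when within half the adjacent inter-peak gap,
#' otherwise left unassigned.
#'
#' @param geom A [compartment_geometry()] result.
#' @param bin_width Histogram bin in Angstrom (default 10).
#' @param bandwidth KDE bandwidth in Angstrom (default 8; two shells closer
#'   than about twice the bandwidth may merge into one peak -- the peak count
#'   in the result makes this visible rather than silent).
#' @param min_separation Minimum distance between reported peaks (default 50 A).
#' @param min_prominence Minimum peak prominence as a fraction of the density
#'   maximum (default 0.05).
#' @param pooled Pool all non-small compartments (default); otherwise profile
#'   each compartment separately and return a list.
#' @return Object of class `cbx_radial_profile`: bin `breaks`/`counts`,
#'   `density` (KDE), `peaks_A`, per-particle `layer` assignment (indices into
#'   `peaks_A`, NA when unassigned), and adjacent `peak_spacing_A`.
#' @export
radial_profile <- function(geom, bin_width = 10, bandwidth = 8,
                           min_separation = 50, min_prominence = 0.05,
                           pooled = TRUE) {
  stopifnot(inherits(geom, "cbx_geometry"))
  if (!pooled) {
    out <- lapply(split(seq_len(nrow(geom$table)), geom$table$compartment_id),
                  function(rows) {
                    g <- geom; g$table <- geom$table[rows, , drop = FALSE]
                    radial_profile(g, bin_width, bandwidth, min_separation,
                                   min_prominence, pooled = TRUE)
                  })
    return(out)
  }
  rows <- pooled_rows(geom)
  r <- geom$table$r_A[rows]
  r <- r[is.finite(r)]
  if (!length(r)) {
    return(structure(list(breaks = numeric(0), counts = integer(0),
                          density = NULL, peaks_A = numeric(0),
                          layer = rep(NA_integer_, nrow(geom$table)),
                          peak_spacing_A = numeric(0), n = 0),
                     class = "cbx_radial_profile"))
  }
  breaks <- seq(0, max(r) + bin_width, by = bin_width)
  h <- graphics::hist(r, breaks = breaks, plot = FALSE)
  dens <- stats::density(r, bw = bandwidth, from = 0, to = max(r) + 3 * bandwidth,
                         n = 2048)
  pk <- find_peaks(dens$x, dens$y, min_separation, min_prominence)
  peaks <- dens$x[pk]
  # assign every profiled particle to its nearest peak within half the gap
  layer <- rep(NA_integer_, nrow(geom$table))
  if (length(peaks)) {
    gaps <- diff(peaks)
    half_gap <- if (length(gaps)) min(gaps) / 2 else Inf
    rr <- geom$table$r_A
    nearest <- vapply(rr, function(x)
      if (is.finite(x)) which.min(abs(peaks - x)) else NA_integer_, integer(1))
    ok <- is.finite(rr) & abs(rr - peaks[nearest]) <= half_gap
    ok[-rows] <- FALSE
    layer[ok] <- nearest[ok]
  }
  structure(list(breaks = h$breaks, counts = h$counts, density = dens,
                 peaks_A = peaks, layer = layer,
                 peak_spacing_A = diff(peaks), n = length(r)),
            class = "cbx_radial_profile")
}

#' @export
print.cbx_radial_profile <- function(x, ...) {
  cat(sprintf("<radial profile: %d particles, %d peak(s) at %s A>\n", x$n,
              length(x$peaks_A), paste(sprintf("%.0f", x$peaks_A), collapse = ", ")))
  invisible(x)
}

#' Pooled angular profile of the fourfold axis against the radial direction
#'
#' Histogram of theta over \[0, 90\] degrees and the modal angle, defined as
#' the midpoint of the bin with the highest smoothed (KDE) density.  The mean
#' is reported alongside the mode.
#'
#' @param geom A [compartment_geometry()] result.
#' @param bin_width Bin width in degrees (default 2.5).
#' @param bandwidth KDE bandwidth in degrees (default 2).
#' @return Object of class `cbx_angular_profile` with `breaks`, `counts`,
#'   `mode_deg`, `mean_deg`, `n`.
#' @export
angular_profile <- function(geom, bin_width = 2.5, bandwidth = 2) {
  stopifnot(inherits(geom, "cbx_geometry"))
  th <- geom$table$theta_deg[pooled_rows(geom)]
  th <- th[is.finite(th)]
  breaks <- seq(0, 90, by = bin_width)
  if (!length(th))
    return(structure(list(breaks = breaks, counts = integer(length(breaks) - 1),
                          mode_deg = NA_real_, mean_deg = NA_real_, n = 0),
                     class = "cbx_angular_profile"))
  h <- graphics::hist(th, breaks = breaks, plot = FALSE)
  dens <- stats::density(th, bw = bandwidth, from = 0, to = 90, n = 1024)
  mids <- h$mids
  dens_at_mid <- stats::approx(dens$x, dens$y, xout = mids)$y
  structure(list(breaks = h$breaks, counts = h$counts,
                 mode_deg = mids[which.max(dens_at_mid)],
                 mean_deg = mean(th), n = length(th)),
            class = "cbx_angular_profile")
}

#' @export
print.cbx_angular_profile <- function(x, ...) {
  cat(sprintf("<angular profile: %d particles, mode %.2f deg, mean %.2f deg>\n",
              x$n, x$mode_deg, x$mean_deg))
  invisible(x)
}

#' Nearest-neighbor distances within compartments
#'
#' Euclidean nearest neighbor of every particle within its own compartment;
#' singleton compartments are excluded.
#'
#' @param geom A [compartment_geometry()] result.
#' @return List with per-particle `nn_A` (NA outside compartments) and
#'   `summary` (mean, median, sd).
#' @export
neighbor_distances <- function(geom) {
  stopifnot(inherits(geom, "cbx_geometry"))
  t <- geom$table
  pos <- particle_positions(t)
  nn <- rep(NA_real_, nrow(t))
  for (cid in unique(stats::na.omit(t$compartment_id))) {
    rows <- which(t$compartment_id == cid)
    if (length(rows) < 2) next
    d <- as.matrix(stats::dist(pos[rows, , drop = FALSE]))
    diag(d) <- Inf
    nn[rows] <- apply(d, 1, min)
  }
  v <- nn[is.finite(nn)]
  list(nn_A = nn,
       summary = c(mean = mean(v), median = stats::median(v), sd = stats::sd(v)))
}

#' Per-compartment particle counts
#'
#' @param geom A [compartment_geometry()] result.
#' @return List with `counts` (named per compartment) and `mean`/`sd` over the
#'   population.
#' @export
count_particles <- function(geom) {
  stopifnot(inherits(geom, "cbx_geometry"))
  counts <- geom$compartments$n
  names(counts) <- geom$compartments$compartment_id
  list(counts = counts,
       mean = if (length(counts)) mean(counts) else NA_real_,
       sd = if (length(counts) > 1) stats::sd(counts) else NA_real_)
}
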