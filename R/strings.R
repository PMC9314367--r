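# Tandem Rubisco string detection and statistics.
#
# Two tandem particles must (i) have their fourfold axes pointing in the same
# or opposite direction (the D4 twofolds make the axis undirected), (ii) have
# both axes lying along the inter-particle displacement, and (iii) be
# separated by close to one particle diameter.  Strings are maximal simple
# paths in the graph of tandem pairs after branches are resolved by best
# collinearity; each string carries a per-step D4-folded twist.

#' Parameters of the tandem-string detector
#'
#' @param d_min,d_max Tandem distance window in Angstrom (default 85-130,
#'   a window around one Rubisco diameter).
#' @param axis_parallel_tol Maximum undirected angle between the two fourfold
#'   axes, degrees (default 20).
#' @param axis_displacement_tol Maximum undirected angle between each axis and
#'   the displacement vector, degrees (default 25) -- the fourfold axis must
#'   lie along the string.
#' @param min_string_length Minimum members for a reported string (default 2,
#'   so dimers and the "fewer than 3 in a row" classification boundary are
#'   decidable).
#' @return Object of class `string_params`.
#' @export
string_params <- function(d_min = 85, d_max = 130, axis_parallel_tol = 20,
                          axis_displacement_tol = 25, min_string_length = 2) {
  if (!(0 < d_min && d_min < d_max)) stopf("need 0 < d_min < d_max")
  if (axis_parallel_tol <= 0 || axis_parallel_tol >= 90 ||
      axis_displacement_tol <= 0 || axis_displacement_tol >= 90)
    stopf("tolerances must lie in (0, 90) degrees")
  if (min_string_length < 2) stopf("min_string_length must be >= 2")
  structure(list(d_min = d_min, d_max = d_max,
                 axis_parallel_tol = axis_parallel_tol,
                 axis_displacement_tol = axis_displacement_tol,
                 min_string_length = as.integer(min_string_length)),
            class = "string_params")
}

#' Tandem-pair test for two particles
#'
#' @param p1,p2 Length-3 positions (Angstrom).
#' @param o1,o2 Orientation matrices.
#' @param params A [string_params()].
#' @return TRUE iff the pair satisfies the tandem restraints (axes parallel or
#'   antiparallel, both along the displacement, distance within the window).
#' @export
is_tandem <- function(p1, p2, o1, o2, params = string_params()) {
  disp <- p2 - p1
  d <- sqrt(sum(disp^2))
  if (d < params$d_min || d > params$d_max) return(FALSE)
  a1 <- o1[, 3]; a2 <- o2[, 3]
  if (axis_angle(a1, a2) > params$axis_parallel_tol) return(FALSE)
  axis_angle(a1, disp) <= params$axis_displacement_tol &&
    axis_angle(a2, disp) <= params$axis_displacement_tol
}

# all tandem pairs among rows of pos/axes; returns data.frame(i, j, score)
# score = sum of the two axis-displacement angles (smaller = more collinear)
tandem_pairs <- function(pos, axes, params) {
  n <- nrow(pos)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), score = numeric(0)))
  d <- as.matrix(stats::dist(pos))
  idx <- which(upper.tri(d) & d >= params$d_min & d <= params$d_max,
               arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(i = integer(0), j = integer(0), score = numeric(0)))
  i <- idx[, 1]; j <- idx[, 2]
  ang_axes <- axis_angles_rowwise(axes[i, , drop = FALSE], axes[j, , drop = FALSE])
  disp <- pos[j, , drop = FALSE] - pos[i, , drop = FALSE]
  ang_i <- axis_angles_rowwise(axes[i, , drop = FALSE], disp)
  ang_j <- axis_angles_rowwise(axes[j, , drop = FALSE], disp)
  ok <- ang_axes <= params$axis_parallel_tol &
    ang_i <= params$axis_displacement_tol &
    ang_j <= params$axis_displacement_tol
  data.frame(i = i[ok], j = j[ok], score = (ang_i + ang_j)[ok])
}

axis_angles_rowwise <- function(A, B) {
  d <- rowSums(A * B)
  acos(clamp(abs(d / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2)))), 0, 1)) * .rad2deg
}

# Greedy branch resolution: take edges in order of increasing collinearity
# score (ties: lowest particle indices), accept when both endpoints still have
# fewer than two string neighbors and no cycle is closed.  The surviving graph
# is a union of simple paths.
resolve_branches <- function(edges, n) {
  if (!nrow(edges)) return(edges)
  ord <- order(edges$score, edges$i, edges$j)
  deg <- integer(n)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- logical(nrow(edges))
  for (e in ord) {
    i <- edges$i[e]; j <- edges$j[e]
    if (deg[i] >= 2L || deg[j] >= 2L) next
    ri <- find(i); rj <- find(j)
    if (ri == rj) next
    parent[ri] <- rj
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    keep[e] <- TRUE
  }
  edges[keep, , drop = FALSE]
}

# walk the path components of a degree-<=2 acyclic graph; returns list of
# integer vectors (ordered member rows), each starting at its lowest-index end
walk_paths <- function(edges, n) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  deg <- lengths(adj)
  visited <- logical(n)
  paths <- list()
  for (s in which(deg == 1L)) {
    if (visited[s]) next
    path <- s; visited[s] <- TRUE
    cur <- s
    repeat {
      nxt <- adj[[cur]][!visited[adj[[cur]]]]
      if (!length(nxt)) break
      cur <- nxt[1]; visited[cur] <- TRUE
      path <- c(path, cur)
    }
    if (path[1] > path[length(path)]) path <- rev(path)
    paths[[length(paths) + 1L]] <- path
  }
  paths
}

#' Detect tandem Rubisco strings
#'
#' Builds the tandem-pair graph within each compartment, resolves branches so
#' no particle has more than two string neighbors (keeping the most collinear
#' pairs, deterministic tie-break on particle order), and emits the maximal
#' simple paths of length >= `min_string_length`.
#'
#' @param t A [particle_table()] (compartments assigned; particles without a
#'   compartment are ignored).
#' @param params A [string_params()].
#' @return Object of class `cbx_strings`: `$strings` is a list, each with
#'   `particle_ids` (ordered), `rows`, `compartment_id`, `length`, `axis`
#'   (unit principal direction, oriented first-to-last) and
#'   `step_distances_A`; `$assignment` maps each table row to a string index
#'   or NA (unstringed).
#' @export
detect_strings <- function(t, params = string_params()) {
  stopifnot(inherits(t, "particle_table"))
  if (!"compartment_id" %in% names(t))
    stopf("assign_compartments() must be run before detect_strings()")
  pos <- particle_positions(t)
  axes <- particle_axes(t)
  strings <- list()
  assignment <- rep(NA_integer_, nrow(t))
  for (cid in unique(stats::na.omit(t$compartment_id))) {
    rows <- which(t$compartment_id == cid)
    ed <- tandem_pairs(pos[rows, , drop = FALSE], axes[rows, , drop = FALSE],
                       params)
    ed <- resolve_branches(ed, length(rows))
    for (path in walk_paths(ed, length(rows))) {
      if (length(path) < params$min_string_length) next
      prow <- rows[path]
      p <- pos[prow, , drop = FALSE]
      ctr <- colMeans(p)
      pc <- svd(sweep(p, 2, ctr))$v[, 1]
      if (sum(pc * (p[nrow(p), ] - p[1, ])) < 0) pc <- -pc
      strings[[length(strings) + 1L]] <- list(
        particle_ids = t$particle_id[prow], rows = prow,
        compartment_id = cid, length = length(prow),
        axis = pc, centroid = ctr,
        step_distances_A = sqrt(rowSums(diff(p)^2)))
      assignment[prow] <- length(strings)
    }
  }
  structure(list(strings = strings, assignment = assignment, params = params),
            class = "cbx_strings")
}

#' @export
print.cbx_strings <- function(x, ...) {
  lens <- vapply(x$strings, `[[`, 0L, "length")
  cat(sprintf("<cbx_strings: %d string(s), lengths %s>\n", length(lens),
              if (length(lens)) paste(range(lens), collapse = "-") else "-"))
  invisible(x)
}

#' String counts and length distribution
#'
#' @param strings A [detect_strings()] result.
#' @param t The [particle_table()] the strings were detected in (for the
#'   per-compartment universe and the in-string particle fraction).
#' @param min_length Count only strings at least this long (default 2, the
#'   shortest reported tandem unit).
#' @return List: per-compartment `count` (named, zero-filled over all
#'   compartments), `count_mean`, `count_sd`, pooled `lengths`,
#'   `length_mean`, `length_sd`, and `frac_in_strings` (fraction of all
#'   compartment particles lying in counted strings).
#' @export
string_statistics <- function(strings, t, min_length = 2) {
  stopifnot(inherits(strings, "cbx_strings"), inherits(t, "particle_table"))
  sel <- vapply(strings$strings, function(s) s$length >= min_length, TRUE)
  ss <- strings$strings[sel]
  cids <- sort(unique(stats::na.omit(t$compartment_id)))
  count <- stats::setNames(integer(length(cids)), cids)
  for (s in ss) count[s$compartment_id] <- count[s$compartment_id] + 1L
  lens <- vapply(ss, `[[`, 0L, "length")
  n_in <- sum(lens)
  n_tot <- sum(!is.na(t$compartment_id))
  list(count = count,
       count_mean = if (length(count)) mean(count) else NA_real_,
       count_sd = if (length(count) > 1) stats::sd(count) else NA_real_,
       lengths = lens,
       length_mean = if (length(lens)) mean(lens) else NA_real_,
       length_sd = if (length(lens) > 1) stats::sd(lens) else NA_real_,
       frac_in_strings = if (n_tot) n_in / n_tot else NA_real_)
}

#' Coordination number of parallel strings in a bundle
#'
#' Two strings of the same compartment are adjacent when their axes are
#' parallel within `axis_parallel_tol` and their perpendicular
#' centerline-centerline distance falls within `(1 +/- lattice_tol)` of the
#' bundle's lattice spacing, estimated as the modal nearest parallel-string
#' distance.  In a hexagonally packed bundle the interior strings have six
#' such neighbors.
#'
#' @param strings A [detect_strings()] result (>= 2 strings needed for any
#'   adjacency).
#' @param axis_parallel_tol Degrees (default 20).
#' @param lattice_tol Fractional window around the spacing estimate
#'   (default 0.3).
#' @return List: per-string `coordination`, `modal_coordination` (mode over
#'   all strings; for a bundle with at least one full ring this is the
#'   interior coordination), `spacing_A` (per-compartment estimate).
#' @export
string_coordination <- function(strings, axis_parallel_tol = 20,
                                lattice_tol = 0.3) {
  stopifnot(inherits(strings, "cbx_strings"))
  ss <- strings$strings
  coord <- integer(length(ss))
  spacing <- c()
  comp <- vapply(ss, `[[`, "", "compartment_id")
  for (cid in unique(comp)) {
    ix <- which(comp == cid)
    if (length(ix) < 2) next
    axes <- t(vapply(ss[ix], `[[`, numeric(3), "axis"))
    ctrs <- t(vapply(ss[ix], `[[`, numeric(3), "centroid"))
    m <- length(ix)
    dperp <- matrix(Inf, m, m)
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      if (axis_angle(axes[a, ], axes[b, ]) > axis_parallel_tol) next
      u <- axes[a, ] * sign(sum(axes[a, ] * axes[b, ]))
      u <- unit3(u + axes[b, ])
      dv <- ctrs[b, ] - ctrs[a, ]
      dv <- dv - sum(dv * u) * u
      dperp[a, b] <- dperp[b, a] <- sqrt(sum(dv^2))
    }
    nearest <- apply(dperp, 1, min)
    nearest <- nearest[is.finite(nearest)]
    if (!length(nearest)) next
    sp <- stats::median(nearest)
    spacing[cid] <- sp
    adj <- dperp >= (1 - lattice_tol) * sp & dperp <= (1 + lattice_tol) * sp
    coord[ix] <- rowSums(adj)
  }
  # strings with no parallel neighbor (coordination 0) sit outside any bundle
  # and are excluded from the mode, which then reflects the bundle interior
  tab <- table(coord[coord > 0])
  modal <- if (length(tab)) as.integer(names(tab)[which.max(tab)])
           else if (length(ss)) 0L else NA_integer_
  list(coordination = coord, modal_coordination = modal, spacing_A = spacing)
}

#' Per-step twist angles along a string
#'
#' D4-folded canonical twist between every consecutive pair of string members.
#'
#' @param strings A [detect_strings()] result.
#' @param t The [particle_table()] the strings came from.
#' @param sym Point symmetry (default D4).
#' @param axis_tol Collinearity tolerance handed to [canonical_twist()]
#'   (default 30 degrees; pairs were already screened by the tandem gate).
#' @return List: `per_string` (list of per-step twist vectors, degrees),
#'   `steps` (all steps pooled), `mean_deg`, `sd_deg`, and `string_means`.
#' @export
string_twists <- function(strings, t, sym = point_symmetry("D", 4),
                          axis_tol = 30) {
  stopifnot(inherits(strings, "cbx_strings"), inherits(t, "particle_table"))
  ori <- particle_orientations(t)
  per <- lapply(strings$strings, function(s) {
    if (s$length < 2) return(numeric(0))
    vapply(seq_len(s$length - 1), function(k)
      canonical_twist(ori[, , s$rows[k]], ori[, , s$rows[k + 1]],
                      sym = sym, axis_tol = axis_tol), numeric(1))
  })
  steps <- unlist(per)
  list(per_string = per, steps = steps,
       mean_deg = if (length(steps)) mean(steps) else NA_real_,
       sd_deg = if (length(steps) > 1) stats::sd(steps) else NA_real_,
       string_means = vapply(per, function(v)
         if (length(v)) mean(v) else NA_real_, numeric(1)))
}

#' Classify a compartment by its string ordering
#'
#' Four classes by the maximum detected string length L: `random` (L < 3),
#' `short` (3 <= L < 7), and for L >= 7 `high` when at least `high_count`
#' strings reach length >= `long_min`, else `moderate`.  `moderate` and
#' `high` together form the ordered classes.
#'
#' @param lengths Integer vector of detected string lengths for one
#'   compartment (possibly empty).
#' @param short_min,long_min,high_count Class thresholds (defaults 3, 7, 5).
#' @return One of `"random"`, `"short"`, `"moderate"`, `"high"`.
#' @export
classify_compartment <- function(lengths, short_min = 3, long_min = 7,
                                 high_count = 5) {
  classify_lengths(lengths, short_min, long_min, high_count)
}

#' Population-level ordering summary
#'
#' @param classes Named character vector: class per compartment.
#' @param strings A [detect_strings()] result for the same table.
#' @param t The [particle_table()].
#' @param ordered_min_length Strings at least this long count as ordered
#'   material for the in-string particle fraction (default 3, the same
#'   boundary that separates `random` from the string-bearing classes).
#' @return List: `n_compartments`, `class_counts`, `ordered_fraction`
#'   (moderate + high, as a fraction), and `in_string_fraction` -- the
#'   fraction of particles of ordered-class compartments that lie in counted
#'   strings.
#' @export
population_summary <- function(classes, strings, t, ordered_min_length = 3) {
  stopifnot(inherits(strings, "cbx_strings"), inherits(t, "particle_table"))
  n <- length(classes)
  cc <- table(factor(classes, levels = c("random", "short", "moderate", "high")))
  ordered_ids <- names(classes)[classes %in% c("moderate", "high")]
  in_ordered <- t$compartment_id %in% ordered_ids
  n_tot <- sum(in_ordered)
  n_in <- 0L
  for (s in strings$strings)
    if (s$compartment_id %in% ordered_ids && s$length >= ordered_min_length)
      n_in <- n_in + s$length
  list(n_compartments = n, class_counts = c(cc),
       ordered_fraction = if (n) sum(cc[c("moderate", "high")]) / n else NA_real_,
       in_string_fraction = if (n_tot) n_in / n_tot else NA_real_)
}
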