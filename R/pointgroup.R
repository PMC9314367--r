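# Point-group-aware angular statistics.
#
# Rubisco is a D4 hexadecamer: one fourfold axis plus four perpendicular
# twofold axes.  Subtomogram orientations are therefore only defined up to
# right-multiplication by a group element, which makes the fourfold axis
# undirected and relative twist angles equivalent modulo 90 degrees and sign.
# Everything downstream (radial angles, tandem restraints, string twists)
# folds through this module.

#' Define a cyclic or dihedral point symmetry
#'
#' @param family `"C"` (cyclic, n rotations about z) or `"D"` (dihedral,
#'   n rotations plus n twofolds perpendicular to z; order 2n).
#' @param order The rotational order n (>= 1).  Rubisco is `point_symmetry("D", 4)`.
#' @return An object of class `point_symmetry`.
#' @examples
#' d4 <- point_symmetry("D", 4)
#' length(sym_elements(d4))   # 8
#' @export
point_symmetry <- function(family = c("D", "C"), order = 4L) {
  family <- match.arg(family)
  order <- as.integer(order)
  if (order < 1) stopf("symmetry order must be >= 1")
  structure(list(family = family, order = order),
            class = "point_symmetry")
}

#' @export
print.point_symmetry <- function(x, ...) {
  cat(sprintf("<point symmetry %s%d, %d elements>\n", x$family, x$order,
              if (x$family == "D") 2L * x$order else x$order))
  invisible(x)
}

#' Enumerate the rotation matrices of a point group
#'
#' Particle-frame group elements: `Rz(k * 360/n)` for Cn, plus
#' `Rz(k * 360/n) %*% Rx(180)` for the dihedral twofolds of Dn.
#'
#' @param sym A [point_symmetry()].
#' @return List of 3x3 rotation matrices (n for Cn, 2n for Dn).
#' @export
sym_elements <- function(sym) {
  stopifnot(inherits(sym, "point_symmetry"))
  step <- 360 / sym$order
  els <- lapply(seq_len(sym$order) - 1L, function(k) rot_z(k * step))
  if (sym$family == "D") {
    flips <- lapply(seq_len(sym$order) - 1L,
                    function(k) rot_z(k * step) %*% rot_x(180))
    els <- c(els, flips)
  }
  els
}

#' Undirected angle between two axes
#'
#' `acos(|a.b|)` in degrees, in \[0, 90\].  Axes (not vectors): antiparallel
#' inputs fold to 0 because the dihedral twofolds make the fourfold axis
#' sign-ambiguous.
#'
#' @param a,b Non-zero 3-vectors (normalized internally).
#' @return Angle in degrees in \[0, 90\].
#' @examples
#' axis_angle(c(0, 0, 1), c(0, 0, -1))   # 0
#' axis_angle(c(0, 0, 1), c(1, 0, 0))    # 90
#' @export
axis_angle <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  acos(clamp(abs(sum(a * b)), 0, 1)) * .rad2deg
}

# vectorized: angle between rows of A and rows of B (or a single axis b)
axis_angles <- function(A, b) {
  if (is.matrix(b)) d <- rowSums(A * b) else d <- as.vector(A %*% b)
  nA <- sqrt(rowSums(A^2))
  nb <- if (is.matrix(b)) sqrt(rowSums(b^2)) else sqrt(sum(b^2))
  acos(clamp(abs(d / (nA * nb)), 0, 1)) * .rad2deg
}

#' Fold an angle into the fundamental range of a point group
#'
#' Reduces an angle modulo `360 / order` and, when `signed_equiv`, identifies
#' an angle with its negative, returning the minimal non-negative
#' representative.  For D4 with `signed_equiv = TRUE` the range is \[0, 45\].
#'
#' @param angle Angle(s) in degrees (finite; vectorized).
#' @param sym A [point_symmetry()].
#' @param signed_equiv Also fold by sign (the dihedral twofold action).
#'   Defaults to `TRUE` for D-family symmetry.
#' @return Folded angle(s) in degrees.
#' @examples
#' fold_to_range(97.3, point_symmetry("D", 4))   # 7.3
#' fold_to_range(45, point_symmetry("D", 4))     # 45 (boundary fixed point)
#' @export
fold_to_range <- function(angle, sym, signed_equiv = sym$family == "D") {
  stopifnot(inherits(sym, "point_symmetry"), all(is.finite(angle)))
  period <- 360 / sym$order
  x <- angle %% period
  if (signed_equiv) x <- pmin(x, period - x)
  x
}

#' Canonical symmetry-folded twist between two oriented particles
#'
#' Decomposes the body-frame relative rotation `t(o1) %*% o2` into swing and
#' twist about the shared particle symmetry axis (+z) and folds the twist by
#' the two-sided group action.  For D4 the result is the canonical
#' representative in \[0, 45\] degrees: equivalent modulo 90 degrees (the C4
#' period) and under sign (the twofolds).  The value is exactly invariant
#' under global rotations and under right-multiplication of either
#' orientation by any group element, and is symmetric in its arguments.
#'
#' @param o1,o2 Orientation matrices (3x3 proper rotations).
#' @param sym A [point_symmetry()]; default D4.
#' @param axis_tol Collinearity pre-screen: the two symmetry axes must lie
#'   within this undirected angle (degrees) or an error is raised.  Callers
#'   tracing strings should pre-screen pairs with the same gate.
#' @return Folded twist angle in degrees (scalar).
#' @examples
#' o <- euler_to_matrix(20, 30, 40)
#' canonical_twist(o, o %*% rot_z(82.7))   # 7.3  (82.7 == -7.3 mod 90)
#' @export
canonical_twist <- function(o1, o2, sym = point_symmetry("D", 4),
                            axis_tol = 15) {
  check_rotation(o1); check_rotation(o2)
  stopifnot(inherits(sym, "point_symmetry"))
  d <- sum(o1[, 3] * o2[, 3])
  if (sym$family == "C" && d < 0)
    stopf("antiparallel symmetry axes are not equivalent under cyclic symmetry")
  misalign <- acos(clamp(if (sym$family == "D") abs(d) else d, -1, 1)) * .rad2deg
  if (misalign > axis_tol)
    stopf("symmetry axes misaligned by %.2f deg (> tolerance %.2f deg)",
          misalign, axis_tol)
  Q <- crossprod(o1, o2)                # t(o1) %*% o2, body-frame relative
  if (Q[3, 3] < 0) Q <- Q %*% rot_x(180)  # apply a twofold: align the axes
  q <- rot_to_quat(Q)
  twist <- 2 * atan2(q[4], q[1]) * .rad2deg
  fold_to_range(twist, sym)
}
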