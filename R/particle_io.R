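# Particle metadata tables.
#
# A particle table is a data.frame (class "particle_table") with one row per
# particle and the canonical columns
#   particle_id, tomogram_id, x_A, y_A, z_A, rot_deg, tilt_deg, psi_deg, score
# plus an optional compartment_id added by assign_compartments().  Positions
# are always Angstroms internally; Euler angles are intrinsic ZYZ degrees (see
# euler_to_matrix).  STAR coordinates on disk are pixel-valued and require an
# explicit pixel size -- there is deliberately no default.

PT_COLUMNS <- c("particle_id", "tomogram_id", "x_A", "y_A", "z_A",
                "rot_deg", "tilt_deg", "psi_deg", "score")

#' Construct a particle table
#'
#' @param df data.frame with columns `particle_id`, `tomogram_id`, `x_A`,
#'   `y_A`, `z_A`, `rot_deg`, `tilt_deg`, `psi_deg` and optionally `score`
#'   (in \[0,1\]) and `compartment_id`.
#' @param pixel_size Pixel size in Angstrom/pixel kept as metadata (used when
#'   writing STAR, whose coordinates are pixel-valued).
#' @return A `particle_table` (data.frame subclass).
#' @export
particle_table <- function(df, pixel_size = NA_real_) {
  if (!"score" %in% names(df)) df$score <- NA_real_
  missing <- setdiff(PT_COLUMNS, names(df))
  if (length(missing))
    stopf("particle table is missing column(s): %s", paste(missing, collapse = ", "))
  df <- df[, c(PT_COLUMNS, intersect("compartment_id", names(df))), drop = FALSE]
  df$particle_id <- as.character(df$particle_id)
  df$tomogram_id <- as.character(df$tomogram_id)
  for (cc in c("x_A", "y_A", "z_A", "rot_deg", "tilt_deg", "psi_deg", "score"))
    df[[cc]] <- as.numeric(df[[cc]])
  if (anyDuplicated(df$particle_id))
    stopf("particle_id values must be unique within a table")
  if (!all(is.finite(as.matrix(df[, c("x_A", "y_A", "z_A")]))))
    stopf("particle positions must be finite")
  sc <- df$score[!is.na(df$score)]
  if (length(sc) && (min(sc) < 0 || max(sc) > 1))
    stopf("scores must lie in [0, 1]")
  attr(df, "pixel_size") <- pixel_size
  class(df) <- c("particle_table", "data.frame")
  df
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf("<particle_table: %d particles, %d tomogram(s)%s>\n",
              nrow(x), length(unique(x$tomogram_id)),
              if (!is.na(attr(x, "pixel_size")))
                sprintf(", %.3g A/px", attr(x, "pixel_size")) else ""))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... and %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Particle positions as an n x 3 matrix (Angstrom)
#' @param t A [particle_table()].
#' @export
particle_positions <- function(t) {
  as.matrix(as.data.frame(t)[, c("x_A", "y_A", "z_A")])
}

#' Orientation matrices of all particles
#' @param t A [particle_table()].
#' @return 3 x 3 x n array; slice `[ , , i]` maps particle-frame to tomogram frame.
#' @export
particle_orientations <- function(t) {
  euler_to_matrices(t$rot_deg, t$tilt_deg, t$psi_deg)
}

#' Fourfold axes of all particles (n x 3, unit rows)
#' @param t A [particle_table()].
#' @export
particle_axes <- function(t) {
  fourfold_axes(t$rot_deg, t$tilt_deg)
}

#' Read a particle metadata table
#'
#' Supports two dialects: a RELION-style STAR loop (pixel-valued coordinates,
#' converted to Angstrom with the mandatory `pixel_size`) and a plain CSV with
#' the canonical header `particle_id,tomogram_id,x_A,y_A,z_A,rot_deg,tilt_deg,
#' psi_deg,score` already in Angstrom.
#'
#' @param path File to read.
#' @param dialect `"star"` or `"csv"` (default guessed from the extension).
#' @param pixel_size Angstrom/pixel; required for STAR, ignored for CSV.
#' @return A [particle_table()], row order preserved.
#' @export
read_particle_table <- function(path, dialect = c("auto", "star", "csv"),
                                pixel_size = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.star$", path, ignore.case = TRUE)) "star" else "csv"
  if (dialect == "star") read_star_particles(path, pixel_size)
  else read_csv_particles(path)
}

# STAR columns used (RELION naming); coordinates are pixels
STAR_REQUIRED <- c("rlnCoordinateX", "rlnCoordinateY", "rlnCoordinateZ",
                   "rlnAngleRot", "rlnAngleTilt", "rlnAnglePsi",
                   "rlnMicrographName")

read_star_particles <- function(path, pixel_size) {
  if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0)
    stopf("STAR coordinates are pixel-valued: an explicit positive pixel_size (A/px) is required")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  loop_at <- which(lines == "loop_")
  if (!length(loop_at)) stopf("no loop_ block found in STAR file %s", path)
  i <- loop_at[1] + 1L
  cols <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    cols <- c(cols, sub("^_([^ \t]+).*$", "\\1", lines[i]))
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(body)]
  missing <- setdiff(STAR_REQUIRED, cols)
  if (length(missing))
    stopf("STAR file is missing required column(s): %s", paste(missing, collapse = ", "))
  fields <- strsplit(body, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) != length(cols))
  if (length(bad))
    stopf("STAR row %d has %d fields, expected %d", bad[1],
          length(fields[[bad[1]]]), length(cols))
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) stopf("non-numeric value in column %s at row %d", col, which(is.na(v))[1])
    v
  }
  df <- data.frame(
    particle_id = if ("rlnImageName" %in% cols) m[, "rlnImageName"]
                  else sprintf("p%06d", seq_len(nrow(m))),
    tomogram_id = m[, "rlnMicrographName"],
    x_A = num("rlnCoordinateX") * pixel_size,
    y_A = num("rlnCoordinateY") * pixel_size,
    z_A = num("rlnCoordinateZ") * pixel_size,
    rot_deg = num("rlnAngleRot"),
    tilt_deg = num("rlnAngleTilt"),
    psi_deg = num("rlnAnglePsi"),
    score = if ("rlnAutopickFigureOfMerit" %in% cols)
              num("rlnAutopickFigureOfMerit") else NA_real_,
    stringsAsFactors = FALSE)
  particle_table(df, pixel_size = pixel_size)
}

read_csv_particles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(PT_COLUMNS, "score"), names(df))
  if (length(missing))
    stopf("CSV is missing required column(s): %s", paste(missing, collapse = ", "))
  for (cc in c("x_A", "y_A", "z_A", "rot_deg", "tilt_deg", "psi_deg")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stopf("non-numeric value in column %s at row %d", cc, which(is.na(v))[1])
    df[[cc]] <- v
  }
  particle_table(df)
}

#' Write a particle table
#'
#' @param t A [particle_table()].
#' @param path Output file.
#' @param dialect `"csv"` (canonical header, Angstrom) or `"star"`
#'   (pixel-valued coordinates; requires a pixel size).
#' @param pixel_size Angstrom/pixel for STAR output; defaults to the table's
#'   metadata pixel size.
#' @return `path`, invisibly.
#' @export
write_particle_table <- function(t, path, dialect = c("csv", "star"),
                                 pixel_size = attr(t, "pixel_size")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(t, "particle_table"))
  if (dialect == "csv") {
    df <- as.data.frame(t)[, PT_COLUMNS]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    if (is.null(pixel_size) || !is.finite(pixel_size) || pixel_size <= 0)
      stopf("writing STAR requires a positive pixel_size (A/px)")
    header <- c("", "data_particles", "", "loop_",
                "_rlnImageName #1", "_rlnMicrographName #2",
                "_rlnCoordinateX #3", "_rlnCoordinateY #4", "_rlnCoordinateZ #5",
                "_rlnAngleRot #6", "_rlnAngleTilt #7", "_rlnAnglePsi #8",
                "_rlnAutopickFigureOfMerit #9")
    rows <- sprintf("%s %s %.12g %.12g %.12g %.12g %.12g %.12g %.6g",
                    t$particle_id, t$tomogram_id,
                    t$x_A / pixel_size, t$y_A / pixel_size, t$z_A / pixel_size,
                    t$rot_deg, t$tilt_deg, t$psi_deg,
                    ifelse(is.na(t$score), 0, t$score))
    writeLines(c(header, rows), path)
  }
  invisible(path)
}

#' Export place-back markers for visualization
#'
#' Writes one record per particle with its position (Angstrom), fourfold-axis
#' unit vector and score.  `marker_csv` is a plain table
#' (`x_A,y_A,z_A,ax,ay,az,score`); `cmm` is a Chimera marker-set XML readable
#' by standard visualization tools (axis components carried as extra marker
#' attributes, markers colored red-to-blue by score over the 0.1-0.3
#' cross-correlation range).
#'
#' @param t A non-empty [particle_table()].
#' @param path Output file.
#' @param format `"marker_csv"` or `"cmm"`.
#' @param marker_radius Marker radius in Angstrom for CMM (default 50, about
#'   half a Rubisco diameter).
#' @return `path`, invisibly.
#' @export
export_placeback <- function(t, path, format = c("marker_csv", "cmm"),
                             marker_radius = 50) {
  format <- match.arg(format)
  stopifnot(inherits(t, "particle_table"))
  if (nrow(t) == 0) stopf("cannot export place-back markers from an empty table")
  ax <- particle_axes(t)
  if (format == "marker_csv") {
    df <- data.frame(x_A = t$x_A, y_A = t$y_A, z_A = t$z_A,
                     ax = ax[, 1], ay = ax[, 2], az = ax[, 3],
                     score = t$score)
    utils::write.csv(format(df, digits = 9, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    sc <- ifelse(is.na(t$score), 0.2, t$score)
    frac <- clamp((sc - 0.1) / 0.2, 0, 1)        # 0.1 -> red, 0.3 -> blue
    rows <- sprintf(
      paste0('<marker id="%d" x="%.4f" y="%.4f" z="%.4f" r="%.3f" g="0" ',
             'b="%.3f" radius="%g" ax="%.6f" ay="%.6f" az="%.6f" score="%.4f"/>'),
      seq_len(nrow(t)), t$x_A, t$y_A, t$z_A, 1 - frac, frac,
      marker_radius, ax[, 1], ax[, 2], ax[, 3], sc)
    writeLines(c('<marker_set name="cbxpack place-back">', rows, "</marker_set>"),
               path)
  }
  invisible(path)
}

#' Apply a global rigid transform to a particle table
#'
#' Positions become `R p + shift`; orientations are left-multiplied by `R`.
#' All analysis outputs of the package are invariant under this operation.
#'
#' @param t A [particle_table()].
#' @param R 3x3 proper rotation (default identity).
#' @param shift Length-3 translation in Angstrom (default 0).
#' @return Transformed [particle_table()].
#' @export
transform_particles <- function(t, R = diag(3), shift = c(0, 0, 0)) {
  check_rotation(R)
  pos <- particle_positions(t) %*% t(R)
  ori <- particle_orientations(t)
  df <- as.data.frame(t)
  df$x_A <- pos[, 1] + shift[1]
  df$y_A <- pos[, 2] + shift[2]
  df$z_A <- pos[, 3] + shift[3]
  for (i in seq_len(nrow(df))) {
    e <- matrix_to_euler(R %*% ori[, , i])
    df$rot_deg[i] <- e[1]; df$tilt_deg[i] <- e[2]; df$psi_deg[i] <- e[3]
  }
  out <- particle_table(df, pixel_size = attr(t, "pixel_size"))
  if ("compartment_id" %in% names(df)) out$compartment_id <- df$compartment_id
  out
}
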