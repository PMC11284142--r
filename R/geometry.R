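# 2D geometric primitives underlying every axis drawn on an axial CT slice.
#
# Coordinate convention: x increases to image-right, y increases anteriorly,
# units are millimetres. Axes are undirected: a direction d and -d name the
# same axis, so all angle comparisons are modulo 180 degrees and angles to
# the horizontal are folded into (-90, 90].

RAD2DEG <- 180 / pi
DEG2RAD <- pi / 180

#' Coerce a point set to a two-column numeric matrix
#'
#' Accepts an n x 2 matrix, a data frame with x/y (or x_mm/y_mm) columns,
#' or a length-2 numeric vector (a single point).
#'
#' @param points Point coordinates in mm.
#' @return An n x 2 numeric matrix with columns `x`, `y`.
#' @keywords internal
as_points <- function(points) {
  if (is.data.frame(points)) {
    cols <- intersect(c("x", "x_mm"), names(points))
    rows <- intersect(c("y", "y_mm"), names(points))
    if (length(cols) == 0L || length(rows) == 0L) {
      stop("point data frame must have columns x/y or x_mm/y_mm", call. = FALSE)
    }
    points <- cbind(points[[cols[1L]]], points[[rows[1L]]])
  }
  if (is.null(dim(points))) {
    if (length(points) != 2L) {
      stop("a bare numeric point must have length 2", call. = FALSE)
    }
    points <- matrix(points, nrow = 1L)
  }
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must have two columns (x, y)", call. = FALSE)
  if (!is.numeric(points) || any(!is.finite(points))) {
    stop("point coordinates must be finite numbers", call. = FALSE)
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  points
}

#' Construct an axis (undirected 2D line)
#'
#' An axis is stored as an anchor point plus a unit direction; the direction
#' is only meaningful modulo 180 degrees and is normalised to the upper
#' half-plane representative (dy > 0, or dy == 0 and dx > 0).
#'
#' @param anchor Length-2 numeric, a point on the line (mm).
#' @param direction Length-2 numeric, any non-zero vector along the line.
#' @return An object of class `"torsion_axis"`.
#' @export
new_axis <- function(anchor, direction) {
  anchor <- as.numeric(anchor)
  direction <- as.numeric(direction)
  stopifnot(length(anchor) == 2L, length(direction) == 2L)
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm < 1e-12) {
    stop("axis direction must be a non-zero finite vector", call. = FALSE)
  }
  structure(
    list(anchor = anchor, direction = upper_half(direction / nrm)),
    class = "torsion_axis"
  )
}

#' @export
print.torsion_axis <- function(x, ...) {
  cat(sprintf(
    "<axis> through (%.3f, %.3f) at %.3f deg to horizontal\n",
    x$anchor[1L], x$anchor[2L], axis_angle(x)
  ))
  invisible(x)
}

# Upper half-plane representative of an undirected unit vector.
upper_half <- function(d) {
  if (d[2L] < 0 || (d[2L] == 0 && d[1L] < 0)) -d else d
}

#' Fold an angle in degrees into (-90, 90]
#'
#' Undirected axes only carry an angle modulo 180 degrees; this is the
#' canonical representative used throughout.
#'
#' @param deg Angle(s) in degrees.
#' @return Angle(s) folded into (-90, 90].
#' @export
fold_angle <- function(deg) {
  a <- deg %% 180
  ifelse(a > 90, a - 180, a)
}

#' Algebraic least-squares circle fit (Kasa method)
#'
#' Fits a circle to >= 3 non-collinear points by linear least squares on the
#' algebraic form x^2 + y^2 + D x + E y + F = 0. Exact (zero residual) when
#' the points lie on a common circle; deterministic and closed-form, which is
#' sufficient at landmark-placement noise scales (tenths of a millimetre).
#'
#' @param points Point set (matrix, data frame, see [as_points()]); >= 3
#'   points, not all collinear.
#' @param label Optional structure label used in error messages.
#' @return A list of class `"circle_fit"` with `center` (length-2, mm),
#'   `radius` (mm) and `rms_residual` (mm, RMS of radial residuals).
#' @examples
#' fit_circle(rbind(c(0, 1), c(1, 0), c(0, -1)))  # unit circle about origin
#' @export
fit_circle <- function(points, label = NULL) {
  p <- as_points(points)
  what <- if (is.null(label)) "circle fit" else sprintf("circle fit for '%s'", label)
  if (nrow(p) < 3L) {
    stop(sprintf("%s needs at least 3 points, got %d", what, nrow(p)), call. = FALSE)
  }
  # Collinearity: rank of [x y 1] must be 3.
  A <- cbind(p, 1)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (sv[3L] <= max(sv) * 1e-10) {
    stop(sprintf("%s: points are collinear or degenerate", what), call. = FALSE)
  }
  b <- -(p[, 1L]^2 + p[, 2L]^2)
  coef <- qr.solve(A, b)
  center <- -coef[1:2] / 2
  r2 <- sum(center^2) - coef[3L]
  if (r2 <= 0) stop(sprintf("%s: degenerate radius", what), call. = FALSE)
  radius <- sqrt(r2)
  dists <- sqrt((p[, 1L] - center[1L])^2 + (p[, 2L] - center[2L])^2)
  structure(
    list(center = unname(center), radius = unname(radius),
         rms_residual = sqrt(mean((dists - radius)^2))),
    class = "circle_fit"
  )
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.4f, %.4f) mm, radius %.4f mm, rms residual %.2e mm\n",
              x$center[1L], x$center[2L], x$radius, x$rms_residual))
  invisible(x)
}

#' Total least-squares line fit
#'
#' Fits the first principal direction through the centroid of >= 2 distinct
#' points. Total (orthogonal) least squares is used rather than ordinary
#' regression of y on x because anatomical tangent lines can be
#' near-vertical.
#'
#' @param points Point set with >= 2 distinct points.
#' @param label Optional structure label used in error messages.
#' @return A `"torsion_axis"` through the centroid.
#' @examples
#' axis_angle(fit_line(rbind(c(0, 0), c(1, 1))))  # 45 degrees
#' @export
fit_line <- function(points, label = NULL) {
  p <- as_points(points)
  what <- if (is.null(label)) "line fit" else sprintf("line fit for '%s'", label)
  if (nrow(unique(p)) < 2L) {
    stop(sprintf("%s needs at least 2 distinct points", what), call. = FALSE)
  }
  ctr <- colMeans(p)
  cc <- sweep(p, 2L, ctr)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  new_axis(ctr, ev$vectors[, 1L])
}

#' Bisector of two axes, taken closer to the vertical
#'
#' Two bisectors of a pair of undirected lines exist, 90 degrees apart. For
#' talar facet tangents (near-sagittal lines) the anatomically meaningful
#' bisector is the anteroposterior one, so the representative closer to the
#' vertical (+y) axis is returned. Parallel inputs return their common
#' direction unchanged.
#'
#' @param a,b Axes (`"torsion_axis"`) or unit direction vectors.
#' @return A unit direction vector (upper half-plane representative),
#'   defined modulo 180 degrees.
#' @export
bisector_direction <- function(a, b) {
  u <- axis_direction(a)
  v <- axis_direction(b)
  cross <- u[1L] * v[2L] - u[2L] * v[1L]
  if (abs(cross) < 1e-12) {
    return(upper_half(u))
  }
  if (sum(u * v) < 0) v <- -v
  w1 <- u + v
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- c(-w1[2L], w1[1L])
  # pick the bisector closer to vertical
  if (abs(w1[2L]) >= abs(w2[2L])) upper_half(w1) else upper_half(w2)
}

axis_direction <- function(a) {
  if (inherits(a, "torsion_axis")) return(a$direction)
  a <- as.numeric(a)
  stopifnot(length(a) == 2L)
  nrm <- sqrt(sum(a^2))
  if (nrm < 1e-12) stop("zero direction vector", call. = FALSE)
  a / nrm
}

#' Perpendicular axis direction
#'
#' Rotates a direction by 90 degrees counterclockwise and reduces it to the
#' upper half-plane representative. On undirected axes this is an
#' involution: applying it twice returns the original axis.
#'
#' @param direction A `"torsion_axis"` or unit direction vector.
#' @return A unit direction vector.
#' @export
perpendicular <- function(direction) {
  d <- axis_direction(direction)
  upper_half(c(-d[2L], d[1L]))
}

#' Raw angle of an axis to the horizontal
#'
#' Counterclockwise angle in degrees from the +x (image-right) axis to the
#' line, folded into (-90, 90].
#'
#' @param a A `"torsion_axis"` or direction vector.
#' @return Angle in degrees in (-90, 90].
#' @export
axis_angle <- function(a) {
  d <- axis_direction(a)
  fold_angle(atan2(d[2L], d[1L]) * RAD2DEG)
}

#' Apply the anatomical sign convention to a raw axis angle
#'
#' Internally rotated axes carry negative angles and externally rotated axes
#' positive ones, for either limb. With anterior up and image-right equal to
#' patient-left, a right-sided raw angle is kept as measured while a
#' left-sided one is negated, so mirror-image limbs of one patient yield
#' identical anatomical values.
#'
#' @param raw_angle Raw angle(s) in degrees, in (-90, 90].
#' @param side `"left"` or `"right"`.
#' @return Signed anatomical angle(s) in degrees, in (-90, 90].
#' @export
anatomical_sign <- function(raw_angle, side) {
  side <- check_side(side)
  out <- if (side == "right") raw_angle else -raw_angle
  fold_angle(out)
}

check_side <- function(side) {
  if (length(side) != 1L || !is.character(side) || !side %in% c("left", "right")) {
    stop(sprintf("side must be \"left\" or \"right\", got %s",
                 paste(deparse(side), collapse = " ")), call. = FALSE)
  }
  side
}

#' Rotate points about a center
#'
#' @param points Point set.
#' @param theta_deg Counterclockwise rotation angle in degrees.
#' @param center Length-2 center of rotation (default origin).
#' @return Rotated n x 2 matrix.
#' @export
rotate_points <- function(points, theta_deg, center = c(0, 0)) {
  p <- as_points(points)
  th <- theta_deg * DEG2RAD
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  out <- sweep(sweep(p, 2L, center) %*% t(R), 2L, center, "+")
  colnames(out) <- c("x", "y")
  out
}

#' Mirror points about a vertical line x = x0
#'
#' @param points Point set.
#' @param x0 The vertical mirror line (default 0).
#' @return Mirrored n x 2 matrix.
#' @export
mirror_points <- function(points, x0 = 0) {
  p <- as_points(points)
  p[, 1L] <- 2 * x0 - p[, 1L]
  p
}
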