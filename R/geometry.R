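# Rigid-rotation geometry on 3D landmark coordinates.
#
# All rotations are proper (determinant +1); the package never scales,
# shears or reflects.  Angles are radians internally; user-facing entry
# points take degrees.

# tolerance below which |u x v| / (|u||v|) is treated as parallel
.PARALLEL_TOL <- 1e-12

vec_norm <- function(v) sqrt(sum(v^2))

cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

check_vec3 <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 3L)
    abort_validation(sprintf("%s must be a numeric vector of length 3", what))
  if (!all(is.finite(v)))
    abort_validation(sprintf("%s has non-finite components", what))
  invisible(v)
}

check_unit <- function(v, what = "axis", tol = 1e-9) {
  check_vec3(v, what)
  if (abs(vec_norm(v) - 1) > tol)
    abort_validation(sprintf("%s must be a unit vector (|%s| = %.12g)",
                             what, what, vec_norm(v)))
  invisible(v)
}

# coerce a single configuration to a p x 3 numeric matrix
as_pointset <- function(points, what = "points") {
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 3L)
    points <- matrix(points, ncol = 3L)
  if (!is.matrix(points) || ncol(points) != 3L || !is.numeric(points))
    abort_validation(sprintf("%s must be a numeric matrix with 3 columns", what))
  if (!all(is.finite(points)))
    abort_validation(sprintf("%s contains non-finite coordinates", what))
  points
}

check_landmark_index <- function(i, n, what = "landmark") {
  if (length(i) != 1L || !is.finite(i) || i != round(i))
    abort_index(sprintf("%s index must be a single whole number", what))
  if (i < 1L || i > n)
    abort_index(sprintf("%s index %d out of range [1, %d]", what, as.integer(i), n))
  as.integer(i)
}

#' Unit normal of the plane spanned by two vectors
#'
#' Returns the normalized cross product `(u x v) / |u x v|`, the rotation
#' axis used to bring `u` onto `v` within their common plane.  The
#' orientation follows the argument order exactly.
#'
#' @param u,v Numeric vectors of length 3; must be nonzero and not
#'   (anti)parallel.
#' @return A unit vector of length 3 orthogonal to both `u` and `v`.
#' @examples
#' plane_normal(c(1, 0, 0), c(0, 1, 0))  # c(0, 0, 1)
#' @export
plane_normal <- function(u, v) {
  check_vec3(u, "u"); check_vec3(v, "v")
  nu <- vec_norm(u); nv <- vec_norm(v)
  if (nu == 0 || nv == 0)
    abort_degenerate("plane normal undefined for a zero vector")
  w <- cross3(u, v)
  nw <- vec_norm(w)
  if (nw / (nu * nv) < .PARALLEL_TOL)
    abort_degenerate("plane normal undefined: vectors are parallel or antiparallel")
  w / nw
}

#' Angle between two 3D vectors
#'
#' Computes `acos(u . v / (|u| |v|))` in radians, clamped to the valid
#' domain to absorb floating-point drift.  Always in `[0, pi]`, symmetric
#' in its arguments and invariant to rescaling of either vector.
#'
#' @inheritParams plane_normal
#' @return The angle in radians, in `[0, pi]`.
#' @export
vector_angle <- function(u, v) {
  check_vec3(u, "u"); check_vec3(v, "v")
  nu <- vec_norm(u); nv <- vec_norm(v)
  if (nu == 0 || nv == 0)
    abort_validation("angle undefined for a zero vector")
  acos(min(1, max(-1, sum(u * v) / (nu * nv))))
}

#' Axis-angle (Rodrigues) rotation matrix
#'
#' The 3x3 proper rotation matrix for a rotation of `theta` radians about
#' the unit axis `w`, following the right-hand rule.
#'
#' @param w Unit axis of rotation (length-3 numeric, `|w| = 1` within
#'   1e-9; a non-unit axis is an error, never silently normalized).
#' @param theta Rotation angle in radians.
#' @return A 3x3 orthonormal matrix with determinant +1; `R %*% w == w`.
#' @examples
#' R <- rotation_matrix(c(0, 0, 1), pi / 2)
#' R %*% c(1, 0, 0)  # (0, 1, 0)
#' @export
rotation_matrix <- function(w, theta) {
  check_unit(w, "w")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    abort_validation("theta must be a single finite number (radians)")
  cs <- cos(theta); sn <- sin(theta); C <- 1 - cs
  w1 <- w[1L]; w2 <- w[2L]; w3 <- w[3L]
  matrix(c(
    cs + w1 * w1 * C,      w1 * w2 * C - w3 * sn, w1 * w3 * C + w2 * sn,
    w2 * w1 * C + w3 * sn, cs + w2 * w2 * C,      w2 * w3 * C - w1 * sn,
    w3 * w1 * C - w2 * sn, w3 * w2 * C + w1 * sn, cs + w3 * w3 * C),
    nrow = 3L, byrow = TRUE)
}

#' Rotation carrying one vector onto another
#'
#' Builds the proper rotation that takes `u / |u|` to `v / |v|` by rotating
#' within the plane the two vectors span, about that plane's unit normal,
#' by the angle between them.
#'
#' Parallel inputs return the identity.  For antiparallel inputs the
#' in-plane axis is undefined; the axis is then chosen deterministically as
#' the canonical basis vector most orthogonal to `u` (projected
#' perpendicular to `u`) and the rotation angle is pi.
#'
#' @inheritParams plane_normal
#' @return A 3x3 rotation matrix `R` with `R %*% (u/|u|) == v/|v|`.
#' @export
align_rotation <- function(u, v) {
  check_vec3(u, "u"); check_vec3(v, "v")
  nu <- vec_norm(u); nv <- vec_norm(v)
  if (nu == 0 || nv == 0)
    abort_degenerate("alignment undefined for a zero vector")
  s <- vec_norm(cross3(u, v)) / (nu * nv)
  cosang <- sum(u * v) / (nu * nv)
  if (s < .PARALLEL_TOL) {
    if (cosang > 0) return(diag(3))           # already aligned
    axis <- perpendicular_axis(u / nu)        # antiparallel: rotate by pi
    return(rotation_matrix(axis, pi))
  }
  rotation_matrix(plane_normal(u, v), vector_angle(u, v))
}

# canonical basis vector most orthogonal to unit u, projected into the
# plane perpendicular to u and normalized (ties broken in x, y, z order)
perpendicular_axis <- function(u) {
  k <- which.min(abs(u))
  e <- c(0, 0, 0); e[k] <- 1
  p <- e - sum(e * u) * u
  p / vec_norm(p)
}

#' Apply a rotation matrix to a set of points
#'
#' Rotates every row of a point matrix about the origin: `p_i -> R p_i`.
#' A rigid motion -- all pairwise distances, and the origin, are preserved.
#'
#' @param points A `p x 3` numeric matrix (one landmark per row), or a
#'   single length-3 vector.
#' @param R A 3x3 rotation matrix.
#' @return The rotated points, same shape as the input matrix.
#' @export
rotate_points <- function(points, R) {
  points <- as_pointset(points)
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)) || !all(is.finite(R)))
    abort_validation("R must be a finite 3x3 matrix")
  out <- points %*% t(R)
  dimnames(out) <- dimnames(points)
  out
}

# Right-handed in-plane frame perpendicular to a unit axis.  `direction`
# picks the in-plane direction that the constraint landmark is driven
# toward; by default the canonical basis vector most orthogonal to the
# axis (which reproduces the quadrant-aware arctan((r)_3 / (r)_1)
# correction for axis (0, 1, 0)).
in_axis_frame <- function(axis, direction = NULL) {
  if (is.null(direction)) {
    k <- which.min(abs(axis))
    direction <- c(0, 0, 0); direction[k] <- 1
  }
  check_vec3(direction, "direction")
  e1 <- direction - sum(direction * axis) * axis
  n1 <- vec_norm(e1)
  if (n1 < 1e-12)
    abort_validation("direction must not be parallel to the rotation axis")
  e1 <- e1 / n1
  list(e1 = e1, e2 = cross3(axis, e1))
}

#' In-axis constraint rotation
#'
#' After a structure's main axis has been aligned with `axis`, one degree
#' of freedom remains: spin about that axis.  This operation removes it by
#' rotating all points about `axis` so that a designated constraint
#' landmark comes to rest in the plane spanned by `axis` and a reference
#' in-plane direction, on the positive side of that direction.  The spin
#' angle is computed with the two-argument (quadrant-aware) arctangent of
#' the landmark's two off-axis components, so the landmark's out-of-plane
#' coordinate is driven to zero and its in-plane coordinate is strictly
#' positive in a single rotation -- this is also what fixes a "mirrored"
#' placement of the structure.
#'
#' @param points A `p x 3` matrix with the structure's axis already along
#'   `axis` (base landmark at the origin).
#' @param constraint 1-based index of the landmark to be placed in-plane.
#' @param axis Unit rotation axis (the structure's aligned main axis).
#' @param direction Optional in-plane unit direction the constraint
#'   landmark is driven toward; defaults to the canonical basis vector
#'   most orthogonal to `axis`.
#' @return The rotated `p x 3` matrix.
#' @export
in_axis_correction <- function(points, constraint, axis, direction = NULL) {
  points <- as_pointset(points)
  check_unit(axis, "axis")
  constraint <- check_landmark_index(constraint, nrow(points), "constraint")
  fr <- in_axis_frame(axis, direction)
  r <- points[constraint, ]
  alpha <- sum(r * fr$e1)
  beta  <- sum(r * fr$e2)
  off <- sqrt(alpha^2 + beta^2)
  scale <- max(vec_norm(r), 1)
  if (off < 1e-9 * scale)
    abort_degenerate("constraint landmark lies on the rotation axis; in-axis rotation undefined")
  rotate_points(points, rotation_matrix(axis, -atan2(beta, alpha)))
}

#' Unit vector at a given angle from (1, 0, 0)
#'
#' Converts a target angle in degrees into the unit vector in the
#' xy-plane forming that angle with the x-axis: `(cos t, sin t, 0)`.
#' This is the vector the articulation procedures align the second
#' structure's axis with.
#'
#' @param angle_deg Angle in degrees, from 0 to 360.
#' @return A unit length-3 vector with zero third component.
#' @examples
#' vector_from_angle(90)  # c(0, 1, 0)
#' @export
vector_from_angle <- function(angle_deg) {
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L || !is.finite(angle_deg))
    abort_validation("angle must be a single finite number in degrees")
  if (angle_deg < 0 || angle_deg > 360)
    abort_validation("angle must lie between 0 and 360 degrees")
  t <- angle_deg * pi / 180
  v <- c(cos(t), sin(t), 0)
  # snap exact quadrant angles so e.g. 90 gives (0, 1, 0) exactly
  v[abs(v) < 1e-15] <- 0
  v
}
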