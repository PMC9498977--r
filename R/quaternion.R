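# Quaternion helpers. Convention throughout the package: scalar-first
# (w, x, y, z), unit norm, interpreted as an ACTIVE rotation taking body-frame
# vectors into the world frame (v_world = R(q) v_body).

#' Normalize quaternions to unit norm
#'
#' @param q numeric vector of length 4 or an n x 4 matrix, scalar-first.
#' @return Same shape as input, each quaternion scaled to unit norm.
#' @export
quat_normalize <- function(q) {
  if (is.null(dim(q))) {
    return(q / sqrt(sum(q^2)))
  }
  q / sqrt(rowSums(q^2))
}

quat_norm <- function(q) {
  if (is.null(dim(q))) sqrt(sum(q^2)) else sqrt(rowSums(q^2))
}

#' Quaternion from an axis-angle rotation
#'
#' @param axis length-3 direction (need not be unit).
#' @param angle_deg rotation angle in degrees (right-hand rule about `axis`).
#' @return Length-4 unit quaternion (w, x, y, z).
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  half <- angle_deg * pi / 360
  c(cos(half), sin(half) * u)
}

#' Hamilton product of two quaternions
#'
#' `quat_multiply(a, b)` composes rotations: the result rotates by `b` first,
#' then by `a`.
#'
#' @param a,b length-4 quaternions (w, x, y, z).
#' @return Length-4 quaternion.
#' @export
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Rotation matrix of a quaternion
#'
#' @param q length-4 unit quaternion or n x 4 matrix.
#' @return For a single quaternion a 3 x 3 rotation matrix; for a matrix of
#'   quaternions an n x 9 matrix whose rows hold the rotation matrix in
#'   column-major order (columns 1:3 = world coordinates of body +X, etc.).
#' @export
quat_to_matrix <- function(q) {
  single <- is.null(dim(q))
  if (single) q <- matrix(q, nrow = 1)
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  m <- cbind(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),   # body +X
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),   # body +Y
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)    # body +Z
  )
  if (single) matrix(m, 3, 3) else m
}

#' Rotate a body-frame vector into the world frame
#'
#' @param q length-4 unit quaternion.
#' @param v length-3 body-frame vector.
#' @return Length-3 world-frame vector.
#' @export
quat_rotate <- function(q, v) {
  drop(quat_to_matrix(q) %*% v)
}

#' Spherical linear interpolation between unit quaternions
#'
#' Interpolates along the shortest great-circle arc (the second endpoint is
#' negated when the quaternion dot product is negative, so an antipodal
#' representation never induces a long-way sweep).
#'
#' @param q0,q1 n x 4 matrices (or length-4 vectors) of unit quaternions.
#' @param u numeric vector in `[0, 1]`, recycled against rows.
#' @return n x 4 matrix of unit quaternions.
#' @export
quat_slerp <- function(q0, q1, u) {
  if (is.null(dim(q0))) q0 <- matrix(q0, nrow = 1)
  if (is.null(dim(q1))) q1 <- matrix(q1, nrow = 1)
  n <- max(nrow(q0), nrow(q1), length(u))
  q0 <- q0[rep_len(seq_len(nrow(q0)), n), , drop = FALSE]
  q1 <- q1[rep_len(seq_len(nrow(q1)), n), , drop = FALSE]
  u <- rep_len(u, n)
  d <- rowSums(q0 * q1)
  flip <- d < 0
  q1[flip, ] <- -q1[flip, ]
  d <- pmin(1, abs(d))
  theta <- acos(d)
  out <- matrix(0, n, 4)
  small <- theta < 1e-8
  if (any(small)) {
    # endpoints (nearly) coincide: linear blend, renormalized below
    out[small, ] <- (1 - u[small]) * q0[small, , drop = FALSE] +
      u[small] * q1[small, , drop = FALSE]
  }
  if (any(!small)) {
    s <- sin(theta[!small])
    w0 <- sin((1 - u[!small]) * theta[!small]) / s
    w1 <- sin(u[!small] * theta[!small]) / s
    out[!small, ] <- w0 * q0[!small, , drop = FALSE] + w1 * q1[!small, , drop = FALSE]
  }
  quat_normalize(out)
}
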