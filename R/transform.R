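#' Rigid transforms and quaternion utilities
#'
#' A proper rigid motion in 3D is stored as a unit quaternion plus a
#' translation, convention `v' = R v + t`, right-handed axes, millimetres.
#' Quaternions are `(w, x, y, z)` with the sign canonicalized so that
#' `w >= 0` (a quaternion and its negative encode the same rotation).
#'
#' @name rigid-transform
NULL

QUAT_UNIT_TOL <- 1e-9

#' Construct a rigid transform
#'
#' @param quaternion numeric(4), `(w, x, y, z)`; must be unit length to 1e-9.
#' @param translation numeric(3), mm.
#' @return An object of class `rigid_transform` with elements `q` (canonical
#'   unit quaternion) and `t` (translation).
#' @export
rigid_transform <- function(quaternion = c(1, 0, 0, 0), translation = c(0, 0, 0)) {
  q <- as.numeric(quaternion)
  t <- as.numeric(translation)
  if (length(q) != 4L || anyNA(q)) stop("quaternion must be numeric(4) (w, x, y, z)")
  if (length(t) != 3L || anyNA(t)) stop("translation must be numeric(3)")
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > QUAT_UNIT_TOL) {
    stop(sprintf("quaternion norm %.12g deviates from 1 beyond tolerance %g", n, QUAT_UNIT_TOL))
  }
  structure(list(q = quat_canonical(q / n), t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  cat(sprintf("  quaternion (w,x,y,z): % .6f % .6f % .6f % .6f\n",
              x$q[1], x$q[2], x$q[3], x$q[4]))
  cat(sprintf("  translation (mm):     % .6f % .6f % .6f\n", x$t[1], x$t[2], x$t[3]))
  cat(sprintf("  rotation angle:       %.4f deg\n", rotation_angle(x$q)))
  invisible(x)
}

#' Canonicalize quaternion sign
#'
#' Ensures `w >= 0`; if `w` is (numerically) zero, the first non-zero
#' component among `(x, y, z)` is made positive.
#'
#' @param q numeric(4) quaternion.
#' @return numeric(4) with canonical sign.
#' @export
quat_canonical <- function(q) {
  if (q[1] < 0) return(-q)
  if (q[1] == 0) {
    for (i in 2:4) {
      if (q[i] != 0) return(if (q[i] < 0) -q else q)
    }
  }
  q
}

#' Quaternion to rotation matrix
#' @param q unit quaternion `(w, x, y, z)`.
#' @return 3x3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotation matrix to quaternion (Shepperd's method)
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @return canonical unit quaternion `(w, x, y, z)`.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  # pick the largest pivot for numerical stability
  pivots <- c(tr, R[1, 1], R[2, 2], R[3, 3])
  k <- which.max(pivots)
  if (k == 1L) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (k == 2L) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (k == 3L) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  quat_canonical(q / sqrt(sum(q^2)))
}

#' Hamilton product of two quaternions
#' @param a,b quaternions `(w, x, y, z)`.
#' @return quaternion of the composed rotation `a` after `b` applied... see
#'   [rt_compose()] for the transform-level composition.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion from axis and angle
#' @param axis numeric(3), need not be unit.
#' @param angle_deg rotation angle in degrees.
#' @return canonical unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("rotation axis must be non-zero")
  half <- angle_deg * pi / 360
  quat_canonical(c(cos(half), sin(half) * axis / n))
}

#' Rotation angle of a unit quaternion
#'
#' Angle of the rotation encoded by `q`, computed as
#' `2 * atan2(||(x,y,z)||, |w|)` (stable near 0 and 180 degrees, and
#' invariant to the sign ambiguity `q == -q`).
#'
#' @param q unit quaternion `(w, x, y, z)` or a `rigid_transform`.
#' @return angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(q) {
  if (inherits(q, "rigid_transform")) q <- q$q
  q <- as.numeric(q)
  if (length(q) != 4L) stop("expected a quaternion (w, x, y, z)")
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-6) stop(sprintf("quaternion norm %.8g is not unit within 1e-6", n))
  q <- q / n
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}

#' Apply a rigid transform to points
#' @param tf `rigid_transform`.
#' @param points n x 3 matrix (or numeric(3)).
#' @return transformed points, same shape.
#' @export
rt_apply <- function(tf, points) {
  R <- quat_to_matrix(tf$q)
  if (is.null(dim(points))) {
    return(as.numeric(R %*% points) + tf$t)
  }
  sweep(points %*% t(R), 2, tf$t, `+`)
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the motion "first `b`, then `a`":
#' `(a o b)(v) = a(b(v))`.
#' @param a,b `rigid_transform` objects.
#' @return `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  q <- quat_multiply(a$q, b$q)
  q <- q / sqrt(sum(q^2))
  Ra <- quat_to_matrix(a$q)
  rigid_transform(q, as.numeric(Ra %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf `rigid_transform`.
#' @return `rigid_transform` with `rt_compose(tf, rt_inverse(tf))` the identity.
#' @export
rt_inverse <- function(tf) {
  qi <- c(tf$q[1], -tf$q[2:4])
  Ri <- t(quat_to_matrix(tf$q))
  rigid_transform(qi, -as.numeric(Ri %*% tf$t))
}

#' Rigid transform as a 4x4 homogeneous matrix
#' @param tf `rigid_transform`.
#' @return 4x4 matrix, last row `(0, 0, 0, 1)`.
#' @export
rt_to_homogeneous <- function(tf) {
  M <- diag(4)
  M[1:3, 1:3] <- quat_to_matrix(tf$q)
  M[1:3, 4] <- tf$t
  M
}

#' Rigid transform from a 4x4 homogeneous matrix
#'
#' Validates that the rotation block is orthonormal with determinant +1
#' within `tol`, then re-orthonormalizes it by SVD projection before
#' conversion to a quaternion. Reflections (det <= 0) are rejected: a
#' reduction plan cannot mirror a fragment.
#'
#' @param M 4x4 numeric matrix, row-major convention `v' = R v + t`.
#' @param tol orthonormality tolerance on the rotation block (default 1e-6).
#' @return `rigid_transform`.
#' @export
rt_from_homogeneous <- function(M, tol = 1e-6) {
  M <- as.matrix(M)
  if (!is.numeric(M) || !all(dim(M) == c(4L, 4L)) || anyNA(M)) {
    stop("pose must be a numeric 4x4 homogeneous matrix")
  }
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > tol) {
    stop("invalid pose: bottom row of the homogeneous matrix must be (0, 0, 0, 1)")
  }
  R <- M[1:3, 1:3]
  d <- det(R)
  if (d <= 0) {
    stop(sprintf("invalid pose: rotation block has determinant %.6g <= 0 (reflection or degenerate)", d))
  }
  ortho_err <- max(abs(crossprod(R) - diag(3)))
  if (ortho_err > tol) {
    stop(sprintf("invalid pose: rotation block deviates from orthonormality by %.3g (tolerance %g)",
                 ortho_err, tol))
  }
  # project onto SO(3): nearest rotation in Frobenius norm
  s <- svd(R)
  Rn <- s$u %*% t(s$v)
  if (det(Rn) < 0) stop("invalid pose: projection produced a reflection")
  rigid_transform(matrix_to_quat(Rn), M[1:3, 4])
}

#' Uniform random rotation (quaternion) from the current RNG stream
#' @return canonical unit quaternion drawn uniformly from SO(3).
#' @keywords internal
random_quaternion <- function() {
  # Shoemake subgroup algorithm
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_canonical(q[c(4, 1, 2, 3)])
}

#' Uniform random direction on the unit sphere
#' @keywords internal
random_direction <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}
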