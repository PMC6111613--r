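#' Rotation matrix from yaw/pitch/roll angles
#'
#' Builds the rotation matrix \code{Rx(theta) \%*\% Ry(phi) \%*\% Rz(psi)},
#' i.e. the product of the three basic rotations about the x, y and z axes,
#' in that left-to-right order. This is the parameterisation used to draw
#' random sensor-unit orientations.
#'
#' @param theta,phi,psi Rotation angles in radians about the x, y and z axes.
#' @return A 3x3 rotation matrix (orthonormal, determinant +1).
#' @examples
#' rotmat_from_euler(0, 0, pi / 2)
#' @export
rotmat_from_euler <- function(theta, phi, psi) {
  if (!all(is.finite(c(theta, phi, psi)))) {
    stop("rotmat_from_euler: angles must be finite")
  }
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi);   sp <- sin(phi)
  cs <- cos(psi);   ss <- sin(psi)
  Rx <- matrix(c(1, 0, 0,  0, ct, st,  0, -st, ct), 3, 3)
  Ry <- matrix(c(cp, 0, -sp,  0, 1, 0,  sp, 0, cp), 3, 3)
  Rz <- matrix(c(cs, ss, 0,  -ss, cs, 0,  0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Uniformly random rotation from independent yaw/pitch/roll angles
#'
#' Draws the three angles independently and uniformly on \code{[-pi, pi)} and
#' composes them with [rotmat_from_euler()]. Used to re-orient sensor units
#' randomly (one draw per segment per unit).
#'
#' @param seed Optional integer seed; if supplied the draw is deterministic
#'   and the caller's RNG state is left untouched.
#' @return A 3x3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  ang <- with_seed(seed, stats::runif(3, -pi, pi))
  rotmat_from_euler(ang[1], ang[2], ang[3])
}

# Run expr under a temporary seed (or as-is when seed is NULL).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Unit quaternion from a rotation matrix
#'
#' Scalar-first convention \code{(q1, q2, q3, q4)}. The main branch computes
#' \code{q1 = sqrt(1 + d11 + d22 + d33) / 2} and the vector part
#' \code{(d32 - d23, d13 - d31, d21 - d12) / (4 q1)}; for rotations near 180
#' degrees (trace close to -1) the standard largest-diagonal branch is used
#' for numerical robustness. The sign is fixed so that \code{q1 >= 0}.
#'
#' @param R A 3x3 rotation matrix.
#' @return Numeric vector of length 4 with unit norm, scalar first.
#' @export
quat_from_rotmat <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)), all(is.finite(R)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > -1 + 1e-8) {
    q1 <- sqrt(1 + tr) / 2
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (4 * q1)
    q <- c(q1, v)
  } else {
    # near 180-degree rotation: pick the largest diagonal element
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    j <- i %% 3L + 1L
    k <- j %% 3L + 1L
    s <- sqrt(pmax(R[i, i] - R[j, j] - R[k, k] + 1, 0))
    v <- numeric(3)
    v[i] <- s / 2
    v[j] <- (R[j, i] + R[i, j]) / (2 * s)
    v[k] <- (R[k, i] + R[i, k]) / (2 * s)
    q <- c((R[k, j] - R[j, k]) / (2 * s), v)
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

#' Rotation matrix from a unit quaternion
#'
#' Inverse of [quat_from_rotmat()] up to the quaternion's sign (q and -q map
#' to the same rotation). A non-unit input is normalized first with a warning.
#'
#' @param q Numeric length-4 quaternion, scalar first.
#' @return A 3x3 rotation matrix.
#' @export
rotmat_from_quat <- function(q) {
  stopifnot(length(q) == 4L, all(is.finite(q)))
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > 1e-9) {
    warning("rotmat_from_quat: input not unit norm; normalizing")
    q <- q / n
  }
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c + a * d), 2 * (b * d - a * c),
    2 * (b * c - a * d), a * a - b * b + c * c - d * d, 2 * (c * d + a * b),
    2 * (b * d + a * c), 2 * (c * d - a * b), a * a - b * b - c * c + d * d
  ), 3, 3)
}

#' Quaternion algebra (Hamilton convention, scalar first)
#'
#' \code{quat_multiply} is the Hamilton product, \code{quat_conjugate} negates
#' the vector part and \code{quat_normalize} rescales to unit norm.
#'
#' @param a,b Numeric length-4 quaternions, scalar first.
#' @return A numeric length-4 quaternion.
#' @export
quat_multiply <- function(a, b) {
  stopifnot(length(a) == 4L, length(b) == 4L, all(is.finite(c(a, b))))
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' @rdname quat_multiply
#' @export
quat_conjugate <- function(a) {
  stopifnot(length(a) == 4L, all(is.finite(a)))
  c(a[1], -a[2], -a[3], -a[4])
}

#' @rdname quat_multiply
#' @export
quat_normalize <- function(a) {
  stopifnot(length(a) == 4L, all(is.finite(a)))
  n <- sqrt(sum(a^2))
  if (n == 0) stop("quat_normalize: zero quaternion")
  a / n
}

# ---- vectorized internals -------------------------------------------------
# Trajectories are stored row-wise: Q is N x 4 (scalar first), rotation
# matrices as N x 9 in column-major order (r11,r21,r31,r12,...,r33).

quat_rows_to_rotmat_rows <- function(Q) {
  a <- Q[, 1]; b <- Q[, 2]; c <- Q[, 3]; d <- Q[, 4]
  cbind(
    a * a + b * b - c * c - d * d,        # r11
    2 * (b * c + a * d),                  # r21
    2 * (b * d - a * c),                  # r31
    2 * (b * c - a * d),                  # r12
    a * a - b * b + c * c - d * d,        # r22
    2 * (c * d + a * b),                  # r32
    2 * (b * d + a * c),                  # r13
    2 * (c * d - a * b),                  # r23
    a * a - b * b - c * c + d * d         # r33
  )
}

# rows of V (N x 3) rotated by the per-row matrices in Rr (N x 9): R v
rotate_rows <- function(Rr, V) {
  cbind(
    Rr[, 1] * V[, 1] + Rr[, 4] * V[, 2] + Rr[, 7] * V[, 3],
    Rr[, 2] * V[, 1] + Rr[, 5] * V[, 2] + Rr[, 8] * V[, 3],
    Rr[, 3] * V[, 1] + Rr[, 6] * V[, 2] + Rr[, 9] * V[, 3]
  )
}

# rows rotated by the transposes: R^T v
rotate_rows_t <- function(Rr, V) {
  cbind(
    Rr[, 1] * V[, 1] + Rr[, 2] * V[, 2] + Rr[, 3] * V[, 3],
    Rr[, 4] * V[, 1] + Rr[, 5] * V[, 2] + Rr[, 6] * V[, 3],
    Rr[, 7] * V[, 1] + Rr[, 8] * V[, 2] + Rr[, 9] * V[, 3]
  )
}

# per-row products A_i B_i^T for N x 9 inputs (used for differential rotations
# D_n = R_{n+1} R_n^T)
rotmat_rows_mult_bt <- function(A, B) {
  out <- matrix(0, nrow(A), 9L)
  # out[, 3*(j-1)+i] = sum_k A[i,k] B[j,k]
  for (i in 1:3) {
    for (j in 1:3) {
      s <- A[, i] * B[, j] + A[, i + 3L] * B[, j + 3L] + A[, i + 6L] * B[, j + 6L]
      out[, 3L * (j - 1L) + i] <- s
    }
  }
  out
}

# vectorized rotmat rows -> quaternion rows (main branch; fallback loop for
# rows with trace near -1); sign fixed to q1 >= 0
rotmat_rows_to_quat_rows <- function(Rr) {
  tr <- Rr[, 1] + Rr[, 5] + Rr[, 9]
  Q <- matrix(0, nrow(Rr), 4L)
  ok <- tr > -1 + 1e-8
  q1 <- sqrt(pmax(1 + tr[ok], 0)) / 2
  Q[ok, ] <- cbind(
    q1,
    (Rr[ok, 6] - Rr[ok, 8]) / (4 * q1),
    (Rr[ok, 7] - Rr[ok, 3]) / (4 * q1),
    (Rr[ok, 2] - Rr[ok, 4]) / (4 * q1)
  )
  if (any(!ok)) {
    for (idx in which(!ok)) {
      Q[idx, ] <- quat_from_rotmat(matrix(Rr[idx, ], 3, 3))
    }
  }
  Q <- Q / sqrt(rowSums(Q^2))
  flip <- Q[, 1] < 0
  Q[flip, ] <- -Q[flip, ]
  Q
}
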