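# Independent oracles and small fixtures used across the test files.

# axis-angle quaternion of a rotation matrix, computed without the package's
# conversion path: angle from the trace, axis from the skew part
quat_axis_angle_oracle <- function(R) {
  # angle via atan2 of the skew-part magnitude and (trace-1)/2, which stays
  # well conditioned where acos((trace-1)/2) does not
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  s <- sqrt(sum(v^2)) / 2
  cc <- (sum(diag(R)) - 1) / 2
  ang <- atan2(s, cc)
  if (s < 1e-12) return(c(1, 0, 0, 0))
  q <- c(cos(ang / 2), sin(ang / 2) * v / (2 * s))
  if (q[1] < 0) q <- -q
  q
}

# brute-force greedy DFT peak picker on a one-sided spectrum (R reference
# for the compiled implementation)
dft_peaks_oracle <- function(sp, k = 5L, minsep = 11L) {
  nb <- length(sp)
  is_max <- vapply(seq_len(nb), function(i) {
    (i == 1L || sp[i] >= sp[i - 1L]) && (i == nb || sp[i] >= sp[i + 1L])
  }, TRUE)
  cand <- which(is_max)
  cand <- cand[order(-sp[cand], cand)]
  chosen <- integer(0)
  for (i in cand) {
    if (length(chosen) == k) break
    if (all(abs(i - chosen) >= minsep)) chosen <- c(chosen, i)
  }
  list(mag = c(sp[chosen], rep(0, k - length(chosen))),
       bin = c(chosen, rep(0, k - length(chosen))))
}

# angle in degrees between the rotations encoded by two quaternion rows
quat_err_deg <- function(Q1, Q2) {
  2 * acos(pmin(abs(rowSums(Q1 * Q2)), 1)) * 180 / pi
}

# constant-orientation synthetic stream aligned with the Earth references
static_stream <- function(n = 50, rate = 25, gravity = 9.81) {
  list(acc = matrix(rep(c(0, 0, gravity), each = n), n, 3),
       gyro = matrix(0, n, 3),
       mag = matrix(rep(mag_reference(), each = n), n, 3),
       rate = rate)
}

# rotate a unit segment's three streams by the constant matrix P
# (emulates the unit worn at a different fixed orientation)
rotate_segment <- function(seg, P) {
  unit_segment(seg$acc %*% t(P), seg$gyro %*% t(P), seg$mag %*% t(P),
               rate = seg$rate, unit = seg$unit)
}

# ground-truth trajectory object from a simulate_unit() result
truth_traj <- function(sim, rate = 25) {
  structure(list(quat = sim$truth$quat, rate = rate),
            class = "orientation_trajectory")
}

# trajectory of the same motion observed from a re-oriented unit: data
# premultiplied by P correspond to orientations R P^T
rotated_traj <- function(traj, P) {
  n <- nrow(traj$quat)
  qp <- quat_from_rotmat(t(P))
  Q <- t(apply(traj$quat, 1L, function(q) quat_multiply(q, qp)))
  structure(list(quat = Q, rate = traj$rate),
            class = "orientation_trajectory")
}

# three well-separated Gaussian blobs (off-origin class means)
gaussian_blobs <- function(n = 60L, d = 5L, sep = 8, seed = 1L) {
  set.seed(seed)
  mu <- diag(sep, 3L, d)
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(n * d), n, d), 2L, mu[k, ], "+")
  }))
  list(X = X, y = factor(rep(1:3, each = n)))
}

noiseless <- c(acc = 0, gyro = 0, mag = 0)
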