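#' Construct a sensor-unit segment
#'
#' Bundles one sensor unit's tri-axial accelerometer, gyroscope and
#' magnetometer sequences over a time window.
#'
#' @param acc,gyro,mag Numeric \code{N x 3} matrices (same N).
#' @param rate Sampling rate in Hz.
#' @param unit Optional unit identifier.
#' @return A list of class \code{"unit_segment"}.
#' @export
unit_segment <- function(acc, gyro, mag, rate = 25, unit = 1L) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro); mag <- as.matrix(mag)
  n <- nrow(acc)
  stopifnot(ncol(acc) == 3L, ncol(gyro) == 3L, ncol(mag) == 3L,
            nrow(gyro) == n, nrow(mag) == n,
            all(is.finite(acc)), all(is.finite(gyro)), all(is.finite(mag)),
            rate > 0)
  structure(list(acc = acc, gyro = gyro, mag = mag, rate = rate,
                 unit = unit), class = "unit_segment")
}

new_transformed <- function(channels, technique) {
  structure(list(channels = channels, technique = technique),
            class = "transformed_segment")
}

#' @export
print.transformed_segment <- function(x, ...) {
  cat("Transformed segment (", x$technique, "): ", nrow(x$channels),
      " samples x ", ncol(x$channels), " channels\n", sep = "")
  invisible(x)
}

tri_names <- function(prefix, suffix = c("x", "y", "z")) {
  paste(prefix, suffix, sep = "_")
}

#' Pass-through transform (fixed sensor orientations)
#'
#' The baseline in which data are used untransformed, assuming every sensor
#' unit keeps its nominal orientation. Nine channels per unit.
#'
#' @param seg A [unit_segment()].
#' @return A \code{"transformed_segment"} with 9 channels.
#' @export
t_reference <- function(seg) {
  ch <- cbind(seg$acc, seg$gyro, seg$mag)
  colnames(ch) <- c(tri_names("acc"), tri_names("gyro"), tri_names("mag"))
  new_transformed(ch, "reference")
}

#' Random re-orientation of a sensor unit
#'
#' Emulates a unit worn at an arbitrary fixed orientation within the
#' segment: one random rotation (yaw/pitch/roll independent, uniform on
#' \code{[-pi, pi)}) pre-multiplies all three tri-axial streams.
#'
#' @param seg A [unit_segment()].
#' @param seed Optional integer seed for a deterministic rotation.
#' @return A \code{"transformed_segment"} with 9 channels.
#' @export
t_random_rotation <- function(seg, seed = NULL) {
  P <- random_rotation(seed)
  ch <- cbind(seg$acc %*% t(P), seg$gyro %*% t(P), seg$mag %*% t(P))
  colnames(ch) <- c(tri_names("acc"), tri_names("gyro"), tri_names("mag"))
  new_transformed(ch, "random")
}

#' Per-sample Euclidean norms
#'
#' Replaces each tri-axial stream by its per-sample Euclidean norm: three
#' channels per unit, exactly invariant to unit orientation.
#'
#' @param seg A [unit_segment()].
#' @return A \code{"transformed_segment"} with 3 channels.
#' @export
t_norm <- function(seg) {
  ch <- cbind(sqrt(rowSums(seg$acc^2)),
              sqrt(rowSums(seg$gyro^2)),
              sqrt(rowSums(seg$mag^2)))
  colnames(ch) <- c("acc_norm", "gyro_norm", "mag_norm")
  new_transformed(ch, "norm")
}

#' Decomposition along and perpendicular to the gravity estimate
#'
#' The gravity direction is estimated as the normalised time-average of the
#' acceleration over the segment. Each sensor stream is then summarised by
#' its signed projection onto that direction and the magnitude of the
#' perpendicular component: six channels per unit, exactly invariant to
#' unit orientation.
#'
#' @param seg A [unit_segment()].
#' @param eps Threshold below which the mean acceleration is considered
#'   degenerate.
#' @return A \code{"transformed_segment"} with 6 channels.
#' @export
t_gravity <- function(seg, eps = 1e-8) {
  g <- colMeans(seg$acc)
  gn <- sqrt(sum(g^2))
  if (gn < eps) stop("t_gravity: mean acceleration is (near) zero")
  ghat <- g / gn
  decomp <- function(X) {
    along <- as.numeric(X %*% ghat)
    perp <- sqrt(pmax(rowSums(X^2) - along^2, 0))
    cbind(along, perp)
  }
  ch <- cbind(decomp(seg$acc), decomp(seg$gyro), decomp(seg$mag))
  colnames(ch) <- c("acc_along", "acc_perp", "gyro_along", "gyro_perp",
                    "mag_along", "mag_perp")
  new_transformed(ch, "gravity")
}

#' Representation in data-driven principal axes (SVD)
#'
#' Concatenates the unit's three tri-axial streams into a 3 x 3N matrix,
#' takes its left singular vectors (descending singular values) as axes and
#' re-expresses every stream in those axes. Each axis's sign is fixed so
#' that the largest-magnitude projection of the data onto it is positive
#' (ties broken toward the earlier sample), which makes the output
#' deterministic and, up to this convention, exactly invariant to a
#' constant re-orientation of the unit.
#'
#' @param seg A [unit_segment()].
#' @return A \code{"transformed_segment"} with 9 channels.
#' @export
t_svd <- function(seg) {
  M <- cbind(t(seg$acc), t(seg$gyro), t(seg$mag))  # 3 x 3N
  if (all(M == 0)) {
    warning("t_svd: all-zero data; using identity axes")
    U <- diag(3)
  } else {
    U <- svd(M, nu = 3, nv = 0)$u
    for (k in 1:3) {
      p <- as.numeric(crossprod(U[, k], M))
      j <- which.max(abs(p))
      if (p[j] < 0) U[, k] <- -U[, k]
    }
  }
  ch <- cbind(seg$acc %*% U, seg$gyro %*% U, seg$mag %*% U)
  colnames(ch) <- c(tri_names("acc", c("p1", "p2", "p3")),
                    tri_names("gyro", c("p1", "p2", "p3")),
                    tri_names("mag", c("p1", "p2", "p3")))
  new_transformed(ch, "svd")
}

#' Sensor sequences re-expressed in the Earth frame
#'
#' Pre-multiplies every sample of every tri-axial stream by the sensor
#' orientation at that sample, yielding North-East-Down Earth-frame
#' components: nine channels per unit.
#'
#' @param seg A [unit_segment()].
#' @param traj An \code{"orientation_trajectory"} of the same length as the
#'   segment (typically from [estimate_orientation()]).
#' @return A \code{"transformed_segment"} with 9 channels.
#' @export
t_earth <- function(seg, traj) {
  Q <- traj$quat
  if (nrow(Q) != nrow(seg$acc)) {
    stop("t_earth: trajectory length does not match segment length")
  }
  Rr <- quat_rows_to_rotmat_rows(Q)
  ch <- cbind(rotate_rows(Rr, seg$acc), rotate_rows(Rr, seg$gyro),
              rotate_rows(Rr, seg$mag))
  colnames(ch) <- c(tri_names("accE", c("N", "E", "D")),
                    tri_names("gyroE", c("N", "E", "D")),
                    tri_names("magE", c("N", "E", "D")))
  new_transformed(ch, "earth")
}

#' Differential sensor rotations in the Earth frame
#'
#' For consecutive orientations \code{R_n}, the sensor-frame rotation
#' between samples is \code{C_n = R_n^T R_(n+1)}; expressed in the Earth
#' frame by the similarity transformation it becomes
#' \code{D_n = R_(n+1) R_n^T}, which is invariant to any constant
#' re-orientation of the unit. Each \code{D_n} is also encoded as a unit
#' quaternion with non-negative scalar part; for small inter-sample
#' rotations these are close to \code{(1, 0, 0, 0)}. The sequence is padded
#' by repeating the final value so its length equals the trajectory length.
#'
#' @param traj An \code{"orientation_trajectory"} (length >= 2).
#' @return A list of class \code{"differential_rotation_seq"} with
#'   \code{D} (N x 9 rotation-matrix rows, column-major) and \code{quat}
#'   (N x 4).
#' @export
differential_rotations <- function(traj) {
  Q <- traj$quat
  n <- nrow(Q)
  if (n < 2L) stop("differential_rotations: need at least 2 samples")
  Rr <- quat_rows_to_rotmat_rows(Q)
  D <- rotmat_rows_mult_bt(Rr[2:n, , drop = FALSE],
                           Rr[1:(n - 1), , drop = FALSE])
  D <- rbind(D, D[n - 1L, ])
  qd <- rotmat_rows_to_quat_rows(D)
  structure(list(D = D, quat = qd), class = "differential_rotation_seq")
}

#' Earth-frame sequences plus differential quaternions
#'
#' The orientation-invariant representation combining the nine Earth-frame
#' channels of [t_earth()] with the four components of the differential
#' quaternion sequence of [differential_rotations()]: 13 channels per unit.
#'
#' @inheritParams t_earth
#' @return A \code{"transformed_segment"} with 13 channels.
#' @export
t_proposed <- function(seg, traj) {
  e <- t_earth(seg, traj)
  qd <- differential_rotations(traj)$quat
  colnames(qd) <- paste0("qdiff_", 1:4)
  new_transformed(cbind(e$channels, qd), "proposed")
}

#' Transform technique registry
#' @return Character vector of the seven technique names.
#' @export
har_techniques <- function() {
  c("reference", "random", "norm", "gravity", "svd", "earth", "proposed")
}

#' Apply a named transform technique to a unit segment
#'
#' Dispatcher over the seven pre-processing techniques. For the Earth-frame
#' techniques a ground-truth or estimated orientation trajectory may be
#' supplied; otherwise one is estimated from the segment itself.
#'
#' @param seg A [unit_segment()].
#' @param technique One of [har_techniques()].
#' @param traj Optional \code{"orientation_trajectory"} for
#'   \code{"earth"}/\code{"proposed"}.
#' @param seed Optional seed for \code{"random"}.
#' @param config [filter_config()] used when a trajectory must be estimated.
#' @return A \code{"transformed_segment"}.
#' @export
transform_segment <- function(seg, technique, traj = NULL, seed = NULL,
                              config = filter_config()) {
  technique <- match.arg(technique, har_techniques())
  if (technique %in% c("earth", "proposed") && is.null(traj)) {
    traj <- estimate_orientation(seg, config)
  }
  switch(technique,
    reference = t_reference(seg),
    random = t_random_rotation(seg, seed),
    norm = t_norm(seg),
    gravity = t_gravity(seg),
    svd = t_svd(seg),
    earth = t_earth(seg, traj),
    proposed = t_proposed(seg, traj)
  )
}

#' Channels per unit for each technique
#' @param technique One of [har_techniques()].
#' @return Integer channel count per sensor unit.
#' @export
channels_per_unit <- function(technique) {
  technique <- match.arg(technique, har_techniques())
  switch(technique, reference = 9L, random = 9L, norm = 3L, gravity = 6L,
         svd = 9L, earth = 9L, proposed = 13L)
}
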