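# Synthetic IMU generation with ground-truth orientation.
#
# A unit's orientation evolves as a fixed posture composed with a smooth
# oscillatory rotation R(t) = P Rx(a(t)) Ry(b(t)) Rz(c(t)) whose angles are
# sinusoids; the emitted gyroscope signal is the exact body-frame angular
# velocity of that trajectory, the accelerometer is R^T (g_E + a_E(t)) so a
# static reading points Earth-down (North-East-Down convention), and the
# magnetometer is R^T m_E with a configurable dip. Class identity lives in
# the sinusoid frequencies/amplitudes, the Earth-frame motion directions,
# the rotation-oscillation axis and (for stationary classes) the posture.

#' Motion specification for one activity class
#'
#' @param class_id Integer class identifier.
#' @param stationary Logical: posture only, no oscillatory motion.
#' @param posture_angles Length-3 yaw/pitch/roll angles (rad) of the base
#'   posture.
#' @param rot_amp,rot_freq Length-3 amplitudes (rad) and frequencies (Hz)
#'   of the oscillatory rotation angles about x, y, z.
#' @param acc_dirs 3 x 2 matrix of Earth-frame unit directions of the two
#'   motion-acceleration sinusoids.
#' @param acc_amp,acc_freq Length-2 amplitudes (m/s^2) and frequencies (Hz)
#'   of those sinusoids.
#' @param noise Named standard deviations: \code{acc} (m/s^2), \code{gyro}
#'   (rad/s), \code{mag} (relative to the unit field magnitude).
#' @param gravity Gravity magnitude (m/s^2).
#' @param mag_dip_deg Magnetic dip angle (degrees).
#' @return A list of class \code{"motion_spec"}.
#' @export
motion_spec <- function(class_id = 1L, stationary = FALSE,
                        posture_angles = c(0, 0, 0),
                        rot_amp = c(0, 0, 0), rot_freq = c(1, 1, 1),
                        acc_dirs = cbind(c(0, 0, 1), c(1, 0, 0)),
                        acc_amp = c(0, 0), acc_freq = c(1, 2),
                        noise = c(acc = 0.05, gyro = 0.005, mag = 0.01),
                        gravity = 9.81, mag_dip_deg = 60) {
  stopifnot(all(rot_amp >= 0), all(acc_amp >= 0),
            length(rot_amp) == 3L, length(rot_freq) == 3L,
            length(acc_amp) == 2L, length(acc_freq) == 2L)
  structure(list(class_id = class_id, stationary = stationary,
                 posture_angles = posture_angles, rot_amp = rot_amp,
                 rot_freq = rot_freq, acc_dirs = acc_dirs,
                 acc_amp = acc_amp, acc_freq = acc_freq, noise = noise,
                 gravity = gravity, mag_dip_deg = mag_dip_deg),
            class = "motion_spec")
}

#' Default motion specifications for the activity classes
#'
#' Builds a deterministic table of per-class motion signatures. The first
#' four classes are stationary postures (distinct attitudes, no motion),
#' mirroring sitting/standing/lying-type activities; the rest are
#' oscillatory motions whose base frequency, motion-acceleration direction
#' and rotation-oscillation axis vary systematically, so that some class
#' triplets share their amplitude spectra (hence are hard for
#' magnitude-only representations) while differing in motion direction.
#'
#' @param n_classes Number of classes (default 19).
#' @param n_stationary Number of stationary classes (default 4).
#' @param noise Sensor noise standard deviations, see [motion_spec()].
#' @return List of \code{"motion_spec"} objects.
#' @export
motion_specs <- function(n_classes = 19L,
                         n_stationary = min(4L, n_classes %/% 2L),
                         noise = c(acc = 0.05, gyro = 0.005, mag = 0.01)) {
  stopifnot(n_classes >= 1L, n_stationary >= 0L, n_stationary <= n_classes)
  postures_stat <- list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                        c(pi / 2, 0, pi / 2), c(0, pi / 2, pi / 2),
                        c(pi / 2, pi / 2, 0))
  specs <- vector("list", n_classes)
  for (k in seq_len(n_classes)) {
    if (k <= n_stationary) {
      pk <- postures_stat[[(k - 1L) %% length(postures_stat) + 1L]]
      specs[[k]] <- motion_spec(k, stationary = TRUE, posture_angles = pk,
                                noise = noise)
    } else {
      j <- k - n_stationary
      f_base <- 0.5 + 0.25 * ((j - 1L) %% 5L)
      grp <- (j - 1L) %/% 5L
      axis <- (j - 1L) %% 3L + 1L
      rot_amp <- rep(0.12, 3L)
      rot_amp[axis] <- 0.6
      dirs <- switch(grp %% 4L + 1L,
        cbind(c(0, 0, 1), c(1, 0, 0)),
        cbind(c(1, 0, 0), c(0, 1, 0)),
        cbind(c(1, 0, 1) / sqrt(2), c(0, 1, 0)),
        cbind(c(0, 1, 0), c(0, 0, 1))
      )
      specs[[k]] <- motion_spec(
        k, stationary = FALSE,
        posture_angles = c(0.3 * j, 0.15 * j, 0.45 * j) %% (2 * pi),
        rot_amp = rot_amp, rot_freq = rep(1.4 * f_base, 3L),
        acc_dirs = dirs,
        acc_amp = c(2 + 0.4 * ((j - 1L) %% 5L), 0.8),
        acc_freq = c(f_base, 2 * f_base),
        noise = noise
      )
    }
  }
  specs
}

# rotation-matrix rows (N x 9, column-major) of Rx(a) Ry(b) Rz(c)
euler_rows <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a)
  cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  cbind(
    cb * cc,                      # r11
    ca * sc + sa * sb * cc,       # r21
    sa * sc - ca * sb * cc,       # r31
    -cb * sc,                     # r12
    ca * cc - sa * sb * sc,       # r22
    sa * cc + ca * sb * sc,       # r32
    sb,                           # r13
    -sa * cb,                     # r23
    ca * cb                       # r33
  )
}

# left-multiply every row-matrix in M (N x 9) by the constant 3x3 matrix P
premult_rows <- function(P, M) {
  out <- matrix(0, nrow(M), 9L)
  for (i in 1:3) {
    for (j in 1:3) {
      col <- 3L * (j - 1L) + i
      out[, col] <- P[i, 1] * M[, 3L * (j - 1L) + 1L] +
        P[i, 2] * M[, 3L * (j - 1L) + 2L] +
        P[i, 3] * M[, 3L * (j - 1L) + 3L]
    }
  }
  out
}

#' Simulate one sensor unit with ground-truth orientation
#'
#' Generates a tri-axial accelerometer/gyroscope/magnetometer stream whose
#' readings are exactly consistent (before noise) with a known orientation
#' trajectory: the gyroscope is the analytic body-frame angular velocity,
#' the accelerometer reads \code{R^T (g_E + a_E)} and the magnetometer
#' \code{R^T m_E}.
#'
#' @param spec A [motion_spec()].
#' @param duration_s Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Optional seed (phases and noise); when \code{NULL}, draws
#'   from the current RNG state.
#' @param posture Optional 3x3 rotation overriding the posture implied by
#'   \code{spec$posture_angles} (used to compose unit-placement offsets).
#' @return List with \code{stream} (a [unit_segment()]) and \code{truth}
#'   (list: \code{quat} N x 4 ground-truth orientation, \code{acc_E}
#'   Earth-frame motion acceleration, \code{mag_E}, \code{gravity_E}).
#' @export
simulate_unit <- function(spec, duration_s, rate = 25, seed = NULL,
                          posture = NULL) {
  n <- round(duration_s * rate)
  if (n < 2L) stop("simulate_unit: duration * rate must be >= 2")
  if (any(c(spec$rot_freq[spec$rot_amp > 0], spec$acc_freq[spec$acc_amp > 0])
          >= rate / 2)) {
    stop("simulate_unit: oscillation frequency at or above Nyquist")
  }
  with_seed(seed, {
    tt <- (seq_len(n) - 1L) / rate
    ph_rot <- stats::runif(3L, 0, 2 * pi)
    ph_acc <- stats::runif(2L, 0, 2 * pi)
    wr <- 2 * pi * spec$rot_freq
    a <- spec$rot_amp[1] * sin(wr[1] * tt + ph_rot[1])
    b <- spec$rot_amp[2] * sin(wr[2] * tt + ph_rot[2])
    c_ <- spec$rot_amp[3] * sin(wr[3] * tt + ph_rot[3])
    da <- spec$rot_amp[1] * wr[1] * cos(wr[1] * tt + ph_rot[1])
    db <- spec$rot_amp[2] * wr[2] * cos(wr[2] * tt + ph_rot[2])
    dc <- spec$rot_amp[3] * wr[3] * cos(wr[3] * tt + ph_rot[3])
    M <- euler_rows(a, b, c_)
    P <- if (is.null(posture)) {
      rotmat_from_euler(spec$posture_angles[1], spec$posture_angles[2],
                        spec$posture_angles[3])
    } else posture
    Rr <- premult_rows(P, M)
    # body-frame angular velocity of R(t) = P Rx(a) Ry(b) Rz(c):
    # omega = da * (Rz^T Ry^T x) + db * (Rz^T y) + dc * z
    cb <- cos(b); sb <- sin(b); cc <- cos(c_); sc <- sin(c_)
    omega <- cbind(da * cb * cc + db * sc,
                   -da * cb * sc + db * cc,
                   da * sb + dc)
    wa <- 2 * pi * spec$acc_freq
    acc_E <- outer(spec$acc_amp[1] * sin(wa[1] * tt + ph_acc[1]),
                   spec$acc_dirs[, 1]) +
             outer(spec$acc_amp[2] * sin(wa[2] * tt + ph_acc[2]),
                   spec$acc_dirs[, 2])
    g_E <- c(0, 0, spec$gravity)
    dip <- spec$mag_dip_deg * pi / 180
    m_E <- c(cos(dip), 0, sin(dip))
    acc <- rotate_rows_t(Rr, sweep(acc_E, 2L, g_E, "+"))
    mag <- rotate_rows_t(Rr, matrix(m_E, n, 3L, byrow = TRUE))
    ns <- spec$noise
    if (any(ns > 0)) {
      acc <- acc + matrix(stats::rnorm(3L * n, 0, ns[["acc"]]), n, 3L)
      omega <- omega + matrix(stats::rnorm(3L * n, 0, ns[["gyro"]]), n, 3L)
      mag <- mag + matrix(stats::rnorm(3L * n, 0, ns[["mag"]]), n, 3L)
    }
    list(stream = unit_segment(acc, omega, mag, rate = rate),
         truth = list(quat = rotmat_rows_to_quat_rows(Rr), acc_E = acc_E,
                      mag_E = m_E, gravity_E = g_E))
  })
}

# fixed body-placement attitude offsets for the five units
# (torso, right arm, left arm, right leg, left leg)
unit_offsets <- function(units) {
  tab <- list(c(0, 0, 0), c(pi / 2, 0, 0), c(-pi / 2, 0, 0),
              c(0, pi / 2, 0), c(0, -pi / 2, 0))
  lapply(seq_len(units), function(u) {
    ang <- tab[[(u - 1L) %% length(tab) + 1L]]
    rotmat_from_euler(ang[1], ang[2], ang[3])
  })
}

#' Simulate a complete multi-subject activity dataset in memory
#'
#' Generates, for every subject and activity class, a continuous multi-unit
#' recording with per-subject parameter jitter (amplitudes, frequencies and
#' posture vary mildly across subjects) and per-unit placement offsets,
#' together with the ground-truth orientation trajectory of every unit.
#'
#' @param n_subjects,n_classes Numbers of subjects and activity classes.
#' @param minutes Recording duration per subject-activity (default 5).
#' @param rate Sampling rate in Hz (default 25).
#' @param units Number of sensor units (default 5).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param noise Sensor noise standard deviations, see [motion_spec()].
#' @param specs Optional list of [motion_spec()] overriding the defaults.
#' @return Object of class \code{"har_dataset"}: \code{streams} (list of
#'   \code{N x (9 units)} matrices, channel order per unit acc x/y/z,
#'   gyro x/y/z, mag x/y/z), \code{meta} (data frame with \code{subject},
#'   \code{activity}), \code{truth} (per stream, per unit: ground-truth
#'   quaternion trajectory), \code{rate}, \code{units}.
#' @export
simulate_har_data <- function(n_subjects = 8L, n_classes = 19L, minutes = 5,
                              rate = 25, units = 5L, seed = 1L,
                              noise = c(acc = 0.05, gyro = 0.005,
                                        mag = 0.01),
                              specs = NULL) {
  stopifnot(n_subjects >= 1L, n_classes >= 1L, units >= 1L, minutes > 0)
  if (is.null(specs)) specs <- motion_specs(n_classes, noise = noise)
  stopifnot(length(specs) == n_classes)
  offsets <- unit_offsets(units)
  duration <- minutes * 60
  unit_amp <- c(1, 0.8, 0.8, 1.2, 1.2)[(seq_len(units) - 1L) %% 5L + 1L]
  streams <- vector("list", n_subjects * n_classes)
  truth <- vector("list", n_subjects * n_classes)
  meta <- data.frame(
    subject = rep(seq_len(n_subjects), each = n_classes),
    activity = rep(seq_len(n_classes), times = n_subjects)
  )
  with_seed(seed, {
    idx <- 0L
    for (s in seq_len(n_subjects)) {
      for (k in seq_len(n_classes)) {
        idx <- idx + 1L
        sp <- specs[[k]]
        amp_scale <- exp(stats::rnorm(1, 0, 0.08))
        freq_scale <- exp(stats::rnorm(1, 0, 0.03))
        jit <- stats::rnorm(3, 0, 0.06)
        sp$rot_amp <- sp$rot_amp * amp_scale
        sp$acc_amp <- sp$acc_amp * amp_scale
        sp$rot_freq <- sp$rot_freq * freq_scale
        sp$acc_freq <- sp$acc_freq * freq_scale
        post <- rotmat_from_euler(sp$posture_angles[1] + jit[1],
                                  sp$posture_angles[2] + jit[2],
                                  sp$posture_angles[3] + jit[3])
        X <- matrix(0, round(duration * rate), 9L * units)
        tr <- vector("list", units)
        for (u in seq_len(units)) {
          spu <- sp
          spu$rot_amp <- sp$rot_amp * unit_amp[u]
          sim <- simulate_unit(spu, duration, rate,
                               posture = post %*% offsets[[u]])
          cols <- (u - 1L) * 9L
          X[, cols + 1:3] <- sim$stream$acc
          X[, cols + 4:6] <- sim$stream$gyro
          X[, cols + 7:9] <- sim$stream$mag
          tr[[u]] <- sim$truth$quat
        }
        streams[[idx]] <- X
        truth[[idx]] <- tr
      }
    }
  })
  structure(list(streams = streams, meta = meta, truth = truth, rate = rate,
                 units = units, n_subjects = n_subjects,
                 n_classes = n_classes),
            class = "har_dataset")
}

#' @export
print.har_dataset <- function(x, ...) {
  n <- nrow(x$streams[[1]])
  cat("Synthetic activity dataset:", x$n_subjects, "subjects x",
      x$n_classes, "activities,", x$units, "units,", n, "samples at",
      x$rate, "Hz per recording\n")
  invisible(x)
}
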