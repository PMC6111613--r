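#' Orientation filter configuration
#'
#' Settings for the complementary orientation filter. Per sample, the filter
#' predicts the orientation by integrating the gyroscope (reliable in the
#' short term), solves for the orientation that aligns the measured
#' acceleration with Earth-down and the horizontal magnetic field with North
#' by Gauss-Newton iterations (reliable in the long term), and fuses the two
#' by a normalised weighted average.
#'
#' @param mu Fusion weight in (0,1) given to the gyroscope prediction;
#'   \code{1 - mu} goes to the Gauss-Newton solution. Default 0.98.
#' @param gn_max_iter Maximum Gauss-Newton iterations per sample.
#' @param gn_tol Step-norm tolerance that stops the Gauss-Newton iterations.
#' @param gravity Magnitude of gravity (m/s^2) used by consumers that need a
#'   dimensional reference; the alignment cost itself uses unit vectors.
#' @param mag_dip_deg Magnetic dip angle (degrees): the Earth-frame field is
#'   \code{(cos(dip), 0, sin(dip))} in North-East-Down axes. Only the
#'   horizontal component enters the alignment cost.
#' @param prefix_seconds Duration of the steady-state prefix prepended before
#'   filtering: zero angular rate with the first sample's acceleration and
#'   magnetic field held constant. Default 1 s.
#' @return A list of class \code{"filter_config"}.
#' @export
filter_config <- function(mu = 0.98, gn_max_iter = 10L, gn_tol = 1e-8,
                          gravity = 9.81, mag_dip_deg = 60,
                          prefix_seconds = 1) {
  stopifnot(mu > 0, mu < 1, gn_max_iter >= 1, gn_tol > 0,
            gravity > 0, prefix_seconds >= 0)
  structure(list(mu = mu, gn_max_iter = as.integer(gn_max_iter),
                 gn_tol = gn_tol, gravity = gravity,
                 mag_dip_deg = mag_dip_deg,
                 prefix_seconds = prefix_seconds),
            class = "filter_config")
}

#' Earth-frame magnetic field reference for a configuration
#' @param config A [filter_config()].
#' @return Unit 3-vector in North-East-Down axes.
#' @export
mag_reference <- function(config = filter_config()) {
  dip <- config$mag_dip_deg * pi / 180
  c(cos(dip), 0, sin(dip))
}

#' One gyroscope integration step
#'
#' First-order quaternion kinematic update
#' \code{q + (dt/2) q x (0, omega)}, renormalised.
#'
#' @param q_prev Unit quaternion at the previous sample (scalar first).
#' @param omega Angular rate (rad/s) in the sensor frame, length 3.
#' @param dt Sample interval in seconds.
#' @return Unit quaternion after the step.
#' @export
integrate_gyro <- function(q_prev, omega, dt) {
  stopifnot(length(omega) == 3L, dt > 0, all(is.finite(c(q_prev, omega))))
  quat_normalize(q_prev + (dt / 2) * quat_multiply(q_prev, c(0, omega)))
}

#' Gauss-Newton accelerometer/magnetometer orientation correction
#'
#' Finds the unit quaternion (near \code{q_init}) minimising the squared
#' residual between the measured acceleration rotated into the Earth frame
#' and Earth-down, plus the normalised horizontal component of the rotated
#' magnetic field and North. When acceleration and magnetic field are
#' parallel the orientation is unobservable and \code{q_init} is returned
#' with a warning.
#'
#' @param q_init Starting unit quaternion.
#' @param acc,mag Measured 3-vectors in the sensor frame (non-zero).
#' @param config A [filter_config()].
#' @return Unit quaternion with non-negative scalar part.
#' @export
gauss_newton_correction <- function(q_init, acc, mag,
                                    config = filter_config()) {
  stopifnot(length(acc) == 3L, length(mag) == 3L,
            all(is.finite(c(q_init, acc, mag))))
  an <- sqrt(sum(acc^2)); mn <- sqrt(sum(mag^2))
  if (an == 0 || mn == 0) stop("gauss_newton_correction: zero acc or mag")
  cr <- crossprod_vec3(acc / an, mag / mn)
  if (sqrt(sum(cr^2)) < 1e-8) {
    warning("acc and mag are parallel; orientation unobservable")
    return(quat_normalize(q_init))
  }
  gn_correct_cpp(quat_normalize(q_init), as.numeric(acc), as.numeric(mag),
                 config$gn_max_iter, config$gn_tol)
}

crossprod_vec3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic analytic initial attitude from one accel/mag pair (TRIAD):
# rows of R are the Earth axes expressed in the sensor frame.
triad_init <- function(acc, mag) {
  d <- acc / sqrt(sum(acc^2))
  e <- crossprod_vec3(d, mag)
  en <- sqrt(sum(e^2))
  if (en < 1e-10) {
    # degenerate: pick any axis orthogonal to down
    e <- crossprod_vec3(d, c(1, 0, 0))
    if (sqrt(sum(e^2)) < 1e-10) e <- crossprod_vec3(d, c(0, 1, 0))
    en <- sqrt(sum(e^2))
  }
  e <- e / en
  n <- crossprod_vec3(e, d)
  quat_from_rotmat(rbind(n, e, d))
}

#' Estimate the orientation trajectory of a sensor unit
#'
#' Runs the complementary filter over a stream of accelerometer, gyroscope
#' and magnetometer samples. A steady-state prefix (zero angular rate, the
#' first sample's acceleration and magnetic field held constant, duration
#' \code{config$prefix_seconds}) is prepended before filtering and its
#' outputs are dropped, so the returned trajectory has one unit quaternion
#' per input sample. The quaternion at sample n encodes the rotation
#' mapping sensor-frame vectors to the North-East-Down Earth frame.
#'
#' @param stream A list with numeric \code{N x 3} matrices \code{acc},
#'   \code{gyro}, \code{mag} and sampling \code{rate} in Hz (e.g. one
#'   element of a segment as returned by [read_segment_file()]).
#' @param config A [filter_config()].
#' @return An object of class \code{"orientation_trajectory"}: list with
#'   \code{quat} (N x 4, scalar first, unit rows) and \code{rate}.
#' @export
estimate_orientation <- function(stream, config = filter_config()) {
  acc <- as.matrix(stream$acc); gyro <- as.matrix(stream$gyro)
  mag <- as.matrix(stream$mag)
  n <- nrow(acc)
  if (is.null(n) || n < 2L) stop("estimate_orientation: need >= 2 samples")
  stopifnot(ncol(acc) == 3L, ncol(gyro) == 3L, ncol(mag) == 3L,
            nrow(gyro) == n, nrow(mag) == n, all(is.finite(acc)),
            all(is.finite(gyro)), all(is.finite(mag)))
  rate <- stream$rate
  stopifnot(is.numeric(rate), rate > 0)
  dt <- 1 / rate
  n_pre <- round(config$prefix_seconds * rate)
  if (n_pre > 0) {
    acc_f <- rbind(matrix(acc[1, ], n_pre, 3, byrow = TRUE), acc)
    gyro_f <- rbind(matrix(0, n_pre, 3), gyro)
    mag_f <- rbind(matrix(mag[1, ], n_pre, 3, byrow = TRUE), mag)
  } else {
    acc_f <- acc; gyro_f <- gyro; mag_f <- mag
  }
  q0 <- triad_init(acc[1, ], mag[1, ])
  Q <- filter_core_cpp(acc_f, gyro_f, mag_f, dt, config$mu,
                       config$gn_max_iter, config$gn_tol, q0, n_pre)
  Q <- Q[(n_pre + 1):(n_pre + n), , drop = FALSE]
  structure(list(quat = Q, rate = rate), class = "orientation_trajectory")
}

#' @export
print.orientation_trajectory <- function(x, ...) {
  cat("Orientation trajectory:", nrow(x$quat), "samples at", x$rate, "Hz\n")
  invisible(x)
}

# angle (degrees) between the rotations encoded by two quaternion rows
quat_angle_deg <- function(Q1, Q2) {
  d <- abs(rowSums(Q1 * Q2))
  2 * acos(pmin(d, 1)) * 180 / pi
}
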