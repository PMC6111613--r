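test_that("gyroscope integration reproduces constant-rate rotations", {
  q <- c(1, 0, 0, 0)
  expect_equal(integrate_gyro(q, c(0, 0, 0), 0.04), q)
  # constant pi/2 rad/s about z for 1 s at 25 Hz
  for (i in 1:25) q <- integrate_gyro(q, c(0, 0, pi / 2), 1 / 25)
  q_true <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  expect_lt(sqrt(sum((q - q_true)^2)), 1e-3)
  # halving the step reduces the error (first-order integrator)
  q2 <- c(1, 0, 0, 0)
  for (i in 1:50) q2 <- integrate_gyro(q2, c(0, 0, pi / 2), 1 / 50)
  expect_lt(sqrt(sum((q2 - q_true)^2)), sqrt(sum((q - q_true)^2)))
})

test_that("Gauss-Newton correction recovers a known attitude", {
  cfg <- filter_config()
  # measurements equal to the references: identity is already optimal
  q <- gauss_newton_correction(c(1, 0, 0, 0), c(0, 0, 9.81),
                               mag_reference(cfg), cfg)
  expect_lt(2 * acos(min(abs(q[1]), 1)) * 180 / pi, 1e-4)
  # synthetic measurements from a known attitude, init perturbed by ~5 deg
  set.seed(21)
  for (i in 1:20) {
    ang <- runif(3, -1, 1)
    R <- rotmat_from_euler(ang[1], ang[2], ang[3])
    q_true <- quat_from_rotmat(R)
    acc <- drop(t(R) %*% c(0, 0, 9.81))
    mag <- drop(t(R) %*% mag_reference(cfg))
    d <- 5 * pi / 180
    perturb <- quat_from_rotmat(rotmat_from_euler(d, 0, 0))
    q0 <- quat_multiply(q_true, perturb)
    q <- gauss_newton_correction(q0, acc, mag, cfg)
    expect_lt(quat_err_deg(matrix(q, 1), matrix(q_true, 1)), 0.5)
  }
  expect_warning(
    gauss_newton_correction(c(1, 0, 0, 0), c(0, 0, 1), c(0, 0, 2), cfg),
    "parallel")
})

test_that("static streams yield the identity orientation", {
  tr <- estimate_orientation(static_stream(60))
  expect_equal(nrow(tr$quat), 60L)
  expect_lt(max(quat_err_deg(tr$quat,
                             matrix(c(1, 0, 0, 0), 60, 4, byrow = TRUE))),
            1e-4)
  expect_error(estimate_orientation(list(acc = matrix(0, 1, 3),
                                         gyro = matrix(0, 1, 3),
                                         mag = matrix(0, 1, 3), rate = 25)),
               "samples")
})

test_that("the filter tracks noiseless simulated trajectories", {
  # smooth rotational trajectories (sub-1.5 Hz oscillation; faster motions
  # sampled at 25 Hz carry irreducible discretisation error, see vignette)
  specs <- motion_specs(19, noise = noiseless)
  for (cls in c(5, 6, 7)) {
    sp <- specs[[cls]]
    sp$acc_amp <- c(0, 0)  # pure rotation: accelerometer reads gravity only
    sim <- simulate_unit(sp, 5, 25, seed = cls)
    est <- estimate_orientation(sim$stream)
    err <- quat_err_deg(est$quat, sim$truth$quat)
    expect_lt(max(err[26:125]), 2)
    # gravity mapped through the estimate points Earth-down
    Rr <- orientHAR:::quat_rows_to_rotmat_rows(est$quat)
    gE <- orientHAR:::rotate_rows(Rr, sim$stream$acc)
    gE <- gE / sqrt(rowSums(gE^2))
    dev <- acos(pmin(gE[, 3], 1)) * 180 / pi
    expect_lt(mean(dev[26:125]), 2)
  }
})

test_that("estimates are equivariant under a constant re-orientation", {
  sp <- motion_specs(19, noise = noiseless)[[8]]
  sp$acc_amp <- c(0, 0)
  sim <- simulate_unit(sp, 5, 25, seed = 4)
  P <- random_rotation(seed = 17)
  est1 <- estimate_orientation(sim$stream)
  est2 <- estimate_orientation(rotate_segment(sim$stream, P))
  # data premultiplied by P <=> unit re-oriented by P^T: estimates R P^T
  expected <- rotated_traj(est1, P)
  expect_lt(max(quat_err_deg(est2$quat, expected$quat)[26:125]), 2)
})

test_that("the fusion weight interpolates between its two limits", {
  sp <- motion_specs(19, noise = noiseless)[[7]]
  sp$acc_amp <- c(0, 0)
  sim <- simulate_unit(sp, 5, 25, seed = 9)
  st <- sim$stream
  # mu -> 1: pure gyro integration from the analytic initial attitude
  est <- estimate_orientation(st, filter_config(mu = 1 - 1e-12))
  q <- orientHAR:::triad_init(st$acc[1, ], st$mag[1, ])
  n_pre <- 25L
  gyro_pad <- rbind(matrix(0, n_pre, 3), st$gyro)  # 1-s zero-rate prefix
  manual <- matrix(0, nrow(gyro_pad), 4)
  manual[1, ] <- q
  for (i in 2:nrow(gyro_pad)) {
    if (i == n_pre + 1L) {  # no rotation elapses across the prefix boundary
      manual[i, ] <- q
      next
    }
    w <- (gyro_pad[i - 1, ] + gyro_pad[i, ]) / 2
    wn <- sqrt(sum(w^2))
    half <- wn * (1 / st$rate) / 2
    dq <- if (wn < 1e-12) c(1, 0, 0, 0) else c(cos(half), sin(half) * w / wn)
    q <- quat_normalize(quat_multiply(q, dq))
    manual[i, ] <- q
  }
  expect_lt(max(quat_err_deg(est$quat,
                             manual[(n_pre + 1):nrow(manual), ])), 1e-4)
  # mu -> 0: tracks the per-sample Gauss-Newton solution (static stream)
  st2 <- static_stream(40)
  est0 <- estimate_orientation(st2, filter_config(mu = 1e-12))
  gn <- gauss_newton_correction(c(1, 0, 0, 0), st2$acc[5, ], st2$mag[5, ])
  expect_lt(max(quat_err_deg(est0$quat[5, , drop = FALSE],
                             matrix(gn, 1))), 1e-3)
})
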