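make_seg <- function(seed = 7, cls = 8, noise = c(acc = 0.05, gyro = 0.005,
                                                  mag = 0.01)) {
  sp <- motion_specs(19, noise = noise)[[cls]]
  simulate_unit(sp, 5, 25, seed = seed)
}

test_that("reference and random-rotation transforms have the stated shape", {
  sim <- make_seg()
  seg <- sim$stream
  ref <- t_reference(seg)
  expect_equal(ncol(ref$channels), 9L)
  expect_equal(unname(ref$channels), unname(cbind(seg$acc, seg$gyro,
                                                  seg$mag)))
  rr1 <- t_random_rotation(seg, seed = 5)
  rr2 <- t_random_rotation(seg, seed = 5)
  expect_identical(rr1$channels, rr2$channels)
  # rotations are isometries: per-sample norms preserved per sensor type
  expect_equal(rowSums(rr1$channels[, 1:3]^2), rowSums(seg$acc^2))
  expect_equal(rowSums(rr1$channels[, 4:6]^2), rowSums(seg$gyro^2))
  expect_equal(rowSums(rr1$channels[, 7:9]^2), rowSums(seg$mag^2))
})

test_that("norm and gravity transforms are exactly orientation-invariant", {
  sim <- make_seg()
  seg <- sim$stream
  expect_equal(t_norm(seg)$channels[1, "acc_norm"],
               c(acc_norm = sqrt(sum(seg$acc[1, ]^2))))
  expect_equal(ncol(t_norm(seg)$channels), 3L)
  expect_equal(ncol(t_gravity(seg)$channels), 6L)
  for (s in 1:5) {
    P <- random_rotation(seed = s)
    rot <- rotate_segment(seg, P)
    expect_lt(max(abs(t_norm(seg)$channels - t_norm(rot)$channels)), 1e-9)
    expect_lt(max(abs(t_gravity(seg)$channels - t_gravity(rot)$channels)),
              1e-9)
  }
  # constant vertical acceleration decomposes into pure along-component
  g <- unit_segment(matrix(rep(c(0, 0, 9.8), each = 10), 10, 3),
                    matrix(0, 10, 3), matrix(1, 10, 3), 25)
  tg <- t_gravity(g)
  expect_equal(unname(tg$channels[, "acc_along"]), rep(9.8, 10))
  expect_equal(unname(tg$channels[, "acc_perp"]), rep(0, 10))
  zero <- unit_segment(matrix(0, 10, 3), matrix(0, 10, 3),
                       matrix(0, 10, 3), 25)
  expect_error(t_gravity(zero), "zero")
})

test_that("SVD axes absorb a constant re-orientation up to sign fixing", {
  sim <- make_seg()
  seg <- sim$stream
  sv <- t_svd(seg)
  expect_equal(ncol(sv$channels), 9L)
  for (s in 1:5) {
    rot <- rotate_segment(seg, random_rotation(seed = s))
    expect_lt(max(abs(sv$channels - t_svd(rot)$channels)), 1e-9)
  }
  # orthogonal change of basis preserves singular values
  M0 <- cbind(t(seg$acc), t(seg$gyro), t(seg$mag))
  M1 <- cbind(t(sv$channels[, 1:3]), t(sv$channels[, 4:6]),
              t(sv$channels[, 7:9]))
  expect_equal(svd(M0)$d, svd(M1)$d, tolerance = 1e-9)
  # axis-aligned data with descending variance maps to itself up to sign
  set.seed(2)
  A <- qr.Q(qr(matrix(rnorm(125 * 3), 125, 3))) %*% diag(c(5, 2, 0.5))
  aligned <- unit_segment(A, A * 0.5, A * 0.1, 25)
  out <- t_svd(aligned)$channels[, 1:3]
  expect_lt(max(abs(abs(out) - abs(A))), 1e-6)
})

test_that("Earth-frame transform uses the trajectory and preserves norms", {
  st <- static_stream(125)
  seg <- unit_segment(st$acc, st$gyro, st$mag, 25)
  tr <- estimate_orientation(seg)
  te <- t_earth(seg, tr)
  expect_lt(max(abs(te$channels - cbind(seg$acc, seg$gyro, seg$mag))), 1e-3)
  sim <- make_seg(noise = noiseless)
  tt <- truth_traj(sim)
  te2 <- t_earth(sim$stream, tt)
  expect_equal(rowSums(te2$channels[, 1:3]^2), rowSums(sim$stream$acc^2))
  # Earth-frame magnetometer is constant when the true orientation is used
  expect_lt(max(apply(te2$channels[, 7:9], 2, stats::sd)), 1e-12)
  expect_error(t_earth(sim$stream,
                       structure(list(quat = tt$quat[1:10, ], rate = 25),
                                 class = "orientation_trajectory")),
               "length")
})

test_that("differential rotations obey the similarity-transform identity", {
  sim <- make_seg(noise = noiseless)
  tt <- truth_traj(sim)
  d <- differential_rotations(tt)
  expect_equal(nrow(d$D), nrow(tt$quat))
  expect_true(all(d$quat[, 1] >= 0))
  # constant trajectory: every inter-sample rotation is the identity
  const <- structure(list(quat = matrix(rep(quat_from_rotmat(
    random_rotation(seed = 3)), each = 20), 20, 4), rate = 25),
    class = "orientation_trajectory")
  dc <- differential_rotations(const)
  expect_lt(max(abs(dc$quat - matrix(c(1, 0, 0, 0), 20, 4, byrow = TRUE))),
            1e-12)
  # constant spin about Earth z: D_n is the z-rotation by omega * dt
  wz <- 0.8
  n <- 50
  Q <- t(sapply((0:(n - 1)) / 25, function(t0) {
    quat_from_rotmat(rotmat_from_euler(0, 0, wz * t0))
  }))
  ds <- differential_rotations(structure(list(quat = Q, rate = 25),
                                         class = "orientation_trajectory"))
  Dz <- rotmat_from_euler(0, 0, wz / 25)
  expect_lt(max(abs(ds$D[1:(n - 1), ] - matrix(rep(as.vector(Dz),
                                                   each = n - 1),
                                               n - 1, 9))), 1e-9)
})

test_that("the proposed transform is invariant given consistent trajectories", {
  sim <- make_seg(noise = noiseless)
  tt <- truth_traj(sim)
  pr <- t_proposed(sim$stream, tt)
  expect_equal(ncol(pr$channels), 13L)
  for (s in 1:5) {
    P <- random_rotation(seed = 100 + s)
    pr2 <- t_proposed(rotate_segment(sim$stream, P), rotated_traj(tt, P))
    expect_lt(max(abs(pr$channels - pr2$channels)), 1e-9)
  }
  # static input: differential quaternions sit at the identity
  st <- static_stream(125)
  seg <- unit_segment(st$acc, st$gyro, st$mag, 25)
  prs <- t_proposed(seg, estimate_orientation(seg))
  expect_lt(max(abs(prs$channels[, 10:13] -
                    matrix(c(1, 0, 0, 0), 125, 4, byrow = TRUE))), 1e-6)
})

test_that("technique dispatch and channel counts match the registry", {
  sim <- make_seg()
  counts <- c(reference = 9, random = 9, norm = 3, gravity = 6, svd = 9,
              earth = 9, proposed = 13)
  for (te in har_techniques()) {
    out <- transform_segment(sim$stream, te, seed = 1)
    expect_equal(ncol(out$channels), unname(counts[te]))
    expect_equal(nrow(out$channels), 125L)
    expect_equal(out$technique, te)
  }
  expect_error(transform_segment(sim$stream, "bogus"))
})
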