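test_that("triad construction matches the hand-computed cross products", {
  td <- build_triad(c(0, 0, 0), c(80, 0, 0), c(0, 1, 0))
  expect_equal(td$uL, c(1, 0, 0))
  expect_equal(td$uN, c(0, 0, -1))
  expect_equal(td$uT, c(0, 1, 0))
})

test_that("triads are orthonormal and right-handed for random inputs", {
  set.seed(43)
  for (rep in 1:20) {
    ra <- rnorm(3, sd = 10)
    rb <- ra + rnorm(3, sd = 10)
    td <- build_triad(ra, rb, rnorm(3))
    M <- cbind(td$uL, td$uN, td$uT)
    expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
    cp <- c(td$uN[2] * td$uT[3] - td$uN[3] * td$uT[2],
            td$uN[3] * td$uT[1] - td$uN[1] * td$uT[3],
            td$uN[1] * td$uT[2] - td$uN[2] * td$uT[1])
    expect_equal(sum(td$uL * cp), 1, tolerance = 1e-9)
  }
  expect_error(build_triad(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "parallel")
  expect_error(build_triad(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)), "coincide")
})

test_that("helix axis points from N- to C-terminus", {
  # 60 full turns, 1.5 A rise per turn, 1.0 A radius: long enough that
  # the finite-helix tilt of the principal axis is below 1e-3
  t_ <- seq(0, 120 * pi, length.out = 601)[-601]  # whole turns, uniform
  helix <- cbind(1.5 * t_ / (2 * pi), 1.0 * cos(t_), 1.0 * sin(t_))
  ax <- helix_axis(helix)
  expect_equal(ax, c(1, 0, 0), tolerance = 1e-3)
  expect_equal(helix_axis(helix[rev(seq_len(nrow(helix))), ]), -ax,
               tolerance = 1e-6)
  line <- cbind(0, 0, 1:6)
  expect_equal(helix_axis(line), c(0, 0, 1))
  expect_error(helix_axis(helix[1:3, ]), "at least 4")
})

test_that("the pose of the reference itself is identically zero", {
  fx <- kinematics_fixture()
  traj <- make_rigid_motion_trajectory(fx$body,
                                       translation_schedule = matrix(0, 2, 3),
                                       static_points = fx$anchors)
  ps <- pose_series(traj, fx$triad, fx$body_sel,
                    list(sheet_section = fx$body_sel))
  expect_equal(ps$dL, c(0, 0), tolerance = 1e-12)
  expect_equal(ps$dN, c(0, 0), tolerance = 1e-12)
  expect_equal(ps$dT, c(0, 0), tolerance = 1e-12)
  expect_equal(ps$theta_beta, c(0, 0), tolerance = 1e-12)
})

test_that("displacements track a prescribed translation along the triad", {
  fx <- kinematics_fixture()
  tsch <- outer(0:4 * 2, fx$triad$uL)
  traj <- make_rigid_motion_trajectory(fx$body, translation_schedule = tsch,
                                       static_points = fx$anchors)
  ps <- pose_series(traj, fx$triad, fx$body_sel)
  expect_equal(ps$dL, 0:4 * 2, tolerance = 1e-6)
  expect_equal(ps$dN, rep(0, 5), tolerance = 1e-6)
  expect_equal(ps$dT, rep(0, 5), tolerance = 1e-6)
})

test_that("azimuthal angle tracks a prescribed rotation schedule", {
  fx <- kinematics_fixture()
  # +5 deg per frame about the vertical axis (-uN): increases phi
  rot <- lapply(0:4 * 5, function(a) rotation_about(-fx$triad$uN, a))
  traj <- make_rigid_motion_trajectory(fx$body, rotation_schedule = rot,
                                       static_points = fx$anchors)
  ps <- pose_series(traj, fx$triad, fx$body_sel,
                    list(sheet_section = fx$body_sel))
  expect_equal(ps$phi_beta, 0:4 * 5, tolerance = 1e-6)
})

test_that("pose quantities are invariant under a global rigid transform", {
  fx <- kinematics_fixture()
  rot <- lapply(0:3 * 7, function(a) rotation_about(-fx$triad$uN, a))
  traj <- make_rigid_motion_trajectory(fx$body, rotation_schedule = rot,
                                       static_points = fx$anchors)
  base <- pose_series(traj, fx$triad, fx$body_sel,
                      list(sheet_section = fx$body_sel))
  set.seed(47)
  tf <- random_transform()
  moved <- traj
  for (k in 1:4) moved$coords[, , k] <- apply_transform(traj$coords[, , k], tf)
  anchors2 <- apply_transform(fx$anchors, tf)
  triad2 <- build_triad(anchors2[1, ], anchors2[2, ],
                        as.numeric(tf$rotation %*% c(0, 1, 0)))
  got <- pose_series(moved, triad2, fx$body_sel,
                     list(sheet_section = fx$body_sel),
                     reference = apply_transform(frame_coords(traj, 1), tf))
  expect_equal(got$dL, base$dL, tolerance = 1e-8)
  expect_equal(got$dN, base$dN, tolerance = 1e-8)
  expect_equal(got$dT, base$dT, tolerance = 1e-8)
  expect_equal(got$phi_beta, base$phi_beta, tolerance = 1e-8)
})

test_that("mobility of a static trajectory is zero", {
  fx <- kinematics_fixture()
  traj <- make_rigid_motion_trajectory(fx$body,
                                       translation_schedule = matrix(0, 3, 3),
                                       static_points = fx$anchors)
  mp <- mobility_profile(traj, align_selection = fx$anchor_sel)
  expect_equal(max(mp$displacement), 0, tolerance = 1e-10)
  expect_equal(max(mp$rmsd), 0, tolerance = 1e-10)
})

test_that("a constant 2 A offset gives displacement 2 and zero fluctuation", {
  set.seed(53)
  base <- matrix(rnorm(30, sd = 5), 10, 3)
  nf <- 6
  coords <- array(rep(base, nf), dim = c(10, 3, nf))
  for (k in 2:nf) coords[4, , k] <- base[4, ] + c(2, 0, 0)
  traj <- trajectory(atom_table(n = 10), coords)
  mp <- mobility_profile(traj, align_selection = c(1:3, 5:10),
                         window = c(traj$frame_interval,
                                    (nf - 1) * traj$frame_interval))
  expect_equal(mp$displacement[4], 2, tolerance = 1e-8)
  expect_equal(mp$rmsd[4], 0, tolerance = 1e-8)
  expect_equal(max(mp$displacement[-4]), 0, tolerance = 1e-8)
})

test_that("isotropic jitter gives RMSD near sigma * sqrt(3)", {
  set.seed(59)
  sigma <- 0.3
  nf <- 2000
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10),
                c(5, 5, 0))
  coords <- array(rep(base, nf), dim = c(5, 3, nf))
  coords[5, , ] <- coords[5, , ] + matrix(rnorm(3 * nf, sd = sigma), 3, nf)
  traj <- trajectory(atom_table(n = 5), coords)
  mp <- mobility_profile(traj, align_selection = 1:4)
  se <- sigma / sqrt(2 * nf)
  expect_lt(abs(mp$rmsd[5] - sigma * sqrt(3)), 3 * se)
})

test_that("rolling mean displacement handles thresholds and steps", {
  fx <- kinematics_fixture()
  # static: nothing passes 1 A -> all NA
  st <- make_rigid_motion_trajectory(fx$body,
                                     translation_schedule = matrix(0, 10, 3),
                                     static_points = fx$anchors)
  rd <- rolling_mean_displacement(st, align_selection = fx$anchor_sel,
                                  window_ns = 1)
  expect_true(all(is.na(rd$mean_displacement)))

  # step of 3 A from mid-trajectory on
  nf <- 40
  tsch <- rbind(matrix(0, nf / 2, 3),
                matrix(rep(c(3, 0, 0), nf / 2), ncol = 3, byrow = TRUE))
  stp <- make_rigid_motion_trajectory(fx$body, translation_schedule = tsch,
                                      static_points = fx$anchors)
  rd2 <- rolling_mean_displacement(stp, align_selection = fx$anchor_sel,
                                   window_ns = 5 * 0.24)
  expect_true(all(is.na(rd2$mean_displacement[1:(nf / 2)])))
  expect_equal(rd2$mean_displacement[(nf / 2 + 1):nf], rep(3, nf / 2),
               tolerance = 1e-8)
  expect_equal(rd2$rolling[nf], 3, tolerance = 1e-8)

  # threshold 0 equals the plain mean displacement series
  set.seed(61)
  jit <- st
  jit$coords[fx$body_sel, , ] <- jit$coords[fx$body_sel, , ] +
    array(rnorm(length(fx$body_sel) * 3 * 10, sd = 0.2),
          dim = c(length(fx$body_sel), 3, 10))
  rd3 <- rolling_mean_displacement(jit, align_selection = fx$anchor_sel,
                                   exclude_selection = fx$anchor_sel,
                                   threshold = 0, window_ns = 1)
  ref <- frame_coords(jit, 1)
  direct <- vapply(1:10, function(k) {
    tf <- superpose(jit$coords[, , k], ref, fx$anchor_sel)
    p <- apply_transform(jit$coords[fx$body_sel, , k], tf)
    mean(sqrt(rowSums((p - ref[fx$body_sel, ])^2)))
  }, numeric(1))
  expect_equal(rd3$mean_displacement[-1], direct[-1], tolerance = 1e-10)
})

test_that("displacement is frame-order invariant, fluctuation RMSD is not tied to order", {
  set.seed(67)
  base <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(3, 3, 3))
  nf <- 12
  coords <- array(rep(base, nf), dim = c(5, 3, nf))
  coords[5, , ] <- coords[5, , ] + matrix(rnorm(3 * nf, sd = 0.5), 3, nf)
  traj <- trajectory(atom_table(n = 5), coords)
  # permute frames 2..nf, keeping the reference frame in place
  perm <- c(1, 1 + sample(nf - 1))
  shuf <- traj
  shuf$coords <- traj$coords[, , perm]
  mp1 <- mobility_profile(traj, align_selection = 1:4)
  mp2 <- mobility_profile(shuf, align_selection = 1:4)
  expect_equal(mp1$displacement, mp2$displacement, tolerance = 1e-12)
  expect_equal(mp1$rmsd, mp2$rmsd, tolerance = 1e-12)
})
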