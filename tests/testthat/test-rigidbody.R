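# regular tetrahedron, 70 mm edges (a typical technical-cluster scale)
tetra <- matrix(c(0, 0, 0, 70, 0, 0, 35, 60.62, 0, 35, 20.21, 57.16),
                4, 3, byrow = TRUE)

test_that("pose estimation is exact on noise-free rigid motion", {
  p0 <- estimate_pose(tetra, tetra)
  expect_lt(max(abs(p0$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(p0$translation)), 1e-12)
  expect_lt(p0$rms_residual, 1e-12)

  R <- cardan_compose(c(0, 0, 30), "yxz")  # 30 deg about z
  obs <- sweep(tetra %*% t(R), 2, c(10, 0, 0), `+`)
  p <- estimate_pose(tetra, obs)
  expect_lt(max(abs(p$rotation - R)), 1e-9)
  expect_equal(p$translation, c(10, 0, 0), tolerance = 1e-9)
  expect_lt(p$rms_residual, 1e-9)
  expect_equal(det(p$rotation), 1, tolerance = 1e-9)
})

test_that("pose estimation degrades gracefully under marker noise", {
  # six-marker octahedral cluster, 70 mm between adjacent markers
  r <- 70 / sqrt(2)
  hexa <- rbind(c(r, 0, 0), c(-r, 0, 0), c(0, r, 0),
                c(0, -r, 0), c(0, 0, r), c(0, 0, -r))
  set.seed(21)
  errs <- replicate(300, {
    R <- random_rotation()
    t <- rnorm(3, 0, 50)
    obs <- sweep(hexa %*% t(R), 2, t, `+`) + rnorm(18, 0, 0.5)
    p <- estimate_pose(hexa, obs)
    ang <- acos(min(1, (sum(diag(crossprod(R, p$rotation))) - 1) / 2))
    ang * 180 / pi
  })
  expect_lt(median(errs), 0.5)
  expect_gt(median(errs), 0)
})

test_that("pose estimation is equivariant and guards degenerate inputs", {
  set.seed(22)
  R <- random_rotation()
  obs <- sweep(tetra %*% t(R), 2, c(5, -3, 8), `+`) + rnorm(12, 0, 0.3)
  Q <- random_rotation()
  p1 <- estimate_pose(tetra, obs)
  p2 <- estimate_pose(sweep(tetra %*% t(Q), 2, c(1, 2, 3), `+`), obs)
  # pre-rotating the reference conjugates the recovered rotation
  expect_equal(p2$rotation %*% Q, p1$rotation, tolerance = 1e-9)

  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(estimate_pose(line, line), "collinear")
  expect_error(estimate_pose(tetra, tetra[1:3, ]), "mismatched")
  expect_error(estimate_pose(tetra[1:2, ], tetra[1:2, ]), "at least 3")

  # reflection guard: noisy near-planar clouds still return det +1
  planar <- cbind(c(0, 60, 0, 60), c(0, 0, 60, 60), c(0, 0.1, -0.1, 0))
  for (i in 1:20) {
    obs <- sweep(planar %*% t(random_rotation()), 2, rnorm(3), `+`) +
      rnorm(12, 0, 1)
    expect_equal(det(estimate_pose(planar, obs)$rotation), 1, tolerance = 1e-9)
  }
})

test_that("the CAST chain is the identity on the calibration frame", {
  set.seed(23)
  R <- random_rotation(); t <- c(12, -40, 7)
  obs <- sweep(tetra %*% t(R), 2, t, `+`)
  pose <- estimate_pose(tetra, obs)
  p_global <- c(150, -30, 60)
  lp <- calibrate_local(p_global, pose, owner_segment = "hindfoot")
  expect_equal(reconstruct_global(lp, pose), p_global, tolerance = 1e-9)

  # the cluster origin maps to local zero
  lp0 <- calibrate_local(pose$translation + as.vector(pose$rotation %*% c(0, 0, 0)),
                         pose)
  expect_equal(lp0$coords, c(0, 0, 0), tolerance = 1e-9)
})

test_that("calibrated points track rigid motion exactly and noise boundedly", {
  set.seed(24)
  cal_pose <- estimate_pose(tetra, tetra)   # identity calibration frame
  p <- c(120, 15, -20)
  lp <- calibrate_local(p, cal_pose)
  errs_clean <- errs_noisy <- numeric(200)
  for (i in 1:200) {
    R <- random_rotation(); t <- rnorm(3, 0, 100)
    truth <- as.vector(R %*% p) + t
    obs <- sweep(tetra %*% t(R), 2, t, `+`)
    errs_clean[i] <- sqrt(sum((reconstruct_global(lp, estimate_pose(tetra, obs)) -
                                 truth)^2))
    obs_n <- obs + rnorm(12, 0, 0.5)
    errs_noisy[i] <- sqrt(sum((reconstruct_global(lp, estimate_pose(tetra, obs_n)) -
                                 truth)^2))
  }
  expect_lt(max(errs_clean), 1e-6)
  expect_lt(median(errs_noisy), 3 * 0.5 * 3)  # well inside ~3 sigma per axis
})
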