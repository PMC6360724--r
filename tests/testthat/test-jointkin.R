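test_that("Cardan decomposition inverts composition away from gimbal lock", {
  expect_equal(unclass(jcs_angles(diag(3), diag(3)))[1:3], c(0, 0, 0))
  a <- cardan_decompose(cardan_compose(c(0, 0, 10), "yxz"), "yxz")
  expect_equal(a[1:3], c(0, 0, 10), tolerance = 1e-9)

  set.seed(51)
  for (seq_ in c("yxz", "xyz", "zxy", "zyx")) {
    worst <- 0
    for (i in 1:250) {
      ang <- runif(3, -80, 80) * c(1, 0.9, 1)  # keep middle away from 90
      R <- cardan_compose(ang, seq_)
      back <- cardan_compose(cardan_decompose(R, seq_), seq_)
      worst <- max(worst, max(abs(back - R)))
    }
    expect_lt(worst, 1e-9)
  }

  g <- cardan_decompose(cardan_compose(c(0, 88, 0), "yxz"), "yxz")
  expect_true(attr(g, "gimbal"))
  expect_error(jcs_angles(diag(3), matrix(1, 3, 3)), "rotation")
})

test_that("the MTPJ transverse angle follows its construction", {
  met <- diag(3)
  MT1 <- c(100, 0, 0); MTB1 <- c(20, 0, 0)
  # HAL on the anterior axis: zero
  expect_equal(mtpj_transverse_angle(MT1, MTB1, c(160, 0, 0), met), 0,
               tolerance = 1e-12)
  # 15 deg lateral (right side: lateral = -y): the mild-class boundary
  hal15 <- MT1 + 60 * c(cos(-15 * pi / 180), sin(-15 * pi / 180), 0)
  expect_equal(mtpj_transverse_angle(MT1, MTB1, hal15, met, "right"), 15,
               tolerance = 1e-9)
  expect_equal(mtpj_transverse_angle(MT1, MTB1, hal15, met, "left"), -15,
               tolerance = 1e-9)
  # purely vertical displacement projects away
  expect_equal(mtpj_transverse_angle(MT1, MTB1, c(160, 0, 40), met), 0,
               tolerance = 1e-12)
  expect_error(mtpj_transverse_angle(MT1, MTB1, MT1 + c(0, 0, 5), met),
               "undefined-angle")
})

test_that("the MTPJ angle is invariant to rigid motion of the whole foot", {
  set.seed(52)
  MT1 <- c(100, 5, 2); MTB1 <- c(20, 3, 9)
  hal <- MT1 + 60 * c(cos(-0.2), sin(-0.2), 0.05)
  met <- turnoutfoot:::.gs_xz(turnoutfoot:::unitize(MT1 - MTB1), c(0, 0, 1))
  a0 <- mtpj_transverse_angle(MT1, MTB1, hal, met)
  for (i in 1:20) {
    Q <- random_rotation(); t <- rnorm(3, 0, 100)
    mv <- function(p) as.vector(Q %*% p) + t
    a1 <- mtpj_transverse_angle(mv(MT1), mv(MTB1), mv(hal), Q %*% met)
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("foot abduction recovers an isolated prescribed rotation, both sides", {
  for (side in c("right", "left")) {
    conds <- zero_offsets()
    conds$functional["foot_abduction"] <- 12
    cfg <- quick_config(seed = 53, side = side, conditions = conds)
    qt <- quick_trials(cfg, extra = "functional_turnout")
    cal <- calibrate_subject(qt$trials)
    fr <- build_frames(qt$trials$functional_turnout, cal)
    ab <- foot_abduction(fr$segments$tibia$R[, , 1], fr$segments$foot$R[, , 1],
                         side)
    expect_equal(ab, 12, tolerance = 0.1)
    frn <- build_frames(qt$trials$natural, cal)
    expect_lt(abs(foot_abduction(frn$segments$tibia$R[, , 1],
                                 frn$segments$foot$R[, , 1], side)), 1e-6)
  }
})

test_that("knee transverse rotation is signed external-positive", {
  for (er in c(20, -15)) {
    cfg <- quick_config(seed = 54, knee_er_passive = er)
    qt <- quick_trials(cfg, extra = "seated_passive_er")
    cal <- calibrate_subject(qt$trials)
    fr <- build_frames(qt$trials$seated_passive_er, cal)
    k <- knee_transverse_angle(fr$segments$thigh$R[, , 1],
                               fr$segments$tibia$R[, , 1], "right")
    expect_equal(k, er, tolerance = 0.1)
  }
  # identical orientations give zero
  expect_equal(knee_transverse_angle(diag(3), diag(3))[[1]], 0)
})

test_that("filtered saute streams recover prescribed waveforms under noise", {
  # one frontal and one transverse variable at 0.5 mm marker noise
  for (v in c("hindfoot_eversion", "mtpj_abduction")) {
    conds <- zero_offsets()
    conds$saute[v] <- 12
    cfg <- quick_config(seed = 55, noise_sd = 0.5, conditions = conds)
    qt <- quick_trials(cfg, extra = "saute")
    cal <- calibrate_subject(qt$trials)
    tr <- filter_trial(qt$trials$saute, 26)
    ang <- trial_angles(build_frames(tr, cal), tr)
    expect_lt(sqrt(mean((ang[[v]] - qt$truths$saute[[v]])^2)), 0.5)
  }
})
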