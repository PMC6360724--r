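test_that("generation is deterministic and markers are segment-rigid", {
  cfg <- quick_config(seed = 91, noise_sd = 0.5)
  a <- generate_trial(cfg, "saute")
  b <- generate_trial(cfg, "saute")
  expect_identical(a$trial$data, b$trial$data)

  clean <- generate_trial(quick_config(seed = 91), "saute")$trial
  geom <- synth_geometry("right")
  for (seg in c("hindfoot", "first_metatarsal", "forefoot")) {
    nm <- intersect(rownames(geom[[seg]]$markers), clean$markers)
    if (length(nm) < 2) next
    d12 <- sqrt(rowSums((clean$data[, nm[1], ] - clean$data[, nm[2], ])^2))
    expect_lt(max(d12) - min(d12), 1e-9)
  }
})

test_that("a neutral configuration passes through the pipeline as zero", {
  cfg <- quick_config(seed = 92)
  qt <- quick_trials(cfg, extra = "natural")
  cal <- calibrate_subject(qt$trials)
  ang <- trial_angles(build_frames(qt$trials$natural, cal), qt$trials$natural)
  for (v in c("hindfoot_eversion", "midfoot_abduction", "forefoot_abduction",
              "foot_abduction", "mtpj_abduction", "knee_rotation"))
    expect_lt(max(abs(ang[[v]])), 1e-6)
})

test_that("a prescribed functional-turnout eversion offset is recovered", {
  conds <- zero_offsets()
  conds$functional["hindfoot_eversion"] <- 5.7
  cfg <- quick_config(seed = 93, conditions = conds)
  qt <- quick_trials(cfg, extra = "functional_turnout")
  cal <- calibrate_subject(qt$trials)
  ang <- trial_angles(build_frames(qt$trials$functional_turnout, cal),
                      qt$trials$functional_turnout)
  expect_equal(mean(ang$hindfoot_eversion), 5.7, tolerance = 1e-3)
})

test_that("noisy static recovery is unbiased across seeds", {
  conds <- zero_offsets()
  conds$functional["hindfoot_eversion"] <- 5.7
  recovered <- vapply(1:10, function(s) {
    cfg <- quick_config(seed = 900 + s, noise_sd = 0.5, conditions = conds)
    qt <- quick_trials(cfg, extra = "functional_turnout")
    cal <- calibrate_subject(qt$trials)
    ang <- trial_angles(build_frames(qt$trials$functional_turnout, cal),
                        qt$trials$functional_turnout)
    mean(ang$hindfoot_eversion)
  }, numeric(1))
  expect_lt(abs(mean(recovered) - 5.7), 0.3)
})

test_that("cohort draws honour degenerate and null effect maps", {
  em0 <- default_effect_map()
  em0$sd_trait[] <- 0
  em0$sd_gain[] <- 0
  em0$sd_within[] <- 0
  em0$foot_resid_sd <- 0
  em0$foot_natural_sd <- 0
  em0$knee$resid_passive <- em0$knee$resid_active <- 0
  co <- generate_cohort(n_subjects = 2, effect_map = em0, seed = 94,
                        values_only = TRUE)
  for (cn in condition_levels()) {
    sub <- co$values[co$values$condition == cn & co$values$subject == 1, ]
    mu <- em0$mu[[cn]]
    mu["navicular_drop"] <- if (cn == "natural") 0 else mu["navicular_drop"]
    expect_equal(stats::setNames(sub$value, sub$variable)[names(mu)], mu,
                 tolerance = 1e-12)
  }

  # zero between-condition differences: rejection rate near alpha
  em_null <- default_effect_map()
  em_null$mu <- lapply(em_null$mu, function(x) em_null$mu$natural)
  set.seed(95)
  rej <- 0
  for (i in 1:200) {
    cv <- generate_cohort(18, em_null, seed = 9000 + i, values_only = TRUE)
    w <- cv$values[cv$values$variable == "hindfoot_eversion", ]
    m <- matrix(w$value[order(w$subject, w$condition)], 18, 4, byrow = TRUE)
    if (rm_anova_gg(m)$p_gg < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 200, 0.01)
  expect_lt(rej / 200, 0.10)
})

test_that("the default cohort reproduces the printed functional effect", {
  co <- generate_cohort(n_subjects = 18, seed = 96, values_only = TRUE)
  w <- co$values[co$values$variable == "hindfoot_eversion", ]
  d <- w$value[w$condition == "functional"] - w$value[w$condition == "natural"]
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 4.6), 2 * se + 0.5)
})

test_that("soft-tissue artifact and invalid labels are handled", {
  cfg <- quick_config(seed = 97, sta_amplitude_mm = 2)
  tr <- generate_trial(cfg, "natural")$trial
  cal_tr <- generate_trial(quick_config(seed = 97), "natural")$trial
  expect_gt(max(abs(tr$data - cal_tr$data)), 0.5)
  expect_error(generate_trial(cfg, "grand_jete"), "unknown trial label")
})
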