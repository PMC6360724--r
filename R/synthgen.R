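# Forward-kinematic synthetic marker generator for a pelvis-thigh-shank-foot
# chain with articulated hindfoot, midfoot, forefoot, first-metatarsal and
# hallux segments. Emits trials in the canonical format together with ground
# truth for every pipeline stage.
#
# The shank (tibia) is the kinematic root: intra-foot joints articulate
# distally, the thigh and pelvis hang proximally through the inverse knee and
# hip rotations, so prescribed joint angles are exactly the relative segment
# rotations the pipeline should recover. Arch lowering (navicular drop) is a
# world-vertical translation of the midfoot subtree so the prescribed drop
# equals the noise-free navicular height change exactly.

#' Default synthetic skeleton geometry
#'
#' Neutral-posture marker and joint-origin coordinates (mm) for a plausible
#' adult lower limb and foot; declared test geometry, not an anthropometric
#' claim. Lab axes: x anterior, y to the subject's left, z up; right-side
#' geometry mirrors in y for the left.
#'
#' @param side `"right"` or `"left"`.
#' @return List of segments, each with `parent`, `origin` and a named
#'   markers matrix (rows = markers).
#' @export
synth_geometry <- function(side = "right") {
  side <- match.arg(side, c("right", "left"))
  m <- function(...) {
    v <- c(...)
    mat <- matrix(v[-seq(1, length(v), by = 4)], ncol = 3, byrow = TRUE)
    rownames(mat) <- v[seq(1, length(v), by = 4)]
    storage.mode(mat) <- "double"
    mat
  }
  segs <- list(
    tibia = list(parent = NA, origin = c(0, 0, 480), markers = m(
      "TIB1", -30, -45, 300, "TIB2", -50, 0, 380, "TIB3", -25, 50, 320,
      "LMAL", 0, -45, 78, "MMAL", 0, 40, 84)),
    hindfoot = list(parent = "tibia", origin = c(0, -2.5, 81), markers = m(
      "CAL", -85, 0, 40, "SUS", -28, 25, 33, "HDL", -33, -25, 68,
      "CALe", -110, 0, 25)),
    midfoot = list(parent = "hindfoot", origin = c(30, 0, 50), markers = m(
      "NAV", 30, 32, 48, "CUB", 32, -32, 32, "MFM", 78, 0, 54)),
    forefoot = list(parent = "midfoot", origin = c(95, 0, 40), markers = m(
      "MT2", 155, 10, 32, "MT5", 140, -25, 26, "FFM", 85, 10, 44)),
    first_metatarsal = list(parent = "midfoot", origin = c(85, 25, 35),
                            markers = m(
      "MTB1", 85, 25, 35, "MTS1", 126, 55, 35, "MTS2", 150, 0, 58,
      "MT1", 175, 25, 27)),
    hallux = list(parent = "first_metatarsal", origin = c(175, 25, 27),
                  markers = NULL),  # HAL filled in below
    thigh = list(parent = "tibia", origin = c(0, 0, 480), markers = m(
      "THI1", 20, -50, 640, "THI2", 0, 15, 720, "THI3", 40, 45, 610,
      "LFC", 0, -50, 480, "MFC", 0, 50, 480)),
    pelvis = list(parent = "thigh", origin = c(0, 0, 900), markers = m(
      "PELV1", -60, -80, 980, "PELV2", -90, 0, 1010, "PELV3", -60, 80, 980))
  )
  # HAL sits on the MTB1 -> MT1 line so the neutral MTPJ angle is exactly 0
  mt1 <- segs$first_metatarsal$markers["MT1", ]
  mtb1 <- segs$first_metatarsal$markers["MTB1", ]
  hal <- mt1 + 95 * unitize(mt1 - mtb1)
  segs$hallux$markers <- matrix(hal, 1, 3, dimnames = list("HAL", NULL))
  if (side == "left") {
    segs <- lapply(segs, function(s) {
      s$origin[2] <- -s$origin[2]
      s$markers[, 2] <- -s$markers[, 2]
      s
    })
  }
  segs
}

#' Synthetic-trial configuration
#'
#' Study conditions of the emulated protocol: capture rate, saute tempo and
#' cycle count, marker noise, and the per-condition clinical angle offsets
#' (degrees; navicular drop in mm). Defaults emulate the published cohort
#' means for each condition.
#'
#' @param seed Integer seed controlling all noise draws.
#' @param rate Sampling rate, Hz.
#' @param tempo_bpm Saute tempo, one saute per beat.
#' @param n_cycles Number of sautes per trial.
#' @param noise_sd Gaussian marker noise SD, mm.
#' @param side `"right"` or `"left"`.
#' @param conditions Named list (`natural`, `functional`, `forced`, `saute`)
#'   of named vectors with elements `hindfoot_eversion`, `midfoot_abduction`,
#'   `forefoot_abduction`, `foot_abduction`, `mtpj_abduction`,
#'   `navicular_drop`; `saute` gives demi-plie peak values.
#' @param knee_er_passive,knee_er_active Seated external tibiofemoral
#'   rotation, degrees.
#' @param static_frames,squat_frames,seated_frames Frames per static /
#'   functional-calibration trial.
#' @param saute_excursion_mm Pelvis height excursion per saute.
#' @param saute_excursion_jitter Relative SD of the per-cycle excursion.
#' @param repeat_jitter_deg SD of the between-repeat angle jitter for the
#'   repeated static turnout trials.
#' @param sta_amplitude_mm Optional low-frequency soft-tissue-artifact
#'   sinusoid amplitude (0 = rigid markers).
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1L, rate = 250, tempo_bpm = 95,
                         n_cycles = 10L, noise_sd = 0, side = "right",
                         conditions = default_condition_offsets(),
                         knee_er_passive = 40, knee_er_active = 45,
                         static_frames = 100L, squat_frames = 400L,
                         seated_frames = 100L,
                         saute_excursion_mm = 120,
                         saute_excursion_jitter = 0.05,
                         repeat_jitter_deg = 0.2,
                         sta_amplitude_mm = 0) {
  stopifnot(noise_sd >= 0, rate > 0, n_cycles >= 1)
  structure(list(seed = as.integer(seed), rate = rate, tempo_bpm = tempo_bpm,
                 n_cycles = as.integer(n_cycles), noise_sd = noise_sd,
                 side = match.arg(side, c("right", "left")),
                 conditions = conditions,
                 knee_er_passive = knee_er_passive,
                 knee_er_active = knee_er_active,
                 static_frames = as.integer(static_frames),
                 squat_frames = as.integer(squat_frames),
                 seated_frames = as.integer(seated_frames),
                 saute_excursion_mm = saute_excursion_mm,
                 saute_excursion_jitter = saute_excursion_jitter,
                 repeat_jitter_deg = repeat_jitter_deg,
                 sta_amplitude_mm = sta_amplitude_mm),
            class = "synth_config")
}

#' Default per-condition clinical offsets
#'
#' Published cohort means per condition: hindfoot eversion, midfoot and
#' forefoot abduction, MTPJ abduction (degrees) and navicular drop (mm);
#' whole-foot abduction is not printed for the cohort and uses plausible
#' turnout magnitudes.
#'
#' @return Named list of named numeric vectors.
#' @export
default_condition_offsets <- function() {
  v <- function(hf, mid, fore, foot, mtpj, nav)
    c(hindfoot_eversion = hf, midfoot_abduction = mid,
      forefoot_abduction = fore, foot_abduction = foot,
      mtpj_abduction = mtpj, navicular_drop = nav)
  list(natural    = v(1.1, 2.8, 7.6, 8, 10.7, 0),
       functional = v(5.7, 5.6, 8.4, 25, 12.0, 1.6),
       forced     = v(7.1, 6.3, 8.8, 32, 13.5, 1.9),
       saute      = v(15.8, 7.7, 8.7, 25, 13.1, 12.9))
}

# ---------------------------------------------------------------------------
# forward kinematics

# schedule: list of per-frame numeric vectors (deg / mm):
# ev, footabd, midabd, foreabd, mtpj, navdrop, knee_flex, knee_er,
# hip_flex, hip_abd, pelvis_dz
.fk_markers <- function(geom, schedule, side) {
  nf <- length(schedule$ev)
  s_ev <- .sign_eversion(side); s_ab <- .sign_abduction(side)
  d2r <- pi / 180
  all_names <- unlist(lapply(geom, function(s) rownames(s$markers)))
  out <- array(NA_real_, c(nf, length(all_names), 3),
               dimnames = list(NULL, all_names, c("X", "Y", "Z")))
  nav_n_z <- geom$midfoot$markers["NAV", 3]
  truth_nav <- numeric(nf)
  # MTPJ rotations are prescribed about the metatarsal frame's own vertical
  # axis (the axis the transverse-plane angle is measured about), which is
  # tilted from the lab vertical by the metatarsal declination
  met_x <- unitize(geom$first_metatarsal$markers["MT1", ] -
                     geom$first_metatarsal$markers["MTB1", ])
  met_y <- unitize(cross3(c(0, 0, 1), met_x))
  met_z <- cross3(met_x, met_y)
  for (f in seq_len(nf)) {
    Jank <- rot_x(s_ev * schedule$ev[f] * d2r) %*%
      rot_z(s_ab * schedule$footabd[f] * d2r)
    Jmid <- rot_z(s_ab * schedule$midabd[f] * d2r)
    Jfore <- rot_z(s_ab * schedule$foreabd[f] * d2r)
    Jhal <- rot_axis(met_z, s_ab * schedule$mtpj[f] * d2r)
    Jknee <- rot_y(schedule$knee_flex[f] * d2r) %*%
      rot_z(s_ab * schedule$knee_er[f] * d2r)
    Jhip <- rot_y(schedule$hip_flex[f] * d2r) %*%
      rot_x(schedule$hip_abd[f] * d2r)

    Tw <- list(tibia = list(R = diag(3), o = geom$tibia$origin,
                            on = geom$tibia$origin))
    place <- function(seg, R, o_w) {
      list(R = R, o = o_w, on = geom[[seg]]$origin)
    }
    tf <- function(Tr, x) Tr$o + as.vector(Tr$R %*% (x - Tr$on))
    Tw$hindfoot <- place("hindfoot", Jank,
                         tf(Tw$tibia, geom$hindfoot$origin))
    # midfoot: world-vertical arch translation so the noise-free NAV height
    # equals the neutral height minus the prescribed drop, exactly
    Rmid <- Tw$hindfoot$R %*% Jmid
    o_mid <- tf(Tw$hindfoot, geom$midfoot$origin)
    nav_z_unshifted <- (o_mid + Rmid %*% (geom$midfoot$markers["NAV", ] -
                                            geom$midfoot$origin))[3]
    o_mid[3] <- o_mid[3] + (nav_n_z - schedule$navdrop[f]) - nav_z_unshifted
    Tw$midfoot <- list(R = Rmid, o = o_mid, on = geom$midfoot$origin)
    truth_nav[f] <- nav_n_z - schedule$navdrop[f]
    Tw$forefoot <- place("forefoot", Rmid %*% Jfore,
                         tf(Tw$midfoot, geom$forefoot$origin))
    Tw$first_metatarsal <- place("first_metatarsal", Rmid,
                                 tf(Tw$midfoot, geom$first_metatarsal$origin))
    Tw$hallux <- place("hallux", Rmid %*% Jhal,
                       tf(Tw$first_metatarsal, geom$hallux$origin))
    Tw$thigh <- place("thigh", t(Jknee), tf(Tw$tibia, geom$thigh$origin))
    o_pel <- tf(Tw$thigh, geom$pelvis$origin)
    o_pel[3] <- o_pel[3] + schedule$pelvis_dz[f]
    Tw$pelvis <- place("pelvis", Tw$thigh$R %*% t(Jhip), o_pel)

    for (seg in names(geom)) {
      mk <- geom[[seg]]$markers
      Tr <- Tw[[seg]]
      out[f, rownames(mk), ] <-
        sweep(mk %*% t(Tr$R), 2,
              Tr$o - as.vector(Tr$R %*% Tr$on), `+`)
    }
  }
  list(markers = out, truth_nav_height = truth_nav)
}

.const_schedule <- function(nf, cond, knee_flex = 0, knee_er = 0,
                            hip_flex = 0, hip_abd = 0) {
  rep1 <- function(x) rep(x, nf)
  list(ev = rep1(cond["hindfoot_eversion"]),
       footabd = rep1(cond["foot_abduction"]),
       midabd = rep1(cond["midfoot_abduction"]),
       foreabd = rep1(cond["forefoot_abduction"]),
       mtpj = rep1(cond["mtpj_abduction"]),
       navdrop = rep1(cond["navicular_drop"]),
       knee_flex = rep1(knee_flex), knee_er = rep1(knee_er),
       hip_flex = rep1(hip_flex), hip_abd = rep1(hip_abd),
       pelvis_dz = rep1(0))
}

#' Generate one synthetic trial with ground truth
#'
#' Poses each segment by composing the prescribed joint rotations along the
#' chain, places markers rigidly in their segments, and adds i.i.d. Gaussian
#' noise. Saute trials modulate the foot angles, navicular drop and pelvis
#' height sinusoidally at the tempo; static trials hold the condition
#' offsets; the squat/circumduction trial sweeps the knee hinge (4 squats)
#' then the hip (3 circumduction circles); seated trials hold the prescribed
#' external tibiofemoral rotation at a flexed knee.
#'
#' @param config A [synth_config()].
#' @param label Trial label, one of `trial_labels()`.
#' @param angle_jitter Optional named vector added to the condition offsets
#'   (used for repeated static trials).
#' @param seed_offset Added to `config$seed` for this trial's noise stream.
#' @return List with `trial` (a [trial()]) and `truth` (prescribed per-frame
#'   angle waveforms, navicular height, and for sautes the plie frames and
#'   per-cycle excursions).
#' @export
generate_trial <- function(config, label, angle_jitter = NULL,
                           seed_offset = 0L) {
  if (!label %in% trial_labels())
    stop("input error: unknown trial label '", label, "'", call. = FALSE)
  geom <- synth_geometry(config$side)
  cond_of <- function(name) {
    v <- config$conditions[[name]]
    if (!is.null(angle_jitter)) v[names(angle_jitter)] <-
        v[names(angle_jitter)] + angle_jitter
    v
  }
  rate <- config$rate
  truth_extra <- list()
  if (label == "natural") {
    sch <- .const_schedule(config$static_frames, cond_of("natural"))
  } else if (label == "functional_turnout") {
    sch <- .const_schedule(config$static_frames, cond_of("functional"))
  } else if (label == "forced_turnout") {
    sch <- .const_schedule(config$static_frames, cond_of("forced"))
  } else if (label == "lunge") {
    sch <- .const_schedule(config$static_frames, cond_of("natural"),
                           knee_flex = 30, hip_flex = 30)
  } else if (label %in% c("seated_passive_er", "seated_active_er")) {
    er <- if (label == "seated_passive_er") config$knee_er_passive
          else config$knee_er_active
    sch <- .const_schedule(config$seated_frames, cond_of("natural"),
                           knee_flex = 80, knee_er = er, hip_flex = 80)
    truth_extra$knee_er <- er
  } else if (label == "squat_circumduction") {
    nf <- config$squat_frames
    n1 <- floor(0.6 * nf)
    u1 <- seq(0, 1, length.out = n1)
    u2 <- seq(0, 1, length.out = nf - n1)
    knee_flex <- c(60 * (1 - cos(2 * pi * 4 * u1)) / 2, rep(0, nf - n1))
    hip_flex <- c(40 * (1 - cos(2 * pi * 4 * u1)) / 2,
                  25 * sin(2 * pi * 3 * u2))
    hip_abd <- c(rep(0, n1), 25 * cos(2 * pi * 3 * u2) - 25)
    sch <- .const_schedule(nf, cond_of("natural"))
    sch$knee_flex <- knee_flex; sch$hip_flex <- hip_flex; sch$hip_abd <- hip_abd
  } else if (label == "saute") {
    freq <- config$tempo_bpm / 60
    nf <- ceiling(config$n_cycles / freq * rate)
    t <- (0:(nf - 1)) / rate
    mphase <- (1 - cos(2 * pi * freq * t)) / 2
    cyc <- pmin(config$n_cycles, floor(freq * t) + 1L)
    set.seed((config$seed + seed_offset + 77L) %% .Machine$integer.max)
    exc <- config$saute_excursion_mm *
      (1 + stats::rnorm(config$n_cycles, 0, config$saute_excursion_jitter))
    nat <- cond_of("natural"); peak <- cond_of("saute")
    wav <- function(key) nat[key] + (peak[key] - nat[key]) * mphase
    sch <- list(ev = wav("hindfoot_eversion"),
                footabd = wav("foot_abduction"),
                midabd = wav("midfoot_abduction"),
                foreabd = wav("forefoot_abduction"),
                mtpj = wav("mtpj_abduction"),
                navdrop = wav("navicular_drop"),
                knee_flex = rep(0, nf), knee_er = rep(0, nf),
                hip_flex = rep(0, nf), hip_abd = rep(0, nf),
                pelvis_dz = -exc[cyc] * mphase)
    truth_extra$plie_frames <-
      round((seq_len(config$n_cycles) - 0.5) / freq * rate) + 1L
    truth_extra$excursions <- exc
  } else stop("input error: unhandled label '", label, "'", call. = FALSE)

  fk <- .fk_markers(geom, sch, config$side)
  markers <- fk$markers
  calib_trial <- label %in% c("natural", "lunge")
  if (!calib_trial) {
    schema <- default_marker_schema(config$side)
    keep <- intersect(dimnames(markers)[[2]],
                      schema_required_markers(schema, calibration = FALSE))
    markers <- markers[, keep, , drop = FALSE]
  }
  set.seed((config$seed + seed_offset + 13L) %% .Machine$integer.max)
  if (config$sta_amplitude_mm > 0) {
    t <- (seq_len(dim(markers)[1]) - 1) / rate
    ph <- stats::runif(dim(markers)[2], 0, 2 * pi)
    for (m in seq_len(dim(markers)[2]))
      markers[, m, ] <- markers[, m, ] +
        config$sta_amplitude_mm * sin(2 * pi * 1.0 * t + ph[m])
  }
  if (config$noise_sd > 0)
    markers <- markers + stats::rnorm(length(markers), 0, config$noise_sd)

  tr <- trial(markers, dimnames(markers)[[2]], rate = rate, label = label,
              up_axis = "z", side = config$side)
  truth <- c(list(
    hindfoot_eversion = unname(sch$ev),
    midfoot_abduction = unname(sch$midabd),
    forefoot_abduction = unname(sch$foreabd),
    foot_abduction = unname(sch$footabd),
    mtpj_abduction = unname(sch$mtpj),
    navicular_drop = unname(sch$navdrop),
    navicular_height = unname(fk$truth_nav_height),
    knee_flexion = unname(sch$knee_flex)), truth_extra)
  list(trial = tr, truth = truth)
}

#' Generate a complete synthetic subject
#'
#' All trials of the emulated protocol: one natural-stance calibration trial,
#' three repeats each of functional and forced turnout (with small
#' between-repeat angle jitter), one 10-cycle saute, the lunge (knee joint
#' centre), the squat/circumduction functional calibration, and the two
#' seated external-rotation trials.
#'
#' @param config A [synth_config()].
#' @return List with `trials` (named; `functional_turnout` and
#'   `forced_turnout` are lists of 3) and `truths` (matching structure).
#' @export
generate_subject <- function(config) {
  one <- function(label, off = 0L, jit = NULL)
    generate_trial(config, label, angle_jitter = jit, seed_offset = off)
  set.seed((config$seed + 5L) %% .Machine$integer.max)
  jits <- lapply(1:6, function(i)
    stats::rnorm(5, 0, config$repeat_jitter_deg) |>
      stats::setNames(c("hindfoot_eversion", "midfoot_abduction",
                        "forefoot_abduction", "foot_abduction",
                        "mtpj_abduction")))
  res <- list(
    natural = one("natural", 1L),
    functional_turnout = lapply(1:3, function(r)
      one("functional_turnout", 100L + r, jits[[r]])),
    forced_turnout = lapply(1:3, function(r)
      one("forced_turnout", 200L + r, jits[[3 + r]])),
    saute = one("saute", 300L),
    lunge = one("lunge", 400L),
    squat_circumduction = one("squat_circumduction", 500L),
    seated_passive_er = one("seated_passive_er", 600L),
    seated_active_er = one("seated_active_er", 700L)
  )
  pick <- function(x, what) if (!is.null(x$trial)) x[[what]] else lapply(x, `[[`, what)
  list(trials = lapply(res, pick, "trial"),
       truths = lapply(res, pick, "truth"))
}

# ---------------------------------------------------------------------------
# cohort generation

#' Default cohort effect map
#'
#' Generative model for the emulated cohort: condition means = published
#' cohort means. Each subject carries two random effects per variable: a
#' postural trait (present in every condition, including natural stance) and
#' a turnout gain (how much the variable changes when the dancer assumes a
#' turnout condition; absent in natural stance). Whole-foot abduction is
#' coupled to the subject's hindfoot-eversion gain (slope sized for a
#' foot-abduction regression R^2 near 0.55) and seated external tibiofemoral
#' rotation is negatively coupled to the same gain (r near -0.6): dancers
#' with limited knee external rotation compensate through hindfoot
#' pronation. Within-subject (condition-by-subject) SDs sit on the published
#' F scale, smaller in the highly reproducible natural stance.
#'
#' @return List with `mu` (condition list), `sd_trait`, `sd_gain`,
#'   `sd_within`, `natural_within_factor`, `foot_beta`, `foot_resid_sd`,
#'   `foot_natural_sd`, `knee` (means/couplings/residual SDs).
#' @export
default_effect_map <- function() {
  list(mu = default_condition_offsets(),
       sd_trait = c(hindfoot_eversion = 1.5, midfoot_abduction = 4.5,
                    forefoot_abduction = 3.8, mtpj_abduction = 6.0,
                    navicular_drop = 0),
       sd_gain = c(hindfoot_eversion = 4.2, midfoot_abduction = 2.0,
                   forefoot_abduction = 1.2, mtpj_abduction = 1.5,
                   navicular_drop = 3.0),
       sd_within = c(hindfoot_eversion = 3.0, midfoot_abduction = 1.4,
                     forefoot_abduction = 1.1, mtpj_abduction = 2.6,
                     navicular_drop = 3.0, foot_abduction = 1.2),
       natural_within_factor = 0.4,
       foot_beta = 1.4, foot_resid_sd = 1.3, foot_natural_sd = 1.0,
       knee = list(mu_passive = 40, mu_active = 45,
                   g_passive = 1.44, g_active = 1.49,
                   resid_passive = 5.2, resid_active = 5.0))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject condition values around the effect map's generative
#' means (shared subject random effects induce the repeated-measures
#' correlation) and either returns the value table directly
#' (`values_only = TRUE`, for statistical simulation) or emits the full
#' marker trials per subject via [generate_subject()].
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param effect_map See [default_effect_map()].
#' @param seed Integer seed.
#' @param values_only If `TRUE`, skip marker synthesis and return the drawn
#'   per-subject condition values.
#' @param config_template A [synth_config()] supplying rate/tempo/noise for
#'   the full-marker mode.
#' @return List with `values` (data.frame subject, condition, variable,
#'   value), `knee` (data.frame subject, measurement, value), `truth`
#'   (generative means), and in full mode `subjects` (list of
#'   [generate_subject()] outputs).
#' @export
generate_cohort <- function(n_subjects = 18, effect_map = default_effect_map(),
                            seed = 1L, values_only = FALSE,
                            config_template = synth_config(noise_sd = 0.5)) {
  if (n_subjects < 2) stop("need n_subjects >= 2", call. = FALSE)
  em <- effect_map
  set.seed(seed %% .Machine$integer.max)
  vars <- names(em$sd_trait)
  conds <- condition_levels()
  values <- list(); knee <- list()
  subj_cfg <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    u_trait <- stats::rnorm(length(vars), 0, em$sd_trait)
    u_gain <- stats::rnorm(length(vars), 0, em$sd_gain)
    names(u_trait) <- names(u_gain) <- vars
    u_gain["navicular_drop"] <- max(u_gain["navicular_drop"], -3)
    g_hf <- u_gain["hindfoot_eversion"]
    u_foot <- em$foot_beta * g_hf + stats::rnorm(1, 0, em$foot_resid_sd)
    foot_trait <- stats::rnorm(1, 0, em$foot_natural_sd)
    per_cond <- lapply(conds, function(cn) {
      wf <- if (cn == "natural") em$natural_within_factor else 1
      mu <- em$mu[[cn]]
      w <- stats::rnorm(length(vars), 0, wf * em$sd_within[vars])
      names(w) <- vars
      v <- mu
      v[vars] <- mu[vars] + u_trait + w +
        if (cn == "natural") 0 else u_gain
      v["foot_abduction"] <- mu["foot_abduction"] + foot_trait +
        (if (cn == "natural") 0 else u_foot) +
        stats::rnorm(1, 0, wf * em$sd_within["foot_abduction"])
      if (cn == "natural") v["navicular_drop"] <- 0
      v
    })
    names(per_cond) <- conds
    kp <- em$knee$mu_passive - em$knee$g_passive * g_hf +
      stats::rnorm(1, 0, em$knee$resid_passive)
    ka <- em$knee$mu_active - em$knee$g_active * g_hf +
      stats::rnorm(1, 0, em$knee$resid_active)
    for (cn in conds)
      values[[length(values) + 1L]] <- data.frame(
        subject = s, condition = cn,
        variable = c(names(per_cond[[cn]])),
        value = unname(per_cond[[cn]]))
    knee[[length(knee) + 1L]] <- data.frame(
      subject = s, measurement = c("passive", "active"),
      value = c(kp, ka))
    if (!values_only) {
      cfg <- config_template
      cfg$seed <- (seed + 10000L * s) %% .Machine$integer.max
      cfg$conditions <- per_cond
      cfg$knee_er_passive <- kp
      cfg$knee_er_active <- ka
      subj_cfg[[s]] <- cfg
    }
  }
  out <- list(values = do.call(rbind, values), knee = do.call(rbind, knee),
              truth = em)
  if (!values_only)
    out$subjects <- lapply(subj_cfg, generate_subject)
  out
}
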